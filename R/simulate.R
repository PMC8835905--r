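# Seeded synthetic small RNA-seq libraries with known ground truth.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic library generator. Defaults
#' describe a plasma-like library sequenced on a 75 nt single-read machine:
#' log-normal endogenous abundances spanning roughly five decades (so the
#' panel's 0.005-50 amol ladder brackets most features), a moderate
#' multiplicative ligation-efficiency bias per miRNA, and a capture slope
#' of 1000 reads per attomole.
#'
#' @param n_mirnas Number of endogenous miRNAs to simulate (default 600,
#'   typical of the distinct miRNAs detectable in plasma).
#' @param abundance_log10_mean,abundance_log10_sd Mean and sd of the
#'   per-miRNA true amount on the log10 attomole scale (defaults -0.5, 1.0).
#' @param bias_log10_sd Sd of the per-miRNA log10 ligation-efficiency bias
#'   factor, centred at 1 (default 0.5; 0 disables bias).
#' @param capture_beta True calibration slope in reads per attomole
#'   (default 1000); used directly by the `"poisson"` and `"none"` noise
#'   modes, and implied by `depth` in `"multinomial"` mode.
#' @param depth Total reads in `"multinomial"` mode (default 1e6).
#' @param adapter 3' adapter appended to every insert (default the Illumina
#'   small-RNA adapter `TGGAATTCTCGGGTGCCAAGG`).
#' @param read_len Machine read length; inserts plus adapter are padded /
#'   truncated to this length (default 75).
#' @param read_qchar Constant Phred quality character (default `"I"`, Q40).
#' @param equimolar If TRUE, all endogenous amounts equal `equimolar_amol`
#'   (emulating an equimolar synthetic reference pool).
#' @param equimolar_amol Amount used in equimolar mode (default 1 amol).
#' @param noise `"multinomial"` (counts drawn at exactly `depth` reads),
#'   `"poisson"` (independent Poisson counts at `capture_beta * amount *
#'   bias`), or `"none"` (counts are the rounded Poisson means; with
#'   integer-valued means the calibration chain is exact).
#' @param seed Integer seed; all outputs are deterministic given the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mirnas = 600L,
                       abundance_log10_mean = -0.5,
                       abundance_log10_sd = 1.0,
                       bias_log10_sd = 0.5,
                       capture_beta = 1000,
                       depth = 1e6,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_len = 75L,
                       read_qchar = "I",
                       equimolar = FALSE,
                       equimolar_amol = 1,
                       noise = c("multinomial", "poisson", "none"),
                       seed = 1L) {
  noise <- match.arg(noise)
  stopifnot_scalar_number(n_mirnas, "n_mirnas", min = 1)
  stopifnot_scalar_number(depth, "depth", min = 1)
  stopifnot_scalar_number(capture_beta, "capture_beta", min = 0,
                          allow_zero = FALSE)
  stopifnot_scalar_number(bias_log10_sd, "bias_log10_sd", min = 0)
  stopifnot_scalar_number(abundance_log10_sd, "abundance_log10_sd", min = 0)
  if (!nzchar(adapter)) stop("'adapter' must be non-empty", call. = FALSE)
  structure(list(
    n_mirnas = as.integer(n_mirnas),
    abundance_log10_mean = abundance_log10_mean,
    abundance_log10_sd = abundance_log10_sd,
    bias_log10_sd = bias_log10_sd,
    capture_beta = capture_beta,
    depth = depth,
    adapter = toupper(adapter),
    read_len = as.integer(read_len),
    read_qchar = read_qchar,
    equimolar = isTRUE(equimolar),
    equimolar_amol = equimolar_amol,
    noise = noise,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate random mature miRNA reference sequences
#'
#' Synthetic stand-ins for a mature reference catalogue: random RNA
#' sequences of miRNA-typical length (17-25 nt), uniquely named.
#'
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @param len_range Length range in nt (default `c(17, 25)`).
#' @param path Optional FASTA output path.
#' @return Named character vector of RNA sequences.
#' @export
simulate_mature_refs <- function(n, seed = 1L, len_range = c(17L, 25L),
                                 path = NULL) {
  stopifnot_scalar_number(n, "n", min = 1)
  seqs <- with_seed(seed, {
    lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("sim-miR-%04d", seq_len(n))
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
  }
  seqs
}

#' Read mature miRNA reference sequences from FASTA
#'
#' Accepts RNA or DNA alphabet; sequences are normalised to RNA.
#'
#' @param path FASTA path.
#' @return Named character vector of RNA sequences.
#' @export
read_mature_refs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- dna_to_rna(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(out))) {
    stop("duplicate mature miRNA names in ", path, call. = FALSE)
  }
  out
}

# Uniform random flank strings of length `len` (DNA alphabet), one per read.
random_flanks <- function(n, len) {
  if (n == 0L) return(character(0))
  chars <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
  do.call(paste0, as.data.frame(matrix(chars, nrow = n), optional = TRUE))
}

#' Simulate a spiked small RNA-seq library
#'
#' Draws per-feature read counts with expected share proportional to
#' `amount * bias` (bias fixed at 1 for spike-ins), then materialises reads:
#' an endogenous read is the mature sequence, a spike-in read is
#' `flank + core + flank` with independent uniform random flanks per read;
#' every insert gets the 3' adapter appended and is padded with `A` (or
#' truncated) to the machine read length.
#'
#' @param config A [sim_config()].
#' @param panel A [build_panel()] spike-in panel.
#' @param mirna_refs Named character vector of mature sequences (RNA or
#'   DNA), or a FASTA path.
#' @param amounts Optional named numeric vector overriding the endogenous
#'   amounts (amol) drawn from the configuration; names must be reference
#'   names. Used by [simulate_dilution_series()].
#' @param bias Optional named numeric vector of bias factors to reuse
#'   across libraries (e.g. along a dilution series).
#' @param fastq Optional path; when given the reads are written as FASTQ
#'   via [Biostrings::writeXStringSet()].
#' @param return_reads If TRUE the read table (`id`, `seq`, `qual`) is kept
#'   in the returned object; defaults to TRUE when `fastq` is NULL and
#'   reads are cheap to keep, but can be switched off for count-level work
#'   at high depth.
#'
#' @return An object of class `mind_sim`: list with `truth` (data frame
#'   `feature`, `class`, `amount_amol`, `bias`, `expected_count`, `count`),
#'   `capture_beta` (the true slope in reads/amol implied by the realised
#'   library), `config`, `panel`, and optionally `reads` and `fastq`.
#' @export
simulate_library <- function(config, panel, mirna_refs,
                             amounts = NULL, bias = NULL,
                             fastq = NULL, return_reads = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "spike_panel"))
  if (is.character(mirna_refs) && length(mirna_refs) == 1L &&
      file.exists(mirna_refs)) {
    mirna_refs <- read_mature_refs(mirna_refs)
  }
  mirna_refs <- dna_to_rna(mirna_refs)
  if (nrow(panel) == 0L) stop("empty spike-in panel", call. = FALSE)
  if (length(mirna_refs) < config$n_mirnas) {
    stop("mirna_refs provides fewer sequences than n_mirnas", call. = FALSE)
  }
  refs <- mirna_refs[seq_len(config$n_mirnas)]
  if (any(nchar(refs) < 17L)) {
    stop("mature reference sequences must be at least 17 nt", call. = FALSE)
  }

  with_seed(config$seed, {
    # endogenous truth
    if (!is.null(amounts)) {
      if (!all(names(refs) %in% names(amounts))) {
        stop("'amounts' must name every simulated miRNA", call. = FALSE)
      }
      amt <- unname(amounts[names(refs)])
    } else if (config$equimolar) {
      amt <- rep(config$equimolar_amol, length(refs))
    } else {
      amt <- 10^stats::rnorm(length(refs), config$abundance_log10_mean,
                             config$abundance_log10_sd)
    }
    if (is.null(bias)) {
      bias <- if (config$bias_log10_sd > 0) {
        10^stats::rnorm(length(refs), 0, config$bias_log10_sd)
      } else {
        rep(1, length(refs))
      }
      names(bias) <- names(refs)
    } else {
      if (!all(names(refs) %in% names(bias))) {
        stop("'bias' must name every simulated miRNA", call. = FALSE)
      }
      bias <- bias[names(refs)]
    }
    truth <- data.frame(
      feature = c(panel$label, names(refs)),
      class = rep(c("spike", "mirna"), c(nrow(panel), length(refs))),
      amount_amol = c(panel$amount_amol, amt),
      bias = c(rep(1, nrow(panel)), unname(bias)),
      stringsAsFactors = FALSE
    )
    weight <- truth$amount_amol * truth$bias
    if (config$noise == "multinomial") {
      truth$expected_count <- config$depth * weight / sum(weight)
      truth$count <- as.integer(stats::rmultinom(1, config$depth,
                                                 weight / sum(weight)))
      beta_true <- config$depth / sum(weight)
    } else {
      mu <- config$capture_beta * weight
      truth$expected_count <- mu
      truth$count <- if (config$noise == "poisson") {
        stats::rpois(length(mu), mu)
      } else {
        as.integer(round(mu))
      }
      beta_true <- config$capture_beta
    }

    out <- structure(list(truth = truth, capture_beta = beta_true,
                          config = config, panel = panel,
                          refs = refs),
                     class = "mind_sim")

    if (!is.null(fastq) || isTRUE(return_reads)) {
      is_spike <- truth$class == "spike"
      core_dna <- rna_to_dna(panel$core)
      n_spike_reads <- truth$count[is_spike]
      spike_inserts <- paste0(
        random_flanks(sum(n_spike_reads), panel$flank_len[1]),
        rep(core_dna, n_spike_reads),
        random_flanks(sum(n_spike_reads), panel$flank_len[1])
      )
      mirna_inserts <- rep(rna_to_dna(unname(refs)), truth$count[!is_spike])
      inserts <- c(spike_inserts, mirna_inserts)
      full <- paste0(inserts, config$adapter,
                     strrep("A", config$read_len))
      reads <- data.frame(
        id = sprintf("sim_%07d", seq_along(full)),
        seq = substr(full, 1L, config$read_len),
        qual = strrep(config$read_qchar, config$read_len),
        stringsAsFactors = FALSE
      )
      if (!is.null(fastq)) {
        write_fastq(reads, fastq)
        out$fastq <- fastq
      }
      if (isTRUE(return_reads)) out$reads <- reads
    }
    out
  })
}

#' @export
print.mind_sim <- function(x, ...) {
  tab <- x$truth
  cat(sprintf(paste0("Simulated library: %d features (%d spike-in, %d",
                     " miRNA), %s reads\n"),
              nrow(tab), sum(tab$class == "spike"),
              sum(tab$class == "mirna"),
              format(sum(tab$count), big.mark = ",")))
  cat(sprintf("True capture slope: %.4g reads/amol; noise: %s; seed: %d\n",
              x$capture_beta, x$config$noise, x$config$seed))
  invisible(x)
}

# Write a read table (id, seq, qual) as 4-line FASTQ.
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$id
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Simulate a two-pool dilution series
#'
#' Mixes two endogenous truth profiles A and B at each fraction `p` of A
#' (per-feature mixed amount `p * A + (1 - p) * B`) and simulates one
#' library per fraction. Bias factors are drawn once and shared across the
#' series, as a single protocol run would.
#'
#' @param poolA_truth,poolB_truth Named numeric vectors of per-feature true
#'   amounts (amol) over the same feature universe.
#' @param fractions Numeric vector of mixing fractions of pool A in [0, 1].
#' @param config A [sim_config()]; per-library seeds are derived from
#'   `config$seed`.
#' @inheritParams simulate_library
#' @return List of `mind_sim` objects, one per fraction, each carrying a
#'   `fraction` element and the `mixed_truth` amounts.
#' @export
simulate_dilution_series <- function(poolA_truth, poolB_truth, fractions,
                                     config, panel, mirna_refs,
                                     return_reads = FALSE) {
  if (!setequal(names(poolA_truth), names(poolB_truth))) {
    stop("pool A and pool B must share the same feature set", call. = FALSE)
  }
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  poolB_truth <- poolB_truth[names(poolA_truth)]
  bias <- with_seed(config$seed, {
    b <- if (config$bias_log10_sd > 0) {
      10^stats::rnorm(length(poolA_truth), 0, config$bias_log10_sd)
    } else {
      rep(1, length(poolA_truth))
    }
    names(b) <- names(poolA_truth)
    b
  })
  child_seeds <- with_seed(config$seed, sample.int(2^31 - 2, length(fractions)))
  lapply(seq_along(fractions), function(i) {
    p <- fractions[i]
    mixed <- p * poolA_truth + (1 - p) * poolB_truth
    cfg <- config
    cfg$seed <- child_seeds[i]
    sim <- simulate_library(cfg, panel, mirna_refs, amounts = mixed,
                            bias = bias, return_reads = return_reads)
    sim$fraction <- p
    sim$mixed_truth <- mixed
    sim
  })
}
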