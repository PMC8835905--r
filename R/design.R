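# Spike-in panel design: candidate generation, genome screening, selection.

#' Generate candidate spike-in core sequences
#'
#' Draws `n` distinct random RNA k-mers subject to composition constraints.
#' The constraints keep candidates miRNA-like and synthesizable: a GC
#' fraction window and a cap on homopolymer runs.
#'
#' @param n Number of distinct candidates to generate.
#' @param core_len Core length in nucleotides (default 13).
#' @param seed Integer seed; the same `(n, core_len, seed, constraints)`
#'   always yields the same candidate list.
#' @param constraints List with elements `gc` (length-2 numeric, allowed GC
#'   fraction range, default `c(0.40, 0.60)`) and `max_run` (maximum
#'   homopolymer run length, default 3). Use `NULL` entries to disable a
#'   constraint.
#' @param max_tries Retry budget; generation aborts if `n` distinct
#'   constraint-satisfying sequences cannot be found within
#'   `max_tries * n` draws (a sign the constrained space is too small).
#'
#' @return A data frame of class `core_candidates` with columns `sequence`
#'   (RNA), `gc_fraction`, and `hit_count` (`NA` until screened).
#' @examples
#' head(generate_candidates(10, seed = 1))
#' @export
generate_candidates <- function(n, core_len = 13L, seed = 1L,
                                constraints = list(gc = c(0.40, 0.60),
                                                   max_run = 3L),
                                max_tries = 1000L) {
  stopifnot_scalar_number(n, "n", min = 1)
  stopifnot_scalar_number(core_len, "core_len", min = 1)
  gc_range <- constraints$gc
  max_run <- constraints$max_run
  alphabet <- c("A", "C", "G", "U")
  ok <- function(seqs) {
    keep <- rep(TRUE, length(seqs))
    if (!is.null(gc_range)) {
      gc <- gc_fraction(seqs)
      keep <- keep & gc >= gc_range[1] & gc <= gc_range[2]
    }
    if (!is.null(max_run)) {
      keep <- keep & max_homopolymer_run(seqs) <= max_run
    }
    keep
  }
  seqs <- with_seed(seed, {
    found <- character(0)
    tries <- 0L
    batch <- max(n, 64L)
    while (length(found) < n) {
      if (tries >= max_tries * n) {
        stop(sprintf(paste("could not generate %d distinct candidates of",
                           "length %d under the constraints within the",
                           "retry budget"), n, core_len), call. = FALSE)
      }
      draw <- vapply(seq_len(batch), function(i) {
        paste(sample(alphabet, core_len, replace = TRUE), collapse = "")
      }, character(1))
      tries <- tries + batch
      draw <- draw[ok(draw)]
      found <- unique(c(found, draw))
    }
    found[seq_len(n)]
  })
  out <- data.frame(sequence = seqs, gc_fraction = gc_fraction(seqs),
                    hit_count = NA_integer_, stringsAsFactors = FALSE)
  class(out) <- c("core_candidates", "data.frame")
  out
}

#' Read a reference sequence set from FASTA
#'
#' @param path FASTA file of DNA reference sequences (genomes, contigs).
#' @return Named character vector of upper-case DNA sequences.
#' @export
read_reference_set <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  if (length(out) == 0L) stop("reference FASTA is empty", call. = FALSE)
  if (anyDuplicated(names(out))) {
    stop("duplicate reference record names", call. = FALSE)
  }
  out
}

#' Count mismatch-tolerant genomic occurrences of a core sequence
#'
#' Transcribes the RNA core to DNA (U to T) and counts all windows across
#' the reference records whose Hamming distance to the core is at most
#' `max_mismatch`. With `both_strands = TRUE` (the default) windows on the
#' reverse complement are counted too: a core present on either strand
#' would compromise the exogeneity of the spike-in. Overlapping windows are
#' all counted; reference positions containing `N` never match.
#'
#' @param core RNA (or DNA) core sequence.
#' @param refs Named character vector of DNA references, as returned by
#'   [read_reference_set()], or a `Biostrings::DNAStringSet`.
#' @param max_mismatch Maximum Hamming distance (default 1).
#' @param both_strands Scan the reverse complement as well (default TRUE).
#' @return Total window count across all records (and strands).
#' @examples
#' refs <- c(chr = "ACGATCGGCTCTAAAAT")
#' count_reference_hits("ACGAUCGGCUCUA", refs, max_mismatch = 0)
#' @export
count_reference_hits <- function(core, refs, max_mismatch = 1L,
                                 both_strands = TRUE) {
  if (length(refs) == 0L) stop("empty reference set", call. = FALSE)
  stopifnot_scalar_number(max_mismatch, "max_mismatch", min = 0)
  core_dna <- rna_to_dna(core)
  if (!grepl("^[ACGT]+$", core_dna)) {
    stop("core must be an unambiguous RNA/DNA sequence", call. = FALSE)
  }
  subj <- if (inherits(refs, "DNAStringSet")) refs else {
    Biostrings::DNAStringSet(unname(toupper(refs)))
  }
  usable <- Biostrings::width(subj) >= nchar(core_dna)
  if (!any(usable)) return(0L)
  subj <- subj[usable]
  pat <- Biostrings::DNAString(core_dna)
  hits <- sum(Biostrings::vcountPattern(pat, subj,
                                        max.mismatch = max_mismatch,
                                        with.indels = FALSE, fixed = TRUE))
  if (isTRUE(both_strands)) {
    hits <- hits + sum(Biostrings::vcountPattern(
      Biostrings::reverseComplement(pat), subj,
      max.mismatch = max_mismatch, with.indels = FALSE, fixed = TRUE))
  }
  as.integer(hits)
}

#' Screen candidates against reference sequence sets
#'
#' Fills the `hit_count` column of a candidate table with
#' [count_reference_hits()] totals.
#'
#' @param candidates A `core_candidates` data frame.
#' @inheritParams count_reference_hits
#' @return The candidate table with `hit_count` filled.
#' @export
screen_candidates <- function(candidates, refs, max_mismatch = 1L,
                              both_strands = TRUE) {
  stopifnot(is.data.frame(candidates), "sequence" %in% names(candidates))
  candidates$hit_count <- vapply(candidates$sequence, function(s) {
    count_reference_hits(s, refs, max_mismatch = max_mismatch,
                         both_strands = both_strands)
  }, integer(1), USE.NAMES = FALSE)
  candidates
}

# Hamming distance between two equal-length sequence strings.
hamming_dist <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Select minimal-overlap cores from screened candidates
#'
#' Greedily picks `k` cores with the lowest reference `hit_count`. Ties on
#' hit count are broken by the greater minimum pairwise Hamming distance to
#' the cores already selected (preferring mutually dissimilar cores, which
#' minimises classification cross-talk), and remaining ties
#' lexicographically, so the output is deterministic and invariant under
#' permutation of the input.
#'
#' @param candidates A screened `core_candidates` table (`hit_count` set).
#' @param k Number of cores to select.
#' @return The selected rows, in selection order.
#' @export
select_cores <- function(candidates, k) {
  stopifnot(is.data.frame(candidates),
            all(c("sequence", "hit_count") %in% names(candidates)))
  if (any(is.na(candidates$hit_count))) {
    stop("candidates must be screened before selection (hit_count missing)",
         call. = FALSE)
  }
  if (k > nrow(candidates)) {
    stop("'k' exceeds the number of candidates", call. = FALSE)
  }
  # canonical order removes any dependence on input permutation
  cand <- candidates[order(candidates$sequence), , drop = FALSE]
  chosen <- integer(0)
  for (i in seq_len(k)) {
    remaining <- setdiff(seq_len(nrow(cand)), chosen)
    hc <- cand$hit_count[remaining]
    pool <- remaining[hc == min(hc)]
    if (length(pool) > 1L && length(chosen) > 0L) {
      min_d <- vapply(pool, function(j) {
        min(vapply(chosen, function(c0) {
          hamming_dist(cand$sequence[j], cand$sequence[c0])
        }, numeric(1)))
      }, numeric(1))
      pool <- pool[min_d == max(min_d)]
    }
    # pool is in lexicographic order already; take the smallest
    chosen <- c(chosen, pool[1])
  }
  out <- cand[chosen, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design a spike-in panel end to end
#'
#' Convenience wrapper: generate candidates, screen them against the
#' references, select the `k` lowest-overlap cores and assemble a panel at
#' the given amounts.
#'
#' @inheritParams generate_candidates
#' @inheritParams count_reference_hits
#' @param k Number of cores in the final panel.
#' @param amounts_amol Amounts for the selected oligos (recycled from the
#'   default seven-oligo ladder when `k = 7`).
#' @param flank_len Randomized flank length per side.
#' @return A `spike_panel`.
#' @export
design_panel <- function(refs, n = 227L, core_len = 13L, k = 7L,
                         max_mismatch = 1L, seed = 1L,
                         amounts_amol = NULL, flank_len = 4L,
                         constraints = list(gc = c(0.40, 0.60),
                                            max_run = 3L)) {
  cand <- generate_candidates(n, core_len = core_len, seed = seed,
                              constraints = constraints)
  cand <- screen_candidates(cand, refs, max_mismatch = max_mismatch)
  sel <- select_cores(cand, k)
  if (is.null(amounts_amol)) {
    amounts_amol <- if (k == 7L) {
      c(50, 10, 2.5, 1.5, 0.1, 0.01, 0.005)
    } else {
      50 / 10^(seq_len(k) - 1)
    }
  }
  build_panel(sel$sequence, amounts_amol,
              labels = make.unique(LETTERS[seq_len(k)]),
              flank_len = flank_len)
}
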