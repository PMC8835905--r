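# End-to-end orchestration: config validation, staged runs, manifests.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L,
    params = list()
  )
  p_defaults <- list(adapter = "TGGAATTCTCGGGTGCCAAGG", min_len = 17L,
                     max_len = 30L, min_q = 20L, max_mismatch = 1L,
                     len_tol = 2L, rpm_denominator = "mirna_mapped")
  config <- utils::modifyList(defaults, config)
  config$params <- utils::modifyList(p_defaults, config$params)
  config
}

read_sample_sheet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "fastq", "rna_input_ul", "elution_ul",
            "biofluid_ul")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

# Light FASTQ well-formedness check (first `n_records` records); returns a
# character vector of problems, empty when clean.
check_fastq_format <- function(path, n_records = 100L) {
  lines <- tryCatch(readLines(path, n = 4L * n_records),
                    error = function(e) conditionMessage(e))
  if (!is.character(lines) || length(lines) == 0L) {
    return(sprintf("'%s': unreadable or empty", path))
  }
  probs <- character(0)
  n_full <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L && length(lines) < 4L * n_records) {
    probs <- c(probs, sprintf("'%s': truncated record at end of file", path))
  }
  for (i in seq_len(n_full)) {
    id <- lines[4L * i - 3L]
    sq <- lines[4L * i - 2L]
    pl <- lines[4L * i - 1L]
    qu <- lines[4L * i]
    if (!startsWith(id, "@")) {
      probs <- c(probs, sprintf("'%s' record %d: header does not start with @",
                                path, i))
    } else if (!startsWith(pl, "+")) {
      probs <- c(probs, sprintf("'%s' record %s: separator line missing",
                                path, sub("^@", "", id)))
    } else if (nchar(sq) != nchar(qu)) {
      probs <- c(probs,
                 sprintf("'%s' record %s: sequence and quality lengths differ",
                         path, sub("^@", "", id)))
    }
    if (length(probs) >= 5L) break
  }
  probs
}

#' Validate pipeline inputs
#'
#' Checks the run configuration without computing anything: referenced
#' paths exist, the panel sheet parses and satisfies its invariants, the
#' mature reference FASTA is readable, FASTQ files are well formed (first
#' records), and sample volumes are positive. Problems are returned as
#' diagnostics rather than raised, so callers can report all of them.
#'
#' @param config Run configuration: a YAML path or a list with elements
#'   `panel`, `mirna_refs`, `samples` (sample sheet TSV with columns
#'   `sample_id`, `fastq`, `rna_input_ul`, `elution_ul`, `biofluid_ul`),
#'   `outdir`, optional `seed` and `params`.
#' @return Data frame of diagnostics with columns `level` (`"error"`),
#'   `check`, `message`; zero rows when everything is well formed.
#' @export
validate_inputs <- function(config) {
  config <- read_run_config(config)
  diags <- list()
  add <- function(check, message) {
    diags[[length(diags) + 1L]] <<- data.frame(
      level = "error", check = check, message = message,
      stringsAsFactors = FALSE)
  }
  for (key in c("panel", "mirna_refs", "samples")) {
    if (is.null(config[[key]])) {
      add("config", sprintf("missing required path '%s'", key))
    } else if (!file.exists(config[[key]])) {
      add("config", sprintf("%s file not found: %s", key, config[[key]]))
    }
  }
  if (!is.null(config$panel) && file.exists(config$panel)) {
    p <- tryCatch(read_panel(config$panel), error = function(e) e)
    if (inherits(p, "error")) add("panel", conditionMessage(p))
  }
  if (!is.null(config$mirna_refs) && file.exists(config$mirna_refs)) {
    r <- tryCatch(read_mature_refs(config$mirna_refs),
                  error = function(e) e)
    if (inherits(r, "error")) {
      add("mirna_refs", conditionMessage(r))
    } else if (length(r) == 0L) {
      add("mirna_refs", "mature reference FASTA is empty")
    }
  }
  if (!is.null(config$samples) && file.exists(config$samples)) {
    sheet <- tryCatch(read_sample_sheet(config$samples),
                      error = function(e) e)
    if (inherits(sheet, "error")) {
      add("samples", conditionMessage(sheet))
    } else {
      if (anyDuplicated(sheet$sample_id)) {
        add("samples", sprintf("duplicate sample id '%s'",
                               sheet$sample_id[duplicated(sheet$sample_id)][1]))
      }
      for (i in seq_len(nrow(sheet))) {
        if (!file.exists(sheet$fastq[i])) {
          add("samples", sprintf("sample '%s': FASTQ not found: %s",
                                 sheet$sample_id[i], sheet$fastq[i]))
        } else {
          for (pr in check_fastq_format(sheet$fastq[i])) add("fastq", pr)
        }
        vols <- unlist(sheet[i, c("rna_input_ul", "elution_ul",
                                  "biofluid_ul")])
        if (any(!is.finite(vols)) || any(vols <= 0)) {
          add("samples", sprintf("sample '%s': volumes must be positive",
                                 sheet$sample_id[i]))
        }
      }
    }
  }
  if (length(diags)) do.call(rbind, diags) else
    data.frame(level = character(0), check = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  df <- data.frame(feature = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(stage, sample = NULL, expr) {
  tryCatch(expr, error = function(e) {
    where <- if (is.null(sample)) stage else paste0(stage, " [", sample, "]")
    stop(sprintf("pipeline stage '%s' failed: %s", where,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full quantify-calibrate-QC pipeline
#'
#' Validates the configuration, then executes the stages in order:
#' quantification (trimming, filtering, classification into the count
#' matrix), per-sample spike-in calibration, abundance conversion (RPM,
#' amol, molecules per uL of RNA and of biofluid), and QC (calibration
#' summary, analytical measurement range, and, with at least two samples
#' treated as replicates, CV repeatability and detection inconsistency).
#' All outputs are plain TSV/JSON under `outdir`, listed in a manifest
#' with input/output MD5 hashes, the parameters and the seed; a rerun with
#' an identical configuration reproduces identical outputs (the timestamp
#' is isolated in its own manifest field).
#'
#' @inheritParams validate_inputs
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  diags <- validate_inputs(config)
  if (nrow(diags)) {
    stop("invalid inputs:\n", paste0("  - ", diags$message, collapse = "\n"),
         call. = FALSE)
  }
  if (is.null(config$outdir)) stop("config must set 'outdir'", call. = FALSE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  seed <- as.integer(config$seed)
  # one documented fan-out: stage i uses child_seeds[i]
  child_seeds <- with_seed(seed, sample.int(2^31 - 2, 4L))

  panel <- read_panel(config$panel)
  refs <- read_mature_refs(config$mirna_refs)
  sheet <- read_sample_sheet(config$samples)

  # --- stage 1: quantify ---
  samples <- stats::setNames(as.list(sheet$fastq), sheet$sample_id)
  counts <- run_stage("quantify", NULL, count_samples(
    samples, panel, refs, adapter = p$adapter, min_len = p$min_len,
    max_len = p$max_len, min_q = p$min_q, max_mismatch = p$max_mismatch,
    len_tol = p$len_tol))

  # --- stage 2: calibrate ---
  fits <- lapply(sheet$sample_id, function(s) {
    run_stage("calibrate", s,
              fit_calibration(counts$counts[panel$label, s], panel))
  })
  names(fits) <- sheet$sample_id
  rpm <- run_stage("calibrate", NULL,
                   rpm_normalize(counts, panel,
                                 denominator = p$rpm_denominator))
  amol <- run_stage("calibrate", NULL, to_amol(counts, fits, panel))
  volumes <- lapply(seq_len(nrow(sheet)), function(i) {
    sample_volumes(sheet$rna_input_ul[i], sheet$elution_ul[i],
                   sheet$biofluid_ul[i])
  })
  names(volumes) <- sheet$sample_id
  mol_rna <- to_molecules_per_ul(amol, volumes, target = "rna")
  mol_bio <- to_molecules_per_ul(amol, volumes, target = "biofluid")

  # --- stage 3: qc ---
  mirna_rows <- names(counts$feature_class)[counts$feature_class == "mirna"]
  lo_label <- panel$label[which.min(panel$amount_amol)]
  hi_label <- panel$label[which.max(panel$amount_amol)]
  qc <- list(
    calibration = lapply(fits, function(f) {
      list(beta = f$beta, r_log = f$r_log, r_linear = f$r_linear,
           n_points = f$n_points)
    }),
    measurement_range = tryCatch({
      mr <- measurement_range(rpm[mirna_rows, , drop = FALSE],
                              rpm[lo_label, ], rpm[hi_label, ])
      list(pct_within = as.list(mr$pct_within), mean_pct = mr$mean_pct)
    }, error = function(e) list(error = conditionMessage(e))),
    seed_fanout = list(quantify = child_seeds[1], calibrate = child_seeds[2],
                       qc = child_seeds[3], subsample = child_seeds[4])
  )
  if (ncol(counts$counts) >= 2L) {
    cvr <- run_stage("qc", NULL,
                     cv_report(amol[mirna_rows, , drop = FALSE]))
    qc$cv <- list(frac_below = cvr$frac_below,
                  threshold_pct = cvr$threshold_pct, n_used = cvr$n_used)
    qc$inconsistency_pct <- run_stage("qc", NULL,
      inconsistency_pct(counts$counts[mirna_rows, , drop = FALSE]))
  }

  # --- outputs ---
  out <- list(
    counts = write_tsv(counts$counts, file.path(config$outdir, "counts.tsv")),
    rpm = write_tsv(rpm, file.path(config$outdir, "rpm.tsv")),
    amol = write_tsv(amol, file.path(config$outdir, "amol.tsv")),
    molecules_per_ul_rna =
      write_tsv(mol_rna, file.path(config$outdir,
                                   "molecules_per_ul_rna.tsv")),
    molecules_per_ul_biofluid =
      write_tsv(mol_bio, file.path(config$outdir,
                                   "molecules_per_ul_biofluid.tsv")),
    sample_stats = {
      f <- file.path(config$outdir, "sample_stats.tsv")
      utils::write.table(counts$stats, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f
    },
    qc_summary = {
      f <- file.path(config$outdir, "qc_summary.json")
      jsonlite::write_json(qc, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      f
    }
  )

  inputs <- c(panel = config$panel, mirna_refs = config$mirna_refs,
              samples = config$samples,
              stats::setNames(sheet$fastq, paste0("fastq_", sheet$sample_id)))
  manifest <- list(
    seed = seed,
    params = p,
    inputs = lapply(inputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    outputs = lapply(out, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
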