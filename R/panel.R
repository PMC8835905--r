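#' Spike-in panel objects
#'
#' A spike-in panel is an ordered set of exogenous RNA oligonucleotides.
#' Each oligo consists of a fixed core sequence (the identity segment used
#' for read classification) flanked on both sides by `flank_len` randomized
#' nucleotides, and is added to every library at a known molar amount in
#' attomoles. The known amounts are the independent variable of the
#' calibration model fitted by [fit_calibration()].
#'
#' @param cores Character vector of core sequences, 5'-3' RNA (`ACGU`).
#'   A DNA alphabet (`ACGT`) is accepted and normalised to RNA.
#' @param amounts_amol Positive numeric vector, attomoles of each oligo per
#'   library.
#' @param labels Character vector of unique oligo labels. Defaults to
#'   `LETTERS` prefixes when missing.
#' @param flank_len Number of randomized nucleotides on each side of the
#'   core (default 4, giving `4^(2*4) = 65536` distinct oligos per core).
#'
#' @return An object of class `spike_panel`: a data frame with columns
#'   `label`, `core` (RNA), `flank_len`, `amount_amol`.
#'
#' @examples
#' p <- build_panel(c("ACGAUCGGCUCUA", "UGAACGUCCGUAC"), c(50, 10))
#' p
#' @seealso [mind_panel()] for the default seven-oligo panel,
#'   [write_panel()] and [read_panel()] for the sheet format.
#' @export
build_panel <- function(cores, amounts_amol, labels = NULL, flank_len = 4L) {
  cores <- dna_to_rna(cores)
  if (is.null(labels)) labels <- make.unique(LETTERS[seq_along(cores)])
  n <- length(cores)
  if (length(amounts_amol) != n || length(labels) != n) {
    stop("'cores', 'amounts_amol' and 'labels' must have equal length",
         call. = FALSE)
  }
  if (n < 1L) stop("panel must contain at least one oligo", call. = FALSE)
  if (anyDuplicated(labels)) stop("duplicate oligo labels", call. = FALSE)
  if (anyDuplicated(cores)) stop("duplicate core sequences", call. = FALSE)
  if (any(!grepl("^[ACGU]+$", cores))) {
    stop("core sequences must be RNA over the alphabet ACGU", call. = FALSE)
  }
  if (length(unique(nchar(cores))) != 1L) {
    stop("all cores must have the same length", call. = FALSE)
  }
  if (!is.numeric(amounts_amol) || any(is.na(amounts_amol)) ||
      any(amounts_amol <= 0)) {
    stop("all amounts must be positive", call. = FALSE)
  }
  stopifnot_scalar_number(flank_len, "flank_len", min = 0)
  out <- data.frame(
    label = as.character(labels),
    core = cores,
    flank_len = as.integer(flank_len),
    amount_amol = as.numeric(amounts_amol),
    stringsAsFactors = FALSE
  )
  class(out) <- c("spike_panel", "data.frame")
  out
}

#' Default seven-oligo spike-in panel
#'
#' The reference panel of seven 13-nt cores, each flanked by four randomized
#' nucleotides, mixed at amounts spanning 0.005-50 amol to bracket the
#' dynamic range of circulating miRNAs in plasma.
#'
#' @return A [build_panel()] object with oligos I, K, M, N, H, C, E.
#' @examples
#' mind_panel()
#' @export
mind_panel <- function() {
  build_panel(
    cores = c("ACGAUCGGCUCUA", "UGAACGUCCGUAC", "UCUCGCGCGCGUU",
              "CGAGUAAUGAACG", "GCUACACACGUCG", "UAUUCGCGGUGAC",
              "ACCUCCGUUUACG"),
    amounts_amol = c(50, 10, 2.5, 1.5, 0.1, 0.01, 0.005),
    labels = c("I", "K", "M", "N", "H", "C", "E"),
    flank_len = 4L
  )
}

#' @export
print.spike_panel <- function(x, ...) {
  cat(sprintf("Spike-in panel: %d oligos, %d nt cores, %d nt flanks per side\n",
              nrow(x), nchar(x$core[1]), x$flank_len[1]))
  cat(sprintf("Amount range: %g-%g amol (%.1f log10)\n",
              min(x$amount_amol), max(x$amount_amol),
              log10(max(x$amount_amol) / min(x$amount_amol))))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Write / read a panel sheet
#'
#' The sheet is a TSV with columns `label`, `core_sequence` (5'-3' RNA),
#' `flank_len`, `amount_amol`.
#'
#' @param panel A `spike_panel`.
#' @param path File path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` returns
#'   a `spike_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "spike_panel"))
  df <- data.frame(label = panel$label, core_sequence = panel$core,
                   flank_len = panel$flank_len,
                   amount_amol = panel$amount_amol)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "integer", "numeric"))
  need <- c("label", "core_sequence", "flank_len", "amount_amol")
  if (!all(need %in% names(df))) {
    stop("panel sheet must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  build_panel(df$core_sequence, df$amount_amol, df$label,
              flank_len = df$flank_len[1])
}

#' Expanded oligo templates with N flanks
#'
#' Returns the oligo templates as RNA strings in which each randomized flank
#' position is written `N`, e.g. `NNNNACGAUCGGCUCUANNNN`, and optionally
#' writes them as FASTA.
#'
#' @param panel A `spike_panel`.
#' @param path Optional FASTA path; when given the templates are written
#'   via [Biostrings::writeXStringSet()].
#' @return Named character vector of templates (invisibly when `path` is
#'   given).
#' @export
panel_templates <- function(panel, path = NULL) {
  stopifnot(inherits(panel, "spike_panel"))
  fl <- strrep("N", panel$flank_len)
  tpl <- paste0(fl, panel$core, fl)
  names(tpl) <- panel$label
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::RNAStringSet(tpl), path)
    return(invisible(tpl))
  }
  tpl
}

#' Size of the randomized-flank sequence space
#'
#' With `flank_len` randomized nucleotides on each side of the core, every
#' spike-in is a pool of `4^(2 * flank_len)` distinct sequences (65,536 for
#' the default four-nucleotide flanks); the randomized ends average out
#' sequence-specific ligation bias across the pool.
#'
#' @param flank_len Nonnegative number of randomized nucleotides per side.
#' @return Number of distinct oligo sequences per core.
#' @examples
#' flank_space_size(4) # 65536
#' @export
flank_space_size <- function(flank_len) {
  stopifnot_scalar_number(flank_len, "flank_len")
  if (flank_len < 0) stop("'flank_len' must be >= 0", call. = FALSE)
  4^(2 * flank_len)
}
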