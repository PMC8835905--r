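# Internal helpers shared across modules.

#' Run code with a temporary RNG state
#'
#' Seeds the generator, runs `code`, and restores the caller's RNG state so
#' seeded package functions do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# U/T interconversion; sequences are handled uppercase throughout.
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

stopifnot_scalar_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (x < min || (!allow_zero && x == 0)) {
    stop(sprintf("'%s' must be %s %s", name,
                 if (allow_zero) ">=" else ">", min), call. = FALSE)
  }
  invisible(x)
}

# GC fraction of an upper-case sequence string (exact rational value).
gc_fraction <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)
  vapply(chars, function(s) sum(s %in% c("G", "C")) / length(s), numeric(1))
}

# Length of the longest homopolymer run.
max_homopolymer_run <- function(seq) {
  vapply(strsplit(seq, "", fixed = TRUE), function(s) {
    max(rle(s)$lengths)
  }, numeric(1))
}

# Decode a vector of quality strings into a list of integer Phred vectors.
decode_phred <- function(qual, offset = 33L) {
  if (length(qual) == 0L) return(list())
  lens <- nchar(qual)
  all_q <- utf8ToInt(paste(qual, collapse = "")) - offset
  split(all_q, rep(seq_along(qual), lens))
}
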