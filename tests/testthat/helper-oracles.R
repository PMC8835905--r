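# Independent oracles, deliberately naive: plain-R reimplementations used
# only to cross-check package results.

# Brute-force sliding-window Hamming scan over every record (and reverse
# complements when both_strands).
oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGT", "TGCA",
                   strsplit(s, "", fixed = TRUE)[[1]])), collapse = "")
}

oracle_hit_count <- function(core, refs, max_mismatch, both_strands = TRUE) {
  core <- chartr("U", "T", toupper(core))
  k <- nchar(core)
  core_chars <- strsplit(core, "", fixed = TRUE)[[1]]
  count_one <- function(ref) {
    n <- nchar(ref)
    if (n < k) return(0L)
    chars <- strsplit(ref, "", fixed = TRUE)[[1]]
    hits <- 0L
    for (s in seq_len(n - k + 1L)) {
      w <- chars[s:(s + k - 1L)]
      mm <- sum(w != core_chars | w == "N")
      if (mm <= max_mismatch) hits <- hits + 1L
    }
    hits
  }
  total <- sum(vapply(toupper(refs), count_one, integer(1)))
  if (both_strands) {
    total <- total +
      sum(vapply(vapply(toupper(refs), oracle_revcomp, character(1)),
                 count_one, integer(1)))
  }
  total
}

# Iteratively refined grid minimiser of sum((rc - b * amt)^2).
oracle_grid_beta <- function(amt, rc, lo = NULL, hi = NULL, passes = 6L,
                             points = 201L) {
  if (is.null(lo)) lo <- 0
  if (is.null(hi)) hi <- 2 * max(rc) / min(amt[amt > 0])
  for (p in seq_len(passes)) {
    grid <- seq(lo, hi, length.out = points)
    sse <- vapply(grid, function(b) sum((rc - b * amt)^2), numeric(1))
    i <- which.min(sse)
    step <- grid[2] - grid[1]
    lo <- max(0, grid[i] - step)
    hi <- grid[i] + step
  }
  grid[i]
}

# Independent greedy re-implementation of the core selection rule.
oracle_select <- function(df, k) {
  df <- df[order(df$sequence), , drop = FALSE]
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  picked <- character(0)
  for (i in seq_len(k)) {
    pool <- df[!(df$sequence %in% picked), , drop = FALSE]
    pool <- pool[pool$hit_count == min(pool$hit_count), , drop = FALSE]
    if (length(picked) && nrow(pool) > 1L) {
      d <- vapply(pool$sequence, function(s) {
        min(vapply(picked, function(p) hd(s, p), numeric(1)))
      }, numeric(1))
      pool <- pool[d == max(d), , drop = FALSE]
    }
    picked <- c(picked, sort(pool$sequence)[1])
  }
  picked
}

# Direct-formula Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
}

# Subsampling oracle: shuffle expanded read labels, take a prefix.
oracle_subsample_detected <- function(counts, target) {
  labels <- sample(rep.int(seq_along(counts), counts))
  length(unique(labels[seq_len(target)]))
}
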