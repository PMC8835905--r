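# Assay validation statistics: ligation bias, consistency, repeatability,
# measurement range, dilution-series accuracy, depth subsampling.

#' Ligation-bias report on an equimolar pool
#'
#' For replicate libraries of an equimolar pool, averages the RPM of each
#' feature across replicates, expresses it as the fold change (FC) relative
#' to the median over detected features (mean RPM > 0), and reports the
#' percentage of detected features whose FC lies within the 100x window
#' 0.1 to 10 (inclusive). With no ligation bias every FC is 1 and the
#' percentage is 100; sequence-specific ligation efficiency spreads the FC
#' distribution multiplicatively around the median.
#'
#' @param rpm Matrix of RPM values over the endogenous features
#'   (features x replicates).
#' @return List of class `bias_report`: `mean_rpm`, `fc` (fold change vs
#'   median, detected features only), `pct_within` (percentage with
#'   `0.1 <= FC <= 10`), `n_detected`.
#' @export
bias_report <- function(rpm) {
  m <- as.matrix(rpm)
  if (all(m == 0)) stop("all-zero abundance matrix", call. = FALSE)
  mean_rpm <- rowMeans(m)
  detected <- mean_rpm > 0
  med <- stats::median(mean_rpm[detected])
  fc <- mean_rpm[detected] / med
  structure(list(
    mean_rpm = mean_rpm,
    fc = fc,
    pct_within = 100 * mean(fc >= 0.1 & fc <= 10),
    n_detected = sum(detected)
  ), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf(paste0("Ligation-bias report: %d detected features, %.1f%%",
                     " within 0.1- to 10-fold of the median\n"),
              x$n_detected, x$pct_within))
  invisible(x)
}

#' Between-dataset bias correlation matrix
#'
#' Pearson correlation of log10 fold-change vectors across datasets,
#' computed on the features detected (FC available) in every dataset.
#'
#' @param fc_list Named list of fold-change vectors (named by feature), as
#'   from `bias_report()$fc`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
bias_correlation <- function(fc_list) {
  if (length(fc_list) < 2L) stop("need at least two datasets", call. = FALSE)
  shared <- Reduce(intersect, lapply(fc_list, names))
  if (length(shared) < 3L) {
    stop("fewer than 3 shared detected features", call. = FALSE)
  }
  logfc <- vapply(fc_list, function(v) log10(v[shared]),
                  numeric(length(shared)))
  stats::cor(logfc)
}

#' Replicate detection inconsistency
#'
#' Percentage of features detected (count >= 1) in exactly one of the
#' replicates, among features detected in at least one replicate. High
#' values indicate stochastic borderline detection.
#'
#' @param counts Matrix of counts (features x replicates), n >= 2
#'   replicates.
#' @return Percentage in [0, 100].
#' @export
inconsistency_pct <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) < 2L) stop("need at least two replicates", call. = FALSE)
  det <- rowSums(m >= 1)
  if (all(det == 0)) stop("no feature detected in any replicate",
                          call. = FALSE)
  100 * sum(det == 1) / sum(det >= 1)
}

#' Coefficient-of-variation repeatability report
#'
#' Per-feature CV% (`100 * sd / mean`, sample sd) across replicate
#' abundances, by default restricted to features detected (> 0) in all
#' replicates, and the fraction of those features with CV strictly below
#' the threshold.
#'
#' @param abundance Matrix (features x replicates) of abundances, typically
#'   in amol.
#' @param threshold_pct CV threshold in percent (default 50).
#' @param detected_in_all Restrict to features with all replicate values
#'   > 0 (default TRUE).
#' @return List of class `cv_report`: `cv` (named CV% vector),
#'   `frac_below` (fraction with `CV < threshold_pct`), `threshold_pct`,
#'   `n_used`, `n_excluded`.
#' @export
cv_report <- function(abundance, threshold_pct = 50,
                      detected_in_all = TRUE) {
  m <- as.matrix(abundance)
  if (ncol(m) < 2L) stop("need at least two replicates", call. = FALSE)
  keep <- if (detected_in_all) rowSums(m > 0) == ncol(m) else
    rowSums(m > 0) >= 2
  n_excluded <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no usable features for CV", call. = FALSE)
  cv <- 100 * apply(m, 1, stats::sd) / rowMeans(m)
  structure(list(
    cv = cv,
    frac_below = mean(cv < threshold_pct),
    threshold_pct = threshold_pct,
    n_used = nrow(m),
    n_excluded = n_excluded
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("Repeatability: %.1f%% of %d features with CV < %g%%",
                     " (%d excluded)\n"),
              100 * x$frac_below, x$n_used, x$threshold_pct, x$n_excluded))
  invisible(x)
}

#' Analytical measurement range
#'
#' The calibrated interval is bracketed by the highest and lowest spike-in;
#' this reports, per sample, the percentage of detected endogenous features
#' (RPM > 0) whose RPM lies within `[spike_rpm_low, spike_rpm_high]`
#' (inclusive), evaluated against each sample's own spike-in RPM values,
#' plus the across-sample mean.
#'
#' @param rpm Matrix of endogenous RPM values (features x samples).
#' @param spike_rpm_low,spike_rpm_high RPM of the lowest / highest spike-in
#'   per sample (scalars are recycled). A zero or missing low spike-in
#'   signals an out-of-range calibration and is an error.
#' @return List of class `measurement_range`: `pct_within` (per sample),
#'   `mean_pct`.
#' @export
measurement_range <- function(rpm, spike_rpm_low, spike_rpm_high) {
  m <- as.matrix(rpm)
  lo <- rep_len(spike_rpm_low, ncol(m))
  hi <- rep_len(spike_rpm_high, ncol(m))
  if (any(is.na(lo)) || any(lo <= 0)) {
    stop(paste("lowest spike-in undetected in at least one sample;",
               "measurement range undefined"), call. = FALSE)
  }
  if (any(hi < lo)) {
    stop("inverted range: spike_rpm_low exceeds spike_rpm_high",
         call. = FALSE)
  }
  pct <- vapply(seq_len(ncol(m)), function(k) {
    v <- m[, k]
    v <- v[v > 0]
    if (!length(v)) return(NA_real_)
    100 * mean(v >= lo[k] & v <= hi[k])
  }, numeric(1))
  names(pct) <- colnames(m)
  structure(list(pct_within = pct, mean_pct = mean(pct, na.rm = TRUE)),
            class = "measurement_range")
}

#' @export
print.measurement_range <- function(x, ...) {
  cat(sprintf(paste0("Analytical measurement range: %.2f%% of detected",
                     " features within the spike-in bounds (mean over %d",
                     " samples)\n"), x$mean_pct, length(x$pct_within)))
  invisible(x)
}

#' Fisher z transformation
#'
#' `z = atanh(r)`, the variance-stabilising transform of the Pearson
#' correlation; `|r|` is capped at `1 - 1e-12` so perfect correlations map
#' to a large finite z.
#'
#' @param r Correlation(s) in [-1, 1].
#' @return z value(s).
#' @examples
#' fisher_z(0.5) # 0.5493
#' @export
fisher_z <- function(r) {
  atanh(pmin(abs(r), 1 - 1e-12)) * sign(r)
}

#' Dilution-series relative accuracy report
#'
#' For two pools mixed at fractions `p` of pool A, the expected abundance
#' of a feature is `p * A + (1 - p) * B`. This compares the observed
#' abundances to those expectations: per-feature recovery
#' `100 * observed / expected` at every fraction, the per-feature Pearson
#' correlation over the (expected, observed) pairs with its Fisher z, the
#' mean z across features, and the number of features whose mean recovery
#' falls in the 50-200% window.
#'
#' @param observed Matrix (features x fractions) of observed abundances of
#'   the mixed samples, columns ordered as `fractions`.
#' @param pureA,pureB Named numeric vectors of the pure-pool abundances for
#'   every assessed feature.
#' @param fractions Mixing fractions of pool A, length >= 2.
#' @return List of class `accuracy_report`: `expected` and `recovery_pct`
#'   matrices, per-feature `r` and `z`, `mean_z`, `n_recovery_in_range`,
#'   `n_features`, and `excluded` (features dropped for an expected value
#'   of zero).
#' @export
accuracy_report <- function(observed, pureA, pureB, fractions) {
  obs <- as.matrix(observed)
  if (length(fractions) < 2L) stop("need at least two fractions",
                                   call. = FALSE)
  if (ncol(obs) != length(fractions)) {
    stop("'observed' must have one column per fraction", call. = FALSE)
  }
  feats <- rownames(obs)
  if (is.null(feats)) stop("'observed' must have feature rownames",
                           call. = FALSE)
  if (!all(feats %in% names(pureA)) || !all(feats %in% names(pureB))) {
    stop("pure-pool values missing for some assessed features",
         call. = FALSE)
  }
  expected <- outer(pureA[feats], fractions) +
    outer(pureB[feats], 1 - fractions)
  colnames(expected) <- colnames(obs)
  excluded <- feats[apply(expected, 1, function(e) any(e == 0))]
  use <- setdiff(feats, excluded)
  if (!length(use)) stop("no feature has nonzero expected values",
                         call. = FALSE)
  expected <- expected[use, , drop = FALSE]
  obs <- obs[use, , drop = FALSE]
  recovery <- 100 * obs / expected
  r <- vapply(use, function(f) {
    if (stats::sd(expected[f, ]) == 0 || stats::sd(obs[f, ]) == 0) {
      return(NA_real_)
    }
    stats::cor(expected[f, ], obs[f, ])
  }, numeric(1))
  z <- fisher_z(r)
  mean_rec <- rowMeans(recovery)
  structure(list(
    expected = expected,
    recovery_pct = recovery,
    r = r,
    z = z,
    mean_z = mean(z, na.rm = TRUE),
    n_recovery_in_range = sum(mean_rec >= 50 & mean_rec <= 200),
    n_features = length(use),
    excluded = excluded
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(paste0("Relative accuracy: mean Fisher z = %.3f; %d of %d",
                     " features with mean recovery in 50-200%%\n"),
              x$mean_z, x$n_recovery_in_range, x$n_features))
  if (length(x$excluded)) {
    cat(sprintf("  excluded (expected = 0): %s\n",
                paste(x$excluded, collapse = ", ")))
  }
  invisible(x)
}

# Multivariate hypergeometric draw: subsample a count vector to exactly
# `target` total without replacement (sequential conditional rhyper).
rmvhyper <- function(counts, target) {
  total <- sum(counts)
  out <- integer(length(counts))
  remaining <- total
  left <- target
  for (i in seq_along(counts)) {
    if (left == 0L) break
    if (remaining == counts[i]) {
      out[i] <- left
      break
    }
    out[i] <- stats::rhyper(1, counts[i], remaining - counts[i], left)
    left <- left - out[i]
    remaining <- remaining - counts[i]
  }
  out
}

#' Subsample a count vector to a target depth
#'
#' Without-replacement subsampling of reads (multivariate hypergeometric on
#' the count vector, the count-level equivalent of drawing a random subset
#' of reads), replicated `n_reps` times with derived seeds. Reports the
#' subsampled count vectors and detected-feature counts (count >= 1).
#'
#' @param counts Named integer vector (or single-column matrix) of feature
#'   counts.
#' @param target_depth Total reads after subsampling; must not exceed the
#'   available depth.
#' @param n_reps Number of replicate draws (default 1).
#' @param seed Integer seed.
#' @return List of class `subsample_draw`: `counts` (features x reps
#'   matrix, columns summing exactly to `target_depth`), `detected`
#'   (per-rep detected-feature counts), `target_depth`.
#' @export
subsample_counts <- function(counts, target_depth, n_reps = 1L, seed = 1L) {
  v <- if (is.matrix(counts)) counts[, 1] else counts
  v <- stats::setNames(as.integer(round(v)), names(v))
  if (target_depth > sum(v)) {
    stop("target depth exceeds available depth", call. = FALSE)
  }
  m <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) rmvhyper(v, as.integer(target_depth)),
           integer(length(v)))
  })
  m <- matrix(m, nrow = length(v),
              dimnames = list(names(v), paste0("rep", seq_len(n_reps))))
  structure(list(counts = m, detected = colSums(m >= 1),
                 target_depth = target_depth),
            class = "subsample_draw")
}

#' Detection curve across sequencing depths
#'
#' Subsamples a count vector to each target depth with `n_reps` replicates
#' and records the number of detected features, tracing how sequencing
#' depth drives detection. In nested mode a single random read ordering is
#' drawn per replicate and depths are prefixes of it, so detection counts
#' are non-decreasing in depth within a replicate.
#'
#' @inheritParams subsample_counts
#' @param depths Vector of target depths (reads).
#' @param nested Use nested prefix subsampling (default FALSE).
#' @return List of class `subsample_curve`: `depths`, `detected` (depths x
#'   reps matrix), `n_reps`.
#' @export
detection_curve <- function(counts, depths, n_reps = 5L, seed = 1L,
                            nested = FALSE) {
  v <- if (is.matrix(counts)) counts[, 1] else counts
  v <- stats::setNames(as.integer(round(v)), names(v))
  if (any(depths > sum(v)) || any(depths <= 0)) {
    stop("depths must be positive and not exceed the available depth",
         call. = FALSE)
  }
  depths <- sort(depths)
  det <- with_seed(seed, {
    if (nested) {
      vapply(seq_len(n_reps), function(r) {
        labels <- sample(rep.int(seq_along(v), v))
        vapply(depths, function(d) {
          length(unique(labels[seq_len(d)]))
        }, integer(1))
      }, integer(length(depths)))
    } else {
      vapply(seq_len(n_reps), function(r) {
        vapply(depths, function(d) {
          sum(rmvhyper(v, as.integer(d)) >= 1)
        }, integer(1))
      }, integer(length(depths)))
    }
  })
  det <- matrix(det, nrow = length(depths),
                dimnames = list(paste0("depth", depths),
                                paste0("rep", seq_len(n_reps))))
  structure(list(depths = depths, detected = det, n_reps = n_reps),
            class = "subsample_curve")
}

#' @export
print.subsample_curve <- function(x, ...) {
  cat("Detection curve (mean detected features per depth):\n")
  print(data.frame(depth = x$depths, detected = rowMeans(x$detected)),
        row.names = FALSE)
  invisible(x)
}
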