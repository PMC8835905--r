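# Spike-in calibration: the linear model without intercept, and unit
# conversions from read counts to absolute abundances.

#' Fit the spike-in calibration model
#'
#' Fits the relation between the known attomolar amounts of the spike-ins
#' and their observed read counts using a linear model without intercept,
#' `RC = beta * C`, by ordinary least squares through the origin on the
#' linear scale: `beta = sum(C * RC) / sum(C^2)` over all panel oligos.
#' The slope `beta` (reads per attomole) is the sample's capture
#' efficiency; its inverse converts any feature's read count to attomoles.
#' Goodness of fit is summarised by the Pearson correlation of
#' `log10(RC)` vs `log10(C)` over spike-ins with nonzero counts (the scale
#' on which calibration curves are usually drawn), alongside the
#' linear-scale correlation.
#'
#' A failed spike-in addition is detectable here: if fewer than two oligos
#' have nonzero counts the fit is refused.
#'
#' @param spike_counts Named numeric vector of spike-in read counts; names
#'   must match the panel labels.
#' @param panel A [build_panel()] object carrying the known amounts.
#' @param weights Optional per-oligo weights for a weighted fit
#'   (`beta = sum(w C RC) / sum(w C^2)`); default unweighted.
#' @param log_scale If TRUE, fit the slope on log10-transformed positive
#'   pairs instead (regression of `log10 RC` on `log10 C` with unit slope
#'   offset is *not* used; the through-origin model is refitted on logs by
#'   least squares of `RC - beta C` after back-transform). Default FALSE;
#'   the linear-scale through-origin fit is the model of record.
#' @return Object of class `mind_calibration` with elements `beta`
#'   (reads/amol), `r_log`, `r_linear`, `n_points` (oligos with count > 0),
#'   `amounts`, `counts`, `fitted`, `residuals`.
#' @examples
#' panel <- mind_panel()
#' counts <- stats::setNames(1000 * panel$amount_amol, panel$label)
#' fit <- fit_calibration(counts, panel)
#' coef(fit)
#' @export
fit_calibration <- function(spike_counts, panel, weights = NULL,
                            log_scale = FALSE) {
  stopifnot(inherits(panel, "spike_panel"))
  if (is.null(names(spike_counts))) {
    if (length(spike_counts) != nrow(panel)) {
      stop("unnamed 'spike_counts' must match the panel length",
           call. = FALSE)
    }
    names(spike_counts) <- panel$label
  }
  missing <- setdiff(panel$label, names(spike_counts))
  if (length(missing)) {
    stop("spike_counts missing oligos: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rc <- as.numeric(spike_counts[panel$label])
  if (any(is.na(rc)) || any(rc < 0)) {
    stop("spike-in counts must be nonnegative numbers", call. = FALSE)
  }
  amt <- panel$amount_amol
  pos <- rc > 0
  if (sum(pos) < 2L) {
    stop(paste("calibration impossible: fewer than two spike-ins with",
               "nonzero counts (failed spike-in addition?)"), call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(rc))
  if (isTRUE(log_scale)) {
    # through-origin fit on log-transformed positive pairs:
    # minimises sum (log10 RC - log10 beta - log10 C)^2
    beta <- 10^mean(log10(rc[pos]) - log10(amt[pos]))
  } else {
    beta <- sum(weights * amt * rc) / sum(weights * amt^2)
  }
  fitted <- beta * amt
  r_log <- stats::cor(log10(amt[pos]), log10(rc[pos]))
  r_linear <- stats::cor(amt, rc)
  structure(list(
    beta = beta,
    r_log = r_log,
    r_linear = r_linear,
    n_points = sum(pos),
    amounts = stats::setNames(amt, panel$label),
    counts = stats::setNames(rc, panel$label),
    fitted = stats::setNames(fitted, panel$label),
    residuals = stats::setNames(rc - fitted, panel$label),
    log_scale = isTRUE(log_scale)
  ), class = "mind_calibration")
}

#' @export
print.mind_calibration <- function(x, ...) {
  cat("Spike-in calibration (linear model without intercept)\n")
  cat(sprintf("  beta: %.6g reads/amol  (%d of %d oligos detected)\n",
              x$beta, x$n_points, length(x$counts)))
  cat(sprintf("  Pearson r (log10): %.4f   (linear): %.4f\n",
              x$r_log, x$r_linear))
  invisible(x)
}

#' @export
summary.mind_calibration <- function(object, ...) {
  tab <- data.frame(
    oligo = names(object$counts),
    amount_amol = object$amounts,
    count = object$counts,
    fitted = object$fitted,
    residual = object$residuals,
    est_amol = object$counts / object$beta,
    row.names = NULL
  )
  out <- list(fit = object, table = tab)
  class(out) <- "summary.mind_calibration"
  out
}

#' @export
print.summary.mind_calibration <- function(x, ...) {
  print(x$fit)
  cat("\nPer-oligo calibration table:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.mind_calibration <- function(object, ...) {
  c(beta = object$beta)
}

#' @export
residuals.mind_calibration <- function(object, ...) object$residuals

#' @export
fitted.mind_calibration <- function(object, ...) object$fitted

#' Predict read counts from amounts under a calibration fit
#'
#' @param object A `mind_calibration`.
#' @param newdata Numeric vector of amounts in amol; defaults to the fitted
#'   panel amounts.
#' @param ... Unused.
#' @return Expected read counts `beta * amount`.
#' @export
predict.mind_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  object$beta * newdata
}

#' Simulate spike-in counts from a calibration fit
#'
#' Draws Poisson counts at the fitted means, useful for parametric
#' bootstrap checks of the slope.
#'
#' @param object A `mind_calibration`.
#' @param nsim Number of replicate count vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Matrix (oligos x nsim) of simulated counts.
#' @export
simulate.mind_calibration <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() stats::rpois(length(object$fitted), object$fitted)
  m <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  m <- matrix(m, nrow = length(object$fitted),
              dimnames = list(names(object$fitted), NULL))
  m
}

#' Plot a calibration fit
#'
#' Log-log scatter of observed counts vs known amounts with the fitted
#' through-origin line (slope 1 in log space, intercept `log10 beta`).
#'
#' @param x A `mind_calibration`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mind_calibration <- function(x, ...) {
  pos <- x$counts > 0
  graphics::plot(log10(x$amounts[pos]), log10(x$counts[pos]),
                 xlab = "log10 amount (amol)", ylab = "log10 read count",
                 main = sprintf("Spike-in calibration (beta = %.3g, r = %.3f)",
                                x$beta, x$r_log), ...)
  graphics::abline(log10(x$beta), 1, lty = 2)
  graphics::text(log10(x$amounts[pos]), log10(x$counts[pos]),
                 labels = names(x$amounts)[pos], pos = 3, cex = 0.8)
  invisible(x)
}

#' Fit per-sample calibrations for a count matrix
#'
#' @param counts A `mind_counts` object or integer matrix with spike-in
#'   rows named by the panel labels.
#' @param panel A `spike_panel`.
#' @param ... Passed to [fit_calibration()].
#' @return Named list of `mind_calibration`, one per sample.
#' @export
calibrate_samples <- function(counts, panel, ...) {
  m <- if (inherits(counts, "mind_counts")) counts$counts else counts
  fits <- lapply(colnames(m), function(s) {
    fit_calibration(m[panel$label, s], panel, ...)
  })
  names(fits) <- colnames(m)
  fits
}

# Extract the count matrix and spike/mirna partition from either a
# mind_counts object or a plain matrix + panel.
count_parts <- function(counts, panel) {
  m <- if (inherits(counts, "mind_counts")) counts$counts else counts
  if (is.null(rownames(m))) stop("counts must have feature rownames",
                                 call. = FALSE)
  spike_rows <- intersect(rownames(m), panel$label)
  mirna_rows <- setdiff(rownames(m), c(panel$label, "unmapped"))
  list(m = m, spike = spike_rows, mirna = mirna_rows)
}

#' Reads-per-million normalisation
#'
#' `RPM = count * 1e6 / denominator`, where the denominator is either the
#' miRNA-mapped total (spike-in and unmapped rows excluded — RPM is defined
#' over endogenous content) or all surviving reads in the sample. Spike-in
#' features are excluded from the denominator but still receive RPM values,
#' so endogenous abundances can be placed relative to the spike ladder.
#'
#' @param counts A `mind_counts` or count matrix (features x samples).
#' @param panel A `spike_panel` identifying the spike-in rows.
#' @param denominator `"mirna_mapped"` (default) or `"all_surviving"`.
#' @return Numeric matrix of RPM values (unit attribute `"RPM"`); the
#'   `"unmapped"` row, if present, is dropped.
#' @export
rpm_normalize <- function(counts, panel,
                          denominator = c("mirna_mapped", "all_surviving")) {
  denominator <- match.arg(denominator)
  p <- count_parts(counts, panel)
  denom <- if (denominator == "mirna_mapped") {
    colSums(p$m[p$mirna, , drop = FALSE])
  } else {
    colSums(p$m)
  }
  zero <- denom <= 0
  if (any(zero)) {
    stop("zero denominator for sample(s): ",
         paste(colnames(p$m)[zero], collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(rownames(p$m), "unmapped")
  out <- sweep(p$m[keep, , drop = FALSE], 2, denom, "/") * 1e6
  attr(out, "unit") <- "RPM"
  out
}

#' Convert read counts to attomoles
#'
#' `amol = RC / beta` per feature and sample, using each sample's own
#' calibration slope. Spike-in rows are retained: their estimates should
#' recover the panel amounts, a per-sample QC in itself.
#'
#' @param counts A `mind_counts` or count matrix.
#' @param fits Named list of per-sample [fit_calibration()] objects (or a
#'   single fit applied to a one-sample matrix).
#' @param panel A `spike_panel` (used to drop the `"unmapped"` row).
#' @return Numeric matrix of amounts in attomoles (unit attribute
#'   `"amol"`).
#' @export
to_amol <- function(counts, fits, panel) {
  p <- count_parts(counts, panel)
  if (inherits(fits, "mind_calibration")) fits <- list(fits)
  if (length(fits) == 1L && ncol(p$m) == 1L && is.null(names(fits))) {
    names(fits) <- colnames(p$m)
  }
  missing <- setdiff(colnames(p$m), names(fits))
  if (length(missing)) {
    stop("missing calibration fit for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(rownames(p$m), "unmapped")
  betas <- vapply(colnames(p$m), function(s) fits[[s]]$beta, numeric(1))
  out <- sweep(p$m[keep, , drop = FALSE], 2, betas, "/")
  attr(out, "unit") <- "amol"
  out
}

#' Sample volume metadata
#'
#' Volumes entering the molecules-per-microlitre conversions: `rna_input_ul`
#' microlitres of RNA eluate go into library preparation, out of
#' `elution_ul` total eluate extracted from `biofluid_ul` of biofluid.
#'
#' @param rna_input_ul,elution_ul,biofluid_ul Positive volumes in uL;
#'   `rna_input_ul` must not exceed `elution_ul`.
#' @return A list of class `sample_volumes`.
#' @examples
#' sample_volumes(rna_input_ul = 8.5, elution_ul = 30, biofluid_ul = 200)
#' @export
sample_volumes <- function(rna_input_ul, elution_ul, biofluid_ul) {
  for (v in c(rna_input_ul, elution_ul, biofluid_ul)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("all volumes must be single positive numbers", call. = FALSE)
    }
  }
  if (rna_input_ul > elution_ul) {
    stop("rna_input_ul cannot exceed elution_ul", call. = FALSE)
  }
  structure(list(rna_input_ul = rna_input_ul, elution_ul = elution_ul,
                 biofluid_ul = biofluid_ul), class = "sample_volumes")
}

#' Avogadro constant (molecules per mole)
#' @export
AVOGADRO <- 6.02214076e23

#' Convert attomole abundances to molecules per microlitre
#'
#' One attomole is `1e-18 * N_A ~ 602,214` molecules. The library contains
#' `amol * 1e-18 * N_A` molecules drawn from `rna_input_ul` uL of eluate,
#' so molecules per uL RNA is that number divided by `rna_input_ul`;
#' scaling by `elution_ul / biofluid_ul` re-expresses it per uL of the
#' source biofluid.
#'
#' @param amol_matrix Matrix of abundances in attomoles (features x
#'   samples) as from [to_amol()].
#' @param volumes A [sample_volumes()] object, or a named list of one per
#'   sample.
#' @param target `"rna"` (molecules per uL input RNA) or `"biofluid"`.
#' @return Numeric matrix with unit attribute
#'   `"molecules_per_ul_rna"` or `"molecules_per_ul_biofluid"`.
#' @examples
#' m <- matrix(1, 1, 1, dimnames = list("miR-x", "s1"))
#' vol <- sample_volumes(1, 30, 200)
#' to_molecules_per_ul(m, vol, target = "rna") # 602214.076
#' @export
to_molecules_per_ul <- function(amol_matrix, volumes,
                                target = c("rna", "biofluid")) {
  target <- match.arg(target)
  m <- as.matrix(amol_matrix)
  if (inherits(volumes, "sample_volumes")) {
    volumes <- rep(list(volumes), ncol(m))
    names(volumes) <- colnames(m)
  }
  missing <- setdiff(colnames(m), names(volumes))
  if (length(missing)) {
    stop("missing volumes for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- m
  for (s in colnames(m)) {
    v <- volumes[[s]]
    stopifnot(inherits(v, "sample_volumes"))
    per_ul_rna <- m[, s] * 1e-18 * AVOGADRO / v$rna_input_ul
    out[, s] <- if (target == "rna") {
      per_ul_rna
    } else {
      per_ul_rna * v$elution_ul / v$biofluid_ul
    }
  }
  attr(out, "unit") <- paste0("molecules_per_ul_", target)
  out
}
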