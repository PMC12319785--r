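# ICC(3,1) consistency analysis: two-way (subjects x sessions) ANOVA
# mean squares, the consistency ICC, F-based confidence intervals and
# threshold classification.

#' ANOVA mean squares underlying ICC(3,1)
#'
#' Standard two-way decomposition of an `n x k` subjects-by-sessions
#' matrix without replicates: between-subjects mean square (BMS, df
#' n - 1), between-sessions mean square (JMS, df k - 1; reported but
#' unused by the consistency ICC) and residual (error) mean square
#' (EMS, df (n - 1)(k - 1)).
#'
#' @param m Numeric matrix, subjects in rows, sessions in columns
#'   (n >= 3, k = 2, no missing values).
#' @return Object of class `icc_components`: list with `BMS`, `JMS`,
#'   `EMS`, `n`, `k`.
#' @examples
#' icc_components(cbind(c(1, 2, 3, 4, 5), c(2, 1, 3, 4, 5)))
#' @export
icc_components <- function(m) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("non-finite values in input", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (k != 2) stop("exactly 2 sessions expected", call. = FALSE)
  g <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ss_subj <- k * sum((rm_ - g)^2)
  ss_sess <- n * sum((cm_ - g)^2)
  ss_tot <- sum((m - g)^2)
  ss_err <- max(ss_tot - ss_subj - ss_sess, 0)
  structure(list(BMS = ss_subj / (n - 1),
                 JMS = ss_sess / (k - 1),
                 EMS = ss_err / ((n - 1) * (k - 1)),
                 n = n, k = k),
            class = "icc_components")
}

#' Consistency intraclass correlation ICC(3,1)
#'
#' `ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) * EMS)`: two-way mixed
#' model, single measurement, consistency form. Insensitive to additive
#' session offsets. Errors when BMS = EMS = 0 (no variance at all); the
#' pipeline treats such degenerate edges as inconsistent.
#'
#' @param components An [icc_components()] object.
#' @return The ICC value (in (-1, 1]).
#' @export
icc_3_1 <- function(components) {
  stopifnot(inherits(components, "icc_components"))
  with(components, {
    if (BMS == 0 && EMS == 0)
      stop("undefined ICC: BMS and EMS are both zero", call. = FALSE)
    (BMS - EMS) / (BMS + (k - 1) * EMS)
  })
}

#' F-based 95% confidence interval for ICC(3,1)
#'
#' Shrout-Fleiss interval: with `F = BMS/EMS` on (n - 1, (n - 1)(k - 1))
#' df, the bounds are `(F/Fq - 1)/(F/Fq + k - 1)` and
#' `(F*Fq' - 1)/(F*Fq' + k - 1)` with `Fq`, `Fq'` the upper-tail F
#' quantiles for the two df orders. With EMS = 0 the interval collapses
#' to the point estimate (with a warning).
#'
#' @param components An [icc_components()] object.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
icc_ci <- function(components, conf = 0.95) {
  stopifnot(inherits(components, "icc_components"), conf > 0, conf < 1)
  n <- components$n; k <- components$k
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  if (df2 <= 0) stop("no error degrees of freedom", call. = FALSE)
  if (components$EMS == 0) {
    warning("EMS is zero; confidence interval collapses to the estimate",
            call. = FALSE)
    est <- icc_3_1(components)
    return(c(low = est, high = est))
  }
  Fobs <- components$BMS / components$EMS
  a <- (1 - conf) / 2
  FL <- Fobs / stats::qf(1 - a, df1, df2)
  FU <- Fobs * stats::qf(1 - a, df2, df1)
  c(low = (FL - 1) / (FL + k - 1), high = (FU - 1) / (FU + k - 1))
}

#' Classify an ICC value against a consistency threshold
#'
#' `"consistent"` iff the ICC is strictly above the threshold (0.4 by
#' default; 0.5 for the stricter replication convention).
#'
#' @param icc Finite ICC value (NA allowed: classified inconsistent).
#' @param threshold Consistency threshold (default 0.4).
#' @return `"consistent"` or `"inconsistent"`.
#' @export
icc_classify <- function(icc, threshold = 0.4) {
  ifelse(!is.na(icc) & icc > threshold, "consistent", "inconsistent")
}

#' Consistency analysis of one subjects-by-sessions series
#'
#' Convenience wrapper computing the ANOVA components, ICC(3,1), the
#' F-based confidence interval and the consistency label in one call.
#' Degenerate series (zero variance everywhere) return an `NA` estimate
#' labeled inconsistent instead of erroring.
#'
#' @param m `n x 2` subjects-by-sessions matrix (e.g. a
#'   `parcel_edge_series`).
#' @param threshold Consistency threshold (default 0.4).
#' @param conf Confidence level for the interval (default 0.95).
#' @return Object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `label`, `threshold`, `components`, `degenerate`.
#' @examples
#' icc(cbind(rnorm(10), rnorm(10)))
#' @export
icc <- function(m, threshold = 0.4, conf = 0.95) {
  comp <- icc_components(unclass(as.matrix(m)))
  if (comp$BMS == 0 && comp$EMS == 0) {
    res <- list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                label = "inconsistent", threshold = threshold,
                components = comp, degenerate = TRUE)
    return(structure(res, class = "icc_result"))
  }
  est <- icc_3_1(comp)
  ci <- suppressWarnings(icc_ci(comp, conf))
  structure(list(icc = est, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 label = icc_classify(est, threshold), threshold = threshold,
                 components = comp, degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$degenerate) {
    cat("ICC(3,1): degenerate (zero variance); labeled inconsistent\n")
    return(invisible(x))
  }
  cat(sprintf("ICC(3,1) = %.3f, 95%% CI [%.3f, %.3f] -> %s (threshold %.1f)\n",
              x$icc, x$ci_low, x$ci_high, x$label, x$threshold))
  invisible(x)
}
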