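# Properties of consistent vs. inconsistent connections: per-edge
# behavioral regression screen, chi-square association tests,
# Mann-Whitney comparisons, laterality labeling and the pooled report.

#' Behavioral regression screen for one edge
#'
#' Ordinary least squares of the per-subject mean-over-sessions
#' task-contrast on the three behavioral scores (letter fluency,
#' category fluency, RAN/RAS composite) with intercept; the overall
#' model F-test on (3, n - 4) df decides the `fitted` flag (p < 0.05).
#' No multiple-testing correction is applied, by design: the screen is
#' used symmetrically for the consistent and inconsistent groups.
#'
#' @param y Per-subject outcome (mean-over-sessions summed contrast).
#' @param behavior Behavior data.frame with columns `fluency_s`,
#'   `fluency_animal`, `ran_ras_mean` (>= 6 complete subjects).
#' @return List with `F`, `p`, `fitted`, `df1`, `df2`.
#' @export
behavior_association <- function(y, behavior) {
  res <- behavior_screen(matrix(y, ncol = 1), behavior)
  list(F = res$F[1], p = res$p[1], fitted = res$fitted[1],
       df1 = res$df1[1], df2 = res$df2[1])
}

#' Vectorized behavioral regression screen
#'
#' Same model as [behavior_association()] applied to every column of an
#' outcome matrix; the shared design matrix is factorized once.
#'
#' @param Y `n_subjects x n_edges` outcome matrix.
#' @param behavior Behavior data.frame (see [behavior_association()]).
#' @return data.frame with one row per edge: `F`, `p`, `fitted`,
#'   `df1`, `df2`.
#' @export
behavior_screen <- function(Y, behavior) {
  Y <- as.matrix(Y)
  pred <- c("fluency_s", "fluency_animal", "ran_ras_mean")
  miss <- setdiff(pred, names(behavior))
  if (length(miss))
    stop("behavior table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(behavior[, pred]))
  n <- nrow(X)
  if (nrow(Y) != n)
    stop("outcome and behavior tables have different subject counts",
         call. = FALSE)
  if (!all(is.finite(X)))
    stop("non-finite behavioral scores", call. = FALSE)
  if (n < 6)
    stop("behavioral screen needs at least 6 subjects", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear predictors: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fitted_vals <- qr.fitted(qrX, Y)
  rss <- colSums((Y - fitted_vals)^2)
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  df1 <- ncol(X) - 1L
  df2 <- n - ncol(X)
  Fstat <- ((tss - rss) / df1) / (rss / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  data.frame(F = Fstat, p = p, fitted = p < 0.05, df1 = df1, df2 = df2)
}

#' Pearson chi-square test of independence
#'
#' Chi-square test on an r x c contingency table. In `"auto"` mode the
#' Yates continuity correction is applied iff the table is 2 x 2 --
#' the convention consistent with both reference statistics this
#' package reproduces (an uncorrected 2 x 3 and a corrected 2 x 2).
#' Zero row or column margins are an error.
#'
#' @param tab Matrix of counts (at least 2 x 2, all >= 0).
#' @param correction `"auto"` (Yates iff 2 x 2), `"on"` or `"off"`.
#' @return Object of class `comparison_result` with `kind = "chi2"`,
#'   `statistic`, `df`, `p`, `continuity_correction`, `observed`,
#'   `expected`.
#' @examples
#' chi2_independence(rbind(c(8, 5, 14), c(6, 17, 9)))
#' @export
chi2_independence <- function(tab, correction = c("auto", "on", "off")) {
  correction <- match.arg(correction)
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table must be at least 2 x 2", call. = FALSE)
  if (any(tab < 0)) stop("negative counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin", call. = FALSE)
  is2x2 <- nrow(tab) == 2 && ncol(tab) == 2
  corr <- switch(correction,
                 auto = is2x2,
                 on = { if (!is2x2) warning(
                   "continuity correction only defined for 2 x 2 tables; not applied",
                   call. = FALSE); is2x2 },
                 off = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = corr))
  structure(list(kind = "chi2",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value,
                 continuity_correction = corr,
                 observed = tab,
                 expected = ct$expected),
            class = "comparison_result")
}

#' Reconstruct a 2 x 2 consistency-by-fit table from reported percentages
#'
#' Recovers integer counts from a total N, the percentage of consistent
#' connections and the fitted percentages within each group, all given
#' at reported precision (1 decimal). Resolves rounding by exhaustive
#' integer search constrained to match every reported percentage; if
#' several tables qualify, the one closest to the reported percentages
#' is returned with a warning.
#'
#' @param n_total Total connection count.
#' @param pct_consistent Reported percentage of consistent connections.
#' @param pct_fitted_consistent,pct_fitted_inconsistent Reported fitted
#'   percentages within the consistent / inconsistent group.
#' @param digits Reported precision (default 1 decimal).
#' @return 2 x 2 integer matrix, rows `consistent`/`inconsistent`,
#'   columns `fitted`/`not_fitted`.
#' @examples
#' reconstruct_consistency_table(514, 11.5, 10.2, 4.6)
#' @export
reconstruct_consistency_table <- function(n_total, pct_consistent,
                                          pct_fitted_consistent,
                                          pct_fitted_inconsistent,
                                          digits = 1) {
  matches <- function(count, total, pct)
    total > 0 & abs(100 * count / total - pct) <= 10^(-digits) / 2 + 1e-9
  nc <- which(matches(0:n_total, n_total, pct_consistent)) - 1L
  sols <- list()
  for (ncon in nc) {
    nin <- n_total - ncon
    fc <- which(matches(0:ncon, ncon, pct_fitted_consistent)) - 1L
    fi <- which(matches(0:nin, nin, pct_fitted_inconsistent)) - 1L
    for (a in fc) for (b in fi) {
      err <- (100 * ncon / n_total - pct_consistent)^2 +
        (100 * a / ncon - pct_fitted_consistent)^2 +
        (100 * b / nin - pct_fitted_inconsistent)^2
      sols[[length(sols) + 1L]] <- list(tab = matrix(
        c(a, ncon - a, b, nin - b), 2, 2, byrow = TRUE,
        dimnames = list(c("consistent", "inconsistent"),
                        c("fitted", "not_fitted"))), err = err)
    }
  }
  if (!length(sols))
    stop("no integer table matches the reported percentages", call. = FALSE)
  if (length(sols) > 1) {
    warning(length(sols), " candidate tables match; returning the closest",
            call. = FALSE)
    sols <- sols[order(vapply(sols, `[[`, 0, "err"))]
  }
  sols[[1]]$tab
}

#' Two-sided Mann-Whitney U comparison
#'
#' U statistic from midranks. The p-value uses exact enumeration of the
#' U distribution when both groups have at most 20 observations and
#' there are no ties, and the tie-corrected normal approximation (with
#' continuity correction) otherwise. Group medians are reported.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param continuity Continuity correction in the normal branch
#'   (default TRUE).
#' @return Object of class `comparison_result` with `kind =
#'   "mannwhitneyU"`, `statistic` (U for `x`), `p`, `exact`,
#'   `median_x`, `median_y`, `n_x`, `n_y`.
#' @examples
#' mwu_compare(c(1, 2, 3), c(4, 5, 6))
#' @export
mwu_compare <- function(x, y, continuity = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && nx <= 20 && ny <= 20) {
    p <- if (U > nx * ny / 2)
      2 * stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    else
      2 * stats::pwilcox(U, nx, ny)
    exact <- TRUE
  } else {
    mu <- nx * ny / 2
    N <- nx + ny
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- U - mu
    if (continuity) z <- z - sign(z) * 0.5
    z <- z / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  structure(list(kind = "mannwhitneyU", statistic = U, p = min(p, 1),
                 exact = exact,
                 median_x = stats::median(x), median_y = stats::median(y),
                 n_x = nx, n_y = ny,
                 continuity_correction = !exact && continuity),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$kind == "chi2") {
    cat(sprintf("Chi-square independence: X2(%d) = %.4g, p = %.4g%s\n",
                x$df, x$statistic, x$p,
                if (x$continuity_correction) " (Yates-corrected)" else ""))
  } else {
    cat(sprintf("Mann-Whitney: U = %g, p = %.4g (%s); medians %.4g vs %.4g\n",
                x$statistic, x$p,
                if (x$exact) "exact" else "normal approx.",
                x$median_x, x$median_y))
  }
  invisible(x)
}

#' Absolute mean strength of a parcel edge
#'
#' The absolute value of the mean, over subjects and both sessions, of
#' the summed parcel-level contrast (absolute value applied after
#' averaging).
#'
#' @param series A `parcel_edge_series` matrix.
#' @return Nonnegative scalar.
#' @export
strength_summary <- function(series) {
  abs(mean(series))
}

#' Laterality of parcel edges
#'
#' `"left"` if both parcels are in the left hemisphere, `"right"` if
#' both in the right, `"bilateral"` otherwise. Vectorized.
#'
#' @param parcel_a,parcel_b Parcel id vectors.
#' @param parcellation Parcellation data.frame.
#' @return Character vector.
#' @export
edge_laterality <- function(parcel_a, parcel_b, parcellation) {
  ha <- parcellation$hemisphere[match(parcel_a, parcellation$parcel_id)]
  hb <- parcellation$hemisphere[match(parcel_b, parcellation$parcel_id)]
  if (anyNA(ha) || anyNA(hb))
    stop("unresolvable parcel id", call. = FALSE)
  ifelse(ha != hb, "bilateral", ifelse(ha == "left", "left", "right"))
}

#' Pooled property report: consistent vs. inconsistent connections
#'
#' Pools edges over bands and windows and compares the consistent to
#' the inconsistent group: (a) 2 x 2 consistency-by-behavioral-fit
#' chi-square, (b) laterality-by-direction chi-square over the
#' consistent edges, (c) Mann-Whitney comparisons of absolute strength,
#' direct streamline count, structural shortest path length (finite
#' values only; infinite entries counted) and edge betweenness, with
#' group medians. Comparisons whose groups are empty or degenerate are
#' skipped with a notice.
#'
#' @param edges data.frame with one row per pooled edge and columns
#'   `label` (`"consistent"`/`"inconsistent"`), `fitted` (logical),
#'   `direction`, `laterality`, `strength`, and optionally
#'   `mean_streamlines`, `mean_spl`, `mean_ebc`.
#' @param chi2_correction Correction mode passed to
#'   [chi2_independence()].
#' @return Object of class `property_report`: list with `n_edges`,
#'   `n_consistent`, `comparisons` (named list of `comparison_result`),
#'   `medians`, `notices`.
#' @export
property_report <- function(edges, chi2_correction = "auto") {
  stopifnot(is.data.frame(edges),
            all(c("label", "fitted", "direction", "laterality",
                  "strength") %in% names(edges)))
  cons <- edges$label == "consistent"
  comparisons <- list()
  notices <- character(0)
  medians <- list()

  if (!any(cons) || all(cons)) {
    notices <- c(notices,
                 "consistency-by-fit chi-square skipped: one group empty")
  } else {
    tab <- rbind(consistent = c(fitted = sum(cons & edges$fitted),
                                not_fitted = sum(cons & !edges$fitted)),
                 inconsistent = c(sum(!cons & edges$fitted),
                                  sum(!cons & !edges$fitted)))
    if (any(colSums(tab) == 0)) {
      notices <- c(notices,
                   "consistency-by-fit chi-square skipped: zero margin")
    } else {
      comparisons$consistency_fit <- chi2_independence(tab, chi2_correction)
    }
  }

  lat <- table(factor(edges$direction[cons],
                      levels = c("increase", "decrease")),
               factor(edges$laterality[cons],
                      levels = c("left", "right", "bilateral")))
  lat <- lat[rowSums(lat) > 0, colSums(lat) > 0, drop = FALSE]
  if (nrow(lat) < 2 || ncol(lat) < 2) {
    notices <- c(notices,
                 "laterality-by-direction chi-square skipped: degenerate table")
  } else {
    comparisons$laterality_direction <-
      chi2_independence(unclass(lat), chi2_correction)
  }

  mwu_var <- function(var) {
    a <- edges[[var]][cons]
    b <- edges[[var]][!cons]
    n_inf <- sum(is.infinite(c(a, b)))
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (!length(a) || !length(b)) {
      notices <<- c(notices, paste0(var,
        " comparison skipped: a group has no finite values"))
      return(NULL)
    }
    if (n_inf)
      notices <<- c(notices, sprintf(
        "%s: %d infinite value(s) excluded from comparison", var, n_inf))
    medians[[var]] <<- c(consistent = stats::median(a),
                         inconsistent = stats::median(b))
    mwu_compare(a, b)
  }
  for (var in intersect(c("strength", "mean_streamlines", "mean_spl",
                          "mean_ebc"), names(edges))) {
    res <- mwu_var(var)
    if (!is.null(res)) comparisons[[var]] <- res
  }

  structure(list(n_edges = nrow(edges),
                 n_consistent = sum(cons),
                 pct_consistent = 100 * mean(cons),
                 comparisons = comparisons,
                 medians = medians,
                 notices = notices),
            class = "property_report")
}

#' @export
print.property_report <- function(x, ...) {
  cat(sprintf("Property report: %d pooled edges, %d consistent (%.1f%%)\n",
              x$n_edges, x$n_consistent, x$pct_consistent))
  for (nm in names(x$comparisons)) {
    cat(sprintf("  %s: ", nm)); print(x$comparisons[[nm]])
  }
  for (nt in x$notices) cat("  note:", nt, "\n")
  invisible(x)
}
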