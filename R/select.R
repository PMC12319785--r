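# Connection selection: mass-univariate paired t-tests on session-1
# task contrasts, endpoint-distance filter, single-linkage bundle
# clustering, parcel-pair mapping, parcel-level aggregation, modulation
# direction, and the task power screen.

#' Uncorrected selection thresholds
#'
#' The two named selection presets: A (p < 1e-3, uncorrected) and
#' B (p < 1e-4, uncorrected).
#'
#' @param preset `"A"` or `"B"`.
#' @return The alpha level.
#' @export
selection_alpha <- function(preset = c("A", "B")) {
  c(A = 1e-3, B = 1e-4)[[match.arg(preset)]]
}

#' Paired t-tests on task contrasts for all connections
#'
#' For every connection, a paired t-test over subjects of the
#' naming-minus-visual coherence difference in one session (the first,
#' by design, so that selection stays independent of the second session
#' used by the consistency analysis). Two-sided p-values from the
#' t-distribution with n - 1 df. Connections with zero-variance
#' differences are flagged degenerate (t and p set to `NA`) and are
#' excluded by [threshold_connections()].
#'
#' @param tensor A `conn_tensor`.
#' @param band,window Band and window names.
#' @param session Session used for selection (default 1).
#' @return data.frame with columns `connection`, `i`, `j`,
#'   `mean_contrast`, `t`, `p`, `degenerate`.
#' @export
paired_t_contrast <- function(tensor, band, window, session = 1L) {
  stopifnot(inherits(tensor, "conn_tensor"))
  if (tensor$n_subjects < 3)
    stop("paired t-tests need at least 3 subjects", call. = FALSE)
  d <- tensor$values[, , session, "naming", band, window] -
       tensor$values[, , session, "visual", band, window]
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  n <- ncol(d)
  m <- rowMeans(d)
  ss <- pmax(rowSums(d * d) - n * m * m, 0)
  s <- sqrt(ss / (n - 1))
  degenerate <- s <= 0
  tt <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  tt[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  if (any(degenerate))
    message(sum(degenerate), " degenerate (zero-variance) connection(s) flagged")
  data.frame(connection = seq_len(nrow(d)),
             i = tensor$pairs[, 1], j = tensor$pairs[, 2],
             mean_contrast = m, t = tt, p = p, degenerate = degenerate)
}

# Euclidean endpoint distance (mm) of each connection
connection_lengths <- function(stats, geometry) {
  co <- as.matrix(geometry[, c("x", "y", "z")])
  sqrt(rowSums((co[stats$i, , drop = FALSE] -
                co[stats$j, , drop = FALSE])^2))
}

#' Threshold connections by significance and endpoint distance
#'
#' Keeps connections with p below `alpha` whose endpoint distance is at
#' least `min_distance_mm` (the minimum-distance limit is inclusive:
#' exactly 4 cm is retained). Degenerate connections are dropped.
#'
#' @param stats Output of [paired_t_contrast()].
#' @param geometry Geometry data.frame (same grid as the stats).
#' @param alpha Significance level; see [selection_alpha()].
#' @param min_distance_mm Minimum endpoint distance in mm (default 40,
#'   i.e. 4 cm).
#' @return Subset of `stats` with an added `distance_mm` column. An
#'   empty result is valid (downstream stages no-op).
#' @export
threshold_connections <- function(stats, geometry, alpha = 1e-3,
                                  min_distance_mm = 40) {
  stopifnot(alpha > 0, alpha < 1)
  dist <- connection_lengths(stats, geometry)
  keep <- !stats$degenerate & !is.na(stats$p) & stats$p < alpha &
    dist >= min_distance_mm
  out <- stats[keep, , drop = FALSE]
  out$distance_mm <- dist[keep]
  attr(out, "alpha") <- alpha
  out
}

# inter-connection distance between blocks of connections:
# d(c1, c2) = min over the two endpoint pairings of the larger
# endpoint-to-endpoint distance (connections are undirected)
.conn_dist_block <- function(A1, B1, A2, B2) {
  cross <- function(X, Y) {
    d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) +
      outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * X %*% t(Y)
    sqrt(pmax(d2, 0))
  }
  pmin(pmax(cross(A1, A2), cross(B1, B2)),
       pmax(cross(A1, B2), cross(B1, A2)))
}

#' Cluster selected connections into spatial bundles
#'
#' Links two connections when their inter-connection distance is at most
#' `max_link_mm`; bundles are the connected components of the resulting
#' graph (single linkage). The inter-connection distance of two
#' undirected connections is the smaller, over the two ways of pairing
#' their endpoints, of the larger endpoint-to-endpoint distance.
#' Components with fewer than `min_size` members are discarded.
#'
#' @param connections data.frame with grid-point columns `i`, `j`
#'   (e.g. from [threshold_connections()]).
#' @param geometry Geometry data.frame.
#' @param max_link_mm Single-linkage threshold in mm (default 13,
#'   i.e. 1.3 cm).
#' @param min_size Minimum bundle membership (default 20).
#' @return List of integer vectors (row indices into `connections`),
#'   one per retained bundle, ordered by decreasing size.
#' @export
cluster_bundles <- function(connections, geometry, max_link_mm = 13,
                            min_size = 20) {
  m <- nrow(connections)
  if (m == 0) return(list())
  co <- as.matrix(geometry[, c("x", "y", "z")])
  A <- co[connections$i, , drop = FALSE]
  B <- co[connections$j, , drop = FALSE]
  block <- 1024L
  from <- integer(0); to <- integer(0)
  for (start in seq(1L, m, by = block)) {
    idx <- start:min(start + block - 1L, m)
    D <- .conn_dist_block(A, B, A[idx, , drop = FALSE],
                          B[idx, , drop = FALSE])
    hit <- which(D <= max_link_mm, arr.ind = TRUE)
    from <- c(from, hit[, 1])
    to <- c(to, idx[hit[, 2]])
  }
  keep <- from < to
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(from[keep], to[keep]))
  comp <- igraph::components(g)
  bundles <- split(seq_len(m), comp$membership)
  bundles <- bundles[lengths(bundles) >= min_size]
  bundles <- bundles[order(lengths(bundles), decreasing = TRUE)]
  unname(bundles)
}

#' Map bundles to parcel-level edges
#'
#' Emits a parcel edge \{a, b\} whenever any bundle member has one
#' endpoint in parcel a and the other in parcel b. Duplicate pairs are
#' merged; self-pairs and pairs touching excluded (anterior) parcels are
#' dropped.
#'
#' @param bundles List of member index vectors from [cluster_bundles()].
#' @param connections The data.frame the bundle indices refer to.
#' @param geometry,parcellation Geometry and parcellation data.frames.
#' @param band,window Labels attached to the emitted edges.
#' @return data.frame with columns `parcel_a`, `parcel_b`
#'   (`parcel_a < parcel_b`), `band`, `window`.
#' @export
bundles_to_parcel_edges <- function(bundles, connections, geometry,
                                    parcellation, band = NA, window = NA) {
  if (!length(bundles))
    return(data.frame(parcel_a = integer(0), parcel_b = integer(0),
                      band = character(0), window = character(0)))
  members <- unlist(bundles, use.names = FALSE)
  pa <- geometry$parcel_id[connections$i[members]]
  pb <- geometry$parcel_id[connections$j[members]]
  a <- pmin(pa, pb); b <- pmax(pa, pb)
  ok <- a != b &
    parcellation$included[match(a, parcellation$parcel_id)] &
    parcellation$included[match(b, parcellation$parcel_id)]
  a <- a[ok]; b <- b[ok]
  key <- !duplicated(paste(a, b))
  out <- data.frame(parcel_a = a[key], parcel_b = b[key],
                    band = band, window = window)
  out[order(out$parcel_a, out$parcel_b), , drop = FALSE]
}

#' Aggregate a parcel edge to its subject-by-session contrast series
#'
#' Sums the naming-minus-visual coherence difference over all grid
#' pairs in the tensor's connection index with one endpoint in each
#' parcel (all possible inter-parcel connections, not only the
#' t-test-selected ones), per subject and session.
#'
#' @param tensor A `conn_tensor`.
#' @param geometry Geometry data.frame.
#' @param parcel_a,parcel_b Parcel ids of the edge.
#' @param band,window Band and window names.
#' @return `n_subjects x 2` matrix (class `parcel_edge_series`) of
#'   summed contrasts, columns = sessions.
#' @export
parcel_aggregate <- function(tensor, geometry, parcel_a, parcel_b,
                             band, window) {
  stopifnot(inherits(tensor, "conn_tensor"), parcel_a != parcel_b)
  pg <- geometry$parcel_id
  pa <- pg[tensor$pairs[, 1]]
  pb <- pg[tensor$pairs[, 2]]
  sel <- which((pa == parcel_a & pb == parcel_b) |
               (pa == parcel_b & pb == parcel_a))
  if (!length(sel))
    stop(sprintf("no grid pairs between parcels %s and %s in the connection index",
                 parcel_a, parcel_b), call. = FALSE)
  out <- matrix(NA_real_, tensor$n_subjects, 2,
                dimnames = list(NULL, session = c("1", "2")))
  for (d in 1:2) {
    v <- tensor$values[sel, , d, "naming", band, window] -
         tensor$values[sel, , d, "visual", band, window]
    if (is.null(dim(v))) v <- matrix(v, nrow = 1)
    out[, d] <- colSums(v)
  }
  structure(out, class = c("parcel_edge_series", "matrix"),
            parcel_a = parcel_a, parcel_b = parcel_b,
            band = band, window = window, n_grid_pairs = length(sel))
}

#' Modulation direction of a parcel edge
#'
#' `"increase"` if the group mean of the session-1 summed contrast is
#' positive, `"decrease"` otherwise. An exact zero mean (probability
#' zero under the generator) is labeled `"increase"` with a warning.
#'
#' @param series A `parcel_edge_series` matrix.
#' @param session Session defining the direction (default 1).
#' @return `"increase"` or `"decrease"`.
#' @export
modulation_direction <- function(series, session = 1L) {
  m <- mean(series[, session])
  if (m == 0) {
    warning("group-mean contrast exactly zero; labeling 'increase'",
            call. = FALSE)
    return("increase")
  }
  if (m > 0) "increase" else "decrease"
}

#' Screen parcels for task power differences
#'
#' Flags parcel/band/window combinations where the relative power
#' difference between the tasks, `|P_naming - P_visual|` normalized by
#' the condition mean, exceeds `threshold` for at least `min_subjects`
#' subjects ("more than four"). Zero power in both tasks gives a
#' relative difference of 0. Flagged parcels are reported, not
#' auto-excluded.
#'
#' @param power 5-d array `[subject, parcel, band, window, task]` with
#'   task dimnames containing `"naming"` and `"visual"`; values >= 0.
#' @param threshold Relative-difference threshold (default 0.20).
#' @param min_subjects Minimum number of subjects above threshold for a
#'   flag (default 5).
#' @return data.frame of flagged combinations with columns `parcel`,
#'   `band`, `window`, `n_subjects_above`.
#' @export
power_screen <- function(power, threshold = 0.20, min_subjects = 5L) {
  stopifnot(length(dim(power)) == 5, all(power >= 0, na.rm = TRUE))
  pn <- power[, , , , "naming", drop = FALSE]
  pv <- power[, , , , "visual", drop = FALSE]
  denom <- (pn + pv) / 2
  r <- abs(pn - pv) / denom
  r[denom == 0] <- 0
  above <- r > threshold
  counts <- apply(above, c(2, 3, 4), sum)
  hit <- which(counts >= min_subjects, arr.ind = TRUE)
  dn <- dimnames(power)
  lab <- function(k, d) if (!is.null(dn[[d + 1]])) dn[[d + 1]][k] else k
  data.frame(parcel = lab(hit[, 1], 1),
             band = lab(hit[, 2], 2),
             window = lab(hit[, 3], 3),
             n_subjects_above = counts[hit])
}

#' Run the full connection-selection stage
#'
#' For every band and window: paired t-tests on session-1 contrasts,
#' significance + distance thresholding, bundle clustering, mapping to
#' parcel edges, parcel-level aggregation and direction labeling.
#'
#' @param tensor A `conn_tensor`.
#' @param geometry,parcellation Geometry and parcellation data.frames.
#' @param alpha Uncorrected selection threshold (see [selection_alpha()]).
#' @param min_distance_mm,max_link_mm,min_size Filter and clustering
#'   parameters (defaults 40 mm, 13 mm, 20).
#' @param verbose Emit per-stage edge counts (default TRUE).
#' @return List with `edges` (data.frame: parcel pair, band, window,
#'   direction, `n_grid_pairs`), `series` (list of
#'   `parcel_edge_series`, one per edge row) and `counts` (per
#'   band/window bookkeeping of connections surviving each filter).
#' @export
select_connections <- function(tensor, geometry, parcellation,
                               alpha = selection_alpha("A"),
                               min_distance_mm = 40, max_link_mm = 13,
                               min_size = 20, verbose = TRUE) {
  bn <- names(tensor$bands)
  wn <- names(tensor$windows)
  edges <- list(); series <- list(); counts <- list()
  for (b in bn) for (w in wn) {
    st <- paired_t_contrast(tensor, b, w)
    sel <- threshold_connections(st, geometry, alpha, min_distance_mm)
    bun <- cluster_bundles(sel, geometry, max_link_mm, min_size)
    pe <- bundles_to_parcel_edges(bun, sel, geometry, parcellation, b, w)
    counts[[paste(b, w, sep = ".")]] <-
      data.frame(band = b, window = w, n_connections = nrow(st),
                 n_selected = nrow(sel),
                 n_bundled = length(unlist(bun)),
                 n_bundles = length(bun), n_parcel_edges = nrow(pe))
    if (verbose)
      message(sprintf("%s/%s: %d selected, %d bundle(s), %d parcel edge(s)",
                      b, w, nrow(sel), length(bun), nrow(pe)))
    if (!nrow(pe)) next
    for (r in seq_len(nrow(pe))) {
      s <- parcel_aggregate(tensor, geometry, pe$parcel_a[r], pe$parcel_b[r],
                            b, w)
      pe$direction[r] <- modulation_direction(s)
      pe$n_grid_pairs[r] <- attr(s, "n_grid_pairs")
      series[[length(series) + 1L]] <- s
    }
    edges[[length(edges) + 1L]] <- pe
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(parcel_a = integer(0), parcel_b = integer(0),
               band = character(0), window = character(0),
               direction = character(0), n_grid_pairs = integer(0))
  rownames(edges) <- NULL
  list(edges = edges, series = series,
       counts = do.call(rbind, c(counts, list(make.row.names = FALSE))))
}
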