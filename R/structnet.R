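# Structural-connectome metrics: streamline-weight to length mapping,
# weighted shortest paths (Dijkstra), edge betweenness centrality with
# fractional credit for tied shortest paths, and per-edge structural
# profiles averaged over subjects.

#' Convert a streamline-weight matrix to a length graph
#'
#' Stronger connections are topologically closer: edge length is the
#' reciprocal of the streamline weight (the usual connectivity-toolbox
#' convention); zero-weight pairs have no edge (infinite length). An
#' alternative `-log(w / max(w))` mapping is available.
#'
#' @param W Symmetric nonnegative weight matrix with zero diagonal.
#' @param mode `"reciprocal"` (default) or `"neglog"`.
#' @return Object of class `length_graph`: list with `lengths` (matrix,
#'   `Inf` for absent edges), `weights`, `nodes`.
#' @export
weight_to_length <- function(W, mode = c("reciprocal", "neglog")) {
  mode <- match.arg(mode)
  W <- as.matrix(W)
  if (!isSymmetric(unname(W), tol = 1e-8))
    stop("weight matrix must be symmetric", call. = FALSE)
  if (any(W < 0)) stop("negative weights", call. = FALSE)
  if (any(diag(W) != 0)) stop("diagonal must be zero", call. = FALSE)
  L <- matrix(Inf, nrow(W), ncol(W), dimnames = dimnames(W))
  pos <- W > 0
  L[pos] <- switch(mode,
                   reciprocal = 1 / W[pos],
                   neglog = -log(W[pos] / max(W)))
  diag(L) <- 0
  nodes <- rownames(W)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(W)))
  structure(list(lengths = L, weights = W, nodes = nodes),
            class = "length_graph")
}

# single-source Dijkstra on a dense length matrix; returns list with
# dist, sigma (shortest-path counts), preds (predecessor lists) and the
# settle order -- the machinery shared by path lengths and betweenness
.dijkstra <- function(L, s, tol = 1e-12) {
  n <- nrow(L)
  dist <- rep(Inf, n); dist[s] <- 0
  sigma <- numeric(n); sigma[s] <- 1
  preds <- vector("list", n)
  done <- logical(n)
  order_out <- integer(0)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    order_out <- c(order_out, u)
    w <- L[u, ]
    nb <- which(is.finite(w) & !done & seq_len(n) != u)
    for (v in nb) {
      nd <- dist[u] + w[v]
      eps <- tol * max(1, abs(nd))
      if (nd < dist[v] - eps) {
        dist[v] <- nd
        sigma[v] <- sigma[u]
        preds[[v]] <- u
      } else if (abs(nd - dist[v]) <= eps) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_out)
}

#' Weighted shortest path lengths
#'
#' Minimum total edge length between nodes of a [weight_to_length()]
#' graph, by Dijkstra's algorithm. `Inf` for disconnected pairs; 0 for
#' a node to itself.
#'
#' @param graph A `length_graph`.
#' @param from,to Node names or indices. With both: a scalar. With only
#'   `from`: a vector of distances to all nodes. With neither: the full
#'   symmetric matrix.
#' @return Numeric scalar, vector, or matrix.
#' @export
shortest_path_length <- function(graph, from = NULL, to = NULL) {
  stopifnot(inherits(graph, "length_graph"))
  L <- graph$lengths
  resolve <- function(x) {
    i <- if (is.character(x)) match(x, graph$nodes) else as.integer(x)
    if (anyNA(i) || any(i < 1) || any(i > nrow(L)))
      stop("unknown node", call. = FALSE)
    i
  }
  if (is.null(from)) {
    n <- nrow(L)
    D <- matrix(Inf, n, n, dimnames = list(graph$nodes, graph$nodes))
    for (s in seq_len(n)) D[s, ] <- .dijkstra(L, s)$dist
    return(D)
  }
  s <- resolve(from)
  d <- .dijkstra(L, s)$dist
  names(d) <- graph$nodes
  if (is.null(to)) d else unname(d[resolve(to)])
}

#' Edge betweenness centrality on a weighted graph
#'
#' For every edge, the number of shortest paths (by total length)
#' between all unordered node pairs that traverse it, with fractional
#' credit when multiple shortest paths tie (Brandes accumulation over
#' Dijkstra trees). Disconnected pairs contribute nothing. Counts are
#' unnormalized by default; `normalize = TRUE` divides by
#' `n(n-1)/2`.
#'
#' @param graph A `length_graph`.
#' @param normalize Divide by the number of node pairs (default FALSE).
#' @return Symmetric matrix of per-edge centralities (0 where no edge).
#' @export
edge_betweenness <- function(graph, normalize = FALSE) {
  stopifnot(inherits(graph, "length_graph"))
  L <- graph$lengths
  n <- nrow(L)
  EBC <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  for (s in seq_len(n)) {
    dj <- .dijkstra(L, s)
    delta <- numeric(n)
    for (w in rev(dj$order)) {
      for (u in dj$preds[[w]]) {
        c_uw <- dj$sigma[u] / dj$sigma[w] * (1 + delta[w])
        EBC[u, w] <- EBC[u, w] + c_uw
        EBC[w, u] <- EBC[w, u] + c_uw
        delta[u] <- delta[u] + c_uw
      }
    }
  }
  EBC <- EBC / 2  # each unordered pair was counted from both sources
  if (normalize) EBC <- EBC * 2 / (n * (n - 1))
  EBC
}

#' Structural profiles of parcel edges across subjects
#'
#' For each edge and subject: the direct streamline weight, the
#' weighted shortest path length between the two parcels, and that
#' edge's betweenness centrality (0 if the direct edge is absent);
#' averaged across subjects. A subject in whom the pair is disconnected
#' contributes `Inf` to the path length, making the mean `Inf`; the
#' count of finite subjects is reported alongside.
#'
#' @param edges data.frame with columns `parcel_a`, `parcel_b`.
#' @param connectomes List of symmetric weight matrices (one per
#'   subject) with parcel ids as dimnames.
#' @param mode Weight-to-length mapping (see [weight_to_length()]).
#' @return data.frame with one row per edge: `parcel_a`, `parcel_b`,
#'   `mean_streamlines`, `mean_spl`, `n_finite_spl`, `mean_ebc`.
#' @export
structural_profiles <- function(edges, connectomes,
                                mode = "reciprocal") {
  stopifnot(is.data.frame(edges), length(connectomes) >= 1)
  key <- paste(pmin(edges$parcel_a, edges$parcel_b),
               pmax(edges$parcel_a, edges$parcel_b))
  uniq <- !duplicated(key)
  ua <- as.character(pmin(edges$parcel_a, edges$parcel_b)[uniq])
  ub <- as.character(pmax(edges$parcel_a, edges$parcel_b)[uniq])
  ukey <- key[uniq]
  m <- length(ukey)
  acc_w <- matrix(0, m, length(connectomes))
  acc_spl <- matrix(0, m, length(connectomes))
  acc_ebc <- matrix(0, m, length(connectomes))
  for (s in seq_along(connectomes)) {
    W <- connectomes[[s]]
    nodes <- rownames(W)
    ia <- match(ua, nodes); ib <- match(ub, nodes)
    if (anyNA(ia) || anyNA(ib))
      stop("edge parcels missing from connectome node set of subject ", s,
           call. = FALSE)
    g <- weight_to_length(W, mode)
    D <- shortest_path_length(g)
    E <- edge_betweenness(g)
    acc_w[, s] <- W[cbind(ia, ib)]
    acc_spl[, s] <- D[cbind(ia, ib)]
    acc_ebc[, s] <- E[cbind(ia, ib)]
  }
  prof <- data.frame(parcel_a = as.integer(ua), parcel_b = as.integer(ub),
                     mean_streamlines = rowMeans(acc_w),
                     mean_spl = rowMeans(acc_spl),
                     n_finite_spl = rowSums(is.finite(acc_spl)),
                     mean_ebc = rowMeans(acc_ebc))
  prof[match(key, ukey), , drop = FALSE]
}

#' Structural profile of one parcel edge
#'
#' Single-edge convenience wrapper around [structural_profiles()].
#'
#' @param parcel_a,parcel_b Parcel ids.
#' @param connectomes List of subject weight matrices.
#' @param mode Weight-to-length mapping.
#' @return One-row data.frame (see [structural_profiles()]).
#' @export
structural_profile <- function(parcel_a, parcel_b, connectomes,
                               mode = "reciprocal") {
  structural_profiles(data.frame(parcel_a = parcel_a, parcel_b = parcel_b),
                      connectomes, mode)
}
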