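# Independent oracles used to validate the package's own
# implementations: brute-force / enumeration / closed-form routes that
# share no code with the functions they check.

# Floyd-Warshall all-pairs shortest paths on a dense length matrix
oracle_floyd_warshall <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# brute-force edge betweenness by enumerating all simple paths between
# every node pair (feasible for n <= 8); fractional credit for ties
oracle_edge_betweenness <- function(L, tol = 1e-9) {
  n <- nrow(L)
  EBC <- matrix(0, n, n)
  all_paths <- function(from, to) {
    out <- list()
    walk <- function(path, len) {
      u <- path[length(path)]
      if (u == to) { out[[length(out) + 1L]] <<- list(path = path, len = len); return() }
      for (v in seq_len(n)) {
        if (v %in% path) next
        if (!is.finite(L[u, v])) next
        walk(c(path, v), len + L[u, v])
      }
    }
    walk(from, 0)
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- all_paths(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, `[[`, 0, "len")
    best <- min(lens)
    hit <- which(lens <= best + tol * max(1, best))
    for (h in hit) {
      pth <- ps[[h]]$path
      for (e in seq_len(length(pth) - 1)) {
        a <- pth[e]; b <- pth[e + 1]
        EBC[a, b] <- EBC[a, b] + 1 / length(hit)
        EBC[b, a] <- EBC[b, a] + 1 / length(hit)
      }
    }
  }
  EBC
}

# transitive closure of the "linked at threshold" relation: brute-force
# single-linkage components over a full pairwise distance matrix
oracle_single_linkage <- function(D, thr) {
  A <- (D <= thr) * 1
  diag(A) <- 1
  repeat {
    A2 <- ((A %*% A) > 0) * 1
    if (identical(A2, A)) break
    A <- A2
  }
  comp <- integer(nrow(A))
  cur <- 0L
  for (i in seq_len(nrow(A))) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[A[i, ] > 0] <- cur
    }
  }
  comp
}

# pairwise inter-connection distances computed naively (loops), the
# definition the clustering is supposed to implement
oracle_conn_dist <- function(connections, geometry) {
  co <- as.matrix(geometry[, c("x", "y", "z")])
  m <- nrow(connections)
  D <- matrix(0, m, m)
  ed <- function(p, q) sqrt(sum((co[p, ] - co[q, ])^2))
  for (a in seq_len(m)) for (b in seq_len(m)) {
    i1 <- connections$i[a]; j1 <- connections$j[a]
    i2 <- connections$i[b]; j2 <- connections$j[b]
    D[a, b] <- min(max(ed(i1, i2), ed(j1, j2)),
                   max(ed(i1, j2), ed(j1, i2)))
  }
  D
}

# exhaustive two-sided Mann-Whitney p by enumerating every assignment
# of the pooled observations to the two groups
oracle_mwu_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
  pl <- mean(us <= u_obs + 1e-9)
  pu <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(pl, pu)))
}

# vectorized Monte-Carlo sampler of the ICC(3,1) sampling distribution
# for n subjects, k = 2 sessions at true consistency rho
oracle_icc_sample <- function(rho, n, reps) {
  sb <- sqrt(rho / (1 - rho))
  subj <- matrix(stats::rnorm(reps * n, 0, sb), reps, n)
  x1 <- subj + matrix(stats::rnorm(reps * n), reps, n)
  x2 <- subj + matrix(stats::rnorm(reps * n), reps, n)
  g <- (rowMeans(x1) + rowMeans(x2)) / 2
  sm <- (x1 + x2) / 2
  ss_subj <- 2 * rowSums((sm - g)^2)
  ss_sess <- n * ((rowMeans(x1) - g)^2 + (rowMeans(x2) - g)^2)
  ss_tot <- rowSums((x1 - g)^2 + (x2 - g)^2)
  bms <- ss_subj / (n - 1)
  ems <- pmax(ss_tot - ss_subj - ss_sess, 0) / (n - 1)
  (bms - ems) / (bms + ems)
}

# independent graph-library route: igraph edge betweenness / distances
# from a weight matrix (lengths = reciprocal weights)
oracle_igraph_ebc <- function(W) {
  n <- nrow(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = idx[, 1], to = idx[, 2], weight = 1 / W[idx]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  eb <- igraph::edge_betweenness(g, directed = FALSE,
                                 weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(g)
  E <- matrix(0, n, n)
  for (k in seq_len(nrow(el))) {
    a <- as.integer(el[k, 1]); b <- as.integer(el[k, 2])
    E[a, b] <- E[b, a] <- eb[k]
  }
  E
}

# random sparse symmetric length graph for the graph-metric checks
rand_length_graph <- function(n, p_edge = 0.7) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- stats::runif(length(ut)) < p_edge
  W[ut[on]] <- stats::rlnorm(sum(on))
  W <- W + t(W)
  weight_to_length(W)
}
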