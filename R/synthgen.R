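# Synthetic-data generators: geometry/parcellation, connectivity tensor,
# behavior table, structural connectomes. All draws are made on seeded
# substreams of design$seed so each generator is individually
# deterministic and independent of call order.

.seed_for <- function(design, stage) {
  off <- c(geometry = 101L, connectivity = 202L, behavior = 303L,
           structural = 404L)[[stage]]
  (design$seed + off) %% .Machine$integer.max
}

#' Generate grid geometry and parcellation
#'
#' Places `n_grid_points` source points on two hemispheric shells
#' (left: x < 0, right: x > 0) of radius `shell_radius_mm` with a small
#' radial jitter, and partitions each hemisphere into
#' `n_parcels_per_hemi` parcels by nearest-seed-centroid assignment.
#' Parcel seed centroids are themselves sampled grid points, so every
#' parcel is non-empty and every point's parcel centroid is its nearest
#' centroid within the hemisphere. Parcels whose centroid lies anterior
#' of `anterior_exclude_mm` (y-coordinate) are flagged `included = FALSE`.
#'
#' @param design A [synth_design()].
#' @return A list with components `geometry` (data.frame: `point_id`,
#'   `x`, `y`, `z` in mm, `hemisphere`, `parcel_id`) and `parcellation`
#'   (data.frame: `parcel_id`, `name`, `hemisphere`, `included`, and
#'   centroid coordinates `cx`, `cy`, `cz`).
#' @export
gen_geometry <- function(design) {
  stopifnot(inherits(design, "synth_design"))
  set.seed(.seed_for(design, "geometry"))
  n <- design$n_grid_points
  k <- design$n_parcels_per_hemi
  n_left <- n %/% 2L
  n_right <- n - n_left
  if (n_left < k || n_right < k)
    stop("invalid design: too few grid points for requested parcels",
         call. = FALSE)

  shell_points <- function(m, sign_x) {
    v <- matrix(stats::rnorm(3 * m), m, 3)
    v <- v / sqrt(rowSums(v^2))
    v[, 1] <- sign_x * abs(v[, 1])
    r <- design$shell_radius_mm * stats::runif(m, 0.92, 1.05)
    v * r
  }
  pts <- rbind(shell_points(n_left, -1), shell_points(n_right, +1))
  hemi <- rep(c("left", "right"), c(n_left, n_right))

  # parcel seeds are sampled points of the same hemisphere
  seed_left <- sample(which(hemi == "left"), k)
  seed_right <- sample(which(hemi == "right"), k)
  seeds <- c(seed_left, seed_right)
  centroids <- pts[seeds, , drop = FALSE]
  parcel_hemi <- rep(c("left", "right"), each = k)

  parcel_id <- integer(n)
  for (h in c("left", "right")) {
    idx <- which(hemi == h)
    cid <- which(parcel_hemi == h)
    d2 <- outer(rowSums(pts[idx, , drop = FALSE]^2), rep(1, length(cid))) +
      outer(rep(1, length(idx)), rowSums(centroids[cid, , drop = FALSE]^2)) -
      2 * pts[idx, , drop = FALSE] %*% t(centroids[cid, , drop = FALSE])
    parcel_id[idx] <- cid[max.col(-d2, ties.method = "first")]
  }

  geometry <- data.frame(point_id = seq_len(n),
                         x = pts[, 1], y = pts[, 2], z = pts[, 3],
                         hemisphere = hemi, parcel_id = parcel_id)
  parcellation <- data.frame(
    parcel_id = seq_len(2L * k),
    name = paste0(ifelse(parcel_hemi == "left", "L", "R"),
                  formatC(rep(seq_len(k), 2), width = 2, flag = "0")),
    hemisphere = parcel_hemi,
    included = centroids[, 2] <= design$anterior_exclude_mm,
    cx = centroids[, 1], cy = centroids[, 2], cz = centroids[, 3])
  for (h in c("left", "right"))
    if (!any(parcellation$included & parcellation$hemisphere == h))
      stop("anterior exclusion left no included parcel in ", h,
           " hemisphere", call. = FALSE)
  list(geometry = geometry, parcellation = parcellation)
}

# all unordered grid-point pairs i < j as a 2-column integer matrix
all_grid_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) seq.int(k + 1L, n)),
              use.names = FALSE)
  cbind(i = i, j = j)
}

# behavioral scores on their own substream: n_subjects x 3 iid N(0,1)
.behavior_scores <- function(design) {
  set.seed(.seed_for(design, "behavior"))
  matrix(stats::rnorm(design$n_subjects * 3L), design$n_subjects, 3L,
         dimnames = list(NULL, c("fluency_s", "fluency_animal",
                                 "ran_ras_mean")))
}

# behavioral axis entering coupled latents: mean of the three scores
.behavior_axis <- function(scores) rowMeans(scores)

#' Generate the synthetic connectivity tensor
#'
#' Draws coherence values for every grid-point pair (i < j), subject,
#' session, task, band and window. For each grid pair belonging to a
#' planted parcel pair in a given band/window, subject `s` draws a
#' latent contrast `delta ~ N(mu, sigma_b^2)` (plus a behavioral term
#' for coupled edges); the observed session-`d` contrast is
#' `delta + eps`, `eps ~ N(0, sigma_e^2)` i.i.d. Values are realized as
#' `visual = baseline` and `naming = baseline + contrast` with baseline
#' drawn uniformly from `design$baseline_range`, then clipped to [0, 1].
#' Non-planted connections have `mu = sigma_b = 0`. A warning is issued
#' if clipping affects more than 1% of values (ill-scaled design).
#'
#' @param design A [synth_design()].
#' @param geometry Geometry data.frame from [gen_geometry()].
#' @return A list with `tensor` (class `conn_tensor`: 6-d `values` array
#'   \[connection, subject, session, task, band, window\], `pairs`
#'   index, bands, windows) and `ground_truth` (data.frame of planted
#'   edges with `mu`, `sigma_b`, `sigma_e`, `theoretical_icc`,
#'   `coupled`, `boosted`, `n_grid_pairs`).
#' @export
gen_connectivity <- function(design, geometry) {
  stopifnot(inherits(design, "synth_design"))
  set.seed(.seed_for(design, "connectivity"))
  n <- design$n_grid_points
  ns <- design$n_subjects
  pairs <- all_grid_pairs(n)
  m <- nrow(pairs)
  bn <- names(design$bands)
  wn <- names(design$windows)
  pg <- geometry$parcel_id
  pe <- design$planted_edges

  # behavioral term added to coupled latents
  axis <- NULL
  if (!is.null(design$behavior_coupling))
    axis <- .behavior_axis(.behavior_scores(design))

  # connection ids per planted edge (grid pairs between the two parcels)
  planted_conns <- NULL
  if (!is.null(pe)) {
    pa <- pg[pairs[, 1]]
    pb <- pg[pairs[, 2]]
    planted_conns <- lapply(seq_len(nrow(pe)), function(e) {
      which((pa == pe$parcel_a[e] & pb == pe$parcel_b[e]) |
            (pa == pe$parcel_b[e] & pb == pe$parcel_a[e]))
    })
  }

  values <- array(NA_real_,
                  dim = c(m, ns, 2L, 2L, length(bn), length(wn)),
                  dimnames = list(NULL, NULL, session = c("1", "2"),
                                  task = c("naming", "visual"),
                                  band = bn, window = wn))
  se <- design$session_noise_sd
  n_clip <- 0
  for (bi in seq_along(bn)) for (wi in seq_along(wn)) {
    baseline <- stats::runif(m, design$baseline_range[1],
                             design$baseline_range[2])
    delta <- matrix(0, m, ns)
    if (!is.null(pe)) {
      here <- which(pe$band == bn[bi] & pe$window == wn[wi])
      for (e in here) {
        cc <- planted_conns[[e]]
        if (!length(cc)) next
        delta[cc, ] <- stats::rnorm(length(cc) * ns, pe$mu[e], pe$sigma_b[e])
        if (!is.null(design$behavior_coupling)) {
          cp <- design$behavior_coupling
          bsum <- sum(cp$beta[cp$edge == e])
          if (bsum != 0)
            delta[cc, ] <- delta[cc, ] +
              matrix(bsum * axis, length(cc), ns, byrow = TRUE)
        }
      }
    }
    off <- if (design$session_offset_sd > 0)
      stats::rnorm(2L, 0, design$session_offset_sd) else c(0, 0)
    for (d in 1:2) {
      contrast <- delta + stats::rnorm(m * ns, 0, se) + off[d]
      naming <- baseline + contrast
      n_clip <- n_clip + sum(naming < 0 | naming > 1)
      values[, , d, "naming", bi, wi] <- pmin(pmax(naming, 0), 1)
      values[, , d, "visual", bi, wi] <- baseline
    }
  }
  frac_clip <- n_clip / (m * ns * 2 * 2 * length(bn) * length(wn))
  if (frac_clip > 0.01)
    warning(sprintf("clipping affected %.2f%% of values; design ill-scaled",
                    100 * frac_clip), call. = FALSE)

  tensor <- structure(list(values = values, pairs = pairs,
                           bands = design$bands, windows = design$windows,
                           n_subjects = ns, seed = design$seed),
                      class = "conn_tensor")
  ground_truth <- NULL
  if (!is.null(pe)) {
    coupled <- rep(FALSE, nrow(pe))
    if (!is.null(design$behavior_coupling))
      coupled[unique(design$behavior_coupling$edge)] <- TRUE
    ticc <- theoretical_icc(pe$sigma_b, se)
    ground_truth <- data.frame(
      parcel_a = pe$parcel_a, parcel_b = pe$parcel_b,
      band = pe$band, window = pe$window,
      mu = pe$mu, sigma_b = pe$sigma_b, sigma_e = se,
      theoretical_icc = ticc,
      coupled = coupled,
      boosted = ticc > 0.5 & design$structural_boost > 1,
      n_grid_pairs = vapply(planted_conns, length, 1L))
  }
  list(tensor = tensor, ground_truth = ground_truth)
}

#' @export
print.conn_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(paste0("Connectivity tensor: %d connections x %d subjects x ",
                     "%d sessions x %d tasks x %d bands x %d windows\n"),
              d[1], d[2], d[3], d[4], d[5], d[6]))
  invisible(x)
}

#' Generate the behavior table
#'
#' Three behavioral scores per subject (letter fluency, category
#' fluency, and the naming-speed composite `ran_ras_mean`), drawn i.i.d.
#' standard normal so the predictors are approximately uncorrelated.
#' For designs with `behavior_coupling`, these are the same scores whose
#' mean enters the coupled subject latents in [gen_connectivity()]
#' (both draw from the same seeded substream).
#'
#' @param design A [synth_design()].
#' @return data.frame with columns `subject`, `fluency_s`,
#'   `fluency_animal`, `ran_ras_mean`.
#' @export
gen_behavior <- function(design) {
  stopifnot(inherits(design, "synth_design"))
  s <- .behavior_scores(design)
  data.frame(subject = seq_len(design$n_subjects),
             fluency_s = s[, 1], fluency_animal = s[, 2],
             ran_ras_mean = s[, 3])
}

#' Generate synthetic structural connectomes
#'
#' One symmetric nonnegative parcel-by-parcel streamline-weight matrix
#' per subject over the included parcels. Expected weight decays
#' exponentially with inter-centroid distance (scale 40 mm) and is
#' multiplied by heavy-tailed lognormal noise; weights below 0.5 are
#' zeroed (absent edges). Parcel pairs planted with theoretical
#' ICC > 0.5 are multiplied by `design$structural_boost`.
#'
#' @param design A [synth_design()].
#' @param parcellation Parcellation data.frame from [gen_geometry()].
#' @param ground_truth Optional ground-truth data.frame from
#'   [gen_connectivity()] (needed when `structural_boost > 1`).
#' @param weight_scale Expected direct weight at zero distance
#'   (streamline units, default 500).
#' @param decay_mm Distance-decay scale in mm (default 40).
#' @param sdlog Lognormal noise sd on the log scale (default 1).
#' @return List (one per subject) of symmetric weight matrices with
#'   parcel names as dimnames.
#' @export
gen_structural <- function(design, parcellation, ground_truth = NULL,
                           weight_scale = 500, decay_mm = 40, sdlog = 1) {
  stopifnot(inherits(design, "synth_design"))
  set.seed(.seed_for(design, "structural"))
  inc <- parcellation[parcellation$included, ]
  np <- nrow(inc)
  cen <- as.matrix(inc[, c("cx", "cy", "cz")])
  D <- as.matrix(stats::dist(cen))
  expw <- weight_scale * exp(-D / decay_mm)
  boost <- matrix(1, np, np)
  if (!is.null(ground_truth) && design$structural_boost > 1) {
    for (e in which(ground_truth$boosted)) {
      ia <- match(ground_truth$parcel_a[e], inc$parcel_id)
      ib <- match(ground_truth$parcel_b[e], inc$parcel_id)
      if (!is.na(ia) && !is.na(ib))
        boost[ia, ib] <- boost[ib, ia] <- design$structural_boost
    }
  }
  ut <- upper.tri(expw)
  lapply(seq_len(design$n_subjects), function(s) {
    W <- matrix(0, np, np, dimnames = list(inc$parcel_id, inc$parcel_id))
    w <- expw[ut] * stats::rlnorm(sum(ut), -sdlog^2 / 2, sdlog) * boost[ut]
    w[w < 0.5] <- 0
    W[ut] <- w
    W <- W + t(W)
    attr(W, "subject") <- s
    W
  })
}

#' Simulate a complete synthetic study
#'
#' Runs all four generators of a design and bundles geometry,
#' parcellation, connectivity tensor, planted ground truth, behavior
#' table and structural connectomes into one object.
#'
#' @param design A [synth_design()].
#' @param ... Passed to [gen_structural()].
#' @return Object of class `synth_study`.
#' @export
simulate_study <- function(design, ...) {
  geo <- gen_geometry(design)
  conn <- gen_connectivity(design, geo$geometry)
  behavior <- gen_behavior(design)
  connectomes <- gen_structural(design, geo$parcellation,
                                conn$ground_truth, ...)
  structure(list(design = design,
                 geometry = geo$geometry,
                 parcellation = geo$parcellation,
                 tensor = conn$tensor,
                 ground_truth = conn$ground_truth,
                 behavior = behavior,
                 connectomes = connectomes),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat("Synthetic test-retest connectivity study\n")
  print(x$design)
  np <- if (is.null(x$ground_truth)) 0L else nrow(x$ground_truth)
  cat(sprintf("  ground truth: %d planted parcel edges\n", np))
  invisible(x)
}
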