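# Documented synthetic study presets: the strong-effect recovery
# design, per-level ICC parameter-recovery designs and the null design.
# Sizes are chosen once as desk-scale study conditions (rationale in
# the methods vignette) and are not tuning knobs.

#' Strong-effect recovery design
#'
#' A 19-subject study with 500 grid points over 8 parcels per
#' hemisphere and one band with two time windows, planting 12 parcel
#' edges with large mean contrasts: 8 reliable (sigma_b = 0.006,
#' sigma_e = 0.003, theoretical ICC 0.8) and 4 unreliable
#' (sigma_b = 0.001, theoretical ICC 0.1). Reliable edges carry
#' behavioral coupling and a 5-fold structural boost, so the full
#' pipeline should recover them as consistent, behaviorally fitted,
#' functionally strong, structurally strong and topologically close.
#' Planted parcel pairs are chosen (deterministically, given the seed)
#' among included pairs whose centroids are at least 60 mm apart, so
#' the 4 cm endpoint filter leaves their grid pairs largely intact.
#'
#' @param seed Integer seed.
#' @return A [synth_design()].
#' @export
design_strong_effects <- function(seed = 1L) {
  base <- synth_design(n_subjects = 19, n_grid_points = 500,
                       n_parcels_per_hemi = 8,
                       bands = default_bands()["high_beta"],
                       windows = default_windows()[c("w0_400", "w400_800")],
                       session_noise_sd = 0.003, seed = seed)
  geo <- gen_geometry(base)
  inc <- geo$parcellation[geo$parcellation$included, ]
  cen <- as.matrix(inc[, c("cx", "cy", "cz")])
  D <- as.matrix(stats::dist(cen))
  cand <- which(upper.tri(D) & D >= 60, arr.ind = TRUE)
  if (nrow(cand) < 12)
    stop("geometry offers too few well-separated parcel pairs", call. = FALSE)
  # balance planted edge sizes: rank candidate pairs by their grid-pair
  # count and interleave the two reliability groups over the top ranks,
  # so group differences in summed strength reflect the planted mean
  # contrasts rather than parcel size
  npts <- table(factor(geo$geometry$parcel_id,
                       levels = geo$parcellation$parcel_id))
  m_ab <- as.integer(npts[inc$parcel_id[cand[, 1]]]) *
          as.integer(npts[inc$parcel_id[cand[, 2]]])
  cand <- cand[order(m_ab, decreasing = TRUE), , drop = FALSE]
  pick <- cand[seq_len(12), , drop = FALSE]
  unreliable <- c(3, 6, 9, 12)
  reliable <- setdiff(1:12, unreliable)
  ord <- c(reliable, unreliable)
  pe <- data.frame(
    parcel_a = inc$parcel_id[pick[ord, 1]],
    parcel_b = inc$parcel_id[pick[ord, 2]],
    band = "high_beta",
    window = rep(c("w0_400", "w400_800"), length.out = 12),
    mu = c(0.03 * c(1, 1, -1, 1, -1, 1, -1, 1),
           0.012 * c(1, -1, 1, -1)),
    sigma_b = rep(c(0.006, 0.001), c(8, 4)))
  synth_design(n_subjects = 19, n_grid_points = 500,
               n_parcels_per_hemi = 8,
               bands = default_bands()["high_beta"],
               windows = default_windows()[c("w0_400", "w400_800")],
               planted_edges = pe,
               session_noise_sd = 0.003,
               behavior_coupling = data.frame(edge = 1:8, beta = 0.01),
               structural_boost = 5,
               seed = seed)
}

#' ICC parameter-recovery design
#'
#' Plants `n_edges` parcel edges at one true consistency level
#' `rho = sigma_b^2 / (sigma_b^2 + sigma_e^2)` in a 19-subject,
#' 200-point, 12-parcels-per-hemisphere, single band/window study.
#' Used to check that the aggregate-then-ICC pipeline recovers the
#' planted level on average.
#'
#' @param rho True consistency ICC in \[0, 1).
#' @param n_edges Number of planted parcel edges (default 200).
#' @param n_subjects Subjects (default 19).
#' @param seed Integer seed.
#' @return A [synth_design()].
#' @export
design_icc_recovery <- function(rho, n_edges = 200, n_subjects = 19,
                                seed = 1L) {
  stopifnot(rho >= 0, rho < 1)
  sigma_e <- 0.003
  sigma_b <- sigma_e * sqrt(rho / (1 - rho))
  k <- 12L
  pairs <- all_grid_pairs(2L * k)
  if (nrow(pairs) < n_edges)
    stop("too few parcel pairs for requested edges", call. = FALSE)
  pe <- data.frame(parcel_a = pairs[seq_len(n_edges), 1],
                   parcel_b = pairs[seq_len(n_edges), 2],
                   band = "theta", window = "w0_400",
                   mu = 0.02, sigma_b = sigma_b)
  synth_design(n_subjects = n_subjects, n_grid_points = 200,
               n_parcels_per_hemi = k,
               bands = default_bands()["theta"],
               windows = default_windows()["w0_400"],
               planted_edges = pe,
               session_noise_sd = sigma_e, seed = seed)
}

#' Null design
#'
#' No planted effects: every connection contrast is pure session noise.
#' Used for type-I calibration of the selection stage (about `alpha` of
#' connections should pass the t-test threshold) and for null
#' robustness of the end-to-end run. The 142-point grid yields just
#' over 10^4 connections.
#'
#' @param n_grid_points Grid size (default 142).
#' @param seed Integer seed.
#' @return A [synth_design()].
#' @export
design_null <- function(n_grid_points = 142, seed = 1L) {
  synth_design(n_subjects = 19, n_grid_points = n_grid_points,
               n_parcels_per_hemi = 8,
               bands = default_bands()["theta"],
               windows = default_windows()["w0_400"],
               session_noise_sd = 0.003, seed = seed)
}
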