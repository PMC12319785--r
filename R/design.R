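#' Frequency bands of the study design
#'
#' Six canonical MEG frequency bands (Hz) used throughout: theta 4-7,
#' alpha 8-13, low beta 14-20, high beta 21-30, low gamma 31-45 and
#' high gamma 60-90.
#'
#' @return Named list of length-2 numeric vectors (lower, upper) in Hz.
#' @export
default_bands <- function() {
  list(theta      = c(4, 7),
       alpha      = c(8, 13),
       low_beta   = c(14, 20),
       high_beta  = c(21, 30),
       low_gamma  = c(31, 45),
       high_gamma = c(60, 90))
}

#' Time windows of the study design
#'
#' Three post-stimulus time windows (ms): 0-400, 400-800 and 800-1200.
#'
#' @return Named list of length-2 numeric vectors (start, end) in ms.
#' @export
default_windows <- function() {
  list(w0_400    = c(0, 400),
       w400_800  = c(400, 800),
       w800_1200 = c(800, 1200))
}

#' Specify a synthetic two-session connectivity study
#'
#' Defines the full generative design for a synthetic test-retest study:
#' grid geometry, parcellation size, frequency bands and time windows,
#' planted task-contrast effects with controllable between-subject
#' variance (hence controllable true ICC), session noise, behavioral
#' coupling and a structural-weight boost for reliable parcel pairs.
#' The design is consumed by [gen_geometry()], [gen_connectivity()],
#' [gen_behavior()] and [gen_structural()], or by [simulate_study()]
#' which runs all four.
#'
#' The number of sessions is fixed at two, matching the test-retest
#' layout the consistency analysis assumes (ICC with k = 2).
#'
#' @param n_subjects Number of subjects (default 19).
#' @param n_grid_points Total number of source grid points over both
#'   hemispheres (default 300; must be at least `2 * n_parcels_per_hemi`).
#' @param n_parcels_per_hemi Parcels per hemisphere (default 55).
#' @param bands Named list of frequency bands, Hz (see [default_bands()]).
#' @param windows Named list of time windows, ms (see [default_windows()]).
#' @param planted_edges `NULL` or a data.frame with columns `parcel_a`,
#'   `parcel_b` (parcel ids), `band`, `window` (names from `bands` /
#'   `windows`), `mu` (mean naming-minus-visual contrast; its sign is the
#'   planted modulation direction) and `sigma_b` (between-subject sd of
#'   the latent contrast).
#' @param session_noise_sd Session noise sd `sigma_e` per connection
#'   contrast, coherence units (default 0.003; must be positive).
#' @param session_offset_sd Optional sd of an additive per-session offset
#'   common to all subjects and connections (default 0). ICC(3,1) is
#'   insensitive to such offsets; the parameter exists to test exactly
#'   that.
#' @param behavior_coupling `NULL` or a data.frame with columns `edge`
#'   (row index into `planted_edges`) and `beta`: the subject latent
#'   contrast of that edge gains `beta` times the subject's behavioral
#'   axis (mean of the three standardized scores).
#' @param structural_boost Multiplicative streamline-weight factor
#'   applied to planted-reliable parcel pairs (theoretical ICC > 0.5);
#'   must be >= 1 (default 1, i.e. no boost).
#' @param anterior_exclude_mm Parcels whose seed centroid has
#'   y-coordinate above this value (mm, anterior direction) are flagged
#'   excluded, emulating the anterior exclusion of the analysis
#'   (default 50).
#' @param shell_radius_mm Radius of the hemispheric shells on which grid
#'   points are placed (default 70 mm).
#' @param baseline_range Range of the per-connection baseline coherence
#'   drawn for the visual task (default `c(0.2, 0.5)`).
#' @param seed Integer seed; identical designs produce bit-identical
#'   synthetic data.
#'
#' @return An object of class `synth_design`.
#' @examples
#' d <- synth_design(n_subjects = 6, n_grid_points = 40,
#'                   n_parcels_per_hemi = 3,
#'                   bands = default_bands()["theta"],
#'                   windows = default_windows()["w0_400"])
#' d
#' @export
synth_design <- function(n_subjects = 19,
                         n_grid_points = 300,
                         n_parcels_per_hemi = 55,
                         bands = default_bands(),
                         windows = default_windows(),
                         planted_edges = NULL,
                         session_noise_sd = 0.003,
                         session_offset_sd = 0,
                         behavior_coupling = NULL,
                         structural_boost = 1,
                         anterior_exclude_mm = 50,
                         shell_radius_mm = 70,
                         baseline_range = c(0.2, 0.5),
                         seed = 1L) {
  stopifnot(n_subjects >= 3, n_grid_points >= 4, n_parcels_per_hemi >= 1,
            length(bands) >= 1, length(windows) >= 1,
            is.numeric(session_noise_sd), length(session_noise_sd) == 1)
  if (is.null(names(bands)) || is.null(names(windows)))
    stop("'bands' and 'windows' must be named lists", call. = FALSE)
  if (n_grid_points < 2 * n_parcels_per_hemi)
    stop("invalid design: n_grid_points must be >= 2 * n_parcels_per_hemi",
         call. = FALSE)
  if (session_noise_sd < 0)
    stop("session_noise_sd (sigma_e) must be >= 0", call. = FALSE)
  if (structural_boost < 1)
    stop("structural_boost must be >= 1", call. = FALSE)

  n_parcels <- 2L * as.integer(n_parcels_per_hemi)
  if (!is.null(planted_edges)) {
    req <- c("parcel_a", "parcel_b", "band", "window", "mu", "sigma_b")
    miss <- setdiff(req, names(planted_edges))
    if (length(miss))
      stop("planted_edges missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (any(planted_edges$sigma_b < 0))
      stop("sigma_b must be >= 0", call. = FALSE)
    if (!all(planted_edges$band %in% names(bands)))
      stop("planted edge references unknown band", call. = FALSE)
    if (!all(planted_edges$window %in% names(windows)))
      stop("planted edge references unknown window", call. = FALSE)
    bad <- planted_edges$parcel_a == planted_edges$parcel_b |
      planted_edges$parcel_a < 1 | planted_edges$parcel_b < 1 |
      planted_edges$parcel_a > n_parcels | planted_edges$parcel_b > n_parcels
    if (any(bad))
      stop("planted edge references invalid parcel pair", call. = FALSE)
    # canonical unordered order
    a <- pmin(planted_edges$parcel_a, planted_edges$parcel_b)
    b <- pmax(planted_edges$parcel_a, planted_edges$parcel_b)
    planted_edges$parcel_a <- a
    planted_edges$parcel_b <- b
    key <- paste(a, b, planted_edges$band, planted_edges$window)
    if (anyDuplicated(key))
      stop("duplicate planted edges", call. = FALSE)
  }
  if (!is.null(behavior_coupling)) {
    if (is.null(planted_edges))
      stop("behavior_coupling requires planted_edges", call. = FALSE)
    if (!all(c("edge", "beta") %in% names(behavior_coupling)))
      stop("behavior_coupling needs columns 'edge' and 'beta'", call. = FALSE)
    if (!all(behavior_coupling$edge %in% seq_len(nrow(planted_edges))))
      stop("behavior_coupling references non-existent planted edge",
           call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_sessions = 2L,
    n_grid_points = as.integer(n_grid_points),
    n_parcels_per_hemi = as.integer(n_parcels_per_hemi),
    bands = bands,
    windows = windows,
    planted_edges = planted_edges,
    session_noise_sd = session_noise_sd,
    session_offset_sd = session_offset_sd,
    behavior_coupling = behavior_coupling,
    structural_boost = structural_boost,
    anterior_exclude_mm = anterior_exclude_mm,
    shell_radius_mm = shell_radius_mm,
    baseline_range = baseline_range,
    seed = as.integer(seed)
  ), class = "synth_design")
}

#' @export
print.synth_design <- function(x, ...) {
  cat("Synthetic two-session study design\n")
  cat(sprintf("  subjects: %d, sessions: %d, grid points: %d, parcels: %d x 2\n",
              x$n_subjects, x$n_sessions, x$n_grid_points,
              x$n_parcels_per_hemi))
  cat(sprintf("  bands: %s\n", paste(names(x$bands), collapse = ", ")))
  cat(sprintf("  windows: %s\n", paste(names(x$windows), collapse = ", ")))
  np <- if (is.null(x$planted_edges)) 0L else nrow(x$planted_edges)
  cat(sprintf("  planted edges: %d, sigma_e: %g, structural boost: %g, seed: %d\n",
              np, x$session_noise_sd, x$structural_boost, x$seed))
  invisible(x)
}

# theoretical consistency ICC of a planted edge
theoretical_icc <- function(sigma_b, sigma_e) {
  sigma_b^2 / (sigma_b^2 + sigma_e^2)
}
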