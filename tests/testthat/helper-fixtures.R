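# Small fixture builders shared across test files.

# Frozen oracle fixture: two-way ANOVA decomposition of this 10 x 2
# matrix computed once with an independent ANOVA fit (aov), mean
# squares frozen below.
anova_fixture <- matrix(c(7.741917, 3.870604, 5.726257, 6.265725, 5.808537,
                          4.787751, 8.023044, 4.810682, 9.036847, 4.874572,
                          7.609739, 9.573291, 2.222279, 4.442422, 4.733357,
                          6.271901, 4.431494, -0.312911, 0.119066, 7.640227),
                        nrow = 10)
anova_frozen <- c(BMS = 4.6705429542, JMS = 10.1034121768, EMS = 8.7565775986)

# a tiny single-band single-window design
tiny_design <- function(n_subjects = 8, ..., seed = 1L) {
  synth_design(n_subjects = n_subjects, n_grid_points = 60,
               n_parcels_per_hemi = 4,
               bands = default_bands()["theta"],
               windows = default_windows()["w0_400"],
               seed = seed, ...)
}

# build a conn_tensor directly from a connection x subject matrix of
# session-1 naming-minus-visual differences (visual fixed at 0.3);
# session 2 mirrors session 1 unless given
manual_tensor <- function(diff1, diff2 = diff1, pairs = NULL,
                          band = "theta", window = "w0_400") {
  diff1 <- as.matrix(diff1); diff2 <- as.matrix(diff2)
  m <- nrow(diff1); ns <- ncol(diff1)
  if (is.null(pairs)) pairs <- cbind(i = seq_len(m), j = seq_len(m) + m)
  values <- array(NA_real_, dim = c(m, ns, 2, 2, 1, 1),
                  dimnames = list(NULL, NULL, session = c("1", "2"),
                                  task = c("naming", "visual"),
                                  band = band, window = window))
  values[, , 1, "visual", 1, 1] <- 0.3
  values[, , 2, "visual", 1, 1] <- 0.3
  values[, , 1, "naming", 1, 1] <- 0.3 + diff1
  values[, , 2, "naming", 1, 1] <- 0.3 + diff2
  structure(list(values = values, pairs = pairs,
                 bands = list(theta = c(4, 7)),
                 windows = list(w0_400 = c(0, 400)),
                 n_subjects = ns, seed = NA_integer_),
            class = "conn_tensor")
}

# geometry with explicit coordinates; one parcel per point unless given
manual_geometry <- function(coords, parcel_id = NULL, hemisphere = NULL) {
  n <- nrow(coords)
  if (is.null(parcel_id)) parcel_id <- seq_len(n)
  if (is.null(hemisphere))
    hemisphere <- ifelse(coords[, 1] < 0, "left", "right")
  data.frame(point_id = seq_len(n), x = coords[, 1], y = coords[, 2],
             z = coords[, 3], hemisphere = hemisphere,
             parcel_id = parcel_id)
}

manual_parcellation <- function(ids, hemisphere, included = TRUE) {
  data.frame(parcel_id = ids,
             name = paste0("P", ids),
             hemisphere = hemisphere,
             included = rep_len(included, length(ids)),
             cx = 0, cy = 0, cz = 0)
}
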