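test_that("design validation rejects ill-formed specifications", {
  expect_error(synth_design(n_grid_points = 10, n_parcels_per_hemi = 8),
               "n_grid_points")
  expect_error(tiny_design(session_noise_sd = -1), "sigma_e")
  expect_error(tiny_design(structural_boost = 0.5), "structural_boost")
  pe <- data.frame(parcel_a = 1, parcel_b = 99, band = "theta",
                   window = "w0_400", mu = 0.1, sigma_b = 0)
  expect_error(tiny_design(planted_edges = pe), "invalid parcel")
  pe$parcel_b <- 2; pe$band <- "nope"
  expect_error(tiny_design(planted_edges = pe), "unknown band")
  pe$band <- "theta"
  expect_error(tiny_design(planted_edges = pe,
                           behavior_coupling = data.frame(edge = 2, beta = 1)),
               "non-existent planted edge")
})

test_that("geometry partitions points over hemispheres and parcels", {
  d <- synth_design(n_subjects = 5, n_grid_points = 4, n_parcels_per_hemi = 1,
                    bands = default_bands()["theta"],
                    windows = default_windows()["w0_400"],
                    anterior_exclude_mm = Inf)
  g <- gen_geometry(d)
  expect_equal(table(g$geometry$hemisphere), table(c("left", "left", "right", "right")))
  expect_equal(nrow(g$parcellation), 2L)
  expect_true(all(g$geometry$x[g$geometry$hemisphere == "left"] < 0))
  expect_true(all(g$geometry$x[g$geometry$hemisphere == "right"] > 0))

  d2 <- tiny_design()
  g2 <- gen_geometry(d2)
  # partition conservation and hemisphere agreement with the parcel table
  expect_equal(sum(table(g2$geometry$parcel_id)), d2$n_grid_points)
  expect_equal(
    g2$parcellation$hemisphere[match(g2$geometry$parcel_id,
                                     g2$parcellation$parcel_id)],
    g2$geometry$hemisphere)
})

test_that("every point is assigned to its nearest parcel centroid", {
  d <- synth_design(n_subjects = 5, n_grid_points = 200,
                    n_parcels_per_hemi = 10,
                    bands = default_bands()["theta"],
                    windows = default_windows()["w0_400"], seed = 1)
  g <- gen_geometry(d)
  co <- as.matrix(g$geometry[, c("x", "y", "z")])
  cen <- as.matrix(g$parcellation[, c("cx", "cy", "cz")])
  for (p in seq_len(nrow(co))) {
    same_hemi <- which(g$parcellation$hemisphere == g$geometry$hemisphere[p])
    dists <- sqrt(colSums((t(cen[same_hemi, , drop = FALSE]) - co[p, ])^2))
    expect_equal(g$geometry$parcel_id[p],
                 g$parcellation$parcel_id[same_hemi[which.min(dists)]])
  }
})

test_that("identical designs give bit-identical synthetic studies", {
  d <- tiny_design(seed = 42)
  s1 <- simulate_study(d)
  s2 <- simulate_study(d)
  expect_identical(s1$geometry, s2$geometry)
  expect_identical(s1$tensor$values, s2$tensor$values)
  expect_identical(s1$behavior, s2$behavior)
  expect_identical(s1$connectomes, s2$connectomes)
  s3 <- simulate_study(tiny_design(seed = 43))
  expect_false(identical(s1$tensor$values, s3$tensor$values))
})

test_that("noiseless sessions give identical contrasts across sessions", {
  pe <- data.frame(parcel_a = 1, parcel_b = 5, band = "theta",
                   window = "w0_400", mu = 0.05, sigma_b = 0.01)
  d <- tiny_design(planted_edges = pe, session_noise_sd = 0)
  st <- gen_connectivity(d, gen_geometry(d)$geometry)
  v <- st$tensor$values
  c1 <- v[, , 1, "naming", 1, 1] - v[, , 1, "visual", 1, 1]
  c2 <- v[, , 2, "naming", 1, 1] - v[, , 2, "visual", 1, 1]
  expect_equal(c1, c2)
  expect_equal(st$ground_truth$theoretical_icc, 1)
})

test_that("null design has near-zero group-mean contrast and [0,1] values", {
  d <- tiny_design(seed = 5)
  st <- gen_connectivity(d, gen_geometry(d)$geometry)
  v <- st$tensor$values
  expect_true(all(v >= 0 & v <= 1))
  contr <- v[, , 1, "naming", 1, 1] - v[, , 1, "visual", 1, 1]
  expect_lt(abs(mean(contr)), 4 * d$session_noise_sd / sqrt(length(contr)))
  expect_null(st$ground_truth)
})

test_that("ill-scaled designs trigger the clipping warning", {
  pe <- data.frame(parcel_a = 1, parcel_b = 5, band = "theta",
                   window = "w0_400", mu = 5, sigma_b = 0.01)
  d <- tiny_design(planted_edges = pe)
  expect_warning(gen_connectivity(d, gen_geometry(d)$geometry), "clipping")
})

test_that("behavior table has one row per subject and weakly correlated scores", {
  d <- synth_design(n_subjects = 19, n_grid_points = 60,
                    n_parcels_per_hemi = 4,
                    bands = default_bands()["theta"],
                    windows = default_windows()["w0_400"], seed = 2)
  b <- gen_behavior(d)
  expect_equal(dim(b), c(19L, 4L))
  expect_named(b, c("subject", "fluency_s", "fluency_animal", "ran_ras_mean"))
  cors <- cor(b[, -1])
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.6))
})

test_that("structural connectomes satisfy the weight-matrix invariants", {
  d <- tiny_design(seed = 9)
  geo <- gen_geometry(d)
  ws <- gen_structural(d, geo$parcellation)
  expect_length(ws, d$n_subjects)
  for (W in ws[1:3]) {
    expect_true(isSymmetric(unname(W)))
    expect_true(all(diag(W) == 0))
    expect_true(all(W >= 0))
  }
})

test_that("structural boost raises planted-pair weights, no boost leaves them exchangeable", {
  pe <- data.frame(parcel_a = c(1, 2), parcel_b = c(5, 6), band = "theta",
                   window = "w0_400", mu = 0.05, sigma_b = 0.01)
  base <- tiny_design(planted_edges = pe, session_noise_sd = 0.003)
  geo <- gen_geometry(base)
  gt <- gen_connectivity(base, geo$geometry)$ground_truth
  expect_true(all(gt$theoretical_icc > 0.5))

  boosted_design <- tiny_design(planted_edges = pe, session_noise_sd = 0.003,
                                structural_boost = 5)
  gtb <- gen_connectivity(boosted_design, geo$geometry)$ground_truth
  planted_w <- function(ws, gt) {
    unlist(lapply(ws, function(W)
      W[cbind(as.character(gt$parcel_a), as.character(gt$parcel_b))]))
  }
  other_w <- function(ws, gt) {
    unlist(lapply(ws, function(W) {
      M <- W
      M[cbind(as.character(gt$parcel_a), as.character(gt$parcel_b))] <- NA
      M[cbind(as.character(gt$parcel_b), as.character(gt$parcel_a))] <- NA
      M[upper.tri(M)][!is.na(M[upper.tri(M)])]
    }))
  }
  ws5 <- gen_structural(boosted_design, geo$parcellation, gtb)
  expect_gt(median(planted_w(ws5, gtb)), median(other_w(ws5, gtb)))

  # boost = 1: planting has no effect at all on the weights
  ws1 <- gen_structural(base, geo$parcellation, gt)
  expect_identical(ws1, gen_structural(base, geo$parcellation, NULL))
})
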