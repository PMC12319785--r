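test_that("paired t statistics match the closed-form textbook computation", {
  diffs <- c(0.05, 0.07, 0.06, 0.08, 0.04)
  tens <- manual_tensor(matrix(diffs, nrow = 1))
  st <- paired_t_contrast(tens, "theta", "w0_400")
  expect_equal(st$mean_contrast, 0.06)
  expect_equal(st$t, 8.4852813742, tolerance = 1e-9)
  expect_equal(st$p, 0.001057564616, tolerance = 1e-9)

  # sign symmetry: negating all differences negates t, keeps p
  st_neg <- paired_t_contrast(manual_tensor(matrix(-diffs, nrow = 1)),
                              "theta", "w0_400")
  expect_equal(st_neg$t, -st$t)
  expect_equal(st_neg$p, st$p)
})

test_that("identical conditions give zero contrast flagged degenerate", {
  tens <- manual_tensor(matrix(0, nrow = 2, ncol = 5))
  expect_message(st <- paired_t_contrast(tens, "theta", "w0_400"),
                 "degenerate")
  expect_equal(st$mean_contrast, c(0, 0))
  expect_true(all(st$degenerate))
  expect_true(all(is.na(st$t)))
  sel <- threshold_connections(st, manual_geometry(matrix(0, 4, 3)), 0.05)
  expect_equal(nrow(sel), 0L)
})

test_that("distance filter is inclusive at the 4 cm limit and nested over alpha", {
  # three connections: endpoints 39, 40 and 100 mm apart
  co <- rbind(c(0, 0, 0), c(39, 0, 0),
              c(0, 50, 0), c(40, 50, 0),
              c(0, -50, 0), c(100, -50, 0))
  geom <- manual_geometry(co)
  set.seed(1)
  diffs <- matrix(rnorm(3 * 10, mean = 0.05, sd = 0.01), nrow = 3)
  tens <- manual_tensor(diffs, pairs = cbind(c(1, 3, 5), c(2, 4, 6)))
  st <- paired_t_contrast(tens, "theta", "w0_400")
  expect_true(all(st$p < 1e-4))
  sel <- threshold_connections(st, geom, 1e-3)
  expect_setequal(sel$connection, c(2, 3))
  expect_equal(sel$distance_mm, c(40, 100))

  selB <- threshold_connections(st, geom, 1e-4)
  expect_true(all(selB$connection %in% sel$connection))
})

test_that("selection at alpha = 1e-4 is a subset of selection at 1e-3", {
  d <- tiny_design(seed = 21)
  study <- gen_connectivity(d, gen_geometry(d)$geometry)
  geom <- gen_geometry(d)$geometry
  st <- paired_t_contrast(study$tensor, "theta", "w0_400")
  a <- threshold_connections(st, geom, 1e-2)
  b <- threshold_connections(st, geom, 1e-3)
  expect_true(all(b$connection %in% a$connection))
})

test_that("bundle retention respects the minimum size at the boundary", {
  # 19 connections stacked within linkage range: nothing retained;
  # a 20th inside the range completes one bundle of 20
  n <- 20
  co <- cbind(seq(0, by = 5, length.out = n), 0, 0)
  co <- rbind(co, cbind(seq(0, by = 5, length.out = n), 100, 0))
  geom <- manual_geometry(co)
  conns <- data.frame(i = 1:n, j = n + (1:n))
  b19 <- cluster_bundles(conns[1:19, ], geom, max_link_mm = 13, min_size = 20)
  expect_length(b19, 0L)
  b20 <- cluster_bundles(conns, geom, max_link_mm = 13, min_size = 20)
  expect_length(b20, 1L)
  expect_length(b20[[1]], 20L)
})

test_that("well-separated groups form separate bundles", {
  co <- rbind(cbind(seq(0, by = 5, length.out = 25), 0, 0),
              cbind(seq(0, by = 5, length.out = 25), 70, 0),
              cbind(500 + seq(0, by = 5, length.out = 25), 0, 0),
              cbind(500 + seq(0, by = 5, length.out = 25), 70, 0))
  geom <- manual_geometry(co)
  conns <- data.frame(i = c(1:25, 51:75), j = c(26:50, 76:100))
  b <- cluster_bundles(conns, geom, max_link_mm = 13, min_size = 20)
  expect_length(b, 2L)
  expect_setequal(lengths(b), c(25L, 25L))
})

test_that("bundle components equal brute-force transitive closure", {
  set.seed(33)
  for (rep in 1:10) {
    n_pts <- 40
    co <- matrix(runif(n_pts * 3, 0, 60), ncol = 3)
    geom <- manual_geometry(co)
    prs <- t(utils::combn(n_pts, 2))
    prs <- prs[sample(nrow(prs), 30), , drop = FALSE]
    conns <- data.frame(i = prs[, 1], j = prs[, 2])
    D <- oracle_conn_dist(conns, geom)
    comp <- oracle_single_linkage(D, 20)
    expected <- unname(split(seq_len(nrow(conns)), comp))
    expected <- expected[lengths(expected) >= 3]
    got <- cluster_bundles(conns, geom, max_link_mm = 20, min_size = 3)
    key <- function(b) sort(vapply(b, function(x) paste(sort(x), collapse = ","), ""))
    expect_equal(key(got), key(expected))
  }
})

test_that("bundles map to parcel edges by member endpoint enumeration", {
  co <- rbind(c(-10, 0, 0), c(-12, 0, 5), c(10, 0, 0), c(12, 0, 5),
              c(-10, 40, 0), c(10, 40, 0))
  geom <- manual_geometry(co, parcel_id = c(3, 3, 7, 7, 1, 2))
  parc <- manual_parcellation(c(1, 2, 3, 7), c("left", "right", "left", "right"),
                              included = c(FALSE, TRUE, TRUE, TRUE))
  conns <- data.frame(i = c(1, 2, 5), j = c(3, 4, 6))
  # one bundle entirely between parcels 3 and 7 -> exactly one edge {3,7}
  pe <- bundles_to_parcel_edges(list(1:2), conns, geom, parc,
                                "theta", "w0_400")
  expect_equal(nrow(pe), 1L)
  expect_equal(c(pe$parcel_a, pe$parcel_b), c(3, 7))
  # a member touching the excluded parcel 1 contributes no edge
  pe2 <- bundles_to_parcel_edges(list(1:3), conns, geom, parc,
                                 "theta", "w0_400")
  expect_equal(nrow(pe2), 1L)

  # random case against brute-force enumeration over member endpoints
  set.seed(4)
  geom_r <- manual_geometry(matrix(rnorm(60), 20, 3),
                            parcel_id = sample(1:5, 20, replace = TRUE))
  parc_r <- manual_parcellation(1:5, rep(c("left", "right"), c(3, 2)))
  prs <- t(utils::combn(20, 2))
  prs <- prs[sample(nrow(prs), 25), ]
  conns_r <- data.frame(i = prs[, 1], j = prs[, 2])
  got <- bundles_to_parcel_edges(list(1:10, 11:25), conns_r, geom_r, parc_r)
  pa <- geom_r$parcel_id[conns_r$i]; pb <- geom_r$parcel_id[conns_r$j]
  want <- unique(data.frame(parcel_a = pmin(pa, pb), parcel_b = pmax(pa, pb)))
  want <- want[want$parcel_a != want$parcel_b, ]
  expect_setequal(paste(got$parcel_a, got$parcel_b),
                  paste(want$parcel_a, want$parcel_b))
})

test_that("parcel aggregation sums all inter-parcel grid pairs linearly", {
  # geometry: parcel 1 = points 1,2 (left); parcel 2 = points 3,4,5 (right)
  co <- rbind(c(-10, 0, 0), c(-12, 0, 0), c(10, 0, 0), c(12, 0, 0),
              c(14, 0, 0))
  geom <- manual_geometry(co, parcel_id = c(1, 1, 2, 2, 2))
  pairs <- t(utils::combn(5, 2))
  set.seed(8)
  diffs <- matrix(rnorm(nrow(pairs) * 4, 0, 0.02), nrow(pairs), 4)
  tens <- manual_tensor(diffs, diffs + 0.01, pairs = pairs)
  s <- parcel_aggregate(tens, geom, 1, 2, "theta", "w0_400")
  between <- which((geom$parcel_id[pairs[, 1]] != geom$parcel_id[pairs[, 2]]))
  expect_equal(attr(s, "n_grid_pairs"), length(between))
  expect_equal(s[, 1], colSums(diffs[between, ]))
  expect_equal(s[, 2], colSums(diffs[between, ] + 0.01))

  # singleton sum and linearity
  tens1 <- manual_tensor(matrix(0.04, 1, 4), pairs = cbind(1, 3))
  s1 <- parcel_aggregate(tens1, geom, 1, 2, "theta", "w0_400")
  expect_equal(unname(s1[, 1]), rep(0.04, 4))
  tens2 <- manual_tensor(2 * diffs, pairs = pairs)
  s2 <- parcel_aggregate(tens2, geom, 1, 2, "theta", "w0_400")
  expect_equal(s2[, 1], 2 * colSums(diffs[between, ]))

  # permutation invariance to grid-pair ordering
  perm <- sample(nrow(pairs))
  tens_p <- manual_tensor(diffs[perm, ], pairs = pairs[perm, ])
  expect_equal(parcel_aggregate(tens_p, geom, 1, 2, "theta", "w0_400")[, 1],
               s[, 1])

  expect_error(parcel_aggregate(tens1, geom, 1, 1, "theta", "w0_400"))
  geom_iso <- geom; geom_iso$parcel_id <- c(1, 1, 2, 2, 3)
  expect_error(parcel_aggregate(manual_tensor(matrix(0.1, 1, 4),
                                              pairs = cbind(1, 2)),
                                geom_iso, 1, 3, "theta", "w0_400"),
               "no grid pairs")
})

test_that("modulation direction follows the sign of the session-1 group mean", {
  s <- matrix(c(0.1, 0.2, 0.3, 0, 0, 0), ncol = 2)
  expect_equal(modulation_direction(s), "increase")
  expect_equal(modulation_direction(-s), "decrease")
  s2 <- matrix(c(-0.1, 0.3, 0.2, 0, 0, 0), ncol = 2)
  expect_equal(modulation_direction(s2), "increase")
  expect_warning(dir <- modulation_direction(matrix(0, 3, 2)), "zero")
  expect_equal(dir, "increase")
})

test_that("power screen flags at more than four subjects and is scale invariant", {
  pw <- array(1, dim = c(8, 3, 1, 1, 2),
              dimnames = list(NULL, c("p1", "p2", "p3"), "theta", "w0_400",
                              c("naming", "visual")))
  # parcel 1: 5 subjects with 30% relative difference -> flagged
  pw[1:5, 1, 1, 1, "naming"] <- 1.4
  # parcel 2: only 4 subjects above -> not flagged
  pw[1:4, 2, 1, 1, "naming"] <- 1.4
  fl <- power_screen(pw)
  expect_equal(fl$parcel, "p1")
  expect_equal(fl$n_subjects_above, 5L)
  # identical powers: nothing flagged
  expect_equal(nrow(power_screen(array(1, dim = c(8, 2, 1, 1, 2),
    dimnames = list(NULL, NULL, NULL, NULL, c("naming", "visual"))))), 0L)
  # scaling all powers leaves flags unchanged
  fl10 <- power_screen(pw * 10)
  expect_equal(fl, fl10)
  # zero power in both tasks counts as zero difference
  pw0 <- pw; pw0[, 3, 1, 1, ] <- 0
  expect_equal(power_screen(pw0)$parcel, "p1")
})
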