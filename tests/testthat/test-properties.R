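behavior_fixture <- data.frame(
  fluency_s = c(2.287247, -1.196772, -0.694293, -0.412293, -0.970673,
                -0.94728, 0.748139, -0.116955),
  fluency_animal = c(0.152658, 2.189978, 0.356986, 2.716752, 2.281452,
                     0.324021, 1.896067, 0.467681),
  ran_ras_mean = c(-0.893801, -0.307328, -0.004822, 0.988164, 0.83975,
                   0.705342, 1.305965, -1.387996))
y_fixture <- c(1.272917, 0.184193, 0.75228, 0.591745, -0.983053, -0.276064,
               -0.870851, 0.718711)

test_that("regression screen matches the frozen least-squares oracle", {
  # F value frozen from an independent lm() fit of this n = 8 dataset
  res <- behavior_association(y_fixture, behavior_fixture)
  expect_equal(res$F, 1.7357224908, tolerance = 1e-9)
  expect_equal(res$df1, 3L)
  expect_equal(res$df2, 4L)
  expect_false(res$fitted)

  # perfect linear dependence: p ~ 0, fitted
  y_exact <- with(behavior_fixture,
                  1 + 2 * fluency_s - fluency_animal + 0.5 * ran_ras_mean)
  res2 <- behavior_association(y_exact, behavior_fixture)
  expect_lt(res2$p, 1e-12)
  expect_true(res2$fitted)
})

test_that("regression screen validates its inputs", {
  b <- behavior_fixture
  b$ran_ras_mean <- NULL
  expect_error(behavior_screen(matrix(y_fixture), b), "ran_ras_mean")
  b2 <- behavior_fixture
  b2$ran_ras_mean <- 2 * b2$fluency_s
  expect_error(behavior_screen(matrix(y_fixture), b2),
               "collinear.*ran_ras_mean")
  expect_error(behavior_screen(matrix(y_fixture[1:5]),
                               behavior_fixture[1:5, ]), "6 subjects")
})

test_that("vectorized screen agrees with per-edge fits", {
  set.seed(12)
  Y <- matrix(rnorm(8 * 6), 8, 6)
  scr <- behavior_screen(Y, behavior_fixture)
  for (k in c(1, 4, 6)) {
    one <- behavior_association(Y[, k], behavior_fixture)
    expect_equal(scr$F[k], one$F)
    expect_equal(scr$p[k], one$p)
  }
})

test_that("chi-square reproduces the reference laterality and fit statistics", {
  # 2 x 3 laterality-by-direction table: uncorrected Pearson
  lat <- rbind(increase = c(left = 8, right = 5, bilateral = 14),
               decrease = c(6, 17, 9))
  res <- chi2_independence(lat)
  expect_false(res$continuity_correction)
  expect_equal(res$df, 2L)
  expect_equal(round(res$statistic, 2), 7.55)
  expect_equal(round(res$p, 3), 0.023)

  # 2 x 2 consistency-by-fit table: Yates-corrected
  tab <- reconstruct_consistency_table(514, 11.5, 10.2, 4.6)
  expect_equal(unname(tab),
               matrix(c(6, 21, 53, 434), 2))
  res2 <- chi2_independence(tab)
  expect_true(res2$continuity_correction)
  expect_equal(round(res2$statistic, 2), 2.22)
  expect_equal(round(res2$p, 2), 0.14)
})

test_that("chi-square handles degenerate and proportional tables", {
  expect_error(chi2_independence(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(chi2_independence(matrix(1:3, 1)), "2 x 2")
  prop <- rbind(c(10, 20, 30), c(5, 10, 15))
  res <- chi2_independence(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_warning(chi2_independence(prop, correction = "on"), "2 x 2")
  res_off <- chi2_independence(rbind(c(6, 53), c(21, 434)), "off")
  expect_false(res_off$continuity_correction)
  expect_gt(res_off$statistic, 2.22)
})

test_that("Mann-Whitney exact branch matches enumeration and invariances hold", {
  res <- mwu_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)
  expect_true(res$exact)

  # identical multisets: ties force the normal branch, p ~ 1
  res_id <- mwu_compare(c(1, 2, 3), c(1, 2, 3))
  expect_false(res_id$exact)
  expect_equal(res_id$p, 1)

  # translation invariance
  set.seed(5)
  x <- rnorm(7); y <- rnorm(9)
  a <- mwu_compare(x, y); b <- mwu_compare(x + 3, y + 3)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p, b$p)

  # exhaustive-enumeration oracle at a few sizes
  for (sz in list(c(3, 4), c(5, 5), c(4, 7))) {
    x <- rnorm(sz[1]); y <- rnorm(sz[2])
    o <- oracle_mwu_exact(x, y)
    got <- mwu_compare(x, y)
    expect_equal(got$statistic, o$U)
    expect_equal(got$p, o$p, tolerance = 1e-12)
  }
})

test_that("strength summary is the absolute value of the grand mean", {
  expect_equal(strength_summary(matrix(0.5, 4, 2)), 0.5)
  expect_equal(strength_summary(matrix(c(-1, 1, -2, 2), 2, 2)), 0)
  s <- matrix(c(0.1, -0.3, 0.2, 0.4, 0.0, -0.2, 0.6, 0.0), 4, 2)
  expect_equal(strength_summary(s), abs(mean(s)))
})

test_that("laterality follows parcel hemispheres", {
  parc <- manual_parcellation(1:4, c("left", "left", "right", "right"))
  expect_equal(edge_laterality(1, 2, parc), "left")
  expect_equal(edge_laterality(3, 4, parc), "right")
  expect_equal(edge_laterality(1, 3, parc), "bilateral")
  expect_equal(edge_laterality(c(1, 3, 2), c(2, 4, 3), parc),
               c("left", "right", "bilateral"))
  expect_error(edge_laterality(1, 9, parc), "unresolvable")
})

test_that("property report pools, compares and conserves edge counts", {
  set.seed(20)
  n <- 40
  edges <- data.frame(
    label = rep(c("consistent", "inconsistent"), c(15, 25)),
    fitted = c(runif(15) < 0.5, runif(25) < 0.1),
    direction = sample(c("increase", "decrease"), n, replace = TRUE),
    laterality = sample(c("left", "right", "bilateral"), n, replace = TRUE),
    strength = c(rlnorm(15, 1), rlnorm(25, 0)),
    mean_streamlines = rlnorm(n, 3),
    mean_spl = c(rlnorm(n - 1, -2), Inf),
    mean_ebc = rlnorm(n))
  rep_ <- property_report(edges)
  expect_equal(rep_$n_edges, n)
  expect_equal(rep_$n_consistent, 15)
  expect_s3_class(rep_$comparisons$consistency_fit, "comparison_result")
  expect_s3_class(rep_$comparisons$strength, "comparison_result")
  expect_true(any(grepl("infinite", rep_$notices)))
  expect_equal(sum(rep_$comparisons$consistency_fit$observed), n)

  # degenerate grouping: everything consistent -> chi-square skipped
  edges2 <- edges; edges2$label <- "consistent"
  rep2 <- property_report(edges2)
  expect_null(rep2$comparisons$consistency_fit)
  expect_true(any(grepl("skipped", rep2$notices)))
})

test_that("regression screen holds its nominal type-I rate under null coupling", {
  set.seed(77)
  n_edges <- 4000
  Y <- matrix(rnorm(18 * n_edges), 18, n_edges)
  b <- data.frame(fluency_s = rnorm(18), fluency_animal = rnorm(18),
                  ran_ras_mean = rnorm(18))
  rate <- mean(behavior_screen(Y, b)$fitted)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / n_edges))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_edges))
})

test_that("a strongly coupled edge is detected with high power", {
  # Monte-Carlo power check at n = 18: outcome = beta * axis + noise
  set.seed(78)
  reps <- 400
  hits <- 0
  for (r in seq_len(reps)) {
    b <- data.frame(fluency_s = rnorm(18), fluency_animal = rnorm(18),
                    ran_ras_mean = rnorm(18))
    axis <- rowMeans(b)
    y <- 2 * axis + rnorm(18, 0, 0.5)
    hits <- hits + behavior_association(y, b)$fitted
  }
  expect_gt(hits / reps, 0.8)
})
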