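test_that("the K12 estimator reproduces the hand-evaluated single pair", {
  p1 <- point_pattern(5, 5, 10, 10)
  p2 <- point_pattern(5, 6, 10, 10)
  expect_equal(bivariate_K(p1, p2, 1), 100 * (100 / 90), tolerance = 1e-12)
  expect_equal(bivariate_K(p1, p2, 0.5), 0)
  expect_equal(L_transform(bivariate_K(p1, p2, 1), 1),
               sqrt(100 * (100 / 90) / pi) - 1, tolerance = 1e-12)
  expect_error(bivariate_K(p1, p2, 6), "r_max")
})

test_that("L transform fixes independence at zero", {
  r <- 1:10
  expect_equal(L_transform(pi * r^2, r), rep(0, 10))
  expect_equal(L_transform(rep(0, 10), r), -r)
})

test_that("the fast estimator equals the brute-force double loop", {
  set.seed(5)
  for (i in 1:10) {
    p1 <- rpoisson_pattern(sample(20:60, 1))
    p2 <- rpoisson_pattern(sample(20:60, 1))
    r <- 1:10
    expect_lt(max(abs(bivariate_K(p1, p2, r) - k12_brute(p1, p2, r))),
              1e-12)
    ## symmetric in pattern order
    expect_lt(max(abs(bivariate_K(p1, p2, r) - bivariate_K(p2, p1, r))),
              1e-9)
  }
})

test_that("isotropic weights agree with numeric circle-fraction integration", {
  W <- 10; H <- 10
  frac_inside <- function(x, y, d) {
    th <- seq(0, 2 * pi, length.out = 20001)[-1]
    mean(x + d * cos(th) >= 0 & x + d * cos(th) <= W &
         y + d * sin(th) >= 0 & y + d * sin(th) <= H)
  }
  cases <- list(c(5, 5, 2),      # interior: weight 1
                c(0.5, 5, 2),    # one edge
                c(0.5, 0.8, 2),  # corner, overlapping caps
                c(1.5, 5, 2), c(9.5, 9.2, 1.5))
  for (cs in cases) {
    p1 <- point_pattern(cs[1], cs[2], W, H)
    ## place the second point at distance d from p1, inside the window
    x2 <- cs[1] + ifelse(cs[1] < 5, cs[3], -cs[3])
    p2 <- point_pattern(x2, cs[2], W, H)
    K <- bivariate_K(p1, p2, cs[3], correction = "isotropic")
    expect_equal(K, 100 / frac_inside(cs[1], cs[2], cs[3]),
                 tolerance = 1e-3)
  }
})

test_that("torus shifts are periodic and preserve internal structure", {
  set.seed(9)
  p <- rpoisson_pattern(40)
  id0 <- torus_shift(p, 0, 0)
  expect_equal(id0$x, p$x)
  expect_equal(id0$y, p$y)
  idW <- torus_shift(p, p$width, p$height)
  expect_equal(idW$x, p$x)
  expect_equal(idW$y, p$y)
  sh <- torus_shift(p, 13.7, 42.1)
  expect_equal(sh$n, p$n)
  expect_equal(torus_dists(sh), torus_dists(p), tolerance = 1e-9)
})

test_that("envelope test is deterministic given a seed and flags attraction", {
  set.seed(31)
  p1 <- rpoisson_pattern(100)
  ## p2: one point within 1 m of every p1 point (wrapped into the window)
  ang <- runif(100, 0, 2 * pi)
  p2 <- point_pattern((p1$x + 0.6 * cos(ang)) %% 50,
                      (p1$y + 0.6 * sin(ang)) %% 100, 50, 100)
  e1 <- envelope_test(p1, p2, n_sim = 199, seed = 4)
  e2 <- envelope_test(p1, p2, n_sim = 199, seed = 4)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_true(all(e1$classification[e1$r <= 2] == "positive"))
  expect_true(all(e1$env_low <= e1$env_high))
})

test_that("independent Poisson patterns are classified independent", {
  set.seed(77)
  p1 <- rpoisson_pattern(200)
  p2 <- rpoisson_pattern(200)
  e <- envelope_test(p1, p2, n_sim = 499, seed = 5)
  expect_gte(sum(e$classification == "independent"), 9)
})

test_that("envelope limits stabilize as the simulation count grows", {
  ## at matched tail mass (rank/n_sim = 0.005) the envelope estimate is an
  ## order statistic whose sampling noise shrinks with n_sim
  set.seed(12)
  p1 <- rpoisson_pattern(150)
  p2 <- rpoisson_pattern(150)
  hi <- function(n_sim, seed) {
    e <- envelope_test(p1, p2, n_sim = n_sim, seed = seed)
    e$env_high[e$r == 5]
  }
  small <- vapply(1:8, function(s) hi(199, s), 0)
  large <- vapply(1:8, function(s) hi(999, s), 0)
  expect_gt(sd(small), sd(large))
})

test_that("layer association skips empty cells and fills populated ones", {
  ## single-growth-form stand with both layers present
  set.seed(6)
  n <- 60
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    tr_row(paste0("T", i), "sp1", "EH", runif(1, 0, 50), runif(1, 0, 100),
           2002, if (i <= 30) runif(1, 2, 9.9) else runif(1, 10, 30),
           "alive")))
  tab <- census_table(rows, census_years = c(2002L, 2007L))
  la <- layer_association(tab, 2002, n_sim = 99, seed = 2)
  cells <- unlist(lapply(la, function(row) lapply(row, function(cell)
    inherits(cell, "l12_result"))))
  expect_equal(sum(cells), 1L)
  expect_true(inherits(la$EH$EH, "l12_result"))
  expect_match(la$EC$EH, "skipped")
})

test_that("planted conspecific clustering is recovered as positive association", {
  cfg <- sim_config(seed = 15, species = list(
    species_spec("eh1", "EH", density = 700, dbh_scale = 4, max_dbh = 30,
                 spatial = "thomas", thomas_parents = 30, thomas_sigma = 1.5,
                 mort_baseline = 0.01, recruit_rate = 10,
                 recruit_clustered = TRUE)))
  tab <- simulate_stand(cfg)
  al <- tab$trees[tab$trees$census_year == 2002 &
                  tab$trees$status == "alive", ]
  under <- al[al$dbh < 10, ]; over <- al[al$dbh >= 10, ]
  p1 <- point_pattern(under$x, under$y, 50, 100)
  p2 <- point_pattern(over$x, over$y, 50, 100)
  e <- envelope_test(p1, p2, n_sim = 499, seed = 8)
  expect_true(any(e$classification[e$r <= 2] == "positive"))
})
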