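test_that("no mortality and no recruitment conserves the alive count", {
  cfg <- sim_config(seed = 4, species = list(
    species_spec("sp1", "EC", density = 200, mort_baseline = 0,
                 recruit_rate = 0)))
  tab <- simulate_stand(cfg)
  counts <- vapply(tab$census_years, function(y)
    sum(tab$trees$census_year == y & tab$trees$status == "alive"), 0L)
  expect_true(all(counts == counts[1]))
})

test_that("the same seed reproduces the table exactly", {
  cfg1 <- sim_config(seed = 11, species = default_species_pool())
  cfg2 <- sim_config(seed = 11, species = default_species_pool())
  expect_identical(simulate_stand(cfg1)$trees, simulate_stand(cfg2)$trees)
  expect_false(identical(
    simulate_stand(sim_config(seed = 12))$trees,
    simulate_stand(cfg1)$trees))
})

test_that("constant annual death probability matches the binomial oracle", {
  tab <- simulate_stand(oracle_config(seed = 21, n_per_ha = 4000,
                                      p_death = 0.02))
  r <- species_rates(tab, c(2002, 2015), "plot")
  true_rate <- -log(0.98) * 100           # ~2.02 %/yr
  s13 <- 0.98^13
  se <- sqrt((1 - s13) / (s13 * r$N_i)) / 13 * 100
  expect_lt(abs(r$mortality - true_rate), 3 * se)
})

test_that("stem counts balance: alive(t+1) = alive(t) - deaths + surviving recruits", {
  tab <- small_stand(seed = 5)
  truth <- attr(tab, "truth")
  cy <- tab$census_years
  for (i in seq_len(length(cy) - 1)) {
    y0 <- cy[i]; y1 <- cy[i + 1]
    alive0 <- sum(truth$birth_year <= y0 &
                  (is.na(truth$death_year) | truth$death_year > y0))
    alive1 <- sum(truth$birth_year <= y1 &
                  (is.na(truth$death_year) | truth$death_year > y1))
    deaths <- sum(truth$birth_year <= y0 & !is.na(truth$death_year) &
                  truth$death_year > y0 & truth$death_year <= y1)
    recr <- sum(truth$birth_year > y0 & truth$birth_year <= y1 &
                (is.na(truth$death_year) | truth$death_year > y1))
    expect_equal(alive1, alive0 - deaths + recr)
    ## and the census table records exactly the alive stems
    expect_equal(sum(tab$trees$census_year == y1 &
                     tab$trees$status == "alive"), alive1)
  }
})

test_that("without noise or tree effects ADGR equals a0 + a2*DBH exactly", {
  cfg <- sim_config(seed = 2, census_years = c(2002L, 2003L),
                    species = list(species_spec(
                      "sp1", "EC", density = 100, mort_baseline = 0,
                      recruit_rate = 0, tree_sd = 0, resid_sd = 0,
                      growth_a0 = 0.06, growth_a2 = 0.005)))
  tab <- simulate_stand(cfg)
  des <- build_design(tab)
  ## DBH is recorded at 0.01 cm so the identity holds to that precision
  expect_lt(max(abs(des$adgr - (0.06 + 0.005 * des$dbh))), 0.011)
})

test_that("Thomas-mode patterns are clustered at short range", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(seed = 100 + s, census_years = c(2002L, 2003L),
                      species = list(species_spec(
                        "sp1", "EH", density = 1200, spatial = "thomas",
                        thomas_parents = 60, thomas_sigma = 1.5,
                        mort_baseline = 0, recruit_rate = 0)))
    tab <- simulate_stand(cfg)
    al <- tab$trees[tab$trees$census_year == 2002 &
                    tab$trees$status == "alive", ]
    p <- point_pattern(al$x, al$y, 50, 100)
    K3 <- bivariate_K(p, p, r_grid = 3)     # r = 2*sigma
    if (K3 > pi * 9) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("matrix simulation: identity survival keeps counts constant", {
  sch <- size_class_scheme(c(2, 4, 8))
  A <- diag(3)
  out <- simulate_from_matrix(A, sch, n0 = c(50, 30, 20), n_steps = 4,
                              seed = 5)
  expect_true(all(apply(out$counts, 2, function(v) all(v == v[1]))))
})

test_that("matrix simulation tracks lambda and is seed-reproducible", {
  sch <- size_class_scheme(c(2, 4, 8))
  ## row 1 columns 2+ are fecundities; rest survival/growth
  A <- rbind(c(0.80, 0.10, 0.80),
             c(0.10, 0.80, 0.00),
             c(0.00, 0.10, 0.85))
  lam <- dominant_eigen(A)$lambda
  out1 <- simulate_from_matrix(A, sch, n0 = 3000, n_steps = 5, seed = 9)
  out2 <- simulate_from_matrix(A, sch, n0 = 3000, n_steps = 5, seed = 9)
  expect_identical(out1$counts, out2$counts)
  growth <- sum(out1$counts[6, ]) / sum(out1$counts[1, ])
  expect_lt(abs(growth - lam^5) / lam^5, 0.15)
})

test_that("ring simulation: no noise and no episodes gives a constant series", {
  cfg <- ring_sim_config(seed = 1, n_trees = c(sp = 2), noise_sd = 0,
                         episodes = list())
  out <- simulate_rings(cfg)
  expect_true(all(vapply(out$series, function(s)
    all(s$widths == s$widths[1]), TRUE)))
  out2 <- simulate_rings(cfg)
  expect_identical(out$series, out2$series)
})

test_that("a planted noiseless episode is found at the step year", {
  cfg <- ring_sim_config(seed = 1, n_trees = c(sp = 1), noise_sd = 0,
                         span = c(1950L, 2000L),
                         episodes = list(list(start = 1975L, duration = 15L,
                                              multiplier = 3)))
  out <- simulate_rings(cfg)
  ev <- detect_releases(out$series[[1]])
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$year - 1975L), 1L)
  expect_equal(ev$magnitude, "major")
})
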