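test_that("rate formulas evaluate correctly on hand inputs", {
  ## ingrowth
  expect_equal(ingrowth_rate(1, 1, 13), 0)
  expect_equal(ingrowth_rate(1.0, 1.2, 13), log(1.2) * 100 / 13)
  expect_equal(ingrowth_rate(1.2, 1.0, 13), -ingrowth_rate(1.0, 1.2, 13))
  expect_error(ingrowth_rate(0, 1, 13))
  ## mortality: zero-recruitment reference-stand rows round to the printed
  ## 0.496 and 1.186 %/yr
  expect_equal(round(mortality_rate(16, 15, 13), 3), 0.496)
  expect_equal(round(mortality_rate(14, 12, 13), 3), 1.186)
  expect_equal(mortality_rate(40, 40, 7), 0)
  und <- mortality_rate(5, 0, 13)
  expect_true(is.na(und))
  expect_match(attr(und, "undefined"), "N_s = 0")
  ## recruitment
  expect_equal(recruitment_rate(100, 100, 13), 0)
  expect_equal(recruitment_rate(120, 100, 13), log(1.2) * 100 / 13)
  expect_equal(recruitment_rate(9, 3, 13), log(3) * 100 / 13)
})

test_that("species_rates counts recruits that died before the period end", {
  tab <- toy_table()
  r <- species_rates(tab, c(2002, 2012), "species")
  ## initial: A, B, E; survivors: A, E; recruits: C (died by 2012), D
  expect_equal(r$N_i, 3)
  expect_equal(r$N_s, 2)
  expect_equal(r$N_f, 4)
  expect_equal(r$mortality, log(3 / 2) * 100 / 10)
  expect_equal(r$recruitment, log(4 / 2) * 100 / 10)
  expect_true(r$flag_low_n)   # N_s = 2 < 5
  ## ingrowth: BA_i covers every initial stem (including B, which died);
  ## BA_s only the survivors at period end
  ba_i <- (pi * 25 + pi * 6.25 + pi * 100) * 1e-4
  ba_s <- (pi * 36 + pi * 121) * 1e-4
  expect_equal(r$ingrowth, log(ba_s / ba_i) * 100 / 10)
  expect_error(species_rates(tab, c(2002, 2013)), "census years")
})

test_that("a zero-death stand has zero mortality everywhere", {
  tab <- simulate_stand(sim_config(seed = 3, species = list(
    species_spec("sp1", "EC", density = 150, mort_baseline = 0,
                 recruit_rate = 2))))
  r <- species_rates(tab, range(tab$census_years), "species")
  expect_equal(r$mortality, 0)
})

test_that("sub-period mortalities recompose the whole-period rate", {
  tab <- simulate_stand(oracle_config(seed = 31, n_per_ha = 2000,
                                      p_death = 0.03,
                                      years = c(2002L, 2007L, 2012L, 2015L)))
  whole <- species_rates(tab, c(2002, 2015), "plot")$mortality
  parts <- vapply(list(c(2002, 2007), c(2007, 2012), c(2012, 2015)),
                  function(p) {
                    r <- species_rates(tab, p, "plot")
                    r$mortality * r$t
                  }, 0)
  expect_equal(sum(parts) / 13, whole, tolerance = 1e-12)
})

test_that("bootstrap CI collapses when every tree shares one fate", {
  rows <- do.call(rbind, lapply(1:8, function(i) rbind(
    tr_row(paste0("T", i), "sp1", "EC", i, i, 2002, 5, "alive"),
    tr_row(paste0("T", i), "sp1", "EC", i, i, 2015, 6, "alive"))))
  tab <- census_table(rows, census_years = c(2002L, 2015L))
  ci <- bootstrap_ci(tab, list(statistic = "mortality",
                               period = c(2002, 2015)), B = 200, seed = 1)
  expect_equal(ci[1], 0)
  expect_equal(ci[2], 0)
  expect_equal(attr(ci, "point"), 0)
})

test_that("bootstrap CI brackets the point estimate on simulated stands", {
  for (s in 1:5) {
    tab <- simulate_stand(oracle_config(seed = 40 + s, n_per_ha = 600,
                                        p_death = 0.025))
    ci <- bootstrap_ci(tab, list(statistic = "mortality",
                                 period = c(2002, 2015)),
                       B = 1000, seed = s)
    pt <- attr(ci, "point")
    expect_lte(ci[1], pt)
    expect_gte(ci[2], pt)
    expect_gt(ci[2], ci[1])
  }
})

test_that("size-class mortality rebins cohorts at each period start", {
  rows <- rbind(
    tr_row("X", "sp1", "EC", 1, 1, 2002, 2.5, "alive"),
    tr_row("X", "sp1", "EC", 1, 1, 2007, 2.6, "standing_dead"),
    tr_row("Y", "sp1", "EC", 2, 2, 2002, 5.0, "alive"),
    tr_row("Y", "sp1", "EC", 2, 2, 2007, 5.5, "alive"),
    tr_row("Y", "sp1", "EC", 2, 2, 2012, 6.0, "alive"),
    tr_row("Z", "sp1", "EC", 3, 3, 2002, 3.9, "alive"),
    tr_row("Z", "sp1", "EC", 3, 3, 2007, 4.1, "alive"),
    tr_row("Z", "sp1", "EC", 3, 3, 2012, 4.3, "alive"))
  tab <- census_table(rows, census_years = c(2002L, 2007L, 2012L))
  m <- size_class_mortality(tab)
  p1c1 <- m[m$start == 2002 & m$class == "[2,4)", ]
  expect_equal(p1c1$N_i, 2)   # X and Z
  expect_equal(p1c1$N_s, 1)   # Z survives
  p2c2 <- m[m$start == 2007 & m$class == "[4,8)", ]
  expect_equal(p2c2$N_i, 2)   # Y and the advanced Z
  expect_equal(p2c2$mortality, 0)
})

test_that("class counts conserve stems on simulator output", {
  tab <- small_stand(seed = 9)
  m <- size_class_mortality(tab, by = "plot")
  cy <- tab$census_years
  for (i in seq_len(length(cy) - 1)) {
    mi <- m[m$start == cy[i], ]
    expect_equal(sum(mi$N_i, na.rm = TRUE),
                 sum(tab$trees$census_year == cy[i] &
                     tab$trees$status == "alive"))
    expect_equal(sum(mi$N_s, na.rm = TRUE),
                 sum(tab$trees$tree_id %in%
                       tab$trees$tree_id[tab$trees$census_year == cy[i + 1] &
                                         tab$trees$status == "alive"] &
                     tab$trees$census_year == cy[i] &
                     tab$trees$status == "alive"))
  }
})

test_that("standing-dead fractions follow the death-mode probabilities", {
  ## all standing
  rows <- do.call(rbind, lapply(1:4, function(i) rbind(
    tr_row(paste0("T", i), "sp1", "EC", i, i, 2002, 5, "alive"),
    tr_row(paste0("T", i), "sp1", "EC", i, i, 2015, 5, "standing_dead"))))
  tab <- census_table(rows, census_years = c(2002L, 2015L))
  f <- standing_dead_fraction(tab)
  expect_true(all(f$pct_standing == 100))
  ## single uprooted death
  rows2 <- rbind(tr_row("U", "sp1", "EC", 1, 1, 2002, 5, "alive"),
                 tr_row("U", "sp1", "EC", 1, 1, 2015, 5, "uprooted"))
  tab2 <- census_table(rows2, census_years = c(2002L, 2015L))
  f2 <- standing_dead_fraction(tab2)
  expect_equal(f2$pct_standing, 0)
  ## multinomial oracle at ~500 deaths
  cfg <- sim_config(seed = 17, species = list(species_spec(
    "sp1", "EC", density = 3000, mort_baseline = 0.02,
    mort_size_slope = 0, recruit_rate = 0,
    death_modes = c(standing_dead = 0.7, stem_broken = 0.2,
                    uprooted = 0.1))))
  tab3 <- simulate_stand(cfg)
  f3 <- standing_dead_fraction(tab3)
  n_dead <- sum(f3$n_dead)
  frac <- sum(f3$n_standing) / n_dead
  expect_gt(n_dead, 300)
  expect_lt(abs(frac - 0.7), 4 * sqrt(0.7 * 0.3 / n_dead))
})
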