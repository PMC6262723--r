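test_that("ADGR is a plain annualized diameter difference", {
  expect_equal(adgr(10, 12, 5), 0.4)
  expect_equal(adgr(10, 10, 5), 0)
  expect_equal(adgr(10, 9.8, 3), -0.2 / 3)
  expect_error(adgr(NA, 12, 5), "both censuses")
})

test_that("crowding sums neighbors in the quadrat, excluding the target", {
  rows <- rbind(
    tr_row("A", "sp1", "DH", 5, 5, 2002, 5, "alive"),     # target
    tr_row("B", "sp2", "EC", 6, 6, 2002, 10, "alive"),    # same quadrat
    tr_row("C", "sp1", "DH", 7, 3, 2002, 5, "alive"),     # equal-DBH DH
    tr_row("D", "sp3", "EH", 25, 5, 2002, 30, "alive"))   # other quadrat
  tab <- census_table(rows, census_years = c(2002L, 2007L))
  two <- crowding(tab, "A", 2002, "two_sided")
  expect_equal(two[["EC"]], pi * 25 / 100)   # 0.785 cm2/m2
  expect_equal(two[["DH"]], pi * 6.25 / 100)
  expect_equal(two[["EH"]], 0)
  one <- crowding(tab, "A", 2002, "one_sided")
  expect_equal(one[["EC"]], pi * 25 / 100)
  expect_equal(one[["DH"]], 0)               # equal DBH excluded
  ## lone tree
  lone <- census_table(tr_row("A", "sp1", "DH", 45, 95, 2002, 5, "alive"),
                       census_years = c(2002L, 2007L))
  expect_equal(unname(crowding(lone, "A", 2002)), c(0, 0, 0))
})

test_that("build_design matches the per-tree crowding function", {
  tab <- small_stand(seed = 13)
  des <- build_design(tab, periods = list(c(2002, 2007)))
  set.seed(1)
  pick <- des[sample.int(nrow(des), 25), ]
  for (i in seq_len(nrow(pick))) {
    two <- crowding(tab, pick$tree_id[i], 2002, "two_sided")
    one <- crowding(tab, pick$tree_id[i], 2002, "one_sided")
    expect_equal(c(pick$ba_ec2[i], pick$ba_dh2[i], pick$ba_eh2[i]),
                 unname(two), tolerance = 1e-12)
    expect_equal(c(pick$ba_ec1[i], pick$ba_dh1[i], pick$ba_eh1[i]),
                 unname(one), tolerance = 1e-12)
  }
})

test_that("design bookkeeping: survivors only, per period", {
  rows <- rbind(
    tr_row("A", "sp1", "EC", 1, 1, 2002, 10, "alive"),
    tr_row("A", "sp1", "EC", 1, 1, 2007, 12, "alive"),
    tr_row("A", "sp1", "EC", 1, 1, 2012, 13, "alive"),
    tr_row("B", "sp1", "EC", 2, 2, 2002, 5, "alive"),
    tr_row("B", "sp1", "EC", 2, 2, 2007, 5.5, "alive"),
    tr_row("B", "sp1", "EC", 2, 2, 2012, 5.5, "standing_dead"))
  tab <- census_table(rows, census_years = c(2002L, 2007L, 2012L))
  des <- build_design(tab)
  expect_equal(sum(des$period == "2002-2007"), 2)
  expect_equal(sum(des$period == "2007-2012"), 1)   # B died
  expect_equal(des$adgr[des$tree_id == "A" & des$period == "2002-2007"],
               0.4)
  ## one-sided never exceeds two-sided
  big <- build_design(small_stand(seed = 2))
  expect_true(all(big$ba_ec1 <= big$ba_ec2 + 1e-12))
  expect_true(all(big$ba_dh1 <= big$ba_dh2 + 1e-12))
  expect_true(all(big$ba_eh1 <= big$ba_eh2 + 1e-12))
})

make_lmm_data <- function(n_tree = 150, sigma_u = 0.1, sigma_e = 0.05,
                          beta0 = 0.05, beta_dbh = 0.005, seed = 1) {
  set.seed(seed)
  dbh <- runif(n_tree, 2, 60)
  u <- rnorm(n_tree, 0, sigma_u)
  do.call(rbind, lapply(1:3, function(p) data.frame(
    tree_id = paste0("T", seq_len(n_tree)),
    species = sample(c("s1", "s2"), n_tree, TRUE),
    period = p, dbh = dbh,
    adgr = beta0 + beta_dbh * dbh + u + rnorm(n_tree, 0, sigma_e),
    ba_ec1 = runif(n_tree), ba_dh1 = runif(n_tree), ba_eh1 = runif(n_tree),
    ba_ec2 = runif(n_tree), ba_dh2 = runif(n_tree), ba_eh2 = runif(n_tree),
    stringsAsFactors = FALSE)))
}

test_that("the mixed model recovers noiseless coefficients", {
  d <- make_lmm_data(sigma_u = 0, sigma_e = 1e-8)
  fit <- fit_lmm(d, c("dbh"))
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 0.05), 1e-6)
  expect_lt(abs(fit$coefficients[["dbh"]] - 0.005), 1e-6)
  expect_lt(fit$sigma_u2, 1e-8)
})

test_that("intercept-only fit on a constant response returns the constant", {
  d <- make_lmm_data(sigma_u = 0, sigma_e = 1e-10, beta_dbh = 0,
                     beta0 = 0.42)
  fit <- fit_lmm(d, character(0))
  expect_equal(unname(fit$coefficients[1]), 0.42, tolerance = 1e-6)
})

test_that("AIC bookkeeping matches -2 logLik + 2k and lme4", {
  d <- make_lmm_data()
  fit <- fit_lmm(d, c("species", "dbh", "ba_eh1"))
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$k)
  expect_equal(fit$k, length(fit$coefficients) + 2)
  expect_equal(fit$AIC, AIC(fit$model))
  expect_gte(fit$n_obs, fit$n_trees)
})

test_that("a boundary (zero) random-intercept fit equals ordinary least squares", {
  ## residuals +e/-e within each tree: tree means are exactly on the line,
  ## so the between-tree variance estimate hits the zero boundary
  set.seed(4)
  n <- 80
  dbh <- runif(n, 2, 60)
  e <- rnorm(n, 0, 0.05)
  d <- data.frame(tree_id = rep(paste0("T", 1:n), each = 2),
                  species = "s1", dbh = rep(dbh, each = 2),
                  adgr = rep(0.05 + 0.005 * dbh, each = 2) +
                    as.vector(rbind(e, -e)),
                  stringsAsFactors = FALSE)
  fit <- fit_lmm(d, "dbh")
  ols <- fit_lmm(d, "dbh", random_intercept = FALSE)
  expect_equal(fit$sigma_u2, 0, tolerance = 1e-10)
  expect_lt(max(abs(fit$coefficients - ols$coefficients)), 1e-8)
})

test_that("exhaustive selection attempts all 256 subsets and ranks by AIC", {
  d <- make_lmm_data(n_tree = 120, seed = 3)
  rank <- select_model(d)
  expect_equal(nrow(rank), 256L)
  expect_equal(length(unique(rank$model_id)), 256L)
  expect_false(is.unsorted(rank$AIC, na.rm = TRUE))
  expect_equal(rank$delta_AIC[1], 0)
  best <- attr(rank, "best")
  expect_s3_class(best, "model_fit")
  ## the true signal (dbh) is in the best model
  expect_true(grepl("dbh", rank$terms[1]))
})

test_that("a strong planted crowding effect enters the best model", {
  d <- make_lmm_data(n_tree = 200, seed = 5)
  d$adgr <- d$adgr + 0.25 * d$ba_eh1
  rank <- select_model(d)
  expect_true(grepl("ba_eh1", rank$terms[1]))
})

test_that("fit errors are recorded per subset, not fatal", {
  d <- make_lmm_data(n_tree = 60, seed = 7)
  d$species <- "only_one"
  rank <- select_model(d)
  expect_equal(nrow(rank), 256L)
  with_sp <- grepl("species", rank$terms)
  expect_true(all(rank$error[with_sp] != ""))
  expect_true(all(rank$error[!with_sp] == ""))
})
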