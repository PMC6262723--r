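## Neighborhood competition on tree diameter growth.
##
## The response is the absolute diameter growth rate
## ADGR = (DBH_final - DBH_initial) / t (cm/yr). Crowding covariates are
## per-growth-form basal-area sums over the 10 x 10 m quadrat containing the
## target tree (target excluded), in cm2/m2: one-sided sums count only
## neighbors strictly larger than the target (asymmetric competition for
## light), two-sided sums count all live neighbors >= 2 cm (symmetric
## competition for soil resources). The growth model is a Gaussian linear
## mixed model with a per-tree random intercept, fit by maximum likelihood
## so AIC is comparable across fixed-effect structures; all 2^8 = 256
## subsets of {Species, DBH, 6 crowding terms} are ranked by AIC.

CROWDING_TERMS <- c("ba_ec1", "ba_dh1", "ba_eh1", "ba_ec2", "ba_dh2", "ba_eh2")
CANDIDATE_TERMS <- c("species", "dbh", CROWDING_TERMS)

#' Absolute diameter growth rate
#'
#' @param dbh_i,dbh_f DBH at period start and end, cm.
#' @param t period length, years.
#' @return cm/yr; negative values (shrinkage, measurement error) retained.
#' @export
adgr <- function(dbh_i, dbh_f, t) {
  stopifnot(t > 0)
  if (any(is.na(dbh_i)) || any(is.na(dbh_f)))
    stop("ADGR needs DBH at both censuses")
  (dbh_f - dbh_i) / t
}

quadrat_index <- function(x, w, cell = 10) {
  q <- floor(x / cell)
  pmin(q, ceiling(w / cell) - 1L)   # upper plot edge joins the last quadrat
}

#' Neighborhood crowding of one tree
#'
#' Sum of neighbor basal area per growth form over the tree's 10 x 10 m
#' quadrat, divided by the 100 m2 quadrat area (cm2/m2). The target tree is
#' excluded from its own sums.
#'
#' @param table a [census_table()].
#' @param tree_id target tree.
#' @param year census year (tree must be alive then).
#' @param mode `"two_sided"` (all live neighbors) or `"one_sided"` (only
#'   neighbors with DBH strictly greater than the target's).
#' @return named vector `c(EC = , DH = , EH = )`, cm2/m2.
#' @export
crowding <- function(table, tree_id, year,
                     mode = c("two_sided", "one_sided")) {
  mode <- match.arg(mode)
  al <- alive_at(table, year)
  i <- match(tree_id, al$tree_id)
  if (is.na(i)) stop("tree ", tree_id, " not alive at ", year)
  qx <- quadrat_index(al$x, table$plot_width)
  qy <- quadrat_index(al$y, table$plot_height)
  same <- qx == qx[i] & qy == qy[i] & al$tree_id != tree_id
  if (mode == "one_sided") same <- same & al$dbh > al$dbh[i]
  v <- vapply(c("EC", "DH", "EH"), function(f)
    sum(ba_cm2(al$dbh[same & al$growth_form == f])) / 100, 0)
  v
}

#' Build the growth-competition design table
#'
#' One observation per tree surviving a census period: initial DBH, ADGR,
#' and the six crowding sums evaluated at the period-start census.
#'
#' @param table a [census_table()].
#' @param periods list of `c(start, end)` census-year pairs; defaults to all
#'   consecutive pairs.
#' @return data.frame of class `growth_design` with columns `tree_id`,
#'   `species`, `growth_form`, `period`, `dbh`, `adgr`, `ba_ec1` ...
#'   `ba_eh2`.
#' @export
build_design <- function(table, periods = NULL) {
  if (is.null(periods)) {
    cy <- table$census_years
    periods <- lapply(seq_len(length(cy) - 1L), function(i) cy[i + 0:1])
  }
  out <- list()
  for (p in periods) {
    y0 <- p[1]; y1 <- p[2]; t <- y1 - y0
    a0 <- alive_at(table, y0)
    a1 <- alive_at(table, y1)
    j <- match(a0$tree_id, a1$tree_id)
    surv <- !is.na(j)
    a0s <- a0[surv, , drop = FALSE]
    dbh_f <- a1$dbh[j[surv]]
    ## vectorized crowding: per quadrat, per growth form
    qx <- quadrat_index(a0$x, table$plot_width)
    qy <- quadrat_index(a0$y, table$plot_height)
    qid <- paste(qx, qy)
    ba <- ba_cm2(a0$dbh)
    two <- vapply(c("EC", "DH", "EH"), function(f) {
      tot <- tapply(ba * (a0$growth_form == f), qid, sum)
      as.numeric(tot[qid[surv]]) -
        ba[surv] * (a0$growth_form[surv] == f)
    }, numeric(nrow(a0s)))
    if (nrow(a0s) == 1L) two <- matrix(two, 1, 3,
                                       dimnames = list(NULL, c("EC", "DH", "EH")))
    ## one-sided: strictly larger neighbors — per-quadrat sort and cumsum
    one <- matrix(0, nrow(a0s), 3, dimnames = list(NULL, c("EC", "DH", "EH")))
    qs <- qid[surv]
    for (q in unique(qs)) {
      in_q <- which(qid == q)                 # all stems in quadrat
      tgt <- which(qs == q)                   # surviving targets
      for (fi in 1:3) {
        f <- c("EC", "DH", "EH")[fi]
        nb <- in_q[a0$growth_form[in_q] == f]
        if (!length(nb)) next
        nd <- a0$dbh[nb]; nb_ba <- ba[nb]
        ord <- order(nd)
        nd_s <- nd[ord]; cs <- cumsum(nb_ba[ord])
        tot <- cs[length(cs)]
        ## sum of neighbor BA with DBH > target DBH
        pos <- findInterval(a0s$dbh[tgt], nd_s)  # count of nd <= target
        one[tgt, fi] <- tot - ifelse(pos > 0, cs[pmax(pos, 1)], 0)
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      tree_id = a0s$tree_id, species = a0s$species,
      growth_form = a0s$growth_form,
      period = paste0(y0, "-", y1),
      dbh = a0s$dbh, adgr = (dbh_f - a0s$dbh) / t,
      ba_ec1 = one[, "EC"] / 100, ba_dh1 = one[, "DH"] / 100,
      ba_eh1 = one[, "EH"] / 100,
      ba_ec2 = two[, "EC"] / 100, ba_dh2 = two[, "DH"] / 100,
      ba_eh2 = two[, "EH"] / 100,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("growth_design", "data.frame")
  out
}

#' Fit a random-intercept growth model
#'
#' Gaussian linear mixed model `ADGR = X beta + u_tree + eps`,
#' `u ~ N(0, sigma_u^2)`, `eps ~ N(0, sigma_e^2)`, fit by maximum likelihood
#' (not REML) so that AIC is comparable across fixed-effect structures.
#' `AIC = -2 logLik + 2k` with `k` = number of fixed coefficients + 2
#' variance parameters. With `random_intercept = FALSE` an ordinary least
#' squares fit is returned (`k` = fixed + 1).
#'
#' @param observations a [build_design()] table (or compatible data.frame).
#' @param terms character subset of
#'   `c("species", "dbh", "ba_ec1", "ba_dh1", "ba_eh1", "ba_ec2", "ba_dh2",
#'   "ba_eh2")`; empty for the intercept-only model.
#' @param random_intercept include the per-tree random intercept.
#' @return object of class `model_fit`: list with `terms`, `coefficients`,
#'   `sigma_u2`, `sigma_e2`, `logLik`, `AIC`, `k`, `n_obs`, `n_trees`, and
#'   the underlying `model`.
#' @export
fit_lmm <- function(observations, terms = character(0),
                    random_intercept = TRUE) {
  stopifnot(nrow(observations) >= 2L,
            all(terms %in% CANDIDATE_TERMS))
  if ("species" %in% terms &&
      length(unique(observations$species)) < 2L)
    stop("species term requires >= 2 species")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (random_intercept) {
    fml <- stats::as.formula(paste("adgr ~", rhs, "+ (1 | tree_id)"))
    m <- lme4::lmer(fml, data = observations, REML = FALSE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
    vc <- lme4::VarCorr(m)
    sigma_u2 <- as.numeric(vc$tree_id[1])
    sigma_e2 <- attr(vc, "sc")^2
    beta <- lme4::fixef(m)
    ll <- as.numeric(logLik(m))
    k <- length(beta) + 2L
  } else {
    fml <- stats::as.formula(paste("adgr ~", rhs))
    m <- stats::lm(fml, data = observations)
    sigma_u2 <- 0
    sigma_e2 <- mean(stats::residuals(m)^2)   # ML variance
    beta <- coef(m)
    ll <- as.numeric(logLik(m))
    k <- length(beta) + 1L
  }
  structure(list(terms = terms, coefficients = beta,
                 sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 logLik = ll, AIC = -2 * ll + 2 * k, k = k,
                 n_obs = nrow(observations),
                 n_trees = length(unique(observations$tree_id)),
                 model = m),
            class = "model_fit")
}

#' @exportS3Method print model_fit
print.model_fit <- function(x, ...) {
  cat("model_fit: adgr ~",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
      "+ (1 | tree)\n")
  cat("  AIC", round(x$AIC, 2), " logLik", round(x$logLik, 2),
      " n_obs", x$n_obs, " n_trees", x$n_trees, "\n")
  invisible(x)
}

#' Exhaustive AIC model selection over the eight candidate terms
#'
#' Fits all 2^8 = 256 subsets of
#' {Species, DBH, one- and two-sided crowding of EC/DH/EH} as
#' random-intercept ML fits and ranks them by AIC (ties broken by fewer
#' terms). Fit errors (e.g. a single-species dataset with the Species term)
#' are recorded per subset, not fatal.
#'
#' @param observations a [build_design()] table, normally one growth form.
#' @return data.frame of class `model_ranking`: one row per attempted model
#'   with `model_id`, `terms`, `k`, `logLik`, `AIC`, `delta_AIC`, `error`;
#'   the best fit object is attached as `attr(, "best")`.
#' @export
select_model <- function(observations) {
  nt <- length(CANDIDATE_TERMS)
  rows <- list()
  fits <- vector("list", 2^nt)
  for (id in 0:(2^nt - 1)) {
    inc <- as.logical(bitwAnd(id, 2^(seq_len(nt) - 1)))
    terms <- CANDIDATE_TERMS[inc]
    fit <- tryCatch(fit_lmm(observations, terms),
                    error = function(e) conditionMessage(e))
    ok <- inherits(fit, "model_fit")
    if (ok) fits[[id + 1L]] <- fit
    rows[[id + 1L]] <- data.frame(
      model_id = id,
      terms = if (length(terms)) paste(terms, collapse = "+") else "(intercept)",
      n_terms = length(terms),
      k = if (ok) fit$k else NA_integer_,
      logLik = if (ok) fit$logLik else NA_real_,
      AIC = if (ok) fit$AIC else NA_real_,
      error = if (ok) "" else fit,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ord <- order(out$AIC, out$n_terms, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  out$delta_AIC <- out$AIC - min(out$AIC, na.rm = TRUE)
  rownames(out) <- NULL
  best <- fits[[out$model_id[1] + 1L]]
  structure(out, class = c("model_ranking", "data.frame"), best = best)
}
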