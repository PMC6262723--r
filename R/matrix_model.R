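## Stage-classified matrix population models estimated from census
## transitions. Stages are DBH classes; per census period the estimator
## records stage-specific survival, the distribution of surviving stems over
## destination stages, and per-capita recruitment, annualizes them
## (mortality and advance probabilities via p_annual = 1-(1-p_period)^(1/t),
## fecundity by division by t), pools periods by stem-time weighting, and
## reports the dominant eigenvalue lambda with r = ln(lambda).

#' Construct a projection matrix object
#'
#' @param A s x s non-negative annualized projection matrix: column j holds
#'   the per-capita annual contributions of stage j, with recruitment
#'   confined to row 1.
#' @param scheme the [size_class_scheme()] defining the stages.
#' @param interval_years census-period lengths used in estimation.
#' @return object of class `projection_matrix`.
#' @export
projection_matrix <- function(A, scheme, interval_years = NA) {
  s <- length(scheme$boundaries)
  stopifnot(is.matrix(A), nrow(A) == s, ncol(A) == s, all(A >= 0))
  dimnames(A) <- list(scheme$labels, scheme$labels)
  structure(list(A = A, scheme = scheme, interval_years = interval_years),
            class = "projection_matrix")
}

#' Estimate a stage-classified projection matrix from census data
#'
#' Per period and stage j (DBH class at period start): survival is
#' survivors/initial; surviving stems are distributed over their observed
#' destination stages (multi-stage moves, including retrogression, allowed);
#' recruits reaching 2.0 cm during the period are allocated as per-capita
#' fecundities of stages 2 and above in proportion to stage basal area.
#' Period estimates are annualized and pooled across periods weighted by
#' stem-years at risk.
#'
#' @param table a [census_table()].
#' @param species species token, or `NULL` to pool all stems.
#' @param scheme a [size_class_scheme()].
#' @param periods list of `c(start, end)` pairs; defaults to consecutive
#'   censuses.
#' @param reproductive_stages stages receiving fecundity (default 2:s).
#' @return a [projection_matrix()] with attributes `n_stage` (initial counts
#'   pooled over periods) and `flag_low_n` (fewer than 5 survivors, the
#'   small-denominator caveat).
#' @export
estimate_matrix <- function(table, species = NULL,
                            scheme = size_class_scheme(), periods = NULL,
                            reproductive_stages = NULL) {
  if (is.null(periods)) {
    cy <- table$census_years
    periods <- lapply(seq_len(length(cy) - 1L), function(i) cy[i + 0:1])
  }
  s <- length(scheme$boundaries)
  if (is.null(reproductive_stages)) reproductive_stages <- seq(2L, s)
  tr <- table$trees
  if (!is.null(species)) tr <- tr[tr$species == species, , drop = FALSE]
  if (!nrow(tr)) stop("no stems for species ", species)
  ## accumulators, stem-year weighted
  w_surv <- matrix(0, 1, s)      # stem-years at risk per stage
  acc_mort <- matrix(0, 1, s)    # weighted annual mortality
  acc_move <- matrix(0, s, s)    # weighted annual move prob (to, from)
  acc_fec <- matrix(0, 1, s)     # weighted annual fecundity
  w_fec <- matrix(0, 1, s)
  n_stage_tot <- rep(0, s)
  n_surv_tot <- 0
  for (p in periods) {
    y0 <- p[1]; y1 <- p[2]; t <- y1 - y0
    a0 <- tr[tr$census_year == y0 & tr$status == "alive", ]
    a1 <- tr[tr$census_year == y1 & tr$status == "alive", ]
    if (!nrow(a0)) next
    st0 <- stage_of(a0$dbh, scheme)
    j1 <- match(a0$tree_id, a1$tree_id)
    surv <- !is.na(j1)
    st1 <- stage_of(a1$dbh[j1[surv]], scheme)
    n_surv_tot <- n_surv_tot + sum(surv)
    ## recruits reaching the threshold during the period
    first_alive <- tapply(tr$census_year[tr$status == "alive"],
                          tr$tree_id[tr$status == "alive"], min)
    n_rec <- sum(first_alive > y0 & first_alive <= y1)
    ba_stage <- tapply(ba_cm2(a0$dbh), factor(st0, levels = 1:s), sum,
                       default = 0)
    for (j in 1:s) {
      n_j <- sum(st0 == j)
      n_stage_tot[j] <- n_stage_tot[j] + n_j
      if (n_j == 0) next
      w <- n_j * t
      sigma_p <- sum(surv & st0 == j) / n_j            # period survival
      m_ann <- 1 - sigma_p^(1 / t)                     # annual mortality
      w_surv[j] <- w_surv[j] + w
      acc_mort[j] <- acc_mort[j] + w * m_ann
      ns_j <- sum(surv & st0 == j)
      if (ns_j > 0) {
        dest <- st1[st0[surv] == j]
        move_p <- tabulate(dest, s) / ns_j             # period move fractions
        away_p <- 1 - move_p[j]                        # left stage j
        away_ann <- 1 - (1 - away_p)^(1 / t)
        move_ann <- rep(0, s)
        if (away_p > 0)
          move_ann <- move_p / away_p * away_ann       # distribute annualized
        move_ann[j] <- 1 - away_ann
        acc_move[, j] <- acc_move[, j] + w * move_ann
      } else {
        acc_move[j, j] <- acc_move[j, j] + w           # no information: stasis
      }
    }
    ## fecundity: recruits per initial stem of reproductive stages,
    ## allocated proportional to stage basal area, divided by t
    ba_rep <- sum(ba_stage[reproductive_stages])
    for (j in reproductive_stages) {
      n_j <- sum(st0 == j)
      if (n_j == 0 || ba_rep == 0) next
      f_period <- n_rec * (ba_stage[j] / ba_rep) / n_j
      w <- n_j * t
      w_fec[j] <- w_fec[j] + w
      acc_fec[j] <- acc_fec[j] + w * f_period / t
    }
  }
  if (all(w_surv == 0)) stop("no stems at risk in any period")
  A <- matrix(0, s, s)
  for (j in 1:s) {
    if (w_surv[j] > 0) {
      s_ann <- 1 - acc_mort[j] / w_surv[j]
      move <- acc_move[, j] / w_surv[j]
      A[, j] <- s_ann * move
    } else {
      A[j, j] <- 1                                     # empty stage: inert
    }
    if (w_fec[j] > 0)
      A[1, j] <- A[1, j] + acc_fec[j] / w_fec[j]
  }
  pm <- projection_matrix(A, scheme,
                          interval_years = vapply(periods,
                                                  function(p) diff(p), 0))
  attr(pm, "n_stage") <- n_stage_tot
  attr(pm, "flag_low_n") <- n_surv_tot < 5
  pm
}

#' Dominant eigenvalue and population growth rate
#'
#' Computes the spectral radius by power iteration (tolerance 1e-10, at most
#' 1e5 iterations) and cross-checks it against a direct eigendecomposition;
#' on non-convergence (reducible or periodic matrices) the direct value is
#' used with a warning. Reported alongside are `r = ln(lambda)` — the
#' headline population growth rate, negative for declining populations —
#' and the stable stage distribution (dominant right eigenvector normalized
#' to sum 1).
#'
#' @param A non-negative square matrix or a [projection_matrix()].
#' @param tol,max_iter power-iteration controls.
#' @return object of class `population_growth`: list with `lambda`, `r`,
#'   `stable_stage`, `converged`.
#' @export
dominant_eigen <- function(A, tol = 1e-10, max_iter = 1e5) {
  if (inherits(A, "projection_matrix")) A <- A$A
  stopifnot(is.matrix(A), nrow(A) == ncol(A), all(A >= 0))
  s <- nrow(A)
  v <- rep(1 / s, s)
  lambda <- NA_real_
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    w <- as.numeric(A %*% v)
    nw <- sum(abs(w))
    if (nw == 0) { lambda <- 0; converged <- TRUE; v <- rep(1 / s, s); break }
    w <- w / nw
    if (max(abs(w - v)) < tol) {
      v <- w
      lambda <- sum(A %*% v) / sum(v)
      converged <- TRUE
      break
    }
    v <- w
  }
  ## cross-check / fallback: direct eigendecomposition
  ev <- eigen(A)
  k <- which.max(abs(ev$values))
  lambda_direct <- abs(ev$values[k])
  vec <- abs(Re(ev$vectors[, k]))
  if (!converged || !is.finite(lambda) ||
      abs(lambda - lambda_direct) > 1e-6 * max(1, lambda_direct)) {
    if (!converged)
      warning("power iteration did not converge; using direct eigendecomposition")
    lambda <- lambda_direct
    v <- vec
  }
  v <- v / sum(v)
  structure(list(lambda = lambda, r = log(lambda), stable_stage = v,
                 converged = converged),
            class = "population_growth")
}

#' Population growth rates for the dominant species
#'
#' Species exceeding 2% of plot density or basal area at the first census
#' (the dominance convention) get a projection matrix and a dominant
#' eigenvalue each. `lambda`, `lambda - 1` and `r = ln(lambda)` are all
#' emitted; `r` is the headline rate.
#'
#' @param table a [census_table()].
#' @param scheme a [size_class_scheme()].
#' @param periods list of census-year pairs, as in [estimate_matrix()].
#' @param dominance_pct dominance threshold in percent.
#' @return data.frame: species, growth_form, lambda, lambda_minus_1, r,
#'   flag_low_n.
#' @export
growth_rate_table <- function(table, scheme = size_class_scheme(),
                              periods = NULL, dominance_pct = 2.0) {
  y1 <- table$census_years[1]
  sm <- summarize_species(table, y1)
  sp <- sm$species
  dom <- 100 * sp$density / sum(sp$density) >= dominance_pct |
         100 * sp$basal_area / sum(sp$basal_area) >= dominance_pct
  doms <- sp$species[dom]
  out <- lapply(doms, function(spp) {
    pm <- estimate_matrix(table, species = spp, scheme = scheme,
                          periods = periods)
    pg <- dominant_eigen(pm)
    data.frame(species = spp,
               growth_form = sp$growth_form[sp$species == spp],
               lambda = pg$lambda, lambda_minus_1 = pg$lambda - 1,
               r = pg$r, flag_low_n = attr(pm, "flag_low_n"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
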