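## Census-based demographic rates.
##
## All three rates are annualized log-ratios over a census period of t years:
##   ingrowth    = ln(BA_s / BA_i) * 100 / t   (survivors' basal area)
##   mortality   = ln(N_i / N_s) * 100 / t
##   recruitment = ln(N_f / N_s) * 100 / t
## with N_i initial stems, N_s survivors, N_f = N_s plus recruits reaching
## the 2.0 cm threshold during the period (including recruits that later
## died, observable whenever an intermediate census tagged them).

#' Annualized ingrowth rate of surviving stems
#'
#' @param BA_i total basal area of the initial stems, period start.
#' @param BA_s total basal area of the survivors, period end (same units).
#' @param t period length, years.
#' @return % per year; negative if the surviving cohort shrank.
#' @export
ingrowth_rate <- function(BA_i, BA_s, t) {
  stopifnot(BA_i > 0, BA_s > 0, t > 0)
  log(BA_s / BA_i) * 100 / t
}

#' Annualized mortality rate
#'
#' @param N_i initial number of stems.
#' @param N_s number still alive at period end.
#' @param t period length, years.
#' @return % per year; `NA` with attribute `undefined` when `N_s = 0` (the
#'   rate has no finite value; downstream reports annotate instead of
#'   printing a number).
#' @export
mortality_rate <- function(N_i, N_s, t) {
  stopifnot(t > 0, N_i >= N_s, N_s >= 0)
  if (N_s == 0)
    return(structure(NA_real_, undefined = "no survivors (N_s = 0)"))
  log(N_i / N_s) * 100 / t
}

#' Annualized recruitment rate
#'
#' @param N_f survivors plus recruits reaching 2.0 cm during the period.
#' @param N_s number of surviving initial stems.
#' @param t period length, years.
#' @return % per year; `NA`-annotated when `N_s = 0`. Small denominators
#'   (`N_s < 5`) inflate this rate; see the `flag_low_n` column emitted by
#'   [species_rates()].
#' @export
recruitment_rate <- function(N_f, N_s, t) {
  stopifnot(t > 0, N_f >= N_s, N_s >= 0)
  if (N_s == 0)
    return(structure(NA_real_, undefined = "no survivors (N_s = 0)"))
  log(N_f / N_s) * 100 / t
}

## per-tree fate extraction -------------------------------------------------

## One row per tree relevant to a period: initial / survivor flags, recruit
## flag (first alive record in (start, end]), and basal areas at both ends.
tree_fates <- function(table, period) {
  y0 <- period[1]; y1 <- period[2]
  if (!all(c(y0, y1) %in% table$census_years) || y1 <= y0)
    stop("period must be two census years, start < end")
  tr <- table$trees
  a0 <- tr[tr$census_year == y0 & tr$status == "alive", ]
  a1 <- tr[tr$census_year == y1 & tr$status == "alive", ]
  first_alive <- tapply(tr$census_year[tr$status == "alive"],
                        tr$tree_id[tr$status == "alive"], min)
  ids <- unique(tr$tree_id[tr$status == "alive"])
  fa <- as.numeric(first_alive[ids])
  meta <- tr[match(ids, tr$tree_id), c("tree_id", "species", "growth_form")]
  f <- data.frame(meta,
                  initial = ids %in% a0$tree_id,
                  surv = ids %in% a0$tree_id & ids %in% a1$tree_id,
                  recruit = fa > y0 & fa <= y1,
                  ba_i = ba_cm2(a0$dbh)[match(ids, a0$tree_id)],
                  ba_f = ba_cm2(a1$dbh)[match(ids, a1$tree_id)],
                  stringsAsFactors = FALSE)
  f <- f[f$initial | f$recruit, , drop = FALSE]
  rownames(f) <- NULL
  f
}

rates_from_fates <- function(f, t) {
  N_i <- sum(f$initial); N_s <- sum(f$surv)
  N_f <- N_s + sum(f$recruit)
  BA_i <- sum(f$ba_i[f$initial], na.rm = TRUE)
  BA_s <- sum(f$ba_f[f$surv], na.rm = TRUE)
  list(N_i = N_i, N_s = N_s, N_f = N_f,
       BA_i = BA_i * 1e-4, BA_s = BA_s * 1e-4,   # cm2 -> m2
       mortality = if (N_i == 0) NA_real_ else
         as.numeric(mortality_rate(N_i, N_s, t)),
       recruitment = if (N_s == 0) NA_real_ else
         as.numeric(recruitment_rate(N_f, N_s, t)),
       ingrowth = if (N_s == 0 || BA_i <= 0 || BA_s <= 0) NA_real_ else
         ingrowth_rate(BA_i, BA_s, t))
}

#' Demographic rates per species, growth form, or whole plot
#'
#' Extracts `N_i`, `N_s`, `N_f`, `BA_i`, `BA_s` from the census table for one
#' period and applies the annualized rate formulas. Groups with `N_s < 5`
#' are flagged (`flag_low_n`): their mortality and recruitment rates are
#' divided by a small survivor count and are easily overestimated.
#'
#' @param table a [census_table()].
#' @param period two census years `c(start, end)`; intermediate censuses are
#'   used to observe recruits that died before `end`.
#' @param grouping `"species"`, `"growth_form"`, or `"plot"`.
#' @param bootstrap if `TRUE`, add percentile bootstrap confidence limits for
#'   mortality and recruitment (and ingrowth), resampling trees with
#'   replacement within each group.
#' @param B,level,seed bootstrap replicates, confidence level, RNG seed.
#' @return data.frame of class `rate_table`, one row per group.
#' @export
species_rates <- function(table, period,
                          grouping = c("species", "growth_form", "plot"),
                          bootstrap = FALSE, B = 1000L, level = 0.95,
                          seed = NULL) {
  grouping <- match.arg(grouping)
  t <- period[2] - period[1]
  f <- tree_fates(table, period)
  key <- switch(grouping, species = f$species, growth_form = f$growth_form,
                plot = rep("plot", nrow(f)))
  groups <- sort(unique(key))
  out <- lapply(groups, function(g) {
    fg <- f[key == g, , drop = FALSE]
    r <- rates_from_fates(fg, t)
    ci <- list(mort = c(NA, NA), recr = c(NA, NA), ingr = c(NA, NA))
    if (bootstrap) {
      ci$mort <- bootstrap_fates(fg, t, "mortality", B, level, seed)
      ci$recr <- bootstrap_fates(fg, t, "recruitment", B, level, seed)
      ci$ingr <- bootstrap_fates(fg, t, "ingrowth", B, level, seed)
    }
    data.frame(group = g,
               growth_form = if (grouping == "species")
                 fg$growth_form[1] else g,
               N_i = r$N_i, N_s = r$N_s, N_f = r$N_f,
               BA_i = r$BA_i, BA_s = r$BA_s,
               mortality = r$mortality, mortality_lo = ci$mort[1],
               mortality_hi = ci$mort[2],
               recruitment = r$recruitment, recruitment_lo = ci$recr[1],
               recruitment_hi = ci$recr[2],
               ingrowth = r$ingrowth, ingrowth_lo = ci$ingr[1],
               ingrowth_hi = ci$ingr[2],
               t = t, start = period[1], end = period[2],
               flag_low_n = r$N_s < 5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out)[1] <- grouping
  class(out) <- c("rate_table", "data.frame")
  out
}

## bootstrap ----------------------------------------------------------------

## Vectorized resampling of a fate table, stratified by species when the
## unit pools several. Returns the replicate statistics.
bootstrap_reps <- function(f, t, statistic, B) {
  n <- nrow(f)
  strata <- if (!is.null(f$species)) f$species else rep("s", n)
  draw_idx <- function(B) {
    idx <- matrix(0L, n, B)
    for (rows in split(seq_len(n), strata))
      idx[rows, ] <- matrix(rows[sample.int(length(rows), length(rows) * B,
                                            replace = TRUE)],
                            nrow = length(rows))
    idx
  }
  stat_one <- function(idx) {
    fi <- f[idx, , drop = FALSE]
    r <- rates_from_fates(fi, t)
    r[[statistic]]
  }
  if (statistic %in% c("mortality", "recruitment")) {
    ## counts only: vectorize via column sums over a resample matrix
    idx <- draw_idx(B)
    ini <- matrix(f$initial[idx], nrow = n)
    srv <- matrix(f$surv[idx], nrow = n)
    N_i <- colSums(ini); N_s <- colSums(srv)
    if (statistic == "mortality") {
      reps <- ifelse(N_s == 0, NA_real_, log(N_i / N_s) * 100 / t)
    } else {
      rec <- matrix(f$recruit[idx], nrow = n)
      N_f <- N_s + colSums(rec)
      reps <- ifelse(N_s == 0, NA_real_, log(N_f / N_s) * 100 / t)
    }
  } else {
    idx <- draw_idx(B)
    reps <- vapply(seq_len(B), function(b) stat_one(idx[, b]), 0)
  }
  reps
}

bootstrap_fates <- function(f, t, statistic, B, level, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(f) == 0L || sum(f$initial) == 0L) return(c(NA_real_, NA_real_))
  reps <- bootstrap_reps(f, t, statistic, B)
  n_undef <- sum(is.na(reps))
  if (n_undef > B / 2)
    stop("statistic undefined on more than half of the resamples (",
         n_undef, "/", B, ")")
  tries <- 0L
  while (anyNA(reps) && tries < 20L) {  # redraw undefined resamples
    k <- sum(is.na(reps))
    reps[is.na(reps)] <- bootstrap_reps(f, t, statistic, k)
    tries <- tries + 1L
  }
  reps <- reps[!is.na(reps)]
  a <- (1 - level) / 2
  ci <- as.numeric(quantile(reps, c(a, 1 - a), names = FALSE, type = 7))
  attr(ci, "n_redrawn") <- n_undef
  ci
}

#' Percentile bootstrap confidence interval for a demographic rate
#'
#' Trees are the resampling unit, drawn with replacement within the grouping
#' unit (a species, a growth form, or the whole plot). Resamples on which
#' the statistic is undefined (no survivors) are redrawn and counted; more
#' than 50% undefined aborts with a diagnostic.
#'
#' @param table a [census_table()].
#' @param statistic_spec list with `statistic` (`"mortality"`,
#'   `"recruitment"` or `"ingrowth"`), `period = c(start, end)`, and
#'   optionally `species` or `growth_form` restricting the unit.
#' @param B number of bootstrap replicates.
#' @param level confidence level.
#' @param seed optional RNG seed.
#' @return numeric `c(low, high)` with attributes `point` (the plug-in
#'   estimate) and `n_redrawn`.
#' @export
bootstrap_ci <- function(table, statistic_spec, B = 1000L, level = 0.95,
                         seed = NULL) {
  stopifnot(B >= 1, !is.null(statistic_spec$statistic),
            !is.null(statistic_spec$period))
  f <- tree_fates(table, statistic_spec$period)
  if (!is.null(statistic_spec$species))
    f <- f[f$species == statistic_spec$species, , drop = FALSE]
  if (!is.null(statistic_spec$growth_form))
    f <- f[f$growth_form == statistic_spec$growth_form, , drop = FALSE]
  t <- statistic_spec$period[2] - statistic_spec$period[1]
  point <- rates_from_fates(f, t)[[statistic_spec$statistic]]
  ci <- bootstrap_fates(f, t, statistic_spec$statistic, B, level, seed)
  attr(ci, "point") <- point
  ci
}

## size classes -------------------------------------------------------------

#' DBH size-class scheme
#'
#' @param boundaries strictly increasing lower class boundaries in cm; the
#'   default `c(2, 4, 8, 16, 32)` gives classes 2.0-3.9, 4.0-7.9, 8.0-15.9,
#'   16.0-31.9 and >= 32 cm. The first boundary must equal the census
#'   threshold. Membership is half-open `[lo, hi)`.
#' @return list of class `size_class_scheme` with `boundaries` and `labels`.
#' @export
size_class_scheme <- function(boundaries = c(2, 4, 8, 16, 32)) {
  stopifnot(length(boundaries) >= 2L,
            !is.unsorted(boundaries, strictly = TRUE),
            boundaries[1] == CENSUS_THRESHOLD_CM)
  s <- length(boundaries)
  labels <- c(paste0("[", boundaries[-s], ",", boundaries[-1], ")"),
              paste0(">=", boundaries[s]))
  structure(list(boundaries = boundaries, labels = labels),
            class = "size_class_scheme")
}

stage_of <- function(dbh, scheme) {
  findInterval(dbh, scheme$boundaries)
}

#' Size-class mortality across census periods
#'
#' Class membership is taken from DBH at each period start: recruits reaching
#' 2.0 cm by a period start join that period's initial counts and survivors
#' that advanced classes are re-binned, so the initial numbers are
#' recalculated for every period exactly as in inter-period cohort
#' bookkeeping.
#'
#' @param table a [census_table()].
#' @param scheme a [size_class_scheme()].
#' @param periods list of `c(start, end)` census-year pairs; defaults to all
#'   consecutive pairs.
#' @param by `"plot"` (pooled) or `"growth_form"`.
#' @param bootstrap,B,level,seed as in [species_rates()]; CIs per class.
#' @return data.frame: period, group, class, N_i, N_s, mortality (+ CI);
#'   empty classes carry `NA` counts with mortality annotated absent.
#' @export
size_class_mortality <- function(table, scheme = size_class_scheme(),
                                 periods = NULL,
                                 by = c("plot", "growth_form"),
                                 bootstrap = FALSE, B = 1000L, level = 0.95,
                                 seed = NULL) {
  by <- match.arg(by)
  if (is.null(periods)) {
    cy <- table$census_years
    periods <- lapply(seq_len(length(cy) - 1L), function(i) cy[i + 0:1])
  }
  tr <- table$trees
  out <- list()
  for (p in periods) {
    y0 <- p[1]; y1 <- p[2]; t <- y1 - y0
    a0 <- tr[tr$census_year == y0 & tr$status == "alive", ]
    alive_end <- tr$tree_id[tr$census_year == y1 & tr$status == "alive"]
    a0$class <- stage_of(a0$dbh, scheme)
    a0$surv <- a0$tree_id %in% alive_end
    grp <- if (by == "plot") rep("plot", nrow(a0)) else a0$growth_form
    for (g in sort(unique(grp))) {
      for (k in seq_along(scheme$labels)) {
        sel <- grp == g & a0$class == k
        N_i <- sum(sel); N_s <- sum(a0$surv[sel])
        m <- if (N_i == 0) NA_real_ else as.numeric(mortality_rate(N_i, N_s, t))
        ci <- c(NA_real_, NA_real_)
        if (bootstrap && N_i > 0 && N_s > 0) {
          fg <- data.frame(initial = rep(TRUE, N_i), surv = a0$surv[sel],
                           recruit = FALSE, ba_i = NA, ba_f = NA)
          ci <- bootstrap_fates(fg, t, "mortality", B, level, seed)
        }
        out[[length(out) + 1L]] <- data.frame(
          start = y0, end = y1, group = g, class = scheme$labels[k],
          N_i = if (N_i == 0) NA_integer_ else N_i,
          N_s = if (N_i == 0) NA_integer_ else N_s,
          mortality = m, mortality_lo = ci[1], mortality_hi = ci[2],
          note = if (N_i == 0) "empty class" else
            if (N_s == 0) "no survivors" else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Standing-dead fraction of all deaths per size class
#'
#' Dead stems recorded during the span are partitioned by death mode; the
#' fraction is standing dead / all dead, per DBH class (at death) and growth
#' form. Standing death is read as senescence or suppression, stem breakage
#' and uprooting as mechanical disturbance.
#'
#' @param table a [census_table()].
#' @param scheme a [size_class_scheme()].
#' @param span two census years; deaths recorded at censuses in
#'   `(start, end]` are counted.
#' @param by `"plot"` or `"growth_form"`.
#' @return data.frame: group, class, n_dead, n_standing, pct_standing.
#'   Empty (no deaths anywhere) gives a zero-row result.
#' @export
standing_dead_fraction <- function(table, scheme = size_class_scheme(),
                                   span = NULL,
                                   by = c("plot", "growth_form")) {
  by <- match.arg(by)
  if (is.null(span))
    span <- range(table$census_years)
  tr <- table$trees
  dead <- tr[tr$status %in% DEATH_MODES &
             tr$census_year > span[1] & tr$census_year <= span[2], ]
  if (nrow(dead) == 0L)
    return(data.frame(group = character(0), class = character(0),
                      n_dead = integer(0), n_standing = integer(0),
                      pct_standing = numeric(0)))
  dead$class <- stage_of(dead$dbh, scheme)
  grp <- if (by == "plot") rep("plot", nrow(dead)) else dead$growth_form
  out <- list()
  for (g in sort(unique(grp))) {
    for (k in seq_along(scheme$labels)) {
      sel <- grp == g & dead$class == k
      n <- sum(sel)
      if (n == 0) next
      ns <- sum(dead$status[sel] == "standing_dead")
      out[[length(out) + 1L]] <- data.frame(
        group = g, class = scheme$labels[k], n_dead = n, n_standing = ns,
        pct_standing = 100 * ns / n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
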