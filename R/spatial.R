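## Bivariate spatial association between two tree layers:
## K12(r) with translation (default) or isotropic edge correction,
## L12(r) = sqrt(K12/pi) - r (0 under independence), and a torus-shift
## Monte Carlo null with pointwise 99% envelopes.

#' Construct a planar point pattern in a rectangular window
#'
#' @param x,y coordinates, m.
#' @param width,height window dimensions, m.
#' @param label free-text label.
#' @return object of class `point_pattern`.
#' @export
point_pattern <- function(x, y, width, height, label = "") {
  stopifnot(length(x) == length(y), length(x) >= 1L,
            all(is.finite(x)), all(is.finite(y)),
            all(x >= 0 & x <= width), all(y >= 0 & y <= height))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 width = as.numeric(width), height = as.numeric(height),
                 label = label, n = length(x)),
            class = "point_pattern")
}

#' Bivariate Ripley K between two point patterns
#'
#' `K12_hat(r) = A/(n1 n2) * sum_ij w_ij 1[d_ij <= r]` with the translation
#' edge correction `w_ij = WH / ((W-|dx|)(H-|dy|))` (exact for rectangles and
#' symmetric in pattern order) or, behind a flag, Ripley's isotropic
#' correction.
#'
#' @param p1,p2 [point_pattern()]s sharing one window.
#' @param r_grid distances, m; `max(r_grid)` must not exceed half the shorter
#'   window side.
#' @param correction `"translation"` or `"isotropic"`.
#' @return numeric vector of K values along `r_grid`.
#' @export
bivariate_K <- function(p1, p2, r_grid = 1:10,
                        correction = c("translation", "isotropic")) {
  correction <- match.arg(correction)
  stopifnot(inherits(p1, "point_pattern"), inherits(p2, "point_pattern"),
            p1$width == p2$width, p1$height == p2$height)
  if (max(r_grid) > min(p1$width, p1$height) / 2)
    stop("r_max exceeds half the shorter window side")
  .k12_cpp(p1$x, p1$y, p2$x, p2$y, p1$width, p1$height,
           as.numeric(r_grid), isotropic = correction == "isotropic")
}

#' L transform of a bivariate K function
#'
#' `L12(r) = sqrt(K12(r)/pi) - r`: about 0 when the two patterns are
#' independent, positive under attraction, negative under repulsion.
#'
#' @param K non-negative K values.
#' @param r matching distances.
#' @return L values.
#' @export
L_transform <- function(K, r) {
  stopifnot(all(K >= 0), length(K) == length(r))
  sqrt(K / pi) - r
}

#' Torus-shift a point pattern
#'
#' Each point maps to `((x + dx) mod W, (y + dy) mod H)`; the pattern's
#' internal structure is preserved under toroidal distances.
#'
#' @param pattern a [point_pattern()].
#' @param dx,dy shift vector, m.
#' @return shifted [point_pattern()].
#' @export
torus_shift <- function(pattern, dx, dy) {
  point_pattern((pattern$x + dx) %% pattern$width,
                (pattern$y + dy) %% pattern$height,
                pattern$width, pattern$height, label = pattern$label)
}

#' Torus-shift envelope test of bivariate association
#'
#' Pattern 1 is torus-shifted by `n_sim` uniform random vectors while
#' pattern 2 stays fixed; pointwise envelopes at each distance are the
#' `ceiling(n_sim*(1-level)/2)`-th smallest and symmetric largest simulated
#' L12 values (ranks 5 and 996 for 1,000 simulations at the 99% level).
#' L12 above the upper envelope is classified `positive`, below the lower
#' `negative`, inside `independent`.
#'
#' @param p1,p2 [point_pattern()]s (each needs at least 2 points).
#' @param r_grid distances, m.
#' @param n_sim number of torus shifts (at least 99).
#' @param level envelope level.
#' @param seed optional RNG seed.
#' @param correction edge correction, as in [bivariate_K()].
#' @return object of class `l12_result`: data.frame `r, L12, env_low,
#'   env_high, classification` plus metadata attributes.
#' @export
envelope_test <- function(p1, p2, r_grid = 1:10, n_sim = 1000L,
                          level = 0.99, seed = NULL,
                          correction = c("translation", "isotropic")) {
  correction <- match.arg(correction)
  stopifnot(n_sim >= 99L, p1$n >= 2L, p2$n >= 2L)
  if (!is.null(seed)) set.seed(seed)
  r <- as.numeric(r_grid)
  obs <- L_transform(bivariate_K(p1, p2, r, correction), r)
  dx <- runif(n_sim, 0, p1$width); dy <- runif(n_sim, 0, p1$height)
  Ksim <- .k12_shift_cpp(p1$x, p1$y, p2$x, p2$y, p1$width, p1$height,
                         r, dx, dy, isotropic = correction == "isotropic")
  Lsim <- sweep(sqrt(Ksim / pi), 2, r)
  lo_rank <- ceiling(n_sim * (1 - level) / 2)
  hi_rank <- n_sim + 1L - lo_rank
  env <- apply(Lsim, 2, function(v) sort(v)[c(lo_rank, hi_rank)])
  cls <- ifelse(obs > env[2, ], "positive",
                ifelse(obs < env[1, ], "negative", "independent"))
  out <- data.frame(r = r, L12 = obs, env_low = env[1, ], env_high = env[2, ],
                    classification = cls, stringsAsFactors = FALSE)
  structure(out, class = c("l12_result", "data.frame"),
            n_sim = n_sim, level = level, correction = correction,
            n1 = p1$n, n2 = p2$n)
}

#' Understory-overstory spatial association grid
#'
#' Builds the nine combinations of understory (DBH 2.0-9.9 cm) and overstory
#' (DBH >= 10.0 cm) point patterns of the three growth forms at one census
#' and runs [envelope_test()] on each. Cells whose layer has fewer than 2
#' stems are skipped with an annotation.
#'
#' @param table a [census_table()].
#' @param year census year.
#' @param r_grid,n_sim,level,seed,correction passed to [envelope_test()].
#' @return 3x3 list (understory form x overstory form) of `l12_result` or a
#'   character skip reason, with class `layer_association`.
#' @export
layer_association <- function(table, year, r_grid = 1:10, n_sim = 1000L,
                              level = 0.99, seed = NULL,
                              correction = "translation") {
  al <- alive_at(table, year)
  forms <- c("EC", "DH", "EH")
  pat <- function(rows, lab) {
    if (nrow(rows) < 2L) return(NULL)
    point_pattern(rows$x, rows$y, table$plot_width, table$plot_height, lab)
  }
  under <- lapply(forms, function(f)
    pat(al[al$growth_form == f & al$dbh < 10, ], paste0(f, "_under")))
  over <- lapply(forms, function(f)
    pat(al[al$growth_form == f & al$dbh >= 10, ], paste0(f, "_over")))
  names(under) <- names(over) <- forms
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(forms, function(f1) {
    row <- lapply(forms, function(f2) {
      if (is.null(under[[f1]]))
        return(paste0("skipped: <2 understory ", f1, " stems"))
      if (is.null(over[[f2]]))
        return(paste0("skipped: <2 overstory ", f2, " stems"))
      envelope_test(under[[f1]], over[[f2]], r_grid, n_sim, level,
                    seed = NULL, correction = correction)
    })
    names(row) <- forms
    row
  })
  names(out) <- forms
  structure(out, class = "layer_association", year = year)
}
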