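## Species-level trait synthesis: correlations among demographic traits,
## principal component analysis over {max DBH, mortality, recruitment,
## ingrowth, population growth rate}, and the packaged species-summary
## dataset of the reference stand.

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y equal-length numeric vectors (n >= 3, finite, non-constant).
#' @return list with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Packaged species summary of the reference stand
#'
#' Species-level records from a 0.5-ha conifer-hardwood mixed stand in
#' central Japan censused 2002-2015: the 16 named dominant species (plus
#' pooled remainder rows, flagged) with density and basal area at the first
#' and last census, observed maximum DBH, and annualized mortality,
#' recruitment and ingrowth rates.
#'
#' @return data.frame with columns `species`, `growth_form`, `density_2002`,
#'   `ba_2002`, `density_2015`, `ba_2015`, `max_dbh`, `mortality`,
#'   `recruitment`, `ingrowth`, `pooled` (TRUE for remainder rows).
#' @export
example_species_summary <- function() {
  read.csv(system.file("extdata", "stand_species_summary.csv",
                       package = "standdyn"),
           stringsAsFactors = FALSE)
}

#' Growth-form totals of the reference stand
#'
#' @return data.frame with per-growth-form and grand-total density (stems/ha)
#'   and basal area (m2/ha) at the 2002 and 2015 censuses, plus the pooled
#'   annualized rates.
#' @export
example_growthform_totals <- function() {
  read.csv(system.file("extdata", "stand_growthform_totals.csv",
                       package = "standdyn"),
           stringsAsFactors = FALSE)
}

#' Join demographic rates, matrix-model output and summaries into traits
#'
#' One row per species: maximum DBH, mortality, recruitment, ingrowth and
#' the matrix-model population growth rate `r`. Species with fewer than 5
#' survivors are marked excluded (small-denominator caveat); species present
#' in only some sources are annotated, not dropped.
#'
#' @param demography_out a [species_rates()] table (grouping `"species"`).
#' @param matrix_out a [growth_rate_table()] data.frame, or `NULL`.
#' @param summaries a [summarize_species()] result (supplies max DBH).
#' @return data.frame of class `species_traits`.
#' @export
trait_table <- function(demography_out, matrix_out, summaries) {
  dm <- as.data.frame(demography_out)
  sp <- summaries$species
  all_sp <- sort(union(dm$species, sp$species))
  mx <- if (!is.null(matrix_out)) matrix_out else
    data.frame(species = character(0), r = numeric(0),
               flag_low_n = logical(0))
  out <- data.frame(
    species = all_sp,
    growth_form = sp$growth_form[match(all_sp, sp$species)],
    max_dbh = sp$max_dbh[match(all_sp, sp$species)],
    mortality = dm$mortality[match(all_sp, dm$species)],
    recruitment = dm$recruitment[match(all_sp, dm$species)],
    ingrowth = dm$ingrowth[match(all_sp, dm$species)],
    r = mx$r[match(all_sp, mx$species)],
    stringsAsFactors = FALSE)
  low_n <- dm$flag_low_n[match(all_sp, dm$species)]
  miss <- !(all_sp %in% dm$species) | !(all_sp %in% sp$species)
  out$excluded <- (low_n %in% TRUE)
  out$reason <- ifelse(low_n %in% TRUE, "low_denominator",
                       ifelse(miss, "partial_join", ""))
  class(out) <- c("species_traits", "data.frame")
  out
}

#' Principal component analysis of species traits
#'
#' Traits are z-score standardized and the correlation matrix
#' eigendecomposed; loading signs are fixed so each column's
#' largest-magnitude entry is positive. Variance explained per component
#' equals the eigenvalues (summing to the number of traits).
#'
#' @param traits a [trait_table()] (excluded rows are dropped) or a plain
#'   numeric data.frame/matrix of traits.
#' @param standardize kept for interface clarity; correlation-matrix PCA
#'   implies standardization.
#' @return object of class `pca_result`: list with `loadings` (traits x
#'   components, orthonormal), `scores` (species x components),
#'   `variance_explained`, `species`.
#' @export
pca <- function(traits, standardize = TRUE) {
  if (inherits(traits, "species_traits")) {
    tt <- traits[!traits$excluded, , drop = FALSE]
    X <- as.matrix(tt[, c("max_dbh", "mortality", "recruitment",
                          "ingrowth", "r")])
    rownames(X) <- tt$species
  } else {
    X <- as.matrix(traits)
  }
  if (nrow(X) < 3L) stop("need at least 3 species")
  if (anyNA(X)) stop("traits contain missing values")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) stop("constant trait column: ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X, center = TRUE, scale = standardize)
  R <- if (standardize) stats::cor(X) else stats::cov(X)
  ed <- eigen(R, symmetric = TRUE)
  L <- ed$vectors
  ## deterministic sign: largest-magnitude loading positive per column
  for (k in seq_len(ncol(L))) {
    i <- which.max(abs(L[, k]))
    if (L[i, k] < 0) L[, k] <- -L[, k]
  }
  dimnames(L) <- list(colnames(X), paste0("PC", seq_len(ncol(L))))
  scores <- Z %*% L
  structure(list(loadings = L, scores = scores,
                 variance_explained = ed$values,
                 species = rownames(X)),
            class = "pca_result")
}
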