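# Agreement scoring between MRI-derived and histology-derived non-viable
# tumor volume fractions, and the three-step feature-vector selection:
# (1) coefficient of determination to the line of identity, (2) group-wise
# Pearson correlations with Wolfe's test for dependent correlations,
# (3) pre-treatment rim misassignment.

#' Histology-derived non-viable volume fraction
#'
#' Area-weighted aggregate over sections: the sum of non-viable areas divided
#' by the sum of total tumor areas (not the mean of per-section ratios).
#'
#' @param sections `data.frame` with columns `area_nonviable_mm2` and
#'   `area_total_mm2` (or any two columns passed as `nonviable`/`total`).
#' @param nonviable,total optional numeric vectors overriding the columns.
#' @return The volume fraction in `[0, 1]`.
#' @export
histology_volume_fraction <- function(sections = NULL, nonviable = NULL,
                                      total = NULL) {
  if (is.null(nonviable)) nonviable <- sections$area_nonviable_mm2
  if (is.null(total)) total <- sections$area_total_mm2
  if (any(total <= 0)) stop("total areas must be positive")
  if (any(nonviable > total + 1e-12))
    stop("non-viable area exceeds total area in some section")
  if (any(nonviable < 0)) stop("non-viable areas must be non-negative")
  sum(nonviable) / sum(total)
}

#' Coefficient of determination to the line of identity
#'
#' `R^2 = 1 - sum((y - x)^2) / sum((y - mean(y))^2)`: one-to-one
#' correspondence of paired fractions to `y = x`. Unlike a regression R^2 it
#' can be negative, when the deviations from identity exceed the variance
#' of `y`.
#'
#' @param x,y numeric vectors of equal length (n >= 2), e.g. histology- and
#'   MRI-derived fractions.
#' @return The coefficient of determination (may be negative).
#' @export
r2_to_identity <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("zero variance in y: R^2 to identity undefined")
  1 - sum((y - x)^2) / ss_tot
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation with validation (n >= 3, both
#' variances positive).
#'
#' @param x,y numeric vectors of equal length.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("Pearson correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y, method = "pearson")
}

#' Wolfe's test for comparing dependent correlation coefficients
#'
#' Tests `H0: cor(x, y1) = cor(x, y2)` for two correlations sharing the
#' variable `x`, measured on the same subjects. After standardizing `y1` and
#' `y2` to zero mean and unit variance, `cov(x, y1* - y2*) =
#' sd(x) (cor(x,y1) - cor(x,y2))`, so the hypothesis reduces to the
#' significance of the correlation between `x` and `y1* - y2*`, assessed with
#' the usual t statistic on n - 2 degrees of freedom (two-sided). Identical
#' `y1` and `y2` give statistic 0 and p = 1 by convention.
#'
#' @param x common variable.
#' @param y1,y2 the two variables whose correlations with `x` are compared.
#' @return list with `statistic` (t), `r` (correlation of x with the
#'   standardized difference), `p`, `n`.
#' @export
wolfe_dependent_correlation_test <- function(x, y1, y2) {
  n <- length(x)
  stopifnot(length(y1) == n, length(y2) == n)
  if (n < 4L) stop("Wolfe's test needs n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y1) == 0 || stats::sd(y2) == 0)
    stop("zero variance: test undefined")
  z1 <- (y1 - mean(y1)) / stats::sd(y1)
  z2 <- (y2 - mean(y2)) / stats::sd(y2)
  d <- z1 - z2
  if (stats::sd(d) == 0)
    return(list(statistic = 0, r = 0, p = 1, n = n))
  r <- stats::cor(x, d)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(statistic = t, r = r, p = p, n = n)
}

#' Pre-treatment rim misassignment fraction
#'
#' Fraction of tumor-rim voxels incorrectly labeled non-viable before
#' treatment. The rim is the tumor mask minus its 2-D (per-slice,
#' 4-connected) erosion by `rim_thickness`; where a slice erodes away
#' entirely the rim is the whole in-slice tumor (degenerate thin-tumor
#' behavior). The fraction is computed over included (viable or non-viable)
#' rim voxels of one tumor.
#'
#' @param viability_volume integer viability volume (1 viable, 2 non-viable,
#'   -1 excluded, 0 outside) from [make_viability_map()].
#' @param tumor_mask logical tumor mask.
#' @param rim_thickness rim thickness in voxels (default 3).
#' @return The misassignment fraction in `[0, 1]` (NA if the rim holds no
#'   included voxels).
#' @export
rim_misassignment_fraction <- function(viability_volume, tumor_mask,
                                       rim_thickness = 3L) {
  stopifnot(identical(dim(viability_volume), dim(tumor_mask)))
  rim <- tumor_mask & !erode_slices(tumor_mask, rim_thickness)
  v <- viability_volume[rim]
  n_inc <- sum(v == VIABILITY_CODES[["viable"]] |
                 v == VIABILITY_CODES[["nonviable"]])
  if (n_inc == 0L) return(NA_real_)
  sum(v == VIABILITY_CODES[["nonviable"]]) / n_inc
}

#' Feature-vector selection by agreement with histology
#'
#' Applies the three selection criteria in order: (1) retain feature vectors
#' whose R^2 of MRI-derived vs histology-derived non-viable fractions to the
#' line of identity exceeds `r2_threshold`; (2) report group-wise Pearson
#' correlations ('1h + control' and '72h + control') with Wolfe-test
#' comparisons among the retained vectors; (3) rank the retained vectors by
#' mean pre-treatment rim misassignment and select the lowest. With a single
#' retained vector it is selected regardless of criteria 2-3; with none, the
#' selection is empty but all statistics are still reported.
#'
#' @param pairs `data.frame` with columns `feature_vector`, `animal`, `group`
#'   (`"1h"`, `"72h"` or `"control"`), `histology` and `isodata` (fractions);
#'   one row per tumor per feature vector.
#' @param rim optional `data.frame` with columns `feature_vector` and
#'   `rim_fraction` (mean pre-treatment rim misassignment); required to rank
#'   several retained vectors, otherwise the retained vector with the highest
#'   R^2 is selected.
#' @param r2_threshold criterion-1 cut (default 0.7).
#' @param alpha significance level for the Wolfe comparisons.
#' @return An object of class `feature_evaluation`: list with `r2`
#'   (per-vector R^2 table), `retained`, `correlations`, `wolfe`, `rim`,
#'   `selected` (character or `NA`), and the thresholds used.
#' @export
evaluate_feature_vectors <- function(pairs, rim = NULL, r2_threshold = 0.7,
                                     alpha = 0.05) {
  needed <- c("feature_vector", "animal", "group", "histology", "isodata")
  if (!all(needed %in% names(pairs)))
    stop("pairs must have columns: ", paste(needed, collapse = ", "))
  fvs <- unique(pairs$feature_vector)

  r2 <- data.frame(feature_vector = fvs,
                   r2_identity = vapply(fvs, function(f) {
                     p <- pairs[pairs$feature_vector == f, ]
                     tryCatch(r2_to_identity(p$histology, p$isodata),
                              error = function(e) NA_real_)
                   }, numeric(1)),
                   stringsAsFactors = FALSE)
  retained <- r2$feature_vector[!is.na(r2$r2_identity) &
                                  r2$r2_identity > r2_threshold]

  groups <- list(`1h+control` = c("1h", "control"),
                 `72h+control` = c("72h", "control"))
  cor_rows <- list()
  for (f in fvs) for (g in names(groups)) {
    p <- pairs[pairs$feature_vector == f & pairs$group %in% groups[[g]], ]
    r <- tryCatch(pearson_r(p$histology, p$isodata), error = function(e) NA_real_)
    cor_rows[[paste(f, g)]] <- data.frame(feature_vector = f, group = g,
                                          r = r, n = nrow(p),
                                          stringsAsFactors = FALSE)
  }
  correlations <- do.call(rbind, c(cor_rows, list(make.row.names = FALSE)))

  wolfe_rows <- list()
  if (length(retained) >= 2L) {
    cmb <- utils::combn(retained, 2L)
    for (g in names(groups)) for (j in seq_len(ncol(cmb))) {
      f1 <- cmb[1, j]; f2 <- cmb[2, j]
      p1 <- pairs[pairs$feature_vector == f1 & pairs$group %in% groups[[g]], ]
      p2 <- pairs[pairs$feature_vector == f2 & pairs$group %in% groups[[g]], ]
      p2 <- p2[match(p1$animal, p2$animal), ]
      w <- tryCatch(
        wolfe_dependent_correlation_test(p1$histology, p1$isodata, p2$isodata),
        error = function(e) list(statistic = NA_real_, p = NA_real_,
                                 n = nrow(p1)))
      wolfe_rows[[paste(g, f1, f2)]] <- data.frame(
        group = g, feature_vector_1 = f1, feature_vector_2 = f2,
        statistic = w$statistic, p = w$p, n = w$n,
        significant = !is.na(w$p) && w$p < alpha, stringsAsFactors = FALSE)
    }
  }
  wolfe <- if (length(wolfe_rows))
    do.call(rbind, c(wolfe_rows, list(make.row.names = FALSE))) else NULL

  selected <- NA_character_
  if (length(retained) == 1L) {
    selected <- retained
  } else if (length(retained) > 1L) {
    if (!is.null(rim) && all(retained %in% rim$feature_vector)) {
      rr <- rim$rim_fraction[match(retained, rim$feature_vector)]
      ord <- order(rr, -r2$r2_identity[match(retained, r2$feature_vector)])
      selected <- retained[ord[1]]
    } else {
      selected <- retained[which.max(r2$r2_identity[
        match(retained, r2$feature_vector)])]
    }
  }

  structure(list(r2 = r2, retained = retained, correlations = correlations,
                 wolfe = wolfe, rim = rim, selected = selected,
                 r2_threshold = r2_threshold, alpha = alpha),
            class = "feature_evaluation")
}

#' @export
print.feature_evaluation <- function(x, ...) {
  cat("Feature-vector evaluation (agreement with histology)\n")
  r2 <- x$r2[order(-x$r2$r2_identity), ]
  for (i in seq_len(nrow(r2)))
    cat(sprintf("  %-20s R2 to identity = %6.2f%s\n", r2$feature_vector[i],
                r2$r2_identity[i],
                if (r2$feature_vector[i] %in% x$retained) "  [retained]" else ""))
  if (!is.na(x$selected)) cat("Selected feature vector:", x$selected, "\n")
  else cat("No feature vector passed the R2 threshold of",
           x$r2_threshold, "\n")
  invisible(x)
}
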