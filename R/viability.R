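# Conversion of cluster labels into a binary viable / non-viable tissue map:
# per-tumor cluster occupancy fractions, the temporal paired t-test rule for
# classifying clusters, viability label volumes and per-tumor non-viable
# volume fractions, and per-class parameter summaries.

#' Per-tumor cluster occupancy fractions
#'
#' For every (animal, time point) the fraction of that tumor's included
#' voxels carrying each cluster label. Clusters absent from a tumor get
#' fraction 0, so fractions sum to 1 per tumor and time point.
#'
#' @param model an `isodata_model`.
#' @param fm the `feature_matrix` the model was fitted on (provides the
#'   (animal, time point) back-references).
#' @return A `data.frame` with columns `animal`, `group`, `timepoint`,
#'   `cluster`, `n`, `fraction`.
#' @export
cluster_fraction_table <- function(model, fm) {
  idx <- fm$index
  if (length(model$labels) != nrow(idx))
    stop("label vector and feature-matrix index differ in length")
  key <- interaction(idx$animal, idx$timepoint, drop = TRUE, lex.order = TRUE)
  tums <- !duplicated(key)
  meta <- data.frame(animal = idx$animal[tums], group = idx$group[tums],
                     timepoint = idx$timepoint[tums],
                     key = as.character(key[tums]), stringsAsFactors = FALSE)
  counts <- table(key, factor(model$labels, levels = seq_len(model$k)))
  totals <- rowSums(counts)
  out <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    cr <- counts[meta$key[i], ]
    data.frame(animal = meta$animal[i], group = meta$group[i],
               timepoint = meta$timepoint[i],
               cluster = seq_len(model$k), n = as.integer(cr),
               fraction = as.numeric(cr) / totals[meta$key[i]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Paired Student's t-test
#'
#' Two-sided paired t-test on per-animal values: `t = mean(d) / (sd(d)/sqrt(n))`
#' with `d = after - before` and `n - 1` degrees of freedom. Zero-variance
#' differences use the documented convention `p = 0` when the mean difference
#' is non-zero and `p = 1` when it is zero.
#'
#' @param before,after numeric vectors of equal length (paired by animal).
#' @return list with `t`, `p`, `mean_diff`, `n`, `df`.
#' @export
paired_t_test <- function(before, after) {
  if (length(before) != length(after))
    stop("before and after must have equal length (paired by animal)")
  n <- length(before)
  if (n < 2L) stop("paired t-test needs at least 2 pairs")
  d <- after - before
  md <- mean(d)
  s <- stats::sd(d)
  if (s <= 1e-12 * max(abs(d), 1e-300)) {   # zero variance up to rounding
    t <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    t <- md / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1L)
  }
  list(t = t, p = p, mean_diff = md, n = n, df = n - 1L)
}

#' Classify clusters as viable or non-viable
#'
#' A cluster is called non-viable when, among treated animals only, the
#' fraction of pixels assigned to it increased significantly after treatment
#' -- pre vs 1 h over all treated animals, or pre vs 72 h over the treated
#' animals with a 72 h scan (paired t-test, two-sided `p < alpha`, positive
#' mean difference). All remaining clusters are viable. Controls never enter
#' the tests.
#'
#' @param fractions a cluster fraction table from [cluster_fraction_table()].
#' @param design the [cohort_design()].
#' @param alpha significance level (default 0.05).
#' @return An object of class `cluster_class_map`: `data.frame` with one row
#'   per cluster: the two test statistics and the assigned `class`.
#' @export
classify_clusters <- function(fractions, design, alpha = 0.05) {
  treated <- design$animals$animal[design$animals$group == "treated"]
  if (!length(treated)) stop("no treated animals in the design")
  treated72 <- design$animals$animal[design$animals$group == "treated" &
                                       design$animals$has_72h]
  clusters <- sort(unique(fractions$cluster))
  get_frac <- function(animals, tp, cl) {
    vapply(animals, function(a) {
      v <- fractions$fraction[fractions$animal == a &
                                fractions$timepoint == tp &
                                fractions$cluster == cl]
      if (!length(v)) 0 else v[1]
    }, numeric(1))
  }
  rows <- lapply(clusters, function(cl) {
    t1h <- paired_t_test(get_frac(treated, "pre", cl),
                         get_frac(treated, "1h", cl))
    if (length(treated72) >= 2L) {
      t72 <- paired_t_test(get_frac(treated72, "pre", cl),
                           get_frac(treated72, "72h", cl))
    } else {
      t72 <- list(t = NA_real_, p = NA_real_, mean_diff = NA_real_)
    }
    nonviable <- (t1h$p < alpha && t1h$mean_diff > 0) ||
      (!is.na(t72$p) && t72$p < alpha && t72$mean_diff > 0)
    data.frame(cluster = cl,
               t_1h = t1h$t, p_1h = t1h$p, mean_diff_1h = t1h$mean_diff,
               t_72h = t72$t, p_72h = t72$p, mean_diff_72h = t72$mean_diff,
               class = if (nonviable) "nonviable" else "viable",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_class_map", class(out))
  out
}

# Integer codes of viability label volumes (0 = outside tumor).
VIABILITY_CODES <- c(outside = 0L, viable = 1L, nonviable = 2L, excluded = -1L)

#' Viability label volumes and per-tumor non-viable fractions
#'
#' Maps every included tumor voxel to viable or non-viable through the cluster
#' class map and computes, per tumor and time point, the non-viable volume
#' fraction over included voxels (excluded voxels appear in neither numerator
#' nor denominator).
#'
#' @param model an `isodata_model`.
#' @param fm the `feature_matrix` the model was fitted on.
#' @param class_map a `cluster_class_map` from [classify_clusters()].
#' @param fitted_scans the scan list used to build `fm` (provides masks).
#' @return list with `volumes` (named list of integer volumes: 1 viable,
#'   2 non-viable, -1 excluded, 0 outside the tumor) and `fractions`
#'   (`data.frame` per animal x time point).
#' @export
make_viability_map <- function(model, fm, class_map, fitted_scans) {
  if (!all(model$labels %in% class_map$cluster))
    stop("class map does not cover all cluster labels")
  cls <- class_map$class[match(model$labels, class_map$cluster)]
  idx <- fm$index
  volumes <- list()
  fr_rows <- list()
  for (i in seq_along(fitted_scans)) {
    sc <- fitted_scans[[i]]
    rows <- which(idx$scan == i)
    vol <- array(VIABILITY_CODES[["outside"]], dim(sc$maps$tumor_mask))
    vol[sc$maps$exclusion_mask] <- VIABILITY_CODES[["excluded"]]
    vol[idx$voxel[rows]] <- ifelse(cls[rows] == "nonviable",
                                   VIABILITY_CODES[["nonviable"]],
                                   VIABILITY_CODES[["viable"]])
    key <- paste(sc$animal, sc$timepoint, sep = "_")
    volumes[[key]] <- vol
    n_nv <- sum(cls[rows] == "nonviable")
    n_v <- sum(cls[rows] == "viable")
    fr_rows[[key]] <- data.frame(
      animal = sc$animal, group = sc$group, timepoint = sc$timepoint,
      sacrifice = isTRUE(sc$sacrifice),
      n_viable = n_v, n_nonviable = n_nv,
      fraction = if (n_v + n_nv > 0) n_nv / (n_v + n_nv) else NA_real_,
      stringsAsFactors = FALSE)
  }
  fractions <- do.call(rbind, c(fr_rows, list(make.row.names = FALSE)))
  list(volumes = volumes, fractions = fractions)
}

#' Per-class MRI parameter summary
#'
#' Mean R1, R2 (voxelwise reciprocals of the fitted T1, T2 maps, averaged
#' after conversion), ADC and MTR in viable and non-viable tumor tissue of the
#' treated animals: per animal, the viable mean pools that animal's viable
#' voxels over all its time points; non-viable means are per post-treatment
#' time point. Group values are mean and SD across animals, with paired
#' t-tests viable vs non-viable at 1 h and at 72 h (animals without
#' non-viable voxels at a compared time point are dropped from that pairing
#' with a warning).
#'
#' @param fitted_scans scan list with `maps` per scan.
#' @param viability result of [make_viability_map()].
#' @param design the [cohort_design()].
#' @return list with `summary` (`data.frame`: parameter, tissue class, mean,
#'   sd, n animals) and `tests` (paired viable-vs-non-viable t-tests).
#' @export
summarize_parameters <- function(fitted_scans, viability, design) {
  treated <- design$animals$animal[design$animals$group == "treated"]
  params <- c("R1", "R2", "ADC", "MTR")
  voxel_values <- function(sc, code) {
    vol <- viability$volumes[[paste(sc$animal, sc$timepoint, sep = "_")]]
    sel <- which(vol == code)
    list(R1 = 1000 / sc$maps$T1[sel], R2 = 1000 / sc$maps$T2[sel],
         ADC = sc$maps$ADC[sel], MTR = sc$maps$MTR[sel])
  }
  per_animal <- list()
  scanned <- list(nonviable_1h = character(0), nonviable_72h = character(0))
  for (a in treated) {
    scans_a <- Filter(function(s) s$animal == a, fitted_scans)
    viable_vals <- lapply(params, function(p) numeric(0))
    names(viable_vals) <- params
    nv_1h <- nv_72h <- NULL
    for (sc in scans_a) {
      vv <- voxel_values(sc, VIABILITY_CODES[["viable"]])
      for (p in params) viable_vals[[p]] <- c(viable_vals[[p]], vv[[p]])
      if (sc$timepoint == "1h") {
        nv_1h <- voxel_values(sc, VIABILITY_CODES[["nonviable"]])
        scanned$nonviable_1h <- c(scanned$nonviable_1h, a)
      }
      if (sc$timepoint == "72h") {
        nv_72h <- voxel_values(sc, VIABILITY_CODES[["nonviable"]])
        scanned$nonviable_72h <- c(scanned$nonviable_72h, a)
      }
    }
    per_animal[[a]] <- list(
      viable = vapply(params, function(p) mean(viable_vals[[p]]), numeric(1)),
      nonviable_1h = if (!is.null(nv_1h) && length(nv_1h$ADC))
        vapply(params, function(p) mean(nv_1h[[p]]), numeric(1)) else NULL,
      nonviable_72h = if (!is.null(nv_72h) && length(nv_72h$ADC))
        vapply(params, function(p) mean(nv_72h[[p]]), numeric(1)) else NULL
    )
  }
  gather <- function(slot) {
    vals <- Filter(Negate(is.null), lapply(per_animal, `[[`, slot))
    if (!length(vals)) return(NULL)
    do.call(rbind, vals)
  }
  sum_rows <- list()
  for (slot in c("viable", "nonviable_1h", "nonviable_72h")) {
    M <- gather(slot)
    if (is.null(M)) next
    for (p in params)
      sum_rows[[paste(slot, p)]] <- data.frame(
        parameter = p, class = slot, mean = mean(M[, p]),
        sd = stats::sd(M[, p]), n_animals = nrow(M),
        stringsAsFactors = FALSE)
  }
  test_rows <- list()
  for (tp_slot in c("nonviable_1h", "nonviable_72h")) {
    have <- names(Filter(function(x) !is.null(x[[tp_slot]]), per_animal))
    # warn only about animals that were scanned but have no non-viable voxels
    dropped <- setdiff(scanned[[tp_slot]], have)
    if (length(dropped))
      warning(sprintf("no non-viable voxels at %s for: %s (dropped)",
                      sub("nonviable_", "", tp_slot),
                      paste(dropped, collapse = ", ")))
    if (length(have) < 2L) next
    for (p in params) {
      v <- vapply(per_animal[have], function(x) x$viable[[p]], numeric(1))
      nv <- vapply(per_animal[have], function(x) x[[tp_slot]][[p]], numeric(1))
      tst <- paired_t_test(v, nv)
      test_rows[[paste(tp_slot, p)]] <- data.frame(
        parameter = p, comparison = tp_slot, t = tst$t, p_value = tst$p,
        mean_diff = tst$mean_diff, n = tst$n, stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, c(sum_rows, list(make.row.names = FALSE))),
       tests = if (length(test_rows))
         do.call(rbind, c(test_rows, list(make.row.names = FALSE))) else NULL)
}
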