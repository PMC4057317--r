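# ISODATA clustering of pooled tumor voxels: feature-matrix assembly across
# animals and time points, z-score normalization, and the iterative
# split/merge clustering algorithm with k-means++ seeding.

#' The eleven study feature vectors
#'
#' Ordered subsets of the quantitative MRI parameters used as clustering
#' feature vectors when reproducing the study design.
#'
#' @return A named list of character vectors.
#' @export
study_feature_vectors <- function() {
  fvs <- list(
    c("T2"), c("ADC"),
    c("T1", "T2"), c("T2", "ADC"), c("T1", "ADC"), c("ADC", "MTR"),
    c("T1", "T2", "ADC"), c("T2", "ADC", "MTR"), c("T1", "ADC", "MTR"),
    c("T1", "T2", "MTR"),
    c("T1", "T2", "ADC", "MTR")
  )
  names(fvs) <- vapply(fvs, paste, "", collapse = "+")
  fvs
}

#' Assemble the pooled voxel feature matrix
#'
#' Pools the included tumor voxels of all scans (animals x time points) into
#' one matrix with the requested features as columns, in the given order.
#' Row order is deterministic: scans in cohort order, voxels in array linear
#' order. Excluded voxels (noise level or unfittable) never appear.
#'
#' @param fitted_scans list of scans, each a list with `animal`, `group`,
#'   `timepoint`, `sacrifice` and `maps` (a `parameter_map_set`).
#' @param features character vector, subset of `c("T1","T2","ADC","MTR")`.
#' @return An object of class `feature_matrix`: list with numeric matrix `X`
#'   (voxels x features), `index` (`data.frame` back-referencing scan, animal,
#'   group, timepoint and voxel linear index) and `features`.
#' @export
assemble_feature_matrix <- function(fitted_scans, features) {
  stopifnot(length(features) >= 1L)
  bad <- setdiff(features, c("T1", "T2", "ADC", "MTR"))
  if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "))
  xs <- vector("list", length(fitted_scans))
  idx <- vector("list", length(fitted_scans))
  for (i in seq_along(fitted_scans)) {
    sc <- fitted_scans[[i]]
    maps <- sc$maps
    if (is.null(maps)) stop(sprintf("missing maps for %s/%s",
                                    sc$animal, sc$timepoint))
    vox <- which(maps$included_mask)
    cols <- lapply(features, function(f) {
      v <- maps[[f]][vox]
      if (anyNA(v)) stop(sprintf("missing %s map values for %s/%s",
                                 f, sc$animal, sc$timepoint))
      v
    })
    xs[[i]] <- do.call(cbind, cols)
    idx[[i]] <- data.frame(scan = i, animal = sc$animal, group = sc$group,
                           timepoint = sc$timepoint, voxel = vox,
                           stringsAsFactors = FALSE)
  }
  X <- do.call(rbind, xs)
  colnames(X) <- features
  structure(list(X = X, index = do.call(rbind, idx), features = features),
            class = "feature_matrix")
}

#' Z-score feature normalization
#'
#' Centers each feature to mean 0 and scales it to (sample) standard
#' deviation 1 to remove scaling differences between parameters before
#' clustering. The statistics are stored for inverse transformation and for
#' normalizing out-of-sample voxels.
#'
#' @param fm a `feature_matrix` (or plain numeric matrix).
#' @return The input with normalized `X` and added `center`/`scale` vectors.
#' @export
normalize_features <- function(fm) {
  plain <- !inherits(fm, "feature_matrix")
  X <- if (plain) as.matrix(fm) else fm$X
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(!is.finite(scl)) || any(scl <= 0))
    stop("zero-variance feature column: cannot normalize")
  Xn <- sweep(sweep(X, 2L, ctr, `-`), 2L, scl, `/`)
  if (plain) {
    attr(Xn, "center") <- ctr
    attr(Xn, "scale") <- scl
    return(Xn)
  }
  fm$X <- Xn
  fm$center <- ctr
  fm$scale <- scl
  fm
}

#' ISODATA parameters
#'
#' @param n_init initial number of clusters (k-means++ seeding).
#' @param min_size minimum cluster size (voxels); clusters falling below it
#'   are discarded and their members reassigned. `NULL` means
#'   `max(25, 0.0005 * n_rows)`.
#' @param split_sd split threshold: a cluster whose largest per-dimension SD
#'   (normalized feature units) exceeds this is split along that dimension.
#' @param merge_dist merge threshold: centroid pairs closer (Euclidean,
#'   normalized space) than this are merged.
#' @param max_merge maximum number of merges per merge phase.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on centroid motion.
#' @param split,merge logical switches; disabling both reduces the algorithm
#'   to Lloyd's k-means from the k-means++ initialization.
#' @param seed integer seed for the initialization.
#' @return An object of class `isodata_params`.
#' @export
isodata_params <- function(n_init = 16L, min_size = NULL, split_sd = 0.8,
                           merge_dist = 0.4, max_merge = 2L, max_iter = 200L,
                           tol = 1e-4, split = TRUE, merge = TRUE, seed = 1L) {
  if (!is.null(min_size) && min_size < 1) stop("min_size must be >= 1")
  if (split_sd <= 0 || merge_dist <= 0 || tol <= 0)
    stop("split_sd, merge_dist and tol must be positive")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(n_init = as.integer(n_init), min_size = min_size,
                 split_sd = split_sd, merge_dist = merge_dist,
                 max_merge = as.integer(max_merge),
                 max_iter = as.integer(max_iter), tol = tol,
                 split = isTRUE(split), merge = isTRUE(merge),
                 seed = as.integer(seed)),
            class = "isodata_params")
}

# squared Euclidean distances rows(X) x rows(C)
dist2_to_centers <- function(X, C) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  pmax(d2, 0)
}

nearest_center <- function(X, C) {
  max.col(-dist2_to_centers(X, C), ties.method = "first")
}

# k-means++ seeding with a fixed seed.
kmeanspp_init <- function(X, k, seed) {
  n <- nrow(X)
  with_seed(seed, {
    C <- matrix(NA_real_, k, ncol(X))
    i <- sample.int(n, 1L)
    C[1L, ] <- X[i, ]
    d2 <- rowSums(sweep(X, 2L, C[1L, ], `-`)^2)
    for (j in seq_len(k - 1L) + 1L) {
      i <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
      C[j, ] <- X[i, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, C[j, ], `-`)^2))
    }
    C
  })
}

update_centers <- function(X, labels, k) {
  sizes <- tabulate(labels, k)
  C <- rowsum(X, factor(labels, levels = seq_len(k)), reorder = TRUE)
  C / pmax(sizes, 1L)
}

#' ISODATA iterative split/merge clustering
#'
#' K-means-like clustering in which the number of clusters is adjusted
#' iteratively: after each assignment pass, clusters smaller than the minimum
#' size are discarded, clusters whose largest per-dimension standard deviation
#' exceeds the split threshold are split in two (centroids offset by half the
#' threshold along that dimension; only while the cluster count is below twice
#' the initial count, on alternating iterations), and centroid pairs closer
#' than the merge threshold are merged (up to `max_merge` per merge phase).
#' Iteration stops when labels are stable with no structural change, when
#' centroid motion falls below the tolerance, or at `max_iter` (with a
#' warning flag in the iteration log).
#'
#' @param x a normalized `feature_matrix` (from [normalize_features()]) or a
#'   plain numeric matrix already in normalized space.
#' @param params an [isodata_params()].
#' @return An object of class `isodata_model`: list with `centers` (k x p, in
#'   normalized space), `labels` (per input row; clusters renumbered by
#'   decreasing size), `k`, `sizes`, `wcss`, iteration `log`, `converged`,
#'   the normalization `center`/`scale` (if available) and `features`.
#' @export
isodata_cluster <- function(x, params = isodata_params()) {
  stopifnot(inherits(params, "isodata_params"))
  fm <- if (inherits(x, "feature_matrix")) x else NULL
  X <- if (is.null(fm)) as.matrix(x) else fm$X
  n <- nrow(X)
  if (n < params$n_init)
    stop("fewer rows than initial clusters")
  min_size <- params$min_size %||% max(25, ceiling(5e-4 * n))

  C <- kmeanspp_init(X, params$n_init, params$seed)
  labels <- rep(0L, n)
  log_rows <- list()
  converged <- FALSE

  for (iter in seq_len(params$max_iter)) {
    new_labels <- nearest_center(X, C)
    sizes <- tabulate(new_labels, nrow(C))
    structural <- FALSE
    n_disc <- 0L
    # discard empty / undersized clusters (always keep at least one)
    small <- which(sizes < min_size)
    if (length(small) && length(small) < nrow(C)) {
      C <- C[-small, , drop = FALSE]
      n_disc <- length(small)
      structural <- TRUE
      new_labels <- nearest_center(X, C)
      sizes <- tabulate(new_labels, nrow(C))
    }
    Cnew <- update_centers(X, new_labels, nrow(C))
    motion <- sqrt(max(rowSums((Cnew - C)^2)))
    C <- Cnew
    wcss <- sum((X - C[new_labels, , drop = FALSE])^2)
    stable <- iter > 1L && all(new_labels == labels)
    labels <- new_labels

    n_split <- 0L
    n_merge <- 0L
    if (params$split && iter %% 2L == 1L && nrow(C) < 2L * params$n_init) {
      sds <- matrix(0, nrow(C), ncol(X))
      for (j in seq_len(nrow(C))) {
        mem <- labels == j
        if (sum(mem) >= 2L)
          sds[j, ] <- apply(X[mem, , drop = FALSE], 2L, stats::sd)
      }
      worst <- apply(sds, 1L, max)
      to_split <- order(worst, decreasing = TRUE)
      to_split <- to_split[worst[to_split] > params$split_sd]
      for (j in to_split) {
        if (nrow(C) >= 2L * params$n_init) break
        dim_j <- which.max(sds[j, ])
        offset <- rep(0, ncol(X))
        offset[dim_j] <- params$split_sd / 2
        C <- rbind(C, C[j, ] + offset)
        C[j, ] <- C[j, ] - offset
        n_split <- n_split + 1L
      }
      if (n_split > 0L) structural <- TRUE
    } else if (params$merge && iter %% 2L == 0L && nrow(C) > 1L) {
      D <- dist2_to_centers(C, C)
      diag(D) <- Inf
      pairs <- which(D < params$merge_dist^2, arr.ind = TRUE)
      pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
      if (nrow(pairs)) {
        pairs <- pairs[order(D[pairs]), , drop = FALSE]
        used <- rep(FALSE, nrow(C))
        drop_idx <- integer(0)
        sizes <- tabulate(labels, nrow(C))
        for (r in seq_len(nrow(pairs))) {
          if (n_merge >= params$max_merge) break
          i1 <- pairs[r, 1]; i2 <- pairs[r, 2]
          if (used[i1] || used[i2]) next
          w <- sizes[i1] + sizes[i2]
          C[i1, ] <- (sizes[i1] * C[i1, ] + sizes[i2] * C[i2, ]) /
            max(w, 1L)
          used[i1] <- used[i2] <- TRUE
          drop_idx <- c(drop_idx, i2)
          n_merge <- n_merge + 1L
        }
        if (length(drop_idx)) {
          C <- C[-drop_idx, , drop = FALSE]
          structural <- TRUE
        }
      }
    }

    log_rows[[iter]] <- data.frame(iter = iter, k = nrow(C), wcss = wcss,
                                   motion = motion, discarded = n_disc,
                                   splits = n_split, merges = n_merge,
                                   structural = structural)
    if (!structural && (stable || motion < params$tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("ISODATA did not converge within max_iter; returning best state")

  # final consolidation pass so the model invariants hold exactly
  labels <- nearest_center(X, C)
  C <- update_centers(X, labels, nrow(C))
  labels <- nearest_center(X, C)
  C <- update_centers(X, labels, nrow(C))

  # canonical numbering: decreasing size, ties by first centroid coordinate
  sizes <- tabulate(labels, nrow(C))
  ord <- order(-sizes, C[, 1])
  relabel <- integer(nrow(C))
  relabel[ord] <- seq_len(nrow(C))
  labels <- relabel[labels]
  C <- C[ord, , drop = FALSE]
  sizes <- sizes[ord]

  structure(list(
    centers = C, labels = labels, k = nrow(C), sizes = sizes,
    wcss = sum((X - C[labels, , drop = FALSE])^2),
    log = do.call(rbind, log_rows), converged = converged,
    params = params,
    center = fm$center %||% attr(x, "center"),
    scale = fm$scale %||% attr(x, "scale"),
    features = fm$features %||% colnames(X)
  ), class = "isodata_model")
}

#' @export
print.isodata_model <- function(x, ...) {
  cat(sprintf("ISODATA model: %d clusters over %d rows (features: %s)\n",
              x$k, length(x$labels), paste(x$features, collapse = ", ")))
  cat(sprintf("  WCSS %.4g; converged: %s; iterations: %d\n",
              x$wcss, x$converged, nrow(x$log)))
  invisible(x)
}

#' Assign new voxels to fitted ISODATA clusters
#'
#' Normalizes new rows with the model's stored statistics (when the model was
#' fitted through [normalize_features()]) and labels each row with its nearest
#' centroid; distance ties go to the lowest cluster index.
#'
#' @param model an `isodata_model`.
#' @param features a `feature_matrix` (raw, un-normalized) or plain numeric
#'   matrix in the same feature space the model was trained on (raw units if
#'   the model stores normalization statistics, normalized units otherwise).
#' @return Integer vector of cluster labels.
#' @export
assign_to_clusters <- function(model, features) {
  X <- if (inherits(features, "feature_matrix")) {
    if (!identical(features$features, model$features))
      stop("feature spec mismatch between model and new data")
    features$X
  } else as.matrix(features)
  if (ncol(X) != ncol(model$centers))
    stop("feature spec mismatch: expected ", ncol(model$centers), " columns")
  if (!is.null(model$center))
    X <- sweep(sweep(X, 2L, model$center, `-`), 2L, model$scale, `/`)
  nearest_center(X, model$centers)
}
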