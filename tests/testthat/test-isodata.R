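# Feature-matrix assembly, normalization and the ISODATA clustering loop,
# including the k-means oracle equivalences.

fake_fitted_scan <- function(animal, timepoint, dims = c(4, 4, 2),
                             value = 1, excluded_vox = integer(0)) {
  mk <- function(v) array(v, dims)
  tumor <- array(TRUE, dims)
  excl <- array(FALSE, dims)
  excl[excluded_vox] <- TRUE
  list(animal = animal, group = "treated", timepoint = timepoint,
       sacrifice = FALSE,
       maps = structure(list(T1 = mk(value), T2 = mk(value * 2),
                             ADC = mk(value * 3), MTR = mk(value * 4),
                             tumor_mask = tumor, exclusion_mask = excl,
                             included_mask = tumor & !excl),
                        class = "parameter_map_set"))
}

test_that("feature matrix pools included voxels with ordered columns", {
  scans <- list(fake_fitted_scan("A", "pre"), fake_fitted_scan("A", "1h"),
                fake_fitted_scan("B", "pre", excluded_vox = 1:5),
                fake_fitted_scan("B", "1h"))
  fm <- assemble_feature_matrix(scans, c("T1", "T2", "ADC"))
  expect_identical(nrow(fm$X), 4L * 32L - 5L)
  expect_identical(colnames(fm$X), c("T1", "T2", "ADC"))
  # excluded voxels never appear as rows
  b_pre <- fm$index[fm$index$animal == "B" & fm$index$timepoint == "pre", ]
  expect_identical(nrow(b_pre), 27L)
  expect_false(any(b_pre$voxel %in% 1:5))
  # column order follows the spec order, not map order
  fm2 <- assemble_feature_matrix(scans, c("ADC", "T1"))
  expect_identical(colnames(fm2$X), c("ADC", "T1"))
  expect_error(assemble_feature_matrix(scans, c("T1", "FA")), "unknown")
})

test_that("feature normalization is the sample z-score", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  Xn <- normalize_features(X)
  expect_equal(Xn[, "a"], c(-1, 0, 1))            # sample-SD convention
  expect_equal(colMeans(Xn), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(apply(Xn, 2, sd), c(a = 1, b = 1), tolerance = 1e-10)
  # idempotence and affine invariance
  expect_equal(unclass(normalize_features(Xn)), unclass(Xn),
               ignore_attr = TRUE)
  expect_equal(unclass(normalize_features(5 * X + 2)), unclass(Xn),
               ignore_attr = TRUE)
  expect_error(normalize_features(cbind(c(1, 1, 1), c(1, 2, 3))),
               "zero-variance")
})

test_that("ISODATA recovers well-separated blobs and matches k-means", {
  skip_if_not_installed("mclust")
  centers <- rbind(c(0, 0), c(10, 0), c(5, 8.66))
  X <- make_blobs(centers, 100, 0.3, seed = 42)
  truth <- rep(1:3, each = 100)
  Xn <- normalize_features(X)
  model <- isodata_cluster(Xn, isodata_params(seed = 7))
  expect_identical(model$k, 3L)
  km <- with_seed_test(1, stats::kmeans(Xn, 3, nstart = 20))
  expect_identical(mclust::adjustedRandIndex(model$labels, km$cluster), 1)
  expect_identical(mclust::adjustedRandIndex(model$labels, truth), 1)
  # model invariants: nearest-centroid labels, centroids are member means
  d2 <- as.matrix(dist(rbind(model$centers, Xn)))[-(1:3), 1:3]
  expect_identical(max.col(-d2), model$labels)
  for (j in 1:3)
    expect_equal(colMeans(Xn[model$labels == j, , drop = FALSE]),
                 model$centers[j, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("with splits and merges disabled ISODATA is Lloyd's k-means", {
  centers <- rbind(c(0, 0), c(4, 0), c(2, 3.5))
  X <- make_blobs(centers, 60, 0.8, seed = 9)
  Xn <- normalize_features(X)
  p <- isodata_params(n_init = 3, min_size = 1, split = FALSE, merge = FALSE,
                      seed = 5)
  model <- isodata_cluster(Xn, p)
  init <- mpmriseg:::kmeanspp_init(Xn, 3, 5)
  km <- stats::kmeans(Xn, centers = init, algorithm = "Lloyd", iter.max = 500)
  expect_true(same_partition(model$labels, km$cluster))
})

test_that("close centroids merge and degenerate inputs collapse", {
  # two blobs closer than the merge threshold end as one cluster
  X <- make_blobs(rbind(c(0, 0), c(0.2, 0)), 100, 0.05, seed = 3)
  model <- isodata_cluster(X, isodata_params(n_init = 2, min_size = 1,
                                             merge_dist = 0.4, seed = 2))
  expect_identical(model$k, 1L)
  # all rows identical: a single cluster holding every row
  Xi <- matrix(1, 60, 3)
  mi <- isodata_cluster(Xi, isodata_params(n_init = 10, min_size = 1,
                                           seed = 1))
  expect_identical(mi$k, 1L)
  expect_identical(mi$sizes, 60L)
  expect_error(isodata_cluster(Xi[1:5, ], isodata_params(n_init = 10)),
               "fewer rows")
})

test_that("row permutation only renumbers the partition", {
  centers <- rbind(c(0, 0), c(6, 0), c(3, 5))
  X <- make_blobs(centers, 80, 0.5, seed = 12)
  Xn <- normalize_features(X)
  perm <- with_seed_test(2, sample(nrow(Xn)))
  m1 <- isodata_cluster(Xn, isodata_params(seed = 4))
  m2 <- isodata_cluster(Xn[perm, ], isodata_params(seed = 4))
  expect_true(same_partition(m1$labels[perm], m2$labels))
})

test_that("within-cluster sum of squares never increases between pure iterations", {
  centers <- rbind(c(0, 0), c(2, 0), c(1, 1.5), c(4, 3))
  X <- make_blobs(centers, 70, 0.9, seed = 8)
  model <- isodata_cluster(normalize_features(X), isodata_params(seed = 6))
  lg <- model$log
  pure <- which(!lg$structural[-nrow(lg)] & !lg$structural[-1])
  if (length(pure))
    expect_true(all(lg$wcss[pure + 1] <= lg$wcss[pure] + 1e-8))
})

test_that("out-of-sample assignment is consistent with deterministic ties", {
  centers <- rbind(c(0, 0), c(8, 0))
  X <- make_blobs(centers, 50, 0.4, seed = 15)
  Xn <- normalize_features(X)
  model <- isodata_cluster(Xn, isodata_params(n_init = 2, min_size = 1,
                                              seed = 3))
  # training rows re-assigned reproduce the stored labels (raw units in,
  # model applies its stored normalization)
  expect_identical(assign_to_clusters(model, X), model$labels)
  # a point exactly at a centroid gets that centroid's label; an equidistant
  # point goes to the lowest cluster index
  C <- model$centers
  mid <- (C[1, ] + C[2, ]) / 2
  lab <- assign_to_clusters(structure(list(centers = C, center = NULL,
                                           features = NULL),
                                      class = "isodata_model"),
                            rbind(C[2, ], mid))
  expect_identical(lab, c(2L, 1L))
  expect_error(assign_to_clusters(model, X[, 1, drop = FALSE]), "mismatch")
})
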