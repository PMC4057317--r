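# Cluster occupancy fractions, the paired t-test, the temporal
# classification rule and the viability label maps.

# minimal model/feature-matrix pair: `labels[i]` for voxels described by idx
fake_model_fm <- function(labels, animal, timepoint, k = max(labels),
                          group = "treated") {
  model <- structure(list(labels = labels, k = k), class = "isodata_model")
  fm <- structure(list(index = data.frame(
    scan = 1L, animal = animal, group = group, timepoint = timepoint,
    voxel = seq_along(labels), stringsAsFactors = FALSE)),
    class = "feature_matrix")
  list(model = model, fm = fm)
}

test_that("cluster fractions normalize per tumor and cover absent clusters", {
  labels <- c(rep(1L, 40), rep(2L, 60))
  x <- fake_model_fm(labels, "T01", "pre", k = 3L)
  tab <- cluster_fraction_table(x$model, x$fm)
  expect_equal(tab$fraction[tab$cluster == 1], 0.40)
  expect_equal(tab$fraction[tab$cluster == 2], 0.60)
  expect_equal(tab$fraction[tab$cluster == 3], 0)   # absent cluster
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-12)

  # dropping voxels (exclusion) changes no numerator but the denominator
  x2 <- fake_model_fm(labels[-(1:5)], "T01", "pre", k = 3L)
  tab2 <- cluster_fraction_table(x2$model, x2$fm)
  expect_equal(tab2$fraction[tab2$cluster == 1], 35 / 95)
  expect_equal(sum(tab2$fraction), 1, tolerance = 1e-12)
})

test_that("paired t-test matches the closed form and its conventions", {
  d <- c(0.30, 0.35, 0.40, 0.30, 0.35, 0.40, 0.35)
  res <- paired_t_test(rep(0, 7), d)
  expect_equal(res$mean_diff, 0.35)
  expect_equal(res$t, 22.68, tolerance = 1e-3)
  expect_lt(res$p, 1e-6)
  expect_identical(res$df, 6L)

  # agrees with the reference implementation on random pairs
  with_seed_test(8, {
    a <- rnorm(12); b <- rnorm(12)
  })
  ref <- stats::t.test(b, a, paired = TRUE)
  mine <- paired_t_test(a, b)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  # identical before/after: mean difference 0, p = 1
  same <- paired_t_test(d, d)
  expect_identical(same$p, 1)
  expect_identical(same$mean_diff, 0)
  # zero-variance non-zero difference: p = 0 by convention
  shift <- paired_t_test(d, d + 0.1)
  expect_identical(shift$p, 0)
  # sign-flipping all differences flips t, keeps the two-sided p
  flip <- paired_t_test(d, rep(0, 7))
  expect_equal(flip$t, -res$t)
  expect_equal(flip$p, res$p)

  expect_error(paired_t_test(1:3, 1:4), "equal length")
  expect_error(paired_t_test(1, 2), "at least 2")
})

make_fraction_table <- function(design, cluster_frac) {
  # cluster_frac: list cluster -> function(animal, timepoint) -> fraction
  rows <- list()
  for (i in seq_len(nrow(design$animals))) {
    a <- design$animals[i, ]
    tps <- if (a$has_72h || a$group == "control") c("pre", "1h", "72h")
           else c("pre", "1h")
    for (tp in tps) for (cl in seq_along(cluster_frac)) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal = a$animal, group = a$group, timepoint = tp, cluster = cl,
        n = 100L, fraction = cluster_frac[[cl]](a$animal, tp),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("temporal classification applies the direction-gated paired test", {
  design <- cohort_design(14, 7, 7)
  # cluster 1: strong consistent increase at 1 h -> non-viable
  # cluster 2: identical at all time points -> viable
  # cluster 3: significant DEcrease -> viable (direction gate)
  # cluster 4: increases only at 72 h -> non-viable (OR rule)
  with_seed_test(3, {
    jitter <- stats::setNames(rnorm(14, 0, 0.02),
                              sprintf("T%02d", 1:14))
  })
  tabs <- make_fraction_table(design, list(
    function(a, tp) if (tp == "pre" || grepl("C", a)) 0.05
                    else 0.40 + jitter[a],
    function(a, tp) 0.10,
    function(a, tp) if (tp == "pre" || grepl("C", a)) 0.40
                    else 0.10 + jitter[a],
    function(a, tp) if (tp == "72h" && grepl("T", a)) 0.30 + jitter[a]
                    else 0.02
  ))
  cm <- classify_clusters(tabs, design, alpha = 0.05)
  expect_identical(cm$class, c("nonviable", "viable", "viable", "nonviable"))
  # hand-check cluster 1 against the closed form
  d1 <- (0.40 + jitter) - 0.05
  expect_equal(cm$t_1h[1], mean(d1) / (sd(d1) / sqrt(14)), tolerance = 1e-12)
  # the decreasing cluster is significant but gated by direction
  expect_lt(cm$p_1h[3], 0.05)
  expect_lt(cm$mean_diff_1h[3], 0)
  # a design without treated animals cannot be classified
  d0 <- cohort_design(1, 0, 1)
  d0$animals$group <- "control"
  expect_error(classify_clusters(tabs, d0), "no treated animals")
})

test_that("viability maps partition included voxels and count fractions", {
  dims <- c(10, 10, 1)
  tumor <- array(TRUE, dims)
  labels <- c(rep(1L, 30), rep(2L, 70))
  model <- structure(list(labels = labels, k = 2L), class = "isodata_model")
  excl <- array(FALSE, dims)
  fm <- structure(list(index = data.frame(
    scan = 1L, animal = "T01", group = "treated", timepoint = "1h",
    voxel = 1:100, stringsAsFactors = FALSE)), class = "feature_matrix")
  scans <- list(list(animal = "T01", group = "treated", timepoint = "1h",
                     sacrifice = TRUE,
                     maps = list(tumor_mask = tumor, exclusion_mask = excl)))
  cmap <- data.frame(cluster = 1:2, class = c("nonviable", "viable"),
                     stringsAsFactors = FALSE)
  viab <- make_viability_map(model, fm, cmap, scans)
  expect_equal(viab$fractions$fraction, 0.30)
  vol <- viab$volumes[["T01_1h"]]
  expect_identical(sum(vol == 2L), 30L)
  expect_identical(sum(vol == 1L), 70L)

  # all clusters viable: fraction 0
  cmap0 <- data.frame(cluster = 1:2, class = "viable")
  expect_equal(make_viability_map(model, fm, cmap0, scans)$fractions$fraction,
               0)
  # classification depends only on the partition, not the numbering
  relab <- structure(list(labels = 3L - labels, k = 2L),
                     class = "isodata_model")
  cmap_r <- data.frame(cluster = 1:2, class = c("viable", "nonviable"))
  expect_equal(make_viability_map(relab, fm, cmap_r, scans)$fractions$fraction,
               0.30)
  # unmapped label is an error
  expect_error(make_viability_map(model, fm, cmap[1, ], scans), "class map")
})
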