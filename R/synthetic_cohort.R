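# Synthetic longitudinal multiparametric tumor MRI cohorts with known
# ground-truth tissue labels, raw signal series and matched synthetic
# histology. Tissue classes carry quantitative T1/T2/ADC/MTR distributions;
# treated animals develop a growing non-viable lesion after ablation.

# Integer codes used in ground-truth label volumes.
LABELS <- c(background = 0L, muscle = 1L, viable = 2L, nonviable = 3L, edema = 4L)

#' Default tissue-class parameter table
#'
#' Mean quantitative MRI parameters per tissue state, with the within-tissue
#' voxel standard deviations used by the cohort generator. Relaxation rates
#' are given as R1 = 1/T1 and R2 = 1/T2 in 1/s, the apparent diffusion
#' coefficient (ADC) in mm^2/s and the magnetization transfer ratio (MTR) in
#' percent. Means for viable and non-viable (1 h and 72 h after ablation)
#' tumor tissue follow published values for thermally ablated murine colon
#' carcinoma; edema has elevated T2 and ADC at viable-like R1/MTR, and the
#' background class is all zero (no signal).
#'
#' @return A `data.frame` with one row per tissue class and columns
#'   `name`, `R1_mean`, `R1_sd`, `R2_mean`, `R2_sd`, `ADC_mean`, `ADC_sd`,
#'   `MTR_mean`, `MTR_sd`.
#' @export
default_tissue_params <- function() {
  data.frame(
    name = c("viable", "nonviable_1h", "nonviable_72h", "edema", "muscle",
             "background"),
    R1_mean = c(0.45, 0.61, 0.60, 0.45, 0.70, 0),
    R1_sd   = c(0.03, 0.10, 0.08, 0.03, 0.04, 0),
    R2_mean = c(21.7, 35.8, 34.0, 14.0, 28.0, 0),
    R2_sd   = c(2.5, 12.0, 12.0, 2.0, 2.5, 0),
    ADC_mean = c(0.84e-3, 1.09e-3, 1.25e-3, 1.35e-3, 1.40e-3, 0),
    ADC_sd   = c(0.10e-3, 0.16e-3, 0.16e-3, 0.12e-3, 0.10e-3, 0),
    MTR_mean = c(23.3, 26.4, 26.4, 23.3, 35.0, 0),
    MTR_sd   = c(4.0, 4.0, 4.0, 4.0, 2.0, 0),
    stringsAsFactors = FALSE
  )
}

validate_tissue_params <- function(tp) {
  needed <- c("name", "R1_mean", "R1_sd", "R2_mean", "R2_sd",
              "ADC_mean", "ADC_sd", "MTR_mean", "MTR_sd")
  if (!all(needed %in% names(tp)))
    stop("tissue parameter table is missing columns: ",
         paste(setdiff(needed, names(tp)), collapse = ", "))
  non_bg <- tp$name != "background"
  if (any(tp$R1_mean[non_bg] <= 0) || any(tp$R2_mean[non_bg] <= 0) ||
      any(tp$ADC_mean[non_bg] <= 0))
    stop("tissue means must be positive for all classes except background")
  sds <- unlist(tp[, grep("_sd$", names(tp))])
  if (any(sds < 0)) stop("tissue SDs must be non-negative")
  if (any(tp$MTR_mean < 0 | tp$MTR_mean > 100))
    stop("MTR_mean must lie in [0, 100]")
  invisible(tp)
}

#' Longitudinal cohort design
#'
#' Describes the study structure: `n_treated` ablated animals scanned before
#' (`pre`) and 1 h after treatment, of which `n_treated_72h` are also scanned
#' at 72 h; `n_control` untreated animals scanned at all three matching days.
#' Each animal is sacrificed for histology directly after its last scan, so
#' treated animals without a 72 h scan pair their histology with the 1 h
#' scan, and all other animals with the 72 h (Day 4) scan.
#'
#' @param n_treated number of treated animals.
#' @param n_treated_72h number of treated animals with a 72 h scan
#'   (must not exceed `n_treated`).
#' @param n_control number of untreated control animals.
#' @return An object of class `cohort_design`: a list with the animal table
#'   (`animals`), the ordered time-point labels and the group sizes.
#' @export
cohort_design <- function(n_treated = 14L, n_treated_72h = 7L, n_control = 7L) {
  n_treated <- as.integer(n_treated)
  n_treated_72h <- as.integer(n_treated_72h)
  n_control <- as.integer(n_control)
  if (n_treated < 1L) stop("need at least one treated animal")
  if (n_treated_72h < 0L || n_treated_72h > n_treated)
    stop("n_treated_72h must lie between 0 and n_treated")
  if (n_control < 0L) stop("n_control must be non-negative")
  ids_t <- sprintf("T%02d", seq_len(n_treated))
  ids_c <- if (n_control > 0L) sprintf("C%02d", seq_len(n_control)) else character(0)
  has72 <- c(rep(c(FALSE, TRUE),
                 c(n_treated - n_treated_72h, n_treated_72h)),
             rep(TRUE, n_control))
  animals <- data.frame(
    animal = c(ids_t, ids_c),
    group = rep(c("treated", "control"), c(n_treated, n_control)),
    has_72h = has72,
    sacrifice = ifelse(has72, "72h", "1h"),
    stringsAsFactors = FALSE
  )
  structure(list(animals = animals,
                 timepoints = c("pre", "1h", "72h"),
                 n_treated = n_treated,
                 n_treated_72h = n_treated_72h,
                 n_control = n_control),
            class = "cohort_design")
}

animal_timepoints <- function(design, animal_row) {
  if (animal_row$group == "control") c("pre", "1h", "72h")
  else if (animal_row$has_72h) c("pre", "1h", "72h")
  else c("pre", "1h")
}

#' Acquisition protocol
#'
#' Grid geometry and raw-series sampling scheme: a 15-point inversion-recovery
#' Look-Locker T1 series (first sample 30 ms, 400 ms pulse separation, 20
#' degree flip angle), a 7-echo T2 series spanning 1-82 ms, a 4 b-value
#' diffusion series (0, 100, 200, 400 s/mm^2) applied in 3 orthogonal
#' directions, a magnetization-transfer saturated/unsaturated pair and a
#' T2-weighted anatomical reference. Default grid: 128 x 128 in-plane over a
#' 4 x 4 cm field of view with 1 mm slices.
#'
#' @param matrix_size in-plane matrix size (square).
#' @param n_slices number of slices covering the tumor.
#' @param fov_mm in-plane field of view in mm.
#' @param slice_mm slice thickness in mm.
#' @param ir_first_ms,ir_spacing_ms,ir_n inversion-recovery sampling: time of
#'   the first sample, sample spacing and number of samples (ms).
#' @param flip_deg Look-Locker readout flip angle in degrees.
#' @param te_ms echo times of the multi-echo T2 series (ms).
#' @param b_values diffusion weightings in s/mm^2 (non-negative, increasing).
#' @param n_directions number of orthogonal diffusion directions.
#' @param s0 equilibrium signal amplitude inside tissue (arbitrary units).
#' @param noise_sd Rician noise standard deviation in the same units as `s0`.
#' @param t2w_te_ms echo time of the T2-weighted anatomical reference (ms).
#' @return An object of class `acquisition_protocol` (a validated list).
#' @export
acquisition_protocol <- function(matrix_size = 128L, n_slices = 14L,
                                 fov_mm = 40, slice_mm = 1,
                                 ir_first_ms = 30, ir_spacing_ms = 400,
                                 ir_n = 15L, flip_deg = 20,
                                 te_ms = seq(1, 82, length.out = 7),
                                 b_values = c(0, 100, 200, 400),
                                 n_directions = 3L,
                                 s0 = 1000, noise_sd = 25,
                                 t2w_te_ms = 30) {
  if (any(b_values < 0) || any(diff(b_values) <= 0))
    stop("b-values must be non-negative and strictly increasing")
  if (any(diff(te_ms) <= 0)) stop("echo times must be strictly increasing")
  if (length(te_ms) < 2L || length(b_values) < 2L || ir_n < 2L)
    stop("each fitted series needs at least 2 samples")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(
    matrix_size = as.integer(matrix_size), n_slices = as.integer(n_slices),
    fov_mm = fov_mm, slice_mm = slice_mm,
    ir_times_ms = ir_first_ms + ir_spacing_ms * (seq_len(ir_n) - 1),
    ir_spacing_ms = ir_spacing_ms, flip_deg = flip_deg,
    te_ms = te_ms, b_values = b_values, n_directions = as.integer(n_directions),
    s0 = s0, noise_sd = noise_sd, t2w_te_ms = t2w_te_ms,
    pixdim = c(fov_mm / matrix_size, fov_mm / matrix_size, slice_mm)
  ), class = "acquisition_protocol")
}

#' Lesion, edema and hemorrhage settings for the cohort generator
#'
#' @param fractions per-treated-animal target non-viable volume fraction at
#'   the sacrifice time point, each in `[0, 0.9]`. `NULL` spreads fractions
#'   evenly from 0 to 0.5 across the treated animals.
#' @param growth_1h for animals sacrificed at 72 h, the 1 h lesion fraction as
#'   a multiple of the 72 h fraction (lesion grows between 1 h and 72 h).
#' @param center_offset lesion center offset from the tumor center, as a
#'   fraction of the tumor semi-axes (x, y, z).
#' @param edema logical; add a peritumoral edema shell at post-treatment time
#'   points where the rim lies within `edema_reach` voxels of the lesion.
#' @param edema_reach in-plane dilation (voxels) of the lesion used to find
#'   rim voxels affected by edema.
#' @param rim_thickness rim shell thickness in voxels (2-D per slice).
#' @param void_fraction fraction of lesion voxels flagged as hemorrhage-induced
#'   signal voids at post-treatment time points.
#' @return An object of class `lesion_spec` (a validated list).
#' @export
lesion_spec <- function(fractions = NULL, growth_1h = 0.6,
                        center_offset = c(0.35, 0, 0),
                        edema = TRUE, edema_reach = 3L, rim_thickness = 3L,
                        void_fraction = 0.02) {
  if (!is.null(fractions) && (any(fractions < 0) || any(fractions > 0.9)))
    stop("requested lesion fractions must lie in [0, 0.9]")
  if (growth_1h <= 0 || growth_1h > 1)
    stop("growth_1h must lie in (0, 1]: the lesion cannot shrink after 1 h")
  if (void_fraction < 0 || void_fraction > 1)
    stop("void_fraction must lie in [0, 1]")
  structure(list(fractions = fractions, growth_1h = growth_1h,
                 center_offset = center_offset, edema = isTRUE(edema),
                 edema_reach = as.integer(edema_reach),
                 rim_thickness = as.integer(rim_thickness),
                 void_fraction = void_fraction),
            class = "lesion_spec")
}

ellipsoid_mask <- function(dims, center, semi) {
  ii <- (seq_len(dims[1]) - center[1]) / semi[1]
  jj <- (seq_len(dims[2]) - center[2]) / semi[2]
  kk <- (seq_len(dims[3]) - center[3]) / semi[3]
  d2 <- outer(outer(ii^2, jj^2, `+`), kk^2, `+`)
  d2 <= 1
}

# Fixed phantom geometry shared by all animals: an ellipsoidal tumor inside a
# cylindrical muscle "limb", background elsewhere. Tumor masks are inputs in
# real use; the shared geometry keeps the generator simple.
cohort_geometry <- function(protocol) {
  n <- protocol$matrix_size
  ns <- protocol$n_slices
  dims <- c(n, n, ns)
  center <- (dims + 1) / 2
  semi <- c(0.42 * n / 2, 0.42 * n / 2, 0.38 * ns)
  tumor <- ellipsoid_mask(dims, center, semi)
  rr <- outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, `+`)
  limb2d <- rr <= (0.85 * n / 2)^2
  limb <- array(limb2d, dim = dims)
  muscle <- limb & !tumor
  list(dims = dims, center = center, semi = semi,
       tumor = tumor, muscle = muscle, background = !limb)
}

# Smallest ellipsoid scale whose intersection with the tumor holds at least
# `target_n` voxels; bisection on the (monotone) voxel count.
lesion_mask_for_fraction <- function(geom, fraction, center_offset) {
  n_tumor <- sum(geom$tumor)
  target_n <- round(fraction * n_tumor)
  if (target_n == 0L) return(array(FALSE, geom$dims))
  ctr <- geom$center + center_offset * geom$semi
  count_at <- function(s)
    sum(ellipsoid_mask(geom$dims, ctr, pmax(geom$semi * s, 1e-6)) & geom$tumor)
  lo <- 0; hi <- 3
  if (count_at(hi) < target_n)
    stop("requested lesion is larger than the tumor allows")
  for (i in 1:45) {
    mid <- (lo + hi) / 2
    if (count_at(mid) >= target_n) hi <- mid else lo <- mid
  }
  ellipsoid_mask(geom$dims, ctr, pmax(geom$semi * hi, 1e-6)) & geom$tumor
}

tissue_row <- function(tp, name) tp[match(name, tp$name), ]

# Draw one scan's ground-truth parameter maps. `offsets` is a named numeric
# vector of per-scan additive shifts for R1, R2, ADC, MTR (shared by all
# tissue classes in the scan, emulating between-scan physiological and
# calibration variation).
draw_scan_maps <- function(labels, tissue_params, offsets, nonviable_class) {
  dims <- dim(labels)
  R1 <- array(NA_real_, dims); R2 <- array(NA_real_, dims)
  ADC <- array(NA_real_, dims); MTR <- array(NA_real_, dims)
  class_of <- c(muscle = "muscle", viable = "viable", edema = "edema")
  for (lab in c("muscle", "viable", "nonviable", "edema")) {
    idx <- which(labels == LABELS[[lab]])
    if (!length(idx)) next
    cls <- if (lab == "nonviable") nonviable_class else class_of[[lab]]
    row <- tissue_row(tissue_params, cls)
    R1[idx] <- rnorm_trunc(length(idx), row$R1_mean + offsets["R1"], row$R1_sd,
                           lower = 0.01)
    R2[idx] <- rnorm_trunc(length(idx), row$R2_mean + offsets["R2"], row$R2_sd,
                           lower = 0.5)
    ADC[idx] <- rnorm_trunc(length(idx), row$ADC_mean + offsets["ADC"],
                            row$ADC_sd, lower = 1e-5)
    MTR[idx] <- rnorm_trunc(length(idx), row$MTR_mean + offsets["MTR"],
                            row$MTR_sd, lower = 0, upper = 100)
  }
  list(T1 = 1000 / R1, T2 = 1000 / R2, ADC = ADC, MTR = MTR)
}

#' Generate a synthetic longitudinal cohort
#'
#' Builds, for every animal and time point of the design, ground-truth
#' parameter maps (T1 and T2 in ms, ADC in mm^2/s, MTR in percent), a tissue
#' label volume, a tumor mask and hemorrhage-void flags. Treated animals have
#' no lesion before treatment, an ellipsoidal non-viable core at 1 h and an
#' enlarged (superset) core at 72 h; controls stay fully viable. Voxel values
#' are drawn from truncated Gaussians per tissue class plus a per-scan offset.
#'
#' @param design a [cohort_design()].
#' @param tissue_params tissue table as from [default_tissue_params()].
#' @param lesion a [lesion_spec()].
#' @param protocol an [acquisition_protocol()].
#' @param scan_offset_sd named SDs of the per-scan additive offsets for
#'   `R1` (1/s), `R2` (1/s), `ADC` (mm^2/s) and `MTR` (percent).
#' @param seed integer seed; the same seed reproduces the cohort bit for bit.
#' @return An object of class `mpmri_cohort`: list with `design`, `protocol`,
#'   `lesion`, `geometry` and `scans` (one element per animal x time point,
#'   each holding `maps`, `labels`, `tumor_mask`, `void`,
#'   `true_nonviable_fraction` and scan metadata).
#' @export
generate_cohort <- function(design, tissue_params = default_tissue_params(),
                            lesion = lesion_spec(),
                            protocol = acquisition_protocol(),
                            scan_offset_sd = c(R1 = 0.02, R2 = 1.5,
                                               ADC = 0.05e-3, MTR = 6.0),
                            seed) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(lesion, "lesion_spec"),
            inherits(protocol, "acquisition_protocol"))
  validate_tissue_params(tissue_params)
  if (missing(seed)) stop("an explicit integer seed is required")

  fractions <- lesion$fractions %||%
    seq(0, 0.5, length.out = design$n_treated)
  if (length(fractions) != design$n_treated)
    stop("lesion fractions must have one value per treated animal")
  if (any(fractions < 0 | fractions > 0.9))
    stop("requested lesion fractions must lie in [0, 0.9]")

  geom <- cohort_geometry(protocol)
  n_tumor <- sum(geom$tumor)
  rim <- geom$tumor & !erode_slices(geom$tumor, lesion$rim_thickness)

  scans <- list()
  with_seed(seed, {
    for (a in seq_len(nrow(design$animals))) {
      arow <- design$animals[a, ]
      treated <- arow$group == "treated"
      f_sac <- if (treated) fractions[match(arow$animal,
                                            design$animals$animal)] else 0
      # lesion masks per post-treatment time point (nested: 1 h inside 72 h)
      les <- list(pre = array(FALSE, geom$dims))
      if (treated) {
        f72 <- if (arow$has_72h) f_sac else NA_real_
        f1h <- if (arow$has_72h) lesion$growth_1h * f_sac else f_sac
        les[["1h"]] <- lesion_mask_for_fraction(geom, f1h,
                                                lesion$center_offset)
        if (arow$has_72h)
          les[["72h"]] <- lesion_mask_for_fraction(geom, f72,
                                                   lesion$center_offset)
      } else {
        les[["1h"]] <- les[["72h"]] <- array(FALSE, geom$dims)
      }
      for (tp in animal_timepoints(design, arow)) {
        lmask <- les[[tp]]
        labels <- array(LABELS[["background"]], geom$dims)
        labels[geom$muscle] <- LABELS[["muscle"]]
        labels[geom$tumor] <- LABELS[["viable"]]
        labels[lmask] <- LABELS[["nonviable"]]
        edema_mask <- array(FALSE, geom$dims)
        if (treated && lesion$edema && tp != "pre" && any(lmask)) {
          edema_mask <- dilate_slices(lmask, lesion$edema_reach) & rim & !lmask
          labels[edema_mask] <- LABELS[["edema"]]
        }
        void <- array(FALSE, geom$dims)
        if (treated && tp != "pre" && any(lmask) && lesion$void_fraction > 0) {
          lidx <- which(lmask)
          nv <- round(lesion$void_fraction * length(lidx))
          if (nv > 0) void[sample(lidx, nv)] <- TRUE
        }
        offsets <- c(R1 = stats::rnorm(1, 0, scan_offset_sd["R1"]),
                     R2 = stats::rnorm(1, 0, scan_offset_sd["R2"]),
                     ADC = stats::rnorm(1, 0, scan_offset_sd["ADC"]),
                     MTR = stats::rnorm(1, 0, scan_offset_sd["MTR"]))
        nv_class <- if (tp == "72h") "nonviable_72h" else "nonviable_1h"
        maps <- draw_scan_maps(labels, tissue_params, offsets, nv_class)
        scans[[paste(arow$animal, tp, sep = "_")]] <- list(
          animal = arow$animal, group = arow$group, timepoint = tp,
          sacrifice = identical(tp, arow$sacrifice),
          maps = maps, labels = labels, tumor_mask = geom$tumor,
          void = void,
          true_nonviable_fraction = sum(lmask) / n_tumor,
          pixdim = protocol$pixdim
        )
      }
    }
  })
  structure(list(design = design, protocol = protocol, lesion = lesion,
                 tissue_params = tissue_params, geometry = geom,
                 seed = seed, scans = scans),
            class = "mpmri_cohort")
}

#' @export
print.mpmri_cohort <- function(x, ...) {
  cat("Synthetic multiparametric MRI cohort\n")
  cat(sprintf("  %d treated (%d with 72 h scan), %d controls; %d scans\n",
              x$design$n_treated, x$design$n_treated_72h, x$design$n_control,
              length(x$scans)))
  cat(sprintf("  grid %d x %d x %d, pixdim %.4g x %.4g x %.4g mm\n",
              x$protocol$matrix_size, x$protocol$matrix_size,
              x$protocol$n_slices, x$protocol$pixdim[1], x$protocol$pixdim[2],
              x$protocol$pixdim[3]))
  invisible(x)
}

#' Simulate noiseless raw signal series for one scan
#'
#' Forward models: `S(TE) = S0 exp(-TE/T2)` for the multi-echo series,
#' `S(b) = S0 exp(-b ADC)` per diffusion direction, the three-parameter
#' Look-Locker inversion-recovery model `S(t) = A - B exp(-t/T1*)` with
#' `A = S0 T1*/T1`, `B = A + S0` and `1/T1* = 1/T1 - log(cos(flip))/spacing`
#' (returned as magnitude data), and `S_sat = S0 (1 - MTR/100)` for the
#' magnetization-transfer pair. Background voxels and hemorrhage voids carry
#' zero signal.
#'
#' @param scan one element of `generate_cohort(...)$scans` (or any list with
#'   `maps`, `labels`, `void` and `tumor_mask`).
#' @param protocol an [acquisition_protocol()].
#' @return A list of arrays: `ir` (x,y,z,inversion time), `t2` (x,y,z,echo),
#'   `dwi` (x,y,z,b,direction), `mt` (x,y,z,(unsaturated, saturated)) and the
#'   T2-weighted anatomical reference `t2w`.
#' @export
simulate_signal_series <- function(scan, protocol) {
  maps <- scan$maps
  dims <- dim(scan$labels)
  tissue <- scan$labels != LABELS[["background"]]
  intum <- scan$tumor_mask & !scan$void
  if (any(!is.finite(maps$T1[intum])) || any(maps$T1[intum] <= 0) ||
      any(maps$T2[intum] <= 0) || any(maps$ADC[intum] <= 0))
    stop("non-positive T1/T2/ADC inside the tumor mask")

  s0 <- array(0, dims)
  s0[tissue] <- protocol$s0
  s0[scan$void] <- 0

  T1 <- maps$T1; T2 <- maps$T2; ADC <- maps$ADC; MTR <- maps$MTR
  zero <- function(x) { x[!is.finite(x)] <- 0; x }

  # Look-Locker apparent relaxation
  tau <- 1 / (1 / T1 - log(cos(protocol$flip_deg * pi / 180)) /
                protocol$ir_spacing_ms)
  A <- s0 * tau / T1
  B <- A + s0
  nt <- length(protocol$ir_times_ms)
  ir <- array(0, c(dims, nt))
  for (i in seq_len(nt)) {
    ti <- protocol$ir_times_ms[i]
    ir[, , , i] <- abs(zero(A - B * exp(-ti / tau)))
  }

  ne <- length(protocol$te_ms)
  t2 <- array(0, c(dims, ne))
  for (i in seq_len(ne))
    t2[, , , i] <- zero(s0 * exp(-protocol$te_ms[i] / T2))

  nb <- length(protocol$b_values)
  nd <- protocol$n_directions
  dwi <- array(0, c(dims, nb, nd))
  for (b in seq_len(nb)) {
    sb <- zero(s0 * exp(-protocol$b_values[b] * ADC))
    for (d in seq_len(nd)) dwi[, , , b, d] <- sb
  }

  mt <- array(0, c(dims, 2L))
  mt[, , , 1L] <- s0
  mt[, , , 2L] <- zero(s0 * (1 - MTR / 100))

  t2w <- zero(s0 * exp(-protocol$t2w_te_ms / T2))

  list(ir = ir, t2 = t2, dwi = dwi, mt = mt, t2w = t2w)
}

#' Add Rician noise to a raw series set
#'
#' Each sample `s` is replaced by `sqrt((s + g1)^2 + g2^2)` with `g1`, `g2`
#' independent zero-mean Gaussians of standard deviation `sigma`, the noise
#' model of magnitude MR images. `sigma = 0` returns the input unchanged.
#'
#' @param series a list of signal arrays (as from [simulate_signal_series()])
#'   or a single numeric array.
#' @param sigma noise standard deviation (signal units), non-negative.
#' @param seed integer seed for reproducible noise.
#' @return The input structure with noisy signals.
#' @export
add_rician_noise <- function(series, sigma, seed) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(series)
  if (missing(seed)) stop("an explicit integer seed is required")
  rician <- function(x) {
    g1 <- stats::rnorm(length(x), 0, sigma)
    g2 <- stats::rnorm(length(x), 0, sigma)
    out <- sqrt((x + g1)^2 + g2^2)
    array(out, dim(x) %||% length(x))
  }
  with_seed(seed, {
    if (is.list(series)) lapply(series, rician) else rician(series)
  })
}

#' Simulate histology sections for the sacrificed tumors
#'
#' Emulates cutting each dissected tumor into thin sections at a fixed spacing
#' along the slice axis and measuring, per section, the non-viable and total
#' tumor areas. Sections sample the ground-truth label volume of the animal's
#' sacrifice scan (nearest slice); areas are perturbed multiplicatively with
#' coefficient of variation `area_noise_cv`.
#'
#' @param cohort an `mpmri_cohort`.
#' @param section_spacing_mm distance between sections in mm.
#' @param area_noise_cv multiplicative area noise CV (0 for exact areas).
#' @param seed integer seed.
#' @return A `data.frame` with columns `animal`, `group`, `section`, `z_mm`,
#'   `area_nonviable_mm2`, `area_total_mm2`.
#' @export
simulate_histology <- function(cohort, section_spacing_mm = 0.3,
                               area_noise_cv = 0.05, seed) {
  stopifnot(inherits(cohort, "mpmri_cohort"))
  if (missing(seed)) stop("an explicit integer seed is required")
  protocol <- cohort$protocol
  pix_area <- prod(protocol$pixdim[1:2])
  out <- list()
  with_seed(seed, {
    for (arow_i in seq_len(nrow(cohort$design$animals))) {
      arow <- cohort$design$animals[arow_i, ]
      scan <- cohort$scans[[paste(arow$animal, arow$sacrifice, sep = "_")]]
      tumor_slices <- which(apply(scan$tumor_mask, 3, any))
      z0 <- (min(tumor_slices) - 1) * protocol$slice_mm
      z1 <- max(tumor_slices) * protocol$slice_mm
      if (z0 + section_spacing_mm / 2 > z1) {
        zs <- (z0 + z1) / 2
      } else {
        zs <- seq(z0 + section_spacing_mm / 2, z1, by = section_spacing_mm)
      }
      if (length(zs) < 2L)
        warning(sprintf("animal %s: fewer than 2 histology sections",
                        arow$animal))
      slice_idx <- pmin(pmax(ceiling(zs / protocol$slice_mm), 1L),
                        dim(scan$labels)[3])
      nv <- vapply(slice_idx, function(k)
        sum(scan$labels[, , k] == LABELS[["nonviable"]]), numeric(1))
      tot <- vapply(slice_idx, function(k)
        sum(scan$tumor_mask[, , k]), numeric(1))
      noise <- function(n) rnorm_trunc(n, 1, area_noise_cv, lower = 0)
      a_nv <- nv * pix_area * noise(length(zs))
      a_tot <- tot * pix_area * noise(length(zs))
      out[[arow$animal]] <- data.frame(
        animal = arow$animal, group = arow$group,
        section = seq_along(zs), z_mm = zs,
        area_nonviable_mm2 = pmin(a_nv, a_tot),
        area_total_mm2 = a_tot,
        stringsAsFactors = FALSE
      )
    }
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
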