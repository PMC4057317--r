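# Voxelwise quantitative parameter mapping: mono-exponential T2 and ADC fits,
# three-parameter Look-Locker T1 fitting with polarity restoration, MTR
# computation, and the noise-level exclusion mask. All fitters are vectorized
# over voxels (log-linear initialization + Gauss-Newton, or variable
# projection for the Look-Locker model) so whole multi-slice volumes fit in
# seconds.

# Vectorized least-squares fit of S(x) = S0 * exp(-rate * x) for many voxels.
# Weighted log-linear initialization followed by damped Gauss-Newton.
fit_exp_decay <- function(Y, x, max_iter = 60L, tol = 1e-12) {
  Y <- as_voxel_matrix(Y)
  m <- ncol(Y)
  n <- nrow(Y)
  stopifnot(length(x) == m, m >= 2L)
  ok <- rowSums(is.finite(Y)) == m & rowSums(Y > 0, na.rm = TRUE) >= 2L
  Yf <- Y
  Yf[!is.finite(Yf)] <- 0

  eps <- 1e-12
  W <- pmax(Yf, 0)^2 + eps
  L <- log(pmax(Yf, eps))
  sw <- rowSums(W)
  Sx <- as.vector(W %*% x)
  Sxx <- as.vector(W %*% x^2)
  Sy <- rowSums(W * L)
  Sxy <- as.vector((W * L) %*% x)
  den <- sw * Sxx - Sx^2
  den[den == 0] <- eps
  slope <- (sw * Sxy - Sx * Sy) / den
  inter <- (Sy * Sxx - Sx * Sxy) / den
  rate <- -slope
  S0 <- exp(inter)

  rss_of <- function(S0v, rv) {
    Fm <- exp(-outer(rv, x)) * S0v
    rowSums((Fm - Yf)^2)
  }
  rss <- rss_of(S0, rate)
  for (it in seq_len(max_iter)) {
    E <- exp(-outer(rate, x))
    Fm <- E * S0
    R <- Fm - Yf
    J2 <- -sweep(Fm, 2L, x, `*`)
    a11 <- rowSums(E * E)
    a12 <- rowSums(E * J2)
    a22 <- rowSums(J2 * J2)
    g1 <- rowSums(E * R)
    g2 <- rowSums(J2 * R)
    det <- a11 * a22 - a12^2
    det[abs(det) < 1e-300] <- 1e-300
    d1 <- -(a22 * g1 - a12 * g2) / det
    d2 <- -(a11 * g2 - a12 * g1) / det
    d1[!is.finite(d1)] <- 0
    d2[!is.finite(d2)] <- 0
    lam <- rep(1, n)
    for (h in 1:12) {
      S0n <- S0 + lam * d1
      rn <- rate + lam * d2
      rssn <- rss_of(S0n, rn)
      worse <- is.finite(rssn) & (rssn > rss + 1e-12)
      worse[!is.finite(rssn)] <- TRUE
      if (!any(worse)) break
      lam[worse] <- lam[worse] / 2
    }
    accept <- is.finite(rssn) & rssn <= rss + 1e-12
    relstep <- pmax(abs(lam * d1) / (abs(S0) + eps),
                    abs(lam * d2) / (abs(rate) + eps))
    S0[accept] <- S0n[accept]
    rate[accept] <- rn[accept]
    rss[accept] <- rssn[accept]
    if (max(relstep[accept & ok], 0) < tol) break
  }
  list(S0 = S0, rate = rate, ok = ok & is.finite(rate) & is.finite(S0),
       rss = rss)
}

#' Mono-exponential T2 fit
#'
#' Least-squares fit of `S(TE) = S0 exp(-TE/T2)` per voxel. A constant
#' (non-decaying) or otherwise unfittable series yields `T2 = Inf` and an
#' `ok = FALSE` flag rather than an error; flagged voxels are meant to join
#' the exclusion mask.
#'
#' @param signals numeric vector (one voxel) or matrix (voxels x echoes).
#' @param echo_times echo times in ms.
#' @return list with `T2` (ms), `S0` and logical `ok` per voxel.
#' @export
fit_t2_monoexp <- function(signals, echo_times) {
  fit <- fit_exp_decay(signals, echo_times)
  t2 <- 1 / fit$rate
  ok <- fit$ok & fit$rate > 1e-9 & fit$S0 > 0
  t2[fit$rate <= 1e-9] <- Inf
  list(T2 = t2, S0 = fit$S0, ok = ok)
}

#' Apparent diffusion coefficient fit
#'
#' Fits `S(b) = S0 exp(-b ADC)` separately for each diffusion-encoding
#' direction and returns the arithmetic mean of the per-direction ADC values
#' (orientation invariant). Signal that increases with b yields a negative
#' per-direction ADC, which is permitted but flagged.
#'
#' @param signals per-voxel series: a `b x direction` matrix (one voxel) or a
#'   `voxels x b x direction` array.
#' @param b_values diffusion weightings in s/mm^2.
#' @return list with `ADC` (mm^2/s), matrix `ADC_dir` (voxels x directions),
#'   logical `ok` and logical `flagged` (negative ADC in some direction).
#' @export
fit_adc <- function(signals, b_values) {
  if (length(dim(signals)) == 2L)
    signals <- array(signals, c(1L, dim(signals)))
  stopifnot(length(dim(signals)) == 3L, dim(signals)[2] == length(b_values))
  nd <- dim(signals)[3]
  if (nd < 1L) stop("at least one diffusion direction is required")
  adc_dir <- matrix(NA_real_, dim(signals)[1], nd)
  ok <- rep(TRUE, dim(signals)[1])
  for (d in seq_len(nd)) {
    fit <- fit_exp_decay(signals[, , d, drop = TRUE], b_values)
    adc_dir[, d] <- fit$rate
    ok <- ok & fit$ok
  }
  list(ADC = rowMeans(adc_dir), ADC_dir = adc_dir, ok = ok,
       flagged = rowSums(adc_dir < 0) > 0)
}

#' Look-Locker T1 fit
#'
#' Fits the three-parameter apparent-relaxation model
#' `S(t) = A - B exp(-t/T1*)` to an inversion-recovery Look-Locker series and
#' applies the correction `T1 = T1* (B/A - 1)`. Magnitude data are handled by
#' polarity restoration: for every candidate sign-change position the first
#' samples are negated and the restoration minimizing the residual is kept.
#' The fit uses variable projection (A and B solved linearly for fixed T1*)
#' over a log-spaced T1* grid, refined per voxel by golden-section search.
#' Voxels with `B/A <= 1` (non-physical, e.g. a flat series) are flagged.
#'
#' @param signals numeric vector (one voxel) or matrix (voxels x samples).
#' @param sample_times sample times after inversion in ms.
#' @param flip_deg readout flip angle in degrees (kept for protocol
#'   bookkeeping; the apparent T1* absorbs the flip-angle effect).
#' @param magnitude logical; `TRUE` for magnitude data with polarity
#'   restoration, `FALSE` for signed (already restored) data.
#' @param n_grid number of log-spaced T1* grid values.
#' @param tau_range T1* search range in ms.
#' @return list with `T1` (ms), `T1star`, `A`, `B`, `flip_index` (number of
#'   negated samples) and logical `ok` per voxel.
#' @export
fit_t1_look_locker <- function(signals, sample_times, flip_deg = 20,
                               magnitude = TRUE, n_grid = 48L,
                               tau_range = c(20, 10000)) {
  Y <- as_voxel_matrix(signals)
  m <- ncol(Y)
  n <- nrow(Y)
  stopifnot(length(sample_times) == m, m >= 3L)
  tt <- sample_times
  Yf <- Y
  Yf[!is.finite(Yf)] <- 0
  yty <- rowSums(Yf^2)

  taus <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_grid))
  Em <- exp(-outer(tt, 1 / taus))            # m x n_grid
  s1 <- colSums(Em)
  s2 <- colSums(Em^2)
  det <- m * s2 - s1^2

  # Track, per voxel, the two best polarity candidates over the grid; near a
  # zero-crossing sample the runner-up flip index can win after refinement.
  b1_rss <- rep(Inf, n); b1_tau <- rep(taus[1], n); b1_k <- rep(0L, n)
  b2_rss <- rep(Inf, n); b2_tau <- rep(taus[1], n); b2_k <- rep(0L, n)
  ks <- if (magnitude) 0:(m - 1L) else 0L
  for (k in ks) {
    sgn <- c(rep(-1, k), rep(1, m - k))
    Ys <- sweep(Yf, 2L, sgn, `*`)
    b1v <- rowSums(Ys)                       # n
    B2 <- -(Ys %*% Em)                       # n x n_grid
    A <- (sweep(B2, 2L, s1, `*`) + outer(b1v, s2))
    A <- sweep(A, 2L, det, `/`)
    B <- (sweep(B2, 2L, m, `*`) + outer(b1v, s1))
    B <- sweep(B, 2L, det, `/`)
    RSS <- yty - (A * b1v + B * B2)
    jbest <- max.col(-RSS, ties.method = "first")
    rbest <- RSS[cbind(seq_len(n), jbest)]
    first <- rbest < b1_rss
    b2_rss[first] <- b1_rss[first]; b2_tau[first] <- b1_tau[first]
    b2_k[first] <- b1_k[first]
    b1_rss[first] <- rbest[first]; b1_tau[first] <- taus[jbest[first]]
    b1_k[first] <- k
    second <- !first & rbest < b2_rss
    b2_rss[second] <- rbest[second]; b2_tau[second] <- taus[jbest[second]]
    b2_k[second] <- k
  }

  # golden-section refinement of T1* (per voxel, variable projection)
  ratio <- (tau_range[2] / tau_range[1])^(1 / (n_grid - 1))
  phi <- (sqrt(5) - 1) / 2
  refine <- function(kv, tauv) {
    sgn_mat <- outer(kv, seq_len(m), function(k, j) ifelse(j <= k, -1, 1))
    Ys <- Yf * sgn_mat
    b1v <- rowSums(Ys)
    obj <- function(tv) {
      E <- exp(-outer(1 / tv, tt))
      es1 <- rowSums(E)
      es2 <- rowSums(E^2)
      b2v <- -rowSums(Ys * E)
      dt <- m * es2 - es1^2
      Av <- (es2 * b1v + es1 * b2v) / dt
      Bv <- (es1 * b1v + m * b2v) / dt
      list(rss = yty - (Av * b1v + Bv * b2v), A = Av, B = Bv)
    }
    lo <- tauv / ratio
    hi <- tauv * ratio
    for (it in 1:60) {
      x1 <- hi - phi * (hi - lo)
      x2 <- lo + phi * (hi - lo)
      left <- obj(x1)$rss <= obj(x2)$rss
      hi[left] <- x2[left]
      lo[!left] <- x1[!left]
    }
    tau_hat <- (lo + hi) / 2
    c(list(tau = tau_hat), obj(tau_hat))
  }
  r1 <- refine(b1_k, b1_tau)
  if (magnitude && any(is.finite(b2_rss))) {
    r2 <- refine(b2_k, b2_tau)
    # require a clearly smaller residual: both RSS values come from a
    # cancellation-prone quadratic form
    take2 <- is.finite(r2$rss) & (r2$rss < r1$rss - 1e-10 * yty)
    for (f in c("tau", "rss", "A", "B")) r1[[f]][take2] <- r2[[f]][take2]
    b1_k[take2] <- b2_k[take2]
  }
  ratio_ba <- r1$B / r1$A
  T1 <- r1$tau * (ratio_ba - 1)
  ok <- is.finite(T1) & is.finite(r1$A) & r1$A > 0 & ratio_ba > 1 + 1e-6
  list(T1 = T1, T1star = r1$tau, A = r1$A, B = r1$B,
       flip_index = b1_k, ok = ok)
}

#' Magnetization transfer ratio
#'
#' `MTR = (1 - S/S0) * 100` percent, where `S` and `S0` are the signal
#' intensities with and without off-resonance saturation. Voxels with
#' `S0 <= 0` return `NA` (to be excluded).
#'
#' @param S_sat saturated signal (numeric, any shape).
#' @param S_0 unsaturated signal (same shape).
#' @return MTR in percent, same shape as the input.
#' @export
compute_mtr <- function(S_sat, S_0) {
  out <- (1 - S_sat / S_0) * 100
  out[!is.finite(S_0) | S_0 <= 0] <- NA_real_
  out
}

#' Noise-level exclusion mask
#'
#' Flags tumor voxels whose T2-weighted reference signal is at noise level
#' (e.g. hemorrhage-induced signal voids): voxels below
#' `mean(background) + k * sd(background)` are excluded from clustering.
#'
#' @param t2w_reference T2-weighted signal volume.
#' @param tumor_mask logical tumor mask (same grid).
#' @param background_mask logical mask of non-tissue voxels used to estimate
#'   the noise floor; `NULL` uses a 2-voxel frame at the in-plane edges.
#' @param k threshold multiplier (default 3).
#' @return Logical volume, `TRUE` where excluded; the excluded fraction of
#'   tumor voxels is attached as attribute `"excluded_fraction"`.
#' @export
build_exclusion_mask <- function(t2w_reference, tumor_mask,
                                 background_mask = NULL, k = 3) {
  stopifnot(identical(dim(t2w_reference), dim(tumor_mask)))
  if (is.null(background_mask)) {
    dims <- dim(t2w_reference)
    background_mask <- array(FALSE, dims)
    background_mask[c(1:2, dims[1] - 1:0), , ] <- TRUE
    background_mask[, c(1:2, dims[2] - 1:0), ] <- TRUE
  }
  bg <- t2w_reference[background_mask]
  bg <- bg[is.finite(bg)]
  if (!length(bg)) stop("empty background sample for noise estimation")
  thr <- mean(bg) + k * stats::sd(bg)
  if (!is.finite(thr)) thr <- -Inf   # k = Inf with sd 0 etc.
  excl <- tumor_mask & (t2w_reference < thr)
  excl[!tumor_mask] <- FALSE
  attr(excl, "excluded_fraction") <- sum(excl) / max(sum(tumor_mask), 1L)
  excl
}

#' Fit all parameter maps for one scan
#'
#' Runs the T1, T2 and ADC fitters and the MTR computation on the raw series
#' of one scan, restricted to `fit_mask`, and assembles the exclusion mask
#' from the T2-weighted noise criterion plus all unfittable voxels.
#'
#' @param series raw series set (as from [simulate_signal_series()], possibly
#'   with noise added).
#' @param protocol an [acquisition_protocol()].
#' @param tumor_mask logical tumor mask.
#' @param fit_mask logical mask of voxels to fit (default: the tumor mask).
#' @param background_mask optional noise-estimation mask, see
#'   [build_exclusion_mask()].
#' @param k_exclude threshold multiplier for the noise-level exclusion.
#' @return An object of class `parameter_map_set`: list with `T1`, `T2` (ms),
#'   `ADC` (mm^2/s), `MTR` (percent) volumes (`NA` outside `fit_mask`),
#'   `tumor_mask`, `exclusion_mask`, `included_mask`
#'   (= tumor, fit_mask and not excluded) and `excluded_fraction`.
#' @export
fit_parameter_maps <- function(series, protocol, tumor_mask, fit_mask = NULL,
                               background_mask = NULL, k_exclude = 3) {
  fit_mask <- fit_mask %||% tumor_mask
  dims <- dim(tumor_mask)
  vox <- which(fit_mask)
  nv3 <- prod(dims)
  take <- function(arr, ncols) matrix(arr, nrow = nv3)[vox, , drop = FALSE]

  ir_mat <- take(series$ir)
  t2_mat <- take(series$t2)
  nb <- length(protocol$b_values)
  nd <- protocol$n_directions
  dwi_mat <- array(matrix(series$dwi, nrow = nv3)[vox, , drop = FALSE],
                   c(length(vox), nb, nd))
  mt_mat <- take(series$mt)

  t1fit <- fit_t1_look_locker(ir_mat, protocol$ir_times_ms,
                              flip_deg = protocol$flip_deg)
  t2fit <- fit_t2_monoexp(t2_mat, protocol$te_ms)
  adcfit <- fit_adc(dwi_mat, protocol$b_values)
  mtr_v <- compute_mtr(mt_mat[, 2L], mt_mat[, 1L])

  mk <- function(values) {
    out <- array(NA_real_, dims)
    out[vox] <- values
    out
  }
  T1 <- mk(t1fit$T1); T2 <- mk(t2fit$T2)
  ADC <- mk(adcfit$ADC); MTR <- mk(mtr_v)

  noise_excl <- build_exclusion_mask(series$t2w, tumor_mask,
                                     background_mask = background_mask,
                                     k = k_exclude)
  unfit <- array(FALSE, dims)
  unfit[vox] <- !(t1fit$ok & t2fit$ok & adcfit$ok & is.finite(mtr_v))
  exclusion <- (noise_excl | unfit) & tumor_mask
  included <- tumor_mask & fit_mask & !exclusion
  structure(list(T1 = T1, T2 = T2, ADC = ADC, MTR = MTR,
                 tumor_mask = tumor_mask, exclusion_mask = exclusion,
                 included_mask = included,
                 excluded_fraction = sum(exclusion) / max(sum(tumor_mask), 1L),
                 pixdim = protocol$pixdim),
            class = "parameter_map_set")
}
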