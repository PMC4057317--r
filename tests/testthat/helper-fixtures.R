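# Shared fixtures: small grids, Gaussian blob generators and a cached
# end-to-end pipeline run (built once, reused by the acceptance checks).

small_protocol <- function(...) {
  acquisition_protocol(matrix_size = 32L, n_slices = 6L, fov_mm = 10, ...)
}

demo_protocol <- function(...) {
  acquisition_protocol(matrix_size = 64L, n_slices = 8L, fov_mm = 20, ...)
}

# isotropic Gaussian blobs at given centers (matrix rows), n points each
make_blobs <- function(centers, n_per, sd, seed) {
  with_seed_test(seed, {
    do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      sweep(matrix(stats::rnorm(n_per * ncol(centers), 0, sd),
                   n_per, ncol(centers)), 2L, centers[i, ], `+`)
    }))
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# TRUE when two labelings describe the same partition (up to renumbering)
same_partition <- function(a, b) {
  length(a) == length(b) &&
    nrow(unique(cbind(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# a tiny uniform scan for forward-model checks: constant parameter values
# inside an all-tumor block
uniform_scan <- function(dims = c(4L, 4L, 2L), T1 = 2000, T2 = 46,
                         ADC = 0.84e-3, MTR = 23.3) {
  mk <- function(v) array(v, dims)
  labels <- array(2L, dims)
  list(maps = list(T1 = mk(T1), T2 = mk(T2), ADC = mk(ADC), MTR = mk(MTR)),
       labels = labels, tumor_mask = array(TRUE, dims),
       void = array(FALSE, dims))
}

# cached pipeline runs shared by the end-to-end acceptance checks
.acceptance_cache <- new.env(parent = emptyenv())
get_acceptance_run <- function() {
  if (is.null(.acceptance_cache$run)) {
    .acceptance_cache$run <- suppressWarnings(suppressMessages(
      run_pipeline(run_config(seed = 1))))
  }
  .acceptance_cache$run
}
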