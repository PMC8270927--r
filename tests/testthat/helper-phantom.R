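# Shared fixtures: built once per test run, all generated in code.

default_tes <- c(3.6, 7.2, 10.8, 14.4)

# memoised default phantom (seed 1) used across test files
shared_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- make_phantom(phantom_config(), seed = 1)
    ph
  }
})

shared_t1w <- local({
  v <- NULL
  function() {
    if (is.null(v)) v <<- render_t1w(shared_phantom(), "standalone")
    v
  }
})

# true fat-fraction array of a phantom
phantom_ff <- function(ph) {
  tot <- ph$water_map$data + ph$fat_map$data
  ifelse(tot > 0, ph$fat_map$data / tot, NA_real_)
}

# tiny mask helper: flat array from voxel index list
mask_from_indices <- function(idx, grid) {
  a <- array(0, grid$shape)
  a[idx] <- 1
  as_mask(a, grid)
}

# independent brute-force Dixon fit: dense grid over fat fraction and R2*
# with the amplitude solved in closed form; returns the minimal residual
brute_force_dixon_residual <- function(signals, tes = default_tes,
                                       ff_step = 0.01, r2_step = 1) {
  G <- as.matrix(expand.grid(ff = seq(0, 1, ff_step),
                             r2 = seq(0, 200, r2_step)))
  phase <- cos(2 * pi * tes / 2.4)
  shape <- abs(outer(1 - G[, 1], rep(1, length(tes))) +
                 outer(G[, 1], phase)) *
    exp(-outer(G[, 2], tes / 1000))
  num <- as.numeric(shape %*% signals)
  den <- rowSums(shape^2)
  amp <- pmax(num / den, 0)
  min(sum(signals^2) - 2 * amp * num + amp^2 * den)
}
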