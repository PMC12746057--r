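# Shared in-code fixtures.

# small filled cube mask inside a larger grid
cube_mask <- function(side = 5, grid = side + 4) {
  m <- array(0, rep(grid, 3))
  lo <- floor((grid - side) / 2) + 1
  m[lo:(lo + side - 1), lo:(lo + side - 1), lo:(lo + side - 1)] <- 1
  m
}

# voxelized ball of radius r (voxels)
ball_mask <- function(r = 10) {
  g <- 2 * r + 5
  ctr <- (g + 1) / 2
  co <- as.matrix(expand.grid(1:g, 1:g, 1:g))
  m <- array(0, c(g, g, g))
  m[co[rowSums((co - ctr)^2) <= r^2, ]] <- 1
  m
}

# a small cohort reused across tests (generated once per test run)
small_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- generate_cohort(cohort_config(n_patients = 20,
                                                          seed = 11))
    co
  }
})

# synthetic channels + mask for a single patient
one_patient <- function(seed = 5, n = 12) {
  withr::with_seed(seed, {
    mask <- cube_mask(5)
    channels <- list(
      t2 = array(rnorm(length(mask)), dim(mask)),
      ktrans = array(abs(rnorm(length(mask), 0.15, 0.05)), dim(mask)),
      ve = array(pmin(pmax(rnorm(length(mask), 0.3, 0.1), 1e-3), 1),
                 dim(mask)),
      vp = array(pmin(pmax(rnorm(length(mask), 0.04, 0.02), 1e-3), 1),
                 dim(mask))
    )
    list(channels = channels, mask = mask)
  })
}
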