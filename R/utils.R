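# Internal helpers shared across modules: array geometry, RNG hygiene,
# input checking.

#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats quantile sd var median rnorm runif rbinom qnorm
#'   setNames aggregate coef glm binomial predict optim cor convolve
#' @importFrom utils head tail
NULL

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so seeded package functions do not perturb user code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, kept inside the
# 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647L)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.",
      name, x,
      if (allow_equal_lower) "[" else "(",
      lower, upper,
      if (allow_equal_upper) "]" else ")"
    ))
  }
  invisible(x)
}

check_binary_array <- function(m, name = "mask") {
  if (!is.array(m) || length(dim(m)) != 3L) {
    abort(sprintf("`%s` must be a 3D array.", name))
  }
  if (!all(m %in% c(0, 1))) {
    abort(sprintf("`%s` must be strictly binary (0/1).", name))
  }
  invisible(m)
}

# The 13 unique 3D lattice directions at Chebyshev distance 1 (one half of
# the 26-neighbourhood); rows are (dx, dy, dz).
offsets_13 <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE]
  keep <- (d[, 3] > 0) |
    (d[, 3] == 0 & d[, 2] > 0) |
    (d[, 3] == 0 & d[, 2] == 0 & d[, 1] > 0)
  unname(d[keep, , drop = FALSE])
}

offsets_26 <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE])
}

# For an array of dims `dm` and an offset (a,b,c), return the linear indices
# of the source voxels and of the voxels displaced by the offset (both within
# bounds), as a two-column matrix.
shift_pairs <- function(dm, off) {
  span <- function(ax) {
    lo <- max(1L, 1L - off[ax]); hi <- min(dm[ax], dm[ax] - off[ax])
    if (lo > hi) integer(0) else seq.int(lo, hi)
  }
  rx <- span(1); ry <- span(2); rz <- span(3)
  if (!length(rx) || !length(ry) || !length(rz)) {
    return(cbind(integer(0), integer(0)))
  }
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  ix <- rep(rx, times = length(ry) * length(rz))
  iy <- rep(rep(ry, each = length(rx)), times = length(rz))
  iz <- rep(rz, each = length(rx) * length(ry))
  i1 <- ix + (iy - 1L) * nx + (iz - 1L) * nxy
  i2 <- (ix + off[1]) + (iy + off[2] - 1L) * nx + (iz + off[3] - 1L) * nxy
  cbind(i1, i2)
}

# Voxel coordinates (1-based) of the TRUE entries of a 3D mask, as an
# n x 3 integer matrix.
mask_coords <- function(mask) {
  which(mask > 0) |> arrayInd(dim(mask))
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
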