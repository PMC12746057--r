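# Gray-level texture matrices and their features, computed in 3D on the
# discretized ROI. Directional matrices (GLCM, GLRLM) use the 13 unique
# lattice directions at Chebyshev distance 1 and average the feature values
# over directions; GLSZM zones and GLDM/NGTDM neighbourhoods are
# 26-connected. The gray-level axis always spans 1..max occupied level
# (unoccupied levels kept), which affects the nonuniformity features and is
# therefore fixed here as policy.
#
# All mask-dependent geometry (in-mask voxel pair lists per direction, the
# run-length line decomposition, neighbour counts) depends only on the ROI
# mask, not on the gray levels, and is precomputed once per patient in a
# `mask_context`; fold-wise re-discretization then only re-indexes levels.

eps_log <- 2.2e-16

# Precompute mask-only geometry. ROI voxels are numbered 1..n in linear-index
# order; `pairs[[k]]` holds the in-mask voxel pairs (two columns of ROI voxel
# numbers) for direction k; `runs[[k]]` holds the ordering of ROI voxels along
# the direction's scan lines plus the line-break flags; `nb_cnt` is the
# 26-neighbourhood in-mask neighbour count per ROI voxel.
mask_context <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask > 0)
  n <- length(idx)
  vox <- integer(prod(dm))
  vox[idx] <- seq_len(n)
  offs <- offsets_13()
  pairs <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    pr <- shift_pairs(dm, offs[k, ])
    ok <- mask[pr[, 1]] > 0 & mask[pr[, 2]] > 0
    pairs[[k]] <- cbind(vox[pr[ok, 1]], vox[pr[ok, 2]])
  }
  nb_cnt <- tabulate(c(unlist(lapply(pairs, function(p) p[, 1])),
                       unlist(lapply(pairs, function(p) p[, 2]))), nbins = n)
  co <- arrayInd(idx, dm)
  M <- max(dm) + 2L
  runs <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    d <- offs[k, ]
    ax <- which(d != 0)[1]
    pos <- co[, ax] * d[ax]
    base <- co - pos %*% t(d)
    key <- (base[, 1] + M) + (base[, 2] + M) * (3 * M) +
      (base[, 3] + M) * (9 * M * M)
    ord <- order(key, pos)
    kk <- key[ord]; pp <- pos[ord]
    brk <- c(TRUE, kk[-1] != kk[-n] | pp[-1] != pp[-n] + 1L)
    runs[[k]] <- list(ord = ord, brk = brk)
  }
  list(idx = idx, n = n, pairs = pairs, runs = runs, nb_cnt = nb_cnt)
}

ctx_from_dvol <- function(dvol) {
  mask <- array(as.numeric(!is.na(dvol)), dim(dvol))
  mask_context(mask)
}

levels_from_dvol <- function(dvol, ctx) as.integer(dvol[ctx$idx])

# ---- GLCM ------------------------------------------------------------------

glcm_feature_names <- function() {
  c("autocorrelation", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_average",
    "difference_entropy", "difference_variance", "id", "idm", "idmn", "idn",
    "imc1", "imc2", "inverse_variance", "joint_average", "joint_energy",
    "joint_entropy", "max_probability", "mcc", "sum_average", "sum_entropy",
    "sum_squares")
}

glcm_features_single <- function(P) {
  ng <- nrow(P)
  gi <- seq_len(ng)
  i <- rep(gi, times = ng); j <- rep(gi, each = ng)
  p <- c(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(gi * px); muy <- sum(gi * py)
  sigx <- sqrt(sum((gi - mux)^2 * px))
  sigy <- sqrt(sum((gi - muy)^2 * py))
  adiff <- abs(i - j)
  pdiff <- unname(rowsum(p, adiff))[, 1]          # groups 0..ng-1 (sorted)
  kdiff <- sort(unique(adiff))
  psum <- unname(rowsum(p, i + j))[, 1]           # groups 2..2ng
  ksum <- sort(unique(i + j))
  da <- sum(kdiff * pdiff)
  corr <- if (sigx > 0 && sigy > 0) {
    (sum(i * j * p) - mux * muy) / (sigx * sigy)
  } else 1
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy <- -sum(p[p > 0] * log2(p[p > 0]))
  pxy_prod <- px[i] * py[j]
  hxy1 <- -sum(p * log2(pxy_prod + eps_log))
  hxy2 <- -sum(pxy_prod * log2(pxy_prod + eps_log))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  mcc <- 1
  occ <- which(px > 0)
  if (length(occ) > 1) {
    Psub <- P[occ, occ, drop = FALSE]
    pxs <- px[occ]; pys <- py[occ]
    # Q(a,b) = sum_k P(a,k) P(b,k) / (px(a) py(k))
    Q <- (Psub / pxs) %*% t(sweep(Psub, 2, pys, `/`))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(pmax(ev[2], 0))
  }
  cdev <- i + j - mux - muy
  c(
    autocorrelation = sum(i * j * p),
    cluster_prominence = sum(cdev^4 * p),
    cluster_shade = sum(cdev^3 * p),
    cluster_tendency = sum(cdev^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0])),
    difference_variance = sum((kdiff - da)^2 * pdiff),
    id = sum(p / (1 + adiff)),
    idm = sum(p / (1 + adiff^2)),
    idmn = sum(p / (1 + adiff^2 / ng^2)),
    idn = sum(p / (1 + adiff / ng)),
    imc1 = imc1,
    imc2 = imc2,
    inverse_variance = sum((p / adiff^2)[adiff > 0]),
    joint_average = mux,
    joint_energy = sum(p^2),
    joint_entropy = hxy,
    max_probability = max(p),
    mcc = mcc,
    sum_average = sum(ksum * psum),
    sum_entropy = -sum(psum[psum > 0] * log2(psum[psum > 0])),
    sum_squares = sum((i - mux)^2 * p)
  )
}

glcm_features_ctx <- function(lev, ng, ctx) {
  vals <- vapply(ctx$pairs, function(pr) {
    if (!nrow(pr)) return(rep(NA_real_, 24L))
    v1 <- lev[pr[, 1]]; v2 <- lev[pr[, 2]]
    counts <- tabulate((v1 - 1L) * ng + v2, nbins = ng * ng)
    m <- matrix(counts, ng, ng, byrow = TRUE)
    m <- m + t(m)
    glcm_features_single(m / sum(m))
  }, numeric(24L))
  out <- rowMeans(vals, na.rm = TRUE)
  setNames(out, glcm_feature_names())
}

#' Gray-level co-occurrence features
#'
#' 24 GLCM features, computed per direction on the symmetric normalized
#' distance-1 co-occurrence matrix and averaged over the 13 3D directions.
#' Degenerate single-level ROIs take the limit values (correlation and MCC
#' are 1 by convention).
#'
#' @param dvol Discretized volume (integer levels, `NA` outside the ROI) from
#'   [discretize()].
#' @param ng Number of gray levels (default: max occupied level).
#' @return Named numeric vector of length 24.
#' @export
glcm_features <- function(dvol, ng = attr(dvol, "n_levels")) {
  ctx <- ctx_from_dvol(dvol)
  if (ctx$n < 2L) abort("Need at least 2 ROI voxels.")
  if (!any(vapply(ctx$pairs, nrow, integer(1)) > 0)) {
    abort("No co-occurring voxel pairs in the ROI.")
  }
  glcm_features_ctx(levels_from_dvol(dvol, ctx), ng, ctx)
}

# ---- GLRLM -----------------------------------------------------------------

glrlm_feature_names <- function() {
  c("sre", "lre", "gln", "glnn", "rln", "rlnn", "run_percentage", "glv",
    "rv", "run_entropy", "lglre", "hglre", "srlgle", "srhgle", "lrlgle",
    "lrhgle")
}

glrlm_features_single <- function(P, np) {
  g <- row(P); l <- col(P)
  nr <- sum(P)
  p <- P / nr
  rg <- rowSums(P); cl <- colSums(P)
  mug <- sum(g * p); mul <- sum(l * p)
  pe <- p[p > 0]
  c(
    sre = sum(P / l^2) / nr,
    lre = sum(P * l^2) / nr,
    gln = sum(rg^2) / nr,
    glnn = sum(rg^2) / nr^2,
    rln = sum(cl^2) / nr,
    rlnn = sum(cl^2) / nr^2,
    run_percentage = nr / np,
    glv = sum(p * (g - mug)^2),
    rv = sum(p * (l - mul)^2),
    run_entropy = -sum(pe * log2(pe)),
    lglre = sum(P / g^2) / nr,
    hglre = sum(P * g^2) / nr,
    srlgle = sum(P / (g^2 * l^2)) / nr,
    srhgle = sum(P * g^2 / l^2) / nr,
    lrlgle = sum(P * l^2 / g^2) / nr,
    lrhgle = sum(P * g^2 * l^2) / nr
  )
}

glrlm_features_ctx <- function(lev, ng, ctx) {
  n <- ctx$n
  vals <- vapply(ctx$runs, function(rn) {
    lv <- lev[rn$ord]
    newrun <- rn$brk | c(TRUE, lv[-1] != lv[-n])
    starts <- which(newrun)
    rlen <- diff(c(starts, n + 1L))
    rlev <- lv[starts]
    nrl <- max(rlen)
    counts <- tabulate((rlev - 1L) * nrl + rlen, nbins = ng * nrl)
    glrlm_features_single(matrix(counts, ng, nrl, byrow = TRUE), n)
  }, numeric(16L))
  setNames(rowMeans(vals), glrlm_feature_names())
}

#' Gray-level run-length features
#'
#' 16 GLRLM features, computed per direction and averaged over the 13 3D
#' directions. Out-of-mask voxels break runs.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glrlm_features <- function(dvol, ng = attr(dvol, "n_levels")) {
  ctx <- ctx_from_dvol(dvol)
  if (ctx$n < 1L) abort("Empty ROI.")
  glrlm_features_ctx(levels_from_dvol(dvol, ctx), ng, ctx)
}

# ---- GLSZM -----------------------------------------------------------------

glszm_feature_names <- function() {
  c("sae", "lae", "gln", "glnn", "szn", "sznn", "zone_percentage", "glv",
    "zv", "zone_entropy", "lglze", "hglze", "salgle", "sahgle", "lalgle",
    "lahgle")
}

glszm_features_ctx <- function(lev, ng, ctx) {
  ee <- lapply(ctx$pairs, function(pr) {
    pr[lev[pr[, 1]] == lev[pr[, 2]], , drop = FALSE]
  })
  edges <- do.call(rbind, ee)
  g <- igraph::make_empty_graph(n = ctx$n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  zsize <- comp$csize
  zlev <- lev[match(seq_len(comp$no), comp$membership)]
  smax <- max(zsize)
  counts <- tabulate((zlev - 1L) * smax + zsize, nbins = ng * smax)
  P <- matrix(counts, ng, smax, byrow = TRUE)
  gl <- row(P); s <- col(P)
  nz <- sum(P)
  p <- P / nz
  rg <- rowSums(P); cs <- colSums(P)
  mug <- sum(gl * p); mus <- sum(s * p)
  pe <- p[p > 0]
  out <- c(
    sum(P / s^2) / nz, sum(P * s^2) / nz,
    sum(rg^2) / nz, sum(rg^2) / nz^2,
    sum(cs^2) / nz, sum(cs^2) / nz^2,
    nz / ctx$n,
    sum(p * (gl - mug)^2), sum(p * (s - mus)^2),
    -sum(pe * log2(pe)),
    sum(P / gl^2) / nz, sum(P * gl^2) / nz,
    sum(P / (gl^2 * s^2)) / nz, sum(P * gl^2 / s^2) / nz,
    sum(P * s^2 / gl^2) / nz, sum(P * gl^2 * s^2) / nz
  )
  setNames(out, glszm_feature_names())
}

#' Gray-level size-zone features
#'
#' 16 GLSZM features on the 26-connected constant-level zone decomposition of
#' the ROI.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glszm_features <- function(dvol, ng = attr(dvol, "n_levels")) {
  ctx <- ctx_from_dvol(dvol)
  if (ctx$n < 1L) abort("Empty ROI.")
  glszm_features_ctx(levels_from_dvol(dvol, ctx), ng, ctx)
}

# ---- NGTDM -----------------------------------------------------------------

ngtdm_feature_names <- function() {
  c("coarseness", "contrast", "busyness", "complexity", "strength")
}

# Sum of neighbour levels per ROI voxel (26-neighbourhood).
neighbour_level_sum <- function(lev, ctx) {
  p1 <- unlist(lapply(ctx$pairs, function(p) p[, 1]))
  p2 <- unlist(lapply(ctx$pairs, function(p) p[, 2]))
  out <- numeric(ctx$n)
  acc <- rowsum(c(lev[p2], lev[p1]), c(p1, p2))
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

ngtdm_features_ctx <- function(lev, ng, ctx) {
  valid <- ctx$nb_cnt > 0
  if (!any(valid)) abort("No ROI voxel has an in-mask neighbour.")
  nbs <- neighbour_level_sum(lev, ctx)
  lv <- lev[valid]
  amean <- nbs[valid] / ctx$nb_cnt[valid]
  nvp <- sum(valid)
  n_g <- tabulate(lv, nbins = ng)
  sacc <- rowsum(abs(lv - amean), lv)
  s_g <- numeric(ng)
  s_g[as.integer(rownames(sacc))] <- sacc[, 1]
  p_g <- n_g / nvp
  occ <- which(p_g > 0)
  ngp <- length(occ)
  ii <- rep(occ, each = ngp); jj <- rep(occ, times = ngp)
  pi_ <- p_g[ii]; pj <- p_g[jj]
  coarse_den <- sum(p_g * s_g)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6
  contrast <- if (ngp > 1) {
    (sum(pi_ * pj * (ii - jj)^2) / (ngp * (ngp - 1))) * (sum(s_g) / nvp)
  } else 0
  busy_den <- sum(abs(ii * pi_ - jj * pj))
  busyness <- if (busy_den > 0) sum(p_g * s_g) / busy_den else 0
  complexity <- sum(abs(ii - jj) * (pi_ * s_g[ii] + pj * s_g[jj]) /
                      (pi_ + pj)) / nvp
  strength <- if (sum(s_g) > 0) sum((pi_ + pj) * (ii - jj)^2) / sum(s_g) else 0
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

#' Neighbouring gray-tone difference features
#'
#' 5 NGTDM features. Each masked voxel with at least one masked 26-neighbour
#' contributes `|level - mean(neighbour levels)|` to its gray level's
#' difference sum. Coarseness of a constant ROI is capped at 1e6.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(dvol, ng = attr(dvol, "n_levels")) {
  ctx <- ctx_from_dvol(dvol)
  if (ctx$n < 1L) abort("Empty ROI.")
  ngtdm_features_ctx(levels_from_dvol(dvol, ctx), ng, ctx)
}

# ---- GLDM ------------------------------------------------------------------

gldm_feature_names <- function() {
  c("sde", "lde", "gln", "dn", "dnn", "glv", "dv", "dependence_entropy",
    "lgle", "hgle", "sdlgle", "sdhgle", "ldlgle", "ldhgle")
}

gldm_features_ctx <- function(lev, ng, ctx, alpha = 0) {
  dep <- integer(ctx$n)
  for (pr in ctx$pairs) {
    eq <- abs(lev[pr[, 1]] - lev[pr[, 2]]) <= alpha
    if (any(eq)) {
      t1 <- tabulate(c(pr[eq, 1], pr[eq, 2]), nbins = ctx$n)
      dep <- dep + t1
    }
  }
  dsize <- dep + 1L
  nd <- max(dsize)
  P <- matrix(tabulate((lev - 1L) * nd + dsize, nbins = ng * nd),
              ng, nd, byrow = TRUE)
  g <- row(P); j <- col(P)
  nz <- sum(P)
  p <- P / nz
  rg <- rowSums(P); cj <- colSums(P)
  mug <- sum(g * p); muj <- sum(j * p)
  pe <- p[p > 0]
  c(
    sde = sum(P / j^2) / nz,
    lde = sum(P * j^2) / nz,
    gln = sum(rg^2) / nz,
    dn = sum(cj^2) / nz,
    dnn = sum(cj^2) / nz^2,
    glv = sum(p * (g - mug)^2),
    dv = sum(p * (j - muj)^2),
    dependence_entropy = -sum(pe * log2(pe)),
    lgle = sum(P / g^2) / nz,
    hgle = sum(P * g^2) / nz,
    sdlgle = sum(P / (g^2 * j^2)) / nz,
    sdhgle = sum(P * g^2 / j^2) / nz,
    ldlgle = sum(P * j^2 / g^2) / nz,
    ldhgle = sum(P * g^2 * j^2) / nz
  )
}

#' Gray-level dependence features
#'
#' 14 GLDM features with dependence tolerance `alpha` (default 0): a
#' neighbour is dependent when its level differs from the center voxel by at
#' most `alpha` over the 26-neighbourhood. Dependence size is the dependent
#' neighbour count plus one, so an isolated voxel sits in the first column.
#'
#' @inheritParams glcm_features
#' @param alpha Dependence tolerance in gray levels.
#' @return Named numeric vector of length 14.
#' @export
gldm_features <- function(dvol, ng = attr(dvol, "n_levels"), alpha = 0) {
  ctx <- ctx_from_dvol(dvol)
  if (ctx$n < 1L) abort("Empty ROI.")
  gldm_features_ctx(levels_from_dvol(dvol, ctx), ng, ctx, alpha = alpha)
}
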