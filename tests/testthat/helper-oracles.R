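# Independent brute-force oracles for the texture features: everything here
# is computed by direct definition-summation with explicit loops over voxels,
# neighbours and matrix cells, sharing no code with the package's vectorized
# implementations.

oracle_offsets_13 <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    d <- c(dx, dy, dz)
    if (all(d == 0)) next
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0)) {
      out[[length(out) + 1]] <- d
    }
  }
  out
}

oracle_offsets_26 <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    d <- c(dx, dy, dz)
    if (!all(d == 0)) out[[length(out) + 1]] <- d
  }
  out
}

in_bounds <- function(p, dm) all(p >= 1) && all(p <= dm)

# symmetric normalized GLCM for one direction, by scanning every voxel
oracle_glcm_matrix <- function(dvol, ng, off) {
  dm <- dim(dvol)
  m <- matrix(0, ng, ng)
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    a <- dvol[x, y, z]
    if (is.na(a)) next
    q <- c(x, y, z) + off
    if (!in_bounds(q, dm)) next
    b <- dvol[q[1], q[2], q[3]]
    if (is.na(b)) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  if (sum(m) == 0) return(NULL)
  m / sum(m)
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sigx <- 0; sigy <- 0
  for (i in 1:ng) {
    sigx <- sigx + (i - mux)^2 * px[i]; sigy <- sigy + (i - muy)^2 * py[i]
  }
  sigx <- sqrt(sigx); sigy <- sqrt(sigy)
  pd <- numeric(ng); ps <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  eps <- 2.2e-16
  acc <- setNames(numeric(24), c(
    "autocorrelation", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_average",
    "difference_entropy", "difference_variance", "id", "idm", "idmn", "idn",
    "imc1", "imc2", "inverse_variance", "joint_average", "joint_energy",
    "joint_entropy", "max_probability", "mcc", "sum_average", "sum_entropy",
    "sum_squares"))
  hx <- 0; hy <- 0; hxy <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) {
    if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
    if (py[i] > 0) hy <- hy - py[i] * log2(py[i])
  }
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acc["autocorrelation"] <- acc["autocorrelation"] + i * j * p
    acc["cluster_prominence"] <- acc["cluster_prominence"] +
      (i + j - mux - muy)^4 * p
    acc["cluster_shade"] <- acc["cluster_shade"] + (i + j - mux - muy)^3 * p
    acc["cluster_tendency"] <- acc["cluster_tendency"] +
      (i + j - mux - muy)^2 * p
    acc["contrast"] <- acc["contrast"] + (i - j)^2 * p
    acc["id"] <- acc["id"] + p / (1 + abs(i - j))
    acc["idm"] <- acc["idm"] + p / (1 + (i - j)^2)
    acc["idmn"] <- acc["idmn"] + p / (1 + (i - j)^2 / ng^2)
    acc["idn"] <- acc["idn"] + p / (1 + abs(i - j) / ng)
    if (i != j) acc["inverse_variance"] <- acc["inverse_variance"] +
        p / (i - j)^2
    acc["joint_energy"] <- acc["joint_energy"] + p^2
    if (p > 0) hxy <- hxy - p * log2(p)
    hxy1 <- hxy1 - p * log2(px[i] * py[j] + eps)
    hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j] + eps)
    acc["sum_squares"] <- acc["sum_squares"] + (i - mux)^2 * p
  }
  acc["joint_average"] <- mux
  acc["joint_entropy"] <- hxy
  acc["max_probability"] <- max(P)
  acc["correlation"] <- if (sigx > 0 && sigy > 0) {
    (acc[["autocorrelation"]] - mux * muy) / (sigx * sigy)
  } else 1
  for (k in 0:(ng - 1)) {
    acc["difference_average"] <- acc["difference_average"] + k * pd[k + 1]
    if (pd[k + 1] > 0) acc["difference_entropy"] <-
        acc["difference_entropy"] - pd[k + 1] * log2(pd[k + 1])
  }
  for (k in 0:(ng - 1)) {
    acc["difference_variance"] <- acc["difference_variance"] +
      (k - acc[["difference_average"]])^2 * pd[k + 1]
  }
  for (k in 2:(2 * ng)) {
    acc["sum_average"] <- acc["sum_average"] + k * ps[k - 1]
    if (ps[k - 1] > 0) acc["sum_entropy"] <-
        acc["sum_entropy"] - ps[k - 1] * log2(ps[k - 1])
  }
  acc["imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  acc["imc2"] <- sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0))
  occ <- which(px > 0)
  if (length(occ) > 1) {
    Q <- matrix(0, length(occ), length(occ))
    for (ai in seq_along(occ)) for (bi in seq_along(occ)) {
      s <- 0
      for (ki in seq_along(occ)) {
        s <- s + P[occ[ai], occ[ki]] * P[occ[bi], occ[ki]] /
          (px[occ[ai]] * py[occ[ki]])
      }
      Q[ai, bi] <- s
    }
    ev <- sort(Re(eigen(Q)$values), decreasing = TRUE)
    acc["mcc"] <- sqrt(max(ev[2], 0))
  } else {
    acc["mcc"] <- 1
  }
  acc
}

# run-length counts for one direction by walking each line from its start
oracle_glrlm_matrix <- function(dvol, ng, off) {
  dm <- dim(dvol)
  runs <- list()
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    a <- dvol[x, y, z]
    if (is.na(a)) next
    prev <- c(x, y, z) - off
    prev_in <- in_bounds(prev, dm) && !is.na(dvol[prev[1], prev[2], prev[3]]) &&
      dvol[prev[1], prev[2], prev[3]] == a
    if (prev_in) next  # not a run start
    len <- 1
    cur <- c(x, y, z) + off
    while (in_bounds(cur, dm) && !is.na(dvol[cur[1], cur[2], cur[3]]) &&
           dvol[cur[1], cur[2], cur[3]] == a) {
      len <- len + 1
      cur <- cur + off
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  lmax <- max(vapply(runs, `[`, numeric(1), 2))
  P <- matrix(0, ng, lmax)
  for (r in runs) P[r[1], r[2]] <- P[r[1], r[2]] + 1
  P
}

oracle_glrlm_features <- function(P, np) {
  ng <- nrow(P); lm <- ncol(P)
  nr <- sum(P)
  out <- setNames(numeric(16), c("sre", "lre", "gln", "glnn", "rln", "rlnn",
                                 "run_percentage", "glv", "rv", "run_entropy",
                                 "lglre", "hglre", "srlgle", "srhgle",
                                 "lrlgle", "lrhgle"))
  mug <- 0; mul <- 0
  for (g in 1:ng) for (l in 1:lm) {
    mug <- mug + g * P[g, l] / nr; mul <- mul + l * P[g, l] / nr
  }
  for (g in 1:ng) for (l in 1:lm) {
    c0 <- P[g, l]
    out["sre"] <- out["sre"] + c0 / l^2
    out["lre"] <- out["lre"] + c0 * l^2
    out["glv"] <- out["glv"] + c0 / nr * (g - mug)^2
    out["rv"] <- out["rv"] + c0 / nr * (l - mul)^2
    if (c0 > 0) out["run_entropy"] <- out["run_entropy"] -
        c0 / nr * log2(c0 / nr)
    out["lglre"] <- out["lglre"] + c0 / g^2
    out["hglre"] <- out["hglre"] + c0 * g^2
    out["srlgle"] <- out["srlgle"] + c0 / (g^2 * l^2)
    out["srhgle"] <- out["srhgle"] + c0 * g^2 / l^2
    out["lrlgle"] <- out["lrlgle"] + c0 * l^2 / g^2
    out["lrhgle"] <- out["lrhgle"] + c0 * g^2 * l^2
  }
  for (g in 1:ng) out["gln"] <- out["gln"] + sum(P[g, ])^2
  for (l in 1:lm) out["rln"] <- out["rln"] + sum(P[, l])^2
  out[c("sre", "lre", "lglre", "hglre", "srlgle", "srhgle", "lrlgle",
        "lrhgle", "gln", "rln")] <-
    out[c("sre", "lre", "lglre", "hglre", "srlgle", "srhgle", "lrlgle",
          "lrhgle", "gln", "rln")] / nr
  out["glnn"] <- out[["gln"]] / nr
  out["rlnn"] <- out[["rln"]] / nr
  out["run_percentage"] <- nr / np
  out
}

# zones by flood fill (26-connected, equal level)
oracle_glszm_matrix <- function(dvol, ng) {
  dm <- dim(dvol)
  seen <- array(FALSE, dm)
  zones <- list()
  offs <- oracle_offsets_26()
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    if (seen[x, y, z] || is.na(dvol[x, y, z])) next
    lv <- dvol[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (d in offs) {
        q <- p + d
        if (in_bounds(q, dm) && !seen[q[1], q[2], q[3]] &&
            !is.na(dvol[q[1], q[2], q[3]]) &&
            dvol[q[1], q[2], q[3]] == lv) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lv, size)
  }
  smax <- max(vapply(zones, `[`, numeric(1), 2))
  P <- matrix(0, ng, smax)
  for (zn in zones) P[zn[1], zn[2]] <- P[zn[1], zn[2]] + 1
  P
}

oracle_glszm_features <- function(P, np) {
  # same structural definitions as run-length with zone size in place of run
  # length, plus zone percentage against the voxel count
  o <- oracle_glrlm_features(P, np)
  setNames(o, c("sae", "lae", "gln", "glnn", "szn", "sznn",
                "zone_percentage", "glv", "zv", "zone_entropy", "lglze",
                "hglze", "salgle", "sahgle", "lalgle", "lahgle"))
}

oracle_ngtdm <- function(dvol, ng) {
  dm <- dim(dvol)
  offs <- oracle_offsets_26()
  s_g <- numeric(ng); n_g <- numeric(ng)
  nvp <- 0
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    a <- dvol[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (d in offs) {
      q <- c(x, y, z) + d
      if (in_bounds(q, dm) && !is.na(dvol[q[1], q[2], q[3]])) {
        nb <- c(nb, dvol[q[1], q[2], q[3]])
      }
    }
    if (!length(nb)) next
    nvp <- nvp + 1
    n_g[a] <- n_g[a] + 1
    s_g[a] <- s_g[a] + abs(a - mean(nb))
  }
  list(s = s_g, n = n_g, nvp = nvp)
}

oracle_ngtdm_features <- function(dvol, ng) {
  st <- oracle_ngtdm(dvol, ng)
  p <- st$n / st$nvp
  occ <- which(p > 0)
  ngp <- length(occ)
  coarse_den <- sum(p * st$s)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  for (i in occ) for (j in occ) {
    contrast <- contrast + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    complexity <- complexity +
      abs(i - j) * (p[i] * st$s[i] + p[j] * st$s[j]) / (p[i] + p[j])
    strength <- strength + (p[i] + p[j]) * (i - j)^2
  }
  contrast <- if (ngp > 1) contrast / (ngp * (ngp - 1)) * sum(st$s) / st$nvp else 0
  c(coarseness = coarseness,
    contrast = contrast,
    busyness = if (busy_den > 0) sum(p * st$s) / busy_den else 0,
    complexity = complexity / st$nvp,
    strength = if (sum(st$s) > 0) strength / sum(st$s) else 0)
}

oracle_gldm_matrix <- function(dvol, ng, alpha = 0) {
  dm <- dim(dvol)
  offs <- oracle_offsets_26()
  deps <- list()
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    a <- dvol[x, y, z]
    if (is.na(a)) next
    dcount <- 0
    for (d in offs) {
      q <- c(x, y, z) + d
      if (in_bounds(q, dm) && !is.na(dvol[q[1], q[2], q[3]]) &&
          abs(dvol[q[1], q[2], q[3]] - a) <= alpha) {
        dcount <- dcount + 1
      }
    }
    deps[[length(deps) + 1]] <- c(a, dcount + 1)
  }
  jmax <- max(vapply(deps, `[`, numeric(1), 2))
  P <- matrix(0, ng, jmax)
  for (dd in deps) P[dd[1], dd[2]] <- P[dd[1], dd[2]] + 1
  P
}

oracle_gldm_features <- function(P) {
  ng <- nrow(P); jm <- ncol(P)
  nz <- sum(P)
  out <- setNames(numeric(14), c("sde", "lde", "gln", "dn", "dnn", "glv",
                                 "dv", "dependence_entropy", "lgle", "hgle",
                                 "sdlgle", "sdhgle", "ldlgle", "ldhgle"))
  mug <- 0; muj <- 0
  for (g in 1:ng) for (j in 1:jm) {
    mug <- mug + g * P[g, j] / nz; muj <- muj + j * P[g, j] / nz
  }
  for (g in 1:ng) for (j in 1:jm) {
    c0 <- P[g, j]
    out["sde"] <- out["sde"] + c0 / j^2
    out["lde"] <- out["lde"] + c0 * j^2
    out["glv"] <- out["glv"] + c0 / nz * (g - mug)^2
    out["dv"] <- out["dv"] + c0 / nz * (j - muj)^2
    if (c0 > 0) out["dependence_entropy"] <- out["dependence_entropy"] -
        c0 / nz * log2(c0 / nz)
    out["lgle"] <- out["lgle"] + c0 / g^2
    out["hgle"] <- out["hgle"] + c0 * g^2
    out["sdlgle"] <- out["sdlgle"] + c0 / (g^2 * j^2)
    out["sdhgle"] <- out["sdhgle"] + c0 * g^2 / j^2
    out["ldlgle"] <- out["ldlgle"] + c0 * j^2 / g^2
    out["ldhgle"] <- out["ldhgle"] + c0 * g^2 * j^2
  }
  for (g in 1:ng) out["gln"] <- out["gln"] + sum(P[g, ])^2
  for (j in 1:jm) out["dn"] <- out["dn"] + sum(P[, j])^2
  out[c("sde", "lde", "lgle", "hgle", "sdlgle", "sdhgle", "ldlgle", "ldhgle",
        "gln", "dn")] <-
    out[c("sde", "lde", "lgle", "hgle", "sdlgle", "sdhgle", "ldlgle",
          "ldhgle", "gln", "dn")] / nz
  out["dnn"] <- out[["dn"]] / nz
  out
}

# direction-averaged oracle feature vectors ready to compare against the
# package implementations
oracle_texture_all <- function(dvol, ng) {
  np <- sum(!is.na(dvol))
  glcm_list <- list(); glrlm_list <- list()
  for (off in oracle_offsets_13()) {
    P <- oracle_glcm_matrix(dvol, ng, off)
    if (!is.null(P)) glcm_list[[length(glcm_list) + 1]] <-
        oracle_glcm_features(P)
    glrlm_list[[length(glrlm_list) + 1]] <-
      oracle_glrlm_features(oracle_glrlm_matrix(dvol, ng, off), np)
  }
  list(
    glcm = Reduce(`+`, glcm_list) / length(glcm_list),
    glrlm = Reduce(`+`, glrlm_list) / length(glrlm_list),
    glszm = oracle_glszm_features(oracle_glszm_matrix(dvol, ng), np),
    ngtdm = oracle_ngtdm_features(dvol, ng),
    gldm = oracle_gldm_features(oracle_gldm_matrix(dvol, ng))
  )
}

# random discretized test volume with an irregular mask
random_dvol <- function(dm = c(6, 6, 6), ng = 4, mask_frac = 0.8, seed = 1) {
  withr::with_seed(seed, {
    dvol <- array(sample.int(ng, prod(dm), replace = TRUE), dm)
    drop_n <- round((1 - mask_frac) * prod(dm))
    if (drop_n > 0) dvol[sample.int(prod(dm), drop_n)] <- NA
    if (all(is.na(dvol))) dvol[1] <- 1L
    attr(dvol, "n_levels") <- ng
    dvol
  })
}
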