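# Brute-force oracles for the texture-matrix families, written as
# direct enumerations independent of the package's C++ kernels. Only
# suitable for tiny patches.

# The 13 unique lattice directions (one per antipodal pair), restated
# here independently of the implementation.
oracle_directions <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# Symmetrized co-occurrence counts for one direction.
oracle_glcm_counts <- function(lv, ng, dir) {
  d <- dim(lv)
  M <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    for (k in seq_len(d[3])) {
      p2 <- c(i, j, k) + dir
      if (!in_grid(p2, d)) next
      a <- lv[i, j, k]
      b <- lv[p2[1], p2[2], p2[3]]
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
  M
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  f <- c(contrast = 0, joint_entropy = 0, idm = 0, energy = 0)
  mux <- 0; muy <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    f["contrast"] <- f["contrast"] + (i - j)^2 * p
    if (p > 0) f["joint_entropy"] <- f["joint_entropy"] - p * log2(p)
    f["idm"] <- f["idm"] + p / (1 + (i - j)^2)
    f["energy"] <- f["energy"] + p^2
    mux <- mux + i * p; muy <- muy + j * p
  }
  sx2 <- 0; sy2 <- 0; cv <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    sx2 <- sx2 + (i - mux)^2 * p
    sy2 <- sy2 + (j - muy)^2 * p
    cv <- cv + (i - mux) * (j - muy) * p
  }
  f["correlation"] <- if (sx2 > 0 && sy2 > 0) cv / sqrt(sx2 * sy2) else 0
  f
}

# Run-length counts for one direction: walk every maximal line.
oracle_glrlm_counts <- function(lv, ng, dir) {
  d <- dim(lv)
  M <- matrix(0, ng, max(d))
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    for (k in seq_len(d[3])) {
      if (in_grid(c(i, j, k) - dir, d)) next  # not a line start
      pos <- c(i, j, k)
      cur <- lv[pos[1], pos[2], pos[3]]
      len <- 0
      while (in_grid(pos, d)) {
        g <- lv[pos[1], pos[2], pos[3]]
        if (g == cur) len <- len + 1
        else {
          M[cur, len] <- M[cur, len] + 1
          cur <- g; len <- 1
        }
        pos <- pos + dir
      }
      M[cur, len] <- M[cur, len] + 1
    }
  M
}

oracle_glrlm_features <- function(M, np) {
  nr <- sum(M)
  l <- seq_len(ncol(M))
  c(sre = sum(colSums(M) / l^2) / nr,
    lre = sum(colSums(M) * l^2) / nr,
    gln = sum(rowSums(M)^2) / nr,
    rln = sum(colSums(M)^2) / nr,
    rp = nr / np)
}

# 26-connected equal-level zones by label propagation.
oracle_glszm_zones <- function(lv) {
  d <- dim(lv)
  lab <- array(0L, dim = d)
  nextlab <- 0L
  coords <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                  k = seq_len(d[3])))
  for (r in seq_len(nrow(coords))) {
    p <- coords[r, ]
    if (lab[p[1], p[2], p[3]] != 0) next
    nextlab <- nextlab + 1L
    g <- lv[p[1], p[2], p[3]]
    queue <- list(p)
    lab[p[1], p[2], p[3]] <- nextlab
    while (length(queue) > 0) {
      q <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        nb <- q + c(di, dj, dk)
        if (!in_grid(nb, d)) next
        if (lab[nb[1], nb[2], nb[3]] != 0) next
        if (lv[nb[1], nb[2], nb[3]] != g) next
        lab[nb[1], nb[2], nb[3]] <- nextlab
        queue[[length(queue) + 1]] <- nb
      }
    }
  }
  sizes <- tabulate(lab, nbins = nextlab)
  levels <- vapply(seq_len(nextlab),
                   function(z) lv[which(lab == z)[1]], integer(1))
  cbind(level = levels, size = sizes)
}

oracle_glszm_features <- function(zones, np, ng) {
  nz <- nrow(zones)
  s <- zones[, "size"]
  c(sae = sum(1 / s^2) / nz,
    lae = sum(s^2) / nz,
    zp = nz / np,
    gln = sum(tabulate(zones[, "level"], nbins = ng)^2) / nz)
}

oracle_gldm_counts <- function(lv, ng, alpha) {
  d <- dim(lv)
  M <- matrix(0, ng, 27)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    for (k in seq_len(d[3])) {
      g <- lv[i, j, k]
      dep <- 0
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        nb <- c(i + di, j + dj, k + dk)
        if (!in_grid(nb, d)) next
        if (abs(lv[nb[1], nb[2], nb[3]] - g) <= alpha) dep <- dep + 1
      }
      M[g, dep + 1] <- M[g, dep + 1] + 1
    }
  M
}

oracle_gldm_features <- function(M) {
  nd <- sum(M)
  jj <- seq_len(ncol(M))
  c(sde = sum(colSums(M) / jj^2) / nd,
    lde = sum(colSums(M) * jj^2) / nd,
    dn = sum(colSums(M)^2) / nd)
}

oracle_ngtdm <- function(lv, ng) {
  d <- dim(lv)
  s <- numeric(ng); n <- numeric(ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    for (k in seq_len(d[3])) {
      g <- lv[i, j, k]
      vals <- c()
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        nb <- c(i + di, j + dj, k + dk)
        if (in_grid(nb, d)) vals <- c(vals, lv[nb[1], nb[2], nb[3]])
      }
      if (length(vals) == 0) next
      s[g] <- s[g] + abs(g - mean(vals))
      n[g] <- n[g] + 1
    }
  list(s = s, n = n)
}

oracle_ngtdm_features <- function(s, n, ng) {
  N <- sum(n)
  p <- n / N
  i <- seq_len(ng)
  act <- p > 0
  ngp <- sum(act)
  den <- sum(p * s)
  coarse <- if (den > 0) 1 / den else 1e6
  contrast <- 0
  if (ngp > 1) {
    acc <- 0
    for (a in which(act)) for (b in which(act)) {
      acc <- acc + p[a] * p[b] * (a - b)^2
    }
    contrast <- acc / (ngp * (ngp - 1)) * sum(s) / N
  }
  bden <- 0
  for (a in which(act)) for (b in which(act)) {
    bden <- bden + abs(a * p[a] - b * p[b])
  }
  busy <- if (bden > 0) den / bden else 0
  c(coarseness = min(coarse, 1e6), contrast = contrast, busyness = busy)
}

# Random small integer patch and its quantized_patch wrapper.
random_level_patch <- function(dims, ng) {
  array(sample.int(ng, prod(dims), replace = TRUE), dim = dims)
}

as_qpatch <- function(lv, ng) {
  structure(list(levels = array(as.integer(lv), dim = dim(lv)),
                 n_levels = as.integer(ng), source = NULL),
            class = "quantized_patch")
}
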