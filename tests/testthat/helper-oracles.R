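# Independent brute-force oracles.  These deliberately share no code with the
# package internals: the distance oracle is the O(n^2) pairwise minimum, the
# morphology oracles are literal Minkowski shifts over the explicit offset
# set, and the flood oracle replaces the priority queue with a linear scan
# over an append-only frontier.

brute_edt <- function(fg, spacing = c(1, 1, 1)) {
  d <- dim(fg)
  co <- arrayInd(which(fg), d)
  stopifnot(nrow(co) > 0)
  all_co <- arrayInd(seq_len(prod(d)), d)
  A <- sweep(all_co, 2, spacing, "*")
  B <- sweep(co, 2, spacing, "*")
  dd <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  out <- array(sqrt(pmax(apply(dd, 1, min), 0)), d)
  out[fg] <- 0 # exact by definition; avoids sqrt of cancellation residue
  out
}

ball_offsets <- function(r, weights = c(1, 1, 1)) {
  rng <- lapply(weights, function(w) seq.int(-floor(r / w), floor(r / w)))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  g[(g[, 1] * weights[1])^2 + (g[, 2] * weights[2])^2 +
      (g[, 3] * weights[3])^2 <= r^2 + 1e-9, , drop = FALSE]
}

brute_dilate <- function(mask, offs) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    src <- lapply(1:3, function(a) max(1, 1 - o[a]):min(d[a], d[a] - o[a]))
    dst <- lapply(1:3, function(a) src[[a]] + o[a])
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] | mask[src[[1]], src[[2]], src[[3]]]
  }
  out
}

brute_erode <- function(mask, offs) {
  d <- dim(mask)
  out <- array(TRUE, d)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    sh <- array(FALSE, d)
    vr <- lapply(1:3, function(a) max(1, 1 - o[a]):min(d[a], d[a] - o[a]))
    sr <- lapply(1:3, function(a) vr[[a]] + o[a])
    sh[vr[[1]], vr[[2]], vr[[3]]] <- mask[sr[[1]], sr[[2]], sr[[3]]]
    out <- out & sh
  }
  out
}

# Closing on the padded lattice so border voxels behave as on an infinite
# background, matching the package semantics.
brute_closing <- function(mask, offs, r) {
  d <- dim(mask)
  m <- as.integer(ceiling(r)) + 1L
  big <- array(FALSE, d + 2L * m)
  big[m + seq_len(d[1]), m + seq_len(d[2]), m + seq_len(d[3])] <- mask
  cl <- brute_erode(brute_dilate(big, offs), offs)
  cl[m + seq_len(d[1]), m + seq_len(d[2]), m + seq_len(d[3])]
}

# Naive priority flood: same claim-at-enqueue semantics as the watershed
# (labels 0/1/2; fg voxels untouched), but max selection by linear scan of an
# insertion-ordered frontier (first maximum = FIFO tie-break) instead of a
# heap.
naive_flood <- function(dval, seeds, fg) {
  d <- dim(dval)
  lab <- seeds
  qv <- which(lab != 0L)
  qd <- dval[qv]
  alive <- rep(TRUE, length(qv))
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[order(nb[, "dz"], nb[, "dy"], nb[, "dx"]), ]
  nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0 & nb[, 3] == 0), , drop = FALSE]
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[which.max(qd[cand])]
    alive[best] <- FALSE
    v <- qv[best]
    ai <- arrayInd(v, d)
    for (r in seq_len(nrow(nb))) {
      ii <- ai[1] + nb[r, 1]; jj <- ai[2] + nb[r, 2]; kk <- ai[3] + nb[r, 3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3]) next
      w <- ii + d[1] * ((jj - 1) + d[2] * (kk - 1))
      if (fg[w] || lab[w] != 0L) next
      lab[w] <- lab[v]
      qv <- c(qv, w); qd <- c(qd, dval[w]); alive <- c(alive, TRUE)
    }
  }
  lab
}

# Small independent connected-components (26) by iterative label propagation:
# every mask voxel starts in its own component; neighbouring components merge
# by repeated minimum-propagation over the 26 shift directions until a fixed
# point, then labels are renumbered by first appearance.
r_cc26 <- function(mask) {
  d <- dim(mask)
  comp <- array(0, d)
  comp[mask] <- which(mask)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  repeat {
    prev <- comp
    for (r in seq_len(nrow(nb))) {
      o <- nb[r, ]
      src <- lapply(1:3, function(a) max(1, 1 - o[a]):min(d[a], d[a] - o[a]))
      dst <- lapply(1:3, function(a) src[[a]] + o[a])
      sub_d <- comp[dst[[1]], dst[[2]], dst[[3]]]
      sub_s <- comp[src[[1]], src[[2]], src[[3]]]
      both <- sub_d > 0 & sub_s > 0
      sub_d[both] <- pmin(sub_d[both], sub_s[both])
      comp[dst[[1]], dst[[2]], dst[[3]]] <- sub_d
    }
    if (identical(comp, prev)) break
  }
  ids <- unique(comp[comp > 0])
  out <- array(0L, d)
  out[comp > 0] <- match(comp[comp > 0], ids)
  out
}

# ---- geometry helpers ------------------------------------------------------

# UV-sphere triangle mesh of radius r centred at the origin.
sphere_mesh <- function(r, nlat = 24, nlon = 48) {
  theta <- seq(0, pi, length.out = nlat + 1)[2:nlat]
  phi <- seq(0, 2 * pi, length.out = nlon + 1)[-(nlon + 1)]
  V <- rbind(c(0, 0, r))
  for (t in theta)
    V <- rbind(V, cbind(r * sin(t) * cos(phi), r * sin(t) * sin(phi),
                        r * cos(t)))
  V <- rbind(V, c(0, 0, -r))
  ring <- function(i) 1L + (i - 1L) * nlon + seq_len(nlon)
  F <- NULL
  r1 <- ring(1)
  F <- rbind(F, cbind(1L, r1, c(r1[-1], r1[1])))
  for (i in seq_len(nlat - 2)) {
    a <- ring(i); b <- ring(i + 1)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    F <- rbind(F, cbind(a, b, b2), cbind(a, b2, a2))
  }
  last <- ring(nlat - 1)
  bot <- nrow(V)
  F <- rbind(F, cbind(bot, c(last[-1], last[1]), last))
  tri_mesh(V, F)
}

# Solid bone block with spherical cavities carved out; air border band of
# `margin` voxels around the block.  Unit spacing.
block_with_cavities <- function(dims, centers, radii, margin = 6,
                                bone = 400, air = -1000) {
  d <- as.integer(dims)
  x <- seq_len(d[1]) - 1; y <- seq_len(d[2]) - 1; z <- seq_len(d[3]) - 1
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  solid <- X >= margin & X <= d[1] - 1 - margin &
    Y >= margin & Y <= d[2] - 1 - margin &
    Z >= margin & Z <= d[3] - 1 - margin
  for (i in seq_along(radii)) {
    cc <- centers[[i]]
    solid <- solid & !((X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2 <= radii[i]^2)
  }
  voxel_grid(array(ifelse(solid, bone, air), d))
}

# Radial distance (mm) of every voxel centre from the domain centre.
radius_field <- function(vol) {
  d <- dim(vol$values)
  ctr <- (d - 1) / 2 * vol$spacing
  x <- (seq_len(d[1]) - 1) * vol$spacing[1] - ctr[1]
  y <- (seq_len(d[2]) - 1) * vol$spacing[2] - ctr[2]
  z <- (seq_len(d[3]) - 1) * vol$spacing[3] - ctr[3]
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  sqrt(X^2 + Y^2 + Z^2)
}

endo_mask <- function(labels) labels$values == LABELS[["endocast"]]
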