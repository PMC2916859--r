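# Independent brute-force oracles, deliberately written without reusing
# the package's own code paths.

# Half-site consensus mismatch count by explicit class sets.
oracle_half_mismatch <- function(seq10) {
  classes <- list(c("A", "G"), c("A", "G"), c("A", "G"), "C",
                  c("A", "T"), c("A", "T"), "G",
                  c("C", "T"), c("C", "T"), c("C", "T"))
  b <- strsplit(toupper(seq10), "")[[1]]
  sum(!mapply(function(bb, cl) bb %in% cl, b, classes))
}

# Frame-by-frame all-pairs minimum distance (no vectorisation).
oracle_min_dist <- function(ens, donor_idx, acceptor_idx, frame_idx) {
  sapply(frame_idx, function(f) {
    fr <- frame_coords(ens, f)
    best <- Inf
    for (i in donor_idx) for (j in acceptor_idx) {
      d <- sqrt(sum((fr[i, ] - fr[j, ])^2))
      if (d < best) best <- d
    }
    best
  })
}

oracle_occupancy <- function(dists, cutoff) 100 * mean(dists <= cutoff)

# Horn's quaternion method for optimal superposition RMSD.
oracle_quaternion_rmsd <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  X <- sweep(mobile, 2, cm); Y <- sweep(ref, 2, cr)
  S <- t(X) %*% Y
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w * w + x * x - y * y - z * z, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w * w - x * x + y * y - z * z, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x),
    w * w - x * x - y * y + z * z), 3, 3, byrow = TRUE)
  sqrt(mean(rowSums((X %*% t(R) - Y)^2)))
}

# Planar angle via the law of cosines (independent of vector_angle's
# clamped-acos route).
oracle_angle <- function(a, b, c) {
  ab <- sqrt(sum((a - b)^2)); cb <- sqrt(sum((c - b)^2))
  ac <- sqrt(sum((a - c)^2))
  acos((ab^2 + cb^2 - ac^2) / (2 * ab * cb)) * 180 / pi
}

# Random rigid-body transform applied to every frame of an ensemble.
random_rigid_transform <- function(ens, seed = 99) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0.3, 2.5)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  t0 <- rnorm(3, 0, 20)
  xyz <- ens$xyz
  for (f in seq_len(nrow(xyz))) {
    fr <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    xyz[f, ] <- as.numeric(t(sweep(fr %*% t(R), 2, t0, "+")))
  }
  ensemble(ens$topology, xyz)
}
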