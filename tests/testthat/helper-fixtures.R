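# Deterministic fixtures and independent oracles shared across tests.

# white canvas with black disks at given integer centers/radii
disk_mask <- function(centers, radii, side = 300L) {
  m <- matrix(TRUE, side, side)
  rows <- row(m); cols <- col(m)
  for (i in seq_along(radii))
    m[(rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <= radii[i]^2] <- FALSE
  m
}

# exhaustive all-pairs signed EDT (O(n^2)), the oracle for signed_edt()
sedt_brute <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pts <- cbind(rep(seq_len(H), times = W), rep(seq_len(W), each = H))
  white <- as.vector(mask)
  out <- matrix(NA_real_, H, W)
  for (k in seq_len(H * W)) {
    opp <- pts[white != white[k], , drop = FALSE]
    if (nrow(opp) == 0L) { out[pts[k, 1], pts[k, 2]] <- if (white[k]) Inf else -Inf; next }
    dmin <- sqrt(min((opp[, 1] - pts[k, 1])^2 + (opp[, 2] - pts[k, 2])^2))
    out[pts[k, 1], pts[k, 2]] <- if (white[k]) dmin else -dmin
  }
  out
}

# number of points of a diagram alive at threshold delta, per dimension
alive_at <- function(diag, delta, dim) {
  sum(diag$dim == dim & diag$birth <= delta & diag$death > delta)
}

# exhaustive-scan Otsu oracle: splits the raw pixel vector at every t
otsu_brute <- function(img) {
  px <- as.vector(img)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    lo <- px[px <= t]; hi <- px[px > t]
    if (!length(lo) || !length(hi)) next
    v <- (length(lo) / length(px)) * (length(hi) / length(px)) *
      (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}
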