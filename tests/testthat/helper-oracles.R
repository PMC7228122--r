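# Brute-force autocorrelogram oracle: loop over all pixel pairs.
brute_autocorrelogram <- function(pixels, distances, levels) {
  per_ch <- round(levels^(1 / 3))
  q <- 1 + pmin(floor(pixels[, , 1] / 256 * per_ch), per_ch - 1) +
    per_ch * (pmin(floor(pixels[, , 2] / 256 * per_ch), per_ch - 1) +
                per_ch * pmin(floor(pixels[, , 3] / 256 * per_ch), per_ch - 1))
  h <- nrow(q); w <- ncol(q)
  out <- matrix(0, levels, length(distances))
  for (di in seq_along(distances)) {
    d <- distances[di]
    same <- numeric(levels); tot <- numeric(levels)
    for (r in 1:h) for (c in 1:w) {
      for (dr in -d:d) for (dc in -d:d) {
        if (max(abs(dr), abs(dc)) != d) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
        tot[q[r, c]] <- tot[q[r, c]] + 1
        if (q[r2, c2] == q[r, c]) same[q[r, c]] <- same[q[r, c]] + 1
      }
    }
    out[, di] <- ifelse(tot > 0, same / tot, 0)
  }
  as.vector(t(out))
}
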