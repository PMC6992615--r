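# Independent brute-force oracles, deliberately written with different
# machinery than the package implementations.

# Exact two-sided signed-rank p by enumerating every sign vector.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  m <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  ws <- as.vector(signs %*% r)
  w <- sum(r[d > 0])
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# Exact two-sided Mann-Whitney p by enumerating every group labeling.
oracle_mwu_p <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  combos <- utils::combn(length(r), na)
  us <- apply(combos, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
}

# Exhaustive between-class variance search over all split points.
oracle_otsu <- function(counts, values) {
  n <- sum(counts)
  best <- -Inf; best_v <- values[1]
  for (k in seq_len(length(counts) - 1)) {
    w0 <- sum(counts[1:k]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * values[1:k]) / w0
    mu1 <- sum(counts[-(1:k)] * values[-(1:k)]) / w1
    sb <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (sb > best + 1e-12) { best <- sb; best_v <- values[k] }
  }
  best_v
}

# Dense arc-sampling contact rates: n points per part, strict gas-side test.
oracle_contact_rates <- function(eye, bubble, posture, angle_deg, n = 1e5) {
  ori <- gastamponade:::eye_orientation(posture, angle_deg)
  plane <- meniscus_plane(eye, bubble)
  part <- retinal_partition(eye)
  sapply(seq_len(nrow(part)), function(i) {
    phi <- seq(part$phi_start[i], part$phi_end[i], length.out = n)
    w <- eye$radius * (cos(phi) * ori$anterior[2] + sin(phi) * ori$superior[2])
    100 * mean(w >= plane$offset_mm)
  })
}
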