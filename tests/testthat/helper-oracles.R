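# Independent oracle: direct loop over every histogram cut point, computing
# class weights and means from the binned sample by plain summation.
otsu_brute <- function(values, n_bins = 256L) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  counts <- tabulate(bin, nbins = n_bins)
  best <- -Inf; best_cuts <- numeric(0)
  for (k in seq_len(n_bins - 1L)) {
    n1 <- sum(counts[1:k]); n2 <- sum(counts) - n1
    if (n1 == 0 || n2 == 0) next
    mu1 <- sum(counts[1:k] * mids[1:k]) / n1
    mu2 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n2
    w1 <- n1 / sum(counts); w2 <- n2 / sum(counts)
    s <- w1 * w2 * (mu1 - mu2)^2
    if (s > best + 1e-12 * max(best, 1)) {
      best <- s; best_cuts <- edges[k + 1L]
    } else if (abs(s - best) <= 1e-12 * max(best, 1)) {
      best_cuts <- c(best_cuts, edges[k + 1L])
    }
  }
  mean(best_cuts)
}

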