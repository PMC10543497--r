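#' Otsu threshold of a 1-D sample
#'
#' Histogram-based Otsu thresholding: the sample is binned into `n_bins`
#' equal-width bins over its range and the cut point maximizing the
#' between-class variance `w1*w2*(mu1 - mu2)^2` over all bin boundaries is
#' returned. Deterministic for fixed input; when several boundaries tie
#' (e.g. two well-separated point masses, where every cut in the gap is
#' equally good) the mean of the tied boundary positions is returned.
#'
#' The threshold is equivariant under affine maps of the sample
#' (`x -> a*x + b`, `a > 0` shifts the threshold by the same map, up to
#' binning resolution).
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @param n_bins Number of histogram bins (default 256).
#' @return Scalar threshold; classify as `value > threshold`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || length(unique(values)) < 2L)
    stop("no contrast to threshold: need at least two distinct values")
  rng <- range(values)
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  p <- counts / sum(counts)
  w1 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[n_bins]
  # between-class variance at each interior boundary k (cut after bin k)
  k <- seq_len(n_bins - 1L)
  w1k <- w1[k]; w2k <- 1 - w1k
  valid <- w1k > 0 & w2k > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  mu1 <- mu_cum[k][valid] / w1k[valid]
  mu2 <- (mu_tot - mu_cum[k][valid]) / w2k[valid]
  sigma_b[valid] <- w1k[valid] * w2k[valid] * (mu1 - mu2)^2
  best <- max(sigma_b)
  ties <- which(abs(sigma_b - best) <= 1e-12 * max(best, 1))
  mean(edges[ties + 1L])
}
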