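# Signal decomposition: empirical mode decomposition (2-mode sifting) for
# walking signals and an empirical wavelet transform (spectrum-adaptive
# brick-wall filter bank) for stance signals.

# Indices of strict local maxima/minima.
local_extrema <- function(x) {
  d <- diff(x)
  # collapse exact plateaus so sign changes are detectable
  d[d == 0] <- .Machine$double.eps
  s <- sign(d)
  list(max = which(diff(s) < 0) + 1L,
       min = which(diff(s) > 0) + 1L)
}

# One envelope-mean sifting iteration; returns NULL when too few extrema.
sift_mean <- function(h) {
  ext <- local_extrema(h)
  if (length(ext$max) < 2L || length(ext$min) < 2L) return(NULL)
  n <- length(h)
  # anchor envelopes at the endpoints to limit end swings
  up_x <- c(1L, ext$max, n)
  up_y <- c(max(h[1], h[ext$max[1]]), h[ext$max],
            max(h[n], h[ext$max[length(ext$max)]]))
  lo_x <- c(1L, ext$min, n)
  lo_y <- c(min(h[1], h[ext$min[1]]), h[ext$min],
            min(h[n], h[ext$min[length(ext$min)]]))
  upper <- stats::spline(up_x, up_y, xout = seq_len(n))$y
  lower <- stats::spline(lo_x, lo_y, xout = seq_len(n))$y
  (upper + lower) / 2
}

#' Two-mode empirical mode decomposition
#'
#' Standard EMD sifting truncated to two intrinsic mode functions. `imf1`
#' carries the highest-frequency oscillatory content; the residual is
#' `signal - imf1 - imf2`. Signals with too few extrema (e.g. constants)
#' yield zero IMFs.
#'
#' @param signal numeric vector, at least 256 samples
#' @param max_sift maximum sifting iterations per IMF
#' @param tol relative envelope-mean energy at which sifting stops
#' @return list with `imf1`, `imf2`, `residual`
#' @export
decompose_walk_axis <- function(signal, max_sift = 12L, tol = 1e-4) {
  n <- length(signal)
  if (n < 256L)
    cipn_error("need at least 256 samples for decomposition",
               "cipnsense_insufficient_data_error")
  residual <- signal
  imfs <- list()
  for (k in 1:2) {
    h <- residual
    extracted <- FALSE
    for (s in seq_len(max_sift)) {
      m <- sift_mean(h)
      if (is.null(m)) break
      extracted <- TRUE
      h <- h - m
      if (sum(m^2) / max(sum(h^2), .Machine$double.eps) < tol) break
    }
    imf <- if (extracted) h else rep(0, n)
    imfs[[k]] <- imf
    residual <- residual - imf
  }
  list(imf1 = imfs[[1]], imf2 = imfs[[2]], residual = residual)
}

#' Empirical wavelet transform of a stance signal
#'
#' Partitions the spectrum into `n_bands` contiguous bands with
#' data-adaptive boundaries: the most prominent, well-separated peaks of
#' the smoothed magnitude spectrum define band centres and each boundary is
#' placed at the spectral minimum between consecutive centres (equally
#' spaced boundaries fill in when fewer peaks exist). Bands are realized as
#' ideal (brick-wall) filters over disjoint FFT bins, so the sub-bands sum
#' to the input exactly and their energies satisfy Parseval's identity.
#'
#' @param signal numeric vector, at least 256 samples
#' @param sampling_rate Hz
#' @param n_bands number of sub-bands (default 4)
#' @return list of `n_bands` numeric vectors (low to high frequency), with
#'   attribute `boundaries` (Hz)
#' @export
decompose_stance_axis <- function(signal, sampling_rate, n_bands = 4L) {
  n <- length(signal)
  if (n < 256L)
    cipn_error("need at least 256 samples for decomposition",
               "cipnsense_insufficient_data_error")
  X <- stats::fft(signal)
  n_half <- floor(n / 2) + 1L
  mag <- Mod(X[seq_len(n_half)])
  mag_s <- moving_mean(mag, 5L)

  # candidate peaks of the smoothed spectrum, strongest first,
  # greedily enforcing a minimum spacing
  ext <- local_extrema(mag_s)$max
  ext <- ext[order(mag_s[ext], decreasing = TRUE)]
  min_gap <- max(2L, floor(n_half / (4L * n_bands)))
  centres <- integer()
  for (p in ext) {
    if (all(abs(p - centres) >= min_gap)) centres <- c(centres, p)
    if (length(centres) >= n_bands) break
  }
  centres <- sort(centres)

  bounds <- integer()
  if (length(centres) >= 2L) {
    for (i in seq_len(length(centres) - 1L)) {
      seg <- centres[i]:centres[i + 1L]
      bounds <- c(bounds, seg[which.min(mag_s[seg])])
    }
  }
  need <- (n_bands - 1L) - length(bounds)
  if (need > 0L) {
    lo <- if (length(bounds)) max(bounds) else 1L
    extra <- round(seq(lo, n_half, length.out = need + 2L))
    bounds <- c(bounds, extra[2:(need + 1L)])
  }
  bounds <- sort(unique(pmin(pmax(bounds, 2L), n_half - 1L)))
  if (length(bounds) < n_bands - 1L) {  # degenerate spectra
    pool <- setdiff(round(seq(2L, n_half - 1L, length.out = n_bands + 2L)),
                    bounds)
    bounds <- sort(c(bounds, pool[seq_len(n_bands - 1L - length(bounds))]))
  }

  edges <- c(1L, bounds, n_half)
  bands <- vector("list", n_bands)
  for (b in seq_len(n_bands)) {
    lo <- if (b == 1L) 1L else edges[b] + 1L
    hi <- edges[b + 1L]
    mask <- rep(0, n)
    if (hi >= lo) {
      idx <- lo:hi
      mask[idx] <- 1
      mirror <- n - idx + 2L           # conjugate bins
      mirror <- mirror[mirror >= 1L & mirror <= n]
      mask[mirror] <- 1
    }
    bands[[b]] <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  }
  freq_res <- sampling_rate / n
  attr(bands, "boundaries") <- (bounds - 1L) * freq_res
  bands
}
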