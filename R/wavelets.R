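# Multilevel discrete wavelet transform with the Sym5 mother wavelet and
# half-sample symmetric boundary extension, plus the soft-threshold
# denoiser built on it.
#
# The filter-bank convention (extension length, downsampling phase,
# reconstruction trim) follows the one used by the common open-source DWT
# implementations, so coefficients are exchangeable with them; decomposition
# filter taps are the standard symlet-5 orthogonal pair.

.sym5 <- local({
  dec_lo <- c(0.027333068345077982, 0.029519490925774643,
              -0.039134249302383094, 0.1993975339773936,
              0.7234076904024206, 0.6339789634582119,
              0.01660210576452232, -0.17532808990845047,
              -0.021101834024758855, 0.019538882735286728)
  dec_hi <- c(-0.019538882735286728, -0.021101834024758855,
              0.17532808990845047, 0.01660210576452232,
              -0.6339789634582119, 0.7234076904024206,
              -0.1993975339773936, -0.039134249302383094,
              -0.029519490925774643, 0.027333068345077982)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi))
})

wavelet_filters <- function(name) {
  if (!identical(name, "sym5"))
    abort("unsupported wavelet '%s'; this package ships 'sym5'", name)
  .sym5
}

# half-sample symmetric extension by p samples each side: ...x2 x1|x1..xn|xn xn-1...
sym_extend <- function(x, p) {
  n <- length(x)
  if (p > n) abort("signal of length %d too short for extension by %d", n, p)
  c(rev(x[seq_len(p)]), x, rev(x[seq.int(n - p + 1L, n)]))
}

# one analysis level: x -> (cA, cD), output length floor((n + F - 1) / 2)
dwt_step <- function(x, filt) {
  F <- length(filt$dec_lo)
  n <- length(x)
  ext <- sym_extend(x, F - 1L)
  m <- n + F - 1L
  full_lo <- convolve(ext, rev(filt$dec_lo), type = "open")
  full_hi <- convolve(ext, rev(filt$dec_hi), type = "open")
  keep <- seq.int(F + 1L, by = 2L, length.out = m %/% 2L)
  list(cA = full_lo[keep], cD = full_hi[keep])
}

# one synthesis level, trimmed to the n_out samples of the originating signal
idwt_step <- function(cA, cD, n_out, filt) {
  F <- length(filt$rec_lo)
  nc <- length(cA)
  up <- function(cf) {
    u <- numeric(2L * nc)
    u[seq.int(1L, 2L * nc, 2L)] <- cf
    u
  }
  y <- convolve(up(cA), rev(filt$rec_lo), type = "open") +
       convolve(up(cD), rev(filt$rec_hi), type = "open")
  y[seq.int(F - 1L, length.out = n_out)]
}

# maximum useful decomposition depth for a signal of length n
dwt_max_level <- function(n, filter_length = 10L) {
  if (n < filter_length) return(0L)
  as.integer(floor(log2(n / (filter_length - 1))))
}

#' Multilevel wavelet decomposition
#'
#' Decomposes a signal into `levels` detail bands plus one approximation
#' band. Detail level 1 is the finest (highest-frequency) band.
#'
#' @param x numeric signal.
#' @param levels decomposition depth.
#' @param wavelet mother wavelet name (only `"sym5"`).
#' @return an object of class `wavelet_decomposition`: approximation
#'   coefficients, per-level detail coefficients, and the per-level input
#'   lengths needed for exact reconstruction.
#' @seealso [wave_reconstruct()], [denoise_record()]
#' @export
wave_decompose <- function(x, levels, wavelet = "sym5") {
  stopifnot(is.numeric(x), is_count(levels))
  filt <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  lengths <- integer(levels)
  cur <- as.numeric(x)
  for (lev in seq_len(levels)) {
    lengths[lev] <- length(cur)
    s <- dwt_step(cur, filt)
    details[[lev]] <- s$cD
    cur <- s$cA
  }
  structure(list(approximation = cur, details = details,
                 lengths = lengths, levels = levels, wavelet = wavelet),
            class = "wavelet_decomposition")
}

#' Invert a multilevel wavelet decomposition
#'
#' @param decomp a `wavelet_decomposition` from [wave_decompose()].
#' @return the reconstructed signal, at the original length.
#' @export
wave_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  filt <- wavelet_filters(decomp$wavelet)
  cur <- decomp$approximation
  for (lev in seq.int(decomp$levels, 1L))
    cur <- idwt_step(cur, decomp$details[[lev]], decomp$lengths[lev], filt)
  cur
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Wavelet denoising plan
#'
#' Declares how [denoise_record()] treats each band: which fine detail
#' levels are soft-thresholded (high-frequency noise) and whether the
#' deepest approximation is zeroed (baseline wander removal). The
#' threshold itself is the universal threshold sigma * sqrt(2 log n), with
#' sigma estimated from the finest detail band as MAD / 0.6745.
#'
#' @param wavelet mother wavelet name; `"sym5"`.
#' @param levels decomposition depth; 8. Reduced automatically (with a
#'   warning) when the signal is too short for the requested depth.
#' @param detail_threshold_levels detail levels (1 = finest) to
#'   soft-threshold; default `1:2`.
#' @param drop_approximation zero the level-`levels` approximation band?
#'   Default `TRUE`.
#' @return an object of class `wavelet_plan`.
#' @export
wavelet_plan <- function(wavelet = "sym5", levels = 8L,
                         detail_threshold_levels = 1:2,
                         drop_approximation = TRUE) {
  stopifnot(is_count(levels),
            is.logical(drop_approximation), length(drop_approximation) == 1L)
  wavelet_filters(wavelet)
  detail_threshold_levels <- as.integer(detail_threshold_levels)
  if (length(detail_threshold_levels) &&
      (any(detail_threshold_levels < 1L)))
    abort("detail_threshold_levels must be >= 1")
  structure(list(wavelet = wavelet, levels = as.integer(levels),
                 detail_threshold_levels = detail_threshold_levels,
                 drop_approximation = drop_approximation),
            class = "wavelet_plan")
}

#' Denoise an ECG record by wavelet shrinkage
#'
#' Decomposes the signal to the plan's depth, soft-thresholds the
#' configured fine detail bands at the universal threshold, optionally
#' zeroes the deepest approximation (baseline wander), and reconstructs a
#' signal of the original length. Sampling frequency, label and subject
#' are unchanged.
#'
#' @param record an [ecg_record()].
#' @param plan a [wavelet_plan()].
#' @return the denoised `ecg_record`.
#' @export
denoise_record <- function(record, plan = wavelet_plan()) {
  stopifnot(inherits(record, "ecg_record"), inherits(plan, "wavelet_plan"))
  x <- record$samples
  n <- length(x)
  if (n < 1L) abort("cannot denoise an empty record")
  filt <- wavelet_filters(plan$wavelet)
  levels <- plan$levels
  max_lev <- dwt_max_level(n, length(filt$dec_lo))
  if (max_lev < 1L)
    abort("record of %d samples is too short for any wavelet decomposition", n)
  if (levels > max_lev) {
    warnf("reducing wavelet depth from %d to %d for a %d-sample record",
          levels, max_lev, n)
    levels <- max_lev
  }
  dec <- wave_decompose(x, levels, plan$wavelet)
  thr_levels <- plan$detail_threshold_levels
  thr_levels <- thr_levels[thr_levels <= levels]
  if (length(thr_levels)) {
    d1 <- dec$details[[1L]]
    sigma <- stats::median(abs(d1 - stats::median(d1))) / 0.6745
    thr <- sigma * sqrt(2 * log(n))
    for (lev in thr_levels)
      dec$details[[lev]] <- soft_threshold(dec$details[[lev]], thr)
  }
  if (plan$drop_approximation)
    dec$approximation[] <- 0
  out <- record
  out$samples <- wave_reconstruct(dec)
  out
}
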