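## Stimulus generation and temporal embedding.
##
## A stimulus movie is a contrast grid on a space (x space) x time lattice
## with an associated frame rate. 1-D movies (bar stimuli, gratings) are
## stored as an n_x x n_frames matrix; 2-D movies (pixel noise) as an
## n_x x n_y x n_frames array. All generated movies follow a zero-mean
## contrast convention except the binary bar stimulus, whose entries are
## exactly +-1.

#' Construct a stimulus movie object
#'
#' Wraps a contrast grid with its frame rate and a kind tag. Most users will
#' not call this directly but obtain movies from [generate_bar_stimulus()],
#' [generate_grating()] or [generate_pink_noise_movie()]; it is exported so
#' that externally recorded or custom stimuli can enter the pipeline.
#'
#' @param values numeric matrix (`n_x` x `n_frames`) for 1-D stimuli or
#'   3-D array (`n_x` x `n_y` x `n_frames`) for 2-D stimuli.
#' @param frame_rate_hz frames per second (positive scalar).
#' @param kind one of `"bars"`, `"grating"`, `"pink_noise"`, `"custom"`.
#' @return An object of class `stimulus_movie` with elements `values`,
#'   `frame_rate_hz`, `kind`, `space_dim` (length 1 or 2) and `n_frames`.
#' @export
stimulus_movie <- function(values, frame_rate_hz, kind = "custom") {
  kind <- match.arg(kind, c("bars", "grating", "pink_noise", "custom"))
  if (!(is.matrix(values) || (is.array(values) && length(dim(values)) == 3)))
    stop("`values` must be a matrix (1-D space) or 3-D array (2-D space)")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be a positive scalar")
  d <- dim(values)
  nd <- length(d)
  structure(list(
    values = values,
    frame_rate_hz = frame_rate_hz,
    kind = kind,
    space_dim = d[-nd],
    n_frames = d[nd]
  ), class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  cat(sprintf("<stimulus_movie> kind=%s  space=%s  frames=%d  rate=%g Hz\n",
              x$kind, paste(x$space_dim, collapse = "x"), x$n_frames,
              x$frame_rate_hz))
  invisible(x)
}

## Maximal-length LFSR tap table (Fibonacci form), orders 2..16.
## Taps give bit positions XORed to form the feedback bit.
.mseq_taps <- list(
  `2` = c(2, 1),  `3` = c(3, 2),  `4` = c(4, 3),  `5` = c(5, 3),
  `6` = c(6, 5),  `7` = c(7, 6),  `8` = c(8, 6, 5, 4), `9` = c(9, 5),
  `10` = c(10, 7), `11` = c(11, 9), `12` = c(12, 6, 4, 1),
  `13` = c(13, 4, 3, 1), `14` = c(14, 5, 3, 1), `15` = c(15, 14),
  `16` = c(16, 15, 13, 4)
)

#' Binary m-sequence
#'
#' Generates one full period (2^order - 1 bits) of a maximal-length
#' shift-register sequence using a fixed built-in table of primitive
#' feedback taps, so the sequence is fully deterministic for a given order.
#'
#' @param order register length (2..16).
#' @return integer vector of 0/1 bits of length `2^order - 1`.
#' @export
mseq_bits <- function(order) {
  taps <- .mseq_taps[[as.character(order)]]
  if (is.null(taps))
    stop("no stored primitive polynomial for m-sequence order ", order,
         " (supported: 2-16)")
  period <- 2L^order - 1L
  reg <- rep(1L, order)
  bits <- integer(period)
  for (i in seq_len(period)) {
    bits[i] <- reg[order]
    fb <- Reduce(bitwXor, reg[taps])
    reg <- c(fb, reg[-order])
  }
  bits
}

#' Generate a binary m-sequence bar stimulus
#'
#' Each frame assigns contrast +1 or -1 to each of `n_bars` spatial
#' positions by reading successive non-overlapping windows of a periodic
#' maximal-length sequence (bit 0 maps to +1, bit 1 to -1). Frame `t`
#' (0-based) at bar `x` (0-based) reads bit `(t * n_bars + x) mod period`.
#' The output is deterministic: same arguments, same movie.
#'
#' @param n_bars number of bars (spatial positions).
#' @param n_frames number of frames.
#' @param mseq_order shift-register order; the period `2^mseq_order - 1`
#'   must be at least `n_bars`.
#' @param frame_rate_hz frame rate, default 100 Hz.
#' @return a [stimulus_movie()] of kind `"bars"` with values in {-1, +1}.
#' @export
generate_bar_stimulus <- function(n_bars, n_frames, mseq_order = 15,
                                  frame_rate_hz = 100) {
  stopifnot(n_bars >= 1, n_frames >= 1, mseq_order >= 2)
  period <- 2L^mseq_order - 1L
  if (period < n_bars)
    stop("m-sequence period ", period, " shorter than n_bars = ", n_bars)
  bits <- mseq_bits(mseq_order)
  idx <- (outer(0:(n_bars - 1L), 0:(n_frames - 1L) * n_bars, `+`)) %% period
  vals <- matrix(ifelse(bits[idx + 1L] == 0L, 1, -1), nrow = n_bars)
  stimulus_movie(vals, frame_rate_hz, "bars")
}

#' Generate a drifting sinusoidal grating movie
#'
#' `value(x, t) = cos(2 pi (spatial_freq x / n_bars - direction
#' temporal_freq t / frame_rate_hz))` with contrast amplitude 1;
#' `direction = +1` drifts toward increasing `x`.
#'
#' @param n_bars spatial positions.
#' @param n_frames frames.
#' @param spatial_freq cycles per stimulus width.
#' @param temporal_freq drift rate in Hz; must respect the Nyquist limit
#'   `temporal_freq < frame_rate_hz / 2`.
#' @param direction `+1` or `-1`.
#' @param frame_rate_hz frame rate, default 100 Hz.
#' @return a [stimulus_movie()] of kind `"grating"`.
#' @export
generate_grating <- function(n_bars, n_frames, spatial_freq, temporal_freq,
                             direction = 1, frame_rate_hz = 100) {
  stopifnot(n_bars >= 1, n_frames >= 1, direction %in% c(-1, 1))
  if (temporal_freq >= frame_rate_hz / 2)
    stop("temporal_freq ", temporal_freq, " Hz aliases at frame rate ",
         frame_rate_hz, " Hz (Nyquist limit ", frame_rate_hz / 2, " Hz)")
  x <- 0:(n_bars - 1L)
  t <- 0:(n_frames - 1L)
  phase <- outer(spatial_freq * x / n_bars,
                 direction * temporal_freq * t / frame_rate_hz, `-`)
  stimulus_movie(cos(2 * pi * phase), frame_rate_hz, "grating")
}

#' Generate a 1/f^a pink-noise movie
#'
#' Seeded Gaussian white noise is shaped in the Fourier domain so its
#' amplitude spectrum falls off as `1/f^exponent` of the radial
#' spatiotemporal frequency (cycles/sample on each axis); the DC component
#' is zeroed. The result is standardized to zero mean and unit variance.
#' With `exponent = 0` the movie is white.
#'
#' @param n_x,n_y spatial size; set `n_y = NULL` for a 1-D (bar-like) movie.
#' @param n_frames frames.
#' @param exponent spectral slope, default 1 (classic pink noise).
#' @param seed integer seed; the same seed reproduces the movie exactly.
#' @param frame_rate_hz frame rate, default 50 Hz.
#' @return a [stimulus_movie()] of kind `"pink_noise"`.
#' @export
generate_pink_noise_movie <- function(n_x, n_y, n_frames, exponent = 1,
                                      seed, frame_rate_hz = 50) {
  stopifnot(n_x >= 2, n_frames >= 2)
  if (!is.null(n_y)) stopifnot(n_y >= 2)
  dims <- if (is.null(n_y)) c(n_x, n_frames) else c(n_x, n_y, n_frames)
  z <- with_seed(seed, array(rnorm(prod(dims)), dim = dims))
  fr <- lapply(dims, fft_freqs)
  if (length(dims) == 2) {
    f <- sqrt(outer(fr[[1]]^2, fr[[2]]^2, `+`))
  } else {
    f <- sqrt(outer(outer(fr[[1]]^2, fr[[2]]^2, `+`), fr[[3]]^2, `+`))
  }
  amp <- 1 / f^exponent
  amp[1] <- 0  # zero DC
  shaped <- Re(fft(fft(z) * amp, inverse = TRUE)) / prod(dims)
  shaped <- (shaped - mean(shaped)) / sd(shaped)
  out <- array(shaped, dim = dims)
  stimulus_movie(out, frame_rate_hz, "pink_noise")
}

#' Temporally embed a stimulus movie into a design matrix
#'
#' Row `t` of the design matrix contains the stimulus at lags
#' `0..n_lags-1` preceding (and including) frame `t`; lag 0 is the frame in
#' the same time bin as the response. Columns follow a fixed space-major,
#' lag-minor ordering: for spatial position `s` (column-major over x, y)
#' and lag `l`, the column index is `(s - 1) * n_lags + l + 1`. The first
#' `n_lags - 1` rows reference frames before the start of the movie; their
#' missing lags are zero-padded and the rows are flagged in the `padded`
#' attribute so estimation routines can exclude them.
#'
#' @param movie a [stimulus_movie()].
#' @param n_lags number of time lags (>= 1, <= number of frames).
#' @return a matrix of class `design_matrix`, `n_frames` rows and
#'   `n_space * n_lags` columns, with attributes `n_lags`, `space_dim`,
#'   `padded` (logical per row) and `frame_rate_hz`.
#' @export
embed_stimulus <- function(movie, n_lags) {
  stopifnot(inherits(movie, "stimulus_movie"), n_lags >= 1,
            n_lags <= movie$n_frames)
  n_space <- prod(movie$space_dim)
  n_frames <- movie$n_frames
  frames <- matrix(movie$values, nrow = n_space, ncol = n_frames)
  X <- matrix(0, nrow = n_frames, ncol = n_space * n_lags)
  for (l in 0:(n_lags - 1L)) {
    cols <- seq.int(l + 1L, by = n_lags, length.out = n_space)
    if (l == 0) {
      X[, cols] <- t(frames)
    } else {
      X[(l + 1L):n_frames, cols] <- t(frames[, 1:(n_frames - l), drop = FALSE])
    }
  }
  structure(X,
            class = c("design_matrix", "matrix", "array"),
            n_lags = n_lags,
            space_dim = movie$space_dim,
            padded = seq_len(n_frames) < n_lags,
            frame_rate_hz = movie$frame_rate_hz)
}

## Rows usable for estimation (not zero-padded).
unpadded <- function(design) !attr(design, "padded")

design_dims <- function(design) {
  list(n_lags = attr(design, "n_lags"),
       space_dim = attr(design, "space_dim"),
       n_space = prod(attr(design, "space_dim")))
}
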