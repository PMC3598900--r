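## Classical tuning metrics.
##
## DSI = (Rp - Rnp) / (Rp + Rnp) contrasts mean rates in the preferred and
## opposite drift direction of the best grating; MI = F1/DC is the
## modulation of the response at the grating temporal frequency relative
## to its mean (MI > 1: phase-modulated "simple" response; MI < 1:
## phase-invariant "complex" response). DSI_RF computes the same
## directional contrast from a filter alone, as the normalized difference
## of summed Fourier power in the two spectral quadrants corresponding to
## the two motion directions.

#' Grating tuning of a model neuron or fitted GNM
#'
#' Simulates responses to drifting sinusoidal gratings over a grid of
#' spatial and temporal frequencies in both directions, discards one
#' transient cycle, and reports the preferred grating, the
#' direction-selectivity index and the modulation index.
#'
#' @param model a [neuron_spec()] or [gnm_model()].
#' @param sf_grid spatial frequencies (cycles/stimulus width).
#' @param tf_grid temporal frequencies (Hz).
#' @param n_cycles steady-state cycles used for the rate estimates
#'   (>= 4; one additional transient cycle is always discarded).
#' @param n_bars spatial size of the probe grating; defaults to the model
#'   filter width.
#' @param frame_rate_hz probe frame rate, default 100 Hz.
#' @return list of class `tuning_metrics`: `dsi` (signed: positive when
#'   drift toward increasing x dominates), `dsi_pref` (= |dsi|, the
#'   conventional preferred/non-preferred contrast), `mi`, `preferred`
#'   (list: `spatial_freq`, `temporal_freq`, `direction`), `rates`
#'   (mean-rate table over the grid).
#' @export
grating_tuning <- function(model, sf_grid = c(1, 2, 3), tf_grid = c(2, 4, 8),
                           n_cycles = 8, n_bars = NULL,
                           frame_rate_hz = 100) {
  stopifnot(n_cycles >= 4)
  filt1 <- if (inherits(model, "neuron_spec")) model$filters[[1]]
           else model$filters[[1]]
  d <- dim(filt1)
  n_lags <- d[length(d)]
  if (is.null(n_bars)) n_bars <- d[1]
  rate_fun <- if (inherits(model, "neuron_spec")) {
    function(des) neuron_rate(model, des)
  } else if (inherits(model, "gnm_model")) {
    function(des) gnm_predict(model, des)
  } else stop("`model` must be a neuron_spec or gnm_model")

  grid <- expand.grid(sf = sf_grid, tf = tf_grid, dir = c(1, -1))
  grid$mean_rate <- NA_real_
  responses <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tf <- grid$tf[i]
    frames_per_cycle <- frame_rate_hz / tf
    n_frames <- ceiling((n_cycles + 1) * frames_per_cycle) + n_lags
    mov <- generate_grating(n_bars, n_frames, grid$sf[i], tf,
                            direction = grid$dir[i],
                            frame_rate_hz = frame_rate_hz)
    des <- embed_stimulus(mov, n_lags)
    r <- rate_fun(des)
    ## drop padding and one transient cycle, keep an integer cycle count
    start <- n_lags + ceiling(frames_per_cycle)
    len <- floor(n_cycles * frames_per_cycle)
    rr <- r[start + seq_len(len)]
    responses[[i]] <- rr
    grid$mean_rate[i] <- mean(rr)
  }
  best <- which.max(grid$mean_rate)
  sf_p <- grid$sf[best]; tf_p <- grid$tf[best]; dir_p <- grid$dir[best]
  r_pos <- grid$mean_rate[grid$sf == sf_p & grid$tf == tf_p & grid$dir == 1]
  r_neg <- grid$mean_rate[grid$sf == sf_p & grid$tf == tf_p & grid$dir == -1]
  dsi <- (r_pos - r_neg) / (r_pos + r_neg)
  ## MI at the preferred grating: F1 amplitude over DC
  rr <- responses[[best]]
  dc <- mean(rr)
  if (dc <= 0) stop("zero mean rate at the preferred grating; MI undefined")
  tt <- seq_along(rr) - 1
  f1 <- 2 * Mod(mean(rr * exp(-2i * pi * tf_p * tt / frame_rate_hz)))
  structure(list(dsi = dsi, dsi_pref = abs(dsi), mi = f1 / dc,
                 preferred = list(spatial_freq = sf_p, temporal_freq = tf_p,
                                  direction = dir_p),
                 rates = grid),
            class = "tuning_metrics")
}

#' @export
print.tuning_metrics <- function(x, ...) {
  cat(sprintf(
    "<tuning_metrics> DSI=%.3f (signed %.3f), MI=%.3f @ sf=%g, tf=%g Hz, dir=%+d\n",
    x$dsi_pref, x$dsi, x$mi, x$preferred$spatial_freq,
    x$preferred$temporal_freq, x$preferred$direction))
  invisible(x)
}

#' Direction-selectivity index of a filter from its Fourier spectrum
#'
#' `DSI_RF = (Q1 - Q2) / (Q1 + Q2)` where `Q1` and `Q2` are the summed
#' power (squared magnitude) of the filter's 2-D discrete Fourier
#' transform over the two quadrants corresponding to opposite motion
#' directions; the zero-frequency row and column (shared by both
#' quadrants) are excluded. Positive values indicate preference for drift
#' toward increasing x. A space-time-separable filter yields exactly 0;
#' mirroring the filter in space exactly negates the index.
#'
#' @param filter a 2-D (space x lag) [strf()] or matrix.
#' @return scalar in `[-1, 1]`.
#' @export
dsi_from_rf <- function(filter) {
  W <- unclass(filter)
  if (length(dim(W)) != 2)
    stop("dsi_from_rf needs a 2-D (space x lag) filter; for 3-D filters ",
         "use project_preferred_axis() first")
  if (all(W == 0)) stop("all-zero filter; DSI_RF undefined")
  P <- Mod(fft(W))^2
  fx <- fft_freqs(nrow(W))
  ft <- fft_freqs(ncol(W))
  ## exclude the zero-frequency axes (shared by both quadrants) and the
  ## unpaired Nyquist row/column of even-sized grids, so the two quadrant
  ## sums are exactly symmetric for separable filters
  pos_x <- fx > 0 & fx < 0.5
  neg_x <- fx < 0 & fx > -0.5
  pos_t <- ft > 0 & ft < 0.5
  q1 <- sum(P[pos_x, pos_t])
  q2 <- sum(P[neg_x, pos_t])
  (q1 - q2) / (q1 + q2)
}

#' Separable decomposition of a space-time filter by SVD
#'
#' Decomposes an x-t filter into a sum of separable (rank-1) components
#' `sigma_r u_r v_r'`. A direction-selective filter is inseparable but is
#' exactly the sum of two separable, individually non-DS components when
#' it is a space-time-oriented sinusoid — the classical construction of DS
#' from non-DS inputs.
#'
#' @param filter a 2-D (space x lag) [strf()] or matrix.
#' @param rank components to keep (<= min(n_x, n_lags)).
#' @return list of class `separable_decomposition`: `spatial_kernels`,
#'   `temporal_kernels` (unit-norm columns), `singular_values`
#'   (descending), `rank_kept`, `reconstruction` (matrix) and
#'   `rel_error` (relative Frobenius reconstruction error).
#' @export
svd_separable <- function(filter, rank = 2) {
  W <- unclass(filter)
  stopifnot(length(dim(W)) == 2, rank >= 1, rank <= min(dim(W)))
  sv <- svd(W)
  keep <- seq_len(rank)
  recon <- sv$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
  structure(list(spatial_kernels = sv$u[, keep, drop = FALSE],
                 temporal_kernels = sv$v[, keep, drop = FALSE],
                 singular_values = sv$d,
                 rank_kept = rank,
                 reconstruction = recon,
                 rel_error = sqrt(sum((W - recon)^2) / sum(W^2))),
            class = "separable_decomposition")
}

#' @export
print.separable_decomposition <- function(x, ...) {
  cat(sprintf("<separable_decomposition> rank %d kept, rel. error %.3g\n",
              x$rank_kept, x$rel_error))
  invisible(x)
}

#' One separable component as a filter
#'
#' @param dec a `separable_decomposition`.
#' @param r component index.
#' @return unit-norm [strf()] of the rank-1 component.
#' @export
separable_component <- function(dec, r) {
  stopifnot(r >= 1, r <= dec$rank_kept)
  strf(tcrossprod(dec$spatial_kernels[, r], dec$temporal_kernels[, r]))
}

#' Estimate the preferred spatial orientation of a 3-D filter
#'
#' Takes the spatial slice at the lag of maximal spatial power and returns
#' the orientation of the dominant (off-DC) spatial frequency component.
#'
#' @param filter3d an `n_x x n_y x n_lags` [strf()] or array.
#' @return orientation in radians (direction of the dominant wave vector).
#' @export
estimate_orientation <- function(filter3d) {
  A <- unclass(filter3d)
  stopifnot(length(dim(A)) == 3)
  pw <- apply(A, 3, function(s) sum((s - mean(s))^2))
  sl <- A[, , which.max(pw)]
  P <- Mod(fft(sl))^2
  fx <- fft_freqs(nrow(sl)); fy <- fft_freqs(ncol(sl))
  P[1, 1] <- 0
  if (max(P) <= .Machine$double.eps * sum(dim(sl)))
    stop("isotropic/degenerate filter: orientation undefined; supply one")
  ij <- which(P == max(P), arr.ind = TRUE)[1, ]
  ang <- atan2(fy[ij[2]], fx[ij[1]])
  ## orientation is axial: report in (-pi/2, pi/2]
  if (ang > pi / 2) ang <- ang - pi
  if (ang <= -pi / 2) ang <- ang + pi
  ang
}

#' Project a 3-D filter onto its preferred motion axis
#'
#' Rotates each spatial slice so the preferred-motion axis is horizontal
#' (bilinear interpolation about the grid center, zero outside) and sums
#' over the orthogonal spatial coordinate, producing an x-t filter
#' directly comparable to bar-stimulus STRFs.
#'
#' @param filter3d an `n_x x n_y x n_lags` [strf()] or array.
#' @param orientation rotation angle in radians; estimated with
#'   [estimate_orientation()] when missing.
#' @return 2-D [strf()] (x-t), not normalized.
#' @export
project_preferred_axis <- function(filter3d, orientation = NULL) {
  A <- unclass(filter3d)
  stopifnot(length(dim(A)) == 3)
  if (is.null(orientation)) orientation <- estimate_orientation(filter3d)
  d <- dim(A)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  co <- cos(orientation); si <- sin(orientation)
  grid <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  xs <- cx + (grid$x - cx) * co - (grid$y - cy) * si
  ys <- cy + (grid$x - cx) * si + (grid$y - cy) * co
  x0 <- floor(xs); y0 <- floor(ys)
  wx <- xs - x0; wy <- ys - y0
  val_at <- function(sl, ix, iy) {
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
    v <- numeric(length(ix))
    v[ok] <- sl[cbind(ix[ok], iy[ok])]
    v
  }
  out <- matrix(0, d[1], d[3])
  for (l in seq_len(d[3])) {
    sl <- A[, , l]
    v <- (1 - wx) * (1 - wy) * val_at(sl, x0, y0) +
      wx * (1 - wy) * val_at(sl, x0 + 1L, y0) +
      (1 - wx) * wy * val_at(sl, x0, y0 + 1L) +
      wx * wy * val_at(sl, x0 + 1L, y0 + 1L)
    rot <- matrix(v, d[1], d[2])
    out[, l] <- rowSums(rot)
  }
  strf(out, normalize = FALSE)
}
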