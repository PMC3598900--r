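## Spatiotemporal receptive-field (STRF) filters.
##
## A filter is a weight grid over space x lag: an n_x x n_lags matrix for
## 1-D (bar) stimuli or an n_x x n_y x n_lags array for 2-D stimuli, with
## class "strf". Vectorized filters use the same space-major, lag-minor
## column ordering as the design matrix, so `filter output = design %*%
## filter_to_vec(k)`.

#' Construct an STRF filter object
#'
#' @param weights matrix (`n_x` x `n_lags`) or array (`n_x` x `n_y` x
#'   `n_lags`) of finite weights.
#' @param normalize if `TRUE` (default) scale to unit Euclidean norm.
#' @param center optional spatial location tag (bar index, 0-based).
#' @return object of class `strf`.
#' @export
strf <- function(weights, normalize = TRUE, center = NULL) {
  stopifnot(is.numeric(weights), all(is.finite(weights)))
  if (is.null(dim(weights)))
    stop("`weights` must have space x lag dimensions")
  w <- weights
  if (normalize) {
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) stop("cannot normalize an all-zero filter")
    w <- w / nrm
  }
  structure(w, class = c("strf", class(weights)), center = center)
}

#' @export
print.strf <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<strf> %s (space x lag), norm=%.6g\n",
              paste(d, collapse = "x"), sqrt(sum(x^2))))
  invisible(x)
}

## space-major, lag-minor vectorization matching embed_stimulus().
filter_to_vec <- function(k) {
  d <- dim(k)
  nd <- length(d)
  n_lags <- d[nd]
  if (nd == 2) {
    as.vector(t(k))
  } else {
    ## (x, y, lag) -> order: s = (x, y) column-major, lag fastest
    as.vector(aperm(unclass(k), c(3, 1, 2)))
  }
}

vec_to_filter <- function(v, space_dim, n_lags, normalize = FALSE) {
  n_space <- prod(space_dim)
  stopifnot(length(v) == n_space * n_lags)
  if (length(space_dim) == 1) {
    w <- t(matrix(v, nrow = n_lags, ncol = n_space))
  } else {
    w <- aperm(array(v, dim = c(n_lags, space_dim)), c(2, 3, 1))
  }
  strf(w, normalize = normalize)
}

## Deterministic sign convention: entry of largest magnitude is positive.
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Parametric Gabor-like STRF
#'
#' Builds a space-time Gabor `cos(2 pi spatial_freq x / n_x +
#' tilt_phase_per_lag * l + phase)` under separable spatial and temporal
#' Gaussian envelopes, normalized to unit norm. A nonzero
#' `tilt_phase_per_lag` tilts the filter in the x-t plane, making it
#' direction selective; with zero tilt the filter is exactly separable
#' (rank 1).
#'
#' @param n_x,n_lags grid size.
#' @param spatial_freq cycles per filter width.
#' @param tilt_phase_per_lag phase advance per lag, radians (sets speed and
#'   direction preference).
#' @param phase carrier phase, radians.
#' @param space_sd,lag_sd Gaussian envelope SDs (grid units).
#' @param space_center,lag_center envelope centers (0-based grid units);
#'   default the grid middle.
#' @return unit-norm [strf()].
#' @export
make_gabor_strf <- function(n_x, n_lags, spatial_freq = 2,
                            tilt_phase_per_lag = 0, phase = 0,
                            space_sd = n_x / 5, lag_sd = n_lags / 4,
                            space_center = (n_x - 1) / 2,
                            lag_center = (n_lags - 1) / 2) {
  stopifnot(n_x >= 4, n_lags >= 4, space_sd > 0, lag_sd > 0)
  x <- 0:(n_x - 1)
  l <- 0:(n_lags - 1)
  carrier <- cos(outer(2 * pi * spatial_freq * x / n_x,
                       tilt_phase_per_lag * l, `+`) + phase)
  env <- outer(exp(-(x - space_center)^2 / (2 * space_sd^2)),
               exp(-(l - lag_center)^2 / (2 * lag_sd^2)))
  strf(carrier * env, center = space_center)
}

#' Spatially shift a 1-D filter by an integer number of bars
#'
#' Weights sliding off the stimulus edge are lost (zero filling); the
#' filter is not renormalized. Used to build the shifted subunit bank of
#' pooled complex cells and to align localized filters.
#'
#' @param k a 2-D (space x lag) [strf()].
#' @param shift integer bar shift (positive = toward larger x).
#' @return shifted [strf()] with updated `center` attribute.
#' @export
shift_filter <- function(k, shift) {
  stopifnot(length(dim(k)) == 2)
  n_x <- nrow(k)
  out <- matrix(0, n_x, ncol(k))
  src <- seq_len(n_x) - shift
  keep <- src >= 1 & src <= n_x
  out[keep, ] <- k[src[keep], , drop = FALSE]
  strf(out, normalize = FALSE,
       center = (attr(k, "center") %||% (n_x - 1) / 2) + shift)
}
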