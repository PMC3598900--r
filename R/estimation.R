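## Spike-triggered characterization.
##
## The spike-triggered average (STA) is the count-weighted mean of the
## embedded stimulus preceding spikes, minus the ensemble mean: the linear
## receptive-field estimate. Spike-triggered covariance (STC) analysis
## eigendecomposes dC = C_spike - C_all, the difference between the
## spike-conditioned and ensemble stimulus covariance; eigenvectors with
## significantly increased (excitatory) or decreased (suppressive) variance
## span the stimulus subspace the neuron cares about. Frames with k spikes
## contribute with weight k, matching the Poisson likelihood used
## downstream. Padded rows are always excluded; the STA is not projected
## out of the STC.

spike_weights <- function(design, spikes) {
  if (length(spikes) != nrow(design))
    stop("spike count length ", length(spikes),
         " does not match design rows ", nrow(design))
  keep <- unpadded(design)
  w <- as.numeric(spikes)
  w[!keep] <- 0
  w
}

#' Spike-triggered average
#'
#' @param design a design matrix from [embed_stimulus()].
#' @param spikes per-frame spike counts aligned to `design`.
#' @return unit-norm [strf()] with attributes `raw` (the unnormalized STA
#'   grid, in contrast units) and `n_spikes`.
#' @export
compute_sta <- function(design, spikes) {
  w <- spike_weights(design, spikes)
  W <- sum(w)
  if (W <= 0) stop("no spikes in unpadded frames; STA undefined")
  keep <- unpadded(design)
  mu_all <- colMeans(design[keep, , drop = FALSE])
  sta_vec <- as.numeric(crossprod(design, w)) / W - mu_all
  d <- design_dims(design)
  raw <- vec_to_filter(sta_vec, d$space_dim, d$n_lags, normalize = FALSE)
  out <- vec_to_filter(fix_sign(sta_vec), d$space_dim, d$n_lags,
                       normalize = TRUE)
  attr(out, "raw") <- unclass(raw)
  attr(out, "n_spikes") <- W
  out
}

#' Spike-triggered covariance analysis
#'
#' Computes `dC = C_spike - C_all` and its symmetric eigendecomposition.
#' Both covariances are mean-subtracted (ensemble mean for `C_all`,
#' spike-triggered mean for `C_spike`), and eigenvalues are returned in
#' descending order with each eigenvector's largest-magnitude entry made
#' positive so results are deterministic.
#'
#' @inheritParams compute_sta
#' @return object of class `stc_result`: list with `sta` (unit [strf()]),
#'   `eigenvalues`, `eigenvectors` (columns, unit norm, design-matrix
#'   layout), `delta_trace`, `n_spikes_used`, `space_dim`, `n_lags`, and
#'   empty significance sets (filled by [select_significant()]).
#' @export
compute_stc <- function(design, spikes) {
  w <- spike_weights(design, spikes)
  W <- sum(w)
  if (W <= 0) stop("no spikes in unpadded frames; STC undefined")
  if (W < 10 * ncol(design))
    warning(sprintf("only %d spikes for %d dimensions; STC will be noisy",
                    as.integer(W), ncol(design)))
  keep <- unpadded(design)
  X <- design[keep, , drop = FALSE]
  wk <- w[keep]
  n <- nrow(X)
  mu_all <- colMeans(X)
  C_all <- crossprod(sweep(X, 2, mu_all)) / n
  mu_spk <- as.numeric(crossprod(X, wk)) / W
  C_spk <- crossprod(X * sqrt(wk)) / W - tcrossprod(mu_spk)
  dC <- C_spk - C_all
  eig <- eigen(dC, symmetric = TRUE)
  vec <- apply(eig$vectors, 2, fix_sign)
  d <- design_dims(design)
  structure(list(
    sta = compute_sta(design, spikes),
    eigenvalues = eig$values,
    eigenvectors = vec,
    delta_trace = sum(diag(dC)),
    n_spikes_used = W,
    space_dim = d$space_dim,
    n_lags = d$n_lags,
    excitatory = integer(0),
    suppressive = integer(0),
    selection = NULL
  ), class = "stc_result")
}

#' @export
print.stc_result <- function(x, ...) {
  cat(sprintf("<stc_result> %d dims, %g spikes; top eigenvalues: %s\n",
              length(x$eigenvalues), x$n_spikes_used,
              paste(signif(utils::head(x$eigenvalues, 3), 3), collapse = ", ")))
  if (length(x$excitatory) || length(x$suppressive))
    cat(sprintf("  significant: %d excitatory, %d suppressive\n",
                length(x$excitatory), length(x$suppressive)))
  invisible(x)
}

#' Extract an STC eigenvector as a filter
#'
#' @param stc an `stc_result`.
#' @param i eigenvector index (into the descending eigenvalue order).
#' @return unit-norm [strf()].
#' @export
stc_filter <- function(stc, i) {
  vec_to_filter(stc$eigenvectors[, i], stc$space_dim, stc$n_lags,
                normalize = TRUE)
}

## Max/min eigenvalues of dC recomputed with circularly shifted spikes.
## The shift (>= n_lags frames) preserves spike-train autostructure while
## destroying the stimulus-spike alignment, giving a conservative null.
stc_shuffle_null <- function(design, spikes, n_shuffles, seed) {
  keep <- unpadded(design)
  X <- design[keep, , drop = FALSE]
  w_full <- as.numeric(spikes)[keep]
  n <- nrow(X)
  n_lags <- attr(design, "n_lags")
  mu_all <- colMeans(X)
  C_all <- crossprod(sweep(X, 2, mu_all)) / n
  shifts <- with_seed(seed,
                      sample(seq.int(n_lags, n - n_lags), n_shuffles,
                             replace = TRUE))
  mx <- mn <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    wk <- w_full[((seq_len(n) - 1L + shifts[s]) %% n) + 1L]
    W <- sum(wk)
    mu_spk <- as.numeric(crossprod(X, wk)) / W
    C_spk <- crossprod(X * sqrt(wk)) / W - tcrossprod(mu_spk)
    ev <- eigen(C_spk - C_all, symmetric = TRUE, only.values = TRUE)$values
    mx[s] <- ev[1]
    mn[s] <- ev[length(ev)]
  }
  list(max = mx, min = mn)
}

#' Select significant STC filters
#'
#' Either takes a fixed number of top/bottom eigenvalues, or keeps the
#' eigenvalues falling outside a two-sided envelope of the extreme
#' eigenvalues obtained from recomputing the STC with circularly
#' time-shifted spike trains (a stimulus-preserving null).
#'
#' @param stc an `stc_result` from [compute_stc()].
#' @param method `"fixed"` or `"shuffle"`.
#' @param n_pos,n_neg numbers of excitatory / suppressive filters
#'   (`method = "fixed"`).
#' @param design,spikes the data used for `stc` (`method = "shuffle"`).
#' @param n_shuffles number of circular-shift recomputations.
#' @param alpha two-sided level: keep eigenvalues above the `1 - alpha/2`
#'   quantile of shuffled maxima or below the `alpha/2` quantile of
#'   shuffled minima.
#' @param seed seed for the shuffle shifts.
#' @return the `stc_result` with `excitatory` and `suppressive` index sets
#'   filled in and a `selection` record of the method.
#' @export
select_significant <- function(stc, method = c("fixed", "shuffle"),
                               n_pos = 2, n_neg = 0,
                               design = NULL, spikes = NULL,
                               n_shuffles = 100, alpha = 0.01, seed = 1) {
  method <- match.arg(method)
  d <- length(stc$eigenvalues)
  if (method == "fixed") {
    if (n_pos + n_neg > d)
      stop("n_pos + n_neg exceeds the subspace dimension ", d)
    stc$excitatory <- seq_len(n_pos)
    stc$suppressive <- if (n_neg > 0) seq.int(d - n_neg + 1L, d) else integer(0)
    stc$selection <- list(method = "fixed", n_pos = n_pos, n_neg = n_neg)
  } else {
    if (is.null(design) || is.null(spikes))
      stop("shuffle selection needs the original `design` and `spikes`")
    null <- stc_shuffle_null(design, spikes, n_shuffles, seed)
    hi <- quantile(null$max, 1 - alpha / 2, names = FALSE)
    lo <- quantile(null$min, alpha / 2, names = FALSE)
    stc$excitatory <- which(stc$eigenvalues > hi)
    stc$suppressive <- which(stc$eigenvalues < lo)
    stc$selection <- list(method = "shuffle", n_shuffles = n_shuffles,
                          alpha = alpha, upper = hi, lower = lo)
  }
  stc
}

#' PCA-whiten a design matrix
#'
#' For correlated stimulus ensembles (pink noise, natural movies) the raw
#' STC is biased by the stimulus covariance. Whitening projects the design
#' matrix onto its first `M` principal components and rescales them to unit
#' variance: `Z = S V D^(-1/2)` with `V` the leading eigenvectors of the
#' stimulus covariance and `D` their eigenvalues. `M` trades reliability of
#' the estimates against spatial resolution.
#'
#' @param design a design matrix.
#' @param M retained dimensions, default 600.
#' @return list with `design` (whitened `design_matrix`, `M` columns, same
#'   padding flags) and `basis` (class `whitening_basis`: `V`, `D`, `M`,
#'   `mean`, plus original layout).
#' @export
whiten_design <- function(design, M = 600) {
  keep <- unpadded(design)
  X <- design[keep, , drop = FALSE]
  if (M > min(nrow(X), ncol(X)))
    stop("M = ", M, " exceeds the design rank bound ",
         min(nrow(X), ncol(X)))
  mu <- colMeans(X)
  C <- crossprod(sweep(X, 2, mu)) / nrow(X)
  eig <- eigen(C, symmetric = TRUE)
  D <- eig$values[seq_len(M)]
  if (D[M] < .Machine$double.eps * max(D) * 1e3)
    stop("retained eigenvalue ", M, " is numerically zero; choose smaller M")
  V <- eig$vectors[, seq_len(M), drop = FALSE]
  Z_full <- sweep(unclass(design), 2, mu) %*% V %*% diag(1 / sqrt(D), M)
  Z_full[!keep, ] <- 0
  d <- design_dims(design)
  Z <- structure(Z_full,
                 class = c("design_matrix", "matrix", "array"),
                 n_lags = 1L, space_dim = M,
                 padded = attr(design, "padded"),
                 frame_rate_hz = attr(design, "frame_rate_hz"))
  basis <- structure(list(V = V, D = D, M = M, mean = mu,
                          space_dim = d$space_dim, n_lags = d$n_lags),
                     class = "whitening_basis")
  list(design = Z, basis = basis)
}

#' Map a whitened-space filter back to stimulus coordinates
#'
#' Applies `b = V D^(1/2) b_w`, which re-weights stimulus dimensions by
#' their standard deviation (effectively smoothing the estimate), and
#' returns the unit-normalized filter in the original space x lag layout.
#'
#' @param b_w numeric vector of length `M` (a filter in whitened
#'   coordinates, e.g. an STC eigenvector of the whitened design).
#' @param basis a `whitening_basis` from [whiten_design()].
#' @return unit-norm [strf()].
#' @export
dewhiten_filter <- function(b_w, basis) {
  b_w <- as.numeric(b_w)
  stopifnot(length(b_w) == basis$M)
  if (sum(b_w^2) == 0) stop("cannot dewhiten an all-zero filter")
  v <- as.numeric(basis$V %*% (sqrt(basis$D) * b_w))
  vec_to_filter(fix_sign(v), basis$space_dim, basis$n_lags, normalize = TRUE)
}
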