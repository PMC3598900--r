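## Localized-filter search in the STC subspace.
##
## STC eigenvectors describe the relevant stimulus subspace but are
## typically spatially extended, unlike the localized inputs a cortical
## neuron receives. Any unit-norm linear combination k_beta = sum_i beta_i
## b_i of the basis filters spans the same subspace; this module finds the
## combinations whose *temporal power* profile
##   R_beta(x) = 1/T sum_t [ <k_beta(x, .)>_t - k_beta(x, t) ]^2
## is most concentrated around a target location c, by minimizing
##   L(c, beta) = sum_x R_beta(x) (c - x)^2   subject to sum_i beta_i^2 = 1.
## Because R_beta is quadratic in the filter and the filter linear in beta,
## L is a quadratic form beta' Q(c) beta; the optimizer works on the
## normalized Rayleigh quotient with multiple seeded restarts.

## Internal basis structure: column-vectorized filters plus the per-position
## temporal-covariance slices A[i, j, x] = 1/T sum_t bc_i(x,t) bc_j(x,t),
## where bc is the basis filter centered across lags at each position.
localization_basis <- function(filters) {
  stopifnot(is.list(filters), length(filters) >= 1,
            all(vapply(filters, inherits, TRUE, "strf")))
  d <- dim(filters[[1]])
  nd <- length(d)
  n_lags <- d[nd]
  space_dim <- d[-nd]
  if (n_lags < 2) stop("temporal power needs n_lags >= 2")
  n_space <- prod(space_dim)
  m <- length(filters)
  ## BC[[i]]: n_space x T lag-centered grids
  BC <- lapply(filters, function(k) {
    g <- matrix(unclass(k), nrow = n_space, ncol = n_lags)
    g - rowMeans(g)
  })
  A <- array(0, dim = c(m, m, n_space))
  for (i in seq_len(m)) for (j in i:m) {
    aij <- rowSums(BC[[i]] * BC[[j]]) / n_lags
    A[i, j, ] <- aij
    A[j, i, ] <- aij
  }
  ## spatial coordinates, 0-based; 2-D space uses the (x, y) grid
  coords <- if (length(space_dim) == 1) {
    matrix(0:(space_dim - 1), ncol = 1)
  } else {
    as.matrix(expand.grid(x = 0:(space_dim[1] - 1),
                          y = 0:(space_dim[2] - 1)))
  }
  Bmat <- vapply(filters, filter_to_vec, numeric(n_space * n_lags))
  list(filters = filters, B = as.matrix(Bmat), A = A, coords = coords,
       space_dim = space_dim, n_lags = n_lags, m = m)
}

## Q(c) = sum_x (c - x)^2 A[,,x] (squared Euclidean distance in grid units)
localization_Q <- function(basis, c_loc) {
  d2 <- colSums((t(basis$coords) - as.numeric(c_loc))^2)
  m <- basis$m
  Q <- matrix(0, m, m)
  for (s in seq_len(nrow(basis$coords)))
    Q <- Q + d2[s] * basis$A[, , s]
  Q
}

#' Temporal power profile of a filter
#'
#' The variance of the filter weights across time lags at each spatial
#' position (population convention, divisor `T`); the profile the
#' localization cost concentrates.
#'
#' @param filter an [strf()] with at least 2 lags.
#' @return numeric vector (1-D space) or matrix (2-D space) of per-position
#'   temporal power.
#' @export
temporal_power <- function(filter) {
  d <- dim(filter)
  nd <- length(d)
  n_lags <- d[nd]
  if (n_lags < 2) stop("temporal power needs n_lags >= 2")
  n_space <- prod(d[-nd])
  g <- matrix(unclass(filter), nrow = n_space, ncol = n_lags)
  R <- rowSums((g - rowMeans(g))^2) / n_lags
  if (nd == 3) matrix(R, d[1], d[2]) else R
}

#' Localization cost of a coefficient vector
#'
#' `L(c, beta) = sum_x R_beta(x) (c - x)^2` for the filter
#' `k_beta = sum_i beta_i b_i`; `beta` is normalized to unit Euclidean norm
#' internally.
#'
#' @param c_loc target spatial location (bar index, 0-based; length-2 for
#'   2-D stimuli).
#' @param beta coefficients on the basis filters.
#' @param basis list of [strf()] basis filters.
#' @return scalar cost.
#' @export
localization_cost <- function(c_loc, beta, basis) {
  lb <- localization_basis(basis)
  beta <- beta / sqrt(sum(beta^2))
  as.numeric(t(beta) %*% localization_Q(lb, c_loc) %*% beta)
}

## Core optimizer on a prebuilt localization_basis, optionally restricted
## to the orthogonal complement of `project_out` (columns, beta space).
localize_at <- function(lb, c_loc, n_restarts, seed, project_out = NULL) {
  Q <- localization_Q(lb, c_loc)
  m <- lb$m
  if (!is.null(project_out)) {
    P <- qr.Q(qr(cbind(project_out, diag(m))))[, -(seq_len(ncol(project_out))),
                                               drop = FALSE]
    P <- P[, seq_len(m - ncol(project_out)), drop = FALSE]
    if (ncol(P) == 0) stop("localized subspace exhausted at this location")
    Q <- t(P) %*% Q %*% P
  }
  dim_opt <- ncol(Q)
  obj <- function(b) {
    nb2 <- sum(b^2)
    as.numeric(t(b) %*% Q %*% b) / nb2
  }
  grd <- function(b) {
    nb2 <- sum(b^2)
    Qb <- as.numeric(Q %*% b)
    (2 / nb2) * (Qb - (sum(b * Qb) / nb2) * b)
  }
  starts <- with_seed(seed, matrix(rnorm(dim_opt * n_restarts), dim_opt))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    b0 <- starts[, r] / sqrt(sum(starts[, r]^2))
    fit <- tryCatch(
      optim(b0, obj, grd, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best))
    stop("localization optimizer failed to converge from any restart at c = ",
         paste(c_loc, collapse = ","))
  b <- best$par / sqrt(sum(best$par^2))
  beta <- if (is.null(project_out)) b else as.numeric(P %*% b)
  list(beta = beta, cost = best$value)
}

## Assemble the public localized-filter record from a beta solution.
make_localized_filter <- function(lb, beta, c_loc, cost) {
  v <- as.numeric(lb$B %*% beta)
  ## sign convention: largest-magnitude filter entry positive
  if (v[which.max(abs(v))] < 0) { v <- -v; beta <- -beta }
  k <- vec_to_filter(v, lb$space_dim, lb$n_lags, normalize = FALSE)
  structure(list(beta = beta,
                 filter = k,
                 center_target = c_loc,
                 cost = cost,
                 power_profile = temporal_power(k)),
            class = "localized_filter")
}

#' @export
print.localized_filter <- function(x, ...) {
  cat(sprintf("<localized_filter> c=%s, cost=%.4g, |beta|=%d\n",
              paste(signif(x$center_target, 4), collapse = ","),
              x$cost, length(x$beta)))
  invisible(x)
}

#' Most localized filter at one target location
#'
#' Minimizes the localization cost over unit-norm combinations of the
#' basis filters using quasi-Newton descent on the normalized objective,
#' taking the best of `n_restarts` random initializations (seeded, so the
#' result is deterministic).
#'
#' @param basis list of [strf()] basis filters (e.g. significant STC
#'   filters of one subspace, via [stc_subspace()]).
#' @param c_loc target location (0-based grid units).
#' @param n_restarts random initializations, default 20.
#' @param seed integer seed for the restarts.
#' @return object of class `localized_filter`: `beta` (unit norm),
#'   `filter` ([strf()], in the basis span), `center_target`, `cost`,
#'   `power_profile`.
#' @export
find_localized_filter <- function(basis, c_loc, n_restarts = 20, seed = 1) {
  lb <- localization_basis(basis)
  sol <- localize_at(lb, c_loc, n_restarts, seed)
  make_localized_filter(lb, sol$beta, c_loc, sol$cost)
}

#' Next most localized filter at a location
#'
#' Repeats the localized search in the orthogonal complement (in
#' coefficient space) of one or more already extracted filters, yielding a
#' filter orthogonal to them — at quadrature locations this recovers the
#' second member of a pair.
#'
#' @inheritParams find_localized_filter
#' @param existing a `localized_filter` or list of them already found at
#'   this location.
#' @return a `localized_filter` orthogonal to `existing`.
#' @export
next_localized_at <- function(basis, c_loc, existing, n_restarts = 20,
                              seed = 1) {
  lb <- localization_basis(basis)
  if (inherits(existing, "localized_filter")) existing <- list(existing)
  P <- vapply(existing, function(e) e$beta, numeric(lb$m))
  sol <- localize_at(lb, c_loc, n_restarts, seed, project_out = as.matrix(P))
  make_localized_filter(lb, sol$beta, c_loc, sol$cost)
}

#' Localized filters over a grid of target locations
#'
#' Runs [find_localized_filter()] at `n_centers` locations evenly covering
#' the stimulus domain (endpoints included). For 2-D stimuli the centers
#' form an approximately square grid with about `n_centers` points.
#'
#' @inheritParams find_localized_filter
#' @param n_centers number of target locations, default 40.
#' @param subspace_tag label stored with the set (`"excitatory"`,
#'   `"suppressive"` or `"combined"`).
#' @return object of class `localized_set`: `filters` (list), `centers`,
#'   `costs`, `subspace_tag`.
#' @export
find_localized_set <- function(basis, n_centers = 40, n_restarts = 20,
                               seed = 1, subspace_tag = "excitatory") {
  lb <- localization_basis(basis)
  if (length(lb$space_dim) == 1) {
    centers <- matrix(seq(0, lb$space_dim - 1, length.out = n_centers),
                      ncol = 1)
  } else {
    n1 <- max(2L, round(sqrt(n_centers)))
    centers <- as.matrix(expand.grid(
      seq(0, lb$space_dim[1] - 1, length.out = n1),
      seq(0, lb$space_dim[2] - 1, length.out = n1)))
  }
  filters <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    sol <- localize_at(lb, centers[i, ], n_restarts, seed + i - 1L)
    filters[[i]] <- make_localized_filter(lb, sol$beta, centers[i, ],
                                          sol$cost)
  }
  structure(list(filters = filters,
                 centers = centers,
                 costs = vapply(filters, `[[`, numeric(1), "cost"),
                 subspace_tag = subspace_tag),
            class = "localized_set")
}

#' @export
print.localized_set <- function(x, ...) {
  cat(sprintf("<localized_set> %s: %d filters over %d centers\n",
              x$subspace_tag, length(x$filters), nrow(x$centers)))
  invisible(x)
}

#' Basis filters of a significant STC subspace
#'
#' @param stc an `stc_result` after [select_significant()].
#' @param which `"excitatory"`, `"suppressive"` or `"both"`.
#' @return list of unit-norm [strf()] filters.
#' @export
stc_subspace <- function(stc, which = c("excitatory", "suppressive", "both")) {
  which <- match.arg(which)
  idx <- switch(which,
                excitatory = stc$excitatory,
                suppressive = stc$suppressive,
                both = c(stc$excitatory, stc$suppressive))
  if (length(idx) == 0)
    stop("no ", which, " filters selected; run select_significant() first")
  lapply(idx, function(i) stc_filter(stc, i))
}

## power centroid of a 1-D filter, 0-based bar units
power_centroid <- function(filter) {
  R <- temporal_power(filter)
  sum((seq_along(R) - 1) * R) / sum(R)
}

#' Align localized filters and summarize them by PCA
#'
#' Each filter is shifted spatially (nearest-integer shift, zero filling)
#' so its temporal-power centroid sits at the grid center, the aligned
#' filters are stacked, and an uncentered PCA (SVD) summarizes the family;
#' for an energy-model-like neuron two components — a quadrature pair —
#' capture essentially all variance.
#'
#' @param set a `localized_set` with at least 3 filters (1-D space).
#' @return list with `pca_basis` (list of unit-norm [strf()] components),
#'   `pca_explained` (fraction of variance per component), and `aligned`
#'   (matrix of aligned vectorized filters, one row each).
#' @export
align_and_pca <- function(set) {
  stopifnot(inherits(set, "localized_set"))
  if (length(set$filters) < 3)
    stop("aligned PCA needs at least 3 localized filters")
  k1 <- set$filters[[1]]$filter
  if (length(dim(k1)) != 2)
    stop("aligned PCA is defined for 1-D (space x lag) filter sets")
  n_x <- nrow(k1); n_lags <- ncol(k1)
  mid <- (n_x - 1) / 2
  aligned <- t(vapply(set$filters, function(f) {
    shift <- round(mid - power_centroid(f$filter))
    filter_to_vec(shift_filter(f$filter, shift))
  }, numeric(n_x * n_lags)))
  sv <- svd(aligned)
  expl <- sv$d^2 / sum(sv$d^2)
  ncomp <- min(4, length(sv$d))
  pca_basis <- lapply(seq_len(ncomp), function(i)
    vec_to_filter(fix_sign(sv$v[, i]), n_x, n_lags, normalize = TRUE))
  list(pca_basis = pca_basis, pca_explained = expl, aligned = aligned)
}
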