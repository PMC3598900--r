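## Generalized nonlinear cascade model (GNM).
##
## The firing rate is modeled as
##   r(t) = F[ sum_i sum_tau h_{i,tau} f_i(k_i . s_{t-tau}) - theta ],
## with F(u) = log(1 + exp(u)) the softplus spiking nonlinearity, k_i fixed
## filters (from STC / localization), f_i fitted scalar nonlinearities on a
## piecewise-linear tent basis with knots at empirical quantiles of the
## filter outputs, and h_i short nonnegative-lag temporal integration
## kernels. Parameters are estimated by maximizing the Poisson
## log-likelihood sum_t [ n_t log r_t - r_t ] (bin width = 1 frame) minus
## squared second-difference smoothness penalties on each f_i and h_i.
## Filters are never refit inside the GNM.

## ---- tent basis ------------------------------------------------------------

## Piecewise-linear hat functions on `knots`, flat beyond the end knots.
tent_basis <- function(x, knots) {
  K <- length(knots)
  Phi <- matrix(0, length(x), K)
  j <- findInterval(x, knots)
  lo <- j == 0L
  hi <- j >= K
  mid <- !(lo | hi)
  Phi[lo, 1] <- 1
  Phi[hi, K] <- 1
  if (any(mid)) {
    jm <- j[mid]
    w <- (x[mid] - knots[jm]) / (knots[jm + 1L] - knots[jm])
    Phi[cbind(which(mid), jm)] <- 1 - w
    Phi[cbind(which(mid), jm + 1L)] <- w
  }
  Phi
}

eval_nonlin <- function(nl, x) {
  if (is.function(nl)) return(nl(x))
  as.numeric(tent_basis(x, nl$knots) %*% nl$coef)
}

second_diff_mat <- function(K) {
  if (K < 3) return(matrix(0, 0, K))
  D <- matrix(0, K - 2, K)
  for (i in seq_len(K - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  D
}

## ---- model object ----------------------------------------------------------

#' Construct a GNM cascade model
#'
#' @param filters list of [strf()] filters `k_i` (held fixed).
#' @param nonlin list, one element per filter: either a plain R function,
#'   or `list(knots, coef)` describing a piecewise-linear tent-basis
#'   nonlinearity.
#' @param h list of temporal integration kernels (numeric, lag 0 first);
#'   default instantaneous (`h = 1`) for every filter.
#' @param theta scalar offset subtracted before the spiking nonlinearity.
#' @param out_gain optional output gain `a` in `r = a log(1 + exp(.))`.
#' @return object of class `gnm_model`.
#' @export
gnm_model <- function(filters, nonlin, h = NULL, theta = 0, out_gain = 1) {
  stopifnot(is.list(filters), length(filters) >= 1,
            all(vapply(filters, inherits, TRUE, "strf")),
            length(nonlin) == length(filters))
  if (is.null(h)) h <- rep(list(1), length(filters))
  stopifnot(length(h) == length(filters),
            all(vapply(h, function(x) all(is.finite(x)), TRUE)))
  structure(list(filters = filters, nonlin = nonlin, h = h,
                 theta = theta, out_gain = out_gain),
            class = "gnm_model")
}

#' @export
print.gnm_model <- function(x, ...) {
  cat(sprintf("<gnm_model> %d filter(s), theta=%.4g, h lengths: %s\n",
              length(x$filters), x$theta,
              paste(lengths(x$h), collapse = ",")))
  invisible(x)
}

## Apply kernel h (lag 0 first) causally to a signal, zero history.
apply_temporal_kernel <- function(u, h) {
  if (length(h) == 1) return(h * u)
  out <- h[1] * u
  n <- length(u)
  for (tau in seq_along(h)[-1]) {
    out[tau:n] <- out[tau:n] + h[tau] * u[1:(n - tau + 1)]
  }
  out
}

#' Predict the firing rate of a GNM
#'
#' @param model a [gnm_model()].
#' @param design a design matrix matching the filter dimensions.
#' @return nonnegative rate per frame (spikes/frame); padded rows get 0.
#' @export
gnm_predict <- function(model, design) {
  K <- vapply(model$filters, filter_to_vec,
              numeric(length(model$filters[[1]])))
  if (nrow(as.matrix(K)) != ncol(design))
    stop("filter dimension does not match design columns")
  G <- design %*% as.matrix(K)
  eta <- rep(-model$theta, nrow(design))
  for (i in seq_along(model$filters)) {
    u <- eval_nonlin(model$nonlin[[i]], G[, i])
    eta <- eta + apply_temporal_kernel(u, model$h[[i]])
  }
  r <- model$out_gain * softplus(eta)
  r[attr(design, "padded")] <- 0
  r
}

## ---- fitting ---------------------------------------------------------------

## Poisson negative log-likelihood (+ gradient wrt eta) under softplus rate.
## Returns list(nll, deta) for counts n and linear predictor eta.
softplus_pois_nll <- function(eta, n) {
  r <- pmax(softplus(eta), 1e-12)
  nll <- -sum(n * log_softplus(eta) - r)
  deta <- -(n / r - 1) * plogis(eta)
  list(nll = nll, deta = deta)
}

#' Hyperparameter specification for GNM fitting
#'
#' Bundles everything [fit_nonlinearities()] and [xval_ll_improvement()]
#' need besides the data: the fixed filters and the fitting
#' hyperparameters.
#'
#' @inheritParams fit_nonlinearities
#' @return list of class `gnm_spec`.
#' @export
gnm_spec <- function(filters, knots = 20, lambda_smooth_f = 1,
                     lambda_smooth_h = 1, h_len = 1) {
  stopifnot(length(filters) >= 1, knots >= 4, h_len >= 1)
  structure(list(filters = filters, knots = knots,
                 lambda_smooth_f = lambda_smooth_f,
                 lambda_smooth_h = lambda_smooth_h, h_len = h_len),
            class = "gnm_spec")
}

## Core fit on explicit rows. G: N x I filter outputs, n: counts.
## Returns model pieces in fitting parameterization plus diagnostics.
fit_gnm_core <- function(G, n, knot_list, lambda_f, lambda_h, h_len,
                         max_outer = 10, tol = 1e-6) {
  N <- nrow(G); I <- ncol(G); K <- length(knot_list[[1]])
  Phi <- lapply(seq_len(I), function(i) tent_basis(G[, i], knot_list[[i]]))
  D2 <- second_diff_mat(K)
  DtD <- crossprod(D2)
  h <- rep(list(c(1, rep(0, h_len - 1))), I)
  rbar <- max(mean(n), 1e-3)
  theta0 <- -log(expm1(rbar))
  alpha <- rep(list(rep(0, K)), I)
  theta <- theta0

  ## stage A: fit alphas + theta given h
  fitA <- function(alpha, theta, h) {
    Psi <- lapply(seq_len(I), function(i) {
      if (length(h[[i]]) == 1 && h[[i]][1] == 1) return(Phi[[i]])
      apply(Phi[[i]], 2, apply_temporal_kernel, h = h[[i]])
    })
    Xf <- do.call(cbind, Psi)
    p0 <- c(unlist(alpha), theta)
    idx <- split(seq_len(I * K), rep(seq_len(I), each = K))
    fn <- function(p) {
      eta <- as.numeric(Xf %*% p[seq_len(I * K)]) - p[I * K + 1]
      out <- softplus_pois_nll(eta, n)$nll
      for (i in seq_len(I))
        out <- out + lambda_f * sum((D2 %*% p[idx[[i]]])^2)
      out / N
    }
    gr <- function(p) {
      eta <- as.numeric(Xf %*% p[seq_len(I * K)]) - p[I * K + 1]
      deta <- softplus_pois_nll(eta, n)$deta
      g <- c(as.numeric(crossprod(Xf, deta)), -sum(deta))
      for (i in seq_len(I))
        g[idx[[i]]] <- g[idx[[i]]] + 2 * lambda_f *
          as.numeric(DtD %*% p[idx[[i]]])
      g / N
    }
    fit <- optim(p0, fn, gr, method = "BFGS",
                 control = list(maxit = 400, reltol = 1e-10))
    list(alpha = lapply(idx, function(ix) fit$par[ix]),
         theta = fit$par[I * K + 1], value = fit$value,
         counts = fit$counts[1], grad_norm = sqrt(sum(gr(fit$par)^2)))
  }

  ## stage B: fit temporal kernels given alphas (skipped when h_len == 1)
  fitB <- function(alpha, theta, h) {
    U <- vapply(seq_len(I), function(i)
      as.numeric(Phi[[i]] %*% alpha[[i]]), numeric(N))
    V <- do.call(cbind, lapply(seq_len(I), function(i)
      vapply(0:(h_len - 1), function(tau)
        apply_temporal_kernel(U[, i], c(rep(0, tau), 1)), numeric(N))))
    D2h <- second_diff_mat(h_len)
    DtDh <- crossprod(D2h)
    p0 <- c(unlist(h), theta)
    idx <- split(seq_len(I * h_len), rep(seq_len(I), each = h_len))
    fn <- function(p) {
      eta <- as.numeric(V %*% p[seq_len(I * h_len)]) - p[I * h_len + 1]
      out <- softplus_pois_nll(eta, n)$nll
      for (i in seq_len(I))
        out <- out + lambda_h * sum((D2h %*% p[idx[[i]]])^2)
      out / N
    }
    gr <- function(p) {
      eta <- as.numeric(V %*% p[seq_len(I * h_len)]) - p[I * h_len + 1]
      deta <- softplus_pois_nll(eta, n)$deta
      g <- c(as.numeric(crossprod(V, deta)), -sum(deta))
      for (i in seq_len(I))
        g[idx[[i]]] <- g[idx[[i]]] + 2 * lambda_h *
          as.numeric(DtDh %*% p[idx[[i]]])
      g / N
    }
    fit <- optim(p0, fn, gr, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-10))
    list(h = lapply(idx, function(ix) fit$par[ix]),
         theta = fit$par[I * h_len + 1], value = fit$value)
  }

  objs <- numeric(0)
  iters <- 0L
  grad_norm <- NA_real_
  repeat {
    a <- fitA(alpha, theta, h)
    alpha <- a$alpha; theta <- a$theta
    iters <- iters + a$counts
    grad_norm <- a$grad_norm
    objs <- c(objs, a$value)
    if (h_len == 1) break
    b <- fitB(alpha, theta, h)
    h <- b$h; theta <- b$theta
    objs <- c(objs, b$value)
    no <- length(objs)
    if (length(objs) >= 4 &&
        abs(objs[no - 2] - objs[no]) <
          tol * (abs(objs[no]) + 1e-12)) break
    if (length(objs) >= 2 * max_outer) break
  }
  ## identifiability: ||h_i|| = 1 with scale folded into alpha_i
  for (i in seq_len(I)) {
    nh <- sqrt(sum(h[[i]]^2))
    if (nh > 0) { alpha[[i]] <- alpha[[i]] * nh; h[[i]] <- h[[i]] / nh }
  }
  list(alpha = alpha, theta = theta, h = h, objective_trace = objs,
       iterations = iters, grad_norm = grad_norm)
}

#' Fit GNM nonlinearities by penalized Poisson maximum likelihood
#'
#' Holds the filters fixed and estimates the per-filter nonlinearities
#' `f_i` (tent basis, knots at empirical quantiles of each filter output),
#' the temporal kernels `h_i` (when `h_len > 1`, by block-alternating
#' ascent with the `f` stage) and the offset `theta`, maximizing
#' `sum_t [n_t log r_t - r_t]` minus squared second-difference penalties
#' `lambda_smooth_f ||D2 f_i||^2` and `lambda_smooth_h ||D2 h_i||^2`.
#' Identifiability is fixed by `f_i(median) = 0` (absorbed into `theta`)
#' and `||h_i|| = 1` (scale absorbed into `f_i`).
#'
#' @param filters list of fixed [strf()] filters.
#' @param design,spikes training data (padded rows excluded internally).
#' @param knots number of tent-basis knots per nonlinearity, default 20.
#' @param lambda_smooth_f,lambda_smooth_h smoothness penalty weights.
#' @param folds if >= 2, additionally compute the cross-validated
#'   log-likelihood improvement via [xval_ll_improvement()].
#' @param h_len temporal kernel length in frames, default 1
#'   (instantaneous).
#' @return list with `model` (a [gnm_model()]) and `report` (class
#'   `gnm_fit_report`: `train_ll` improvement in nats/spike over a
#'   mean-rate model, `xval_ll` mean and per-fold values or `NA`,
#'   `penalty_weights`, `convergence`).
#' @export
fit_nonlinearities <- function(filters, design, spikes, knots = 20,
                               lambda_smooth_f = 1, lambda_smooth_h = 1,
                               folds = 0, h_len = 1) {
  sp <- gnm_spec(filters, knots, lambda_smooth_f, lambda_smooth_h, h_len)
  keep <- unpadded(design)
  n <- as.numeric(spikes)[keep]
  if (sum(n) < 100)
    stop("need at least 100 spikes to fit the GNM (have ", sum(n), ")")
  Kmat <- as.matrix(vapply(filters, filter_to_vec,
                           numeric(length(filters[[1]]))))
  G <- design[keep, , drop = FALSE] %*% Kmat
  knot_list <- lapply(seq_len(ncol(G)), function(i) {
    g <- G[, i]
    if (sd(g) < 1e-12) stop("filter ", i, " has degenerate (constant) output")
    unique(quantile(g, probs = seq(0.005, 0.995, length.out = knots),
                    names = FALSE))
  })
  fit <- fit_gnm_core(G, n, knot_list, lambda_smooth_f, lambda_smooth_h,
                      h_len)
  ## f_i(median) = 0, compensated through theta
  theta <- fit$theta
  nonlin <- vector("list", ncol(G))
  for (i in seq_len(ncol(G))) {
    med <- median(G[, i])
    m_i <- as.numeric(tent_basis(med, knot_list[[i]]) %*% fit$alpha[[i]])
    nonlin[[i]] <- list(knots = knot_list[[i]], coef = fit$alpha[[i]] - m_i)
    theta <- theta - m_i * sum(fit$h[[i]])
  }
  model <- gnm_model(filters, nonlin, h = fit$h, theta = theta)
  ## training LL improvement (nats/spike) over the mean-rate model
  eta_fit <- local({
    r <- gnm_predict(model, design)[keep]
    sum(n * log(pmax(r, 1e-12)) - r)
  })
  rbar <- mean(n)
  ll_null <- sum(n * log(max(rbar, 1e-12)) - rbar)
  report <- structure(list(
    train_ll = (eta_fit - ll_null) / sum(n),
    xval_ll = NA_real_, xval_ll_folds = NULL, folds = folds,
    penalty_weights = c(f = lambda_smooth_f, h = lambda_smooth_h),
    convergence = list(iterations = fit$iterations,
                       grad_norm = fit$grad_norm,
                       objective_trace = fit$objective_trace)
  ), class = "gnm_fit_report")
  if (folds >= 2) {
    xv <- xval_ll_improvement(sp, design, spikes, folds = folds)
    report$xval_ll_folds <- xv
    report$xval_ll <- mean(xv)
  }
  list(model = model, report = report)
}

#' @export
print.gnm_fit_report <- function(x, ...) {
  cat(sprintf("<gnm_fit_report> train LL +%.4f nats/spike; xval %s\n",
              x$train_ll,
              if (is.na(x$xval_ll)) "not run"
              else sprintf("+%.4f nats/spike (%d folds)", x$xval_ll,
                           length(x$xval_ll_folds))))
  invisible(x)
}

## Subset design rows, keeping class and attributes consistent.
design_subset <- function(design, idx) {
  structure(unclass(design)[idx, , drop = FALSE],
            class = c("design_matrix", "matrix", "array"),
            n_lags = attr(design, "n_lags"),
            space_dim = attr(design, "space_dim"),
            padded = attr(design, "padded")[idx],
            frame_rate_hz = attr(design, "frame_rate_hz"))
}

#' Cross-validated log-likelihood improvement of a GNM
#'
#' Splits the recording into `folds` contiguous time blocks; for each
#' fold, fits the GNM on the remaining data and evaluates the held-out
#' Poisson log-likelihood minus that of a constant-rate model whose rate
#' is the training mean, divided by the held-out spike count.
#'
#' @param spec a [gnm_spec()] (filters plus hyperparameters).
#' @param design,spikes full data.
#' @param folds number of contiguous folds, default 10.
#' @return numeric vector of per-fold improvements (nats/spike); folds
#'   without spikes are skipped with a warning.
#' @export
xval_ll_improvement <- function(spec, design, spikes, folds = 10) {
  stopifnot(inherits(spec, "gnm_spec"), folds >= 2)
  rows <- which(unpadded(design))
  fold_id <- cut(seq_along(rows), folds, labels = FALSE)
  out <- numeric(0)
  for (fd in seq_len(folds)) {
    test <- rows[fold_id == fd]
    train <- rows[fold_id != fd]
    n_test <- as.numeric(spikes)[test]
    if (sum(n_test) == 0) {
      warning("fold ", fd, " has no spikes; skipped")
      next
    }
    fit <- fit_nonlinearities(spec$filters, design_subset(design, train),
                              as.numeric(spikes)[train],
                              knots = spec$knots,
                              lambda_smooth_f = spec$lambda_smooth_f,
                              lambda_smooth_h = spec$lambda_smooth_h,
                              h_len = spec$h_len)
    r_test <- gnm_predict(fit$model, design_subset(design, test))
    ll_model <- sum(n_test * log(pmax(r_test, 1e-12)) - r_test)
    rbar <- max(mean(as.numeric(spikes)[train]), 1e-12)
    ll_null <- sum(n_test * log(rbar) - rbar)
    out <- c(out, (ll_model - ll_null) / sum(n_test))
  }
  out
}

#' Sparse selection of relevant localized filters
#'
#' Filters the stimulus with every candidate localized filter and its
#' negative, half-wave rectifies the outputs, and runs L1-penalized
#' logistic regression of the binarized spike train on these features;
#' the sparseness parameter is chosen by cross-validated deviance
#' (contiguous folds) and filters with any nonzero coefficient at the
#' chosen penalty are retained.
#'
#' @param localized a `localized_set` or list of [strf()] candidates.
#' @param design,spikes data.
#' @param lambda_grid optional penalty grid passed to glmnet.
#' @param folds cross-validation folds, default 5.
#' @return list with `selected` (indices into the candidates), `filters`
#'   (the selected [strf()]s), `lambda` (chosen penalty) and `coef`
#'   (nonzero coefficient matrix rows).
#' @export
select_filters_sparse <- function(localized, design, spikes,
                                  lambda_grid = NULL, folds = 5) {
  cand <- if (inherits(localized, "localized_set")) {
    lapply(localized$filters, `[[`, "filter")
  } else localized
  stopifnot(length(cand) >= 1)
  keep <- unpadded(design)
  Kmat <- as.matrix(vapply(cand, function(k)
    filter_to_vec(k) / sqrt(sum(k^2)), numeric(length(cand[[1]]))))
  G <- design[keep, , drop = FALSE] %*% Kmat
  Xf <- cbind(relu(G), relu(-G))
  y <- as.integer(as.numeric(spikes)[keep] > 0)
  fold_id <- cut(seq_len(nrow(Xf)), folds, labels = FALSE)
  cvfit <- glmnet::cv.glmnet(Xf, y, family = "binomial", alpha = 1,
                             foldid = fold_id, lambda = lambda_grid,
                             standardize = TRUE)
  cf <- as.matrix(coef(cvfit, s = "lambda.min"))[-1, , drop = FALSE]
  m <- length(cand)
  nz <- which(abs(cf[, 1]) > 0)
  sel <- sort(unique(((nz - 1L) %% m) + 1L))
  if (length(sel) == 0)
    warning("sparse selection returned an empty filter set at every lambda")
  list(selected = sel, filters = cand[sel],
       lambda = cvfit$lambda.min, coef = cf)
}
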