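test_that("gnm_predict reduces to known cascades exactly", {
  des <- sim_white_design(4000)
  k <- quad_pair()[[1]]

  ## identity nonlinearity, instantaneous kernel: a softplus LN model
  m <- gnm_model(list(k), nonlin = list(identity), theta = 0)
  keep <- !attr(des, "padded")
  expect_equal(gnm_predict(m, des)[keep],
               softplus_direct <- log1p(exp(des[keep, ] %*%
                                              filter_to_vec(k)))[, 1],
               tolerance = 1e-12)

  ## all-zero nonlinearities: constant softplus(-theta)
  m0 <- gnm_model(list(k), nonlin = list(function(u) 0 * u), theta = 1.3)
  expect_equal(unique(round(gnm_predict(m0, des)[keep], 12)),
               round(log1p(exp(-1.3)), 12))

  ## generator/predictor equivalence for the energy model
  ks <- quad_pair()
  gen <- neuron_spec("energy_complex", ks, gain = 1.7, offset = -2.2)
  m2 <- gnm_model(ks, nonlin = list(function(u) 1.7 * u^2,
                                    function(u) 1.7 * u^2),
                  theta = 2.2)
  expect_equal(gnm_predict(m2, des), neuron_rate(gen, des),
               tolerance = 1e-10)

  ## rates strictly positive and finite on unpadded rows
  r <- gnm_predict(m2, des)[keep]
  expect_true(all(r > 0 & is.finite(r)))

  ## temporal kernel: h = delayed delta shifts the response by one frame
  mdel <- gnm_model(list(k), nonlin = list(identity), h = list(c(0, 1)),
                    theta = 0)
  r0 <- gnm_predict(m, des); r1 <- gnm_predict(mdel, des)
  expect_equal(r1[keep][-1], r0[keep][-length(r0[keep])], tolerance = 1e-12)
})

test_that("fitted nonlinearities recover linear, quadratic and rectifying shapes", {
  ## LN cell: fitted f is affine over the central input range
  sim <- sim_ln()
  fit <- fit_nonlinearities(list(sim$filter), sim$design, sim$spikes,
                            knots = 15)
  keep <- !attr(sim$design, "padded")
  g <- (sim$design[keep, ] %*% filter_to_vec(sim$filter))[, 1]
  uu <- seq(quantile(g, 0.05), quantile(g, 0.95), length.out = 60)
  fv <- eval_nonlin(fit$model$nonlin[[1]], uu)
  aff <- lm(fv ~ uu)
  expect_lt(sqrt(mean(resid(aff)^2)) / diff(range(fv)), 0.10)
  expect_gt(coef(aff)[2], 0)
  ## training improvement over the mean-rate model is large
  expect_gt(fit$report$train_ll, 0.3)

  ## energy cell with true quadrature filters: convex, symmetric f_i
  sime <- sim_energy()
  fite <- fit_nonlinearities(sime$filters, sime$design, sime$spikes,
                             knots = 15)
  ge <- (sime$design[keep, ] %*% filter_to_vec(sime$filters[[1]]))[, 1]
  q90 <- quantile(abs(ge), 0.9)
  u2 <- seq(0.05 * q90, q90, length.out = 40)
  for (i in 1:2) {
    fpos <- eval_nonlin(fite$model$nonlin[[i]], u2)
    fneg <- eval_nonlin(fite$model$nonlin[[i]], -u2)
    expect_lt(max(abs(fpos - fneg)) / max(abs(c(fpos, fneg))), 0.15)
    f0 <- eval_nonlin(fite$model$nonlin[[i]], 0)
    expect_lte(f0, min(fpos, fneg) + 0.05 * max(abs(c(fpos, fneg))))
  }

  ## separable_simple cell: rectifying f_i (near zero on the negative axis)
  dec <- svd_separable(quad_pair()[[1]], 2)
  s1 <- separable_component(dec, 1); s2 <- separable_component(dec, 2)
  gen <- neuron_spec("separable_simple", list(s1, s2), gain = 3,
                     offset = -2)
  des <- sim_white_design(30000)
  sp <- poisson_spikes(neuron_rate(gen, des), 13)
  fits <- fit_nonlinearities(list(s1, s2), des, sp, knots = 15)
  for (i in 1:2) {
    gg <- (des[keep, ] %*% filter_to_vec(list(s1, s2)[[i]]))[, 1]
    qq <- quantile(abs(gg), 0.9)
    un <- seq(-qq, -0.05 * qq, length.out = 40)
    up <- -un
    fneg <- eval_nonlin(fits$model$nonlin[[i]], un)
    fall <- eval_nonlin(fits$model$nonlin[[i]], c(un, up))
    expect_lt(mean(abs(fneg)) / max(abs(fall)), 0.15)
    ## monotone non-decreasing over the sampled range
    fgrid <- eval_nonlin(fits$model$nonlin[[i]],
                         seq(-qq, qq, length.out = 80))
    expect_true(all(diff(fgrid) > -0.02 * max(abs(fgrid))))
  }

  ## heavy smoothing drives f_i to an affine function
  fitl <- fit_nonlinearities(list(sim$filter), sim$design, sim$spikes,
                             knots = 15, lambda_smooth_f = 1e7)
  cf <- fitl$model$nonlin[[1]]$coef
  d2 <- subunitscope:::second_diff_mat(length(cf)) %*% cf
  expect_lt(sqrt(sum(d2^2)), 1e-3 * diff(range(cf)))

  expect_error(fit_nonlinearities(list(sim$filter), sim$design,
                                  rep(0L, nrow(sim$design))), "spikes")
})

test_that("penalized objective decreases and the GLM identity holds", {
  sim <- sim_ln()
  fit <- fit_nonlinearities(list(sim$filter), sim$design, sim$spikes,
                            knots = 12)
  tr <- fit$report$convergence$objective_trace
  expect_lte(tr[length(tr)], tr[1])

  ## one filter, f fixed to identity, h = delta: the model is a softplus
  ## GLM in the single covariate g; compare with a direct optim fit of
  ## rate = softplus(a g + b)
  keep <- !attr(sim$design, "padded")
  g <- (sim$design[keep, ] %*% filter_to_vec(sim$filter))[, 1]
  n <- as.numeric(sim$spikes)[keep]
  nll <- function(p) {
    eta <- p[1] * g + p[2]
    r <- pmax(log1p(exp(eta)), 1e-12)
    -sum(n * log(r) - r)
  }
  glm_fit <- optim(c(1, 0), nll, method = "BFGS")
  ## GNM with a rich unpenalized f should achieve at least this likelihood
  fit2 <- fit_nonlinearities(list(sim$filter), sim$design, sim$spikes,
                             knots = 15, lambda_smooth_f = 0)
  r2 <- gnm_predict(fit2$model, sim$design)[keep]
  ll2 <- sum(n * log(pmax(r2, 1e-12)) - r2)
  ## small slack: the tent-basis f clamps beyond its outer knots, so the
  ## affine GLM is not strictly nested and gains slightly on tail samples
  expect_gte(ll2, -glm_fit$value - 5e-4 * abs(glm_fit$value))
})

test_that("cross-validated improvements separate informative models", {
  ## stimulus-independent spikes: improvement indistinguishable from zero
  des <- sim_white_design(20000)
  sp0 <- poisson_spikes(rep(0.4, nrow(des)), 55)
  xv0 <- xval_ll_improvement(gnm_spec(quad_pair()[1], knots = 8), des, sp0,
                             folds = 8)
  ci0 <- paired_ci(xv0)
  expect_true(ci0[1] <= 0 && ci0[2] >= 0)

  ## pooled-complex: full localized model beats the STA-only model in
  ## every fold
  sim <- sim_pooled()
  stc <- select_significant(compute_stc(sim$design, sim$spikes), "fixed",
                            n_pos = 6)
  basis <- stc_subspace(stc, "excitatory")
  locs <- find_localized_set(basis, n_centers = 6, n_restarts = 10,
                             seed = 21)
  inside <- which(locs$centers[, 1] >= 4 & locs$centers[, 1] <= 11)
  loc_filters <- lapply(locs$filters[inside], function(f)
    strf(unclass(f$filter)))
  sta <- compute_sta(sim$design, sim$spikes)
  xv_loc <- xval_ll_improvement(gnm_spec(loc_filters, knots = 10),
                                sim$design, sim$spikes, folds = 5)
  xv_sta <- xval_ll_improvement(gnm_spec(list(sta), knots = 10),
                                sim$design, sim$spikes, folds = 5)
  expect_true(all(xv_loc > xv_sta))
})

test_that("sparse selection keeps true filters and drops noise", {
  sim <- sim_ln()
  set.seed(3)
  noise <- lapply(1:20, function(i) strf(matrix(rnorm(192), 16, 12)))
  cands <- c(list(sim$filter), noise)
  sel <- select_filters_sparse(cands, sim$design, sim$spikes, folds = 4)
  expect_true(1 %in% sel$selected)
  corr_best <- max(vapply(sel$filters, function(f)
    abs(cor(filter_to_vec(f), filter_to_vec(sim$filter))), numeric(1)))
  expect_gte(corr_best, 0.8)
  expect_lte(length(sel$selected), 10)

  ## a huge penalty empties the selection
  expect_warning(
    sel_empty <- select_filters_sparse(cands, sim$design, sim$spikes,
                                       lambda_grid = c(20, 10, 5),
                                       folds = 4),
    "empty")
  expect_length(sel_empty$selected, 0)

  ## duplicating candidates does not change the selected span
  dup <- c(cands, list(sim$filter))
  sel_dup <- select_filters_sparse(dup, sim$design, sim$spikes, folds = 4)
  span <- function(s) {
    V <- vapply(s$filters, filter_to_vec, numeric(192))
    qr(V)$rank
  }
  expect_equal(span(sel_dup), span(sel))
})
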