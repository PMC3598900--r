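test_that("temporal power and localization cost follow their definitions", {
  ## constant across lags: zero temporal power
  flat <- strf(matrix(rep(1:8, 5), 8, 5), normalize = FALSE)
  expect_equal(temporal_power(flat), rep(0, 8))

  ## power confined to one position
  one <- matrix(0, 8, 5); one[3, ] <- c(1, -1, 2, 0, 1)
  R <- temporal_power(strf(one, normalize = FALSE))
  expect_true(all(R[-3] == 0))
  expect_equal(R[3], mean((one[3, ] - mean(one[3, ]))^2))

  ## brute-force bound: total power of a unit filter is at most 1/T ||k||^2
  set.seed(1)
  for (i in 1:20) {
    k <- strf(matrix(rnorm(40), 8, 5))
    expect_lte(sum(temporal_power(k)), sum(k^2) / 5 + 1e-12)
  }

  ## cost arithmetic: power split between c-d and c+d
  two <- matrix(0, 9, 4); two[3, ] <- c(1, -1, 1, -1); two[7, ] <- c(1, -1, 1, -1)
  kk <- strf(two, normalize = FALSE)
  Rtot <- sum(temporal_power(kk))
  cost <- localization_cost(4, 1, list(kk))
  expect_equal(cost, Rtot * 4, tolerance = 1e-12)  # both bumps at distance 2

  ## cost is even in beta
  b <- list(strf(matrix(rnorm(32), 8, 4)), strf(matrix(rnorm(32), 8, 4)))
  expect_equal(localization_cost(3, c(0.6, -0.8), b),
               localization_cost(3, -c(0.6, -0.8), b), tolerance = 1e-12)
})

test_that("localized search matches the closed-form eigenvector solution", {
  ## independent oracle: L(c, beta) = beta' Q beta with |beta| = 1 is
  ## minimized by the smallest eigenvector of Q
  sim <- sim_energy()
  stc <- select_significant(compute_stc(sim$design, sim$spikes), "fixed",
                            n_pos = 4)
  basis <- stc_subspace(stc, "excitatory")
  lb <- subunitscope:::localization_basis(basis)
  for (c_loc in c(2, 7.5, 13)) {
    Q <- subunitscope:::localization_Q(lb, c_loc)
    ev <- eigen(Q, symmetric = TRUE)
    opt <- find_localized_filter(basis, c_loc, n_restarts = 10, seed = 2)
    expect_equal(opt$cost, min(ev$values), tolerance = 1e-8)
    expect_equal(abs(sum(opt$beta * ev$vectors[, length(basis)])), 1,
                 tolerance = 1e-6)
    expect_equal(sum(opt$beta^2), 1, tolerance = 1e-10)
    ## the optimum beats every raw basis filter at this location
    raw_costs <- vapply(seq_along(basis), function(i)
      localization_cost(c_loc, replace(rep(0, 4), i, 1), basis), numeric(1))
    expect_lte(opt$cost, min(raw_costs) + 1e-10)
  }
})

test_that("disjoint bump bases localize onto the requested bump", {
  bump <- function(x0) {
    m <- matrix(0, 16, 6)
    m[x0 + 1, ] <- c(1, -2, 1, 0.5, -0.5, 0)
    strf(m)
  }
  basis <- list(bump(3), bump(12))
  ## brute-force oracle over the unit circle in beta space
  angles <- seq(0, pi, length.out = 20001)
  costs <- vapply(angles, function(a)
    localization_cost(3, c(cos(a), sin(a)), basis), numeric(1))
  expect_equal(find_localized_filter(basis, 3, seed = 1)$cost, min(costs),
               tolerance = 1e-6)
  sol <- find_localized_filter(basis, 3, seed = 1)
  expect_gte(abs(sol$beta[1]), 0.99)

  ## single-filter basis: only feasible points are +-1
  sol1 <- find_localized_filter(basis[1], 3, seed = 1)
  expect_equal(abs(sol1$beta), 1, tolerance = 1e-10)
})

test_that("cost is invariant to orthonormal rotation and basis enlargement", {
  sim <- sim_energy()
  stc <- select_significant(compute_stc(sim$design, sim$spikes), "fixed",
                            n_pos = 4)
  basis <- stc_subspace(stc, "excitatory")
  B <- vapply(basis, filter_to_vec, numeric(192))
  rot <- with(list(), {
    set.seed(8)
    qr.Q(qr(matrix(rnorm(16), 4, 4)))
  })
  basis_rot <- lapply(seq_len(4), function(i)
    subunitscope:::vec_to_filter(as.numeric(B %*% rot[, i]), 16, 12))
  for (c_loc in c(4, 10)) {
    f1 <- find_localized_filter(basis, c_loc, seed = 3)
    f2 <- find_localized_filter(basis_rot, c_loc, seed = 5)
    expect_equal(f1$cost, f2$cost, tolerance = 1e-6)
  }
  ## enlarging the basis never increases the optimal cost
  big <- stc_subspace(select_significant(stc, "fixed", n_pos = 6),
                      "excitatory")
  for (c_loc in c(4, 10)) {
    expect_lte(find_localized_filter(big, c_loc, seed = 3)$cost,
               find_localized_filter(basis, c_loc, seed = 3)$cost + 1e-8)
  }
})

test_that("orthogonal continuation finds the quadrature partner then exhausts", {
  sim <- sim_energy()
  stc <- select_significant(compute_stc(sim$design, sim$spikes), "fixed",
                            n_pos = 2)
  basis <- stc_subspace(stc, "excitatory")
  first <- find_localized_filter(basis, 7.5, seed = 2)
  second <- next_localized_at(basis, 7.5, first, seed = 2)
  expect_lt(abs(sum(first$beta * second$beta)), 1e-6)
  ## 2-D basis: second direction is the analytic orthogonal complement
  expect_equal(abs(sum(second$beta * c(-first$beta[2], first$beta[1]))), 1,
               tolerance = 1e-6)
  ## third request exhausts the subspace
  expect_error(next_localized_at(basis, 7.5, list(first, second), seed = 2),
               "exhausted")

  ## quadrature phase offset: cross-correlation of the two filters across
  ## spatial shifts peaks away from zero lag (90 degree phase offset)
  v1 <- unclass(first$filter); v2 <- unclass(second$filter)
  cc0 <- abs(sum(v1 * v2))
  expect_lt(cc0, 0.35)  # near-orthogonal in phase at zero shift
})

test_that("localized sets are deterministic and PCA-compressible", {
  sim <- sim_pooled()
  stc <- select_significant(compute_stc(sim$design, sim$spikes), "fixed",
                            n_pos = 6)
  basis <- stc_subspace(stc, "excitatory")
  set1 <- find_localized_set(basis, n_centers = 8, n_restarts = 10, seed = 7)
  set2 <- find_localized_set(basis, n_centers = 8, n_restarts = 10, seed = 7)
  expect_identical(lapply(set1$filters, `[[`, "beta"),
                   lapply(set2$filters, `[[`, "beta"))
  expect_equal(set1$centers[, 1], seq(0, 15, length.out = 8))

  ## centers inside the pooling envelope localize onto true subunit planes
  inside <- which(set1$centers[, 1] >= 4.5 & set1$centers[, 1] <= 10.5)
  match <- vapply(set1$filters[inside], function(f)
    pooled_plane_match(f$filter, sim$spec), numeric(1))
  expect_true(all(match >= 0.8))
  ## power centroid tracks the requested center inside the envelope
  cents <- vapply(set1$filters[inside], function(f)
    subunitscope:::power_centroid(f$filter), numeric(1))
  expect_true(all(abs(cents - set1$centers[inside, 1]) <= 2))

  ## identical shifted copies: first PCA component explains everything
  proto <- sim$spec$filters[[1]]
  copies <- structure(list(
    filters = lapply(c(-2, 0, 1, 2), function(s) {
      k <- shift_filter(proto, s)
      list(beta = 1, filter = k, center_target = 7.5 + s, cost = 0,
           power_profile = temporal_power(k))
    }),
    centers = matrix(c(-2, 0, 1, 2) + 7.5), costs = rep(0, 4),
    subspace_tag = "excitatory"), class = "localized_set")
  pc <- align_and_pca(copies)
  expect_gt(pc$pca_explained[1], 0.999)

  ## quadrature-pair family with random phases: exactly two components
  qp <- quad_pair(16, 12, 4, 0.55)
  set.seed(12)
  fam <- structure(list(
    filters = lapply(1:10, function(i) {
      ph <- runif(1, 0, 2 * pi)
      k <- strf(cos(ph) * unclass(qp[[1]]) + sin(ph) * unclass(qp[[2]]),
                normalize = FALSE)
      k <- shift_filter(k, sample(-2:2, 1))
      list(beta = 1, filter = k, center_target = 7.5, cost = 0,
           power_profile = temporal_power(k))
    }),
    centers = matrix(rep(7.5, 10)), costs = rep(0, 10),
    subspace_tag = "excitatory"), class = "localized_set")
  pc2 <- align_and_pca(fam)
  expect_gt(sum(pc2$pca_explained[1:2]), 0.99)

  expect_error(align_and_pca(structure(list(filters = fam$filters[1:2]),
                                       class = "localized_set")),
               "at least 3")
})
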