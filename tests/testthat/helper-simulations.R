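## Shared simulated recordings, built once per test session and cached so
## several test files can reuse them. All seeds fixed.

.sim_cache <- new.env(parent = emptyenv())

sim_cached <- function(key, builder) {
  if (!exists(key, envir = .sim_cache)) assign(key, builder(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

## quadrature pair used throughout: 16 bars x 12 lags, sf 3, tilt 0.5
quad_pair <- function(n_x = 16, n_lags = 12, sf = 3, tilt = 0.5) {
  list(make_gabor_strf(n_x, n_lags, sf, tilt, phase = 0),
       make_gabor_strf(n_x, n_lags, sf, tilt, phase = pi / 2))
}

## Gaussian white stimulus + design (the spherically symmetric ensemble
## STC theory assumes)
sim_white_design <- function(n_frames = 30000, n_lags = 12, seed = 101) {
  sim_cached(sprintf("white_%d_%d_%d", n_frames, n_lags, seed), function() {
    mov <- generate_pink_noise_movie(16, NULL, n_frames, exponent = 0,
                                     seed = seed, frame_rate_hz = 100)
    embed_stimulus(mov, n_lags)
  })
}

## LN simple cell on white noise
sim_ln <- function(n_frames = 30000, seed = 3) {
  sim_cached(sprintf("ln_%d_%d", n_frames, seed), function() {
    des <- sim_white_design(n_frames)
    k <- quad_pair()[[1]]
    spec <- neuron_spec("ln_simple", list(k), gain = 2, offset = -2)
    sp <- poisson_spikes(neuron_rate(spec, des), seed)
    list(design = des, spikes = sp, filter = k, spec = spec)
  })
}

## energy-model complex cell on white noise
sim_energy <- function(n_frames = 30000, seed = 7) {
  sim_cached(sprintf("energy_%d_%d", n_frames, seed), function() {
    des <- sim_white_design(n_frames)
    ks <- quad_pair()
    spec <- neuron_spec("energy_complex", ks, gain = 1, offset = -3)
    sp <- poisson_spikes(neuron_rate(spec, des), seed)
    list(design = des, spikes = sp, filters = ks, spec = spec)
  })
}

## pooled-subunit complex cell: tight quadrature prototypes shifted +-4 bars
pooled_spec <- function(gain = 2, offset = -3) {
  p1 <- make_gabor_strf(16, 12, 4, 0.55, phase = 0, space_sd = 1.3,
                        lag_sd = 2.2)
  p2 <- make_gabor_strf(16, 12, 4, 0.55, phase = pi / 2, space_sd = 1.3,
                        lag_sd = 2.2)
  neuron_spec("pooled_complex", list(p1, p2), subunit_nonlinearity = "square",
              shifts = -4:4, pool_sd = 2.5, pool_center = 0,
              gain = gain, offset = offset)
}

sim_pooled <- function(n_frames = 60000, seed = 9) {
  sim_cached(sprintf("pooled_%d_%d", n_frames, seed), function() {
    des <- sim_white_design(n_frames, seed = 102)
    spec <- pooled_spec()
    sp <- poisson_spikes(neuron_rate(spec, des), seed)
    list(design = des, spikes = sp, spec = spec)
  })
}

## vectorized true subunits of a pooled_complex spec (all shifts x phases)
pooled_truth_vecs <- function(spec) {
  out <- list()
  for (s in spec$shifts) for (k in spec$filters)
    out[[length(out) + 1L]] <- filter_to_vec(shift_filter(k, s))
  out
}

## max |corr| of a filter with the quadrature plane of any true subunit
## shift (projection onto each shifted 2-filter span)
pooled_plane_match <- function(filter, spec) {
  v <- filter_to_vec(filter)
  v <- v / sqrt(sum(v^2))
  best <- 0
  for (s in spec$shifts) {
    P <- vapply(spec$filters,
                function(k) filter_to_vec(shift_filter(k, s)),
                numeric(length(v)))
    qr_P <- qr(P)
    if (qr_P$rank < ncol(P)) next
    proj <- qr.fitted(qr_P, v)
    best <- max(best, sqrt(sum(proj^2)))
  }
  best
}

## largest principal angle (degrees) between the spans of two bases
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  max(acos(pmin(pmax(sv, -1), 1))) * 180 / pi
}

## internal helpers used widely in tests
filter_to_vec <- subunitscope:::filter_to_vec
shift_filter <- subunitscope:::shift_filter
eval_nonlin <- subunitscope:::eval_nonlin

## paired 95% t-interval for a difference vector
paired_ci <- function(d) {
  mean(d) + c(-1, 1) * qt(0.975, length(d) - 1) * sd(d) / sqrt(length(d))
}
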