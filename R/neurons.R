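## Generative model neurons.
##
## Four neuron classes span the classical simple-to-complex continuum:
##   ln_simple        r = F[k . s]                 (one linear filter)
##   separable_simple r = F[sum_i relu(k_i . s)]   (rectified non-DS inputs)
##   energy_complex   r = F[(k_1.s)^2 + (k_2.s)^2] (quadrature-pair energy)
##   pooled_complex   r = F[sum_shifts w_s sum_i f(k_{i,s} . s)]
## where F is a softplus spiking nonlinearity F(g) = log(1 + exp(gain * g +
## offset)) and, for pooled_complex, the prototype subunit filters are
## spatially shifted across the receptive field and pooled under a Gaussian
## weight envelope. Spikes are drawn as independent Poisson counts per frame.

#' Specify a model neuron
#'
#' @param kind one of `"ln_simple"`, `"separable_simple"`,
#'   `"energy_complex"`, `"pooled_complex"`.
#' @param filters list of [strf()] filters: 1 for `ln_simple`, 2 for
#'   `separable_simple` and `energy_complex`; for `pooled_complex` the
#'   prototype subunit set that is replicated across `shifts`.
#' @param subunit_nonlinearity per-subunit nonlinearity for
#'   `pooled_complex`: `"halfwave"` or `"square"` (others ignore it).
#' @param shifts integer bar shifts of the prototype set (`pooled_complex`).
#' @param pool_sd,pool_center Gaussian pooling envelope over shifts
#'   (`pooled_complex`): weight of shift s is proportional to
#'   `exp(-(s - pool_center)^2 / (2 pool_sd^2))`, normalized to sum 1.
#'   Shifted filters are truncated at the stimulus edge, not renormalized.
#' @param gain,offset softplus spiking nonlinearity parameters.
#' @return object of class `neuron_spec`.
#' @export
neuron_spec <- function(kind, filters, subunit_nonlinearity = "halfwave",
                        shifts = 0L, pool_sd = 2, pool_center = 0,
                        gain = 1, offset = 0) {
  kind <- match.arg(kind, c("ln_simple", "separable_simple",
                            "energy_complex", "pooled_complex"))
  subunit_nonlinearity <- match.arg(subunit_nonlinearity,
                                    c("linear", "halfwave", "square"))
  if (!is.list(filters) || !all(vapply(filters, inherits, TRUE, "strf")))
    stop("`filters` must be a list of strf objects")
  n_needed <- switch(kind, ln_simple = 1L, separable_simple = 2L,
                     energy_complex = 2L, pooled_complex = NA_integer_)
  if (!is.na(n_needed) && length(filters) != n_needed)
    stop(kind, " requires exactly ", n_needed, " filter(s)")
  if (kind == "pooled_complex" && length(filters) < 1)
    stop("pooled_complex requires at least one prototype filter")
  structure(list(kind = kind, filters = filters,
                 subunit_nonlinearity = subunit_nonlinearity,
                 shifts = as.integer(shifts),
                 pool_sd = pool_sd, pool_center = pool_center,
                 gain = as.numeric(gain), offset = as.numeric(offset)),
            class = "neuron_spec")
}

#' @export
print.neuron_spec <- function(x, ...) {
  cat(sprintf("<neuron_spec> %s: %d filter(s), gain=%g, offset=%g\n",
              x$kind, length(x$filters), x$gain, x$offset))
  if (x$kind == "pooled_complex")
    cat(sprintf("  %d shifts, pooling sd=%g center=%g, subunit f=%s\n",
                length(x$shifts), x$pool_sd, x$pool_center,
                x$subunit_nonlinearity))
  invisible(x)
}

## Gaussian pooling weights over shifts, normalized to sum 1.
pool_weights <- function(spec) {
  w <- exp(-(spec$shifts - spec$pool_center)^2 / (2 * spec$pool_sd^2))
  w / sum(w)
}

## The full, possibly shifted filter bank of a neuron plus subunit weights.
## Returns list(K = matrix of column-vectorized filters, w = weight per
## column, fun = per-subunit nonlinearity name).
neuron_filter_bank <- function(spec) {
  if (spec$kind != "pooled_complex") {
    K <- vapply(spec$filters, filter_to_vec,
                numeric(length(spec$filters[[1]])))
    return(list(K = as.matrix(K), w = rep(1, length(spec$filters)),
                fun = switch(spec$kind, ln_simple = "linear",
                             separable_simple = "halfwave",
                             energy_complex = "square")))
  }
  w0 <- pool_weights(spec)
  cols <- list(); w <- numeric(0)
  for (j in seq_along(spec$shifts)) {
    for (k in spec$filters) {
      cols[[length(cols) + 1L]] <- filter_to_vec(shift_filter(k, spec$shifts[j]))
      w <- c(w, w0[j])
    }
  }
  list(K = do.call(cbind, cols), w = w, fun = spec$subunit_nonlinearity)
}

#' Firing rate of a model neuron for an embedded stimulus
#'
#' Applies the neuron's cascade (filters, subunit nonlinearity, pooling,
#' softplus spiking nonlinearity) to every row of the design matrix.
#' Zero-padded rows get rate 0.
#'
#' @param spec a [neuron_spec()].
#' @param design a [embed_stimulus()] design matrix whose column count
#'   matches the filter dimensions.
#' @return numeric vector of nonnegative rates (spikes/frame), one per row.
#' @export
neuron_rate <- function(spec, design) {
  bank <- neuron_filter_bank(spec)
  if (nrow(bank$K) != ncol(design))
    stop("filter dimension ", nrow(bank$K),
         " does not match design columns ", ncol(design))
  G <- design %*% bank$K
  U <- switch(bank$fun,
              linear = G,
              halfwave = relu(G),
              square = G^2)
  g <- as.numeric(U %*% bank$w)
  r <- softplus(spec$gain * g + spec$offset)
  r[attr(design, "padded")] <- 0
  r
}

#' Draw Poisson spike counts from a rate vector
#'
#' Independent Poisson counts per frame with the given means, using an
#' explicit seed so simulations are exactly reproducible.
#'
#' @param rate nonnegative finite rate per frame (spikes/frame).
#' @param seed integer seed.
#' @return object of class `spike_counts`: integer vector with attribute
#'   `total_spikes`.
#' @export
poisson_spikes <- function(rate, seed) {
  stopifnot(all(is.finite(rate)), all(rate >= 0))
  counts <- with_seed(seed, rpois(length(rate), rate))
  structure(as.integer(counts), class = "spike_counts",
            total_spikes = sum(counts))
}

#' @export
print.spike_counts <- function(x, ...) {
  cat(sprintf("<spike_counts> %d frames, %d spikes (mean %.3f/frame)\n",
              length(x), attr(x, "total_spikes"),
              attr(x, "total_spikes") / length(x)))
  invisible(x)
}
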