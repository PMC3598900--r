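## Dataset container and spike-train import.
##
## Datasets (stimulus movie + aligned spike counts + optional ground
## truth) travel in a single versioned RDS container. Spike trains can
## also be imported from plain text, one spike time (seconds) per line,
## and are binned at the stimulus frame rate.

.container_version <- 1L

#' Write a dataset container
#'
#' @param path output file (`.rds`).
#' @param movie a [stimulus_movie()].
#' @param spikes optional `spike_counts` aligned to the movie frames.
#' @param ground_truth optional list (e.g. the generating [neuron_spec()]
#'   and its filters) stored verbatim.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(path, movie, spikes = NULL, ground_truth = NULL) {
  stopifnot(inherits(movie, "stimulus_movie"))
  if (!is.null(spikes) && length(spikes) != movie$n_frames)
    stop("spike counts (", length(spikes),
         ") do not align with movie frames (", movie$n_frames, ")")
  obj <- list(version = .container_version,
              stimulus = movie$values,
              frame_rate_hz = movie$frame_rate_hz,
              kind = movie$kind,
              spikes = if (is.null(spikes)) NULL else as.integer(spikes),
              ground_truth = ground_truth)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a dataset container
#'
#' @param path file written by [write_dataset()].
#' @return list with `movie` ([stimulus_movie()]), `spikes`
#'   (`spike_counts` or `NULL`) and `ground_truth` (or `NULL`).
#' @export
read_dataset <- function(path) {
  obj <- readRDS(path)
  req <- c("stimulus", "frame_rate_hz", "kind")
  miss <- setdiff(req, names(obj))
  if (length(miss))
    stop("container is missing dataset(s): ", paste(miss, collapse = ", "))
  movie <- stimulus_movie(obj$stimulus, obj$frame_rate_hz, obj$kind)
  spikes <- NULL
  if (!is.null(obj$spikes)) {
    if (any(obj$spikes != as.integer(obj$spikes)) || any(obj$spikes < 0))
      stop("spike counts must be nonnegative integers")
    if (length(obj$spikes) != movie$n_frames)
      stop("spike counts (", length(obj$spikes),
           ") do not align with movie frames (", movie$n_frames, ")")
    spikes <- structure(as.integer(obj$spikes), class = "spike_counts",
                        total_spikes = sum(obj$spikes))
  }
  list(movie = movie, spikes = spikes, ground_truth = obj$ground_truth)
}

#' Bin spike times from a text file
#'
#' Reads one spike time (seconds) per line and counts spikes in frame
#' bins `[t, t + dt)` at the given frame rate.
#'
#' @param path text file of spike times in seconds.
#' @param frame_rate_hz frame rate defining the bins.
#' @param n_frames number of frames in the recording window.
#' @return `spike_counts` of length `n_frames`; times outside
#'   `[0, n_frames / frame_rate_hz)` are dropped.
#' @export
read_spike_times <- function(path, frame_rate_hz, n_frames) {
  times <- scan(path, what = numeric(), quiet = TRUE)
  bins <- floor(times * frame_rate_hz)
  bins <- bins[bins >= 0 & bins < n_frames]
  counts <- tabulate(bins + 1L, nbins = n_frames)
  structure(as.integer(counts), class = "spike_counts",
            total_spikes = sum(counts))
}
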