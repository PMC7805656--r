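#' Filter specification for the preprocessing chain
#'
#' Two causal filters: a 1st-order Butterworth high-pass at 0.5 Hz that
#' detrends the FMG channels (DC gain exactly 0), and an order-5
#' Hamming-windowed FIR low-pass at 4 Hz (6 taps, normalized to unit DC
#' gain) that smooths both the FMG channels and the six label columns.
#' Filters are applied per trial so no state crosses trial boundaries.
#'
#' @param sample_rate_hz Sampling rate, Hz.
#' @param hp_order High-pass Butterworth order.
#' @param hp_cutoff_hz High-pass cutoff, Hz.
#' @param lp_order FIR low-pass filter order (taps = order + 1).
#' @param lp_cutoff_hz Low-pass cutoff, Hz.
#' @return An `fmg_filter_spec` with the designed coefficients.
#' @export
filter_spec <- function(sample_rate_hz = 10,
                        hp_order = 1L,
                        hp_cutoff_hz = 0.5,
                        lp_order = 5L,
                        lp_cutoff_hz = 4.0) {
  nyq <- sample_rate_hz / 2
  if (hp_cutoff_hz <= 0 || hp_cutoff_hz >= nyq) {
    stop_config("hp_cutoff_hz must lie in (0, Nyquist = ", nyq, ")")
  }
  if (lp_cutoff_hz <= 0 || lp_cutoff_hz >= nyq) {
    stop_config("lp_cutoff_hz must lie in (0, Nyquist = ", nyq, ")")
  }
  hp <- signal::butter(hp_order, hp_cutoff_hz / nyq, type = "high")
  taps <- signal::fir1(lp_order, lp_cutoff_hz / nyq, type = "low",
                       window = signal::hamming(lp_order + 1))
  taps <- as.numeric(taps) / sum(taps) # exact unit DC gain
  structure(
    list(
      sample_rate_hz = sample_rate_hz,
      hp_order = hp_order, hp_cutoff_hz = hp_cutoff_hz,
      lp_order = lp_order, lp_cutoff_hz = lp_cutoff_hz,
      hp_b = as.numeric(hp$b), hp_a = as.numeric(hp$a),
      lp_taps = taps
    ),
    class = "fmg_filter_spec"
  )
}

# Causal filter with steady-state warm start: the filter state is
# initialized as if the first sample had been held constant forever, so a
# step at t = 0 (sensor baseline) produces no startup transient. For the
# first-order IIR the initial-state effect is the homogeneous solution
# z * rho^n and is added in closed form; higher orders fall back to
# constant pre-padding. FIR filters are warm-started exactly by
# pre-padding length(b) - 1 copies of the first sample.
apply_iir <- function(x, b, a) {
  x <- as_matrix(x)
  n <- nrow(x)
  if (length(a) == 1L) {
    pad <- length(b) - 1L
    apply(x, 2, function(col) {
      y <- as.numeric(signal::filter(b, a, c(rep(col[1], pad), col)))
      y[(pad + 1L):(pad + n)]
    })
  } else if (length(a) == 2L) {
    rho_pow <- (-a[2])^(seq_len(n) - 1)
    dc <- sum(b) / sum(a)
    apply(x, 2, function(col) {
      zi <- b[2] * col[1] - a[2] * dc * col[1]
      as.numeric(signal::filter(b, a, col)) + zi * rho_pow
    })
  } else {
    pad <- as.integer(ceiling(50 / (1 - max(abs(polyroot(rev(a)))))))
    apply(x, 2, function(col) {
      y <- as.numeric(signal::filter(b, a, c(rep(col[1], pad), col)))
      y[(pad + 1L):(pad + n)]
    })
  }
}

#' Causal high-pass (detrending) filter
#'
#' Per-channel 1st-order Butterworth high-pass; removes DC and slow trend
#' from the FMG channels. Linear and time-invariant.
#'
#' @param x Samples x channels matrix (or vector).
#' @param spec An [filter_spec()].
#' @param trial_id Optional per-sample trial labels; filtering restarts at
#'   each trial boundary.
#' @return Same-shape matrix.
#' @export
highpass <- function(x, spec = filter_spec(), trial_id = NULL) {
  per_trial(x, trial_id, function(m) apply_iir(m, spec$hp_b, spec$hp_a))
}

#' Causal FIR low-pass (smoothing) filter
#'
#' Hamming-windowed sinc FIR with unit DC gain; applied to FMG channels
#' and label columns alike.
#'
#' @inheritParams highpass
#' @return Same-shape matrix.
#' @export
lowpass <- function(x, spec = filter_spec(), trial_id = NULL) {
  per_trial(x, trial_id, function(m) apply_iir(m, spec$lp_taps, 1))
}

per_trial <- function(x, trial_id, fn) {
  x <- as_matrix(x)
  if (!all(is.finite(x))) stop_input("signal contains non-finite values")
  if (nrow(x) < 10L) stop_input("need at least 10 samples per channel")
  if (is.null(trial_id)) {
    out <- fn(x)
  } else {
    out <- x
    for (tr in unique(trial_id)) {
      idx <- which(trial_id == tr)
      out[idx, ] <- fn(x[idx, , drop = FALSE])
    }
  }
  dimnames(out) <- dimnames(x)
  out
}

#' Apply the full filter chain to a subject dataset
#'
#' FMG channels: high-pass then low-pass. Labels: low-pass only. Each
#' trial is filtered independently.
#'
#' @param ds An `fmg_subject`.
#' @param spec An [filter_spec()].
#' @return Filtered `fmg_subject`.
#' @export
preprocess_subject <- function(ds, spec = filter_spec()) {
  ds$fmg <- lowpass(highpass(ds$fmg, spec, ds$trial_id), spec, ds$trial_id)
  ds$labels <- lowpass(ds$labels, spec, ds$trial_id)
  ds
}

#' Fit a train-referenced min-max normalizer
#'
#' Learns per-channel minima and maxima from the training FMG only.
#' Channels that are constant in training are flagged and mapped to 0.
#'
#' @param train_fmg Training samples x channels matrix.
#' @return An `fmg_norm` object.
#' @export
fit_normalizer <- function(train_fmg) {
  train_fmg <- as_matrix(train_fmg)
  if (nrow(train_fmg) == 0L) stop_input("training matrix is empty")
  mins <- apply(train_fmg, 2, min)
  maxs <- apply(train_fmg, 2, max)
  const <- maxs <= mins
  if (any(const)) {
    warning("constant training channel(s) mapped to 0: ",
            paste(which(const), collapse = ", "))
  }
  structure(list(min = mins, max = maxs, constant = const),
            class = "fmg_norm")
}

#' Apply a fitted min-max normalizer
#'
#' Training channels map into \[0, 1\] exactly; values outside the
#' training range are not clipped and may exceed \[0, 1\].
#'
#' @param ref An [fit_normalizer()] result.
#' @param fmg Samples x channels matrix with the same channel count.
#' @return Normalized matrix.
#' @export
apply_normalizer <- function(ref, fmg) {
  fmg <- as_matrix(fmg)
  if (ncol(fmg) != length(ref$min)) {
    stop_input("channel count (", ncol(fmg), ") does not match normalizer (",
               length(ref$min), ")")
  }
  rng <- ref$max - ref$min
  rng[ref$constant] <- 1
  out <- sweep(sweep(fmg, 2, ref$min, "-"), 2, rng, "/")
  out[, ref$constant] <- 0
  out
}
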