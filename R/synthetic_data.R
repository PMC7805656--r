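#' Protocol configuration for synthetic FMG acquisition
#'
#' Describes the acquisition protocol emulated by the generator: a number
#' of trials, each consisting of six focused-axis sessions (the subject
#' exerts an approximately sinusoidal force or torque along one axis at a
#' time) followed by one free-exertion session in which all six axes are
#' active simultaneously.
#'
#' @param n_trials Number of trials per subject (>= 2; cross-trial
#'   evaluation needs at least two).
#' @param session_order Session labels in acquisition order; the six axis
#'   labels of [FMG_AXES] plus `"free"`.
#' @param session_duration_s Duration of one session in seconds.
#' @param sample_rate_hz Sampling rate in Hz; `session_duration_s *
#'   sample_rate_hz` must be an integer number of samples.
#' @param force_amp_N Nominal peak force amplitude in Newtons.
#' @param torque_amp_Nm Nominal peak torque amplitude in Newton-meters.
#' @param sine_freq_range_hz Interval from which the focused-session
#'   sinusoid frequency is drawn, in Hz. The default gives 2-5 cycles per
#'   40 s session.
#' @param leakage_range Interval from which per-axis cross-talk
#'   coefficients are drawn for focused sessions (fraction of the focused
#'   signal appearing on non-focused axes).
#' @param cross_noise_scale Peak amplitude of the smooth noise added to
#'   non-focused axes, as a fraction of the receiving axis' nominal amplitude.
#' @param free_scale Peak amplitude of each axis in the free session, as
#'   a fraction of that axis' nominal amplitude.
#' @param seed Default RNG seed used by [generate_subject()].
#'
#' @return An object of class `fmg_protocol` (a validated list).
#' @export
protocol_config <- function(n_trials = 5L,
                            session_order = c(FMG_AXES, "free"),
                            session_duration_s = 40,
                            sample_rate_hz = 10,
                            force_amp_N = 20,
                            torque_amp_Nm = 2,
                            sine_freq_range_hz = c(0.05, 0.125),
                            leakage_range = c(0.05, 0.30),
                            cross_noise_scale = 0.1,
                            free_scale = 0.7,
                            seed = 1L) {
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 2L) {
    stop_config("n_trials must be an integer >= 2 (cross-trial evaluation needs held-out trials)")
  }
  if (!all(session_order %in% c(FMG_AXES, "free"))) {
    stop_config("session_order may only contain ", paste(FMG_AXES, collapse = ", "), " and 'free'")
  }
  n_samples <- session_duration_s * sample_rate_hz
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop_config("session_duration_s * sample_rate_hz must be an integer sample count")
  }
  if (length(sine_freq_range_hz) != 2L || any(sine_freq_range_hz <= 0) ||
      any(sine_freq_range_hz >= sample_rate_hz / 2) || diff(sine_freq_range_hz) < 0) {
    stop_config("sine_freq_range_hz must be an increasing interval within (0, Nyquist)")
  }
  if (length(leakage_range) != 2L || any(leakage_range < 0) ||
      any(leakage_range >= 1) || diff(leakage_range) < 0) {
    stop_config("leakage_range must be an increasing interval within [0, 1)")
  }
  structure(
    list(
      n_trials = n_trials,
      session_order = session_order,
      session_duration_s = session_duration_s,
      sample_rate_hz = sample_rate_hz,
      force_amp_N = force_amp_N,
      torque_amp_Nm = torque_amp_Nm,
      sine_freq_range_hz = sine_freq_range_hz,
      leakage_range = leakage_range,
      cross_noise_scale = cross_noise_scale,
      free_scale = free_scale,
      seed = as.integer(seed)
    ),
    class = "fmg_protocol"
  )
}

#' Band layout: channel-to-band assignment and active-sensor mask
#'
#' The default hardware carries 60 force-sensing resistors in four bands
#' worn from the wrist up: 12 at the wrist (position 1), then 16 each at
#' the forearm midway (2), the forearm muscle belly (3) and the upper arm
#' (4). Sensors not in contact with the skin are marked inactive and
#' dropped on load.
#'
#' @param band_sizes Integer vector of length 4, channels per band in
#'   wrist-to-upper-arm order.
#' @param active_mask Logical vector, one entry per channel; `TRUE` keeps
#'   the channel.
#'
#' @return An object of class `fmg_layout` with fields `band_sizes`,
#'   `active_mask`, `channel_band` (band position per channel) and
#'   `channel_names` (zero-padded `ch_###`).
#' @export
band_layout <- function(band_sizes = c(12L, 16L, 16L, 16L),
                        active_mask = rep(TRUE, sum(band_sizes))) {
  band_sizes <- as.integer(band_sizes)
  if (length(band_sizes) != 4L || any(band_sizes < 1L)) {
    stop_config("band_sizes must give a positive channel count for each of the 4 band positions")
  }
  n_ch <- sum(band_sizes)
  if (length(active_mask) != n_ch || !is.logical(active_mask) || anyNA(active_mask)) {
    stop_config("active_mask must be a logical vector with one entry per channel (", n_ch, ")")
  }
  channel_band <- rep(seq_len(4L), times = band_sizes)
  for (b in 1:4) {
    if (!any(active_mask[channel_band == b])) {
      stop_config("band ", b, " has no active channel")
    }
  }
  structure(
    list(
      band_sizes = band_sizes,
      active_mask = active_mask,
      channel_band = channel_band,
      channel_names = sprintf("ch_%03d", seq_len(n_ch))
    ),
    class = "fmg_layout"
  )
}

softplus <- function(x) {
  # numerically safe log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

#' Coupling model mapping 6-DoF load to FMG channel responses
#'
#' A per-subject generative stand-in for the physiology that produces FMG:
#' each channel responds, through a monotone nonlinearity, to a
#' nonnegative mixture of the six force/torque axes, with the mixture
#' gain set by the band the channel sits on. The default gain structure
#' encodes the anatomical prior that the forearm muscle belly (band 3) is
#' informative for all six axes while the upper arm (band 4) carries
#' almost no torque information. Baseline offsets, slow drift, additive
#' noise and a per-trial multiplicative gain emulate sensor
#' non-idealities and band re-seating between trials.
#'
#' @param layout An [band_layout()] object.
#' @param preset Gain-structure preset: `"default"` (muscle-belly
#'   dominant, upper arm torque-blind), `"band3-dominant"` (stronger
#'   contrast of the same structure) or `"uniform"` (all bands equally
#'   informative).
#' @param noise_sd Standard deviation of additive sensor noise (raw
#'   units).
#' @param trial_gain_sd Standard deviation of the per-trial multiplicative
#'   gain (mean 1).
#' @param drift_sd Standard deviation of the per-channel linear drift
#'   rate, in raw units per sample.
#' @param nonlinearity Monotone scalar map applied to the mixed drive
#'   (default softplus).
#' @param force_scale_N,torque_scale_Nm Axis normalization used to bring
#'   forces and torques onto a common drive scale before mixing; defaults
#'   match the protocol amplitudes.
#' @param seed RNG seed for the per-channel weight/baseline/drift draws.
#'
#' @return An object of class `fmg_coupling`.
#' @export
coupling_model <- function(layout = band_layout(),
                           preset = c("default", "band3-dominant", "uniform"),
                           noise_sd = 0.1,
                           trial_gain_sd = 0.05,
                           drift_sd = 5e-5,
                           nonlinearity = softplus,
                           force_scale_N = 20,
                           torque_scale_Nm = 2,
                           seed = 1L) {
  preset <- match.arg(preset)
  band_gain_scale <- switch(
    preset,
    "default" = rbind(
      rep(0.75, 6),
      rep(0.85, 6),
      rep(1.0, 6),
      c(0.85, 0.85, 0.85, 0.03, 0.03, 0.03)
    ),
    "band3-dominant" = rbind(
      rep(0.5, 6),
      rep(0.7, 6),
      rep(1.0, 6),
      c(0.7, 0.7, 0.7, 0.02, 0.02, 0.02)
    ),
    "uniform" = matrix(1, 4, 6)
  )
  dimnames(band_gain_scale) <- list(paste0("band", 1:4), FMG_AXES)
  stopifnot(all(band_gain_scale >= 0))
  n_ch <- sum(layout$band_sizes)
  draws <- with_seed(seed, {
    w <- matrix(stats::runif(n_ch * 6, 0.3, 1.0), n_ch, 6,
                dimnames = list(layout$channel_names, FMG_AXES))
    # rescale so each band's mean weight per axis is exactly the draw
    # mean: channel directions stay diverse, but the band-level
    # effective gain is the encoded band_gain_scale by construction,
    # not a sampling outcome
    for (b in 1:4) {
      idx <- layout$channel_band == b
      w[idx, ] <- sweep(w[idx, , drop = FALSE], 2,
                        0.65 / colMeans(w[idx, , drop = FALSE]), "*")
    }
    list(
      channel_weights = w,
      baseline = stats::runif(n_ch, 0.1, 0.3),
      drift_rate = stats::rnorm(n_ch, 0, drift_sd)
    )
  })
  structure(
    c(draws, list(
      band_gain_scale = band_gain_scale,
      noise_sd = noise_sd,
      trial_gain_sd = trial_gain_sd,
      drift_sd = drift_sd,
      nonlinearity = nonlinearity,
      axis_scale = c(rep(force_scale_N, 3), rep(torque_scale_Nm, 3)),
      preset = preset,
      seed = as.integer(seed)
    )),
    class = "fmg_coupling"
  )
}

# Zero-mean noise with spectral content at or below cutoff_hz, scaled to
# unit peak amplitude. Built by hard-truncating the spectrum of white
# Gaussian noise.
smooth_noise <- function(n, sample_rate_hz, cutoff_hz = 0.4) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * sample_rate_hz / n
  f <- pmin(f, sample_rate_hz - f)
  X[f > cutoff_hz] <- 0+0i
  X[1] <- 0+0i # zero mean
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  m <- max(abs(x))
  if (m > 0) x / m else x
}

axis_amplitude <- function(cfg, axis) {
  if (axis %in% c("Fx", "Fy", "Fz")) cfg$force_amp_N else cfg$torque_amp_Nm
}

#' Generate one focused-axis session of 6-DoF load-cell labels
#'
#' The focused axis follows `A * sin(2*pi*f*t + phase)` with the frequency
#' drawn from `cfg$sine_freq_range_hz` and the amplitude jittered by
#' +/-10% around the nominal axis amplitude. Each non-focused axis
#' receives leakage — the focused waveform scaled by a coefficient drawn
#' from `cfg$leakage_range` — plus independent smooth noise, both
#' expressed as fractions of the *receiving* axis' nominal amplitude
#' (co-activating a torque while pushing a force excites a fraction of
#' the torque range, not of the force range). This emulates the
#' unintended co-activation observed when subjects try to load a single
#' axis.
#'
#' Draws from the current RNG state; seed via [generate_subject()] or
#' `set.seed()`.
#'
#' @param cfg A [protocol_config()].
#' @param axis One of [FMG_AXES].
#' @param leakage Optional named vector of signed leakage coefficients
#'   (one per non-focused axis). Co-activation is a stable subject trait,
#'   so [generate_subject()] draws one leakage matrix per subject and
#'   passes the focused axis' column here; when `NULL` the coefficients
#'   are drawn fresh from `cfg$leakage_range` with random sign.
#'
#' @return A numeric matrix, samples x 6, columns named by [FMG_AXES].
#' @export
generate_focused_session <- function(cfg, axis, leakage = NULL) {
  if (!(axis %in% FMG_AXES)) {
    stop_input("unknown axis label '", axis, "'")
  }
  n <- as.integer(round(cfg$session_duration_s * cfg$sample_rate_hz))
  t <- (seq_len(n) - 1) / cfg$sample_rate_hz
  a_nom <- axis_amplitude(cfg, axis)
  amp <- a_nom * stats::runif(1, 0.9, 1.1)
  freq <- stats::runif(1, cfg$sine_freq_range_hz[1], cfg$sine_freq_range_hz[2])
  phase <- stats::runif(1, 0, 2 * pi)
  focused <- amp * sin(2 * pi * freq * t + phase)
  out <- matrix(0, n, 6, dimnames = list(NULL, FMG_AXES))
  out[, axis] <- focused
  if (is.null(leakage)) leakage <- draw_leakage(cfg)[, axis]
  for (ax in setdiff(FMG_AXES, axis)) {
    scale_ax <- axis_amplitude(cfg, ax) / a_nom
    noise <- cfg$cross_noise_scale * axis_amplitude(cfg, ax) *
      smooth_noise(n, cfg$sample_rate_hz, cutoff_hz = 0.4)
    out[, ax] <- leakage[[ax]] * scale_ax * focused + noise
  }
  out
}

# Signed per-axis-pair leakage coefficients: column = focused axis,
# row = receiving axis. Magnitudes from cfg$leakage_range, random signs.
draw_leakage <- function(cfg) {
  mag <- matrix(stats::runif(36, cfg$leakage_range[1], cfg$leakage_range[2]), 6, 6)
  sgn <- matrix(sample(c(-1, 1), 36, replace = TRUE), 6, 6)
  lk <- mag * sgn
  diag(lk) <- 0
  dimnames(lk) <- list(FMG_AXES, FMG_AXES)
  lk
}

#' Generate one free-exertion session of 6-DoF labels
#'
#' Every axis is an independent smooth (spectral content <= 0.4 Hz)
#' zero-mean signal with peak amplitude `cfg$free_scale` times the axis'
#' nominal amplitude, emulating unconstrained simultaneous multi-axis
#' exertion.
#'
#' @inheritParams generate_focused_session
#' @return A numeric matrix, samples x 6.
#' @export
generate_free_session <- function(cfg) {
  n <- as.integer(round(cfg$session_duration_s * cfg$sample_rate_hz))
  out <- matrix(0, n, 6, dimnames = list(NULL, FMG_AXES))
  for (ax in FMG_AXES) {
    out[, ax] <- cfg$free_scale * axis_amplitude(cfg, ax) *
      smooth_noise(n, cfg$sample_rate_hz, cutoff_hz = 0.4)
  }
  out
}

#' Synthesize FMG channel responses from 6-DoF labels
#'
#' Channel `j` at time `t` responds as
#' `baseline_j + g_trial * f(w_j . y(t)) + drift_j * t + noise`,
#' where `w_j` is the channel's nonnegative axis-weight vector scaled by
#' its band's gain row, `f` is the coupling nonlinearity, `g_trial` is a
#' per-trial gain drawn once per call from `N(1, trial_gain_sd^2)`, and
#' the result is clamped at 0 (force-sensing resistors cannot read
#' negative). Labels are normalized per axis by the coupling's axis scale
#' before mixing so forces and torques contribute comparably.
#'
#' Draws from the current RNG state.
#'
#' @param labels Samples x 6 label matrix.
#' @param coupling An [coupling_model()].
#' @param layout The [band_layout()] the coupling was built for.
#'
#' @return Samples x channels matrix of raw FMG values (all channels,
#'   including inactive ones).
#' @export
synthesize_fmg <- function(labels, coupling, layout = band_layout()) {
  labels <- as_matrix(labels)
  if (ncol(labels) != 6L) {
    stop_input("labels must have 6 columns (", paste(FMG_AXES, collapse = ", "), ")")
  }
  if (!all(is.finite(labels))) stop_input("labels must be finite")
  n_ch <- sum(layout$band_sizes)
  if (nrow(coupling$channel_weights) != n_ch) {
    stop_input("coupling channel count (", nrow(coupling$channel_weights),
               ") does not match layout (", n_ch, ")")
  }
  g_trial <- stats::rnorm(1, 1, coupling$trial_gain_sd)
  w <- coupling$channel_weights *
    coupling$band_gain_scale[layout$channel_band, , drop = FALSE]
  drive <- sweep(labels, 2, coupling$axis_scale, "/") %*% t(w)
  n <- nrow(labels)
  tvec <- seq_len(n) - 1
  resp <- matrix(coupling$baseline, n, n_ch, byrow = TRUE) +
    g_trial * coupling$nonlinearity(drive) +
    outer(tvec, coupling$drift_rate)
  if (coupling$noise_sd > 0) {
    resp <- resp + matrix(stats::rnorm(n * n_ch, 0, coupling$noise_sd), n, n_ch)
  }
  resp[resp < 0] <- 0
  colnames(resp) <- layout$channel_names
  resp
}

#' Generate a complete synthetic subject dataset
#'
#' Concatenates `cfg$n_trials` trials, each running the sessions of
#' `cfg$session_order` back to back. With the default protocol this gives
#' 5 trials x 7 sessions x 400 samples = 14,000 samples. Output is
#' deterministic given the seed.
#'
#' @param cfg A [protocol_config()].
#' @param coupling An [coupling_model()]; built from `layout` with
#'   `sub_seed` of `seed` when `NULL`.
#' @param layout An [band_layout()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#'
#' @return An object of class `fmg_subject`: list with `fmg` (samples x
#'   active channels), `labels` (samples x 6), `trial_id`, `session_id`,
#'   `layout`, and `meta` (seed, preset, config).
#' @export
generate_subject <- function(cfg = protocol_config(),
                             coupling = NULL,
                             layout = band_layout(),
                             seed = cfg$seed) {
  if (cfg$n_trials < 2L) {
    stop_config("n_trials must be >= 2")
  }
  if (is.null(coupling)) {
    coupling <- coupling_model(layout, seed = sub_seed(seed, 999L))
  }
  n_sess <- as.integer(round(cfg$session_duration_s * cfg$sample_rate_hz))
  with_seed(seed, {
    fmg_parts <- vector("list", cfg$n_trials)
    lab_parts <- vector("list", cfg$n_trials)
    trial_ids <- integer(0)
    session_ids <- character(0)
    leakage <- draw_leakage(cfg) # co-activation trait, fixed per subject
    for (k in seq_len(cfg$n_trials)) {
      labs <- lapply(cfg$session_order, function(s) {
        if (s == "free") generate_free_session(cfg)
        else generate_focused_session(cfg, s, leakage = leakage[, s])
      })
      labs <- do.call(rbind, labs)
      fmg_parts[[k]] <- synthesize_fmg(labs, coupling, layout)
      lab_parts[[k]] <- labs
      trial_ids <- c(trial_ids, rep(k, nrow(labs)))
      session_ids <- c(session_ids, rep(cfg$session_order, each = n_sess))
    }
    new_fmg_subject(
      fmg = do.call(rbind, fmg_parts),
      labels = do.call(rbind, lab_parts),
      trial_id = trial_ids,
      session_id = session_ids,
      layout = layout,
      meta = list(seed = as.integer(seed), preset = coupling$preset,
                  config = unclass(cfg)[setdiff(names(cfg), "seed")])
    )
  })
}

#' Construct (and validate) a subject dataset container
#'
#' Inactive channels per `layout$active_mask` are dropped from `fmg`;
#' `fmg` may be supplied either with all channels or already masked.
#'
#' @param fmg Samples x channels FMG matrix.
#' @param labels Samples x 6 label matrix.
#' @param trial_id Integer vector, trial per sample.
#' @param session_id Character vector, session label per sample.
#' @param layout An [band_layout()].
#' @param meta Optional provenance list.
#'
#' @return `fmg_subject` object. `$fmg` holds active channels only;
#'   `$channel_band` gives the band position of each retained column.
#' @export
new_fmg_subject <- function(fmg, labels, trial_id, session_id,
                            layout = band_layout(), meta = list()) {
  fmg <- as_matrix(fmg)
  labels <- as_matrix(labels)
  n_all <- sum(layout$band_sizes)
  if (ncol(fmg) == n_all) {
    colnames(fmg) <- layout$channel_names
    fmg <- fmg[, layout$active_mask, drop = FALSE]
    channel_band <- layout$channel_band[layout$active_mask]
  } else if (ncol(fmg) == sum(layout$active_mask)) {
    colnames(fmg) <- layout$channel_names[layout$active_mask]
    channel_band <- layout$channel_band[layout$active_mask]
  } else {
    stop_input("fmg has ", ncol(fmg), " channels; layout expects ",
               n_all, " (all) or ", sum(layout$active_mask), " (active)")
  }
  if (nrow(fmg) != nrow(labels)) stop_input("fmg and labels disagree on sample count")
  if (ncol(labels) != 6L) stop_input("labels must have 6 columns")
  colnames(labels) <- FMG_AXES
  if (length(trial_id) != nrow(fmg) || length(session_id) != nrow(fmg)) {
    stop_input("trial_id and session_id must have one entry per sample")
  }
  structure(
    list(
      fmg = fmg,
      labels = labels,
      trial_id = as.integer(trial_id),
      session_id = as.character(session_id),
      channel_band = channel_band,
      layout = layout,
      meta = meta
    ),
    class = "fmg_subject"
  )
}

#' @export
print.fmg_subject <- function(x, ...) {
  cat("<fmg_subject> ", nrow(x$fmg), " samples, ", ncol(x$fmg),
      " active channels, ", length(unique(x$trial_id)), " trials, sessions: ",
      paste(unique(x$session_id), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.fmg_subject <- function(x) dim(x$fmg)

# Row subset of a subject dataset (keeps the current channel set;
# no layout revalidation, so it also works after band selection).
subset_rows <- function(ds, idx) {
  ds$fmg <- ds$fmg[idx, , drop = FALSE]
  ds$labels <- ds$labels[idx, , drop = FALSE]
  ds$trial_id <- ds$trial_id[idx]
  ds$session_id <- ds$session_id[idx]
  ds
}

# Layout whose active mask matches the channels currently held by ds.
layout_with_mask <- function(ds) {
  lay <- ds$layout
  mask <- lay$channel_names %in% colnames(ds$fmg)
  band_layout(lay$band_sizes, mask)
}
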