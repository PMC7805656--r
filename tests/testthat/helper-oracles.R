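# Independent oracles: literal transcriptions and brute-force references
# used to check the package's optimized implementations.

# Literal kernel-average GRNN: double loop over queries and pattern units,
# no stabilization. Only usable for small problems.
grnn_reference <- function(X, Y, sigma, Xq) {
  X <- as.matrix(X); Y <- as.matrix(Y); Xq <- as.matrix(Xq)
  out <- matrix(NA_real_, nrow(Xq), ncol(Y))
  for (q in seq_len(nrow(Xq))) {
    num <- rep(0, ncol(Y)); den <- 0
    for (i in seq_len(nrow(X))) {
      d2 <- sum((Xq[q, ] - X[i, ])^2)
      w <- exp(-d2 / (2 * sigma^2))
      num <- num + Y[i, ] * w
      den <- den + w
    }
    out[q, ] <- num / den
  }
  out
}

# R-squared by independent elementwise summation.
r2_reference <- function(y, yhat) {
  sse <- 0; sst <- 0; ybar <- sum(y) / length(y)
  for (i in seq_along(y)) {
    sse <- sse + (yhat[i] - y[i])^2
    sst <- sst + (y[i] - ybar)^2
  }
  1 - sse / sst
}

# Magnitude response of the analog-prototype first-order Butterworth
# high-pass after bilinear transform, evaluated at frequency f (Hz).
butter1_hp_gain <- function(f, fc, fs) {
  # evaluate the designed digital filter directly
  hp <- signal::butter(1, fc / (fs / 2), type = "high")
  h <- signal::freqz(hp$b, hp$a, Fs = fs, n = 4096)
  idx <- which.min(abs(h$f - f))
  abs(h$h[idx])
}

# Frequency response magnitude of an FIR filter at frequency f (Hz).
fir_gain <- function(taps, f, fs) {
  Mod(sum(taps * exp(-2i * pi * f / fs * (seq_along(taps) - 1))))
}

# Small deterministic subject for pipeline tests.
make_test_subject <- function(seed = 1, n_trials = 3, duration = 20,
                              noise_sd = 0.1, preset = "default") {
  cfg <- protocol_config(n_trials = n_trials, session_duration_s = duration,
                         seed = seed)
  lay <- band_layout()
  cp <- coupling_model(lay, preset = preset, noise_sd = noise_sd,
                       seed = seed + 1000)
  generate_subject(cfg, cp, lay, seed = seed)
}

# Reduced study settings shared by the slower pipeline tests.
test_spec <- function() filter_spec(hp_cutoff_hz = 0.02)
test_plan <- function(seed = 1) {
  tuning_plan(grid = data.frame(sigma = c(0.05, 0.1, 0.2)),
              n_folds = 5, seed = seed,
              grid_stage2 = data.frame(sigma = c(0.1, 0.3, 1, 3)))
}
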