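# Shared fixtures and independent oracles used across test files.

# Small study: one arm, few time points, for fast end-to-end unit tests.
tiny_design <- function(snr = Inf, seed = 42L, replicates = 2) {
  study_design(
    arms = list(list(temperature_C = 85, timepoints_h = c(0, 2, 6),
                     replicates = replicates)),
    snr = snr, assay_noise_sd = 0, seed = seed)
}

# Short acquisition grids (same physics, fewer samples).
short_cpmg_grid <- function(n = 400, dt = 0.010)
  acquisition_grid("CPMG", times_s = seq_len(n) * dt)

short_ircpmg_grid <- function(n2 = 60)
  acquisition_grid("IRCPMG",
                   tau1_s = exp(seq(log(0.05), log(10), length.out = 10)),
                   tau2_s = seq_len(n2) * 0.015)

# Exhaustive NNLS oracle: enumerates every support, solves the
# unconstrained least-squares problem on it, and returns the feasible
# candidate with the smallest objective. The NNLS optimum restricted to its
# own support solves the support's LS problem, so it is among the
# candidates. Only usable for small column counts.
nnls_exhaustive <- function(A, b) {
  n <- ncol(A)
  best_obj <- Inf
  best_x <- numeric(n)
  for (mask in 0:(2^n - 1)) {
    P <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    x <- numeric(n)
    if (length(P)) {
      xs <- tryCatch(qr.solve(A[, P, drop = FALSE], b),
                     error = function(e) NULL)
      if (is.null(xs) || any(xs < 0)) next
      x[P] <- xs
    }
    obj <- sum((A %*% x - b)^2)
    if (obj < best_obj) { best_obj <- obj; best_x <- x }
  }
  best_x
}

# Grid-search monoexponential oracle: profiles the amplitude (linear in the
# model) over a dense relaxation-time grid and returns the SSE-minimizing
# pair. Independent of the package's iterative fitter.
grid_fit_monoexp <- function(t, s, kind = c("SR", "CPMG"),
                             T_range = c(0.01, 20), n = 20000) {
  kind <- match.arg(kind)
  Ts <- exp(seq(log(T_range[1]), log(T_range[2]), length.out = n))
  best <- list(sse = Inf, T = NA, A = NA)
  for (T in Ts) {
    m <- if (kind == "SR") 1 - exp(-t / T) else exp(-t / T)
    A <- sum(m * s) / sum(m * m)
    sse <- sum((s - A * m)^2)
    if (sse < best$sse) best <- list(sse = sse, T = T, A = A)
  }
  best
}

# Spectrum object from raw parts (for peak-detection unit tests).
make_spectrum <- function(grid_s, amplitude, alpha = 0) {
  structure(list(grid_s = grid_s, amplitude = amplitude, alpha = alpha,
                 residual_norm = 0), class = "relaxation_spectrum")
}

# Map object from raw parts (for pool-detection unit tests).
make_map <- function(t1_grid_s, t2_grid_s, amplitude, alpha = 0) {
  structure(list(t1_grid_s = t1_grid_s, t2_grid_s = t2_grid_s,
                 amplitude = amplitude, alpha = alpha, residual_norm = 0),
            class = "relaxation_map")
}
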