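# In-silico analogue of the heat-induced glycation study: three temperature
# arms, triplicate TD-NMR acquisitions and reference assay readouts, all
# driven by a latent glycation extent g(t) in [0, 1].

#' Study design for the synthetic glycation experiment
#'
#' Default arms reproduce the study layout: 55 degC sampled daily over 6
#' days, 70 degC over 48 h, 85 degC over 6 h, three replicates each.
#'
#' @param arms list of arms, each a list with \code{temperature_C},
#'   \code{timepoints_h} (must include 0) and \code{replicates} (>= 1).
#' @param snr signal-to-noise ratio of the decay data (max signal / noise
#'   sd); \code{Inf} disables noise. Default 200.
#' @param assay_noise_sd additive noise sd on the free-amino percentage
#'   readout (percentage points). Default 2.
#' @param seed integer seed making the generated study reproducible.
#' @return an object of class \code{study_design}.
#' @export
study_design <- function(arms = default_arms(), snr = 200,
                         assay_noise_sd = 2, seed = 1L) {
  for (a in arms) {
    if (a$replicates < 1) stop("replicates must be >= 1", call. = FALSE)
    if (!0 %in% a$timepoints_h)
      stop("timepoints must include 0", call. = FALSE)
    if (is.unsorted(a$timepoints_h, strictly = TRUE))
      stop("timepoints must be strictly increasing", call. = FALSE)
  }
  if (!(is.infinite(snr) || snr > 0)) stop("snr must be > 0", call. = FALSE)
  structure(list(arms = arms, snr = snr, assay_noise_sd = assay_noise_sd,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @rdname study_design
#' @export
default_arms <- function() {
  list(
    list(temperature_C = 55, timepoints_h = c(0, 24, 48, 72, 96, 120, 144),
         replicates = 3),
    list(temperature_C = 70, timepoints_h = c(0, 3, 6, 12, 24, 36, 48),
         replicates = 3),
    list(temperature_C = 85, timepoints_h = c(0, 0.5, 1, 2, 4, 6),
         replicates = 3)
  )
}

# Per-arm first-order kinetics. The latent extent g(t) = 1 - exp(-k t)
# saturates at g_sat = 0.95 at the last sampled time point; the free-amino
# decline coefficient is scaled so the endpoint matches the arm's printed
# reduction exactly (15/30/40 %).
default_kinetics <- function() {
  list(`55` = list(t_end_h = 144, reduction = 0.15),
       `70` = list(t_end_h = 48,  reduction = 0.30),
       `85` = list(t_end_h = 6,   reduction = 0.40))
}

#' Latent glycation state at a given heating time
#'
#' First-order saturating kinetics: g(t) = 1 - exp(-k_T t), with k_T set so
#' that g reaches 0.95 at the arm's final sampled time point. The remaining
#' free-amino fraction declines linearly in g and hits the arm's endpoint
#' reduction (15 % at 55 degC, 30 % at 70 degC, 40 % at 85 degC) exactly at
#' the final time point.
#'
#' @param temperature_C arm temperature (55, 70 or 85 by default).
#' @param time_h heating time in hours, >= 0.
#' @param kinetics named list (by temperature) of \code{t_end_h} and
#'   \code{reduction}; see \code{default_kinetics} values above.
#' @param g_sat latent saturation level reached at \code{t_end_h}
#'   (default 0.95).
#' @return a list with \code{g} (glycation extent in [0,1]) and
#'   \code{free_amino_fraction}.
#' @export
glycation_trajectory <- function(temperature_C, time_h,
                                 kinetics = default_kinetics(),
                                 g_sat = 0.95) {
  key <- as.character(temperature_C)
  if (!key %in% names(kinetics))
    stop("unknown temperature arm: ", temperature_C, call. = FALSE)
  if (any(time_h < 0)) stop("time_h must be >= 0", call. = FALSE)
  p <- kinetics[[key]]
  k <- -log(1 - g_sat) / p$t_end_h
  g <- 1 - exp(-k * time_h)
  delta_eff <- p$reduction / g_sat
  list(g = g, free_amino_fraction = 1 - delta_eff * g)
}

#' Default alpha/beta proton-pool configuration
#'
#' The alpha pool (solute-water interactions, the dominant signal) moves
#' deterministically with glycation: T1 from 1.75 s down to 1.30 s and T2
#' from 0.90 s down to 0.45 s as g goes 0 to 1, so the T2/T1 ratio falls
#' from 0.514 to 0.346. The beta pool (saccharide-saccharide hydrogen
#' bonding) is re-drawn per replicate: T1 uniform in [0.4, 0.9] s, T2 in
#' [0.05, 0.3] s, amplitude 5-25 % of the alpha amplitude.
#'
#' @return named list of pool parameters.
#' @export
default_pool_config <- function() {
  list(alpha_T1_range_s = c(1.75, 1.30),
       alpha_T2_range_s = c(0.90, 0.45),
       alpha_amplitude = 1.0,
       beta_T1_range_s = c(0.4, 0.9),
       beta_T2_range_s = c(0.05, 0.3),
       beta_amplitude_range = c(0.05, 0.25))
}

#' Relaxation components implied by a glycation state
#'
#' @param state list with glycation extent \code{g} (from
#'   \code{glycation_trajectory}).
#' @param pool_config see \code{\link{default_pool_config}}.
#' @return named list of two \code{relaxation_component}s, \code{alpha} and
#'   \code{beta}. Uses the current RNG stream for the beta-pool draw.
#' @export
relaxation_params_from_glycation <- function(state,
                                             pool_config = default_pool_config()) {
  g <- state$g
  if (!is.finite(g) || g < 0 || g > 1)
    stop("g must be in [0, 1]", call. = FALSE)
  pc <- pool_config
  lerp <- function(r, g) r[1] + (r[2] - r[1]) * g
  alpha <- relaxation_component(
    amplitude = pc$alpha_amplitude,
    T1_s = lerp(pc$alpha_T1_range_s, g),
    T2_s = lerp(pc$alpha_T2_range_s, g)
  )
  beta <- relaxation_component(
    amplitude = stats::runif(1, pc$beta_amplitude_range[1],
                             pc$beta_amplitude_range[2]) * pc$alpha_amplitude,
    T1_s = stats::runif(1, pc$beta_T1_range_s[1], pc$beta_T1_range_s[2]),
    T2_s = stats::runif(1, pc$beta_T2_range_s[1], pc$beta_T2_range_s[2])
  )
  list(alpha = alpha, beta = beta)
}

#' Reference assay readouts implied by a glycation state
#'
#' Emulated trends: the free-amino percentage (OPA-style, water blank = 0,
#' unheated control = 100) declines with glycation; absorbance at 294 nm
#' (early Amadori products) rises with an early plateau; absorbance at
#' 420 nm (late melanoidins) rises sharply late (power law); the soluble
#' protein readout declines at half the free-amino rate. Both absorbance
#' channels carry a small instrument blank so reciprocal series are defined
#' at time zero.
#'
#' @param state list with \code{g} and \code{free_amino_fraction}.
#' @param noise_sd sd of additive Gaussian noise on the free-amino
#'   percentage (default 0).
#' @param blank_absorbance instrument blank added to both absorbance
#'   channels (default 0.02).
#' @return a list: \code{opa_pct}, \code{a294}, \code{a420},
#'   \code{lowry_a680}.
#' @export
assay_readouts_from_glycation <- function(state, noise_sd = 0,
                                          blank_absorbance = 0.02) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  g <- state$g
  f <- state$free_amino_fraction
  eps <- if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
  list(
    opa_pct = 100 * f + eps,
    a294 = blank_absorbance + 0.5 * g / (g + 0.2),
    a420 = blank_absorbance + 1.0 * g^2,
    lowry_a680 = 1.0 * (1 - 0.5 * (1 - f))
  )
}

#' Generate the full synthetic study
#'
#' For every arm, time point and replicate: draws the latent glycation
#' state, the alpha/beta relaxation components (beta re-drawn per
#' replicate), simulates SR, CPMG and IR-CPMG acquisitions with additive
#' Gaussian noise (sd = max |signal| / snr), and the assay panel. The latent
#' truth is stored alongside each record for recovery tests.
#'
#' @param design a \code{study_design}.
#' @param sr_grid,cpmg_grid,ircpmg_grid acquisition grids (instrument
#'   defaults).
#' @param kinetics,pool_config generator parameters (see
#'   \code{\link{glycation_trajectory}}, \code{\link{default_pool_config}}).
#' @return an object of class \code{glyco_study}: the design plus a list of
#'   records, each holding \code{sample_id}, \code{temperature_C},
#'   \code{time_h}, \code{replicate}, the latent \code{state} and
#'   \code{components}, the three acquisitions (\code{sr}, \code{cpmg},
#'   \code{ircpmg}) and \code{assays}.
#' @export
generate_study <- function(design = study_design(),
                           sr_grid = default_sr_grid(),
                           cpmg_grid = default_cpmg_grid(),
                           ircpmg_grid = default_ircpmg_grid(),
                           kinetics = default_kinetics(),
                           pool_config = default_pool_config()) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  add_noise <- function(x, snr) {
    if (is.infinite(snr)) return(x)
    x + stats::rnorm(length(x), 0, max(abs(x)) / snr)
  }
  records <- list()
  idx <- 0L
  for (arm in design$arms) {
    for (tp in arm$timepoints_h) {
      for (rep in seq_len(arm$replicates)) {
        idx <- idx + 1L
        state <- glycation_trajectory(arm$temperature_C, tp, kinetics)
        comps <- relaxation_params_from_glycation(state, pool_config)
        sr_sig <- Reduce(`+`, lapply(comps, function(cm)
          sr_signal(sr_grid$times_s, cm$amplitude, cm$T1_s)))
        cpmg_sig <- Reduce(`+`, lapply(comps, function(cm)
          cpmg_signal(cpmg_grid$times_s, cm$amplitude, cm$T2_s)))
        surf_sig <- outer(
          seq_along(ircpmg_grid$tau2_s), seq_along(ircpmg_grid$tau1_s),
          function(i, j) ircpmg_signal(ircpmg_grid$tau1_s[j],
                                       ircpmg_grid$tau2_s[i], comps))
        assays <- assay_readouts_from_glycation(
          state, noise_sd = design$assay_noise_sd)
        sample_id <- sprintf("T%02d_t%06.1f_r%d", arm$temperature_C, tp, rep)
        records[[idx]] <- list(
          sample_id = sample_id,
          temperature_C = arm$temperature_C,
          time_h = tp, replicate = rep,
          state = state, components = comps,
          sr = decay_curve(sr_grid, add_noise(sr_sig, design$snr),
                           meta = list(sample_id = sample_id)),
          cpmg = decay_curve(cpmg_grid, add_noise(cpmg_sig, design$snr),
                             meta = list(sample_id = sample_id)),
          ircpmg = relaxation_surface(
            ircpmg_grid,
            matrix(add_noise(as.numeric(surf_sig), design$snr),
                   nrow = nrow(surf_sig)),
            meta = list(sample_id = sample_id)),
          assays = assays
        )
      }
    }
  }
  structure(list(design = design, records = records), class = "glyco_study")
}

#' @export
print.glyco_study <- function(x, ...) {
  cat("<glyco_study>", length(x$records), "records,",
      length(x$design$arms), "arms, snr =", x$design$snr, "\n")
  invisible(x)
}

#' Study tables
#'
#' Flatten a generated study into data frames: the sample manifest, the
#' assay panel and the latent-truth table (glycation extent, alpha-pool
#' relaxation times and their T2/T1 ratio).
#'
#' @param study a \code{glyco_study}.
#' @return a data frame.
#' @name study_tables
NULL

#' @rdname study_tables
#' @export
study_manifest <- function(study) {
  do.call(rbind, lapply(study$records, function(r)
    data.frame(sample_id = r$sample_id, temperature_C = r$temperature_C,
               time_h = r$time_h, replicate = r$replicate)))
}

#' @rdname study_tables
#' @export
study_assays <- function(study) {
  do.call(rbind, lapply(study$records, function(r)
    data.frame(sample_id = r$sample_id, temperature_C = r$temperature_C,
               time_h = r$time_h, replicate = r$replicate,
               opa_pct = r$assays$opa_pct, a294 = r$assays$a294,
               a420 = r$assays$a420, lowry_a680 = r$assays$lowry_a680)))
}

#' @rdname study_tables
#' @export
study_truth <- function(study) {
  do.call(rbind, lapply(study$records, function(r)
    data.frame(sample_id = r$sample_id, temperature_C = r$temperature_C,
               time_h = r$time_h, replicate = r$replicate,
               g = r$state$g,
               free_amino_fraction = r$state$free_amino_fraction,
               alpha_T1_s = r$components$alpha$T1_s,
               alpha_T2_s = r$components$alpha$T2_s,
               alpha_t2_t1 = r$components$alpha$T2_s /
                 r$components$alpha$T1_s,
               beta_T1_s = r$components$beta$T1_s,
               beta_T2_s = r$components$beta$T2_s,
               beta_amplitude = r$components$beta$amplitude)))
}
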