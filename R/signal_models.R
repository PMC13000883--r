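# Forward relaxation signal models and discretized kernels shared by the
# fitters, the inverse Laplace solvers and the synthetic study generator.

#' Acquisition grid for a pulse sequence
#'
#' Describes the sampling scheme of one of the three supported pulse
#' sequences: saturation recovery (\code{"SR"}, T1 regrowth), the
#' Carr-Purcell-Meiboom-Gill echo train (\code{"CPMG"}, T2 decay), and the
#' inversion-recovery-prepared CPMG (\code{"IRCPMG"}, joint T1-T2 encoding on
#' a tau1 x tau2 grid). All times are stored in seconds.
#'
#' @param sequence_kind one of \code{"SR"}, \code{"CPMG"}, \code{"IRCPMG"}.
#' @param times_s sampling times in seconds (SR recovery delays or CPMG echo
#'   times); strictly increasing, nonnegative. Ignored for IR-CPMG.
#' @param tau1_s inversion-recovery delays in seconds (IR-CPMG only).
#' @param tau2_s echo times in seconds (IR-CPMG only).
#' @param repetition_time_s repetition time in seconds (metadata only).
#' @return an object of class \code{acquisition_grid}.
#' @export
acquisition_grid <- function(sequence_kind, times_s = NULL, tau1_s = NULL,
                             tau2_s = NULL, repetition_time_s = NA_real_) {
  sequence_kind <- match.arg(sequence_kind, c("SR", "CPMG", "IRCPMG"))
  chk_times <- function(t, what) {
    if (length(t) == 0) stop(what, " must be nonempty", call. = FALSE)
    if (any(!is.finite(t)) || any(t < 0))
      stop(what, " must be finite and >= 0", call. = FALSE)
    if (is.unsorted(t, strictly = TRUE))
      stop(what, " must be strictly increasing", call. = FALSE)
    as.numeric(t)
  }
  if (sequence_kind == "IRCPMG") {
    if (is.null(tau1_s) || is.null(tau2_s))
      stop("IR-CPMG grid needs tau1_s and tau2_s", call. = FALSE)
    tau1_s <- chk_times(tau1_s, "tau1_s")
    tau2_s <- chk_times(tau2_s, "tau2_s")
    times_s <- NULL
  } else {
    if (is.null(times_s)) stop("times_s required for ", sequence_kind, call. = FALSE)
    times_s <- chk_times(times_s, "times_s")
    tau1_s <- tau2_s <- NULL
  }
  structure(
    list(sequence_kind = sequence_kind, times_s = times_s,
         tau1_s = tau1_s, tau2_s = tau2_s,
         repetition_time_s = repetition_time_s),
    class = "acquisition_grid"
  )
}

#' @export
print.acquisition_grid <- function(x, ...) {
  cat("<acquisition_grid>", x$sequence_kind, "\n")
  if (x$sequence_kind == "IRCPMG") {
    cat("  tau1:", length(x$tau1_s), "points in [",
        min(x$tau1_s), ",", max(x$tau1_s), "] s\n")
    cat("  tau2:", length(x$tau2_s), "points in [",
        min(x$tau2_s), ",", max(x$tau2_s), "] s\n")
  } else {
    cat(" ", length(x$times_s), "points in [",
        min(x$times_s), ",", max(x$times_s), "] s\n")
  }
  invisible(x)
}

#' Default acquisition grids
#'
#' Grids mirroring the study's instrument settings: saturation recovery with
#' 20 recovery delays (log-spaced, package choice of span); CPMG with 12,500
#' echoes at a 10 ms echo interval (TR 13 s); IR-CPMG with 200 echoes at a
#' 15 ms echo interval and 10 inversion-recovery delays (log-spaced).
#'
#' @return an \code{acquisition_grid}.
#' @name default_grids
NULL

#' @rdname default_grids
#' @export
default_sr_grid <- function() {
  acquisition_grid("SR",
                   times_s = exp(seq(log(0.02), log(10), length.out = 20)),
                   repetition_time_s = NA_real_)
}

#' @rdname default_grids
#' @export
default_cpmg_grid <- function() {
  acquisition_grid("CPMG",
                   times_s = seq_len(12500) * 0.010,
                   repetition_time_s = 13.0)
}

#' @rdname default_grids
#' @export
default_ircpmg_grid <- function() {
  acquisition_grid("IRCPMG",
                   tau1_s = exp(seq(log(0.05), log(10), length.out = 10)),
                   tau2_s = seq_len(200) * 0.015)
}

#' Relaxation component (one proton pool)
#'
#' @param amplitude signal amplitude, >= 0 (arbitrary units).
#' @param T1_s longitudinal relaxation time in seconds, > 0.
#' @param T2_s transverse relaxation time in seconds, > 0.
#' @return an object of class \code{relaxation_component}.
#' @export
relaxation_component <- function(amplitude, T1_s, T2_s) {
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be finite and >= 0", call. = FALSE)
  if (!is.finite(T1_s) || T1_s <= 0) stop("T1_s must be > 0", call. = FALSE)
  if (!is.finite(T2_s) || T2_s <= 0) stop("T2_s must be > 0", call. = FALSE)
  structure(list(amplitude = amplitude, T1_s = T1_s, T2_s = T2_s),
            class = "relaxation_component")
}

#' Saturation-recovery signal
#'
#' Monoexponential longitudinal regrowth after saturation,
#' S(t) = A (1 - exp(-t / T1)). Zero at t = 0, approaching A for t >> T1.
#'
#' @param t recovery delay(s) in seconds, >= 0.
#' @param amplitude equilibrium amplitude A.
#' @param T1_s longitudinal relaxation time in seconds, > 0.
#' @param offset constant baseline added to the signal (default 0; the
#'   monoexponential model is fit without an offset unless requested).
#' @return signal value(s).
#' @export
sr_signal <- function(t, amplitude, T1_s, offset = 0) {
  if (!is.finite(T1_s) || T1_s <= 0)
    stop("T1_s must be > 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  amplitude * (1 - exp(-t / T1_s)) + offset
}

#' CPMG echo-train envelope
#'
#' Monoexponential transverse decay, S(t) = A exp(-t / T2).
#'
#' @param t echo time(s) in seconds, >= 0.
#' @param amplitude initial amplitude A.
#' @param T2_s transverse relaxation time in seconds, > 0.
#' @return signal value(s).
#' @export
cpmg_signal <- function(t, amplitude, T2_s) {
  if (!is.finite(T2_s) || T2_s <= 0)
    stop("T2_s must be > 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  amplitude * exp(-t / T2_s)
}

#' IR-CPMG signal of a multi-component system
#'
#' Inversion-recovery-prepared CPMG amplitude at inversion delay tau1 and
#' echo time tau2:
#' S(tau1, tau2) = sum_i A_i (1 - (1 + f) exp(-tau1 / T1_i)) exp(-tau2 / T2_i)
#' with inversion efficiency f = 1 (ideal) giving the familiar
#' (1 - 2 exp(-tau1/T1)) factor: -A at tau1 = 0, null at tau1 = T1 ln 2.
#'
#' @param tau1 inversion-recovery delay(s) in seconds, >= 0.
#' @param tau2 echo time(s) in seconds, >= 0 (same length as \code{tau1} or
#'   scalar; standard recycling).
#' @param components list of \code{relaxation_component} objects (nonempty).
#' @param inversion_efficiency f in (0, 1]; default 1 (perfect inversion).
#' @return signal value(s).
#' @export
ircpmg_signal <- function(tau1, tau2, components, inversion_efficiency = 1) {
  if (length(components) == 0)
    stop("components must be nonempty", call. = FALSE)
  if (inherits(components, "relaxation_component"))
    components <- list(components)
  if (any(tau1 < 0) || any(tau2 < 0))
    stop("tau1 and tau2 must be >= 0", call. = FALSE)
  f <- inversion_efficiency
  if (!is.finite(f) || f <= 0 || f > 1)
    stop("inversion_efficiency must be in (0, 1]", call. = FALSE)
  s <- 0
  for (cmp in components) {
    s <- s + cmp$amplitude *
      (1 - (1 + f) * exp(-tau1 / cmp$T1_s)) * exp(-tau2 / cmp$T2_s)
  }
  s
}

#' Discretized Fredholm kernel for a pulse sequence
#'
#' Builds the n_times x n_relax matrix mapping a nonnegative amplitude
#' distribution over relaxation times onto the sampled signal. Entry (j, k)
#' is the unit-amplitude kernel at \code{times[j]}, \code{relax_times[k]}:
#' SR uses 1 - exp(-t/T); CPMG uses exp(-t/T); the IR factor (used by the 2D
#' inversion along the tau1 axis) is 1 - (1 + f) exp(-tau1/T).
#'
#' @param grid an \code{acquisition_grid}, or a character sequence kind
#'   combined with \code{times_s}.
#' @param relax_times_s relaxation-time grid in seconds, strictly
#'   increasing, > 0 (typically log-spaced).
#' @param times_s sampling times when \code{grid} is a character kind; for
#'   \code{"IR"} these are tau1 delays.
#' @param inversion_efficiency IR inversion efficiency f (default 1).
#' @return numeric matrix, \code{length(times) x length(relax_times_s)}.
#' @export
build_kernel <- function(grid, relax_times_s, times_s = NULL,
                         inversion_efficiency = 1) {
  if (inherits(grid, "acquisition_grid")) {
    kind <- grid$sequence_kind
    if (kind == "IRCPMG")
      stop("IR-CPMG kernels are built per axis; use kind 'IR' with tau1 ",
           "times and kind 'CPMG' with tau2 times", call. = FALSE)
    times_s <- grid$times_s
  } else {
    kind <- match.arg(grid, c("SR", "CPMG", "IR"))
    if (is.null(times_s)) stop("times_s required", call. = FALSE)
  }
  if (any(relax_times_s <= 0) || is.unsorted(relax_times_s, strictly = TRUE))
    stop("relax_times_s must be strictly increasing and > 0", call. = FALSE)
  rt <- matrix(relax_times_s, nrow = length(times_s),
               ncol = length(relax_times_s), byrow = TRUE)
  tt <- matrix(times_s, nrow = length(times_s), ncol = length(relax_times_s))
  switch(kind,
         SR   = 1 - exp(-tt / rt),
         CPMG = exp(-tt / rt),
         IR   = 1 - (1 + inversion_efficiency) * exp(-tt / rt))
}
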