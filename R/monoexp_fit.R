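# Monoexponential T1/T2 estimation from SR and CPMG decays by
# Levenberg-Marquardt least squares with analytic Jacobians and
# deterministic log-linear initialization.

#' Fit a monoexponential relaxation model
#'
#' \code{fit_t1} estimates (A, T1) from a saturation-recovery curve with
#' model S(t) = A (1 - exp(-t/T1)); \code{fit_t2} estimates (A, T2) from a
#' CPMG echo train with model S(t) = A exp(-t/T2). Both start from a
#' log-linear transform of the data (regression of log(A_plateau - S) or
#' log S on t) and refine by damped least squares with analytic Jacobians
#' (relative SSE tolerance 1e-10, at most 200 iterations).
#'
#' @param curve a \code{decay_curve} of the matching sequence kind with at
#'   least 4 points.
#' @return a \code{relaxation_estimate}: list with \code{value_s} (the
#'   fitted relaxation time, seconds), \code{amplitude},
#'   \code{residual_rms} and \code{converged}.
#' @name monoexp_fit
NULL

new_estimate <- function(value_s, amplitude, residual_rms, converged) {
  structure(list(value_s = unname(value_s), amplitude = unname(amplitude),
                 residual_rms = residual_rms, converged = converged),
            class = "relaxation_estimate")
}

#' @export
print.relaxation_estimate <- function(x, ...) {
  cat(sprintf("<relaxation_estimate> %.6g s (A = %.4g, rms = %.3g, %s)\n",
              x$value_s, x$amplitude, x$residual_rms,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

check_fit_input <- function(curve, kind) {
  stopifnot(inherits(curve, "decay_curve"))
  if (curve$grid$sequence_kind != kind)
    stop("expected a ", kind, " curve", call. = FALSE)
  if (length(curve$signal) < 4)
    stop("need at least 4 points to fit", call. = FALSE)
  if (diff(range(curve$signal)) == 0 || all(curve$signal == 0))
    stop("degenerate curve: signal constant or all zero", call. = FALSE)
}

# Shared Levenberg-Marquardt driver. residfn/jacfn take par = c(A, T).
run_lm <- function(par0, residfn, jacfn) {
  out <- minpack.lm::nls.lm(
    par = par0, fn = residfn, jac = jacfn,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-12, maxiter = 200))
  par <- out$par
  rms <- sqrt(mean(out$fvec^2))
  converged <- out$info %in% 1:4 && is.finite(par[2]) && par[2] > 0
  list(par = par, rms = rms, converged = converged)
}

#' @rdname monoexp_fit
#' @export
fit_t1 <- function(curve) {
  check_fit_input(curve, "SR")
  t <- curve$grid$times_s
  s <- curve$signal
  # log-linear initialization: A_plateau - S ~ A exp(-t/T1)
  a0 <- max(s)
  d <- a0 * 1.05 - s
  keep <- d > 0
  if (sum(keep) >= 2) {
    co <- stats::coef(stats::lm(log(d[keep]) ~ t[keep]))
    T0 <- if (is.finite(co[2]) && co[2] < 0) -1 / co[2] else max(t) / 3
  } else T0 <- max(t) / 3
  par0 <- c(A = a0, T = max(T0, 1e-6))
  residfn <- function(p) s - p[1] * (1 - exp(-t / p[2]))
  jacfn <- function(p) {
    e <- exp(-t / p[2])
    -cbind(1 - e, -p[1] * e * t / p[2]^2)
  }
  fit <- run_lm(par0, residfn, jacfn)
  if (!fit$converged)
    stop("T1 fit did not converge", call. = FALSE)
  new_estimate(fit$par[2], fit$par[1], fit$rms, TRUE)
}

#' @rdname monoexp_fit
#' @export
fit_t2 <- function(curve) {
  check_fit_input(curve, "CPMG")
  t <- curve$grid$times_s
  s <- curve$signal
  # log-linear initialization on the positive early part of the train
  keep <- s > max(s) * 1e-3
  if (sum(keep) >= 2) {
    co <- stats::coef(stats::lm(log(s[keep]) ~ t[keep]))
    A0 <- exp(co[1])
    T0 <- if (is.finite(co[2]) && co[2] < 0) -1 / co[2] else max(t) / 3
  } else {
    A0 <- max(s); T0 <- max(t) / 3
  }
  par0 <- c(A = A0, T = max(T0, 1e-6))
  residfn <- function(p) s - p[1] * exp(-t / p[2])
  jacfn <- function(p) {
    e <- exp(-t / p[2])
    -cbind(e, p[1] * e * t / p[2]^2)
  }
  fit <- run_lm(par0, residfn, jacfn)
  if (!fit$converged)
    stop("T2 fit did not converge", call. = FALSE)
  new_estimate(fit$par[2], fit$par[1], fit$rms, TRUE)
}

#' Fit all decay curves of a study
#'
#' Runs \code{\link{fit_t1}} on every SR curve and \code{\link{fit_t2}} on
#' every CPMG curve of a generated or loaded study.
#'
#' @param study a \code{glyco_study}.
#' @return data frame: sample_id, temperature_C, time_h, replicate, T1_s,
#'   T2_s, residual rms values and convergence flags.
#' @export
fit_study <- function(study) {
  do.call(rbind, lapply(study$records, function(r) {
    f1 <- fit_t1(r$sr)
    f2 <- fit_t2(r$cpmg)
    data.frame(sample_id = r$sample_id, temperature_C = r$temperature_C,
               time_h = r$time_h, replicate = r$replicate,
               T1_s = f1$value_s, T1_rms = f1$residual_rms,
               T2_s = f2$value_s, T2_rms = f2$residual_rms,
               converged = f1$converged && f2$converged)
  }))
}
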