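# Data containers for sampled relaxation data.

#' Sampled 1D relaxation decay
#'
#' A saturation-recovery or CPMG signal sampled on an acquisition grid.
#'
#' @param grid an \code{acquisition_grid} with kind \code{"SR"} or
#'   \code{"CPMG"}.
#' @param signal numeric vector, one value per grid time.
#' @param meta optional named list of metadata (sample id, units, ...).
#' @return an object of class \code{decay_curve}.
#' @export
decay_curve <- function(grid, signal, meta = list()) {
  stopifnot(inherits(grid, "acquisition_grid"))
  if (grid$sequence_kind == "IRCPMG")
    stop("use relaxation_surface() for IR-CPMG data", call. = FALSE)
  if (length(signal) != length(grid$times_s))
    stop("signal length must match grid", call. = FALSE)
  structure(list(grid = grid, signal = as.numeric(signal), meta = meta),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat("<decay_curve>", x$grid$sequence_kind, "-",
      length(x$signal), "points\n")
  invisible(x)
}

#' IR-CPMG signal surface
#'
#' Signal on a tau1 (inversion delay) x tau2 (echo time) grid, stored as an
#' n_tau2 x n_tau1 matrix.
#'
#' @param grid an \code{acquisition_grid} of kind \code{"IRCPMG"}.
#' @param signal numeric matrix, \code{length(tau2_s) x length(tau1_s)}.
#' @param meta optional named list of metadata.
#' @return an object of class \code{relaxation_surface}.
#' @export
relaxation_surface <- function(grid, signal, meta = list()) {
  stopifnot(inherits(grid, "acquisition_grid"),
            grid$sequence_kind == "IRCPMG")
  signal <- as.matrix(signal)
  if (!all(dim(signal) == c(length(grid$tau2_s), length(grid$tau1_s))))
    stop("signal must be length(tau2_s) x length(tau1_s)", call. = FALSE)
  structure(list(grid = grid, signal = signal, meta = meta),
            class = "relaxation_surface")
}

#' @export
print.relaxation_surface <- function(x, ...) {
  cat("<relaxation_surface> IR-CPMG -", nrow(x$signal), "echoes x",
      ncol(x$signal), "inversion delays\n")
  invisible(x)
}

#' Average acquisitions of the unheated control material
#'
#' All time-zero records of a study are replicates of the same unheated
#' control formulation, so their acquisitions can be averaged before
#' inversion: noise shrinks with the square root of the pooled count, which
#' stabilizes the ill-posed relaxation-time spectra used to characterize
#' the control. Curves must share their acquisition grid.
#'
#' @param study a \code{glyco_study}.
#' @param kind which acquisition to pool: \code{"sr"}, \code{"cpmg"} or
#'   \code{"ircpmg"}.
#' @return a \code{decay_curve} or \code{relaxation_surface} averaged over
#'   all records with heating time zero.
#' @export
pool_control <- function(study, kind = c("sr", "cpmg", "ircpmg")) {
  kind <- match.arg(kind)
  recs <- Filter(function(r) r$time_h == 0, study$records)
  if (length(recs) == 0) stop("study has no control records", call. = FALSE)
  if (kind == "ircpmg") {
    S <- Reduce(`+`, lapply(recs, function(r) r$ircpmg$signal)) / length(recs)
    relaxation_surface(recs[[1]]$ircpmg$grid, S,
                       meta = list(pooled = length(recs)))
  } else {
    sig <- rowMeans(vapply(recs, function(r) r[[kind]]$signal,
                           numeric(length(recs[[1]][[kind]]$signal))))
    decay_curve(recs[[1]][[kind]]$grid, sig,
                meta = list(pooled = length(recs)))
  }
}
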