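# Tikhonov-regularized nonnegative inversion of SR/CPMG decays onto a
# log-spaced relaxation-time grid (T1-ILT / T2-ILT), with L-curve selection
# of the regularization weight and peak detection.

#' Default relaxation-time grid
#'
#' @param n number of grid points (default 64).
#' @param range_s span in seconds (default 0.01 to 10 s, covering all
#'   relaxation times observed in heated protein-sugar formulations).
#' @return strictly increasing log-spaced vector.
#' @export
default_relax_grid <- function(n = 64, range_s = c(0.01, 10)) {
  exp(seq(log(range_s[1]), log(range_s[2]), length.out = n))
}

# Solve min ||K x - s||^2 + alpha^2 ||L x||^2 subject to x >= 0 via the
# augmented-system construction [K; alpha L] x ~ [s; 0] and active-set NNLS.
tikhonov_nnls <- function(K, s, alpha, penalty = c("identity", "second_diff")) {
  penalty <- match.arg(penalty)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  n <- ncol(K)
  if (length(s) != nrow(K))
    stop("kernel/signal dimension mismatch", call. = FALSE)
  if (alpha > 0) {
    L <- if (penalty == "identity") diag(n) else second_diff_matrix(n)
    A <- rbind(K, alpha * L)
    b <- c(s, numeric(nrow(L)))
  } else {
    A <- K
    b <- s
  }
  fit <- pracma::lsqnonneg(A, b)
  x <- fit$x
  x[x < 0] <- 0  # guard against active-set round-off
  x
}

second_diff_matrix <- function(n) {
  L <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
  L
}

# Kernel + (possibly subsampled) signal for a 1D decay.
curve_kernel <- function(curve, grid_s, cpmg_subsample = 10) {
  t <- curve$grid$times_s
  s <- curve$signal
  kind <- curve$grid$sequence_kind
  if (kind == "CPMG" && cpmg_subsample > 1 && length(t) > 2000) {
    keep <- seq(1, length(t), by = cpmg_subsample)
    t <- t[keep]; s <- s[keep]
  }
  list(K = build_kernel(kind, grid_s, times_s = t), s = s, t = t)
}

#' 1D inverse Laplace transform of a relaxation decay
#'
#' Inverts an SR or CPMG decay onto a log-spaced relaxation-time grid by
#' Tikhonov-regularized nonnegative least squares:
#' minimize ||K x - s||^2 + alpha^2 ||L x||^2 with x >= 0, solved through
#' the augmented-system active-set construction. The signal is scaled to
#' unit maximum internally so \code{alpha} is comparable across curves;
#' amplitudes are returned on the original scale. Long CPMG trains are
#' subsampled (default every 10th echo) before inversion.
#'
#' @param curve a \code{decay_curve}.
#' @param grid_s relaxation-time grid (strictly increasing, > 0).
#' @param alpha regularization weight (>= 0), relative to unit-max signal.
#' @param penalty \code{"identity"} (zeroth-order Tikhonov, default) or
#'   \code{"second_diff"} (second-difference smoothing).
#' @param cpmg_subsample keep every k-th echo of long CPMG trains
#'   (default 10).
#' @return a \code{relaxation_spectrum}: \code{grid_s}, nonnegative
#'   \code{amplitude}, \code{alpha}, \code{residual_norm}.
#' @export
invert_1d <- function(curve, grid_s = default_relax_grid(), alpha = 0.01,
                      penalty = c("identity", "second_diff"),
                      cpmg_subsample = 10) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(curve, "decay_curve"))
  if (any(grid_s <= 0) || is.unsorted(grid_s, strictly = TRUE))
    stop("grid_s must be strictly increasing and > 0", call. = FALSE)
  ks <- curve_kernel(curve, grid_s, cpmg_subsample)
  smax <- max(abs(ks$s))
  if (smax == 0) {
    x <- numeric(length(grid_s))
  } else {
    x <- smax * tikhonov_nnls(ks$K, ks$s / smax, alpha, penalty)
  }
  structure(list(grid_s = grid_s, amplitude = x, alpha = alpha,
                 residual_norm = sqrt(sum((ks$K %*% x - ks$s)^2))),
            class = "relaxation_spectrum")
}

#' @export
print.relaxation_spectrum <- function(x, ...) {
  cat("<relaxation_spectrum>", length(x$grid_s), "points, alpha =",
      x$alpha, ", residual =", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

#' Choose the Tikhonov regularization weight
#'
#' \code{"fixed"} returns the supplied \code{alpha}. \code{"lcurve"} runs a
#' log-spaced alpha ladder (default 25 values in [1e-5, 10]), records the
#' residual norm and solution norm at each alpha, and returns the ladder
#' point of maximum curvature of the L-curve (log residual vs log solution
#' norm; Menger curvature over consecutive triplets).
#'
#' @param curve a \code{decay_curve}.
#' @param grid_s relaxation-time grid.
#' @param method \code{"fixed"} or \code{"lcurve"}.
#' @param alpha the fixed value (method \code{"fixed"}).
#' @param ladder alpha ladder for the L-curve (>= 4 values).
#' @param ... passed to \code{\link{invert_1d}}.
#' @return selected alpha (scalar).
#' @export
select_alpha <- function(curve, grid_s = default_relax_grid(),
                         method = c("fixed", "lcurve"), alpha = 0.01,
                         ladder = exp(seq(log(1e-5), log(10),
                                          length.out = 25)), ...) {
  method <- match.arg(method)
  if (method == "fixed") return(alpha)
  if (length(ladder) < 4)
    stop("L-curve ladder needs at least 4 points", call. = FALSE)
  ladder <- sort(ladder)
  rho <- eta <- numeric(length(ladder))
  for (i in seq_along(ladder)) {
    sp <- invert_1d(curve, grid_s, alpha = ladder[i], ...)
    rho[i] <- max(sp$residual_norm, 1e-300)
    eta[i] <- max(sqrt(sum(sp$amplitude^2)), 1e-300)
  }
  ladder[lcurve_corner(log(rho), log(eta))]
}

# Index of maximum Menger curvature along the (x, y) polyline.
lcurve_corner <- function(x, y) {
  n <- length(x)
  curv <- rep(-Inf, n)
  for (i in 2:(n - 1)) {
    ax <- x[i] - x[i - 1]; ay <- y[i] - y[i - 1]
    bx <- x[i + 1] - x[i]; by <- y[i + 1] - y[i]
    cross <- ax * by - ay * bx
    la <- sqrt(ax^2 + ay^2); lb <- sqrt(bx^2 + by^2)
    lc <- sqrt((x[i + 1] - x[i - 1])^2 + (y[i + 1] - y[i - 1])^2)
    if (la > 0 && lb > 0 && lc > 0) curv[i] <- 2 * cross / (la * lb * lc)
  }
  which.max(curv)
}

#' Detect peaks in a relaxation spectrum
#'
#' Contiguous runs of grid points with amplitude above
#' \code{threshold_fraction} of the spectrum maximum become peaks. Each
#' peak's center is the amplitude-weighted centroid, its mass fraction the
#' share of total spectral amplitude, and its bounds the run edges extended
#' by half a (log) grid step. Peaks are sorted by mass fraction descending;
#' ties are broken by smaller center first. Peaks with mass fraction below
#' 0.02 are flagged minor.
#'
#' @param spectrum a \code{relaxation_spectrum}.
#' @param threshold_fraction in (0, 1); default 0.05.
#' @return data frame: \code{center_s}, \code{mass_fraction},
#'   \code{low_s}, \code{high_s}, \code{minor}. Zero rows for a zero
#'   spectrum.
#' @export
detect_peaks_1d <- function(spectrum, threshold_fraction = 0.05) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)", call. = FALSE)
  g <- spectrum$grid_s
  a <- spectrum$amplitude
  empty <- data.frame(center_s = numeric(0), mass_fraction = numeric(0),
                      low_s = numeric(0), high_s = numeric(0),
                      minor = logical(0))
  if (all(a <= 0)) return(empty)
  above <- a > threshold_fraction * max(a)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  total <- sum(a)
  half_step <- sqrt(g[2] / g[1])  # log-spaced grid
  rows <- list()
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    m <- sum(a[idx])
    rows[[length(rows) + 1]] <- data.frame(
      center_s = sum(a[idx] * g[idx]) / m,
      mass_fraction = m / total,
      low_s = g[starts[k]] / half_step,
      high_s = g[ends[k]] * half_step)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$mass_fraction, out$center_s), , drop = FALSE]
  rownames(out) <- NULL
  out$minor <- out$mass_fraction < 0.02
  out
}
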