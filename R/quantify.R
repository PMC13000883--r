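# Method-comparison layer: min-max normalization, reciprocal orientation
# against the free-amino (OPA-style) reference, MAE/RMSE/p agreement rows,
# and one-way ANOVA with Tukey post-test.

#' Min-max normalization
#'
#' Maps a series onto [0, 1] by (v - min) / (max - min). Order-preserving
#' and invariant to positive affine rescaling of the input.
#'
#' @param values numeric vector, length >= 2, not all equal.
#' @return normalized vector with min 0 and max 1.
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 2)
    stop("need at least 2 values", call. = FALSE)
  rng <- range(values)
  if (diff(rng) == 0)
    stop("constant series: min-max normalization undefined", call. = FALSE)
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Orient a metric series against a reference
#'
#' Series that move opposite to the reference (negative Spearman rank
#' correlation) are replaced by their elementwise reciprocals, mirroring the
#' use of 1/Browning, 1/Lowry and the reciprocal map ratio in
#' method-agreement tables.
#'
#' @param values numeric metric series.
#' @param reference reference series (same length).
#' @return list: \code{values} (possibly reciprocal), \code{oriented}
#'   (TRUE if the reciprocal was applied).
#' @export
orient_series <- function(values, reference) {
  if (length(values) != length(reference))
    stop("length mismatch", call. = FALSE)
  rho <- stats::cor(values, reference, method = "spearman")
  if (is.finite(rho) && rho < 0) {
    if (any(values == 0))
      stop("zero value: reciprocal undefined", call. = FALSE)
    list(values = 1 / values, oriented = TRUE)
  } else {
    list(values = values, oriented = FALSE)
  }
}

#' Agreement statistics between a metric and the reference
#'
#' Both series are min-max normalized, then compared by mean absolute
#' error, root-mean-square error, and the two-sided significance of their
#' Pearson correlation.
#'
#' @param metric numeric metric series (raw scale).
#' @param reference reference series, same length (>= 3).
#' @param method_name,arm labels carried into the output row.
#' @param normalize min-max normalize both series first (default TRUE); set
#'   FALSE when the inputs are already on a common normalized scale.
#' @return one-row data frame: \code{method}, \code{temperature_C},
#'   \code{p_value}, \code{mae}, \code{rmse}.
#' @export
compare_methods <- function(metric, reference, method_name = "metric",
                            arm = NA, normalize = TRUE) {
  if (length(metric) != length(reference))
    stop("length mismatch", call. = FALSE)
  if (length(metric) < 3)
    stop("need at least 3 paired values", call. = FALSE)
  if (normalize) {
    m <- minmax_normalize(metric)
    r <- minmax_normalize(reference)
  } else {
    m <- metric
    r <- reference
  }
  d <- m - r
  p <- stats::cor.test(m, r, method = "pearson",
                       alternative = "two.sided")$p.value
  data.frame(method = method_name, temperature_C = arm,
             p_value = p, mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' One-way ANOVA with Tukey HSD post-test
#'
#' Computes the one-way ANOVA F statistic and p-value across groups,
#' Tukey's honestly-significant-difference pairwise comparisons at the 0.05
#' level, and a compact letter display (groups sharing a letter are not
#' significantly different).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return list: \code{F}, \code{p}, \code{df}, \code{tukey} (pairwise
#'   adjusted p-values), \code{letters} (named character vector).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs >= 2 values", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  all_values <- unlist(groups, use.names = FALSE)
  if (diff(range(all_values)) == 0)
    stop("all observations identical: ANOVA degenerate", call. = FALSE)
  df <- data.frame(
    value = all_values,
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$group
  padj <- stats::setNames(tk[, "p adj"], rownames(tk))
  letters <- compact_letters(names(groups), padj,
                             means = vapply(groups, mean, 1))
  list(F = an[1, "F value"], p = an[1, "Pr(>F)"],
       df = an[["Df"]], tukey = padj, letters = letters)
}

# Compact letter display by insert-and-absorb: start from one column
# holding every group, split columns on each significant pair, absorb
# subset columns, letter columns in order of decreasing group mean.
compact_letters <- function(group_names, pairwise_padj, means,
                            level = 0.05) {
  k <- length(group_names)
  cols <- list(seq_len(k))
  pairs <- strsplit(names(pairwise_padj), "-", fixed = TRUE)
  for (pidx in seq_along(pairs)) {
    if (pairwise_padj[pidx] >= level) next
    i <- match(pairs[[pidx]][1], group_names)
    j <- match(pairs[[pidx]][2], group_names)
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (all(c(i, j) %in% col)) {
        cols[[ci]] <- setdiff(col, i)
        cols[[length(cols) + 1]] <- setdiff(col, j)
      }
    }
    # absorb columns contained in another column
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] %in% cols[[b]])) keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  ord <- order(vapply(cols, function(c) max(means[c]), 1), decreasing = TRUE)
  cols <- cols[ord]
  out <- vapply(seq_len(k), function(g)
    paste0(letters[which(vapply(cols, function(c) g %in% c, TRUE))],
           collapse = ""), "")
  names(out) <- group_names
  out
}

#' Build the full method-comparison table
#'
#' Assembles the ten candidate glycation metrics - browning absorbance at
#' 420 nm and 294 nm with their reciprocals, fitted T1 and T2, the
#' (T1/T2)_Map and (T2/T1)_Map alpha-pool ratios, and the soluble-protein
#' readout with its reciprocal - for each temperature arm, and compares each
#' (replicate-averaged per time point, min-max normalized per arm) against
#' the free-amino percentage reference of the same arm.
#'
#' @param study a \code{glyco_study} (supplies assay readouts and the
#'   reference).
#' @param fits output of \code{\link{fit_study}}.
#' @param ratios output of \code{\link{pool_ratio_series}}.
#' @return data frame of 10 methods x arms rows: \code{method},
#'   \code{temperature_C}, \code{p_value}, \code{mae}, \code{rmse}.
#' @export
build_comparison_table <- function(study, fits, ratios) {
  assays <- study_assays(study)
  key <- c("temperature_C", "time_h")
  rep_mean <- function(df, var) {
    agg <- stats::aggregate(df[[var]], df[key], mean)
    names(agg)[3] <- "value"
    agg[order(agg$temperature_C, agg$time_h), ]
  }
  series <- list(
    `Browning (420 nm)`   = rep_mean(assays, "a420"),
    `Browning (294 nm)`   = rep_mean(assays, "a294"),
    `T1`                  = rep_mean(fits, "T1_s"),
    `T2`                  = rep_mean(fits, "T2_s"),
    `(T1/T2)Map`          = rep_mean(ratios, "t1_t2_map"),
    `(T2/T1)Map`          = rep_mean(ratios, "t2_t1_map"),
    `Lowry`               = rep_mean(assays, "lowry_a680"))
  # reciprocal forms listed alongside the raw ones
  for (nm in c("Browning (420 nm)", "Browning (294 nm)", "Lowry")) {
    rec <- series[[nm]]
    rec$value <- 1 / rec$value
    series[[paste0("1/", nm)]] <- rec
  }
  ref <- rep_mean(assays, "opa_pct")
  order_methods <- c("Browning (420 nm)", "1/Browning (420 nm)",
                     "Browning (294 nm)", "1/Browning (294 nm)",
                     "T1", "T2", "(T1/T2)Map", "(T2/T1)Map",
                     "Lowry", "1/Lowry")
  arms <- sort(unique(ref$temperature_C))
  rows <- list()
  for (nm in order_methods) {
    for (arm in arms) {
      s <- series[[nm]][series[[nm]]$temperature_C == arm, ]
      r <- ref[ref$temperature_C == arm, ]
      if (nrow(s) == 0 || nrow(s) != nrow(r)) {
        rows[[length(rows) + 1]] <- data.frame(
          method = nm, temperature_C = arm,
          p_value = NA_real_, mae = NA_real_, rmse = NA_real_)
        next
      }
      rows[[length(rows) + 1]] <-
        compare_methods(s$value, r$value, method_name = nm, arm = arm)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
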