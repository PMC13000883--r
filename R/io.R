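# Delimited-text readers/writers for decay curves, IR-CPMG surfaces and
# study directories. All files are comma-separated with '#' comment
# headers; times are stored in seconds unless the header declares ms.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

header_lines <- function(fields) {
  paste0("# ", names(fields), ": ", unlist(fields))
}

parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  out
}

time_factor <- function(unit) {
  switch(unit, s = 1, ms = 1e-3,
         stop("unsupported time unit: ", unit, call. = FALSE))
}

#' Write / read a decay curve or IR-CPMG surface
#'
#' Files are comma-separated with a '#' comment header declaring at least
#' the sequence kind and the time unit (\code{s} or \code{ms}; values are
#' converted to seconds on read). 1D curves have columns \code{time,signal};
#' IR-CPMG surfaces have \code{tau1,tau2,signal} in tau2-fastest order.
#' Numeric round-trip is lossless to better than 1e-12.
#'
#' @param x a \code{decay_curve} or \code{relaxation_surface}.
#' @param path file path.
#' @return \code{read_decay} returns a \code{decay_curve} or
#'   \code{relaxation_surface}; \code{write_decay} returns \code{path}
#'   invisibly.
#' @name decay_io
NULL

#' @rdname decay_io
#' @export
write_decay <- function(x, path) {
  if (inherits(x, "decay_curve")) {
    lines <- c(header_lines(c(list(sequence = x$grid$sequence_kind,
                                   time_unit = "s"), x$meta)),
               "time,signal",
               paste(fmt_num(x$grid$times_s), fmt_num(x$signal), sep = ","))
  } else if (inherits(x, "relaxation_surface")) {
    g <- expand.grid(tau2 = x$grid$tau2_s, tau1 = x$grid$tau1_s)
    lines <- c(header_lines(c(list(sequence = "IRCPMG", time_unit = "s"),
                              x$meta)),
               "tau1,tau2,signal",
               paste(fmt_num(g$tau1), fmt_num(g$tau2),
                     fmt_num(as.numeric(x$signal)), sep = ","))
  } else stop("unsupported object", call. = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname decay_io
#' @export
read_decay <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- parse_header(lines)
  if (is.null(hdr$sequence))
    stop("format error: header missing 'sequence'", call. = FALSE)
  if (is.null(hdr$time_unit))
    stop("format error: header missing 'time_unit'", call. = FALSE)
  fac <- time_factor(hdr$time_unit)
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"))
  meta <- hdr[setdiff(names(hdr), c("sequence", "time_unit"))]
  if (hdr$sequence == "IRCPMG") {
    tau1 <- sort(unique(dat$tau1)) * fac
    tau2 <- sort(unique(dat$tau2)) * fac
    if (nrow(dat) != length(tau1) * length(tau2))
      stop("format error: incomplete tau1 x tau2 grid", call. = FALSE)
    dat <- dat[order(dat$tau1, dat$tau2), ]
    grid <- acquisition_grid("IRCPMG", tau1_s = tau1, tau2_s = tau2)
    relaxation_surface(grid, matrix(dat$signal, nrow = length(tau2)),
                       meta = meta)
  } else {
    if (is.unsorted(dat$time, strictly = TRUE))
      stop("format error: times must be strictly increasing", call. = FALSE)
    grid <- acquisition_grid(hdr$sequence, times_s = dat$time * fac)
    decay_curve(grid, dat$signal, meta = meta)
  }
}

#' Write a data frame as commented CSV
#'
#' Prepends '#' comment lines (seed, config hash, free-form notes) so every
#' output table records its provenance.
#'
#' @param df data frame.
#' @param path file path.
#' @param comments named list written as '# name: value' lines.
#' @return \code{path}, invisibly.
#' @export
write_table_csv <- function(df, path, comments = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(header_lines(comments), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write a generated study to a directory
#'
#' Lays out the study as inspectable delimited text: \code{manifest.csv},
#' \code{assays.csv}, \code{truth.csv} (latent generator state) and one
#' decay file per acquisition under \code{curves/}.
#'
#' @param study a \code{glyco_study}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "curves"), recursive = TRUE,
             showWarnings = FALSE)
  cm <- list(seed = study$design$seed, snr = study$design$snr)
  write_table_csv(study_manifest(study), file.path(dir, "manifest.csv"), cm)
  write_table_csv(study_assays(study), file.path(dir, "assays.csv"), cm)
  write_table_csv(study_truth(study), file.path(dir, "truth.csv"), cm)
  for (r in study$records) {
    base <- file.path(dir, "curves", r$sample_id)
    write_decay(r$sr, paste0(base, "_sr.csv"))
    write_decay(r$cpmg, paste0(base, "_cpmg.csv"))
    write_decay(r$ircpmg, paste0(base, "_ircpmg.csv"))
  }
  invisible(dir)
}

#' Read a study directory back into a \code{glyco_study}
#'
#' Inverse of \code{\link{write_study}}. The latent truth table is attached
#' when present; generator-only fields not needed by the analysis stages
#' are left minimal.
#'
#' @param dir study directory.
#' @return a \code{glyco_study}.
#' @export
read_study <- function(dir) {
  manifest <- read_table_csv(file.path(dir, "manifest.csv"))
  assays <- read_table_csv(file.path(dir, "assays.csv"))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) read_table_csv(truth_path) else NULL
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$sample_id[i]
    base <- file.path(dir, "curves", id)
    a <- assays[assays$sample_id == id, ]
    rec <- list(sample_id = id,
                temperature_C = manifest$temperature_C[i],
                time_h = manifest$time_h[i],
                replicate = manifest$replicate[i],
                sr = read_decay(paste0(base, "_sr.csv")),
                cpmg = read_decay(paste0(base, "_cpmg.csv")),
                ircpmg = read_decay(paste0(base, "_ircpmg.csv")),
                assays = list(opa_pct = a$opa_pct, a294 = a$a294,
                              a420 = a$a420, lowry_a680 = a$lowry_a680))
    if (!is.null(truth)) {
      tr <- truth[truth$sample_id == id, ]
      rec$state <- list(g = tr$g,
                        free_amino_fraction = tr$free_amino_fraction)
    }
    rec
  })
  arms <- lapply(split(manifest, manifest$temperature_C), function(m)
    list(temperature_C = m$temperature_C[1],
         timepoints_h = sort(unique(m$time_h)),
         replicates = max(m$replicate)))
  names(arms) <- NULL
  hdr <- parse_header(readLines(file.path(dir, "manifest.csv"), n = 5))
  design <- study_design(arms,
                         snr = as.numeric(hdr$snr %||% Inf),
                         seed = as.integer(hdr$seed %||% 0))
  structure(list(design = design, records = records),
            class = "glyco_study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
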