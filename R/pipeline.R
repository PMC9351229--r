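#' Per-marker accuracy rows
#'
#' Computes N, MAF and all six accuracy indices for a list of marker
#' records (after exclusions).  Markers with no usable sample get N = 0 and
#' all indices undefined.
#'
#' @param records List of marker records from [read_markers()] /
#'   [apply_exclusions()].
#' @return A data frame with one row per marker, sorted by position
#'   (stable), carrying list-column `leading_values` plus `SNP`,
#'   `position`, `N`, `maf_pct`, `iam_chance`, `iam_hwe`, `hiq`, `info`,
#'   `r2_mach`, `r2_beagle`.
#' @export
accuracy_table <- function(records) {
  n <- length(records)
  N <- integer(n)
  maf <- iamc <- iamh <- hq <- info <- mach <- beagle <- numeric(n)
  for (k in seq_len(n)) {
    s <- marker_stats(records[[k]]$triplets)
    m <- s$triplets
    N[k] <- s$n_used
    maf[k] <- s$maf_pct
    iamc[k] <- iam_index(m, chance_anchor())
    iamh[k] <- if (is.na(s$theta_hat) || s$theta_hat <= 0 || s$theta_hat >= 1)
      NA_real_ else iam_index(m, hwe_anchor(s$theta_hat))
    hq[k] <- hiq(m)
    info[k] <- impute_info(s)
    mach[k] <- mach_r2(s)
    beagle[k] <- beagle_r2(s)
  }
  out <- data.frame(
    SNP = vapply(records, function(r) r$snp_id, character(1)),
    position = vapply(records, function(r) r$position, numeric(1)),
    N = N, maf_pct = maf, iam_chance = iamc, iam_hwe = iamh, hiq = hq,
    info = info, r2_mach = mach, r2_beagle = beagle,
    stringsAsFactors = FALSE)
  out$leading_values <- lapply(records, function(r) r$leading_values)
  out[order(out$position), , drop = FALSE]
}

#' Run the full accuracy pipeline
#'
#' Reads the dosage file named in `config`, applies marker and sample
#' exclusions, computes all per-marker indices, classifies regions and
#' writes the formatted accuracy table to `config$output`.  Progress and
#' the run report go to standard error so the output stays pipe-friendly.
#'
#' @param config A `"dosage_config"` from [dosage_config()] or
#'   [parse_params()].
#' @param quiet Suppress the log messages.
#' @return Invisibly, a list with `table` (the classified accuracy data
#'   frame), `path` (output file) and `report` (counts of markers read,
#'   excluded and written, samples total and excluded, and any warnings).
#' @export
run_accuracy <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "dosage_config"))
  if (is.null(config$input) || !file.exists(config$input))
    stop("input file not found: ", config$input %||% "<missing>")
  warnings_seen <- character(0)
  records <- withCallingHandlers(
    read_markers(config$input, config),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  n_read <- length(records)
  s_total <- if (n_read) nrow(records[[1L]]$triplets) else 0L
  records <- withCallingHandlers(
    apply_exclusions(records, config),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  n_kept <- length(records)
  s_kept <- if (n_kept) nrow(records[[1L]]$triplets) else s_total

  tab <- accuracy_table(records)
  tab <- classify_regions(tab, config$iam_threshold, config$hiq_threshold)
  out_path <- config$output %||%
    paste0(tools::file_path_sans_ext(config$input), ".accuracy")
  write_accuracy_table(tab, out_path, config)

  report <- list(markers_read = n_read,
                 markers_excluded = n_read - n_kept,
                 markers_written = n_kept,
                 samples_total = s_total,
                 samples_excluded = s_total - s_kept,
                 warnings = warnings_seen)
  if (!quiet) {
    message(sprintf(
      "read %d markers (%d samples); excluded %d markers, %d samples; wrote %d rows to %s",
      n_read, s_total, report$markers_excluded, report$samples_excluded,
      n_kept, out_path))
    for (w in warnings_seen) message("warning: ", w)
  }
  invisible(list(table = tab, path = out_path, report = report))
}

#' Plot an accuracy index along the chromosome
#'
#' Scatter of one index against physical position, point area scaled by
#' minor-allele frequency, with a horizontal line at the filtering
#' threshold and vertical lines at the centres of non-COLD regions.
#'
#' @param rows Classified accuracy data frame from [run_accuracy()] or
#'   [classify_regions()].
#' @param index Column to plot: one of "info", "r2_mach", "r2_beagle",
#'   "iam_chance", "iam_hwe", "hiq".
#' @param threshold Horizontal threshold line (defaults to 0.47 for the
#'   Iam pair, 0.97 for hiQ, none otherwise).
#' @param ... Passed on to [graphics::plot()].
#' @return Invisibly, the data frame of plotted points.
#' @export
plot_accuracy_track <- function(rows, index = "info", threshold = NULL, ...) {
  stopifnot(index %in% c("info", "r2_mach", "r2_beagle",
                         "iam_chance", "iam_hwe", "hiq"))
  y <- rows[[index]]
  ok <- !is.na(y)
  if (!any(ok)) {
    warning("all values of '", index, "' are undefined; empty plot")
    graphics::plot(NA, xlim = range(rows$position, na.rm = TRUE),
                   ylim = c(0, 1), xlab = "position (bp)", ylab = index, ...)
    return(invisible(rows[0, ]))
  }
  if (is.null(threshold))
    threshold <- switch(index, iam_chance = , iam_hwe = 0.47, hiq = 0.97, NULL)
  cex <- 0.5 + 1.5 * sqrt(pmax(rows$maf_pct[ok], 0) / 50)
  graphics::plot(rows$position[ok], y[ok], cex = cex, pch = 16,
                 col = grDevices::adjustcolor("steelblue4", 0.7),
                 xlab = "position (bp)", ylab = index, ...)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2, col = "firebrick")
  if (!is.null(rows$Accuracy)) {
    bad <- rows$Accuracy != "COLD"
    if (any(bad, na.rm = TRUE)) {
      ## centre of each maximal run of non-COLD markers
      r <- rle(as.vector(bad))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        centre <- mean(range(rows$position[starts[j]:ends[j]]))
        graphics::abline(v = centre, col = grDevices::adjustcolor("grey40", 0.6))
      }
    }
  }
  invisible(rows[ok, ])
}
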