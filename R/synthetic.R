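#' Specification for simulated dosage data
#'
#' The generator draws true genotypes from Hardy-Weinberg proportions at
#' allele frequency `theta` and blurs each one toward an anchor
#' distribution: posterior = `lam * vertex(true genotype) + (1 - lam) *
#' anchor`.  `lam = 1` gives perfect (degenerate) imputation, `lam = 0`
#' pure anchor noise.  With the chance anchor this model has the exact
#' closed form Iam_chance = `lam^2` for every genotype vector, which the
#' test-suite exploits.
#'
#' @param n_samples Samples per marker.
#' @param theta True counted-allele frequency.
#' @param lam Fidelity in `[0, 1]`.
#' @param anchor "chance" or "hwe".
#' @param n_markers Number of markers.
#' @param seed Random seed; marker `m` uses the deterministic substream
#'   seed `seed + 7919 * m`, so any subset of markers is reproducible.
#' @param positions Optional integer positions (default `1000 * index`).
#' @return A list of class `"sim_spec"`.
#' @export
sim_spec <- function(n_samples = 100L, theta = 0.3, lam = 0.8,
                     anchor = c("chance", "hwe"), n_markers = 1L,
                     seed = 1L, positions = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(n_samples >= 1L, theta >= 0, theta <= 1, lam >= 0, lam <= 1,
            n_markers >= 1L)
  if (is.null(positions)) positions <- 1000L * seq_len(n_markers)
  stopifnot(length(positions) == n_markers)
  structure(list(n_samples = as.integer(n_samples), theta = theta,
                 lam = lam, anchor = anchor,
                 n_markers = as.integer(n_markers), seed = as.integer(seed),
                 positions = positions),
            class = "sim_spec")
}

#' Simulate dosage markers with known ground truth
#'
#' @param spec A `"sim_spec"`.
#' @return A list with one element per marker, each a list holding
#'   `snp_id`, `position`, `leading_values`, `triplets` (n x 3 matrix) and
#'   `genotype` (the true genotype vector).
#' @export
simulate_markers <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  lapply(seq_len(spec$n_markers), function(m) {
    ## independent, reproducible substream per marker
    set.seed((spec$seed + 7919L * m) %% .Machine$integer.max)
    g <- sample(0:2, spec$n_samples, replace = TRUE,
                prob = hwe_anchor(spec$theta))
    anchor <- if (spec$anchor == "chance") chance_anchor()
              else hwe_anchor(spec$theta)
    vertices <- diag(3)[g + 1L, , drop = FALSE]
    triplets <- spec$lam * vertices +
      (1 - spec$lam) * matrix(anchor, spec$n_samples, 3L, byrow = TRUE)
    snp <- sprintf("sim%05d", m)
    list(snp_id = snp, position = spec$positions[[m]],
         leading_values = c(as.character(m), snp,
                            as.character(spec$positions[[m]])),
         triplets = triplets, genotype = g)
  })
}

#' Write marker records as a dosage file
#'
#' Emits the whitespace-delimited dialect read by [read_markers()]:
#' leading columns followed by three probabilities per sample.  Numbers are
#' printed with up to 6 significant digits and no trailing-zero padding, so
#' identical inputs always yield byte-identical files.
#'
#' @param records List of marker records (from [simulate_markers()] or
#'   [read_markers()]).
#' @param path Output path; a ".gz" suffix writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_dosage_file <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (r in records) {
    probs <- as.vector(t(r$triplets))
    probs[is.na(probs)] <- -1
    writeLines(paste(c(r$leading_values, formatC(probs, format = "fg",
                                                 digits = 6)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Materialize the bundled worked example
#'
#' Writes the four files of the documented worked example into `dir`:
#' `test1.imputed` (7 markers x 5 samples, 18 columns),
#' `exclude_SNP.txt` (the three quality-control markers),
#' `exclude_PROBE.txt` (the two external-control samples) and a matching
#' `params.txt`.
#'
#' @param dir Target directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_worked_example <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  input <- c(
    "1 rs00001 913 1 0 0 1 0 0 1 0 0 1 0 0 1 0 0",
    "2 rs00002 402 0.01 0.99 0 0.01 0.99 0 0.01 0.99 0 0.01 0.99 0 0.01 0.99 0",
    "3 rs00003 644 0.333 0.334 0.333 0.333 0.334 0.333 0.333 0.334 0.333 0.333 0.334 0.333 0.333 0.334 0.333",
    "4 rs00004 222 0.25 0.5 0.25 0.25 0.5 0.25 0.25 0.5 0.25 0.25 0.5 0.25 0.25 0.5 0.25",
    "5 rs00005 221 0.47 0.18 0.35 0.89 0.02 0.09 0.03 0.96 0.01 0.94 0 0.06 0.62 0.34 0.04",
    "6 rs00006 955 0.975 0.002 0.023 0.52 0.154 0.326 0.309 0.21 0.481 0.48 0.509 0.011 0.969 0.004 0.027",
    "7 rs00007 518 0.63 0.14 0.23 0.86 0.09 0.05 0.35 0.24 0.41 0.01 0.23 0.76 0.76 0.05 0.19")
  paths <- c(input = file.path(dir, "test1.imputed"),
             markers = file.path(dir, "exclude_SNP.txt"),
             probes = file.path(dir, "exclude_PROBE.txt"),
             params = file.path(dir, "params.txt"))
  writeLines(input, paths[["input"]])
  writeLines(c("rs00001", "rs00003", "rs00004"), paths[["markers"]])
  writeLines(c("1", "2"), paths[["probes"]])
  writeLines(c(paste0("-i", paths[["input"]]),
               "-l3",
               "-c0",
               paste0("-p", paths[["probes"]]),
               paste0("-m", paths[["markers"]]),
               "-nSNP_no,SSSS,PPPPPP"),
             paths[["params"]])
  invisible(paths)
}
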