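#' Run configuration for a dosage-accuracy analysis
#'
#' Collects everything the parameter file / command-line flags control.
#' Mirrors the flag dialect of the input format: `-i` input file, `-l`
#' number of leading columns (>= 3; columns 2 and 3 must hold the marker
#' name and its physical position), `-c` two-probability mode (the third
#' genotype probability is computed as the remainder to 1), `-p` sample
#' ("probe") exclusion file, `-m` marker exclusion file, `-n` comma-separated
#' names for the leading columns.
#'
#' @param input Path to the genotype-probability file (plain text or gzip).
#' @param leading Number of leading (non-probability) columns; at least 3.
#' @param two_prob Logical; if `TRUE` each sample contributes 2 columns and
#'   the third probability is amended as `1 - p0 - p1`.
#' @param probe_exclusions Integer vector of 1-based sample ordinals to
#'   drop, or path of a file with one ordinal per line.
#' @param marker_exclusions Character vector of marker names to drop, or
#'   path of a file with one name per line.
#' @param leading_names Optional character vector of length `leading` with
#'   names for the leading columns; positions 2 and 3 are always overridden
#'   with "SNP" and "position".
#' @param iam_threshold Failure threshold for the Iam pair (default 0.47).
#' @param hiq_threshold Failure threshold for hiQ (default 0.97).
#' @param output Path for the accuracy table; defaults to the input path
#'   with its extension replaced by ".accuracy".
#' @return A list of class `"dosage_config"`.
#' @export
dosage_config <- function(input = NULL, leading = 3L, two_prob = FALSE,
                          probe_exclusions = NULL, marker_exclusions = NULL,
                          leading_names = NULL,
                          iam_threshold = 0.47, hiq_threshold = 0.97,
                          output = NULL) {
  leading <- as.integer(leading)
  if (is.na(leading) || leading < 3L)
    stop("'leading' must be at least 3: the marker name (column 2) and ",
         "position (column 3) columns are mandatory")
  if (!is.null(leading_names) && length(leading_names) != leading)
    stop("'leading_names' must have length ", leading)
  if (iam_threshold < 0 || iam_threshold > 1 ||
      hiq_threshold < 0 || hiq_threshold > 1)
    stop("thresholds must lie in [0, 1]")
  nm <- if (is.null(leading_names)) paste0("lead", seq_len(leading)) else leading_names
  nm[2L] <- "SNP"
  nm[3L] <- "position"
  if (is.null(output) && !is.null(input))
    output <- paste0(tools::file_path_sans_ext(input), ".accuracy")
  structure(list(input = input, leading = leading,
                 two_prob = isTRUE(two_prob),
                 probe_exclusions = probe_exclusions,
                 marker_exclusions = marker_exclusions,
                 leading_names = nm,
                 iam_threshold = iam_threshold,
                 hiq_threshold = hiq_threshold,
                 output = output),
            class = "dosage_config")
}

#' Parse program parameters from flag tokens
#'
#' Understands the flag dialect used both in `params.txt` (one flag per
#' line, value glued to the flag or separated by whitespace) and on the
#' command line: `-i` input, `-l` leading-column count, `-c` 0/1
#' two-probability mode, `-p` probe-exclusion file, `-m` marker-exclusion
#' file, `-n` comma-separated leading-column names, plus the extensions
#' `--out`, `--iam-threshold`, `--hiq-threshold` and `--plot`.
#'
#' When `tokens` is empty and the session is interactive the parameters are
#' prompted for one at a time; non-interactively an input file is required.
#'
#' @param tokens Character vector of flag tokens (e.g.
#'   `c("-i", "test1.imputed", "-l3")`).
#' @return A `"dosage_config"` (with extra element `plot` when requested).
#' @export
parse_params <- function(tokens = character()) {
  tokens <- tokens[nzchar(trimws(tokens))]
  if (length(tokens) == 0L) {
    if (interactive()) return(prompt_params())
    stop("no parameters given and session is not interactive; ",
         "at least -i <input file> is required")
  }
  vals <- list(l = "3", c = "0")
  i <- 1L
  while (i <= length(tokens)) {
    tok <- trimws(tokens[[i]])
    if (startsWith(tok, "--")) {
      key <- sub("^--", "", tok)
      if (!key %in% c("out", "iam-threshold", "hiq-threshold", "plot"))
        stop("unknown flag '--", key, "'")
      if (i == length(tokens)) stop("flag '--", key, "' needs a value")
      vals[[key]] <- tokens[[i + 1L]]
      i <- i + 2L
      next
    }
    if (!startsWith(tok, "-") || nchar(tok) < 2L)
      stop("expected a flag token, got '", tok, "'")
    flag <- substr(tok, 2L, 2L)
    if (!flag %in% c("f", "i", "l", "c", "p", "m", "n"))
      stop("unknown flag '-", flag, "'")
    rest <- substr(tok, 3L, nchar(tok))
    if (nzchar(rest)) {
      val <- rest
      i <- i + 1L
    } else {
      if (i == length(tokens)) stop("flag '-", flag, "' needs a value")
      val <- tokens[[i + 1L]]
      i <- i + 2L
    }
    if (flag == "f") {
      ftoks <- readLines(val, warn = FALSE)
      return(parse_params(c(ftoks, tokens[seq_len(length(tokens))[-seq_len(i - 1L)]])))
    }
    vals[[flag]] <- val
  }
  if (is.null(vals$i)) stop("no input file given (flag -i)")
  cfg <- dosage_config(
    input = vals$i,
    leading = suppressWarnings(as.integer(vals$l)),
    two_prob = identical(trimws(vals$c), "1"),
    probe_exclusions = vals$p,
    marker_exclusions = vals$m,
    leading_names = if (!is.null(vals$n)) trimws(strsplit(vals$n, ",")[[1]]),
    iam_threshold = as.numeric(vals[["iam-threshold"]] %||% 0.47),
    hiq_threshold = as.numeric(vals[["hiq-threshold"]] %||% 0.97),
    output = vals[["out"]]
  )
  if (!is.null(vals$plot)) cfg$plot <- vals$plot
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

prompt_params <- function() {
  ask <- function(q, default = "") {
    ans <- trimws(readline(sprintf("%s [%s]: ", q, default)))
    if (nzchar(ans)) ans else default
  }
  input <- ask("path to input file")
  if (!nzchar(input)) stop("an input file is required")
  dosage_config(
    input = input,
    leading = as.integer(ask("number of leading columns", "3")),
    two_prob = identical(ask("third probability must be computed (0/1)", "0"), "1"),
    probe_exclusions = {
      p <- ask("sample exclusion file (empty for none)"); if (nzchar(p)) p
    },
    marker_exclusions = {
      m <- ask("marker exclusion file (empty for none)"); if (nzchar(m)) m
    }
  )
}

## gzip is detected by the two magic bytes 1f 8b, not by file extension
open_dosage <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b))))
    gzfile(path, "rt")
  else
    file(path, "rt")
}

#' Read a genotype-probability file
#'
#' Parses the whitespace-delimited dosage dialect: one row per marker,
#' `leading` leading columns (column 2 = marker name, column 3 = position),
#' then 2 or 3 probability columns per sample.  Negative values flag that
#' sample's imputation as missing at that marker.  In two-probability mode
#' the third probability is amended as `1 - p0 - p1` (a remainder within
#' 1e-6 below zero is clamped to 0).  Input may be gzip-compressed
#' (detected by magic bytes).
#'
#' The file is consumed in bounded-size chunks, so memory scales with the
#' number of samples, not the number of markers, once each chunk's records
#' are reduced by the caller.
#'
#' @param path Input file path (or open connection).
#' @param config A `"dosage_config"`; alternatively pass `leading` /
#'   `two_prob` directly.
#' @param callback Optional `function(records)` invoked once per chunk with
#'   the list of marker records; when supplied, records are not
#'   accumulated and `invisible(NULL)` is returned.
#' @param chunk_size Number of rows per chunk.
#' @param leading,two_prob Used when `config` is `NULL`.
#' @return A list of marker records unless `callback` is given.  Each
#'   record is a list with `leading_values` (character), `snp_id`,
#'   `position` and `triplets` (numeric `n x 3` matrix, `NA` rows for
#'   missing samples).
#' @export
read_markers <- function(path, config = NULL, callback = NULL,
                         chunk_size = 512L,
                         leading = 3L, two_prob = FALSE) {
  if (!is.null(config)) {
    leading <- config$leading
    two_prob <- config$two_prob
  }
  con <- if (inherits(path, "connection")) path else open_dosage(path)
  on.exit(close(con), add = TRUE)

  out <- if (is.null(callback)) vector("list", 0L)
  n_samples <- NULL
  row_no <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    if (length(lines) == 0L) break
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) next
    recs <- vector("list", length(lines))
    for (k in seq_along(lines)) {
      row_no <- row_no + 1L
      fields <- strsplit(trimws(lines[[k]]), "[ \t]+")[[1]]
      if (length(fields) <= leading)
        stop("row ", row_no, ": only ", length(fields),
             " fields for ", leading, " leading columns")
      kprob <- if (two_prob) 2L else 3L
      nprob <- length(fields) - leading
      if (nprob %% kprob != 0L)
        stop("row ", row_no, ": ", nprob, " probability fields are not a ",
             "multiple of ", kprob, " per sample")
      s <- nprob %/% kprob
      if (is.null(n_samples)) n_samples <- s
      else if (s != n_samples)
        stop("row ", row_no, ": ", s, " samples but previous rows had ",
             n_samples)
      lead_vals <- fields[seq_len(leading)]
      pos <- suppressWarnings(as.numeric(lead_vals[3L]))
      if (is.na(pos) || pos < 0)
        stop("row ", row_no, ": position ('", lead_vals[3L],
             "') is not a non-negative number")
      if (!nzchar(lead_vals[2L]))
        stop("row ", row_no, ": empty marker name")
      probs <- suppressWarnings(as.numeric(fields[-seq_len(leading)]))
      if (anyNA(probs)) {
        bad <- which(is.na(probs))[1L]
        stop("row ", row_no, ", probability column ", bad, " ('",
             fields[leading + bad], "'): not a number")
      }
      pm <- matrix(probs, nrow = s, ncol = kprob, byrow = TRUE)
      missing <- apply(pm < 0, 1L, any)
      if (two_prob) {
        p2 <- 1 - pm[, 1L] - pm[, 2L]
        p2[p2 < 0 & p2 >= -1e-6] <- 0
        pm <- cbind(pm, p2, deparse.level = 0)
      }
      pm[missing, ] <- NA_real_
      recs[[k]] <- list(leading_values = lead_vals,
                        snp_id = lead_vals[2L],
                        position = pos,
                        triplets = pm)
    }
    if (is.null(callback)) out <- c(out, recs) else callback(recs)
  }
  if (row_no == 0L) stop("input file is empty: ",
                         if (is.character(path)) path else "<connection>")
  if (is.null(callback)) out else invisible(NULL)
}

read_exclusion_file <- function(x) {
  if (is.null(x)) return(character(0))
  if (!is.character(x) || length(x) != 1L || !file.exists(x))
    return(as.character(x))
  ln <- trimws(readLines(x, warn = FALSE))
  ln[nzchar(ln)]
}

#' Apply marker and sample exclusions
#'
#' Removes excluded markers (matched exactly by marker name) and blanks out
#' excluded sample columns (1-based ordinals in file order) so that they
#' contribute to no statistic and not to N.
#'
#' @param records List of marker records from [read_markers()].
#' @param config A `"dosage_config"` carrying `marker_exclusions` and
#'   `probe_exclusions` (vectors or file paths).
#' @return The filtered record list.
#' @export
apply_exclusions <- function(records, config) {
  mex <- read_exclusion_file(config$marker_exclusions)
  pex_raw <- read_exclusion_file(config$probe_exclusions)
  pex <- suppressWarnings(as.integer(pex_raw))
  if (anyNA(pex))
    stop("sample exclusion entries must be 1-based integers; got: ",
         paste(pex_raw[is.na(pex)], collapse = ", "))
  if (length(records)) {
    s <- nrow(records[[1L]]$triplets)
    if (length(pex) && (any(pex < 1L) || any(pex > s)))
      stop("sample exclusion ordinal out of range 1..", s)
  }
  if (length(mex)) {
    present <- vapply(records, function(r) r$snp_id, character(1))
    unknown <- setdiff(mex, present)
    if (length(unknown))
      warning("marker exclusion names not found in input: ",
              paste(unknown, collapse = ", "))
    records <- records[!present %in% mex]
  }
  if (length(pex)) {
    records <- lapply(records, function(r) {
      r$triplets <- r$triplets[-pex, , drop = FALSE]
      r
    })
  }
  records
}

## round-half-even to 3 decimals, trim trailing zeros, keep >= 1 decimal;
## undefined values print as the sentinel -97
format_index <- function(x) {
  vapply(x, function(xi) {
    if (is.na(xi)) return("-97")
    ## pre-round at 9 decimals so accumulated floating-point noise cannot
    ## push a value across a decimal rounding boundary
    s <- sprintf("%.3f", round(round(xi, 9), 3))
    s <- sub("0+$", "", s)
    if (endsWith(s, ".")) s <- paste0(s, "0")
    s
  }, character(1))
}

format_maf <- function(x) {
  ifelse(is.na(x), "-97", sprintf("%.1f", round(round(x, 9), 1)))
}

#' Write the per-marker accuracy table
#'
#' Emits the tab-separated table with the leading columns (columns 2 and 3
#' renamed "SNP" and "position"), then N, MAF (%), Iam_chance_, Iam_HWE_,
#' hiQ, Accuracy, Info, r2_MACH and r2_Beagle.  Rows are sorted by position
#' (stable, so input order breaks ties).  Indices are printed with 3
#' decimals, trailing zeros trimmed but at least one decimal kept; MAF with
#' 1 decimal; undefined values as the sentinel -97.
#'
#' @param rows Accuracy data frame from [accuracy_table()] (with the
#'   `Accuracy` labels already filled in by [classify_regions()]).
#' @param path Output file path.
#' @param config A `"dosage_config"` supplying the leading-column names.
#' @return Invisibly, the formatted character matrix that was written.
#' @export
write_accuracy_table <- function(rows, path, config) {
  lead_names <- config$leading_names
  ord <- order(rows$position)   # stable in R
  rows <- rows[ord, , drop = FALSE]
  lead <- do.call(rbind, lapply(rows$leading_values, function(x) x))
  if (is.null(lead)) lead <- matrix(character(0), 0L, config$leading)
  tab <- cbind(lead,
               as.character(rows$N),
               format_maf(rows$maf_pct),
               format_index(rows$iam_chance),
               format_index(rows$iam_hwe),
               format_index(rows$hiq),
               as.character(rows$Accuracy),
               format_index(rows$info),
               format_index(rows$r2_mach),
               format_index(rows$r2_beagle))
  colnames(tab) <- c(lead_names, "N", "MAF (%)", "Iam_chance_", "Iam_HWE_",
                     "hiQ", "Accuracy", "Info", "r2_MACH", "r2_Beagle")
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  if (nrow(tab))
    writeLines(apply(tab, 1L, paste, collapse = "\t"), con)
  invisible(tab)
}
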