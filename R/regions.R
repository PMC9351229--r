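#' Regional cold/tepid/hot/very-hot accuracy classification
#'
#' Assigns each marker a label describing local enrichment of poorly
#' imputed markers.  A marker first gets a score: the number of its
#' anchor-based indices failing their thresholds (Iam_chance and Iam_HWE
#' below `iam_threshold`, hiQ below `hiq_threshold`; an undefined index
#' counts as failing).  Scores map to labels COLD (0), TEPID (1) and HOT
#' (2 or 3).  A run of at least `very_hot_run` consecutive HOT markers, each
#' within `window_bp` of the next, is upgraded to VERY_HOT, marking a
#' segment of massively inaccurate imputation.  An isolated marker
#' therefore keeps the label implied by its own indices and can never be
#' VERY_HOT.
#'
#' @param rows Accuracy data frame (one row per marker) with columns
#'   `position`, `iam_chance`, `iam_hwe`, `hiq`; must be sorted by
#'   position.
#' @param iam_threshold,hiq_threshold Failure thresholds (defaults 0.47
#'   and 0.97).
#' @param very_hot_run Minimum length of a HOT run for the VERY_HOT
#'   upgrade (default 3).
#' @param window_bp Maximum base-pair gap between consecutive run members
#'   (default 10000).
#' @return `rows` with an `Accuracy` factor column (levels COLD < TEPID <
#'   HOT < VERY_HOT).
#' @export
classify_regions <- function(rows, iam_threshold = 0.47, hiq_threshold = 0.97,
                             very_hot_run = 3L, window_bp = 10000) {
  lv <- c("COLD", "TEPID", "HOT", "VERY_HOT")
  if (nrow(rows) == 0L) {
    rows$Accuracy <- factor(character(0), levels = lv, ordered = TRUE)
    return(rows)
  }
  if (is.unsorted(rows$position))
    stop("'rows' must be sorted by position")
  fails <- function(x, thr) is.na(x) | x < thr
  score <- fails(rows$iam_chance, iam_threshold) +
    fails(rows$iam_hwe, iam_threshold) +
    fails(rows$hiq, hiq_threshold)
  lab <- ifelse(score == 0L, "COLD", ifelse(score == 1L, "TEPID", "HOT"))

  ## upgrade sufficiently long, sufficiently dense runs of HOT markers
  hot <- lab == "HOT"
  if (any(hot)) {
    gap_ok <- c(TRUE, diff(rows$position) <= window_bp)
    run_id <- cumsum(!(hot & c(FALSE, hot[-length(hot)]) & gap_ok[seq_along(hot)]))
    for (id in unique(run_id[hot])) {
      members <- which(run_id == id & hot)
      if (length(members) >= very_hot_run) lab[members] <- "VERY_HOT"
    }
  }
  rows$Accuracy <- factor(lab, levels = lv, ordered = TRUE)
  rows
}
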