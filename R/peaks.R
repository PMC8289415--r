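#' Accessibility peak-calling parameters
#'
#' A deliberately transparent global-threshold caller: smooth the track
#' with a centred moving average, call maximal runs above
#' `mean + k_sigma * max(sd, sigma_floor)` (both computed on the smoothed
#' track), drop short runs and merge nearby ones. All knobs are exposed.
#'
#' @param smooth_bp moving-average width in bp (default 75).
#' @param k_sigma threshold in SDs above the mean (default 3).
#' @param sigma_floor lower bound on the SD used in the threshold, so that
#'   near-constant tracks are not called wall-to-wall (default 1.0).
#' @param min_width_bp minimum peak width (default 100).
#' @param merge_gap_bp merge peaks separated by at most this many bp
#'   (default 50).
#' @return a `peak_params` list.
#' @export
peak_params <- function(smooth_bp = 75, k_sigma = 3, sigma_floor = 1.0,
                        min_width_bp = 100, merge_gap_bp = 50) {
  stopifnot(smooth_bp > 0, k_sigma > 0, sigma_floor > 0, min_width_bp > 0,
            merge_gap_bp > 0)
  structure(list(smooth_bp = as.integer(smooth_bp), k_sigma = k_sigma,
                 sigma_floor = sigma_floor,
                 min_width_bp = as.integer(min_width_bp),
                 merge_gap_bp = as.integer(merge_gap_bp)),
            class = "peak_params")
}

#' Call accessibility peaks on a coverage track
#'
#' @param track tibble with columns `pos` (0-based, per-base, contiguous)
#'   and `coverage`; scaffold taken from the `scaffold` attribute or column.
#' @param params a [peak_params()].
#' @return interval tibble (`scaffold`, `start`, `end`, `score` = maximum
#'   smoothed coverage inside the peak), sorted and non-overlapping.
#' @export
call_peaks <- function(track, params = peak_params()) {
  stopifnot(all(c("pos", "coverage") %in% names(track)))
  if (!nrow(track)) abort("empty coverage track")
  scaffold <- if ("scaffold" %in% names(track)) track$scaffold[1]
              else attr(track, "scaffold") %||% "track"
  y <- moving_average(track$coverage, params$smooth_bp)
  thr <- mean(y) + params$k_sigma * max(sd(y), params$sigma_floor)
  hi <- y >= thr
  runs <- rle(hi)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  if (!length(keep)) return(empty_peaks())
  iv <- tibble::tibble(scaffold = scaffold,
                       start = track$pos[starts[keep]],
                       end = track$pos[ends[keep]] + 1)
  iv <- merge_intervals(iv, gap = params$merge_gap_bp)
  iv <- iv[iv$end - iv$start >= params$min_width_bp, ]
  if (!nrow(iv)) return(empty_peaks())
  iv$score <- vapply(seq_len(nrow(iv)), function(k) {
    max(y[track$pos >= iv$start[k] & track$pos < iv$end[k]])
  }, numeric(1))
  iv
}

empty_peaks <- function() {
  genomic_intervals(character(), numeric(), numeric(), numeric())
}

# centred moving average with edge windows normalized by actual coverage
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  half <- width %/% 2
  k <- 2 * half + 1
  csum <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (csum[hi + 1] - csum[lo]) / (hi - lo + 1)
}

#' Nominate candidate CREs from association and accessibility evidence
#'
#' Returns accessibility peaks having at least 1 bp overlap with any
#' high-association interval, annotated with the best overlapping
#' association score — the integration step that turns two independent
#' evidence tracks into CRE candidates.
#'
#' @param assoc association intervals (e.g. [high_weight_intervals()]),
#'   with optional `score`.
#' @param peaks peak intervals from [call_peaks()].
#' @return the nominated peaks with an added `assoc_score` column (`NA`
#'   when `assoc` has no scores).
#' @export
nominate_cres <- function(assoc, peaks) {
  validate_intervals(assoc); validate_intervals(peaks)
  hits <- overlap_pairs(peaks, assoc)
  if (!nrow(hits)) {
    out <- peaks[integer(), ]
    out$assoc_score <- numeric()
    return(out)
  }
  nominated <- sort(unique(hits$query_idx))
  out <- peaks[nominated, ]
  out$assoc_score <- vapply(nominated, function(i) {
    j <- hits$subject_idx[hits$query_idx == i]
    if ("score" %in% names(assoc)) max(assoc$score[j]) else NA_real_
  }, numeric(1))
  out
}
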