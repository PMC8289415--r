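#' Alignment scoring parameters
#'
#' Affine-gap scoring for global consensus-sequence alignment. A gap of
#' length L costs `gap_open + L * gap_extend` (the open charge is paid
#' once, on top of the per-base extend — both conventions exist in the
#' wild, so this one is stated explicitly). `N` is neutral: it scores 0
#' against anything.
#'
#' @param match match score (default +1).
#' @param mismatch mismatch score (default -1).
#' @param gap_open gap-opening score (default -5, <= 0).
#' @param gap_extend per-base gap-extension score (default -1, <= 0).
#' @return an `alignment_params` list.
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = -5,
                             gap_extend = -1) {
  stopifnot(match > mismatch, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "alignment_params")
}

#' Optimal global affine-gap alignment
#'
#' Needleman-Wunsch/Gotoh three-state dynamic program over {A,C,G,T,N}.
#' Traceback ties are resolved deterministically (match over deletion-in-B
#' over insertion-in-B) and gap runs are then left-normalized: every indel
#' is shifted to the smallest sequence-A coordinate among equal-scoring
#' placements, so reported positions are reproducible.
#'
#' @param seq_a,seq_b nonempty character strings over A/C/G/T/N.
#' @param params an [alignment_params()].
#' @return object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score` and `params`.
#' @examples
#' global_align("ACGTACGT", "ACGTCGT")
#' @export
global_align <- function(seq_a, seq_b, params = alignment_params()) {
  check_seq(seq_a); check_seq(seq_b)
  res <- .gotoh_align(seq_a, seq_b, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  rows <- left_normalize(strsplit(res$aligned_a, "")[[1]],
                         strsplit(res$aligned_b, "")[[1]])
  structure(list(aligned_a = paste(rows$a, collapse = ""),
                 aligned_b = paste(rows$b, collapse = ""),
                 score = res$score, params = params),
            class = "pairwise_alignment")
}

check_seq <- function(s) {
  if (!is.character(s) || length(s) != 1 || !nzchar(s))
    abort("sequences must be nonempty single strings")
  if (grepl("[^ACGTN]", s)) abort("sequences may only contain A/C/G/T/N")
}

# shift each gap run as far left as score-neutrality allows. Moving a run
# [c1, c2] one column left only relocates the flanking gapped-row character
# from c1-1 to c2 (the opposing row is unchanged), which preserves the
# score exactly when the opposing character at c1-1 equals the one at c2.
left_normalize <- function(a, b) {
  shift_runs <- function(g, o) {
    r <- rle(g == "-")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      c1 <- starts[k]; c2 <- ends[k]
      while (c1 > 1 && g[c1 - 1] != "-" && o[c1 - 1] != "-" &&
             o[c1 - 1] == o[c2]) {
        g[c2] <- g[c1 - 1]
        g[c1 - 1] <- "-"
        c1 <- c1 - 1; c2 <- c2 - 1
      }
    }
    g
  }
  a <- shift_runs(a, b)
  b <- shift_runs(b, a)
  list(a = a, b = b)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %g, %d columns\n",
              x$score, nchar(x$aligned_a)))
  wrap <- function(s) substr(s, 1, min(60, nchar(s)))
  cat(" A: ", wrap(x$aligned_a), if (nchar(x$aligned_a) > 60) "..." , "\n", sep = "")
  cat(" B: ", wrap(x$aligned_b), if (nchar(x$aligned_b) > 60) "..." , "\n", sep = "")
  invisible(x)
}

#' Call indels from a pairwise alignment
#'
#' Maximal gap runs in either row, reported in sequence-A coordinates: a
#' gap run in B is a deletion-in-B spanning A bases; a gap run in A is an
#' insertion-in-B at an A position. This is the operation that turns a
#' reference/carrier consensus alignment into genotyped TE-sized indels.
#'
#' @param alignment a [global_align()] result.
#' @param min_len suppress runs shorter than this (default 1).
#' @return tibble `type` (`"insertion_in_B"`/`"deletion_in_B"`), `pos_a`
#'   (0-based on sequence A: first deleted base, or the base before which
#'   the insertion sits), `length`.
#' @export
call_indels <- function(alignment, min_len = 1) {
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  acoord <- cumsum(a != "-")  # A bases consumed up to and including column
  calls <- list()
  for (row in c("a", "b")) {
    g <- if (row == "a") a else b
    r <- rle(g == "-")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      len <- r$lengths[k]
      if (len < min_len) next
      if (row == "b") {
        calls[[length(calls) + 1]] <- tibble::tibble(
          type = "deletion_in_B", pos_a = acoord[starts[k]] - 1, length = len)
      } else {
        calls[[length(calls) + 1]] <- tibble::tibble(
          type = "insertion_in_B", pos_a = acoord[starts[k]], length = len)
      }
    }
  }
  out <- dplyr::bind_rows(calls)
  if (!nrow(out))
    out <- tibble::tibble(type = character(), pos_a = numeric(),
                          length = integer())
  dplyr::arrange(out, .data$pos_a, .data$type)
}

#' Windowed alignment identity track
#'
#' Fraction of identical (match) columns per window of sequence-A
#' coordinates; gap columns count as mismatches. Columns inserted in B
#' (gaps in A) are attributed to the A position before which they sit.
#' Intervals at or above `threshold` give the cross-species identity bars.
#'
#' @param alignment a [global_align()] result.
#' @param window_bp window size in A coordinates (default 100).
#' @param threshold identity threshold for reported intervals (default 0.75).
#' @param scaffold name for the returned intervals (default `"seq_a"`).
#' @return list with `track` (tibble `window_id`, `start`, `end`,
#'   `n_columns`, `identity`) and `intervals` (merged windows with
#'   identity >= threshold).
#' @export
windowed_identity <- function(alignment, window_bp = 100, threshold = 0.75,
                              scaffold = "seq_a") {
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  len_a <- sum(a != "-")
  acoord <- cumsum(a != "-")                # 1-based A position per column
  pos0 <- ifelse(a != "-", acoord - 1, pmin(acoord, len_a - 1))
  match_col <- a != "-" & b != "-" & a == b
  track <- tibble::tibble(pos0 = pos0, match = match_col) |>
    dplyr::mutate(window_id = .data$pos0 %/% window_bp) |>
    dplyr::group_by(.data$window_id) |>
    dplyr::summarise(n_columns = dplyr::n(), identity = mean(.data$match),
                     .groups = "drop") |>
    dplyr::mutate(start = .data$window_id * window_bp,
                  end = pmin(.data$start + window_bp, len_a)) |>
    dplyr::select("window_id", "start", "end", "n_columns", "identity")
  hi <- track[track$identity >= threshold, ]
  intervals <- if (nrow(hi))
    merge_intervals(genomic_intervals(scaffold, hi$start, hi$end))
  else genomic_intervals(character(), numeric(), numeric())
  list(track = track, intervals = intervals)
}
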