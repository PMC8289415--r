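#' Genomic intervals as tibbles
#'
#' Throughout the package an interval set is an ordinary tibble with columns
#' `scaffold` (character), `start`, `end` (0-based, half-open, `start < end`)
#' and optionally `score`. `genomic_intervals()` builds and validates one.
#'
#' @param scaffold scaffold/chromosome identifiers (recycled).
#' @param start,end 0-based half-open coordinates.
#' @param score optional numeric score.
#' @return a tibble with columns `scaffold`, `start`, `end` and, if supplied,
#'   `score`, sorted by scaffold and start.
#' @examples
#' genomic_intervals("chr15", c(0, 100), c(50, 200))
#' @export
genomic_intervals <- function(scaffold, start, end, score = NULL) {
  x <- tibble::tibble(scaffold = as.character(scaffold),
                      start = as.numeric(start), end = as.numeric(end))
  if (!is.null(score)) x$score <- as.numeric(score)
  validate_intervals(x)
  dplyr::arrange(x, .data$scaffold, .data$start)
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("scaffold", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$start < 0 | x$end <= x$start))
    abort("intervals must satisfy 0 <= start < end")
  invisible(x)
}

as_iranges <- function(x) {
  # IRanges is 1-based closed; shift the half-open starts by one
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

from_iranges <- function(ir, scaffold) {
  tibble::tibble(scaffold = scaffold,
                 start = IRanges::start(ir) - 1,
                 end = as.numeric(IRanges::end(ir)))
}

#' Intersect two interval sets
#'
#' Standard half-open intersection, computed per scaffold. `[0,50)` and
#' `[50,100)` do not intersect.
#'
#' @param a,b interval tibbles (see [genomic_intervals()]).
#' @return tibble of intersection intervals.
#' @export
intersect_intervals <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  out <- lapply(intersect(unique(a$scaffold), unique(b$scaffold)), function(sc) {
    ia <- as_iranges(a[a$scaffold == sc, ])
    ib <- as_iranges(b[b$scaffold == sc, ])
    from_iranges(IRanges::intersect(ia, ib), sc)
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(genomic_intervals(character(), numeric(), numeric()))
  dplyr::arrange(res, .data$scaffold, .data$start)
}

#' Merge overlapping or book-ended intervals
#'
#' @param x interval tibble.
#' @param gap merge intervals separated by at most `gap` bp (default 0:
#'   only overlapping/book-ended runs merge).
#' @return merged interval tibble.
#' @export
merge_intervals <- function(x, gap = 0) {
  validate_intervals(x)
  if (!nrow(x)) return(x[c("scaffold", "start", "end")])
  out <- lapply(unique(x$scaffold), function(sc) {
    ir <- IRanges::reduce(as_iranges(x[x$scaffold == sc, ]),
                          min.gapwidth = gap + 1L)
    from_iranges(ir, sc)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$scaffold, .data$start)
}

#' Find overlaps between two interval sets
#'
#' @param query,subject interval tibbles.
#' @return tibble of index pairs (`query_idx`, `subject_idx`, 1-based row
#'   numbers) and the overlap width in bp.
#' @export
overlap_pairs <- function(query, subject) {
  validate_intervals(query); validate_intervals(subject)
  res <- list()
  for (sc in intersect(unique(query$scaffold), unique(subject$scaffold))) {
    qi <- which(query$scaffold == sc); si <- which(subject$scaffold == sc)
    hits <- IRanges::findOverlaps(as_iranges(query[qi, ]), as_iranges(subject[si, ]))
    if (!length(hits)) next
    ov <- IRanges::width(IRanges::pintersect(
      as_iranges(query[qi, ])[S4Vectors::queryHits(hits)],
      as_iranges(subject[si, ])[S4Vectors::subjectHits(hits)]))
    res[[sc]] <- tibble::tibble(query_idx = qi[S4Vectors::queryHits(hits)],
                                subject_idx = si[S4Vectors::subjectHits(hits)],
                                overlap_bp = ov)
  }
  out <- dplyr::bind_rows(res)
  if (!nrow(out))
    out <- tibble::tibble(query_idx = integer(), subject_idx = integer(),
                          overlap_bp = numeric())
  out
}

#' Read/write BED (0-based half-open, 3 or 5 column)
#'
#' @param path file path.
#' @return `read_bed()`: an interval tibble; columns 4/5, when present, are
#'   kept as `name` and `score`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  names(x)[1:3] <- c("scaffold", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  if (ncol(x) >= 5) names(x)[5] <- "score"
  validate_intervals(x)
  tibble::as_tibble(x)
}

#' @rdname read_bed
#' @param x interval tibble.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- c("scaffold", "start", "end")
  if ("name" %in% names(x)) cols <- c(cols, "name")
  if (all(c("name", "score") %in% names(x))) cols <- c(cols, "score")
  readr::write_tsv(x[cols], path, col_names = FALSE)
  invisible(path)
}
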