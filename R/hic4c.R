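#' Contact matrices as sparse triplet tibbles
#'
#' A binned symmetric Hi-C contact matrix is carried as a sparse tibble of
#' upper-triangle triplets (`bin_i < bin_j`, 0-based; zero cells omitted)
#' with attributes `n_bins`, `bin_size` and `scaffold`.
#' `contact_matrix()` validates/normalizes one (symmetrizing and folding
#' duplicate entries), `contact_dense()` densifies it.
#'
#' @param contacts tibble with columns `bin_i`, `bin_j`, `count`.
#' @param n_bins number of bins; default `max(bin) + 1`.
#' @param bin_size bin width in bp (default 5000).
#' @param scaffold scaffold id (default `"unknown"`).
#' @return the validated sparse tibble with attributes set.
#' @export
contact_matrix <- function(contacts, n_bins = NULL, bin_size = 5000,
                           scaffold = "unknown") {
  contacts <- tibble::as_tibble(contacts)
  stopifnot(all(c("bin_i", "bin_j", "count") %in% names(contacts)))
  if (any(contacts$count < 0)) abort("counts must be nonnegative")
  n_bins <- as.integer(n_bins %||% attr(contacts, "n_bins") %||%
                         (max(contacts$bin_i, contacts$bin_j) + 1))
  if (any(contacts$bin_i < 0 | contacts$bin_j >= n_bins))
    abort("bins out of range")
  lo <- pmin(contacts$bin_i, contacts$bin_j)
  hi <- pmax(contacts$bin_i, contacts$bin_j)
  keep <- lo != hi             # diagonal never enters the model
  out <- tibble::tibble(bin_i = lo[keep], bin_j = hi[keep],
                        count = contacts$count[keep]) |>
    dplyr::group_by(.data$bin_i, .data$bin_j) |>
    dplyr::summarise(count = {
      u <- unique(.data$count)
      if (length(u) > 1) abort("asymmetric contact matrix")
      u
    }, .groups = "drop") |>
    dplyr::arrange(.data$bin_i, .data$bin_j)
  attr(out, "n_bins") <- n_bins
  attr(out, "bin_size") <- as.integer(bin_size %||% 5000)
  attr(out, "scaffold") <- scaffold
  out
}

contact_dense <- function(contacts, n_bins = NULL) {
  n_bins <- as.integer(n_bins %||% attr(contacts, "n_bins") %||%
                         (max(contacts$bin_i, contacts$bin_j) + 1))
  m <- matrix(0, n_bins, n_bins)
  m[cbind(contacts$bin_i + 1, contacts$bin_j + 1)] <- contacts$count
  m[cbind(contacts$bin_j + 1, contacts$bin_i + 1)] <- contacts$count
  m
}

#' Virtual-4C profile at an anchor bin
#'
#' The row of the contact matrix at the anchor: contact counts between the
#' anchor and every other bin, i.e. a one-vs-all view of the matrix.
#'
#' @param contacts a [contact_matrix()] tibble.
#' @param anchor 0-based anchor bin.
#' @return tibble `bin`, `count`, `is_anchor` (the self-bin is reported but
#'   flagged), plus `start`/`end` bp coordinates.
#' @export
virtual_profile <- function(contacts, anchor) {
  n_bins <- attr(contacts, "n_bins") %||% (max(contacts$bin_i, contacts$bin_j) + 1)
  bin_size <- attr(contacts, "bin_size") %||% 5000
  if (anchor < 0 || anchor >= n_bins) abort("anchor bin out of range")
  m <- contact_dense(contacts, n_bins)
  tibble::tibble(bin = seq_len(n_bins) - 1,
                 start = (seq_len(n_bins) - 1) * bin_size,
                 end = seq_len(n_bins) * bin_size,
                 count = m[anchor + 1, ],
                 is_anchor = seq_len(n_bins) - 1 == anchor)
}

#' Empirical distance-decay expectation
#'
#' Per-distance statistics over all unordered bin pairs: the empirical
#' expected distribution that contact tests are evaluated against.
#' Self-distance (d = 0) is excluded.
#'
#' @param contacts a [contact_matrix()] tibble.
#' @param n_bins number of bins when the attribute is absent.
#' @return tibble `distance` (in bins, 1..n_bins-1), `n_pairs`
#'   (= n_bins - d), `total`, `mean`, `median`.
#' @export
expected_by_distance <- function(contacts, n_bins = NULL) {
  n_bins <- as.integer(n_bins %||% attr(contacts, "n_bins") %||%
                         (max(contacts$bin_i, contacts$bin_j) + 1))
  d_obs <- contacts$bin_j - contacts$bin_i
  purrr::map_dfr(seq_len(n_bins - 1), function(d) {
    counts <- contacts$count[d_obs == d]
    n_pairs <- n_bins - d
    full <- c(counts, rep(0, n_pairs - length(counts)))  # omitted zeros
    tibble::tibble(distance = d, n_pairs = n_pairs, total = sum(full),
                   mean = mean(full), median = stats::median(full))
  })
}

#' Contact-enrichment test against the distance-decay background
#'
#' Tests whether the observed contact count between two bins exceeds the
#' empirical expectation at their genomic distance. With `o` the observed
#' count, `T` the total count at that distance and `e` the rounded
#' per-pair mean at that distance, the 2x2 table `[[o, T-o], [e, T-e]]` is
#' evaluated by a two-sided Fisher's exact test; the odds ratio is the
#' sample ratio `(o (T-e)) / (e (T-o))` with a Haldane 0.5 correction when
#' any cell is zero.
#'
#' @param contacts a [contact_matrix()] tibble.
#' @param anchor,target 0-based bins, `anchor != target`.
#' @param expected optional precomputed [expected_by_distance()] (reused
#'   across many tests).
#' @return one-row tibble of class `contact_test`: `anchor`, `target`,
#'   `distance`, `observed`, `expected`, `total`, `odds_ratio`, `p_value`.
#' @export
contact_test <- function(contacts, anchor, target, expected = NULL) {
  if (anchor == target) abort("anchor and target must differ")
  n_bins <- attr(contacts, "n_bins") %||% (max(contacts$bin_i, contacts$bin_j) + 1)
  if (min(anchor, target) < 0 || max(anchor, target) >= n_bins)
    abort("bins out of range")
  if (is.null(expected)) expected <- expected_by_distance(contacts, n_bins)
  d <- abs(anchor - target)
  row <- expected[expected$distance == d, ]
  tot <- row$total
  if (tot == 0) abort("no contacts observed at distance ", d)
  i <- min(anchor, target); j <- max(anchor, target)
  hit <- contacts$bin_i == i & contacts$bin_j == j
  o <- if (any(hit)) contacts$count[hit] else 0
  e <- round(row$mean)
  tab <- matrix(c(o, e, tot - o, tot - e), 2, 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- haldane_or(o, tot - o, e, tot - e)
  out <- tibble::tibble(anchor = anchor, target = target, distance = d,
                        observed = o, expected = e, total = tot,
                        expected_mean = row$mean, expected_median = row$median,
                        odds_ratio = or, p_value = p)
  class(out) <- c("contact_test", class(out))
  out
}

haldane_or <- function(a, b, c_, d) {
  if (min(a, b, c_, d) == 0) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  (a * d) / (c_ * b)
}

#' Contact test between two bp features
#'
#' Maps each feature to the bin containing its midpoint (the bin "centred
#' on" the feature) and runs [contact_test()] on the resulting bin pair —
#' the CRE-vs-promoter enrichment test.
#'
#' @param contacts a [contact_matrix()] tibble.
#' @param cre,promoter bp intervals `c(start, end)` (0-based half-open) or
#'   single-row interval tibbles.
#' @inheritParams contact_test
#' @return as [contact_test()], with `anchor` = CRE bin, `target` =
#'   promoter bin.
#' @export
test_cre_promoter <- function(contacts, cre, promoter, expected = NULL) {
  bin_size <- attr(contacts, "bin_size") %||% 5000
  mid_bin <- function(iv) {
    if (is.data.frame(iv)) iv <- c(iv$start[1], iv$end[1])
    floor(((iv[1] + iv[2]) / 2) / bin_size)
  }
  contact_test(contacts, mid_bin(cre), mid_bin(promoter), expected)
}
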