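#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pairwise alignment into its indel calls
#'
#' @param x a [global_align()] result.
#' @param min_len passed to [call_indels()].
#' @param ... unused.
#' @return tibble of indel calls.
#' @export
tidy.pairwise_alignment <- function(x, min_len = 1, ...) {
  call_indels(x, min_len = min_len)
}

#' One-row alignment summary
#'
#' @param x a [global_align()] result.
#' @param ... unused.
#' @return tibble with `score`, `columns`, `len_a`, `len_b`, `n_match`,
#'   `identity` (matches over columns, gaps counting against) and `n_gap_runs`.
#' @export
glance.pairwise_alignment <- function(x, ...) {
  a <- strsplit(x$aligned_a, "")[[1]]
  b <- strsplit(x$aligned_b, "")[[1]]
  m <- sum(a != "-" & b != "-" & a == b)
  gaps <- call_indels(x)
  tibble::tibble(score = x$score, columns = length(a),
                 len_a = sum(a != "-"), len_b = sum(b != "-"),
                 n_match = m, identity = m / length(a),
                 n_gap_runs = nrow(gaps))
}

#' Tidy/summarise a contact-enrichment test
#'
#' `tidy()` returns the core columns; `glance()` adds the underlying 2x2
#' table cells.
#'
#' @param x a [contact_test()] result.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.contact_test <- function(x, ...) {
  tibble::as_tibble(x)[c("anchor", "target", "distance", "observed",
                         "expected", "odds_ratio", "p_value")]
}

#' @rdname tidy.contact_test
#' @export
glance.contact_test <- function(x, ...) {
  tibble::tibble(observed = x$observed, expected = x$expected,
                 total = x$total, odds_ratio = x$odds_ratio,
                 p_value = x$p_value,
                 table_a = x$observed, table_b = x$total - x$observed,
                 table_c = x$expected, table_d = x$total - x$expected)
}

#' Summarise a topology-weighting profile
#'
#' @param x a [weighting_profile()] result.
#' @param ... unused.
#' @return per-topology tibble: mean/max weight and the number of windows
#'   at or above 0.75.
#' @export
glance.weight_profile <- function(x, ...) {
  x |>
    dplyr::group_by(.data$topology) |>
    dplyr::summarise(n_windows = dplyr::n(), mean_weight = mean(.data$weight),
                     max_weight = max(.data$weight),
                     n_high = sum(.data$weight >= 0.75), .groups = "drop")
}
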