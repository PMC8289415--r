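#' Coverage-drop scanning parameters
#'
#' Thresholds for the phenotype-concordant read-depth drop scan. Depth
#' tracks are expected to arrive pre-filtered (the upstream convention is a
#' mapping-quality cutoff, recorded here as provenance only — no alignments
#' are parsed).
#'
#' @param window_bp tiling window in bp (default 50).
#' @param carrier_max maximum normalized depth for a group to count as a
#'   carrier in a window (default 0.75).
#' @param control_min minimum normalized depth for a non-carrier group
#'   (default 0.90).
#' @param min_windows minimum run length, in windows, for a drop call
#'   (default 3).
#' @param mapq_note documented upstream mapping-quality filter (default 30;
#'   provenance only).
#' @return a `covscan_params` list.
#' @export
covscan_params <- function(window_bp = 50, carrier_max = 0.75,
                           control_min = 0.90, min_windows = 3,
                           mapq_note = 30) {
  stopifnot(window_bp >= 1, carrier_max >= 0, carrier_max < control_min,
            min_windows >= 1)
  structure(list(window_bp = as.integer(window_bp), carrier_max = carrier_max,
                 control_min = control_min, min_windows = as.integer(min_windows),
                 mapq_note = mapq_note),
            class = "covscan_params")
}

#' Windowed median depth per individual
#'
#' Tiles each individual's per-base depth into non-overlapping windows of
#' `window_bp` and takes the median per window (mean of the two central
#' values for even counts). A trailing partial window is kept only when it
#' covers at least half a window.
#'
#' @param depth long tibble with columns `sample_id`, `pos` (0-based,
#'   per-base) and `depth`.
#' @param window_bp window size in bp (default 50).
#' @return tibble `sample_id`, `window_id`, `start`, `end`, `median_depth`.
#' @export
window_medians <- function(depth, window_bp = 50) {
  stopifnot(all(c("sample_id", "pos", "depth") %in% names(depth)))
  if (!nrow(depth)) abort("empty depth profile")
  depth |>
    dplyr::mutate(window_id = .data$pos %/% window_bp) |>
    dplyr::group_by(.data$sample_id, .data$window_id) |>
    dplyr::summarise(start = min(.data$pos), n = dplyr::n(),
                     median_depth = stats::median(.data$depth),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= window_bp / 2) |>
    dplyr::mutate(start = .data$window_id * window_bp,
                  end = .data$start + .data$n) |>
    dplyr::select("sample_id", "window_id", "start", "end", "median_depth")
}

#' Normalize windowed medians by the scaffold mean
#'
#' Divides each individual's window medians by that individual's mean depth
#' over all bases of the scaffold, removing the depth scale so that
#' profiles are comparable across individuals and sequencing runs.
#'
#' @param medians output of [window_medians()].
#' @param depth the per-base depth tibble the medians came from (used for
#'   the per-individual scaffold means), or a named numeric vector of
#'   pre-computed scaffold means.
#' @return `medians` with an added `norm_depth` column.
#' @export
normalize_depth <- function(medians, depth) {
  if (is.numeric(depth)) {
    means <- depth
  } else {
    means <- depth |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(m = mean(.data$depth)) |>
      tibble::deframe()
  }
  if (any(means <= 0))
    abort("scaffold mean depth must be > 0 for every individual")
  if (!all(unique(medians$sample_id) %in% names(means)))
    abort("missing scaffold mean for some individuals")
  dplyr::mutate(medians,
                norm_depth = .data$median_depth / unname(means[.data$sample_id]))
}

#' Per-group mean of normalized window depths
#'
#' @param normalized output of [normalize_depth()].
#' @param group_of named character vector `sample_id -> group`, or a tibble
#'   with columns `sample_id`, `group`.
#' @return tibble `group`, `window_id`, `start`, `end`, `mean_norm`, with
#'   every group defined on identical windows.
#' @export
group_mean_depth <- function(normalized, group_of) {
  if (is.data.frame(group_of))
    group_of <- tibble::deframe(group_of[c("sample_id", "group")])
  if (!all(unique(normalized$sample_id) %in% names(group_of)))
    abort("every individual needs a group label")
  out <- normalized |>
    dplyr::mutate(group = unname(group_of[.data$sample_id])) |>
    dplyr::group_by(.data$group, .data$window_id, .data$start, .data$end) |>
    dplyr::summarise(mean_norm = mean(.data$norm_depth), .groups = "drop")
  wins <- out |> dplyr::count(.data$group)
  if (dplyr::n_distinct(wins$n) > 1)
    abort("groups are defined on mismatched windows")
  dplyr::arrange(out, .data$group, .data$window_id)
}

#' Detect phenotype-concordant coverage drops
#'
#' A window is a candidate when the groups split cleanly: a non-empty
#' "carrier" set with mean normalized depth at most `carrier_max`, all
#' remaining groups at least `control_min`, and no group in between.
#' Maximal runs of at least `min_windows` candidate windows with the same
#' carrier set become drop calls. A call is phenotype-concordant when its
#' carrier set is exactly the set of groups of one phenotype — the
#' "explained by phenotype, rather than geography" criterion that separates
#' a shared structural variant from population-specific noise.
#'
#' @param group_profiles output of [group_mean_depth()].
#' @param phenotype_of_group named character vector `group -> phenotype`
#'   (two phenotypes, each with >= 1 group), or a tibble with columns
#'   `group`, `phenotype`.
#' @param params a [covscan_params()].
#' @param scaffold scaffold name for the returned intervals.
#' @return tibble of drop calls: `scaffold`, `start`, `end`,
#'   `carrier_groups` (comma-joined), `carrier_phenotype` (phenotype label
#'   or `NA` when discordant), `concordant`, `carrier_depth`,
#'   `control_depth` (mean normalized depths inside the call) and `score`
#'   (control minus carrier contrast).
#' @export
detect_drops <- function(group_profiles, phenotype_of_group,
                         params = covscan_params(), scaffold = "sim") {
  if (is.data.frame(phenotype_of_group))
    phenotype_of_group <- tibble::deframe(phenotype_of_group[c("group", "phenotype")])
  groups <- sort(unique(group_profiles$group))
  if (!all(groups %in% names(phenotype_of_group)))
    abort("every group needs a phenotype label")
  phen <- phenotype_of_group[groups]
  if (dplyr::n_distinct(phen) != 2)
    abort("exactly two phenotypes required, each with >= 1 group")
  wide <- group_profiles |>
    dplyr::select("group", "window_id", "start", "end", "mean_norm") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean_norm") |>
    dplyr::arrange(.data$window_id)
  m <- as.matrix(wide[groups])
  low <- m <= params$carrier_max
  high <- m >= params$control_min
  candidate <- apply(low | high, 1, all) & rowSums(low) > 0
  carrier_key <- apply(low, 1, function(z) paste(groups[z], collapse = ","))
  carrier_key[!candidate] <- NA_character_
  runs <- rle(carrier_key)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  keep <- which(!is.na(runs$values) & runs$lengths >= params$min_windows)
  if (!length(keep)) return(empty_drop_calls())
  calls <- lapply(keep, function(r) {
    rows <- starts[r]:ends[r]
    carriers <- strsplit(runs$values[r], ",")[[1]]
    controls <- setdiff(groups, carriers)
    pheno_sets <- split(groups, phen)
    hit <- vapply(pheno_sets, setequal, logical(1), y = carriers)
    tibble::tibble(
      scaffold = scaffold,
      start = min(wide$start[rows]), end = max(wide$end[rows]),
      carrier_groups = runs$values[r],
      carrier_phenotype = if (any(hit)) names(pheno_sets)[hit] else NA_character_,
      concordant = any(hit),
      carrier_depth = mean(m[rows, carriers]),
      control_depth = if (length(controls)) mean(m[rows, controls]) else NA_real_,
      score = if (length(controls)) mean(m[rows, controls]) - mean(m[rows, carriers])
              else NA_real_)
  })
  dplyr::bind_rows(calls)
}

empty_drop_calls <- function() {
  tibble::tibble(scaffold = character(), start = numeric(), end = numeric(),
                 carrier_groups = character(), carrier_phenotype = character(),
                 concordant = logical(), carrier_depth = numeric(),
                 control_depth = numeric(), score = numeric())
}

#' One-call coverage-drop scan from per-base depths
#'
#' Convenience composition of [window_medians()], [normalize_depth()],
#' [group_mean_depth()] and [detect_drops()].
#'
#' @inheritParams window_medians
#' @inheritParams group_mean_depth
#' @inheritParams detect_drops
#' @return as [detect_drops()].
#' @export
scan_coverage_drops <- function(depth, group_of, phenotype_of_group,
                                params = covscan_params(), scaffold = "sim") {
  depth |>
    window_medians(params$window_bp) |>
    normalize_depth(depth) |>
    group_mean_depth(group_of) |>
    detect_drops(phenotype_of_group, params, scaffold)
}
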