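#' Read and write haplotype tables
#'
#' The haplotype TSV dialect: one row per sample, first column `sample_id`,
#' remaining columns one per site with the 0-based position as header;
#' missing calls written as `.`.
#'
#' @param path file path.
#' @param groups tibble with `sample_id`, `group` (see
#'   [haplotype_matrix()]); for `read_haplotype_tsv()`, either a tibble or
#'   a groups TSV path.
#' @return `read_haplotype_tsv()`: a [haplotype_matrix()].
#' @export
read_haplotype_tsv <- function(path, groups) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  stopifnot(names(x)[1] == "sample_id")
  alle <- as.matrix(x[, -1])
  rownames(alle) <- x$sample_id
  alle[alle == "."] <- NA_character_
  if (is.character(groups) && length(groups) == 1) groups <- read_groups_tsv(groups)
  haplotype_matrix(alle, as.numeric(colnames(alle)), groups)
}

#' @rdname read_haplotype_tsv
#' @param haps a [haplotype_matrix()].
#' @export
write_haplotype_tsv <- function(haps, path) {
  alle <- haps$alleles
  alle[is.na(alle)] <- "."
  df <- tibble::as_tibble(alle, .name_repair = ~ as.character(haps$positions))
  df <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(haps$alleles)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample/group(/phenotype) table
#'
#' TSV with columns `sample_id`, `group` and optionally `phenotype`.
#'
#' @param path file path.
#' @return tibble.
#' @export
read_groups_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  stopifnot(all(c("sample_id", "group") %in% names(x)))
  x
}

#' Read/write per-base tracks as bedGraph
#'
#' bedGraph is run-length encoded (`chrom start end value`, 0-based
#' half-open); `read_bedgraph()` expands it to the per-base tibble the
#' depth and peak modules consume.
#'
#' @param path file path.
#' @param value_name name for the value column (`"depth"` or `"coverage"`).
#' @return per-base tibble `pos`, `<value_name>` with attribute `scaffold`.
#' @export
read_bedgraph <- function(path, value_name = "coverage") {
  x <- readr::read_tsv(path, col_names = c("scaffold", "start", "end", "value"),
                       show_col_types = FALSE, comment = "#")
  if (dplyr::n_distinct(x$scaffold) > 1)
    abort("one scaffold per bedGraph track expected")
  out <- tibble::tibble(
    pos = unlist(purrr::map2(x$start, x$end, ~ seq(.x, .y - 1))),
    value = rep(x$value, x$end - x$start))
  names(out)[2] <- value_name
  attr(out, "scaffold") <- x$scaffold[1]
  out
}

#' @rdname read_bedgraph
#' @param track per-base tibble with `pos` and a value column.
#' @param scaffold scaffold name; defaults to the track attribute.
#' @export
write_bedgraph <- function(track, path, value_name = "coverage",
                           scaffold = NULL) {
  scaffold <- scaffold %||% attr(track, "scaffold") %||% "track"
  v <- track[[value_name]]
  r <- rle(v)
  ends <- track$pos[cumsum(r$lengths)] + 1
  starts <- c(track$pos[1], head(ends, -1))
  readr::write_tsv(tibble::tibble(scaffold, starts, ends, r$values), path,
                   col_names = FALSE)
  invisible(path)
}

#' Read/write sparse contact matrices
#'
#' Triplet TSV (`bin_i`, `bin_j`, `count`, upper triangle) with a header
#' comment line `# scaffold=<id> bin_size=<bp> n_bins=<n>`.
#'
#' @param path file path.
#' @return a [contact_matrix()] tibble.
#' @export
read_contacts_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- list(scaffold = "unknown", bin_size = 5000, n_bins = NA)
  if (startsWith(hdr, "#")) {
    kv <- strsplit(trimws(sub("^#", "", hdr)), "\\s+")[[1]]
    for (item in kv) {
      p <- strsplit(item, "=")[[1]]
      if (length(p) == 2) meta[[p[1]]] <- p[2]
    }
  }
  x <- readr::read_tsv(path, comment = "#",
                       col_names = c("bin_i", "bin_j", "count"),
                       show_col_types = FALSE)
  contact_matrix(x,
                 n_bins = if (is.na(meta$n_bins)) NULL else as.integer(meta$n_bins),
                 bin_size = as.integer(meta$bin_size),
                 scaffold = meta$scaffold)
}

#' @rdname read_contacts_tsv
#' @param contacts a [contact_matrix()] tibble.
#' @export
write_contacts_tsv <- function(contacts, path) {
  hdr <- sprintf("# scaffold=%s bin_size=%d n_bins=%d",
                 attr(contacts, "scaffold") %||% "unknown",
                 attr(contacts, "bin_size") %||% 5000L,
                 attr(contacts, "n_bins") %||%
                   (max(contacts$bin_i, contacts$bin_j) + 1))
  writeLines(hdr, path)
  readr::write_tsv(contacts[c("bin_i", "bin_j", "count")], path,
                   col_names = FALSE, append = TRUE)
  invisible(path)
}

#' Read/write FASTA sequences
#'
#' Thin wrappers over Biostrings returning/accepting plain named character
#' vectors, the currency of the alignment module.
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read intensity traces from CSV
#'
#' Long format with columns `trace_id`, `intensity` and optionally
#' `scale_type`, as consumed by [batch_spacing()].
#'
#' @param path file path.
#' @return tibble.
#' @export
read_traces_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("trace_id", "intensity") %in% names(x)))
  x
}
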