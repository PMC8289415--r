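#' Enumerate all unrooted group topologies
#'
#' For G group labels there are (2G-5)!! distinct unrooted binary
#' leaf-labelled topologies (1 for G = 3, 3 for G = 4, 15 for G = 5,
#' 105 for G = 6). Each is identified canonically by its set of
#' non-trivial splits, so identical shapes always map to identical ids.
#'
#' @param group_labels character vector of G >= 3 distinct group labels.
#' @return a tibble with one row per topology: `topology` (canonical id,
#'   see [topology_id()]) and `newick` (a display newick string). The
#'   `group_labels` attribute records the label set.
#' @examples
#' enumerate_topologies(c("A", "B", "C", "D"))$topology
#' @export
enumerate_topologies <- function(group_labels) {
  group_labels <- as.character(group_labels)
  g <- length(group_labels)
  if (g < 3) abort("need at least 3 group labels")
  if (anyDuplicated(group_labels)) abort("group labels must be distinct")
  # unrooted topologies on G labels <-> rooted topologies on the first G-1
  # labels, with the last label attached at the root
  rooted <- rooted_shapes(sort(group_labels)[-g])
  last <- sort(group_labels)[g]
  rows <- lapply(rooted, function(tr) {
    splits <- lapply(clades_of(tr), sort)
    splits <- Filter(function(cl) length(cl) >= 2 && length(cl) <= g - 2, splits)
    id <- topology_id_from_splits(splits, sort(group_labels))
    nwk <- paste0("(", shape_newick(tr), ",", last, ");")
    tibble::tibble(topology = id, newick = nwk)
  })
  out <- dplyr::distinct(dplyr::arrange(dplyr::bind_rows(rows), .data$topology))
  stopifnot(nrow(out) == double_factorial(2 * g - 5))
  attr(out, "group_labels") <- sort(group_labels)
  out
}

double_factorial <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

# all rooted binary leaf-labelled shapes on a label set, as nested lists
rooted_shapes <- function(labels) {
  n <- length(labels)
  if (n == 1) return(list(labels))
  out <- list()
  # unordered bipartitions: force labels[1] into the first side
  rest <- labels[-1]
  for (k in 0:(n - 2)) {
    for (idx in combn_list(length(rest), k)) {
      s1 <- c(labels[1], rest[idx])
      s2 <- setdiff(labels, s1)
      for (l in rooted_shapes(s1)) for (r in rooted_shapes(s2))
        out[[length(out) + 1]] <- list(l, r)
    }
  }
  out
}

combn_list <- function(n, k) {
  if (k == 0) return(list(integer()))
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

clades_of <- function(tr) {
  if (!is.list(tr)) return(list(tr))
  l <- clades_of(tr[[1]]); r <- clades_of(tr[[2]])
  c(l, r, list(c(unlist(tr))))
}

shape_newick <- function(tr) {
  if (!is.list(tr)) return(tr)
  kids <- sort(c(shape_newick(tr[[1]]), shape_newick(tr[[2]])))
  paste0("(", paste(kids, collapse = ","), ")")
}

#' Canonical id of a group topology
#'
#' The id is the sorted, semicolon-joined list of non-trivial splits; each
#' split lists the side containing the alphabetically smallest label first
#' and sorts labels within sides (e.g. `"A,B|C,D"`). The star topology on
#' three labels, which has no non-trivial split, is written `"(A,B,C)"`.
#'
#' @param splits list of character vectors, each one side of a split.
#' @param group_labels full label set.
#' @return canonical id string.
#' @export
topology_id <- function(splits, group_labels) {
  topology_id_from_splits(lapply(splits, sort), sort(group_labels))
}

topology_id_from_splits <- function(splits, labels_sorted) {
  if (!length(splits))
    return(paste0("(", paste(labels_sorted, collapse = ","), ")"))
  canon <- vapply(splits, function(side) {
    other <- setdiff(labels_sorted, side)
    sides <- list(sort(side), sort(other))
    if (sides[[2]][1] < sides[[1]][1]) sides <- rev(sides)
    paste0(paste(sides[[1]], collapse = ","), "|", paste(sides[[2]], collapse = ","))
  }, character(1))
  paste(sort(unique(canon)), collapse = ";")
}

# splits of an unrooted phylo as a logical matrix (tips x internal edges);
# entry [i, e] says whether tip i lies on the child side of edge e
tree_split_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  m <- matrix(FALSE, ntip, 0)
  for (p in parts) {
    if (length(p) <= 1 || length(p) >= ntip) next
    col <- rep(FALSE, ntip); col[p] <- TRUE
    m <- cbind(m, col)
  }
  rownames(m) <- tree$tip.label
  m
}

#' Topology induced by one sample per group
#'
#' Restricts a sample tree to one picked leaf per group, suppresses
#' degree-2 nodes and returns the canonical id of the resulting group
#' topology.
#'
#' @param tree an unrooted `phylo` whose tip labels are sample ids.
#' @param picks named character vector: `picks[group] = sample id`.
#' @return canonical topology id string.
#' @export
induced_topology <- function(tree, picks) {
  if (is.null(names(picks)) || any(!nzchar(names(picks))))
    abort("picks must be named by group")
  if (!all(picks %in% tree$tip.label)) abort("picks must be leaves of the tree")
  m <- tree_split_matrix(tree)
  induced_topology_from_splits(m[picks, , drop = FALSE], names(picks))
}

induced_topology_from_splits <- function(mp, groups) {
  g <- length(groups)
  cs <- colSums(mp)
  keep <- which(cs >= 2 & cs <= g - 2)
  splits <- lapply(keep, function(j) sort(groups[mp[, j]]))
  topology_id_from_splits(unique(splits), sort(groups))
}
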