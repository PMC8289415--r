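#' Phased haplotype matrix with group labels
#'
#' The substrate of topology weighting: a samples x sites matrix of phased
#' alleles over {A,C,G,T}, `NA` for missing genotypes, with strictly
#' increasing site positions and a group label per sample.
#'
#' @param alleles character matrix, samples x sites, rownames = sample ids.
#' @param positions numeric vector of 0-based site coordinates, strictly
#'   increasing, one per column.
#' @param groups tibble/data frame with columns `sample_id` and `group`.
#' @return an object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, positions, groups) {
  stopifnot(is.matrix(alleles), !is.null(rownames(alleles)))
  colnames(alleles) <- NULL
  if (length(positions) != ncol(alleles))
    abort("one position per site required")
  if (is.unsorted(positions, strictly = TRUE))
    abort("positions must be strictly increasing")
  ok <- is.na(alleles) | alleles %in% c("A", "C", "G", "T")
  if (!all(ok)) abort("alleles must be A/C/G/T or NA")
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  if (!setequal(groups$sample_id, rownames(alleles)))
    abort("groups must cover exactly the samples in the matrix")
  groups <- groups[match(rownames(alleles), groups$sample_id), ]
  if (any(table(groups$group) < 1)) abort("every group needs >= 1 sample")
  structure(list(alleles = alleles, positions = as.numeric(positions),
                 groups = groups), class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix> %d samples x %d sites, %d groups\n",
              nrow(x$alleles), ncol(x$alleles),
              dplyr::n_distinct(x$groups$group)))
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

#' Sliding-window specification for SNP windows
#'
#' Windows of `size_snps` SNPs advancing by `step_snps`, with the usual
#' usability filter: a window passes when at least `min_sites` of its sites
#' have, in every group, at least `min_genotyped_frac` of that group's
#' samples non-missing.
#'
#' @param size_snps window size in SNPs (default 50).
#' @param step_snps step in SNPs (default 20).
#' @param min_sites minimum usable sites per window (default 10).
#' @param min_genotyped_frac minimum genotyped fraction per group per site
#'   (default 0.5).
#' @return a `window_spec` list.
#' @export
window_spec <- function(size_snps = 50, step_snps = 20, min_sites = 10,
                        min_genotyped_frac = 0.5) {
  stopifnot(step_snps > 0, step_snps <= size_snps,
            min_genotyped_frac > 0, min_genotyped_frac <= 1,
            min_sites <= size_snps)
  structure(list(size_snps = as.integer(size_snps),
                 step_snps = as.integer(step_snps),
                 min_sites = as.integer(min_sites),
                 min_genotyped_frac = min_genotyped_frac),
            class = "window_spec")
}

#' Lay out SNP windows over a haplotype matrix
#'
#' @param haps a [haplotype_matrix()].
#' @param spec a [window_spec()].
#' @return tibble with one row per window: `window_id`, `first_site`,
#'   `last_site` (0-based SNP-index range, half-open as
#'   `[first_site, last_site)`), `start`, `end` (bp span of the window's
#'   site positions, half-open), `n_usable_sites`, `pass`.
#' @export
make_windows <- function(haps, spec = window_spec()) {
  stopifnot(inherits(haps, "haplotype_matrix"), inherits(spec, "window_spec"))
  n_sites <- ncol(haps$alleles)
  starts <- if (n_sites < spec$size_snps) integer()
            else seq(0, n_sites - spec$size_snps, by = spec$step_snps)
  usable <- site_usable(haps, spec$min_genotyped_frac)
  cs <- cumsum(c(0, usable))
  n_ok <- as.integer(cs[starts + spec$size_snps + 1] - cs[starts + 1])
  tibble::tibble(window_id = seq_along(starts),
                 first_site = as.integer(starts),
                 last_site = as.integer(starts + spec$size_snps),
                 start = haps$positions[starts + 1],
                 end = haps$positions[starts + spec$size_snps] + 1,
                 n_usable_sites = n_ok,
                 pass = n_ok >= spec$min_sites)
}

# per-site flag: every group has >= frac of its samples genotyped
site_usable <- function(haps, frac) {
  present <- !is.na(haps$alleles)
  grp <- haps$groups$group
  ok <- rep(TRUE, ncol(present))
  for (g in unique(grp)) {
    rows <- grp == g
    ok <- ok & (colMeans(present[rows, , drop = FALSE]) >= frac)
  }
  ok
}

#' Pairwise normalized Hamming distances
#'
#' Distance between two haplotypes is the mismatch fraction over sites
#' non-missing in both. A pair with no comparable site is an error.
#'
#' @param alleles samples x sites character matrix (`NA` = missing).
#' @return a `dist` object.
#' @export
hamming_dist <- function(alleles) {
  n <- nrow(alleles)
  d <- matrix(0, n, n, dimnames = list(rownames(alleles), rownames(alleles)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- !is.na(alleles[i, ]) & !is.na(alleles[j, ])
    nc <- sum(comp)
    if (nc == 0)
      abort(sprintf("samples %s and %s share no genotyped site",
                    rownames(alleles)[i], rownames(alleles)[j]))
    d[i, j] <- d[j, i] <- sum(alleles[i, comp] != alleles[j, comp]) / nc
  }
  stats::as.dist(d)
}

#' Neighbor-joining tree for a window
#'
#' Builds the window tree by neighbor joining on normalized Hamming
#' distances. Only the topology is consumed downstream; NJ recovers the
#' generating topology exactly whenever the distances are additive.
#'
#' @param haps a [haplotype_matrix()].
#' @param sites optional site-index range `c(first, last)` (0-based,
#'   half-open) selecting the window; default uses all sites.
#' @return an unrooted `phylo`.
#' @export
nj_tree <- function(haps, sites = NULL) {
  alle <- haps$alleles
  if (!is.null(sites)) alle <- alle[, (sites[1] + 1):sites[2], drop = FALSE]
  if (nrow(alle) < 4) abort("need >= 4 samples for an unrooted tree")
  ape::unroot(ape::nj(hamming_dist(alle)))
}

#' Exact topology weighting of a sample tree
#'
#' Enumerates every combination of one sample per group, restricts the tree
#' to each combination, and returns, for each possible group topology, the
#' fraction of combinations inducing it. This is the exhaustive variant and
#' the oracle for [weight_mc()].
#'
#' @param tree unrooted `phylo`, tips = sample ids.
#' @param groups tibble with `sample_id`, `group` covering the tips.
#' @param topology_set optional result of [enumerate_topologies()]; built
#'   from the group labels when absent.
#' @param max_combinations guard on the enumeration size (default 1e6);
#'   above it, use [weight_mc()].
#' @return tibble: `topology`, `count`, `weight` (weights sum to 1 exactly
#'   as a count ratio), with attributes `method = "exact"` and `n_combinations`.
#' @export
weight_exact <- function(tree, groups, topology_set = NULL,
                         max_combinations = 1e6) {
  groups <- tibble::as_tibble(groups)
  members <- split(groups$sample_id, groups$group)
  if (!all(unlist(members) %in% tree$tip.label))
    abort("all grouped samples must be tips of the tree")
  labels <- sort(names(members))
  n_comb <- prod(lengths(members))
  if (n_comb > max_combinations)
    abort("combination count exceeds max_combinations; use weight_mc()")
  if (is.null(topology_set)) topology_set <- enumerate_topologies(labels)
  combos <- as.matrix(expand.grid(members[labels], KEEP.OUT.ATTRS = FALSE,
                                  stringsAsFactors = FALSE))
  ids <- induced_ids(tree, combos, labels)
  tally_weights(ids, topology_set, method = "exact")
}

#' Monte-Carlo topology weighting
#'
#' Uniform independent one-per-group subsampling, the fixed-iteration
#' approximation to [weight_exact()].
#'
#' @inheritParams weight_exact
#' @param n_iter number of subsampling iterations (default 1000).
#' @param seed integer seed; fixed seed gives identical output.
#' @return tibble as in [weight_exact()] with `method = "montecarlo"`.
#' @export
weight_mc <- function(tree, groups, topology_set = NULL, n_iter = 1000,
                      seed = 1) {
  if (n_iter < 1) abort("n_iter must be >= 1")
  groups <- tibble::as_tibble(groups)
  members <- split(groups$sample_id, groups$group)
  labels <- sort(names(members))
  if (is.null(topology_set)) topology_set <- enumerate_topologies(labels)
  combos <- withr::with_seed(seed, {
    vapply(labels, function(g) {
      m <- members[[g]]
      m[sample.int(length(m), n_iter, replace = TRUE)]
    }, character(n_iter))
  })
  if (n_iter == 1) combos <- matrix(combos, nrow = 1, dimnames = list(NULL, labels))
  ids <- induced_ids(tree, combos, labels)
  out <- tally_weights(ids, topology_set, method = "montecarlo")
  attr(out, "seed") <- seed
  out
}

# induced topology id for every row of a picks matrix (columns = groups).
# G = 4 uses the four-point condition on edge-count path distances, which
# resolves every quartet on a binary tree; other G restrict the tree's
# split matrix.
induced_ids <- function(tree, combos, labels) {
  if (length(labels) == 4 && ape::is.binary(tree)) {
    tr <- tree
    tr$edge.length <- rep(1, nrow(tr$edge))
    D <- ape::cophenetic.phylo(tr)
    a <- combos[, 1]; b <- combos[, 2]; c_ <- combos[, 3]; d <- combos[, 4]
    s12 <- D[cbind(a, b)] + D[cbind(c_, d)]   # {1,2}|{3,4}
    s13 <- D[cbind(a, c_)] + D[cbind(b, d)]   # {1,3}|{2,4}
    s14 <- D[cbind(a, d)] + D[cbind(b, c_)]   # {1,4}|{2,3}
    pick <- max.col(-cbind(s12, s13, s14), ties.method = "first")
    ids3 <- c(
      topology_id(list(labels[c(1, 2)]), labels),
      topology_id(list(labels[c(1, 3)]), labels),
      topology_id(list(labels[c(1, 4)]), labels))
    ids3[pick]
  } else {
    m <- tree_split_matrix(tree)
    apply(combos, 1, function(p)
      induced_topology_from_splits(m[p, , drop = FALSE], labels))
  }
}

tally_weights <- function(ids, topology_set, method) {
  counts <- table(factor(ids, levels = topology_set$topology))
  if (any(is.na(match(unique(ids), topology_set$topology))))
    abort("induced topology not in the topology set")
  out <- tibble::tibble(topology = topology_set$topology,
                        count = as.integer(counts),
                        weight = as.integer(counts) / length(ids))
  attr(out, "method") <- method
  attr(out, "n") <- length(ids)
  out
}

#' Sliding-window topology-weighting profile
#'
#' Builds a neighbor-joining tree per passing SNP window and computes
#' topology weights, giving the genomic association profile for a
#' phenotype-grouping hypothesis.
#'
#' @param haps a [haplotype_matrix()].
#' @param spec a [window_spec()].
#' @param topology optional canonical topology id to track; default keeps
#'   all topologies.
#' @param method `"exact"` (default) or `"montecarlo"`.
#' @param n_iter iterations for the Monte-Carlo method.
#' @param seed seed for the Monte-Carlo method.
#' @return long tibble: `window_id`, `start`, `end` (bp span), `topology`,
#'   `weight`, `method`. Windows failing the usability filter are absent.
#' @export
weighting_profile <- function(haps, spec = window_spec(), topology = NULL,
                              method = c("exact", "montecarlo"),
                              n_iter = 1000, seed = 1) {
  method <- match.arg(method)
  windows <- make_windows(haps, spec)
  windows <- windows[windows$pass, ]
  labels <- sort(unique(haps$groups$group))
  topo_set <- enumerate_topologies(labels)
  members <- split(haps$groups$sample_id, haps$groups$group)[labels]
  n_topo <- nrow(topo_set)
  if (method == "exact") {
    if (prod(lengths(members)) > 1e6)
      abort("combination count too large for exact weighting; use montecarlo")
    combos <- as.matrix(expand.grid(members, KEEP.OUT.ATTRS = FALSE,
                                    stringsAsFactors = FALSE))
  }
  W <- matrix(0, nrow(windows), n_topo)
  for (k in seq_len(nrow(windows))) {
    tree <- nj_tree(haps, c(windows$first_site[k], windows$last_site[k]))
    if (method == "montecarlo") {
      combos <- withr::with_seed(seed + windows$window_id[k], {
        vapply(labels, function(g) {
          m <- members[[g]]
          m[sample.int(length(m), n_iter, replace = TRUE)]
        }, character(n_iter))
      })
    }
    ids <- induced_ids(tree, combos, labels)
    W[k, ] <- tabulate(match(ids, topo_set$topology), nbins = n_topo) /
      length(ids)
  }
  out <- tibble::tibble(
    window_id = rep(windows$window_id, each = n_topo),
    start = rep(windows$start, each = n_topo),
    end = rep(windows$end, each = n_topo),
    topology = rep(topo_set$topology, nrow(windows)),
    weight = as.vector(t(W)),
    method = method)
  if (!is.null(topology)) {
    if (!topology %in% topo_set$topology)
      abort("unknown topology id: ", topology)
    out <- out[out$topology == topology, ]
  }
  class(out) <- c("weight_profile", class(out))
  out
}

#' High-weight association intervals
#'
#' Maximal runs of at least `min_windows` consecutive passing windows whose
#' hypothesis weight reaches `threshold`, merged in bp space. These are the
#' candidate association blocks handed to the peak-intersection stage.
#'
#' @param profile a single-topology track from [weighting_profile()] (or a
#'   multi-topology one plus `topology =`).
#' @param threshold minimum weight (default 0.75).
#' @param min_windows minimum run length in windows (default 2).
#' @param topology topology id to extract when `profile` has several.
#' @param scaffold scaffold name for the returned intervals.
#' @return interval tibble with `score` = mean weight over the run.
#' @export
high_weight_intervals <- function(profile, threshold = 0.75, min_windows = 2,
                                  topology = NULL, scaffold = "sim") {
  if (!is.null(topology)) profile <- profile[profile$topology == topology, ]
  if (dplyr::n_distinct(profile$topology) > 1)
    abort("profile covers several topologies; pass `topology =`")
  profile <- dplyr::arrange(profile, .data$window_id)
  hi <- profile$weight >= threshold
  runs <- rle(hi)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values & runs$lengths >= min_windows)
  if (!length(keep))
    return(genomic_intervals(character(), numeric(), numeric(), numeric()))
  iv <- lapply(keep, function(r) {
    rows <- profile[starts[r]:ends[r], ]
    tibble::tibble(scaffold = scaffold, start = min(rows$start),
                   end = max(rows$end), score = mean(rows$weight))
  })
  merge_scored(dplyr::bind_rows(iv))
}

# merge overlapping scored intervals, keeping the max score
merge_scored <- function(x) {
  merged <- merge_intervals(x)
  if (!nrow(merged)) { merged$score <- numeric(); return(merged) }
  hits <- overlap_pairs(merged, x)
  merged$score <- vapply(seq_len(nrow(merged)), function(i)
    max(x$score[hits$subject_idx[hits$query_idx == i]]), numeric(1))
  merged
}
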