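# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (enumeration, brute force,
# closed form) and stays deliberately slow/simple.

# exhaustive affine-gap alignment score by recursive enumeration of all
# alignments (exponential; only for very short sequences)
brute_align_score <- function(sa, sb, match = 1, mismatch = -1,
                              gap_open = -5, gap_extend = -1) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  sc <- function(x, y) if (x == "N" || y == "N") 0 else
    if (x == y) match else mismatch
  rec <- function(i, j, state) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) best <- max(best, rec(i - 1, j - 1, 0) + sc(a[i], b[j]))
    if (i > 0) best <- max(best, rec(i - 1, j, 1) + gap_extend +
                             if (state == 1) 0 else gap_open)
    if (j > 0) best <- max(best, rec(i, j - 1, 2) + gap_extend +
                             if (state == 2) 0 else gap_open)
    best
  }
  rec(length(a), length(b), 0)
}

# two-sided Fisher p for the table [[o, T-o], [e, T-e]] by explicit
# enumeration of the conditional hypergeometric support
hyper_p_oracle <- function(o, e, total) {
  m <- o + e                      # first-column margin
  n2 <- 2 * total - m             # second-column margin
  support <- max(0, m - total):min(m, total)
  dens <- stats::dhyper(support, m, n2, total)
  p_obs <- stats::dhyper(o, m, n2, total)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# all-pairs brute-force interval intersection (single scaffold)
brute_intersect <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (s < e) out[[length(out) + 1]] <- tibble::tibble(
      scaffold = a$scaffold[i], start = s, end = e)
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(res)
  # merge overlaps so the result is comparable to a reduced set
  res <- dplyr::arrange(res, start)
  merged <- res[1, ]
  for (k in seq_len(nrow(res))[-1]) {
    last <- nrow(merged)
    if (res$start[k] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], res$end[k])
    } else merged <- dplyr::bind_rows(merged, res[k, ])
  }
  merged
}

# a random additive distance matrix from a random binary tree; returns the
# generating tree and its cophenetic distances
random_additive <- function(n_tips, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_tips, rooted = FALSE,
                     br = function(k) runif(k, 0.5, 2))
    list(tree = tr, dist = ape::cophenetic.phylo(tr))
  })
}

# unrooted split set of a phylo, as canonical topology id over tip labels
splits_id_oracle <- function(tree) {
  labs <- sort(tree$tip.label)
  parts <- ape::prop.part(ape::unroot(tree))
  sides <- list()
  for (p in parts) {
    tl <- tree$tip.label[p]
    if (length(tl) >= 2 && length(tl) <= length(labs) - 2)
      sides[[length(sides) + 1]] <- tl
  }
  topology_id(sides, labs)
}

# default group fixture for depth scans: 20 individuals, 4 groups, yellow
# phenotype = groups g1, g3
depth_fixture_groups <- function(n = 20) {
  ids <- sprintf("ind_%d", seq_len(n))
  grp <- stats::setNames(rep(sprintf("g%d", 1:4), length.out = n), ids)
  list(ids = ids, group_of = grp,
       phenotype = c(g1 = "yellow", g2 = "melanic",
                     g3 = "yellow", g4 = "melanic"),
       carriers = ids[grp %in% c("g1", "g3")])
}
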