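#' Synthetic inputs with recorded ground truth
#'
#' Each `sim_*()` generator emulates the statistical structure one analysis
#' stage assumes and returns its planted features as a `sim_truth` record,
#' so every downstream detector can be tested by truth recovery without any
#' external data. All generators are bit-reproducible given `seed`.
#'
#' @name synthio
NULL

sim_truth <- function(...) structure(list(...), class = "sim_truth")

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                if (is.atomic(v)) paste(utils::head(v, 8), collapse = " ")
                else paste0("<", class(v)[1], ">")))
  }
  invisible(x)
}

#' Simulate multi-population haplotypes with a phenotype-concordant block
#'
#' Outside the block, sites evolve down a fixed "species" group tree in
#' which groups of the same species cluster (consecutive group pairs);
#' inside the block they evolve down a "phenotype" tree in which
#' alternating (yellow-bar) groups cluster instead. Alleles mutate by
#' symmetric substitution along branches; groups are shallow clades with
#' short tip branches so that within-group variation stays far below
#' between-group divergence. Fixed trees (not a coalescent) make the
#' planted block an exact truth for recovery tests.
#'
#' @param n_groups number of groups (>= 3; even numbers give the paired
#'   species structure; default 4).
#' @param n_per_group haplotypes per group (default 4).
#' @param n_sites number of SNP sites (default 2000).
#' @param block site-index interval `c(start, end)` (0-based half-open)
#'   evolving under the phenotype tree; `NULL` for a null simulation.
#' @param theta_bg per-unit-branch-length substitution scale (default 0.3,
#'   which at the default tree depths leaves most 50-SNP windows with well
#'   over 10 segregating sites).
#' @param missing_rate per-call missingness probability (default 0).
#' @param pos_spacing bp between consecutive sites (default 1: positions
#'   are the site indices).
#' @param seed integer seed.
#' @return list with `haplotypes` (a [haplotype_matrix()]) and `truth`
#'   (`sim_truth` with `association_interval` in site indices, the
#'   phenotype/species topology ids, and the seed).
#' @export
sim_haplotypes <- function(n_groups = 4, n_per_group = 4, n_sites = 2000,
                           block = c(800, 1200), theta_bg = 0.3,
                           missing_rate = 0, pos_spacing = 1, seed = 1) {
  if (n_groups < 3) abort("n_groups must be >= 3")
  if (n_per_group < 1) abort("n_per_group must be >= 1")
  if (!is.null(block)) {
    if (block[1] < 0 || block[2] > n_sites || block[1] >= block[2])
      abort("block must lie within [0, n_sites)")
  }
  glabels <- sprintf("g%d", seq_len(n_groups))
  species_tree <- group_tree(glabels, pairing = "consecutive")
  pheno_tree <- group_tree(glabels, pairing = "alternating")
  sample_ids <- as.vector(t(outer(glabels, seq_len(n_per_group),
                                  function(g, i) paste0(g, "_", i))))
  groups <- tibble::tibble(sample_id = sample_ids,
                           group = rep(glabels, each = n_per_group))
  in_block <- rep(FALSE, n_sites)
  if (!is.null(block)) in_block[(block[1] + 1):block[2]] <- TRUE
  alle <- withr::with_seed(seed, {
    bg <- simulate_sites(species_tree, glabels, n_per_group, sum(!in_block),
                         theta_bg)
    bl <- simulate_sites(pheno_tree, glabels, n_per_group, sum(in_block),
                         theta_bg)
    m <- matrix(NA_character_, length(sample_ids), n_sites,
                dimnames = list(sample_ids, NULL))
    m[, !in_block] <- bg[sample_ids, , drop = FALSE]
    if (any(in_block)) m[, in_block] <- bl[sample_ids, , drop = FALSE]
    if (missing_rate > 0)
      m[runif(length(m)) < missing_rate] <- NA_character_
    m
  })
  haps <- haplotype_matrix(alle, (seq_len(n_sites) - 1) * pos_spacing, groups)
  truth <- sim_truth(
    association_interval = if (is.null(block)) NULL else block,
    phenotype_topology = tree_group_topology(pheno_tree, glabels),
    species_topology = tree_group_topology(species_tree, glabels),
    pos_spacing = pos_spacing, seed = seed)
  list(haplotypes = haps, truth = truth)
}

# fixed group trees: groups as shallow clades (tip branches 0.05) hanging
# off either consecutive pairs ((g1,g2),(g3,g4),...) or alternating pairs
# ((g1,g3),(g2,g4),...); remaining structure is a ladder. Branch lengths
# in substitution-scale units (multiplied by theta).
group_tree <- function(glabels, pairing = c("consecutive", "alternating")) {
  pairing <- match.arg(pairing)
  ord <- if (pairing == "consecutive") seq_along(glabels)
         else order(rep(c(1, 2), length.out = length(glabels)))
  labs <- glabels[ord]
  nodes <- as.list(labs)
  # pair up consecutively, then ladder the pairs together
  while (length(nodes) > 1) {
    nxt <- list()
    i <- 1
    while (i < length(nodes)) {
      nxt[[length(nxt) + 1]] <- list(nodes[[i]], nodes[[i + 1]])
      i <- i + 2
    }
    if (i == length(nodes)) nxt[[length(nxt)]] <- list(nxt[[length(nxt)]], nodes[[i]])
    nodes <- nxt
  }
  nodes[[1]]
}

tree_newick <- function(node, stem = 0.5) {
  if (!is.list(node)) return(sprintf("%s:%g", node, stem))
  sprintf("(%s,%s):%g", tree_newick(node[[1]]), tree_newick(node[[2]]), stem)
}

# the canonical group topology implied by a nested-list group tree
tree_group_topology <- function(node, glabels) {
  clades <- Filter(function(cl) length(cl) >= 2 && length(cl) <= length(glabels) - 2,
                   lapply(clades_of(node), sort))
  topology_id_from_splits(unique(clades), sort(glabels))
}

# simulate independent sites down the group tree expanded to samples:
# group g becomes a clade of n_per tips with tip branch 0.05
simulate_sites <- function(gtree, glabels, n_per, n_sites, theta) {
  ids <- as.vector(t(outer(glabels, seq_len(n_per),
                           function(g, i) paste0(g, "_", i))))
  if (n_sites == 0)
    return(matrix(character(), length(ids), 0, dimnames = list(ids, NULL)))
  expand <- function(node) {
    if (!is.list(node)) {
      tips <- paste0(sprintf("%s_%d", node, seq_len(n_per)), ":0.05")
      return(sprintf("(%s):0.5", paste(tips, collapse = ",")))
    }
    sprintf("(%s,%s):0.5", expand(node[[1]]), expand(node[[2]]))
  }
  nwk <- paste0(sub(":0.5$", "", expand(gtree)), ";")
  phy <- ape::read.tree(text = nwk)
  bases <- c("A", "C", "G", "T")
  n_node <- max(phy$edge)
  seqs <- matrix(NA_integer_, n_node, n_sites)
  root <- length(phy$tip.label) + 1L
  seqs[root, ] <- sample.int(4, n_sites, replace = TRUE)
  edges <- ape::reorder.phylo(phy, "cladewise")
  for (k in seq_len(nrow(edges$edge))) {
    par <- edges$edge[k, 1]; child <- edges$edge[k, 2]
    p <- 1 - exp(-theta * edges$edge.length[k])
    s <- seqs[par, ]
    mut <- runif(n_sites) < p
    if (any(mut))
      s[mut] <- ((s[mut] - 1 + sample.int(3, sum(mut), replace = TRUE)) %% 4) + 1
    seqs[child, ] <- s
  }
  m <- matrix(bases[seqs[seq_along(phy$tip.label), ]],
              length(phy$tip.label), n_sites)
  rownames(m) <- phy$tip.label
  m[ids, , drop = FALSE]
}

#' Simulate per-base depth profiles with a carrier coverage drop
#'
#' Per-base depths are negative-binomial counts at `mean_depth`
#' (`dispersion` is the NB size parameter; large values approach Poisson).
#' For carrier individuals the mean is multiplied by `drop_frac` over
#' `[site, site + footprint)`, the read-depth signature of a structural
#' variant absent from the reference.
#'
#' @param n_individuals number of individuals (default 20).
#' @param length scaffold length in bp (default 10000).
#' @param mean_depth background mean depth (default 30).
#' @param carriers character vector of carrier sample ids (subset of
#'   `ind_1..ind_n`); empty for a null simulation.
#' @param site 0-based drop start (default 5000).
#' @param footprint drop width in bp (> 0; default 300).
#' @param drop_frac multiplicative factor applied to the carrier mean in
#'   the footprint (0 <= drop_frac < 1; default 0.4).
#' @param dispersion NB size parameter (default 10).
#' @param seed integer seed.
#' @return list with `depth` (long tibble `sample_id`, `pos`, `depth`) and
#'   `truth` (`sim_truth` with insertion site/footprint and carrier ids).
#' @export
sim_depth <- function(n_individuals = 20, length = 10000, mean_depth = 30,
                      carriers = character(), site = 5000, footprint = 300,
                      drop_frac = 0.4, dispersion = 10, seed = 1) {
  if (footprint <= 0) abort("footprint must be > 0")
  if (drop_frac < 0 || drop_frac >= 1) abort("drop_frac must be in [0, 1)")
  if (site + footprint > length) abort("footprint must fit in the scaffold")
  ids <- sprintf("ind_%d", seq_len(n_individuals))
  if (!all(carriers %in% ids)) abort("carriers must be simulated sample ids")
  in_fp <- seq(site, site + footprint - 1)
  depth <- withr::with_seed(seed, {
    purrr::map_dfr(ids, function(id) {
      mu <- rep(mean_depth, length)
      if (id %in% carriers) mu[in_fp + 1] <- mean_depth * drop_frac
      tibble::tibble(sample_id = id, pos = seq_len(length) - 1,
                     depth = rnbinom(length, size = dispersion, mu = mu))
    })
  })
  truth <- sim_truth(insertion_site = site, insertion_length = footprint,
                     carrier_ids = carriers, drop_frac = drop_frac,
                     seed = seed)
  list(depth = depth, truth = truth)
}

#' Simulate a binned Hi-C contact matrix with distance decay and loops
#'
#' Counts are `Poisson(scale * |i - j|^-alpha)` off the diagonal, the
#' standard power-law distance decay, multiplied by `enrichment` for
#' planted loop pairs; the matrix is symmetric by construction and the
#' diagonal is zero.
#'
#' @param n_bins number of bins (>= 3).
#' @param bin_size bin width in bp (default 5000).
#' @param scale expected count at distance 1 (default 100).
#' @param alpha decay exponent (> 0; default 1).
#' @param loops tibble/data.frame with columns `bin_i`, `bin_j` (0-based)
#'   and `enrichment` (> 1); `NULL` for none.
#' @param seed integer seed.
#' @return list with `contacts` (sparse tibble `bin_i`, `bin_j`, `count`,
#'   upper triangle, zero cells omitted; attributes `n_bins`, `bin_size`,
#'   `scaffold`) and `truth`.
#' @export
sim_contacts <- function(n_bins, bin_size = 5000, scale = 100, alpha = 1,
                         loops = NULL, seed = 1) {
  if (n_bins < 3) abort("n_bins must be >= 3")
  if (alpha <= 0) abort("alpha must be > 0")
  if (!is.null(loops)) {
    loops <- tibble::as_tibble(loops)
    stopifnot(all(c("bin_i", "bin_j", "enrichment") %in% names(loops)))
    if (any(loops$enrichment <= 1)) abort("loop enrichment must be > 1")
    if (any(loops$bin_i < 0 | loops$bin_j >= n_bins))
      abort("loop bins out of range")
  }
  ut <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
  i <- ut[, 1] - 1L; j <- ut[, 2] - 1L
  mu <- scale * abs(i - j)^(-alpha)
  if (!is.null(loops) && nrow(loops)) {
    li <- pmin(loops$bin_i, loops$bin_j); lj <- pmax(loops$bin_i, loops$bin_j)
    hit <- match(paste(i, j), paste(li, lj))
    mu[!is.na(hit)] <- mu[!is.na(hit)] * loops$enrichment[hit[!is.na(hit)]]
  }
  cnt <- withr::with_seed(seed, rpois(length(mu), mu))
  keep <- cnt > 0
  contacts <- contact_matrix(
    tibble::tibble(bin_i = i[keep], bin_j = j[keep], count = cnt[keep]),
    n_bins = n_bins, bin_size = bin_size, scaffold = "sim")
  truth <- sim_truth(loop_pairs = loops, scale = scale, alpha = alpha,
                     seed = seed)
  list(contacts = contacts, truth = truth)
}

#' Simulate an accessibility coverage track with boxcar peaks
#'
#' Negative-binomial noise around a flat background, plus rectangular
#' (boxcar) peaks of given heights — the shape of accessibility signal over
#' open chromatin.
#'
#' @param length track length in bp.
#' @param background background mean coverage (default 10).
#' @param peaks tibble/data.frame with `start`, `end` (0-based half-open)
#'   and `height` (added to the background mean); `NULL` for none.
#' @param dispersion NB size parameter (default 10).
#' @param seed integer seed.
#' @return list with `track` (tibble `pos`, `coverage`; attribute
#'   `scaffold`) and `truth` (`peak_intervals`).
#' @export
sim_track <- function(length, background = 10, peaks = NULL, dispersion = 10,
                      seed = 1) {
  mu <- rep(background, length)
  if (!is.null(peaks)) {
    peaks <- tibble::as_tibble(peaks)
    stopifnot(all(c("start", "end", "height") %in% names(peaks)))
    if (any(peaks$start < 0 | peaks$end > length)) abort("peaks out of range")
    for (k in seq_len(nrow(peaks)))
      mu[(peaks$start[k] + 1):peaks$end[k]] <- background + peaks$height[k]
  }
  cov <- withr::with_seed(seed, rnbinom(length, size = dispersion, mu = mu))
  track <- tibble::tibble(pos = seq_len(length) - 1, coverage = as.numeric(cov))
  attr(track, "scaffold") <- "sim"
  truth <- sim_truth(peak_intervals = peaks, background = background,
                     seed = seed)
  list(track = track, truth = truth)
}

#' Simulate a sequence pair with planted insertions
#'
#' A random A/C/G/T sequence plus a copy carrying the requested insertions,
#' emulating a reference/carrier consensus pair for indel genotyping.
#'
#' @param base_len length of the base (reference) sequence.
#' @param insertions tibble/data.frame with `pos` (0-based position on the
#'   base sequence before which the insertion goes) and `len` (bp);
#'   `NULL` for an identical pair.
#' @param seed integer seed.
#' @return list with `seq_a` (base), `seq_b` (carrier) as character
#'   strings, and `truth` recording positions and lengths.
#' @export
sim_insertion_pair <- function(base_len, insertions = NULL, seed = 1) {
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    a <- sample(bases, base_len, replace = TRUE)
    ins <- NULL
    b <- a
    if (!is.null(insertions)) {
      ins <- tibble::as_tibble(insertions)
      stopifnot(all(c("pos", "len") %in% names(ins)))
      if (any(ins$pos < 0 | ins$pos > base_len)) abort("insertion pos out of range")
      ins <- dplyr::arrange(ins, dplyr::desc(.data$pos))
      for (k in seq_len(nrow(ins))) {
        seg <- sample(bases, ins$len[k], replace = TRUE)
        p <- ins$pos[k]
        b <- append(b, seg, after = p)
      }
      ins <- dplyr::arrange(ins, .data$pos)
    }
    list(seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = ""),
         truth = sim_truth(insertions = ins, seed = seed))
  })
}

#' Simulate a noisy periodic intensity trace
#'
#' Sinusoid of the given spatial period plus white Gaussian noise,
#' emulating an intensity trace drawn across scale ridges.
#'
#' @param period spatial period in micrometres.
#' @param pixel sampling interval in micrometres per point (default 0.01).
#' @param n_px number of points (default 4096).
#' @param noise_sd Gaussian noise standard deviation (default 0; the
#'   sinusoid amplitude is 1).
#' @param seed integer seed.
#' @return list with `trace` (tibble `pos_um`, `intensity`; attribute
#'   `pixel`) and `truth` (`ridge_period`).
#' @export
sim_trace <- function(period, pixel = 0.01, n_px = 4096, noise_sd = 0,
                      seed = 1) {
  if (period <= 0 || pixel <= 0) abort("period and pixel must be positive")
  x <- (seq_len(n_px) - 1) * pixel
  y <- sin(2 * pi * x / period)
  if (noise_sd > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(n_px, sd = noise_sd))
  trace <- tibble::tibble(pos_um = x, intensity = y)
  attr(trace, "pixel") <- pixel
  list(trace = trace, truth = sim_truth(ridge_period = period, seed = seed))
}
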