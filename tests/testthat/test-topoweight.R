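make_haps <- function(alleles, groups_of, positions = NULL) {
  positions <- positions %||% (seq_len(ncol(alleles)) - 1)
  haplotype_matrix(alleles, positions,
                   tibble::tibble(sample_id = rownames(alleles),
                                  group = groups_of))
}

test_that("window layout follows the size/step arithmetic", {
  alle <- matrix("A", 8, 130,
                 dimnames = list(sprintf("s%d", 1:8), NULL))
  haps <- make_haps(alle, rep(c("A", "B", "C", "D"), each = 2))
  w <- make_windows(haps, window_spec(size_snps = 50, step_snps = 20,
                                      min_sites = 10))
  expect_equal(nrow(w), 5)
  expect_equal(w$first_site, c(0, 20, 40, 60, 80))
  expect_equal(w$last_site, c(50, 70, 90, 110, 130))

  haps49 <- make_haps(alle[, 1:49], rep(c("A", "B", "C", "D"), each = 2))
  expect_equal(nrow(make_windows(haps49)), 0)
})

test_that("the genotyped-fraction filter fails windows with an absent group", {
  alle <- matrix("A", 8, 100, dimnames = list(sprintf("s%d", 1:8), NULL))
  alle[7:8, ] <- NA_character_       # one group entirely missing
  haps <- make_haps(alle, rep(c("A", "B", "C", "D"), each = 2))
  w <- make_windows(haps)
  expect_true(nrow(w) > 0)
  expect_false(any(w$pass))
})

test_that("neighbor joining recovers additive topologies", {
  # 4-taxon additive case with internal edge: split AB|CD
  alle <- rbind(A1 = c(rep("A", 8)),
                B1 = c(rep("A", 6), "C", "C"),
                C1 = c("C", "C", "C", "C", rep("A", 4)),
                D1 = c("C", "C", "C", "C", "A", "A", "G", "G"))
  haps <- make_haps(alle, c("A", "B", "C", "D"))
  tr <- nj_tree(haps)
  expect_equal(induced_topology(tr, c(A = "A1", B = "B1", C = "C1", D = "D1")),
               "A,B|C,D")

  # random additive matrices: NJ output matches the generating tree splits
  for (seed in 1:8) {
    gen <- random_additive(8, seed)
    tr <- ape::nj(stats::as.dist(gen$dist))
    expect_identical(splits_id_oracle(tr), splits_id_oracle(gen$tree))
  }
})

test_that("pairs without comparable sites are an error, not distance zero", {
  alle <- matrix(c("A", NA, NA, "A"), 2, 2,
                 dimnames = list(c("s1", "s2"), NULL))
  expect_error(hamming_dist(alle), "no genotyped site")
})

test_that("exact weighting reproduces hand-enumerated mixed trees", {
  tr <- ape::unroot(ape::read.tree(text = "(((a1,c1),b1),(a2,d1));"))
  groups <- tibble::tibble(sample_id = c("a1", "a2", "b1", "c1", "d1"),
                           group = c("A", "A", "B", "C", "D"))
  w <- weight_exact(tr, groups)
  expect_equal(sum(w$weight), 1)
  expect_equal(w$weight[w$topology == "A,C|B,D"], 0.5)
  expect_equal(w$weight[w$topology == "A,D|B,C"], 0.5)
  expect_equal(w$weight[w$topology == "A,B|C,D"], 0)
})

test_that("monophyletic groups put all weight on the concordant topology", {
  tr <- ape::read.tree(text = "(((a1,a2),(b1,b2)),((c1,c2),(d1,d2)));")
  groups <- tibble::tibble(sample_id = tr$tip.label,
                           group = toupper(substr(tr$tip.label, 1, 1)))
  we <- weight_exact(tr, groups)
  expect_equal(we$weight[we$topology == "A,B|C,D"], 1)
  wm <- weight_mc(tr, groups, n_iter = 200, seed = 5)
  expect_equal(wm$weight[wm$topology == "A,B|C,D"], 1)
})

test_that("Monte-Carlo weighting is seeded and converges to the exact oracle", {
  tr <- ape::unroot(ape::read.tree(text = "(((a1,c1),b1),(a2,d1));"))
  groups <- tibble::tibble(sample_id = c("a1", "a2", "b1", "c1", "d1"),
                           group = c("A", "A", "B", "C", "D"))
  w1 <- weight_mc(tr, groups, n_iter = 1000, seed = 11)
  w2 <- weight_mc(tr, groups, n_iter = 1000, seed = 11)
  expect_identical(w1$weight, w2$weight)
  expect_equal(sum(w1$weight), 1)
  # binomial 3-sigma band around the exact 0.5 weights
  expect_lt(abs(w1$weight[w1$topology == "A,C|B,D"] - 0.5),
            3 * sqrt(0.25 / 1000))
  # convergence: at 1e5 iterations every weight is within 0.01 of exact
  we <- weight_exact(tr, groups)
  wb <- weight_mc(tr, groups, n_iter = 1e5, seed = 12)
  expect_lt(max(abs(wb$weight - we$weight)), 0.01)
})

test_that("weights are equivariant under group relabeling", {
  tr <- ape::unroot(ape::read.tree(text = "(((a1,c1),b1),(a2,d1));"))
  g1 <- tibble::tibble(sample_id = c("a1", "a2", "b1", "c1", "d1"),
                       group = c("A", "A", "B", "C", "D"))
  g2 <- dplyr::mutate(g1, group = dplyr::recode(group, A = "D", D = "A"))
  w1 <- weight_exact(tr, g1)
  w2 <- weight_exact(tr, g2)
  # swapping labels A<->D maps A,C|B,D <-> A,B|C,D and fixes A,D|B,C
  expect_equal(w2$weight[w2$topology == "A,B|C,D"],
               w1$weight[w1$topology == "A,C|B,D"])
  expect_equal(w2$weight[w2$topology == "A,C|B,D"],
               w1$weight[w1$topology == "A,B|C,D"])
  expect_equal(w2$weight[w2$topology == "A,D|B,C"],
               w1$weight[w1$topology == "A,D|B,C"])
  expect_equal(sort(w1$weight), sort(w2$weight))
})

test_that("degenerate all-weight-1 profiles give one spanning interval", {
  prof <- tibble::tibble(window_id = 1:5, start = seq(0, 400, 100),
                         end = seq(149, 549, 100), topology = "T",
                         weight = 1, method = "exact")
  iv <- high_weight_intervals(prof, threshold = 0.9, min_windows = 2)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 0)
  expect_equal(iv$end, 549)
})

test_that("planted association blocks are localised to within one window", {
  sim <- sim_haplotypes(seed = 101)
  prof <- weighting_profile(sim$haplotypes,
                            topology = sim$truth$phenotype_topology)
  iv <- high_weight_intervals(prof)
  expect_equal(nrow(iv), 1)
  # spec'd localisation: boundaries within one window step of the truth
  expect_lt(abs(iv$start - 800), 50)
  expect_lt(abs(iv$end - 1200), 50)

  null <- sim_haplotypes(block = NULL, seed = 102)
  pn <- weighting_profile(null$haplotypes,
                          topology = sim$truth$phenotype_topology)
  expect_equal(nrow(high_weight_intervals(pn)), 0)
})
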