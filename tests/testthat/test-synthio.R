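test_that("generators are bit-reproducible under a fixed seed", {
  h1 <- sim_haplotypes(seed = 42); h2 <- sim_haplotypes(seed = 42)
  expect_identical(h1$haplotypes$alleles, h2$haplotypes$alleles)
  d1 <- sim_depth(seed = 42, n_individuals = 3, length = 500, site = 100,
                  footprint = 50)
  d2 <- sim_depth(seed = 42, n_individuals = 3, length = 500, site = 100,
                  footprint = 50)
  expect_identical(d1$depth, d2$depth)
  c1 <- sim_contacts(50, seed = 42); c2 <- sim_contacts(50, seed = 42)
  expect_identical(c1$contacts, c2$contacts)
  t1 <- sim_trace(0.6, noise_sd = 0.2, seed = 42)
  t2 <- sim_trace(0.6, noise_sd = 0.2, seed = 42)
  expect_identical(t1$trace, t2$trace)
})

test_that("zero mutation scale collapses haplotypes to one sequence", {
  sim <- sim_haplotypes(theta_bg = 0, n_sites = 300, block = c(100, 200),
                        seed = 3)
  alle <- sim$haplotypes$alleles
  expect_true(all(apply(alle, 2, function(col) length(unique(col)) == 1)))
})

test_that("haplotype truth records the planted block and topologies", {
  sim <- sim_haplotypes(block = c(800, 1200), seed = 5)
  expect_equal(sim$truth$association_interval, c(800, 1200))
  expect_equal(sim$truth$phenotype_topology, "g1,g3|g2,g4")
  expect_equal(sim$truth$species_topology, "g1,g2|g3,g4")
  expect_error(sim_haplotypes(block = c(1900, 2100)), "block")
  expect_error(sim_haplotypes(n_per_group = 0), "n_per_group")
})

test_that("depth simulation hits its mean and carrier footprint", {
  # genome-wide mean within 5% at the stated scale
  sim <- sim_depth(n_individuals = 20, length = 10000, mean_depth = 30,
                   seed = 7)
  expect_lt(abs(mean(sim$depth$depth) - 30) / 30, 0.05)

  # drop_frac = 0: carrier depth over the footprint is (almost surely) zero
  z <- sim_depth(n_individuals = 4, length = 2000, mean_depth = 30,
                 carriers = sprintf("ind_%d", 1:4), site = 500,
                 footprint = 300, drop_frac = 0, seed = 8)
  fp <- dplyr::filter(z$depth, pos >= 500, pos < 800)
  expect_equal(mean(fp$depth), 0)
  expect_error(sim_depth(footprint = 0), "footprint")
  expect_error(sim_depth(carriers = "nope"), "carriers")
})

test_that("contact simulation has symmetric power-law decay", {
  sim <- sim_contacts(n_bins = 300, scale = 100, alpha = 1, seed = 9)
  m <- cretrace:::contact_dense(sim$contacts)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  # mean count at small distances tracks scale / d
  exp_tab <- expected_by_distance(sim$contacts)
  for (d in c(1, 2, 5, 10)) {
    mu <- 100 / d
    se <- sqrt(mu / (300 - d))
    expect_lt(abs(exp_tab$mean[exp_tab$distance == d] - mu), 4 * se)
  }
  expect_error(sim_contacts(2), "n_bins")
  expect_error(sim_contacts(10, alpha = 0), "alpha")
  expect_error(sim_contacts(10, loops = tibble::tibble(bin_i = 1, bin_j = 2,
                                                       enrichment = 1)),
               "enrichment")
})

test_that("track simulation places boxcar peaks at the requested heights", {
  flat <- sim_track(2000, background = 10, seed = 10)
  expect_lt(abs(mean(flat$track$coverage) - 10) / 10, 0.1)
  pk <- sim_track(5000, background = 10,
                  peaks = tibble::tibble(start = 1000, end = 1400, height = 30),
                  seed = 11)
  inside <- dplyr::filter(pk$track, pos >= 1000, pos < 1400)
  outside <- dplyr::filter(pk$track, pos < 1000 | pos >= 1400)
  expect_lt(abs(mean(inside$coverage) - 40) / 40, 0.1)
  expect_lt(abs(mean(outside$coverage) - 10) / 10, 0.1)
})

test_that("insertion pairs are identical without insertions and record truth", {
  p0 <- sim_insertion_pair(200, seed = 12)
  expect_identical(p0$seq_a, p0$seq_b)
  p1 <- sim_insertion_pair(200, tibble::tibble(pos = 50, len = 17), seed = 13)
  expect_equal(nchar(p1$seq_b) - nchar(p1$seq_a), 17)
  expect_equal(p1$truth$insertions$len, 17)
  # the flanks are untouched
  expect_identical(substr(p1$seq_b, 1, 50), substr(p1$seq_a, 1, 50))
  expect_identical(substr(p1$seq_b, 68, 217), substr(p1$seq_a, 51, 200))
})

test_that("noiseless traces are pure sinusoids", {
  tr <- sim_trace(0.5, pixel = 0.01, n_px = 256, noise_sd = 0)
  expect_equal(tr$trace$intensity,
               sin(2 * pi * tr$trace$pos_um / 0.5))
  expect_equal(tr$truth$ridge_period, 0.5)
})
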