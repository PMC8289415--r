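flat_depth <- function(ids, length, value) {
  purrr::map_dfr(ids, function(id)
    tibble::tibble(sample_id = id, pos = seq_len(length) - 1, depth = value))
}

test_that("window medians follow the tiling and partial-window rules", {
  d <- tibble::tibble(sample_id = "s", pos = 0:99, depth = 1:100)
  m <- window_medians(d, 50)
  expect_equal(m$median_depth, c(25.5, 75.5))

  const <- flat_depth("s", 300, 30)
  expect_true(all(window_medians(const, 50)$median_depth == 30))

  # trailing window of 20 < 25 bases is dropped
  d120 <- flat_depth("s", 120, 10)
  m120 <- window_medians(d120, 50)
  expect_equal(nrow(m120), 2)
  expect_equal(m120$end, c(50, 100))
  # trailing window of exactly w/2 is kept
  d125 <- flat_depth("s", 125, 10)
  expect_equal(nrow(window_medians(d125, 50)), 3)
})

test_that("normalization divides by the scaffold mean and rejects zero", {
  d <- flat_depth("s", 200, 30)
  n <- normalize_depth(window_medians(d, 50), d)
  expect_true(all(n$norm_depth == 1))
  n2 <- normalize_depth(tibble::tibble(sample_id = "s", window_id = 0:1,
                                       start = c(0, 50), end = c(50, 100),
                                       median_depth = c(10, 30)),
                        c(s = 20))
  expect_equal(n2$norm_depth, c(0.5, 1.5))
  zero <- flat_depth("s", 100, 0)
  expect_error(normalize_depth(window_medians(zero, 50), zero), "> 0")
})

test_that("group means average members and ignore member order", {
  d <- dplyr::bind_rows(flat_depth("s1", 100, 10), flat_depth("s2", 100, 30))
  n <- normalize_depth(window_medians(d, 50), c(s1 = 20, s2 = 20))
  g <- group_mean_depth(n, c(s1 = "G", s2 = "G"))
  expect_true(all(g$mean_norm == 1))
  g2 <- group_mean_depth(n[order(-as.integer(factor(n$sample_id))), ],
                         c(s1 = "G", s2 = "G"))
  expect_equal(g, g2)
})

test_that("constructed drops are detected with the right concordance flag", {
  wins <- tibble::tibble(window_id = 0:59, start = 0:59 * 50,
                         end = 0:59 * 50 + 50)
  prof <- purrr::map_dfr(c("g1", "g2", "g3", "g4"), function(g) {
    v <- rep(1, 60)
    if (g %in% c("g1", "g3")) v[21:24] <- 0.3     # windows [1000, 1200)
    dplyr::mutate(wins, group = g, mean_norm = v)
  })
  pheno <- c(g1 = "yellow", g2 = "melanic", g3 = "yellow", g4 = "melanic")
  calls <- detect_drops(prof, pheno)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$start, calls$end), c(1000, 1200))
  expect_true(calls$concordant)
  expect_equal(calls$carrier_phenotype, "yellow")

  # all groups dipping together is never phenotype-concordant
  prof_all <- purrr::map_dfr(c("g1", "g2", "g3", "g4"), function(g) {
    v <- rep(1, 60); v[21:24] <- 0.3
    dplyr::mutate(wins, group = g, mean_norm = v)
  })
  calls_all <- detect_drops(prof_all, pheno)
  expect_false(any(calls_all$concordant))
})

test_that("drop calls are invariant to depth rescaling and label swap", {
  fx <- depth_fixture_groups()
  sim <- sim_depth(carriers = fx$carriers, seed = 21)
  base <- scan_coverage_drops(sim$depth, fx$group_of, fx$phenotype)
  scaled <- dplyr::mutate(sim$depth, depth = depth * 7)
  rescaled <- scan_coverage_drops(scaled, fx$group_of, fx$phenotype)
  expect_equal(base, rescaled)
  # swapping which phenotype is called "yellow" keeps the same intervals
  flipped <- c(g1 = "melanic", g2 = "yellow", g3 = "melanic", g4 = "yellow")
  swapped <- scan_coverage_drops(sim$depth, fx$group_of, flipped)
  expect_equal(base[c("start", "end", "concordant")],
               swapped[c("start", "end", "concordant")])
})

test_that("simulated carrier drops are recovered and nulls stay silent", {
  fx <- depth_fixture_groups()
  sim <- sim_depth(carriers = fx$carriers, site = 5000, footprint = 300,
                   drop_frac = 0.4, seed = 22)
  calls <- scan_coverage_drops(sim$depth, fx$group_of, fx$phenotype)
  calls <- calls[calls$concordant, ]
  expect_equal(nrow(calls), 1)
  expect_true(calls$start < 5300 && calls$end > 5000)

  null <- sim_depth(carriers = character(), seed = 23)
  expect_equal(nrow(scan_coverage_drops(null$depth, fx$group_of,
                                        fx$phenotype)), 0)
})
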