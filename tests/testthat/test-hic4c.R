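toy_contacts <- function(n_bins, f) {
  ut <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
  contact_matrix(tibble::tibble(bin_i = ut[, 1] - 1, bin_j = ut[, 2] - 1,
                                count = f(abs(ut[, 1] - ut[, 2]))),
                 n_bins = n_bins, bin_size = 1000)
}

test_that("virtual profiles are matrix rows and respect symmetry", {
  cm <- toy_contacts(10, function(d) 100 / d)
  p3 <- virtual_profile(cm, 3)
  p7 <- virtual_profile(cm, 7)
  expect_equal(p3$count[p3$bin == 7], p7$count[p7$bin == 3])
  expect_true(p3$is_anchor[p3$bin == 3])
  zero <- contact_matrix(tibble::tibble(bin_i = 0, bin_j = 1, count = 0),
                         n_bins = 5)
  expect_true(all(virtual_profile(zero, 2)$count == 0))
  expect_error(virtual_profile(cm, 10), "range")
  # a planted spike is the profile's off-diagonal maximum
  cm2 <- contact_matrix(tibble::tibble(bin_i = c(2, 2, 2), bin_j = c(5, 6, 7),
                                       count = c(1, 9, 1)), n_bins = 10)
  pr <- virtual_profile(cm2, 2)
  expect_equal(pr$bin[which.max(pr$count)], 6)
})

test_that("the expected model reproduces exact constructions", {
  cm <- toy_contacts(10, function(d) 100 / d)
  ex <- expected_by_distance(cm)
  expect_equal(ex$n_pairs, 9:1)
  expect_equal(ex$mean, 100 / (1:9))
  expect_equal(ex$median, 100 / (1:9))
  asym <- tibble::tibble(bin_i = c(0, 1), bin_j = c(1, 0), count = c(3, 5))
  expect_error(contact_matrix(asym), "asymmetric")
})

test_that("Fisher p-values match the hypergeometric enumeration oracle", {
  cases <- expand.grid(o = c(0, 1, 3, 10, 30, 60), e = c(0, 1, 5, 20, 50),
                       total = c(5, 20, 100, 500))
  cases <- cases[cases$o <= cases$total & cases$e <= cases$total &
                   cases$o + cases$e > 0, ]
  for (k in seq_len(nrow(cases))) {
    o <- cases$o[k]; e <- cases$e[k]; total <- cases$total[k]
    p_pkg <- stats::fisher.test(matrix(c(o, e, total - o, total - e), 2))$p.value
    expect_equal(p_pkg, hyper_p_oracle(o, e, total), tolerance = 1e-10)
  }
})

test_that("contact tests report odds ratios per the sample-OR convention", {
  cm <- toy_contacts(20, function(d) round(100 / d))
  ex <- expected_by_distance(cm)
  # observed equals expected at every distance by construction
  tt <- contact_test(cm, 2, 7, ex)
  expect_equal(tt$odds_ratio, 1)
  expect_equal(tt$p_value, 1)
  # two-sided monotonicity: p non-increasing away from e on both sides
  total <- 200; e <- 20
  p_of <- function(o) stats::fisher.test(
    matrix(c(o, e, total - o, total - e), 2))$p.value
  ups <- vapply(e:60, p_of, numeric(1))
  downs <- vapply(e:0, p_of, numeric(1))
  expect_true(all(diff(ups) <= 1e-12))
  expect_true(all(diff(downs) <= 1e-12))
  expect_error(contact_test(cm, 3, 3), "differ")
})

test_that("strongly enriched tables are significant with OR > 1", {
  # [[30, 170], [5, 195]]: o = 30, e = 5, total = 200
  cm <- toy_contacts(5, function(d) 1)
  p <- stats::fisher.test(matrix(c(30, 5, 170, 195), 2))$p.value
  expect_lt(p, 1e-4)
  expect_equal(p, hyper_p_oracle(30, 5, 200), tolerance = 1e-10)
  or <- cretrace:::haldane_or(30, 170, 5, 195)
  expect_gt(or, 1)
})

test_that("planted loops are called against the decay background", {
  sim <- sim_contacts(n_bins = 200, scale = 100, alpha = 1,
                      loops = tibble::tibble(bin_i = 40, bin_j = 80,
                                             enrichment = 10), seed = 31)
  tt <- contact_test(sim$contacts, 40, 80)
  expect_lt(tt$p_value, 0.05)
  expect_gt(tt$observed, tt$expected)
})

test_that("bp features map to their midpoint bins", {
  sim <- sim_contacts(n_bins = 40, bin_size = 500, scale = 100, alpha = 1,
                      seed = 32)
  ex <- expected_by_distance(sim$contacts)
  t_bins <- contact_test(sim$contacts, 19, 35, ex)
  t_feat <- test_cre_promoter(sim$contacts, c(9500, 9800), c(17250, 17750), ex)
  expect_equal(t_feat$p_value, t_bins$p_value)
  expect_equal(t_feat$anchor, 19)
  expect_equal(t_feat$target, 35)
})
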