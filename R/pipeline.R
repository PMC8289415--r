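#' End-to-end synthetic CRE localisation run
#'
#' Generates one synthetic locus in which a single cis-regulatory element
#' is supported by all three evidence tiers — a phenotype-concordant
#' association block in the haplotypes, an accessibility peak inside the
#' block (plus a decoy peak outside it), and a carrier coverage drop at the
#' element — together with a chromatin loop between the element and a
#' distal promoter bin. It then runs the full analysis chain and reports
#' which accessibility peaks survive each tier.
#'
#' The default locus is 20 kb: 2000 SNPs at 10 bp spacing, association
#' block sites [800, 1200) (bp [8000, 12000)), planted CRE at
#' [9500, 9800), decoy peak at [2000, 2300), promoter at 17.5 kb, 500 bp
#' contact bins with a 10x loop.
#'
#' @param seed integer seed driving every stage.
#' @param null when `TRUE`, generate the matched null locus (no block, no
#'   carriers, no loop; peaks are still present) so false-positive rates
#'   can be measured.
#' @param weight_threshold,min_windows association-interval parameters
#'   passed to [high_weight_intervals()].
#' @param alpha significance level for the contact tier (default 0.05).
#' @return list with `candidates` (per-peak tibble: interval, `assoc` /
#'   `drop` / `contact` logical tiers, `p_contact`, `nominated` = all three
#'   true), `truth`, and the intermediate `assoc_intervals`, `drop_calls`,
#'   `peaks`.
#' @export
run_synthetic_cre_pipeline <- function(seed = 1, null = FALSE,
                                       weight_threshold = 0.75,
                                       min_windows = 2, alpha = 0.05) {
  spacing <- 10
  cre <- c(9500, 9800); decoy <- c(2000, 2300); promoter <- c(17250, 17750)
  bin_size <- 500; n_bins <- 40

  # tier 1: association block in the haplotypes
  hsim <- sim_haplotypes(block = if (null) NULL else c(800, 1200),
                         pos_spacing = spacing, seed = seed)
  prof <- weighting_profile(hsim$haplotypes,
                            topology = hsim$truth$phenotype_topology)
  assoc <- high_weight_intervals(prof, threshold = weight_threshold,
                                 min_windows = min_windows)

  # tier 2: accessibility peaks (planted CRE + decoy; both always present)
  tsim <- sim_track(length = 20000, background = 10,
                    peaks = tibble::tibble(start = c(cre[1], decoy[1]),
                                           end = c(cre[2], decoy[2]),
                                           height = c(40, 40)),
                    seed = seed + 1000L)
  pk <- call_peaks(tsim$track)

  # tier 3a: carrier depth drop at the CRE in yellow-group individuals
  ids <- sprintf("ind_%d", 1:20)
  group_of <- stats::setNames(rep(sprintf("g%d", 1:4), each = 5), ids)
  pheno <- c(g1 = "yellow", g2 = "melanic", g3 = "yellow", g4 = "melanic")
  carriers <- if (null) character() else ids[group_of[ids] %in% c("g1", "g3")]
  dsim <- sim_depth(n_individuals = 20, length = 20000, mean_depth = 30,
                    carriers = carriers, site = cre[1],
                    footprint = cre[2] - cre[1], drop_frac = 0.4,
                    seed = seed + 2000L)
  drops <- scan_coverage_drops(dsim$depth, group_of, pheno)
  drops <- drops[drops$concordant, ]

  # tier 3b: contact loop CRE <-> promoter
  loop_bins <- c(floor(mean(cre) / bin_size), floor(mean(promoter) / bin_size))
  loops <- if (null) NULL else
    tibble::tibble(bin_i = loop_bins[1], bin_j = loop_bins[2], enrichment = 10)
  csim <- sim_contacts(n_bins = n_bins, bin_size = bin_size, scale = 100,
                       alpha = 1, loops = loops, seed = seed + 3000L)
  expected <- expected_by_distance(csim$contacts)

  nominated <- nominate_cres(assoc, pk)
  cand <- pk
  cand$assoc <- pk$start %in% nominated$start
  cand$drop <- vapply(seq_len(nrow(pk)), function(k) {
    nrow(intersect_intervals(pk[k, ], drops)) > 0
  }, logical(1))
  cand$p_contact <- vapply(seq_len(nrow(pk)), function(k) {
    test_cre_promoter(csim$contacts, c(pk$start[k], pk$end[k]), promoter,
                      expected)$p_value
  }, numeric(1))
  cand$contact <- cand$p_contact < alpha &
    vapply(seq_len(nrow(pk)), function(k) {
      obs_enriched(csim$contacts, c(pk$start[k], pk$end[k]), promoter, expected)
    }, logical(1))
  cand$nominated <- cand$assoc & cand$drop & cand$contact

  truth <- sim_truth(
    cre_interval = if (null) NULL else cre,
    association_interval = if (null) NULL else c(8000, 12000),
    decoy_interval = decoy, promoter_interval = promoter,
    loop_pairs = loops, seed = seed)
  list(candidates = cand, truth = truth, assoc_intervals = assoc,
       drop_calls = drops, peaks = pk)
}

# significance alone is two-sided; the loop tier additionally requires the
# observed count to exceed the distance expectation
obs_enriched <- function(contacts, cre, promoter, expected) {
  tt <- test_cre_promoter(contacts, cre, promoter, expected)
  tt$observed > tt$expected
}
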