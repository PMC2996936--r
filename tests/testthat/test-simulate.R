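# small catalogue keeping module tests fast
small_catalogue <- function() {
  dplyr::mutate(default_te_catalogue()[c(1, 5, 6), ],
                n_copies = c(2L, 1L, 4L))
}

test_that("genome simulation is deterministic and structurally sound", {
  cfg <- genome_sim_config(seed = 7, background_length = 20000,
                           te_catalogue = small_catalogue())
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$region$sequence, g2$region$sequence)
  expect_identical(as.data.frame(g1$annotations), as.data.frame(g2$annotations))

  ann <- g1$annotations
  expect_true(all(ann$start < ann$end))
  expect_true(max(ann$end) <= g1$region$length)
  # subfeatures stay within their parents
  el <- ann[is.na(ann$kind), ]
  sub <- ann[!is.na(ann$kind), ]
  m <- match(sub$parent_id, el$feature_id)
  expect_true(all(sub$start >= el$start[m] & sub$end <= el$end[m]))
  # children nest strictly deeper than their parents
  nested <- el[!is.na(el$parent_id), ]
  if (nrow(nested)) {
    expect_true(all(nested$nesting_level >
                      el$nesting_level[match(nested$parent_id,
                                             el$feature_id)]))
  }
})

test_that("a zero-TE configuration yields a pure background genome", {
  cfg <- genome_sim_config(seed = 3, background_length = 5000,
                           te_catalogue = dplyr::mutate(small_catalogue(),
                                                        n_copies = 0L),
                           n_genes = 0L)
  g <- simulate_genome(cfg)
  expect_equal(g$region$length, 5000L)
  expect_equal(nrow(g$annotations), 0L)
  expect_equal(nrow(g$truth), 0L)
})

test_that("forced nesting respects the depth cap", {
  cfg <- genome_sim_config(seed = 11, background_length = 8000,
                           te_catalogue = dplyr::mutate(
                             default_te_catalogue()[6, ], n_copies = 40L),
                           nesting_probability = 1, max_nesting = 4L)
  g <- simulate_genome(cfg)
  expect_true(max(g$annotations$nesting_level) <= 4L)
  expect_gt(max(g$annotations$nesting_level), 0L)
})

test_that("every genomic simulated read is recovered by the scanner", {
  g <- simulate_genome(genome_sim_config(seed = 7,
                                         background_length = 20000,
                                         te_catalogue = small_catalogue()))
  lib <- simulate_srna_library(g, library_sim_config(seed = 3,
                                                     n_reads = 3000))
  expect_true(all(nchar(lib$reads$sequence) == lib$truth$length))
  db <- build_srna_db(lib$reads)
  expect_equal(sum(db$total_count), 3000L)
  hits <- scan_region(db, g$region$sequence, g$region$region_id)
  genomic <- lib$truth[lib$truth$category != "non_genomic", ]
  key_h <- paste(hits$start, hits$length, hits$strand)
  key_t <- paste(genomic$start, genomic$length, genomic$strand)
  expect_true(all(key_t %in% key_h))
})

test_that("realised length mixture converges to the configured shares", {
  g <- simulate_genome(genome_sim_config(seed = 5, background_length = 30000,
                                         te_catalogue = small_catalogue()[0, ],
                                         n_genes = 0L))
  cfg <- library_sim_config(seed = 9, n_reads = 1e5,
                            origin_weights = c(te_terminal = 0, te_body = 0,
                                               gene = 0, background = 1,
                                               non_genomic = 0))
  lib <- simulate_srna_library(g, cfg)
  shares <- table(lib$truth$length) / 1e5
  expect_equal(unname(shares["21"]), 0.177, tolerance = 0.01 / 0.177)
  expect_equal(unname(shares["24"]), 0.287, tolerance = 0.01 / 0.287)
})

test_that("Mariner-origin reads follow the 21-nt-dominated mixture", {
  g <- simulate_genome(genome_sim_config(seed = 13, background_length = 4000,
                                         te_catalogue = dplyr::mutate(
                                           default_te_catalogue()[6, ],
                                           n_copies = 6L),
                                         n_genes = 0L))
  cfg <- library_sim_config(seed = 2, n_reads = 20000,
                            origin_weights = c(te_terminal = 1, te_body = 0,
                                               gene = 0, background = 0,
                                               non_genomic = 0))
  lib <- simulate_srna_library(g, cfg)
  p21 <- mean(lib$truth$length == 21)
  p24 <- mean(lib$truth$length == 24)
  expect_equal(p21, 0.54, tolerance = 3 * sqrt(0.54 * 0.46 / 20000) / 0.54)
  expect_equal(p24, 0.27, tolerance = 3 * sqrt(0.27 * 0.73 / 20000) / 0.27)
  # all reads really come from TIR subregions
  expect_true(all(lib$truth$kind %in% c("TIR5", "TIR3")))
})

test_that("an undiverged pair is identical; truth matches the tally", {
  ep0 <- evolve_pair(divergence_sim_config(seed = 1, length = 2000,
                                           age_years = 0))
  expect_identical(ep0$pair$seq_a, ep0$pair$seq_b)

  ep <- evolve_pair(divergence_sim_config(seed = 2, length = 5000))
  got <- tally_substitutions(ep$pair)
  expect_same_tally(got, ep$truth$tally)
})

test_that("deletions appear as gaps and never align gap against gap", {
  ep <- evolve_pair(divergence_sim_config(seed = 4, length = 20000,
                                          indel_rate = 0.002))
  a <- strsplit(ep$pair$seq_a, "")[[1]]
  b <- strsplit(ep$pair$seq_b, "")[[1]]
  expect_gt(sum(a == "-") + sum(b == "-"), 0)
  expect_false(any(a == "-" & b == "-"))
  # truth still matches the package tally in the presence of indels
  got <- tally_substitutions(ep$pair)
  expect_same_tally(got, ep$truth$tally)
})

test_that("non-PMS mismatches can only be A/T transversions", {
  # every interior C or G carries a methylation context, so a non-PMS
  # column holds A/T in both genomes and can never show a transition
  ep <- evolve_pair(divergence_sim_config(seed = 8, length = 20000))
  t <- tally_substitutions(ep$pair)
  expect_equal(sum(t$transitions[t$context == "nonPMS"]), 0L)
  expect_gt(sum(t$transitions[t$context != "nonPMS"]), 0L)
})

test_that("a neutral multiplier leaves methylated and reference strata alike", {
  # with m = 1 the PMS transition frequencies of the two strata should be
  # indistinguishable: two-proportion test per replicate at alpha = 0.01
  strata <- tibble::tibble(name = c("te", "genic"),
                           start = c(0L, 10000L), end = c(10000L, 20000L),
                           methylated = c(TRUE, FALSE))
  rejections <- 0L
  for (seed in 1:10) {
    ep <- evolve_pair(divergence_sim_config(seed = seed, length = 20000,
                                            strata = strata,
                                            pms_transition_multiplier = 1))
    t <- tally_substitutions(ep$pair, strata = ep$truth$strata_columns)
    counts <- function(strat) {
      pms <- t$stratum == strat & t$context != "nonPMS"
      c(sum(t$transitions[pms]), sum(t$sites[pms]))
    }
    te <- counts("te")
    ge <- counts("genic")
    p <- suppressWarnings(stats::prop.test(c(te[1], ge[1]),
                                           c(te[2], ge[2]))$p.value)
    rejections <- rejections + (p < 0.01)
  }
  expect_lte(rejections, 1L)
})

test_that("strata localise the elevation and the estimator recovers it", {
  strata <- tibble::tibble(name = c("te", "genic"),
                           start = c(0L, 25000L), end = c(25000L, 50000L),
                           methylated = c(TRUE, FALSE))
  ep <- evolve_pair(divergence_sim_config(seed = 6, length = 50000,
                                          strata = strata,
                                          pms_transition_multiplier = 10))
  t <- tally_substitutions(ep$pair, strata = ep$truth$strata_columns)
  est <- estimate_transition_elevation(t, "te", "genic")
  # the raw ratio is compressed by transitions arising at ancestral A/T
  # sites; the corrected elevation should sit near the configured m = 10
  # at 25 kb per stratum the estimator's sampling error is ~8%, so allow
  # three standard errors around the configured m = 10
  expect_gt(est$ratio, 3)
  expect_lt(est$ratio, 10)
  expect_equal(est$elevation, 10, tolerance = 0.25)
})
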