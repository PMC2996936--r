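test_that("hits are assigned to the innermost containing feature", {
  ann <- toy_annotations()

  # no annotations: everything intergenic
  bare <- assign_hits(toy_hit(10), ann[0, ])
  expect_true(is.na(bare$feature_id))

  # inside the nested MITE (level 2) within the Gypsy (level 0)
  a <- assign_hits(toy_hit(210), ann)
  expect_equal(a$feature_id, "mite1")
  expect_false(a$boundary)

  # inside the Gypsy but outside the MITE
  b <- assign_hits(toy_hit(120), ann)
  expect_equal(b$feature_id, "gypsy1")

  # two hits in the gene, none elsewhere
  g <- assign_hits(dplyr::bind_rows(toy_hit(510), toy_hit(600)), ann)
  expect_equal(g$feature_id, c("gene1", "gene1"))

  # straddling the gene boundary: assigned by start containment, flagged
  s <- assign_hits(toy_hit(690), ann)  # footprint 690-711, gene ends at 700
  expect_equal(s$feature_id, "gene1")
  expect_true(s$boundary)

  # intergenic
  i <- assign_hits(toy_hit(450), ann)
  expect_true(is.na(i$feature_id))
})

test_that("assignment conserves total counts", {
  withr::local_seed(5)
  ann <- toy_annotations()
  hits <- dplyr::bind_rows(lapply(sample(0:770, 50, replace = TRUE),
                                  function(p) toy_hit(p, total = sample(9, 1))))
  a <- assign_hits(hits, ann)
  expect_equal(sum(a$total_count), sum(hits$total_count))
  prof <- profile_features(a, ann)
  intergenic <- sum(a$total_count[is.na(a$feature_id)])
  expect_equal(sum(prof$total_count) + intergenic, sum(hits$total_count))
})

test_that("feature profiles report densities and size-class shares", {
  ann <- toy_annotations()
  # zero hits: density 0 with an explicit zero-total flag
  p0 <- profile_features(assign_hits(toy_hit(0)[0, ], ann), ann)
  expect_true(all(p0$zero_total))
  expect_true(all(p0$density == 0))
  expect_true(all(p0$pct_21 == 0))

  # size-class shares 54% / 27% from counts 54:27:19
  hits <- dplyr::bind_rows(
    toy_hit(210, length = 21, total = 54),
    toy_hit(215, length = 24, total = 27),
    toy_hit(220, length = 20, total = 19)
  )
  prof <- profile_features(assign_hits(hits, ann), ann)
  mite <- prof[prof$feature_id == "mite1", ]
  expect_equal(mite$total_count, 100L)
  expect_equal(mite$pct_21, 54)
  expect_equal(mite$pct_24, 27)
  expect_equal(mite$density, 100 / 60)
})

test_that("decile binning uses floored start offsets and conserves totals", {
  element <- tibble::tibble(feature_id = "el1", start = 0L, end = 200L)
  hits <- dplyr::bind_rows(toy_hit(5, total = 4), toy_hit(172, total = 6))
  hits$feature_id <- "el1"
  dp <- decile_profile(hits, element)
  expect_equal(dp$total[dp$bin == 1], 4)
  expect_equal(dp$total[dp$bin == 9], 6)
  expect_equal(sum(dp$total), 10)

  # length filter restricts the conserved total
  hits$length <- c(21L, 24L)
  dp24 <- decile_profile(hits, element, srna_length = 24)
  expect_equal(sum(dp24$total), 6)

  expect_error(decile_profile(hits, tibble::tibble(feature_id = "x",
                                                   start = 0L, end = 5L)),
               class = "srnascan_config_error")
})

test_that("uniform profiles give a zero statistic; merging sets the df", {
  flat <- uniformity_test(rep(10, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$df, 9L)

  # mirrored terminal-bin averaging reduces the degrees of freedom
  expect_equal(uniformity_test(rep(10, 10), merge_terminal_bins = 2)$df, 7L)
  expect_equal(uniformity_test(rep(10, 10), merge_terminal_bins = 1)$df, 8L)

  # terminally concentrated profile: chi-square by hand is 800
  conc <- uniformity_test(c(100, rep(0, 8), 100))
  expect_equal(conc$statistic, 800)
  expect_lt(conc$p_value, 1e-4)

  expect_error(uniformity_test(rep(0, 10)), class = "srnascan_config_error")
})

test_that("uniformity p-value falls as mass concentrates", {
  spread <- uniformity_test(c(30, rep(10, 8), 30))
  tight <- uniformity_test(c(70, rep(10, 8), 70))
  expect_gt(spread$p_value, tight$p_value)
})

test_that("group density comparison matches a closed-form Welch oracle", {
  pa <- tibble::tibble(density = c(10, 11, 12))
  pb <- tibble::tibble(density = c(0.1, 0.2, 0.1))
  got <- compare_group_density(pa, pb)
  want <- oracle_welch(pa$density, pb$density)
  expect_equal(got$statistic, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_lt(got$p_value, 0.01)

  # identical groups: two-sided p of 1
  same <- compare_group_density(tibble::tibble(density = c(1, 2, 3)),
                                tibble::tibble(density = c(1, 2, 3)))
  expect_equal(same$p_value, 1)

  # directional contrast (top-of-nest vs lower layers)
  oneside <- compare_group_density(pa, pb, alternative = "greater")
  expect_equal(oneside$p_value, got$p_value / 2)

  expect_error(compare_group_density(tibble::tibble(density = 1), pb),
               class = "srnascan_config_error")
})

test_that("correlation test matches the covariance-formula oracle", {
  expect_equal(correlation_test(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(correlation_test(c(1, 2, 3), c(3, 2, 1))$r, -1)

  x <- c(121, 184, 274, 103, 118, 205)
  y <- c(2474, 614, 655, 377, 91, 44)
  got <- correlation_test(x, y)
  expect_equal(got$r, oracle_pearson(x, y), tolerance = 1e-12)

  expect_error(correlation_test(rep(1, 5), 1:5),
               class = "srnascan_config_error")
})

test_that("TE headers parse into classification codes", {
  p <- parse_te_header(c("RLC_Angela_17 complete Triticum aestivum",
                         "DTT_Thalos_3 complete Aegilops tauschii",
                         "RLG_Wham_2 incomplete Triticum turgidum"))
  expect_equal(p$te_class, c("I", "II", "I"))
  expect_equal(p$superfamily, c("Copia", "Mariner", "Gypsy"))
  expect_equal(p$family, c("Angela", "Thalos", "Wham"))
  expect_equal(p$complete, c(TRUE, TRUE, FALSE))
  expect_equal(p$genus, c("Triticum", "Aegilops", "Triticum"))

  expect_warning(bad <- parse_te_header("garbage header"))
  expect_equal(bad$te_class, "unknown")
  expect_equal(bad$superfamily, "unknown")
})

test_that("TE database filtering applies staged criteria with a report", {
  te <- tibble::tibble(
    id = paste0("te", 1:5),
    sequence = c(strrep("A", 50), strrep("C", 50), strrep("G", 50),
                 paste0(strrep("A", 49), "N"), strrep("T", 50)),
    complete = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    genus = c("Triticum", "Triticum", "Hordeum", "Triticum", "Aegilops")
  )
  kept <- filter_te_database(te)
  rep <- filter_report(kept)
  expect_equal(rep$n_after, c(5L, 3L, 2L, 1L))
  expect_equal(kept$id, "te5")

  # empty criteria: identity
  all_kept <- filter_te_database(te, complete_only = FALSE, genera = NULL,
                                 exclude_ambiguous = FALSE)
  expect_equal(nrow(all_kept), 5L)

  # all-clean set: no attrition
  clean <- filter_te_database(te[5, ])
  expect_equal(filter_report(clean)$n_after, rep(1L, 4))
})

test_that("annotations round-trip through GFF3", {
  ann <- toy_annotations()
  ann$kind[2] <- NA  # elements only here; add one subfeature explicitly
  sub <- tibble::tibble(feature_id = "gypsy1:LTR5", region_id = "regA",
                        start = 100L, end = 150L, category = "TE",
                        te_class = "I", superfamily = "Gypsy",
                        family = "Wham", nesting_level = 0L,
                        parent_id = "gypsy1", kind = "LTR5")
  full <- dplyr::bind_rows(ann, sub)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_te_annotations(full, path)
  back <- read_te_annotations(path)
  back <- dplyr::arrange(back, start, dplyr::desc(end))
  full <- dplyr::arrange(full, start, dplyr::desc(end))
  expect_equal(back$feature_id, full$feature_id)
  expect_equal(back$start, full$start)
  expect_equal(back$end, full$end)
  expect_equal(back$category, ifelse(is.na(full$kind), full$category, NA))
  expect_equal(back$nesting_level, full$nesting_level)
  expect_equal(back$kind, full$kind)
  expect_equal(back$parent_id, full$parent_id)
})
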