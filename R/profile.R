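#' Assign hits to annotated features
#'
#' A hit is assigned to the feature whose interval contains its full
#' footprint; when features nest, the innermost (highest `nesting_level`)
#' containing feature wins — small RNAs are thereby attributed to the most
#' recently inserted element. A hit contained in no feature but whose start
#' lies inside one is assigned to that feature and flagged in the
#' `boundary` column; hits contained nowhere get `feature_id = NA`
#' (intergenic).
#'
#' @param hits A hit tibble from [scan_region()].
#' @param annotations An annotation tibble; only element rows
#'   (`is.na(kind)`) take part in the assignment.
#' @return `hits` with added columns `feature_id` and `boundary`.
#' @export
assign_hits <- function(hits, annotations) {
  elements <- annotations[is.na(annotations$kind), , drop = FALSE]
  out <- hits
  out$feature_id <- NA_character_
  out$boundary <- FALSE
  if (nrow(hits) == 0L || nrow(elements) == 0L) return(out)
  for (reg in unique(hits$region_id)) {
    h <- which(hits$region_id == reg)
    e <- which(elements$region_id == reg)
    if (!length(e)) next
    hr <- IRanges::IRanges(start = hits$start[h] + 1L, end = hits$end[h])
    er <- IRanges::IRanges(start = elements$start[e] + 1L,
                           end = elements$end[e])
    ov <- IRanges::findOverlaps(hr, er, type = "within")
    if (length(ov)) {
      cand <- tibble(hit = S4Vectors::queryHits(ov),
                     elem = e[S4Vectors::subjectHits(ov)])
      cand$level <- elements$nesting_level[cand$elem]
      cand$width <- elements$end[cand$elem] - elements$start[cand$elem]
      best <- cand |>
        arrange(.data$hit, desc(.data$level), .data$width) |>
        dplyr::distinct(.data$hit, .keep_all = TRUE)
      out$feature_id[h[best$hit]] <- elements$feature_id[best$elem]
    }
    # boundary-straddling hits: start contained, footprint not
    left <- which(is.na(out$feature_id[h]))
    if (length(left)) {
      sr <- IRanges::IRanges(start = hits$start[h[left]] + 1L, width = 1L)
      ov2 <- IRanges::findOverlaps(sr, er)
      if (length(ov2)) {
        cand <- tibble(hit = left[S4Vectors::queryHits(ov2)],
                       elem = e[S4Vectors::subjectHits(ov2)])
        cand$level <- elements$nesting_level[cand$elem]
        cand$width <- elements$end[cand$elem] - elements$start[cand$elem]
        best <- cand |>
          arrange(.data$hit, desc(.data$level), .data$width) |>
          dplyr::distinct(.data$hit, .keep_all = TRUE)
        out$feature_id[h[best$hit]] <- elements$feature_id[best$elem]
        out$boundary[h[best$hit]] <- TRUE
      }
    }
  }
  out
}

#' Per-feature sRNA profiles
#'
#' Abundance-weighted totals, densities and 21/24-nt size-class shares per
#' annotated element. Features with zero hits are retained with zero density
#' (and `zero_total = TRUE`) so that group comparisons see the full feature
#' population.
#'
#' @param assigned_hits Output of [assign_hits()].
#' @param annotations The annotation tibble used for assignment.
#' @param libraries Optional library count columns to aggregate.
#' @return A tibble with one row per element: classification columns,
#'   `length_bp`, `total_count`, `density` (counts/bp), `n_21`, `n_24`,
#'   `pct_21`, `pct_24`, `zero_total`.
#' @export
profile_features <- function(assigned_hits, annotations, libraries = NULL) {
  elements <- annotations[is.na(annotations$kind), , drop = FALSE]
  std <- c("region_id", "start", "end", "length", "strand", "sequence",
           "total_count", "feature_id", "boundary")
  if (is.null(libraries)) libraries <- setdiff(names(assigned_hits), std)
  per_feat <- assigned_hits |>
    filter(!is.na(feature_id)) |>
    group_by(feature_id) |>
    summarise(
      n_21 = sum(total_count[length == 21L]),
      n_24 = sum(total_count[length == 24L]),
      total_count = sum(total_count),
      across(all_of(libraries), sum),
      .groups = "drop"
    )
  elements |>
    select(feature_id, region_id, category, te_class, superfamily, family,
           nesting_level, start, end) |>
    mutate(length_bp = end - start) |>
    left_join(per_feat, by = "feature_id") |>
    mutate(
      across(c("total_count", "n_21", "n_24", all_of(libraries)),
             ~ tidyr::replace_na(.x, 0L)),
      zero_total = total_count == 0L,
      density = total_count / length_bp,
      pct_21 = if_else(zero_total, 0, 100 * .data$n_21 / total_count),
      pct_24 = if_else(zero_total, 0, 100 * .data$n_24 / total_count)
    ) |>
    select(-start, -end)
}

#' Positional decile profile of an element
#'
#' The element is divided into `n_bins` equal fractions and each hit is
#' binned by its start offset within the element:
#' `bin = floor(n_bins * (start - element_start) / element_length)`, clamped
#' to the valid range. Bin totals are abundance-weighted. Bins are reported
#' 1-based (`bin` 1 is the 5'-most fraction).
#'
#' @param assigned_hits Output of [assign_hits()] (or any hit tibble whose
#'   rows all belong to the element).
#' @param element A one-row tibble with `feature_id`, `start`, `end`.
#' @param srna_length Optional filter: keep only hits of this read length
#'   (e.g. `24L`).
#' @param n_bins Number of fractions (default 10).
#' @return A tibble with columns `element_id`, `bin` (1..n_bins), `total`.
#' @export
decile_profile <- function(assigned_hits, element, srna_length = NULL,
                           n_bins = 10L) {
  stopifnot(nrow(element) == 1L)
  elen <- element$end - element$start
  if (elen < n_bins) {
    abort(sprintf("element length %d is shorter than %d bins", elen, n_bins),
          class = "srnascan_config_error")
  }
  h <- assigned_hits
  if ("feature_id" %in% names(h)) {
    h <- filter(h, feature_id == element$feature_id)
  }
  if (!is.null(srna_length)) h <- filter(h, length == srna_length)
  bins <- pmin(pmax(floor(n_bins * (h$start - element$start) / elen), 0L),
               n_bins - 1L)
  tibble(bin = bins + 1L, total = h$total_count) |>
    count(bin, wt = total, name = "total") |>
    tidyr::complete(bin = seq_len(n_bins), fill = list(total = 0)) |>
    mutate(element_id = element$feature_id, .before = 1L)
}

#' Scan TE reference sequences and profile them in deciles
#'
#' Convenience wrapper for reference elements outside a genomic context:
#' each TE sequence is scanned as its own region (both strands) and its
#' hits binned into deciles.
#'
#' @param db An `srna_db`.
#' @param te_records Tibble with `id` and `sequence` columns
#'   (e.g. from [read_te_fasta()]).
#' @param srna_length Optional read-length filter passed to
#'   [decile_profile()].
#' @param n_bins Number of fractions.
#' @return Row-bound decile profiles, one block of `n_bins` rows per element.
#' @export
te_decile_profiles <- function(db, te_records, srna_length = NULL,
                               n_bins = 10L) {
  purrr::map(seq_len(nrow(te_records)), function(i) {
    hits <- scan_region(db, te_records$sequence[i], te_records$id[i])
    element <- tibble(feature_id = te_records$id[i], start = 0L,
                      end = nchar(te_records$sequence[i]))
    hits$feature_id <- element$feature_id
    decile_profile(hits, element, srna_length = srna_length, n_bins = n_bins)
  }) |>
    purrr::list_rbind()
}

#' Chi-square test of positional uniformity
#'
#' Goodness-of-fit of a decile profile against the uniform expectation.
#' For elements flanked by duplicated terminal repeats the mirrored terminal
#' bins carry the same repeat twice; setting `merge_terminal_bins = k`
#' averages bin `i` with bin `n_bins + 1 - i` for the `k` outermost pairs
#' before testing, reducing the categories to `n_bins - k` and the degrees
#' of freedom to `n_bins - k - 1` (with 10 bins: df 7 for `k = 2`,
#' df 8 for `k = 1`).
#'
#' @param profile A decile profile tibble (column `total`) or a numeric
#'   vector of bin totals.
#' @param merge_terminal_bins Number of mirrored terminal bin pairs to
#'   average before testing.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `test_name`,
#'   `sidedness`.
#' @export
uniformity_test <- function(profile, merge_terminal_bins = 0L) {
  x <- if (is.data.frame(profile)) profile$total else as.numeric(profile)
  k <- as.integer(merge_terminal_bins)
  nb <- length(x)
  stopifnot(k >= 0L, 2L * k < nb)
  if (sum(x) <= 0) {
    abort("profile has zero total counts", class = "srnascan_config_error")
  }
  if (k > 0L) {
    merged <- (x[seq_len(k)] + x[nb + 1L - seq_len(k)]) / 2
    x <- c(merged, x[(k + 1L):(nb - k)])
  }
  expected <- sum(x) / length(x)
  statistic <- sum((x - expected)^2 / expected)
  df <- length(x) - 1L
  tibble(
    statistic = statistic, df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
    test_name = "chi-square goodness of fit vs uniform",
    sidedness = "upper tail"
  )
}

#' Compare sRNA densities between two groups of features
#'
#' Welch's two-sample t-test on per-feature `density` values, e.g. TEs vs
#' genes, or top-layer vs nested elements (use `alternative = "greater"`
#' for the directional top-vs-lower contrast).
#'
#' @param profiles_a,profiles_b Feature-profile tibbles from
#'   [profile_features()] (or any tibbles with a `density` column).
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (A vs B).
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `test_name`, `sidedness`.
#' @export
compare_group_density <- function(profiles_a, profiles_b,
                                  alternative = "two.sided") {
  a <- profiles_a$density
  b <- profiles_b$density
  if (length(a) < 2L || length(b) < 2L) {
    abort("each group needs at least two features",
          class = "srnascan_config_error")
  }
  tt <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
    test_name = "Welch two-sample t", sidedness = alternative
  )
}

#' Correlation with a significance test
#'
#' Pearson correlation (by default) with the two-sided p-value from the
#' t transform, as used to relate per-superfamily sRNA counts to element
#' abundance.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method Passed to [stats::cor.test()].
#' @return A one-row tibble with `r`, `statistic`, `df`, `p_value`,
#'   `test_name`.
#' @export
correlation_test <- function(x, y, method = "pearson") {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("x and y must have equal length >= 3",
          class = "srnascan_config_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance in x or y", class = "srnascan_config_error")
  }
  ct <- stats::cor.test(x, y, method = method)
  tibble(
    r = unname(ct$estimate),
    statistic = unname(ct$statistic),
    df = if (!is.null(ct$parameter)) unname(ct$parameter) else NA_real_,
    p_value = ct$p.value,
    test_name = paste(method, "correlation")
  )
}
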