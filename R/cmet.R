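# H = A, T or C (the non-G bases of the plant methylation contexts)
.H <- c("A", "T", "C")

#' Construct a pairwise aligned sequence pair
#'
#' @param seq_a,seq_b Gapped sequences over A/C/G/T/N/`-`, equal length.
#' @param id_a,id_b Labels.
#' @return A one-row `aligned_pair` tibble with columns `id_a`, `id_b`,
#'   `seq_a`, `seq_b`, `n_columns`.
#' @export
aligned_pair <- function(seq_a, seq_b, id_a = "seq_a", id_b = "seq_b") {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    abort(sprintf("aligned sequences differ in length (%d vs %d)",
                  nchar(seq_a), nchar(seq_b)),
          class = "srnascan_format_error")
  }
  if (grepl("[^ACGTN-]", seq_a) || grepl("[^ACGTN-]", seq_b)) {
    abort("aligned sequences may contain only A/C/G/T/N/-",
          class = "srnascan_format_error")
  }
  both_gap <- which(strsplit(seq_a, "", fixed = TRUE)[[1L]] == "-" &
                      strsplit(seq_b, "", fixed = TRUE)[[1L]] == "-")
  if (length(both_gap)) {
    abort(sprintf("column %d is a gap in both sequences", both_gap[1L]),
          class = "srnascan_format_error")
  }
  structure(
    tibble(id_a = id_a, id_b = id_b, seq_a = seq_a, seq_b = seq_b,
           n_columns = nchar(seq_a)),
    class = c("aligned_pair", class(tibble()))
  )
}

#' Load a pairwise alignment from aligned FASTA
#'
#' Expects exactly two records of equal gapped length, with `-` marking
#' indels (ClustalW-style aligned FASTA).
#'
#' @param path Path to the aligned FASTA file.
#' @return An `aligned_pair` tibble (see [aligned_pair()]).
#' @export
read_aligned_pair <- function(path) {
  seqs <- read_seq_file(path)
  if (length(seqs) != 2L) {
    abort(sprintf("aligned FASTA must contain exactly 2 records, found %d",
                  length(seqs)),
          class = "srnascan_format_error")
  }
  aligned_pair(seqs[[1L]], seqs[[2L]],
               id_a = first_token(names(seqs)[1L]),
               id_b = first_token(names(seqs)[2L]))
}

# context classes for every position of an ungapped character vector.
# A C is classified from its two downstream neighbours (CG > CHG > CHH),
# a G symmetrically from its upstream neighbours read on the reverse
# strand (done by classifying the reverse complement). Truncated terminal
# motifs: a C whose remaining neighbours cannot complete CG/CHG is CHH if
# at least one downstream neighbour exists, else nonPMS. N neighbours
# never complete a motif.
context_classes_forward_c <- function(u) {
  n <- length(u)
  cls <- rep("nonPMS", n)
  if (n == 0L) return(cls)
  un <- u
  un[un == "N"] <- NA_character_
  nxt1 <- c(un[-1L], NA_character_)
  nxt2 <- if (n > 2L) c(un[-c(1L, 2L)], NA, NA) else rep(NA_character_, n)
  isC <- !is.na(un) & un == "C"
  cg <- isC & !is.na(nxt1) & nxt1 == "G"
  h1 <- isC & !cg & !is.na(nxt1) & nxt1 %in% .H
  # flag positions that still have a physical second neighbour
  has2 <- c(rep(TRUE, max(0L, n - 2L)), FALSE, FALSE)[seq_len(n)]
  chg <- h1 & !is.na(nxt2) & nxt2 == "G"
  chh <- h1 & !chg & (is.na(nxt2) | nxt2 %in% .H | !has2)
  cls[chh] <- "CHH"
  cls[chg] <- "CHG"
  cls[cg] <- "CG"
  cls
}

complement_chars <- function(u) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[u])
}

context_classes <- function(u) {
  cls <- context_classes_forward_c(u)
  n <- length(u)
  if (n == 0L) return(cls)
  rc <- rev(complement_chars(u))
  cls_rc <- context_classes_forward_c(rc)
  gpos <- which(u == "G")
  if (length(gpos)) cls[gpos] <- cls_rc[n + 1L - gpos]
  cls
}

.class_rank <- c(CG = 4L, CHG = 3L, CHH = 2L, nonPMS = 1L)

#' Classify alignment columns into methylation contexts
#'
#' Every column of the alignment is classified, for each sequence, as CG,
#' CHG, CHH or nonPMS. Context neighbours are taken from each sequence's
#' own ungapped coordinates (gaps are skipped): a methylation context is a
#' property of a physical chromosome, not of an alignment column. Both the
#' C and the G of a CG or CHG motif receive the motif's class, and a
#' motif present in either genome suffices, so the combined per-column
#' class is the stronger of the two under the precedence
#' CG > CHG > CHH > nonPMS. Columns with a gap in either sequence are
#' excluded (`"gap"`); columns with an N in either sequence are excluded
#' separately (`"ambiguous"`).
#'
#' @param pair An `aligned_pair`.
#' @return A tibble with one row per alignment column: `column` (1-based),
#'   `base_a`, `base_b`, `class_a`, `class_b`, `class` (combined),
#'   `excluded` (`"none"`, `"gap"` or `"ambiguous"`).
#' @export
classify_methylation_sites <- function(pair) {
  a <- strsplit(pair$seq_a[1L], "", fixed = TRUE)[[1L]]
  b <- strsplit(pair$seq_b[1L], "", fixed = TRUE)[[1L]]
  gap_a <- a == "-"
  gap_b <- b == "-"
  ua <- a[!gap_a]
  ub <- b[!gap_b]
  cls_a <- rep(NA_character_, length(a))
  cls_b <- rep(NA_character_, length(b))
  cls_a[!gap_a] <- context_classes(ua)
  cls_b[!gap_b] <- context_classes(ub)
  excluded <- rep("none", length(a))
  excluded[a == "N" | b == "N"] <- "ambiguous"
  excluded[gap_a | gap_b] <- "gap"
  combined <- ifelse(
    excluded == "none",
    names(.class_rank)[5L - pmax(.class_rank[cls_a], .class_rank[cls_b])],
    NA_character_
  )
  tibble(
    column = seq_along(a), base_a = a, base_b = b,
    class_a = cls_a, class_b = cls_b, class = combined, excluded = excluded
  )
}

.ts_pairs <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)

is_transition <- function(x, y) {
  !is.na(.ts_pairs[paste0(x, y)])
}

#' Tally substitutions by methylation context
#'
#' Counts aligned sites, transitions (A<->G, C<->T) and transversions (all
#' other mismatches) per combined methylation context. Columns with a gap
#' or an N in either sequence are excluded from all counts and reported in
#' the attached attributes. Every mismatched usable column is counted
#' exactly once, as a transition xor a transversion.
#'
#' @param pair An `aligned_pair`.
#' @param strata Optional tibble with columns `name`, `start`, `end`
#'   (0-based half-open, alignment-column coordinates) stratifying the
#'   tally, e.g. TE vs intron/UTR footprints. Columns outside every
#'   stratum are reported under `"unstratified"`.
#' @param site_classes Optional precomputed result of
#'   [classify_methylation_sites()] for the same pair.
#' @return A tibble with one row per (stratum x) context — `CG`, `CHG`,
#'   `CHH`, `nonPMS` — and columns `sites`, `transitions`, `transversions`,
#'   plus attributes `aligned_columns_used`, `columns_excluded_by_gap`,
#'   `columns_excluded_by_ambiguity`.
#' @export
tally_substitutions <- function(pair, strata = NULL, site_classes = NULL) {
  sc <- if (is.null(site_classes)) classify_methylation_sites(pair) else
    site_classes
  usable <- sc$excluded == "none"
  mismatch <- usable & sc$base_a != sc$base_b
  ts <- mismatch & is_transition(sc$base_a, sc$base_b)
  tv <- mismatch & !ts
  contexts <- c("CG", "CHG", "CHH", "nonPMS")
  stratum_of <- rep("all", nrow(sc))
  if (!is.null(strata)) {
    stratum_of <- rep("unstratified", nrow(sc))
    for (i in seq_len(nrow(strata))) {
      cols <- sc$column > strata$start[i] & sc$column <= strata$end[i]
      stratum_of[cols] <- strata$name[i]
    }
  }
  strat_levels <- if (is.null(strata)) "all" else
    sort(unique(c(strata$name, stratum_of[usable])))
  f_str <- factor(stratum_of, levels = strat_levels)
  f_ctx <- factor(sc$class, levels = contexts)
  count_in <- function(sel) {
    as.integer(t(table(f_str[sel], f_ctx[sel])))
  }
  out <- tibble(
    stratum = rep(strat_levels, each = length(contexts)),
    context = rep(contexts, times = length(strat_levels)),
    sites = count_in(usable),
    transitions = count_in(ts),
    transversions = count_in(tv)
  )
  if (is.null(strata)) out$stratum <- NULL
  attr(out, "aligned_columns_used") <- sum(usable)
  attr(out, "columns_excluded_by_gap") <- sum(sc$excluded == "gap")
  attr(out, "columns_excluded_by_ambiguity") <- sum(sc$excluded == "ambiguous")
  out
}

#' Per-context substitution percentages
#'
#' Transitions and transversions per site, as percentages, per context.
#' Contexts with zero sites are reported as `NA` rather than raising a
#' division error.
#'
#' @param tally Output of [tally_substitutions()].
#' @return The tally with added columns `pct_transitions`,
#'   `pct_transversions`, `pct_mutations`.
#' @export
context_frequencies <- function(tally) {
  tally |>
    mutate(
      pct_transitions = if_else(sites > 0, 100 * transitions / sites,
                                NA_real_),
      pct_transversions = if_else(sites > 0, 100 * transversions / sites,
                                  NA_real_),
      pct_mutations = if_else(sites > 0,
                              100 * (transitions + transversions) / sites,
                              NA_real_)
    )
}

#' Pooled PMS vs non-PMS mutation contrast
#'
#' Pools CG + CHG + CHH into a single potentially-methylated-site (PMS)
#' class and contrasts its per-site mutation and transition frequencies
#' against non-PMS sites. The fold elevation of the transition frequency
#' at PMS is the mutational footprint of methylation.
#'
#' @param tally Output of [tally_substitutions()] (unstratified, or filter
#'   one stratum first).
#' @return A one-row tibble: sites and frequencies per pooled class and the
#'   `mutation_fold` / `transition_fold` ratios (NA where undefined).
#' @export
pms_contrast <- function(tally) {
  pms <- tally$context %in% c("CG", "CHG", "CHH")
  s_p <- sum(tally$sites[pms]); s_n <- sum(tally$sites[!pms])
  mut_p <- sum(tally$transitions[pms] + tally$transversions[pms])
  mut_n <- sum(tally$transitions[!pms] + tally$transversions[!pms])
  ts_p <- sum(tally$transitions[pms]); ts_n <- sum(tally$transitions[!pms])
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  mut_rate_p <- rate(mut_p, s_p); mut_rate_n <- rate(mut_n, s_n)
  ts_rate_p <- rate(ts_p, s_p); ts_rate_n <- rate(ts_n, s_n)
  tibble(
    pms_sites = s_p, nonpms_sites = s_n,
    pms_mutations_per_site = mut_rate_p,
    nonpms_mutations_per_site = mut_rate_n,
    pms_transitions_per_site = ts_rate_p,
    nonpms_transitions_per_site = ts_rate_n,
    mutation_fold = if (!is.na(mut_rate_n) && mut_rate_n > 0)
      mut_rate_p / mut_rate_n else NA_real_,
    transition_fold = if (!is.na(ts_rate_n) && ts_rate_n > 0)
      ts_rate_p / ts_rate_n else NA_real_
  )
}

#' Estimate the methylation-driven transition elevation between strata
#'
#' Compares the per-site transition frequency at potentially methylated
#' sites (PMS: CG + CHG + CHH) between a methylated test stratum and an
#' unmethylated reference stratum. Because any substitution that creates a
#' C or G also creates a methylation context, transitions arising at
#' ancestral A/T sites flow into the PMS class in both strata and compress
#' the raw ratio; with PMS site share \eqn{s}, a true fold elevation
#' \eqn{m} yields an observed ratio \eqn{R = (s\,m + (1-s))/(s + (1-s))},
#' inverted here as \eqn{\hat m = (R - (1 - s))/s}.
#'
#' @param tally A stratified tally from [tally_substitutions()].
#' @param stratum_test Name of the (putatively methylated) test stratum.
#' @param stratum_ref Name of the unmethylated reference stratum.
#' @return A one-row tibble with the per-stratum PMS transition
#'   frequencies, the raw `ratio`, the PMS site share `pms_share` (from
#'   the reference stratum) and the corrected `elevation`.
#' @export
estimate_transition_elevation <- function(tally, stratum_test,
                                          stratum_ref) {
  freqs <- function(strat) {
    t <- tally[tally$stratum == strat, , drop = FALSE]
    if (nrow(t) == 0L) {
      abort(paste0("no stratum '", strat, "' in tally"),
            class = "srnascan_config_error")
    }
    pms <- t$context != "nonPMS"
    list(ts_freq = sum(t$transitions[pms]) / sum(t$sites[pms]),
         share = sum(t$sites[pms]) / sum(t$sites))
  }
  a <- freqs(stratum_test)
  g <- freqs(stratum_ref)
  ratio <- a$ts_freq / g$ts_freq
  s <- g$share
  tibble(
    test_ts_freq = a$ts_freq, ref_ts_freq = g$ts_freq,
    ratio = ratio, pms_share = s,
    elevation = (ratio - (1 - s)) / s
  )
}
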