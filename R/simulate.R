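#' Default TE catalogue for genome simulation
#'
#' One row per TE family: number of copies, element length range, and the
#' terminal-repeat substructure (`LTR` for retroelements, `TIR` for DNA
#' transposons and MITEs — CACTA terminal repeats start with the CACTA
#' motif — or `none` for LINEs). The defaults yield a gene-island genome
#' of roughly 60% TE sequence with superfamily proportions and LTR/TIR
#' lengths typical of Triticeae gene-rich regions (Gypsy LTRs about twice
#' as long as Copia LTRs; Stowaway-like MITEs that are mostly TIR).
#'
#' @return A tibble with columns `family`, `superfamily`, `te_class`,
#'   `n_copies`, `min_length`, `max_length`, `terminal_kind`,
#'   `terminal_length`.
#' @export
default_te_catalogue <- function() {
  tibble::tribble(
    ~family,   ~superfamily, ~te_class, ~n_copies, ~min_length, ~max_length, ~terminal_kind, ~terminal_length,
    "Angela",  "Copia",      "I",        4L,        6000L,       9000L,       "LTR",          1100L,
    "WIS",     "Copia",      "I",        2L,        6000L,       9000L,       "LTR",          1100L,
    "Sabrina", "Gypsy",      "I",        3L,        8000L,      12000L,       "LTR",          2000L,
    "Wham",    "Gypsy",      "I",        2L,        8000L,      12000L,       "LTR",          2000L,
    "Caspar",  "CACTA",      "II",       3L,        3000L,       6000L,       "TIR",          300L,
    "Thalos",  "Mariner",    "II",       8L,        150L,        400L,        "TIR",          60L,
    "Karin",   "LINE",       "I",        2L,        3000L,       5000L,       "none",         0L
  )
}

#' Genome simulation configuration
#'
#' @param seed Integer seed; all randomness of [simulate_genome()] flows
#'   from it.
#' @param background_length Length of the initial intergenic background
#'   (bp); insertions grow the genome beyond it.
#' @param gc GC content of background, gene and TE consensus sequence.
#' @param te_catalogue Family table, see [default_te_catalogue()].
#' @param copy_mutation_rate Per-site substitution probability applied to
#'   each inserted copy of a family consensus, so copies are near- but not
#'   fully identical (perfect sRNA matches across copies still arise).
#' @param nesting_probability Probability that an insertion lands inside an
#'   existing TE rather than in background.
#' @param max_nesting Maximum nesting depth (layers of nested insertions).
#' @param n_genes,gene_length_range Number and length range of gene
#'   intervals; TEs never insert into genes.
#' @return A `genome_sim_config` list.
#' @export
genome_sim_config <- function(seed = 1L, background_length = 60000L,
                              gc = 0.46,
                              te_catalogue = default_te_catalogue(),
                              copy_mutation_rate = 0.02,
                              nesting_probability = 0.3,
                              max_nesting = 4L,
                              n_genes = 3L,
                              gene_length_range = c(2000L, 5000L)) {
  structure(
    list(seed = as.integer(seed), background_length = background_length,
         gc = gc, te_catalogue = te_catalogue,
         copy_mutation_rate = copy_mutation_rate,
         nesting_probability = nesting_probability,
         max_nesting = as.integer(max_nesting), n_genes = n_genes,
         gene_length_range = gene_length_range),
    class = "genome_sim_config"
  )
}

# build a family consensus with its substructure; returns the element
# string and a tibble of subfeature intervals relative to the element
build_consensus <- function(fam, gc) {
  len <- sample(seq.int(fam$min_length, fam$max_length), 1L)
  tl <- fam$terminal_length
  if (fam$terminal_kind != "none") tl <- min(tl, (len - 10L) %/% 2L)
  if (fam$terminal_kind == "LTR") {
    term <- random_dna(tl, gc)
    elem <- paste0(term, random_dna(len - 2L * tl, gc), term)
    subf <- tibble(kind = c("LTR5", "internal", "LTR3"),
                   start = c(0L, tl, len - tl),
                   end = c(tl, len - tl, len))
  } else if (fam$terminal_kind == "TIR") {
    term <- if (fam$superfamily == "CACTA") {
      paste0("CACTA", random_dna(tl - 5L, gc))
    } else {
      random_dna(tl, gc)
    }
    elem <- paste0(term, random_dna(len - 2L * tl, gc),
                   reverse_complement(term))
    subf <- tibble(kind = c("TIR5", "internal", "TIR3"),
                   start = c(0L, tl, len - tl),
                   end = c(tl, len - tl, len))
  } else {
    elem <- random_dna(len, gc)
    subf <- tibble(kind = character(0), start = integer(0), end = integer(0))
  }
  list(sequence = elem, length = len, subfeatures = subf)
}

#' Simulate a repeat-rich genomic region with nested TE annotation
#'
#' Builds an i.i.d. background, places gene intervals, then splices in TE
#' copies one at a time: each copy is the family consensus with per-copy
#' substitutions, inserted either into background or — with
#' `nesting_probability` — strictly inside an existing TE, whose interval
#' (and any spanning subfeature) is extended accordingly and whose nesting
#' level the new element exceeds by one, up to `max_nesting`. Deterministic
#' for a fixed seed.
#'
#' @param config A [genome_sim_config()].
#' @return A list with `region` (tibble: `region_id`, `sequence`, `length`),
#'   `annotations` (tibble as in [read_te_annotations()]), `truth` (one row
#'   per insertion event, in order) and `config`.
#' @export
simulate_genome <- function(config = genome_sim_config()) {
  withr::local_seed(config$seed)
  region_id <- paste0("simreg_", config$seed)
  genome <- random_dna(config$background_length, config$gc)
  ann <- tibble(
    feature_id = character(0), region_id = character(0),
    start = integer(0), end = integer(0), category = character(0),
    te_class = character(0), superfamily = character(0),
    family = character(0), nesting_level = integer(0),
    parent_id = character(0), kind = character(0)
  )
  truth <- list()

  strictly_inside <- function(p, rows) {
    rows$start < p & p < rows$end
  }
  shift_after_insert <- function(ann, p, L) {
    right <- ann$start >= p
    span <- ann$start < p & ann$end > p
    ann$start[right] <- ann$start[right] + L
    ann$end[right] <- ann$end[right] + L
    ann$end[span] <- ann$end[span] + L
    ann
  }
  splice <- function(genome, p, seq) {
    paste0(substr(genome, 1L, p), seq,
           substr(genome, p + 1L, nchar(genome)))
  }

  # genes first: spliced into background, never overlapping each other
  for (i in seq_len(config$n_genes)) {
    glen <- sample(seq.int(config$gene_length_range[1L],
                           config$gene_length_range[2L]), 1L)
    repeat {
      p <- sample.int(nchar(genome) + 1L, 1L) - 1L
      if (!any(strictly_inside(p, ann))) break
    }
    gid <- sprintf("gene_%02d", i)
    ann <- shift_after_insert(ann, p, glen)
    ann <- dplyr::add_row(ann, feature_id = gid, region_id = region_id,
                          start = p, end = p + glen, category = "gene",
                          te_class = NA, superfamily = NA, family = NA,
                          nesting_level = 0L, parent_id = NA, kind = NA)
    genome <- splice(genome, p, random_dna(glen, config$gc))
  }

  # family consensus sequences, built once
  cat_tbl <- config$te_catalogue
  consensi <- lapply(seq_len(nrow(cat_tbl)), function(i)
    build_consensus(cat_tbl[i, ], config$gc))
  copies <- cat_tbl |>
    mutate(fam_row = dplyr::row_number()) |>
    tidyr::uncount(n_copies, .id = "copy")
  copies <- copies[sample.int(nrow(copies)), , drop = FALSE]

  for (i in seq_len(nrow(copies))) {
    fam <- copies[i, ]
    cons <- consensi[[fam$fam_row]]
    elem_seq <- substitute_sites(cons$sequence, config$copy_mutation_rate)
    L <- cons$length
    elements <- ann[is.na(ann$kind) & ann$category %in% "TE", , drop = FALSE]
    genes <- ann[ann$category %in% "gene" & is.na(ann$kind), , drop = FALSE]
    p <- NA_integer_
    parent <- NA_character_
    level <- 0L
    want_nested <- stats::runif(1L) < config$nesting_probability &&
      nrow(elements) > 0L
    if (want_nested) {
      for (try in seq_len(50L)) {
        host <- elements[sample.int(nrow(elements), 1L), ]
        if (host$end - host$start < 2L) next
        cand <- host$start + sample.int(host$end - host$start - 1L, 1L)
        inside <- elements[strictly_inside(cand, elements), , drop = FALSE]
        lev <- max(inside$nesting_level) + 1L
        if (lev <= config$max_nesting) {
          p <- cand
          level <- lev
          parent <- inside$feature_id[which.max(inside$nesting_level)]
          break
        }
      }
    }
    if (is.na(p)) {
      repeat {
        cand <- sample.int(nchar(genome) + 1L, 1L) - 1L
        if (!any(strictly_inside(cand, elements)) &&
            !any(strictly_inside(cand, genes))) {
          p <- cand
          level <- 0L
          parent <- NA_character_
          break
        }
      }
    }
    eid <- sprintf("%s_%02d", fam$family, fam$copy)
    ann <- shift_after_insert(ann, p, L)
    ann <- dplyr::add_row(ann, feature_id = eid, region_id = region_id,
                          start = p, end = p + L, category = "TE",
                          te_class = fam$te_class,
                          superfamily = fam$superfamily, family = fam$family,
                          nesting_level = level, parent_id = parent,
                          kind = NA)
    if (nrow(cons$subfeatures)) {
      ann <- dplyr::bind_rows(ann, cons$subfeatures |>
        mutate(feature_id = paste0(eid, ":", kind), region_id = region_id,
               start = start + p, end = end + p, category = "TE",
               te_class = fam$te_class, superfamily = fam$superfamily,
               family = fam$family, nesting_level = level, parent_id = eid))
    }
    genome <- splice(genome, p, elem_seq)
    truth[[length(truth) + 1L]] <- tibble(
      order = length(truth) + 1L, feature_id = eid, family = fam$family,
      superfamily = fam$superfamily, insert_point = p, length = L,
      nesting_level = level, parent_id = parent
    )
  }
  list(
    region = tibble(region_id = region_id, sequence = genome,
                    length = nchar(genome)),
    annotations = arrange(ann, start, desc(end)),
    truth = dplyr::bind_rows(truth),
    config = config
  )
}

# per-site substitution of a string with probability `rate`
substitute_sites <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    chars[hit] <- vapply(chars[hit], function(b)
      sample(alt[[b]], 1L), character(1))
  }
  paste(chars, collapse = "")
}

# default read-length mixtures over the 18-33 nt window: the 21- and
# 24-nt shares match the database-wide bimodal peaks; the remainder is
# spread evenly over the other lengths
default_length_probs <- function(p21 = 0.177, p24 = 0.287) {
  lens <- 18:33
  p <- stats::setNames(rep((1 - p21 - p24) / (length(lens) - 2L),
                           length(lens)), lens)
  p["21"] <- p21
  p["24"] <- p24
  p
}

#' sRNA library simulation configuration
#'
#' @param seed Integer seed.
#' @param n_reads Total reads to draw.
#' @param library_id Label attached to the reads.
#' @param length_probs Named probability vector over read lengths (names =
#'   nt); default peaks of 17.7% at 21 nt and 28.7% at 24 nt.
#' @param mariner_length_probs Length mixture used for reads originating
#'   from Mariner-superfamily features (MITEs are dominated by the 21-nt
#'   class: default 54% 21-nt, 27% 24-nt).
#' @param origin_weights Named weights over read origins: `te_terminal`
#'   (LTR/TIR subregions), `te_body` (whole elements), `gene`,
#'   `background` (anywhere on the genome) and `non_genomic` (sequencing
#'   background not drawn from the genome). Must sum to 1.
#' @return A `library_sim_config` list.
#' @export
library_sim_config <- function(seed = 1L, n_reads = 20000L,
                               library_id = "SIM1",
                               length_probs = default_length_probs(),
                               mariner_length_probs =
                                 default_length_probs(0.54, 0.27),
                               origin_weights = c(te_terminal = 0.55,
                                                  te_body = 0.15,
                                                  gene = 0.02,
                                                  background = 0.18,
                                                  non_genomic = 0.10)) {
  if (abs(sum(origin_weights) - 1) > 1e-8) {
    abort("origin_weights must sum to 1", class = "srnascan_config_error")
  }
  structure(
    list(seed = as.integer(seed), n_reads = n_reads,
         library_id = library_id, length_probs = length_probs,
         mariner_length_probs = mariner_length_probs,
         origin_weights = origin_weights),
    class = "library_sim_config"
  )
}

#' Simulate an sRNA library from an annotated genome
#'
#' Draws reads from the configured origin mixture: exact substrings of the
#' genome (forward strand or reverse complement) taken from terminal-repeat
#' subregions, whole TE bodies, genes or anywhere (background), plus a
#' non-genomic sequencing-background component of random sequence. Read
#' lengths follow the configured mixture, with the Mariner-specific mixture
#' for reads originating in Mariner features. Each read's true origin is
#' recorded.
#'
#' @param genome Output of [simulate_genome()], or a genome string (then
#'   supply `annotations`).
#' @param config A [library_sim_config()].
#' @param annotations Annotation tibble when `genome` is a string.
#' @return A list with `reads` (tibble: `sequence`, `library_id`), `truth`
#'   (one row per read: origin category, feature, forward-strand footprint
#'   start, length, strand; `resampled` marks reads rerouted to background
#'   because the drawn feature was shorter than the drawn read) and
#'   `config`.
#' @export
simulate_srna_library <- function(genome, config = library_sim_config(),
                                  annotations = NULL) {
  if (is.list(genome) && !is.null(genome$region)) {
    annotations <- genome$annotations
    genome <- genome$region$sequence[1L]
  }
  withr::local_seed(config$seed)
  n <- config$n_reads
  glen <- nchar(genome)
  w <- config$origin_weights
  if (n == 0L) {
    return(list(reads = tibble(sequence = character(0),
                               library_id = character(0)),
                truth = tibble(), config = config))
  }
  pools <- list(
    te_terminal = annotations[!is.na(annotations$kind) &
                                annotations$kind %in%
                                c("LTR5", "LTR3", "TIR5", "TIR3"), ,
                              drop = FALSE],
    te_body = annotations[is.na(annotations$kind) &
                            annotations$category %in% "TE", , drop = FALSE],
    gene = annotations[is.na(annotations$kind) &
                         annotations$category %in% "gene", , drop = FALSE]
  )
  category <- sample(names(w), n, replace = TRUE, prob = w)
  # origins without available features fall back to background
  for (cat in names(pools)) {
    if (nrow(pools[[cat]]) == 0L) category[category == cat] <- "background"
  }
  lens <- as.integer(names(config$length_probs))
  read_len <- integer(n)
  feature_id <- rep(NA_character_, n)
  kind <- rep(NA_character_, n)
  start <- rep(NA_integer_, n)
  resampled <- logical(n)
  superfam <- rep(NA_character_, n)

  for (cat in names(pools)) {
    idx <- which(category == cat)
    if (!length(idx)) next
    pool <- pools[[cat]]
    row <- sample.int(nrow(pool), length(idx), replace = TRUE)
    feature_id[idx] <- pool$feature_id[row]
    kind[idx] <- pool$kind[row]
    superfam[idx] <- pool$superfamily[row]
  }
  is_mar <- !is.na(superfam) & superfam == "Mariner"
  read_len[is_mar] <- sample(lens, sum(is_mar), replace = TRUE,
                             prob = config$mariner_length_probs)
  read_len[!is_mar] <- sample(lens, sum(!is_mar), replace = TRUE,
                              prob = config$length_probs)

  feat_idx <- match(feature_id, annotations$feature_id)
  genomic <- category %in% c(names(pools))
  fstart <- ifelse(genomic, annotations$start[feat_idx], 0L)
  fend <- ifelse(genomic, annotations$end[feat_idx], glen)
  too_small <- (category %in% c(names(pools), "background")) &
    (fend - fstart < read_len)
  if (any(too_small)) {
    # reroute to whole-genome background and record the resampling
    resampled[too_small] <- TRUE
    category[too_small] <- "background"
    feature_id[too_small] <- NA_character_
    kind[too_small] <- NA_character_
    fstart[too_small] <- 0L
    fend[too_small] <- glen
  }
  drawable <- category %in% c(names(pools), "background")
  width <- fend - fstart - read_len + 1L
  start[drawable] <- fstart[drawable] +
    floor(stats::runif(sum(drawable)) * width[drawable])
  strand <- sample(c("+", "-"), n, replace = TRUE)
  strand[!drawable] <- NA_character_

  sequence <- character(n)
  gi <- which(drawable)
  sequence[gi] <- substring(genome, start[gi] + 1L, start[gi] + read_len[gi])
  minus <- which(drawable & strand == "-")
  if (length(minus)) {
    sequence[minus] <- reverse_complement(sequence[minus])
  }
  ng <- which(!drawable)
  if (length(ng)) {
    sequence[ng] <- vapply(read_len[ng], function(L) random_dna(L, 0.5),
                           character(1))
  }
  list(
    reads = tibble(sequence = sequence, library_id = config$library_id),
    truth = tibble(read_id = seq_len(n), category = category,
                   feature_id = feature_id, kind = kind, start = start,
                   length = read_len, strand = strand,
                   resampled = resampled),
    config = config
  )
}

#' Orthologous-pair divergence simulation configuration
#'
#' @param seed Integer seed.
#' @param length Ancestor length in bp.
#' @param gc Ancestor GC content.
#' @param age_years Time since the two lineages split.
#' @param transition_rate,transversion_rate Baseline substitution rates in
#'   substitutions per site per year; the defaults sum to the genic rate
#'   of 5.5e-9.
#' @param pms_transition_multiplier Fold elevation of the transition rate
#'   at sites that are potentially methylated (CG/CHG/CHH context) in the
#'   ancestor, within methylated strata; models accelerated deamination of
#'   methylcytosine (default 10).
#' @param strata Optional tibble with `name`, `start`, `end` (0-based
#'   half-open, ancestor coordinates) and logical `methylated`; `NULL`
#'   treats the whole sequence as one methylated stratum.
#' @param indel_rate Per-site per-lineage probability of starting a
#'   deletion; deleted sites appear as `-` in the emitted alignment (the
#'   true alignment is emitted, no realignment step).
#' @param indel_mean_length Mean deletion length (geometric).
#' @return A `divergence_sim_config` list.
#' @export
divergence_sim_config <- function(seed = 1L, length = 100000L, gc = 0.46,
                                  age_years = 1.1e6,
                                  transition_rate = 3.5e-9,
                                  transversion_rate = 2.0e-9,
                                  pms_transition_multiplier = 10,
                                  strata = NULL,
                                  indel_rate = 0,
                                  indel_mean_length = 3) {
  stopifnot(pms_transition_multiplier >= 1, transition_rate >= 0,
            transversion_rate >= 0, indel_rate >= 0)
  structure(
    list(seed = as.integer(seed), length = length, gc = gc,
         age_years = age_years, transition_rate = transition_rate,
         transversion_rate = transversion_rate,
         pms_transition_multiplier = pms_transition_multiplier,
         strata = strata, indel_rate = indel_rate,
         indel_mean_length = indel_mean_length),
    class = "divergence_sim_config"
  )
}

.ts_target <- c(A = "G", G = "A", C = "T", T = "C")
.tv_targets <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

# evolve one lineage from the ancestor chars; p_ts/p_tv are per-site
# substitution probabilities over the whole branch (single-hit model)
evolve_lineage <- function(anc, p_ts, p_tv) {
  u <- stats::runif(length(anc))
  out <- anc
  ts_hit <- which(u < p_ts)
  tv_hit <- which(u >= p_ts & u < p_ts + p_tv)
  if (length(ts_hit)) out[ts_hit] <- .ts_target[anc[ts_hit]]
  if (length(tv_hit)) {
    pick <- sample.int(2L, length(tv_hit), replace = TRUE)
    out[tv_hit] <- mapply(function(b, k) .tv_targets[[b]][k],
                          anc[tv_hit], pick)
  }
  out
}

# deletion mask for one lineage: TRUE where the site is deleted
deletion_mask <- function(n, rate, mean_len) {
  del <- logical(n)
  if (rate <= 0) return(del)
  starts <- which(stats::runif(n) < rate)
  if (length(starts)) {
    lens <- 1L + stats::rgeom(length(starts), prob = 1 / mean_len)
    for (i in seq_along(starts)) {
      del[starts[i]:min(n, starts[i] + lens[i] - 1L)] <- TRUE
    }
  }
  del
}

#' Evolve a diverged orthologous pair from a common ancestor
#'
#' Two descendants evolve independently from one ancestor for `age_years`
#' under a single-hit substitution model with separate transition and
#' transversion rates; at ancestor sites in a CG/CHG/CHH context inside
#' methylated strata, the transition rate is multiplied by
#' `pms_transition_multiplier`. Deletions (if any) appear as `-` in the
#' emitted alignment, which is the true alignment; positions deleted in
#' both lineages are dropped. The returned truth tally classifies the
#' emitted columns with an independent position-by-position enumerator
#' (the same context rules, implemented separately from the vectorised
#' scanner), so it can serve as an oracle for [tally_substitutions()].
#'
#' @param config A [divergence_sim_config()].
#' @return A list with `pair` (an [aligned_pair()]), `truth` (list:
#'   `tally` by stratum and context, `strata_columns` in emitted
#'   alignment-column coordinates, `ancestor`, `n_pms_ancestor`) and
#'   `config`.
#' @export
evolve_pair <- function(config = divergence_sim_config()) {
  withr::local_seed(config$seed)
  n <- config$length
  anc <- strsplit(random_dna(n, config$gc), "", fixed = TRUE)[[1L]]
  strata <- config$strata
  if (is.null(strata)) {
    strata <- tibble(name = "all", start = 0L, end = n, methylated = TRUE)
  }
  meth <- logical(n)
  stratum_of <- rep("unstratified", n)
  for (i in seq_len(nrow(strata))) {
    span <- (strata$start[i] + 1L):strata$end[i]
    stratum_of[span] <- strata$name[i]
    meth[span] <- isTRUE(strata$methylated[i])
  }
  anc_pms <- context_classes(anc) != "nonPMS"
  t_years <- config$age_years
  p_ts <- config$transition_rate * t_years *
    ifelse(anc_pms & meth, config$pms_transition_multiplier, 1)
  p_tv <- config$transversion_rate * t_years
  if (any(p_ts + p_tv >= 1)) {
    abort("substitution probabilities exceed 1; reduce rates or age",
          class = "srnascan_config_error")
  }
  d1 <- evolve_lineage(anc, p_ts, p_tv)
  d2 <- evolve_lineage(anc, p_ts, p_tv)
  del1 <- deletion_mask(n, config$indel_rate, config$indel_mean_length)
  del2 <- deletion_mask(n, config$indel_rate, config$indel_mean_length)
  keep <- !(del1 & del2)
  a <- ifelse(del1, "-", d1)[keep]
  b <- ifelse(del2, "-", d2)[keep]
  pair <- aligned_pair(paste(a, collapse = ""), paste(b, collapse = ""),
                       id_a = "lineage_a", id_b = "lineage_b")
  # strata in emitted column coordinates (0-based half-open)
  kept_before <- c(0L, cumsum(keep))
  strata_columns <- strata |>
    mutate(start = kept_before[start + 1L], end = kept_before[end + 1L]) |>
    select(name, start, end)
  truth_tally <- enumerate_pair_tally(a, b, stratum_of[keep])
  list(
    pair = pair,
    truth = list(tally = truth_tally, strata_columns = strata_columns,
                 ancestor = paste(anc, collapse = ""),
                 n_pms_ancestor = sum(anc_pms)),
    config = config
  )
}

# --- independent brute-force enumerator -------------------------------
# classifies one ungapped position by direct inspection of its
# neighbours; used for simulator truth and available to tests as an
# oracle for the vectorised classifier
classify_position <- function(u, i) {
  # an N neighbour is an unknown base: it never completes a CG/CHG motif
  # but leaves a truncated CHH possible, like a missing neighbour
  h <- c("A", "T", "C")
  b <- u[i]
  if (b == "C") {
    n1 <- if (i < length(u)) u[i + 1L] else NA_character_
    n2 <- if (i + 1L < length(u)) u[i + 2L] else NA_character_
    if (!is.na(n1) && n1 == "G") return("CG")
    if (!is.na(n1) && n1 %in% h) {
      if (!is.na(n2) && n2 == "G") return("CHG")
      if (is.na(n2) || n2 == "N" || n2 %in% h) return("CHH")
    }
    return("nonPMS")
  }
  if (b == "G") {
    p1 <- if (i > 1L) u[i - 1L] else NA_character_
    p2 <- if (i > 2L) u[i - 2L] else NA_character_
    if (!is.na(p1) && p1 == "C") return("CG")
    if (!is.na(p1) && p1 %in% c("T", "A", "G")) {
      if (!is.na(p2) && p2 == "C") return("CHG")
      if (is.na(p2) || p2 == "N" || p2 %in% c("T", "A", "G")) return("CHH")
    }
    return("nonPMS")
  }
  "nonPMS"
}

# column-by-column tally of an alignment given as two character vectors
enumerate_pair_tally <- function(a, b, stratum_of = NULL) {
  if (is.null(stratum_of)) stratum_of <- rep("all", length(a))
  ua <- a[a != "-"]
  ub <- b[b != "-"]
  ia <- cumsum(a != "-")
  ib <- cumsum(b != "-")
  rank <- c(CG = 4L, CHG = 3L, CHH = 2L, nonPMS = 1L)
  acc <- list()
  bump <- function(acc, key, field) {
    if (is.null(acc[[key]])) {
      acc[[key]] <- c(sites = 0L, transitions = 0L, transversions = 0L)
    }
    acc[[key]][field] <- acc[[key]][field] + 1L
    acc
  }
  for (col in seq_along(a)) {
    x <- a[col]; y <- b[col]
    if (x == "-" || y == "-") next
    if (x == "N" || y == "N") next
    ca <- classify_position(ua, ia[col])
    cb <- classify_position(ub, ib[col])
    cls <- if (rank[ca] >= rank[cb]) ca else cb
    key <- paste(stratum_of[col], cls, sep = "\r")
    acc <- bump(acc, key, "sites")
    if (x != y) {
      is_ts <- (x == "A" && y == "G") || (x == "G" && y == "A") ||
        (x == "C" && y == "T") || (x == "T" && y == "C")
      acc <- bump(acc, key, if (is_ts) "transitions" else "transversions")
    }
  }
  keys <- names(acc)
  tab <- if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    tibble(
      stratum = vapply(parts, `[`, character(1), 1L),
      context = vapply(parts, `[`, character(1), 2L),
      sites = unname(vapply(acc, `[[`, integer(1), "sites")),
      transitions = unname(vapply(acc, `[[`, integer(1), "transitions")),
      transversions = unname(vapply(acc, `[[`, integer(1), "transversions"))
    )
  } else {
    tibble(stratum = character(0), context = character(0),
           sites = integer(0), transitions = integer(0),
           transversions = integer(0))
  }
  contexts <- c("CG", "CHG", "CHH", "nonPMS")
  tidyr::expand_grid(stratum = unique(stratum_of), context = contexts) |>
    left_join(tab, by = c("stratum", "context")) |>
    mutate(across(c(sites, transitions, transversions),
                  ~ tidyr::replace_na(.x, 0L))) |>
    mutate(context = factor(context, levels = contexts)) |>
    arrange(stratum, context) |>
    mutate(context = as.character(context))
}
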