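# GFF3 feature types used for TE substructure
.subfeature_types <- c(
  long_terminal_repeat = "LTR",
  terminal_inverted_repeat = "TIR"
)

#' Read TE/gene annotations from GFF3
#'
#' Expects element rows (types `transposable_element` / `repeat_region` /
#' `gene`) carrying `te_class`, `superfamily`, `family` and `nesting_level`
#' attributes, and optional subfeature rows of type `long_terminal_repeat`
#' or `terminal_inverted_repeat` with a `kind` attribute (`LTR5`, `LTR3`,
#' `TIR5`, `TIR3`, `internal`) and a `Parent`. Coordinates are converted to
#' 0-based half-open at this boundary.
#'
#' @param path Path to a GFF3 file.
#' @return An annotation tibble: `feature_id`, `region_id`, `start`, `end`,
#'   `category` (`TE`/`gene`), `te_class`, `superfamily`, `family`,
#'   `nesting_level`, `parent_id`, `kind` (NA for elements).
#' @export
read_te_annotations <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  grab <- function(col, default = NA_character_) {
    if (col %in% names(g)) as.character(g[[col]]) else
      rep(default, nrow(g))
  }
  parent <- if ("Parent" %in% names(g)) {
    vapply(g$Parent, function(p) if (length(p)) as.character(p)[1L]
           else NA_character_, character(1))
  } else rep(NA_character_, nrow(g))
  type <- as.character(g$type)
  tibble(
    feature_id = grab("ID"),
    region_id = as.character(g$seqid),
    start = as.integer(g$start) - 1L,
    end = as.integer(g$end),
    category = dplyr::case_when(
      type == "gene" ~ "gene",
      type %in% names(.subfeature_types) ~ NA_character_,
      TRUE ~ "TE"
    ),
    te_class = grab("te_class"),
    superfamily = grab("superfamily"),
    family = grab("family"),
    nesting_level = suppressWarnings(as.integer(grab("nesting_level"))),
    parent_id = parent,
    kind = dplyr::if_else(type %in% names(.subfeature_types),
                          grab("kind"), NA_character_)
  )
}

#' Write an annotation tibble as GFF3
#'
#' @param annotations An annotation tibble as returned by
#'   [read_te_annotations()] or [simulate_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_annotations <- function(annotations, path) {
  ann <- annotations
  is_sub <- !is.na(ann$kind)
  type <- ifelse(is_sub,
                 ifelse(grepl("^LTR", ann$kind), "long_terminal_repeat",
                        ifelse(grepl("^TIR", ann$kind),
                               "terminal_inverted_repeat", "sequence_feature")),
                 ifelse(ann$category == "gene", "gene",
                        "transposable_element"))
  gr <- GenomicRanges::GRanges(
    seqnames = ann$region_id,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end)
  )
  mc <- S4Vectors::DataFrame(
    type = type,
    ID = ann$feature_id,
    Parent = IRanges::CharacterList(lapply(ann$parent_id, function(p)
      if (is.na(p)) character(0) else p)),
    te_class = ann$te_class,
    superfamily = ann$superfamily,
    family = ann$family,
    nesting_level = ann$nesting_level,
    kind = ann$kind
  )
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# classification-code table: three-letter repeat-database codes
.te_code_table <- c(
  RLC = "Copia", RLG = "Gypsy", RIX = "LINE", RIL = "LINE",
  DTC = "CACTA", DTT = "Mariner", DTH = "Harbinger", DTM = "Mutator"
)

#' Parse repeat-database FASTA headers
#'
#' Headers follow the repeat-database convention: the first token is
#' `CODE_Family[_id]` where `CODE` is a three-letter classification code
#' (first letter `R` = class I, `D` = class II; e.g. `RLC` = Copia,
#' `RLG` = Gypsy, `RIX`/`RIL` = LINE, `DTC` = CACTA, `DTT` = Mariner,
#' `DTH` = Harbinger, `DTM` = Mutator). Completeness is read from the
#' words `complete`/`incomplete` in the description and the genus from the
#' first Latin binomial. Unknown codes map to superfamily `"other"`;
#' unparseable headers yield class `"unknown"` with a warning, never an
#' error.
#'
#' @param headers Character vector of FASTA headers (without the `>`).
#' @return A tibble: `header`, `name`, `code`, `te_class`, `superfamily`,
#'   `family`, `complete` (logical), `genus`.
#' @export
#' @examples
#' parse_te_header("RLC_Angela_17 complete Triticum aestivum")
parse_te_header <- function(headers) {
  name <- first_token(headers)
  code <- toupper(sub("^([A-Za-z]{3})_.*$", "\\1", name))
  well_formed <- grepl("^[A-Za-z]{3}_", name)
  code[!well_formed] <- NA_character_
  superfamily <- unname(.te_code_table[code])
  superfamily[well_formed & is.na(superfamily)] <- "other"
  superfamily[!well_formed] <- "unknown"
  te_class <- dplyr::case_when(
    !well_formed ~ "unknown",
    substr(code, 1, 1) == "R" ~ "I",
    substr(code, 1, 1) == "D" ~ "II",
    TRUE ~ "unknown"
  )
  family <- sub("[_[:space:]].*$", "", sub("^[A-Za-z]{3}_", "", name))
  family[!well_formed] <- NA_character_
  complete <- dplyr::case_when(
    grepl("\\bincomplete\\b", headers, ignore.case = TRUE) ~ FALSE,
    grepl("\\bcomplete\\b", headers, ignore.case = TRUE) ~ TRUE,
    TRUE ~ NA
  )
  binom <- stringr::str_match(headers, "\\b([A-Z][a-z]+) [a-z]+\\b")
  genus <- binom[, 2L]
  if (any(!well_formed)) {
    warn(sprintf("%d header(s) did not follow the CODE_Family convention; %s",
                 sum(!well_formed), "classified as 'unknown'"))
  }
  tibble(header = headers, name = name, code = code, te_class = te_class,
         superfamily = superfamily, family = family, complete = complete,
         genus = genus)
}

#' Read a TE reference FASTA with convention headers
#'
#' @param path Path to a FASTA of TE sequences.
#' @return A tibble with `id`, `header`, `sequence`, `length` and the parsed
#'   classification columns of [parse_te_header()].
#' @export
read_te_fasta <- function(path) {
  seqs <- read_seq_file(path)
  parsed <- parse_te_header(names(seqs))
  tibble(id = parsed$name, header = names(seqs),
         sequence = toupper(unname(seqs))) |>
    mutate(length = nchar(sequence)) |>
    dplyr::bind_cols(parsed[, c("code", "te_class", "superfamily", "family",
                                "complete", "genus")])
}

#' Filter a TE reference set by completeness, genus and ambiguity
#'
#' Criteria are applied in order: complete elements only, then genus
#' membership, then exclusion of sequences containing ambiguous base calls
#' (any character outside A/C/G/T). Records lacking the metadata needed by
#' a criterion fail that criterion. The per-stage attrition is attached as
#' a `filter_report` attribute and retrievable with [filter_report()].
#'
#' @param te_records A tibble from [read_te_fasta()] (needs `sequence`,
#'   `complete`, `genus`).
#' @param complete_only Keep complete elements only.
#' @param genera Character vector of genera to keep, or `NULL` to skip.
#' @param exclude_ambiguous Drop sequences with non-A/C/G/T characters.
#' @return The surviving records, with a `filter_report` attribute.
#' @export
filter_te_database <- function(te_records, complete_only = TRUE,
                               genera = c("Triticum", "Aegilops"),
                               exclude_ambiguous = TRUE) {
  stages <- tibble(stage = "input", criterion = "none",
                   n_after = nrow(te_records))
  out <- te_records
  if (isTRUE(complete_only)) {
    out <- out[!is.na(out$complete) & out$complete, , drop = FALSE]
    stages <- dplyr::add_row(stages, stage = "complete",
                             criterion = "complete elements only",
                             n_after = nrow(out))
  }
  if (!is.null(genera)) {
    out <- out[!is.na(out$genus) & out$genus %in% genera, , drop = FALSE]
    stages <- dplyr::add_row(stages, stage = "genus",
                             criterion = paste(genera, collapse = "/"),
                             n_after = nrow(out))
  }
  if (isTRUE(exclude_ambiguous)) {
    out <- out[!grepl("[^ACGT]", out$sequence), , drop = FALSE]
    stages <- dplyr::add_row(stages, stage = "unambiguous",
                             criterion = "no ambiguous base calls",
                             n_after = nrow(out))
  }
  attr(out, "filter_report") <- stages
  out
}

#' Attrition report of a TE database filter
#' @param x Output of [filter_te_database()].
#' @return A tibble with columns `stage`, `criterion`, `n_after`.
#' @export
filter_report <- function(x) attr(x, "filter_report", exact = TRUE)
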