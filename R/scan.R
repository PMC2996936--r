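#' Read genomic regions or TE sequences from FASTA
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A tibble with columns `region_id` (first header token), `header`
#'   (full header), `sequence` (uppercased) and `length`.
#' @export
read_region_fasta <- function(path) {
  seqs <- read_seq_file(path)
  tibble(
    region_id = first_token(names(seqs)),
    header = names(seqs),
    sequence = toupper(unname(seqs))
  ) |>
    mutate(length = nchar(sequence))
}

# per-length index into the database rows, built once per scan
db_length_index <- function(db) {
  split(seq_len(nrow(db)), db$length)
}

# all perfect matches of database sequences on one strand of one string;
# returns 0-based starts in the coordinates of `seq` itself
scan_one_strand <- function(seq, db, idx) {
  n <- nchar(seq)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    L <- as.integer(names(idx)[k])
    if (L > n) next
    starts <- seq_len(n - L + 1L)
    windows <- substring(seq, starts, starts + L - 1L)
    rows <- idx[[k]]
    hit <- match(windows, db$sequence[rows])
    found <- which(!is.na(hit))
    if (length(found)) {
      out[[k]] <- tibble(start = found - 1L, length = L,
                         db_row = rows[hit[found]])
    }
  }
  dplyr::bind_rows(out)
}

#' Exhaustive perfect-match scan of a query sequence
#'
#' Re-implementation of the scrolling-window scan: every window of every
#' allowed read length (1-nt increment) is tested for an exact match against
#' the sRNA database, on the forward strand and, by default, the reverse
#' complement. A minus-strand hit is reported at its forward-strand
#' footprint; its `sequence` is the matching database sRNA, i.e. the reverse
#' complement of the forward-strand substring. `N` in the query matches
#' nothing. The result equals brute-force enumeration of all substrings.
#'
#' @param db An `srna_db`.
#' @param sequence Query sequence (a single string), or use [scan_regions()]
#'   for a table of regions.
#' @param region_id Label for the query.
#' @param strands Subset of `c("+", "-")`.
#' @return A tibble of hits, sorted by (start, length, strand): `region_id`,
#'   `start` (0-based), `end` (half-open), `length`, `strand`, `sequence`,
#'   one count column per library, `total_count`.
#' @export
scan_region <- function(db, sequence, region_id = "query",
                        strands = c("+", "-")) {
  stopifnot(inherits(db, "srna_db"))
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  seq <- toupper(sequence)
  n <- nchar(seq)
  libs <- db_libraries(db)
  empty <- tibble(region_id = character(0), start = integer(0),
                  end = integer(0), length = integer(0), strand = character(0),
                  sequence = character(0))
  for (lib in libs) empty[[lib]] <- integer(0)
  empty$total_count <- integer(0)
  if (n == 0L || nrow(db) == 0L) return(empty)

  idx <- db_length_index(db)
  pieces <- list()
  if ("+" %in% strands) {
    fwd <- scan_one_strand(seq, db, idx)
    if (nrow(fwd)) pieces$fwd <- mutate(fwd, strand = "+")
  }
  if ("-" %in% strands) {
    rev <- scan_one_strand(reverse_complement(seq), db, idx)
    if (nrow(rev)) {
      # reflect reverse-complement coordinates onto the forward strand
      pieces$rev <- rev |>
        mutate(start = n - start - length, strand = "-")
    }
  }
  hits <- dplyr::bind_rows(pieces)
  if (nrow(hits) == 0L) return(empty)
  hits |>
    mutate(region_id = region_id, end = start + length,
           sequence = db$sequence[.data$db_row]) |>
    dplyr::bind_cols(as_tibble(db)[hits$db_row, c(libs, "total_count"),
                                   drop = FALSE]) |>
    select(region_id, start, end, length, strand, sequence,
           all_of(libs), total_count) |>
    arrange(start, length, strand)
}

#' Scan several regions at once
#'
#' @param db An `srna_db`.
#' @param regions A tibble with columns `region_id` and `sequence`
#'   (e.g. from [read_region_fasta()]).
#' @param strands Subset of `c("+", "-")`.
#' @return Row-bound hit tibbles from [scan_region()].
#' @export
scan_regions <- function(db, regions, strands = c("+", "-")) {
  purrr::map(seq_len(nrow(regions)), function(i) {
    scan_region(db, regions$sequence[i], regions$region_id[i], strands)
  }) |>
    purrr::list_rbind()
}

#' Summarise a hit table
#'
#' Each hit contributes its full database abundance (`total_count`) to every
#' applicable cell; counts are abundance-weighted occurrence counts.
#'
#' @param hits A hit tibble from [scan_region()].
#' @param libraries Library count columns present in `hits`; autodetected
#'   from the non-standard columns by default.
#' @return A list with elements `total` (scalar), `by_length`, `by_strand`
#'   and `by_library` (tibbles with counts and percentage shares).
#' @export
aggregate_hit_counts <- function(hits, libraries = NULL) {
  std <- c("region_id", "start", "end", "length", "strand", "sequence",
           "total_count", "feature_id", "boundary")
  if (is.null(libraries)) libraries <- setdiff(names(hits), std)
  total <- sum(hits$total_count)
  shares <- function(x) if (total > 0) 100 * x / total else 0 * x
  by_length <- hits |>
    count(length, wt = total_count, name = "total_count") |>
    mutate(pct = shares(total_count))
  by_strand <- hits |>
    count(strand, wt = total_count, name = "total_count") |>
    mutate(pct = shares(total_count))
  by_library <- if (length(libraries)) {
    hits |>
      summarise(across(all_of(libraries), sum)) |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "library",
                          values_to = "total_count") |>
      mutate(pct = shares(total_count))
  } else {
    tibble(library = character(0), total_count = integer(0), pct = double(0))
  }
  list(total = total, by_length = by_length, by_strand = by_strand,
       by_library = by_library)
}

#' Match density in counts per bp
#'
#' @param hits A hit tibble (its `total_count` column is summed).
#' @param interval_length_bp Length of the scanned interval in bp.
#' @return Abundance-weighted counts per bp (a single number).
#' @export
#' @examples
#' match_density(tibble::tibble(total_count = 10), 200)
match_density <- function(hits, interval_length_bp) {
  if (length(interval_length_bp) != 1L || !is.finite(interval_length_bp) ||
      interval_length_bp <= 0) {
    abort("interval_length_bp must be a single positive number",
          class = "srnascan_config_error")
  }
  sum(hits$total_count) / interval_length_bp
}

#' Write hits as TSV or BED6
#'
#' BED scores are `total_count` capped at 1000 per the BED convention.
#'
#' @param hits A hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_hits_bed <- function(hits, path) {
  bed <- hits |>
    mutate(score = pmin(total_count, 1000L)) |>
    select(region_id, start, end, sequence, "score", strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
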