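#' Read a trimmed small RNA library
#'
#' Loads adapter-trimmed sRNA reads from a FASTA or FASTQ file (optionally
#' gzipped), normalises them to the DNA alphabet (uppercase, U folded to T)
#' and applies the length and alphabet filters. Reads shorter than `min_len`,
#' longer than `max_len`, or containing any character outside A/C/G/T (e.g.
#' N) are rejected; rejection counts by reason are attached to the result and
#' retrievable with [rejection_report()].
#'
#' @param path Path to a FASTA or FASTQ file of trimmed reads.
#' @param library_id Label identifying the library of origin.
#' @param min_len,max_len Inclusive read-length window in nt; the defaults
#'   (18 and 33) are the frame sizes used by the match scanner.
#' @return A tibble with columns `sequence` and `library_id`, one row per
#'   accepted read, with a `rejections` attribute.
#' @seealso [build_srna_db()]
#' @export
read_srna_reads <- function(path, library_id, min_len = 18L, max_len = 33L) {
  stopifnot(min_len >= 1L, max_len >= min_len)
  seqs <- unname(read_seq_file(path))
  seqs <- normalize_sequence(seqs)
  len <- nchar(seqs)
  clean <- grepl("^[ACGT]+$", seqs)
  too_short <- len < min_len
  too_long <- len > max_len
  # one reason per read: length problems take priority over ambiguity
  ambiguous <- !clean & !too_short & !too_long
  keep <- clean & !too_short & !too_long
  out <- tibble(sequence = seqs[keep], library_id = library_id)
  attr(out, "rejections") <- tibble(
    reason = c("too_short", "too_long", "ambiguous_base"),
    n = c(sum(too_short), sum(too_long), sum(ambiguous))
  )
  attr(out, "length_window") <- c(min_len = as.integer(min_len),
                                  max_len = as.integer(max_len))
  out
}

#' Rejection report of a read collection
#'
#' @param reads A read tibble from [read_srna_reads()].
#' @return A tibble with columns `reason` and `n`.
#' @export
rejection_report <- function(reads) {
  rep <- attr(reads, "rejections", exact = TRUE)
  if (is.null(rep)) {
    rep <- tibble(reason = c("too_short", "too_long", "ambiguous_base"),
                  n = c(0L, 0L, 0L))
  }
  rep
}

new_srna_db <- function(records, library_ids, min_len, max_len) {
  structure(records,
            library_ids = as.character(library_ids),
            min_len = as.integer(min_len),
            max_len = as.integer(max_len),
            class = c("srna_db", class(tibble())))
}

#' Library labels of an sRNA database
#' @param db An `srna_db` object.
#' @return Character vector of library labels, in database column order.
#' @export
db_libraries <- function(db) attr(db, "library_ids", exact = TRUE)

#' Length window of an sRNA database
#' @param db An `srna_db` object.
#' @return Integer vector `c(min_len, max_len)`.
#' @export
db_length_window <- function(db) {
  c(attr(db, "min_len", exact = TRUE), attr(db, "max_len", exact = TRUE))
}

#' Consolidate read libraries into an abundance database
#'
#' Merges one or more read collections (from [read_srna_reads()], or any
#' tibble with `sequence` and `library_id` columns) into a single database
#' of distinct sRNA sequences with per-library and total abundance counts.
#' The result is deterministic regardless of input order: records are sorted
#' lexicographically by sequence.
#'
#' @param ... Read tibbles, or a single list of read tibbles. All collections
#'   must share the length window and no library label may appear in more
#'   than one collection.
#' @param min_len,max_len Length window the reads must lie in.
#' @return An `srna_db` tibble with columns `sequence`, `length`, one count
#'   column per library, and `total_count`.
#' @export
#' @examples
#' reads <- tibble::tibble(
#'   sequence = c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA"),
#'   library_id = "L1"
#' )
#' build_srna_db(reads)
build_srna_db <- function(..., min_len = 18L, max_len = 33L) {
  collections <- list(...)
  if (length(collections) == 1L && is.list(collections[[1L]]) &&
      !is.data.frame(collections[[1L]])) {
    collections <- collections[[1L]]
  }
  lib_sets <- lapply(collections, function(x) unique(as.character(x$library_id)))
  library_ids <- unlist(lib_sets)
  if (anyDuplicated(library_ids)) {
    abort(paste0("library_id appears in more than one read collection: ",
                 paste(unique(library_ids[duplicated(library_ids)]),
                       collapse = ", ")),
          class = "srnascan_config_error")
  }
  reads <- dplyr::bind_rows(collections)
  if (nrow(reads) == 0L) {
    empty <- tibble(sequence = character(0), length = integer(0),
                    total_count = integer(0))
    return(new_srna_db(empty, library_ids, min_len, max_len))
  }
  reads$sequence <- normalize_sequence(reads$sequence)
  bad <- nchar(reads$sequence) < min_len | nchar(reads$sequence) > max_len
  if (any(bad)) {
    abort(sprintf("%d reads fall outside the %d-%d nt window", sum(bad),
                  min_len, max_len),
          class = "srnascan_config_error")
  }
  records <- reads |>
    count(sequence, library_id, name = "n_reads") |>
    tidyr::pivot_wider(names_from = library_id, values_from = "n_reads",
                       values_fill = 0L)
  lib_cols <- setdiff(names(records), "sequence")
  # fixed column order: libraries as supplied, then total
  library_ids <- c(library_ids[library_ids %in% lib_cols],
                   setdiff(lib_cols, library_ids))
  records <- records |>
    mutate(length = nchar(sequence),
           total_count = as.integer(rowSums(across(all_of(lib_cols))))) |>
    select(sequence, length, all_of(library_ids), total_count) |>
    arrange(sequence)
  new_srna_db(records, library_ids, min_len, max_len)
}

#' Exact lookup of an sRNA sequence
#'
#' Applies the same normalisation as ingestion (uppercase, U to T) and looks
#' the sequence up by exact string equality.
#'
#' @param db An `srna_db`.
#' @param sequence A single sequence to look up.
#' @return A tibble with the matching record (zero rows if absent).
#' @export
srna_query <- function(db, sequence) {
  s <- normalize_sequence(sequence)
  as_tibble(db)[db$sequence == s, , drop = FALSE]
}

#' Abundance-weighted read-length distribution
#'
#' Counts weight each read by its abundance (a record occurring 50 times
#' contributes 50), so the distribution describes the sequenced read
#' population, not the set of distinct sequences.
#'
#' @param db An `srna_db`.
#' @param by_library If `TRUE`, return one row per length per library with
#'   within-library percentages; summarise across libraries with
#'   [size_distribution_summary()].
#' @return A tibble with columns `length`, `reads`, `pct` (and `library`
#'   when `by_library = TRUE`). Empty database: zero rows.
#' @export
srna_size_distribution <- function(db, by_library = FALSE) {
  win <- db_length_window(db)
  lens <- seq.int(win[1L], win[2L])
  if (nrow(db) == 0L) {
    out <- tibble(length = integer(0), reads = integer(0), pct = double(0))
    if (by_library) out <- mutate(out, library = character(0), .before = "reads")
    return(out)
  }
  if (!by_library) {
    db |>
      as_tibble() |>
      count(length, wt = total_count, name = "reads") |>
      tidyr::complete(length = lens, fill = list(reads = 0)) |>
      mutate(pct = 100 * reads / sum(reads)) |>
      arrange(length)
  } else {
    libs <- db_libraries(db)
    db |>
      as_tibble() |>
      tidyr::pivot_longer(all_of(libs), names_to = "library",
                          values_to = "n_reads") |>
      count(library, length, wt = .data$n_reads, name = "reads") |>
      tidyr::complete(library = libs, length = lens, fill = list(reads = 0)) |>
      group_by(library) |>
      mutate(pct = if (sum(reads) > 0) 100 * reads / sum(reads) else 0) |>
      ungroup() |>
      arrange(library, length)
  }
}

#' Across-library mean and standard deviation of length percentages
#'
#' @param dist A per-library size distribution from
#'   `srna_size_distribution(db, by_library = TRUE)`.
#' @return A tibble with columns `length`, `mean_pct`, `sd_pct`.
#' @export
size_distribution_summary <- function(dist) {
  stopifnot("library" %in% names(dist))
  dist |>
    group_by(length) |>
    summarise(mean_pct = mean(pct), sd_pct = stats::sd(pct), .groups = "drop")
}

#' @export
#' @importFrom generics glance
glance.srna_db <- function(x, ...) {
  win <- db_length_window(x)
  tibble(
    n_distinct = nrow(x),
    total_reads = sum(x$total_count),
    n_libraries = length(db_libraries(x)),
    min_len = win[1L],
    max_len = win[2L]
  )
}

#' @export
#' @importFrom generics tidy
tidy.srna_db <- function(x, ...) as_tibble(x)

#' @export
print.srna_db <- function(x, ...) {
  win <- db_length_window(x)
  cat(sprintf(
    "# sRNA database: %d distinct sequences, %s reads, %d libraries (%d-%d nt)\n",
    nrow(x), format(sum(x$total_count), big.mark = ","),
    length(db_libraries(x)), win[1L], win[2L]))
  NextMethod()
}

#' Write / read an sRNA database as TSV
#'
#' The TSV carries a single header comment line recording the length window
#' and library order so a database round-trips losslessly.
#'
#' @param db An `srna_db`.
#' @param path Output (input) path.
#' @return `write_srna_db()` returns `path` invisibly; `read_srna_db()`
#'   returns an `srna_db`.
#' @export
write_srna_db <- function(db, path) {
  win <- db_length_window(db)
  header <- sprintf("# srnascan-db min_len=%d max_len=%d libraries=%s",
                    win[1L], win[2L], paste(db_libraries(db), collapse = ","))
  writeLines(header, path)
  readr::write_tsv(as_tibble(db), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_srna_db
#' @export
read_srna_db <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# srnascan-db ", header)) {
    abort("not an srnascan database TSV", class = "srnascan_format_error")
  }
  field <- function(key) sub(paste0(".*", key, "="), "", header) |>
    sub(pattern = " .*$", replacement = "")
  min_len <- as.integer(field("min_len"))
  max_len <- as.integer(field("max_len"))
  libs <- strsplit(field("libraries"), ",", fixed = TRUE)[[1L]]
  records <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  new_srna_db(as_tibble(records), libs, min_len, max_len)
}
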