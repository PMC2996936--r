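# fixtures are built in code at test time; nothing is stored on disk

write_temp_fasta <- function(seqs, ids = NULL) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  if (length(seqs)) {
    if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
    writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  } else {
    file.create(path)
  }
  path
}

write_temp_fastq <- function(seqs, ids = NULL) {
  path <- withr::local_tempfile(fileext = ".fq",
                                .local_envir = parent.frame())
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             vapply(seqs, function(s)
                               strrep("I", nchar(s)), character(1)))),
             path)
  path
}

reads_tbl <- function(seqs, library_id = "L1") {
  tibble::tibble(sequence = seqs, library_id = library_id)
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a tiny annotated region used by assignment/profile tests:
# Gypsy element [100, 400) at level 0 containing a Mariner MITE
# [200, 260) at level 2 (an intermediate layer is not materialised),
# and a gene [500, 700)
toy_annotations <- function(region_id = "regA") {
  tibble::tibble(
    feature_id = c("gypsy1", "mite1", "gene1"),
    region_id = region_id,
    start = c(100L, 200L, 500L),
    end = c(400L, 260L, 700L),
    category = c("TE", "TE", "gene"),
    te_class = c("I", "II", NA),
    superfamily = c("Gypsy", "Mariner", NA),
    family = c("Wham", "Thalos", NA),
    nesting_level = c(0L, 2L, 0L),
    parent_id = c(NA, "gypsy1", NA),
    kind = rep(NA_character_, 3)
  )
}

toy_hit <- function(start, length = 21L, total = 1L, region_id = "regA") {
  tibble::tibble(region_id = region_id, start = as.integer(start),
                 end = as.integer(start + length), length = as.integer(length),
                 strand = "+", sequence = strrep("A", length),
                 total_count = as.integer(total))
}
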