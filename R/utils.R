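#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the A/C/G/T/N alphabet.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' reverse_complement("AACGT")
reverse_complement <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

# uppercase and fold RNA U onto DNA T
normalize_sequence <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# i.i.d. random DNA string with a given GC content
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# peek at the first non-blank character to decide FASTA vs FASTQ
sniff_seq_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) return("empty")
    line <- trimws(line)
    if (nzchar(line)) break
  }
  first <- substr(line, 1L, 1L)
  if (first == ">") "fasta" else if (first == "@") "fastq" else "unknown"
}

# read a FASTA/FASTQ file as raw (B)strings; gzip handled by Biostrings
read_seq_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read '", path, "': no such file"),
          class = "srnascan_io_error")
  }
  fmt <- sniff_seq_format(path)
  if (fmt == "empty") {
    return(stats::setNames(character(0), character(0)))
  }
  if (fmt == "unknown") {
    abort(paste0("'", path, "' is neither FASTA nor FASTQ"),
          class = "srnascan_format_error")
  }
  ss <- Biostrings::readBStringSet(path, format = fmt)
  stats::setNames(as.character(ss), names(ss))
}

first_token <- function(x) sub("\\s.*$", "", x)
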