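# independent oracles, kept deliberately naive

# brute-force scan: test every substring of every allowed length on each
# requested strand against the database by set membership
oracle_scan <- function(db, seq, strands = c("+", "-")) {
  n <- nchar(seq)
  win <- db_length_window(db)
  rc <- if ("-" %in% strands) reverse_complement(seq) else NULL
  out <- list()
  for (L in seq.int(win[1L], win[2L])) {
    if (L > n) next
    for (st in strands) {
      s <- if (st == "+") seq else rc
      subs <- substring(s, seq_len(n - L + 1L), seq_len(n - L + 1L) + L - 1L)
      found <- which(subs %in% db$sequence)
      for (p in found) {
        start <- if (st == "+") p - 1L else n - (p - 1L) - L
        out[[length(out) + 1L]] <- tibble::tibble(
          start = as.integer(start), length = L, strand = st,
          sequence = subs[p],
          total_count = db$total_count[match(subs[p], db$sequence)]
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(start = integer(0), length = integer(0),
                          strand = character(0), sequence = character(0),
                          total_count = integer(0))
  }
  dplyr::arrange(res, start, length, strand)
}

# closed-form Welch t statistic and df
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df)
}

# Pearson r straight from the covariance formula
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# tally comparison helper: same counts per (stratum x) context
expect_same_tally <- function(t1, t2) {
  expect_equal(t1$context, t2$context)
  expect_equal(t1$sites, t2$sites, ignore_attr = TRUE)
  expect_equal(t1$transitions, t2$transitions, ignore_attr = TRUE)
  expect_equal(t1$transversions, t2$transversions, ignore_attr = TRUE)
}
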