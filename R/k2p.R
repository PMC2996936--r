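#' Kimura two-parameter distance
#'
#' Computes the K2P distance
#' \deqn{d = -\tfrac{1}{2}\,\ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right]}
#' where \eqn{P} and \eqn{Q} are the transition and transversion
#' proportions per aligned site. Outside the formula's domain
#' (\eqn{2P + Q \ge 1} or \eqn{2Q \ge 1}) the divergence is saturated and a
#' typed error of class `srnascan_saturation_error` is raised rather than
#' returning an infinite distance.
#'
#' @param transitions,transversions,n_sites Substitution counts and number
#'   of aligned (non-gap) sites; vectors are recycled.
#' @return A tibble with columns `n_sites`, `transitions`, `transversions`,
#'   `P`, `Q`, `d`.
#' @export
#' @examples
#' k2p_distance(76, 51, 10397)
k2p_distance <- function(transitions, transversions, n_sites) {
  if (any(n_sites <= 0)) {
    abort("n_sites must be positive", class = "srnascan_config_error")
  }
  P <- transitions / n_sites
  Q <- transversions / n_sites
  if (any(P < 0) || any(Q < 0)) {
    abort("counts must be non-negative", class = "srnascan_config_error")
  }
  if (any(1 - 2 * P - Q <= 0) || any(1 - 2 * Q <= 0)) {
    abort("substitution counts are outside the K2P domain (saturation)",
          class = "srnascan_saturation_error")
  }
  tibble(
    n_sites = n_sites, transitions = transitions,
    transversions = transversions, P = P, Q = Q,
    d = -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  )
}

#' Divergence time from a K2P distance
#'
#' Two lineages accumulate substitutions independently after their split,
#' so `T = d / (2 * rate)`.
#'
#' @param d K2P distance (substitutions/site), or a tibble from
#'   [k2p_distance()] whose `d` column is used (other columns are kept).
#' @param rate Substitution rate in substitutions per site per year
#'   (e.g. `5.5e-9` for genic/low-copy wheat sequence).
#' @return A tibble with `d`, `rate`, `time_years`, `time_my` and
#'   `mode = "divergence"`.
#' @export
#' @examples
#' divergence_time(k2p_distance(76, 51, 10397), rate = 5.5e-9)
divergence_time <- function(d, rate) {
  if (any(rate <= 0)) {
    abort("rate must be positive", class = "srnascan_config_error")
  }
  base <- if (is.data.frame(d)) d else tibble(d = d)
  if (nrow(base) == 1L && length(rate) > 1L) {
    base <- base[rep(1L, length(rate)), , drop = FALSE]
  }
  base |>
    mutate(rate = !!rate, time_years = d / (2 * .data$rate),
           time_my = .data$time_years / 1e6, mode = "divergence")
}

#' Substitution rate from a K2P distance and a known divergence time
#'
#' `rate = d / (2 * T)` for two independently evolving copies.
#'
#' @param d K2P distance, or a tibble from [k2p_distance()].
#' @param time_years Divergence time in years.
#' @return A tibble with `d`, `time_years`, `rate` (substitutions per site
#'   per year) and `mode = "rate"`.
#' @export
#' @examples
#' substitution_rate(k2p_distance(431, 156, 16430), time_years = 1.1e6)
substitution_rate <- function(d, time_years) {
  if (any(time_years <= 0)) {
    abort("time_years must be positive", class = "srnascan_config_error")
  }
  base <- if (is.data.frame(d)) d else tibble(d = d)
  if (nrow(base) == 1L && length(time_years) > 1L) {
    base <- base[rep(1L, length(time_years)), , drop = FALSE]
  }
  base |>
    mutate(time_years = !!time_years, rate = d / (2 * .data$time_years),
           mode = "rate")
}

# transition/transversion/site counts over non-gap, non-N columns of a
# pair of gapped strings
count_pair_substitutions <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) {
    abort("aligned sequences differ in length",
          class = "srnascan_format_error")
  }
  usable <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  mism <- usable & a != b
  ts <- sum(mism & is_transition(a, b))
  list(n_sites = sum(usable), transitions = ts,
       transversions = sum(mism) - ts)
}

#' Insertion age of an LTR retrotransposon from its LTR pair
#'
#' The two long terminal repeats of a retroelement are identical copies of
#' the same template at the moment of insertion; their divergence therefore
#' dates the insertion. Substitutions are counted over the non-gap columns
#' of the aligned LTRs, converted to a K2P distance, and dated with
#' `T = d / (2 * rate)`.
#'
#' @param ltr_a,ltr_b The two aligned LTR sequences (gapped strings of
#'   equal length), or an `aligned_pair` passed as `ltr_a`.
#' @param rate Substitution rate per site per year (e.g. `1.67e-8` for TE
#'   sequence).
#' @return A one-row tibble with the underlying counts, `P`, `Q`, `d`,
#'   `rate`, `time_years`, `time_my` and `mode = "insertion"`.
#' @export
ltr_insertion_time <- function(ltr_a, ltr_b = NULL, rate = 1.67e-8) {
  if (is.data.frame(ltr_a) && is.null(ltr_b)) {
    ltr_b <- ltr_a$seq_b[1L]
    ltr_a <- ltr_a$seq_a[1L]
  }
  counts <- count_pair_substitutions(ltr_a, ltr_b)
  k2p_distance(counts$transitions, counts$transversions, counts$n_sites) |>
    divergence_time(rate = rate) |>
    mutate(mode = "insertion")
}
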