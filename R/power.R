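#' Expected mitochondrial read depth of a sequencing design
#'
#' For an experiment with `M` total reads, a fraction `E` of which are
#' mitochondrial (the enrichment level), and read length `l`, the expected
#' number of reads covering any given mitochondrial base is
#' \deqn{N \approx M \times E \times l / L.}
#'
#' @param total_reads Total reads `M` in the experiment.
#' @param enrichment Mitochondrial enrichment `E`, a fraction in `[0, 1]`
#'   (about 0.002 without laboratory enrichment).
#' @param read_length Read length `l` in nt.
#' @param genome_length Mitochondrial genome length `L` (default 16,569).
#' @return Expected per-base depth `N`.
#' @examples
#' expected_mito_depth(5e7, 0.6, 150)  # ~271,592x
#' @export
expected_mito_depth <- function(total_reads, enrichment, read_length,
                                genome_length = 16569) {
  stopifnot(total_reads >= 0, enrichment >= 0, enrichment <= 1,
            read_length >= 1)
  total_reads * enrichment * read_length / genome_length
}

#' Probability of detecting a deletion at a given heteroplasmy
#'
#' A deletion at heteroplasmy `p` is supported by each mitochondrial read
#' with probability `p * l / L` (the read must come from a deleted copy and
#' overlap the junction), so the support count is Binomial with
#' `round(M * E)` trials.  Detection requires at least `n_min` supporting
#' reads; the binomial tail is evaluated exactly.
#'
#' @inheritParams expected_mito_depth
#' @param n_min Support threshold for calling a deletion (default 10).
#' @param p Heteroplasmy fraction of the deletion, in `[0, 1]`.
#' @return `P(X >= n_min)` with `X ~ Bin(round(M E), p l / L)`.
#' @export
detection_probability <- function(total_reads, enrichment, read_length,
                                  p, n_min = 10, genome_length = 16569) {
  stopifnot(n_min >= 1, p >= 0, p <= 1)
  size <- round(total_reads * enrichment)
  prob <- p * read_length / genome_length
  if (any(prob > 1)) {
    stop("p * l / L exceeds 1; reads are longer than the genome allows",
         call. = FALSE)
  }
  stats::pbinom(n_min - 1, size, prob, lower.tail = FALSE)
}

#' Minimum heteroplasmy detectable with a given probability
#'
#' Inverts [detection_probability()] by bisection (relative tolerance
#' `1e-6`): the smallest heteroplasmy `p` whose detection probability
#' reaches `target_power`.  Answers design questions such as "what is the
#' detection limit of 5e7 reads at 60% enrichment?" (about 0.006% at 95%
#' probability with the default threshold of 10 supporting reads).
#'
#' @inheritParams detection_probability
#' @param target_power Required detection probability (default 0.95).
#' @return The minimum detectable heteroplasmy, as a fraction.
#' @export
min_detectable_heteroplasmy <- function(total_reads, enrichment, read_length,
                                        n_min = 10, target_power = 0.95,
                                        genome_length = 16569) {
  stopifnot(target_power > 0, target_power < 1)
  f <- function(p) detection_probability(total_reads, enrichment,
                                         read_length, p, n_min,
                                         genome_length)
  p_max <- min(1, genome_length / read_length)
  if (f(p_max) < target_power) {
    stop("target power ", target_power, " is unreachable: even at ",
         "heteroplasmy 1 the expected support is below the threshold",
         call. = FALSE)
  }
  lo <- 0
  hi <- p_max
  while (hi - lo > 1e-6 * hi) {
    mid <- (lo + hi) / 2
    if (f(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' Detection-probability curve over a heteroplasmy grid
#'
#' @inheritParams detection_probability
#' @param p Vector of heteroplasmy fractions (default: log-spaced from
#'   1e-6 to 1e-2).
#' @return A tibble with columns `p`, `heteroplasmy_pct` and
#'   `detection_probability`, of class `mito_power_curve` for [autoplot()].
#' @export
detection_power_curve <- function(total_reads, enrichment, read_length,
                                  n_min = 10, genome_length = 16569,
                                  p = 10^seq(-6, -2, length.out = 200)) {
  out <- tibble::tibble(
    p = p,
    heteroplasmy_pct = 100 * p,
    detection_probability = detection_probability(
      total_reads, enrichment, read_length, p, n_min, genome_length)
  )
  attr(out, "design") <- list(total_reads = total_reads,
                              enrichment = enrichment,
                              read_length = read_length, n_min = n_min)
  class(out) <- c("mito_power_curve", class(out))
  out
}
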