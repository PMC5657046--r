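#' Cluster split reads into deletion calls
#'
#' Groups canonicalized split alignments by their exact fusion point `(s, e)`
#' — canonicalization has already absorbed flanking-repeat ambiguity, so no
#' breakpoint-window merging is applied.  Each cluster records its read
#' support `n`, the number of distinct fusion offsets `x` (evidence that the
#' junction was sampled at several positions within reads, not produced by a
#' recurrent artifact), and per-strand read counts.
#'
#' @param splits A tibble of split alignments from [align_candidates()] (or
#'   with columns `s`, `e`, `x`, `strand`).
#' @return A tibble with one row per distinct fusion point, sorted by
#'   descending support then ascending `s`: columns `s`, `e`,
#'   `deleted_start`, `deleted_end`, `deleted_length`, `notation`,
#'   `support_n`, `unique_offsets`, `plus_strand_reads`,
#'   `minus_strand_reads`.
#' @export
cluster_fusions <- function(splits) {
  cols <- c("s", "e", "x", "strand")
  stopifnot(all(cols %in% names(splits)))
  calls <- splits |>
    dplyr::group_by(.data$s, .data$e) |>
    dplyr::summarise(
      support_n = dplyr::n(),
      unique_offsets = dplyr::n_distinct(.data$x),
      plus_strand_reads = sum(.data$strand == "+"),
      minus_strand_reads = sum(.data$strand == "-"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      deleted_start = .data$s + 1L,
      deleted_end = .data$e - 1L,
      deleted_length = .data$e - .data$s - 1L,
      notation = sprintf("m.%d_%ddel%d", .data$s + 1L, .data$e - 1L,
                         .data$e - .data$s - 1L)
    ) |>
    dplyr::arrange(dplyr::desc(.data$support_n), .data$s)
  calls[, c("s", "e", "deleted_start", "deleted_end", "deleted_length",
            "notation", "support_n", "unique_offsets",
            "plus_strand_reads", "minus_strand_reads")]
}

#' Apply evidence filters to clustered deletion calls
#'
#' A call is reported when at least `n_min` split reads support exactly the
#' same fusion point (default 10, a tuning parameter trading sensitivity for
#' specificity) *and* the fusion appears at `u_min` or more distinct read
#' offsets (default 5), which screens out PCR artifacts and reads split on a
#' single substitution.  Both flags are annotated rather than rows dropped,
#' so thresholds can be retuned downstream.
#'
#' @param calls A tibble from [cluster_fusions()].
#' @param u_min Minimum distinct fusion offsets (default 5).
#' @param n_min Minimum supporting reads (default 10).
#' @return `calls` with logical columns `passes_unique_filter`,
#'   `passes_support_filter` and `pass_filters` added.
#' @export
apply_call_filters <- function(calls, u_min = 5, n_min = 10) {
  if (u_min < 1 || n_min < 1) {
    stop("u_min and n_min must be >= 1", call. = FALSE)
  }
  dplyr::mutate(
    calls,
    passes_unique_filter = .data$unique_offsets >= u_min,
    passes_support_filter = .data$support_n >= n_min,
    pass_filters = .data$passes_unique_filter & .data$passes_support_filter
  )
}
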