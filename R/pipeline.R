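#' Call mitochondrial deletions end to end
#'
#' Runs the full calling pipeline — candidate extraction, split alignment,
#' fusion-point clustering, evidence filtering and heteroplasmy
#' quantification — on a whole-genome alignment (SAM/BAM), on raw FASTQ, or
#' on a prebuilt `candidate_pool`.  Calling is deterministic: identical
#' inputs and parameters yield identical tables.
#'
#' Heteroplasmy for each call uses the capture-corrected effective read
#' length `l - 2 * min_overhang + 1`: a junction is only countable when a
#' read overlaps it by at least `min_overhang` bases on each side, so that
#' many (not `l`) start positions capture it.  Pass `read_length` to
#' override the modal read length detected from the input.
#'
#' @param input Path to a SAM/BAM file, one or two FASTQ paths, or a
#'   `candidate_pool`.
#' @param reference Path to the reference FASTA, or an [mt_genome()].
#' @param mito_contig,clip_min,indel_min Passed to [extract_candidates()].
#' @param k,min_overhang,max_mismatch,max_full_mismatches Passed to
#'   [align_candidates()].
#' @param u_min,n_min Passed to [apply_call_filters()].
#' @param alpha Confidence level for per-call intervals (default 0.05).
#' @param read_length Optional override of the effective read length used
#'   for quantification (before capture correction).
#' @param report `"pass"` (default) returns only calls passing both filters;
#'   `"all"` returns every cluster with its flags.
#' @return A tibble of class `mito_calls`, one row per deletion, with the
#'   fusion-point coordinates, support counts, filter flags and heteroplasmy
#'   (percent, with CI).  A run report (counts and parameters) is attached
#'   as `attr(x, "report")`.
#' @examples
#' \donttest{
#' g <- mt_genome(paste(sample(c("A", "C", "G", "T"), 16569, TRUE),
#'                      collapse = ""))
#' sim <- simulate_reads(g, parse_deletion_notation("m.5000_5199del200"),
#'                       coverage_deleted = 70, coverage_intact = 630,
#'                       seed = 7)
#' sam <- tempfile(fileext = ".sam")
#' write_pseudo_sam(sim, g, sam)
#' call_deletions(sam, g)
#' }
#' @export
call_deletions <- function(input, reference,
                           mito_contig = c("chrM", "MT"),
                           clip_min = 20, indel_min = 5,
                           k = 16, min_overhang = 20, max_mismatch = 1,
                           max_full_mismatches = 3,
                           u_min = 5, n_min = 10, alpha = 0.05,
                           read_length = NULL,
                           report = c("pass", "all")) {
  report <- match.arg(report)
  genome <- if (inherits(reference, "mt_genome")) {
    reference
  } else {
    read_mito_reference(reference)
  }

  pool <- if (inherits(input, "candidate_pool")) {
    input
  } else if (is.character(input) &&
             all(grepl("\\.(fq|fastq)(\\.gz)?$", input, ignore.case = TRUE))) {
    if (length(input) == 2L) {
      pool_from_fastq(input[1], input[2])
    } else {
      pool_from_fastq(input[1])
    }
  } else if (is.character(input) && length(input) == 1L) {
    extract_candidates(input, mito_contig = mito_contig,
                       clip_min = clip_min, indel_min = indel_min)
  } else {
    stop("input must be a SAM/BAM path, FASTQ path(s), or a candidate_pool",
         call. = FALSE)
  }

  splits <- align_candidates(pool, genome, k = k,
                             min_overhang = min_overhang,
                             max_mismatch = max_mismatch,
                             max_full_mismatches = max_full_mismatches)
  r <- attr(splits, "r")
  l <- read_length %||% attr(splits, "l")

  calls <- cluster_fusions(splits) |>
    apply_call_filters(u_min = u_min, n_min = n_min)
  calls <- dplyr::mutate(calls, contig = genome$name, .before = 1L)

  # capture-corrected effective length: only overlaps with >= min_overhang
  # bases on each side are countable as split reads
  l_eff <- if (!is.null(l) && !is.na(l)) {
    max(1L, l - 2L * as.integer(min_overhang) + 1L)
  } else {
    NA_integer_
  }

  if (nrow(calls) > 0L && !is.na(r) && r > 0L && !is.na(l_eff)) {
    hets <- lapply(calls$support_n, function(nn) {
      est <- estimate_heteroplasmy(nn, r, read_length = l_eff, alpha = alpha)
      c(est$heteroplasmy, est$ci_heteroplasmy)
    })
    hets <- do.call(rbind, hets)
    calls$heteroplasmy_pct <- 100 * hets[, 1]
    calls$ci_low_pct <- 100 * hets[, 2]
    calls$ci_high_pct <- 100 * hets[, 3]
  } else {
    calls$heteroplasmy_pct <- numeric(nrow(calls))
    calls$ci_low_pct <- numeric(nrow(calls))
    calls$ci_high_pct <- numeric(nrow(calls))
  }

  full <- calls
  if (report == "pass") calls <- calls[calls$pass_filters, ]

  attr(calls, "report") <- list(
    r = r, read_length = l, effective_read_length = l_eff,
    n_candidates = attr(splits, "n_candidates"),
    n_full_match = attr(splits, "n_full_match"),
    n_split = attr(splits, "n_split"),
    n_unaligned = attr(splits, "n_unaligned"),
    n_clusters = nrow(full),
    n_pass = sum(full$pass_filters),
    params = list(mito_contig = mito_contig, clip_min = clip_min,
                  indel_min = indel_min, k = k,
                  min_overhang = min_overhang, max_mismatch = max_mismatch,
                  max_full_mismatches = max_full_mismatches,
                  u_min = u_min, n_min = n_min, alpha = alpha)
  )
  class(calls) <- c("mito_calls", class(calls))
  calls
}

#' @export
print.mito_calls <- function(x, ...) {
  rep <- attr(x, "report")
  if (!is.null(rep)) {
    cat(sprintf(
      "# mtDNA deletion calls: %d reported (%d clusters, %d pass filters)\n",
      nrow(x), rep$n_clusters, rep$n_pass))
    cat(sprintf("# r = %s mtDNA reads; %d candidates -> %d full match, %d split\n",
                format(rep$r, big.mark = ","), rep$n_candidates,
                rep$n_full_match, rep$n_split))
  }
  NextMethod()
}

#' @exportS3Method generics::tidy
tidy.mito_calls <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mito_calls")
  attr(out, "report") <- NULL
  out
}

#' @exportS3Method generics::glance
glance.mito_calls <- function(x, ...) {
  rep <- attr(x, "report")
  tibble::tibble(
    n_reported = nrow(x), n_clusters = rep$n_clusters,
    n_pass = rep$n_pass, r = rep$r,
    n_candidates = rep$n_candidates, n_full_match = rep$n_full_match,
    n_split = rep$n_split
  )
}

#' Write deletion calls and the run report to disk
#'
#' `write_calls_tsv()` writes the calls table as TSV; `write_run_report()`
#' serializes the run report (read counts and every parameter, for
#' provenance) as JSON; `write_calls_vcf()` is a minimal convenience export
#' using symbolic `<DEL>` alleles with `END` and supporting counts in INFO
#' (the fusion-offset semantics do not round-trip through VCF, so TSV is the
#' primary format).
#'
#' @param calls A `mito_calls` tibble from [call_deletions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calls_tsv <- function(calls, path) {
  readr::write_tsv(tidy(calls), path)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
write_run_report <- function(calls, path) {
  jsonlite::write_json(attr(calls, "report"), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @param genome The [mt_genome()] used for calling (for the VCF header).
#' @export
write_calls_vcf <- function(calls, genome, path) {
  stopifnot(inherits(genome, "mt_genome"))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome$name, genome$length),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Deleted segment end\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Deletion length\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting split reads\">",
    "##INFO=<ID=HET,Number=1,Type=Float,Description=\"Heteroplasmy percent\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  rows <- character(0)
  if (nrow(calls) > 0L) {
    ref <- vapply(calls$s, function(s) .base_at(genome, s), character(1))
    rows <- paste(
      genome$name, calls$s, calls$notation, ref, "<DEL>", ".",
      ifelse(calls$pass_filters, "PASS", "lowqual"),
      sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d;SUPPORT=%d;HET=%.4f",
              calls$deleted_end, calls$deleted_length, calls$support_n,
              calls$heteroplasmy_pct),
      sep = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}
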