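# Open a SAM or BAM path as a BamFile, converting SAM via asBam
.as_bamfile <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  Rsamtools::BamFile(path)
}

# per-unique-CIGAR maxima of clip and indel op lengths
.cigar_limits <- function(cigars) {
  u <- unique(cigars)
  ops <- regmatches(u, gregexpr("[0-9]+[MIDNSHP=X]", u))
  lim <- vapply(ops, function(o) {
    if (length(o) == 0L) return(c(0, 0))
    n <- as.integer(sub("[MIDNSHP=X]$", "", o))
    type <- substr(o, nchar(o), nchar(o))
    c(max(c(0L, n[type %in% c("S", "H")])),
      max(c(0L, n[type %in% c("I", "D")])))
  }, numeric(2))
  idx <- match(cigars, u)
  list(clip = lim[1, idx], indel = lim[2, idx])
}

#' Extract fusion-read candidates from a whole-genome alignment
#'
#' Reads spanning a deletion fusion point either fail to align (unmapped) or
#' align only after clipping, so the candidate pool collects all unmapped
#' records plus mapped records whose CIGAR contains a soft/hard clip of at
#' least `clip_min` nt or an insertion/deletion of at least `indel_min` nt.
#' Mapped reads without such CIGAR features are *not* candidates — in a
#' whole-genome alignment this is what keeps nuclear-embedded mitochondrial
#' segments (NUMTs) from leaking in.  Reverse-strand records are restored to
#' their original read orientation before downstream split alignment.
#'
#' The pool also records `r`, the number of primary, non-duplicate,
#' non-supplementary mapped records on the mitochondrial contig — the
#' denominator of the heteroplasmy estimator — and the modal read length of
#' those records.
#'
#' @param path Path to a SAM or BAM file with a header.
#' @param mito_contig Candidate names for the mitochondrial contig; the first
#'   one present in the header is used.
#' @param clip_min Minimum clip length (nt) for a mapped record to become a
#'   candidate (default 20).
#' @param indel_min Minimum CIGAR insertion/deletion length (default 5).
#' @return An object of class `candidate_pool`: a list with `candidates`
#'   (tibble: `id`, `mate`, `sequence`, `quality`, `source`), `r`, `l` and
#'   `mito_contig`.
#' @export
extract_candidates <- function(path, mito_contig = c("chrM", "MT"),
                               clip_min = 20, indel_min = 5) {
  bf <- .as_bamfile(path)
  targets <- Rsamtools::scanBamHeader(bf)$targets
  hit <- mito_contig[mito_contig %in% names(targets)]
  if (length(hit) == 0L) {
    stop("mitochondrial contig not found in header (looked for: ",
         paste(mito_contig, collapse = ", "), ")", call. = FALSE)
  }
  mito <- hit[1]

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual")
  )
  b <- Rsamtools::scanBam(bf, param = param)[[1]]
  flag <- b$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  supplementary <- bitwAnd(flag, 2048L) > 0L
  duplicate <- bitwAnd(flag, 1024L) > 0L
  primary <- !secondary & !supplementary
  on_mito <- !unmapped & !is.na(b$rname) & as.character(b$rname) == mito

  r_mask <- on_mito & primary & !duplicate
  r <- sum(r_mask)
  widths <- Biostrings::width(b$seq)
  l <- if (r > 0L) {
    tab <- table(widths[r_mask])
    as.integer(names(tab)[which.max(tab)])
  } else {
    NA_integer_
  }

  cig <- .cigar_limits(ifelse(is.na(b$cigar), "", b$cigar))
  sv_cigar <- !unmapped & primary &
    (cig$clip >= clip_min | cig$indel >= indel_min)
  keep <- unmapped | sv_cigar
  idx <- which(keep)

  seqs <- as.character(b$seq[idx])
  quals <- as.character(b$qual[idx])
  # restore original read orientation for mapped reverse-strand records
  rev <- bitwAnd(flag[idx], 16L) > 0L & !unmapped[idx]
  if (any(rev)) {
    seqs[rev] <- .revcomp(seqs[rev])
    quals[rev] <- vapply(quals[rev], function(q) {
      paste(rev(strsplit(q, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  # mate index from pairing flags, or from an old-style /1 /2 name suffix
  ids <- b$qname[idx]
  mate <- ifelse(bitwAnd(flag[idx], 128L) > 0L, 2L,
                 ifelse(bitwAnd(flag[idx], 64L) > 0L, 1L, NA_integer_))
  suffixed <- is.na(mate) & grepl("/[12]$", ids)
  mate[suffixed] <- as.integer(sub("^.*/", "", ids[suffixed]))
  ids[suffixed] <- sub("/[12]$", "", ids[suffixed])
  mate[is.na(mate)] <- 1L

  candidates <- tibble::tibble(
    id = ids,
    mate = mate,
    sequence = seqs,
    quality = quals,
    source = ifelse(unmapped[idx], "unmapped",
                    ifelse(cig$indel[idx] >= indel_min & cig$clip[idx] < clip_min,
                           "indel", "clipped"))
  )
  candidates <- dplyr::distinct(candidates, .data$id, .data$mate,
                                .keep_all = TRUE)
  structure(
    list(candidates = candidates, r = r, l = l, mito_contig = mito,
         mode = "alignment"),
    class = "candidate_pool"
  )
}

#' Build a candidate pool directly from FASTQ
#'
#' Aligner-free mode for synthetic or mitochondria-enriched data: every read
#' becomes a candidate, and the mitochondrial read count `r` is determined
#' downstream by the split aligner's full-match classification.  Because no
#' whole-genome alignment soaks up nuclear reads, this mode has no NUMT guard
#' and is intended for simulated or enriched libraries.
#'
#' @param fastq_1 Path to the first (or only) FASTQ file, optionally gzipped.
#' @param fastq_2 Optional mate FASTQ; must contain the same number of reads.
#' @return A `candidate_pool` with `r = NA` (to be set by alignment).
#' @export
pool_from_fastq <- function(fastq_1, fastq_2 = NULL) {
  read_one <- function(path, mate) {
    # the reader warns about dropping (unused) mcols metadata
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    ids <- sub("\\s.*$", "", names(x))
    ids <- sub("/[12]$", "", ids)
    # as.character drops the (unused) mcols with a cosmetic warning
    tibble::tibble(
      id = ids, mate = mate,
      sequence = unname(suppressWarnings(as.character(x))),
      quality = unname(suppressWarnings(
        as.character(Biostrings::quality(x)))),
      source = "fastq"
    )
  }
  p1 <- read_one(fastq_1, 1L)
  if (!is.null(fastq_2)) {
    p2 <- read_one(fastq_2, 2L)
    if (nrow(p1) != nrow(p2)) {
      stop("paired FASTQ files have different read counts (",
           nrow(p1), " vs ", nrow(p2), ")", call. = FALSE)
    }
    p1 <- dplyr::bind_rows(p1, p2)
  }
  l <- if (nrow(p1) > 0L) {
    tab <- table(nchar(p1$sequence))
    as.integer(names(tab)[which.max(tab)])
  } else {
    NA_integer_
  }
  structure(
    list(candidates = p1, r = NA_integer_, l = l, mito_contig = NA_character_,
         mode = "fastq"),
    class = "candidate_pool"
  )
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat(sprintf("<candidate_pool> %d candidates (%s mode); r = %s; l = %s\n",
              nrow(x$candidates), x$mode,
              ifelse(is.na(x$r), "unset", format(x$r, big.mark = ",")),
              x$l))
  invisible(x)
}
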