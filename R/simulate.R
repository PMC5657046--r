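# reverse complement for plain character vectors
.revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert fold-coverage to a read-pair count
#'
#' A haplotype sequenced at fold-coverage `c` with paired reads of length `l`
#' needs `round(c * haplotype_length / (2 l))` pairs.
#'
#' @param coverage Fold-coverage (>= 0).
#' @param haplotype_length Haplotype length in bases.
#' @param read_length Read length in nt.
#' @return Integer number of pairs.
#' @examples
#' coverage_to_pair_count(70, 16569, 150)  # 3866
#' @export
coverage_to_pair_count <- function(coverage, haplotype_length, read_length) {
  stopifnot(coverage >= 0, haplotype_length >= 1, read_length >= 1)
  as.integer(round(coverage * haplotype_length / (2 * read_length)))
}

# inject uniform substitution errors; returns modified sequences
.add_errors <- function(seqs, error_rate) {
  if (length(seqs) == 0L || error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(nerr > 0L)) {
    s <- seqs[i]
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(bases, cur), 1L)
    }
    seqs[i] <- s
  }
  seqs
}

# simulate one haplotype's read pairs; junction = haplotype position of the
# retained base s (NA for the intact haplotype)
.simulate_haplotype <- function(hap_seq, n_pairs, read_length, gap_mean,
                                gap_sd, error_rate, hap_name, junction,
                                del_shift, del_s) {
  l <- read_length
  Lh <- nchar(hap_seq)
  if (l > Lh) stop("read length ", l, " exceeds haplotype length ", Lh,
                   call. = FALSE)
  empty <- tibble::tibble(
    id = character(0), mate = integer(0), haplotype = character(0),
    strand = character(0), start = integer(0), ref_start = integer(0),
    sequence = character(0), quality = character(0),
    harbors_fusion = logical(0), fusion_offset = integer(0)
  )
  if (n_pairs == 0L) return(empty)
  doubled <- paste0(hap_seq, hap_seq)

  starts <- sample.int(Lh, n_pairs, replace = TRUE)
  gaps <- pmax(0L, as.integer(round(stats::rnorm(n_pairs, gap_mean, gap_sd))))
  gaps <- pmin(gaps, Lh - 2L * l)  # fragment must fit on the circle
  flen <- 2L * l + gaps

  fwd_start <- starts                       # + orientation window
  rev_start <- starts + flen - l            # unwrapped index into doubled
  fwd_seq <- substring(doubled, fwd_start, fwd_start + l - 1L)
  rev_seq <- .revcomp(substring(doubled, rev_start, rev_start + l - 1L))
  rev_start_w <- .wrap_pos(rev_start, Lh)

  first_is_fwd <- stats::runif(n_pairs) < 0.5
  ids <- sprintf("%s_p%07d", hap_name, seq_len(n_pairs))

  win_start <- c(fwd_start, rev_start_w)
  reads <- tibble::tibble(
    id = rep(ids, 2L),
    mate = c(ifelse(first_is_fwd, 1L, 2L), ifelse(first_is_fwd, 2L, 1L)),
    haplotype = hap_name,
    strand = rep(c("+", "-"), each = n_pairs),
    start = win_start,
    sequence = c(fwd_seq, rev_seq)
  )

  # truth: does the (oriented) window cover both junction flanks?
  if (is.na(junction)) {
    reads$harbors_fusion <- FALSE
    reads$fusion_offset <- NA_integer_
    reads$ref_start <- reads$start
  } else {
    off <- .wrap_pos(junction - reads$start + 1L, Lh) # 1-based offset of base s
    harbors <- off <= l - 1L
    reads$harbors_fusion <- harbors
    reads$fusion_offset <- ifelse(harbors, off, NA_integer_)
    # haplotype -> reference coordinate map for non-fusion reads
    reads$ref_start <- ifelse(reads$start <= del_s, reads$start,
                              reads$start + del_shift)
    reads$ref_start[harbors] <- NA_integer_
  }

  reads$sequence <- .add_errors(reads$sequence, error_rate)
  reads$quality <- strrep("I", l)
  reads[, names(empty)]
}

#' Simulate a paired-end sequencing experiment over a heteroplasmic mixture
#'
#' Draws read pairs uniformly from a mixture of the intact circular genome and
#' (optionally) a deleted haplotype, at the requested per-haplotype
#' fold-coverages.  Fragments are `2 l + gap` long, where the inner mate
#' distance `gap` is Gaussian (truncated at 0); substitution errors are
#' injected independently per base; qualities are flat.  Every read is
#' annotated with its ground truth: haplotype of origin, orientation, and —
#' for reads covering the deletion fusion point with at least one base on each
#' side — the fusion offset `x`, the position in the light-strand-oriented
#' read that carries genome base `s`.
#'
#' Coverage can be given per haplotype (`coverage_deleted`/`coverage_intact`,
#' as in "deleted genome at 70x and intact at 69930x", i.e. heteroplasmy
#' 0.1%), or as `coverage_total` plus a heteroplasmy `p` which is split as
#' `p * total` deleted and `(1 - p) * total` intact.
#'
#' @param genome An [mt_genome()].
#' @param deletion A [fusion_point()], or `NULL` for a pure intact experiment.
#' @param coverage_deleted,coverage_intact Fold-coverages of the two
#'   haplotypes.
#' @param coverage_total,p Alternative specification: total fold-coverage and
#'   heteroplasmy fraction in `[0, 1]`.
#' @param read_length Read length in nt (default 150).
#' @param gap_mean,gap_sd Mean and standard deviation (nt) of the inner mate
#'   distance between the two reads of a pair (default 300 and 100).
#' @param error_rate Per-base substitution error probability (default 0.001).
#' @param seed Integer seed; fixing it makes the output reproducible.
#' @return A tibble with one row per read (`id`, `mate`, `haplotype`,
#'   `strand`, `start`, `ref_start`, `sequence`, `quality`, `harbors_fusion`,
#'   `fusion_offset`), with the canonical fusion point, genome and parameters
#'   attached as attributes (`attr(x, "fusion")` etc.).
#' @examples
#' g <- mt_genome(paste(sample(c("A","C","G","T"), 2000, TRUE), collapse = ""))
#' sim <- simulate_reads(g, fusion_point(900, 1101), coverage_deleted = 20,
#'                       coverage_intact = 100, read_length = 70, seed = 1)
#' table(sim$haplotype, sim$harbors_fusion)
#' @export
simulate_reads <- function(genome, deletion = NULL,
                           coverage_deleted = NULL, coverage_intact = NULL,
                           coverage_total = NULL, p = NULL,
                           read_length = 150, gap_mean = 300, gap_sd = 100,
                           error_rate = 0.001, seed = NULL) {
  stopifnot(inherits(genome, "mt_genome"))
  if (!is.null(coverage_total)) {
    stopifnot(!is.null(p), p >= 0, p <= 1, coverage_total >= 0)
    coverage_deleted <- p * coverage_total
    coverage_intact <- (1 - p) * coverage_total
  }
  coverage_deleted <- coverage_deleted %||% 0
  stopifnot(coverage_intact >= 0, coverage_deleted >= 0, read_length >= 1)
  if (coverage_deleted > 0 && is.null(deletion)) {
    stop("coverage_deleted > 0 requires a deletion fusion point",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  fusion <- NULL
  hap_del <- NULL
  if (!is.null(deletion)) {
    fusion <- canonical_fusion(genome, deletion)
    hap_del <- apply_deletion(genome, fusion)
  }

  l <- as.integer(read_length)
  n_int <- coverage_to_pair_count(coverage_intact, genome$length, l)
  reads_int <- .simulate_haplotype(genome$sequence, n_int, l, gap_mean,
                                   gap_sd, error_rate, "intact",
                                   NA_integer_, 0L, NA_integer_)
  if (!is.null(hap_del) && coverage_deleted > 0) {
    n_del <- coverage_to_pair_count(coverage_deleted, nchar(hap_del), l)
    reads_del <- .simulate_haplotype(hap_del, n_del, l, gap_mean, gap_sd,
                                     error_rate, "deleted", fusion$s,
                                     fusion$deleted_length, fusion$s)
    reads <- dplyr::bind_rows(reads_del, reads_int)
  } else {
    reads <- reads_int
  }

  attr(reads, "fusion") <- fusion
  attr(reads, "genome_name") <- genome$name
  attr(reads, "genome_length") <- genome$length
  attr(reads, "read_length") <- l
  attr(reads, "coverage_deleted") <- coverage_deleted
  attr(reads, "coverage_intact") <- coverage_intact
  attr(reads, "seed") <- seed
  class(reads) <- c("mito_sim", class(reads))
  reads
}

#' Write simulated reads as a paired FASTQ
#'
#' @param sim A tibble from [simulate_reads()].
#' @param file_1,file_2 Output paths for mate 1 and mate 2.
#' @return Invisibly, the two paths.
#' @export
write_fastq <- function(sim, file_1, file_2) {
  for (m in 1:2) {
    rows <- sim[sim$mate == m, ]
    rows <- rows[order(rows$id), ]
    dna <- Biostrings::DNAStringSet(rows$sequence)
    names(dna) <- paste0(rows$id, "/", m)
    # writeXStringSet warns about dropping (unused) mcols metadata
    suppressWarnings(Biostrings::writeXStringSet(
      dna, filepath = c(file_1, file_2)[m], format = "fastq",
      qualities = Biostrings::BStringSet(rows$quality)
    ))
  }
  invisible(c(file_1, file_2))
}

#' Write simulated reads as a pseudo-alignment SAM file
#'
#' Emulates what a whole-genome aligner produces for a mitochondrial sample:
#' reads that do not span a deletion fusion point are written as mapped
#' records on the mitochondrial contig with a full-match CIGAR (reads that
#' cross the circular origin are soft-clipped at the contig end, as a linear
#' aligner would report them), while fusion-spanning reads are written as
#' unmapped records.  This lets the full calling pipeline be exercised
#' without an external aligner.
#'
#' @param sim A tibble from [simulate_reads()].
#' @param genome The [mt_genome()] the simulation used.
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_pseudo_sam <- function(sim, genome, path) {
  stopifnot(inherits(genome, "mt_genome"))
  l <- attr(sim, "read_length") %||% nchar(sim$sequence[1])
  L <- genome$length

  qname <- paste0(sim$id, "/", sim$mate)
  unmapped <- sim$harbors_fusion
  minus <- sim$strand == "-" & !unmapped

  flag <- integer(nrow(sim))
  flag[unmapped] <- 4L
  flag[minus] <- 16L

  # mapped records store the reference-forward (light-strand) sequence
  seq_out <- sim$sequence
  seq_out[minus] <- .revcomp(seq_out[minus])

  pos <- ifelse(unmapped, 0L, sim$ref_start)
  matched <- pmin(l, L - pos + 1L)
  cigar <- ifelse(unmapped, "*",
                  ifelse(matched >= l, paste0(l, "M"),
                         paste0(matched, "M", l - matched, "S")))
  rname <- ifelse(unmapped, "*", genome$name)
  mapq <- ifelse(unmapped, 0L, 60L)

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$name, L),
              "@PG\tID:mitosplit\tPN:mitosplit")
  records <- paste(qname, flag, rname, pos, mapq, cigar,
                   "*", 0L, 0L, seq_out, sim$quality, sep = "\t")
  writeLines(c(header, records), path)
  invisible(path)
}
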