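#' Build a k-mer seed index over a circular reference
#'
#' Indexes every k-mer of the circularly extended (doubled) reference, with
#' start positions normalized to `1..L`.  The index drives the fast
#' full-match classification of candidate reads; because the mitochondrial
#' reference is tiny, split alignment itself can afford an exhaustive
#' placement search and uses the index only to shortlist diagonals.
#'
#' @param genome An [mt_genome()].
#' @param k Seed length in nt (default 16).
#' @return An object of class `kmer_index`.
#' @export
kmer_index <- function(genome, k = 16) {
  stopifnot(inherits(genome, "mt_genome"))
  k <- as.integer(k)
  L <- genome$length
  if (k < 1L || k > L) {
    stop("seed length k must be in 1..", L, call. = FALSE)
  }
  doubled <- .doubled(genome)
  starts <- seq_len(L)
  kmers <- substring(doubled, starts, starts + k - 1L)
  env <- list2env(split(starts, kmers), hash = TRUE)
  structure(list(k = k, L = L, env = env), class = "kmer_index")
}

#' @rdname kmer_index
#' @param index A `kmer_index`.
#' @param kmer A k-mer string; absent k-mers return an empty integer vector.
#' @export
kmer_hits <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  get0(kmer, envir = index$env, ifnotfound = integer(0))
}

# candidate diagonals (genome position of read base 1, wrapped to 1..L)
# implied by exact seed hits at the given read offsets
.seed_diagonals <- function(read, index, offsets) {
  hits <- lapply(offsets, function(o) {
    h <- kmer_hits(index, substr(read, o, o + index$k - 1L))
    if (length(h)) h - o + 1L else integer(0)
  })
  sort(unique(.wrap_pos(unlist(hits), index$L)))
}

#' Classify a read as a full-length match to the reference
#'
#' Reads that align full-length (on either strand, allowing up to
#' `max_mismatches` substitutions) map to the intact genome and are excluded
#' from split calling; in aligner-free FASTQ mode they are what gets counted
#' toward the mitochondrial read total `r`.  Matching is seeded with exact
#' k-mers at regularly spaced read offsets, so the circular reference is
#' searched on both strands including origin-crossing placements.
#'
#' @param read Read sequence (original orientation).
#' @param index A [kmer_index()].
#' @param genome The indexed [mt_genome()].
#' @param max_mismatches Maximum substitutions tolerated (default 3).
#' @return `NULL`, or a list with `pos` (light-strand position of the
#'   alignment start), `strand` and `mismatches`.
#' @export
classify_full_match <- function(read, index, genome, max_mismatches = 3) {
  stopifnot(inherits(index, "kmer_index"), inherits(genome, "mt_genome"))
  l <- nchar(read)
  if (l > genome$length) {
    stop("read longer than the reference", call. = FALSE)
  }
  if (l < index$k) return(NULL)
  doubled <- .doubled(genome)
  offsets <- unique(c(seq(1L, l - index$k + 1L, by = index$k),
                      l - index$k + 1L))
  best <- NULL
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") read else .revcomp(read)
    for (d in .seed_diagonals(oriented, index, offsets)) {
      mm <- .mm_count(oriented, substr(doubled, d, d + l - 1L))
      if (mm <= max_mismatches &&
          (is.null(best) || mm < best$mismatches ||
           (mm == best$mismatches && d < best$pos && strand == best$strand))) {
        best <- list(pos = d, strand = strand, mismatches = mm)
      }
    }
    if (!is.null(best) && best$mismatches == 0L) break
  }
  best
}

# exhaustive best two-segment split of an oriented read over the given
# diagonals; ri/gi are utf8 codes of the read and doubled genome
.best_split_over <- function(ri, gi, L, diags, min_overhang, max_mismatch) {
  l <- length(ri)
  nd <- length(diags)
  if (nd == 0L) return(NULL)
  idx <- rep.int(diags, l) + rep(0:(l - 1L), each = nd)
  M <- matrix(gi[idx] != rep(ri, each = nd), nd, l)
  A <- M
  for (j in seq(2L, l)) A[, j] <- A[, j - 1L] + M[, j]
  B <- M
  for (j in seq(l - 1L, 1L)) B[, j] <- B[, j + 1L] + M[, j]

  best <- NULL
  for (x in seq(min_overhang, l - min_overhang)) {
    i1 <- which(A[, x] <= max_mismatch)
    if (length(i1) == 0L) next
    i2 <- which(B[, x + 1L] <= max_mismatch)
    if (length(i2) == 0L) next
    cand <- expand.grid(i = i1, j = i2)
    s_n <- .wrap_pos(diags[cand$i] + x - 1L, L)
    e_n <- .wrap_pos(diags[cand$j] + x, L)
    ok <- e_n >= s_n + 2L
    if (!any(ok)) next
    mm1 <- A[cand$i[ok], x]
    mm2 <- B[cand$j[ok], x + 1L]
    hits <- data.frame(s = s_n[ok], e = e_n[ok], x = x,
                       mm1 = mm1, mm2 = mm2, total = mm1 + mm2)
    hmin <- min(hits$total)
    if (is.null(best) || hmin < best$total[1]) {
      best <- hits[hits$total == hmin, , drop = FALSE]
    } else if (hmin == best$total[1]) {
      best <- rbind(best, hits[hits$total == hmin, , drop = FALSE])
    }
  }
  best
}

# canonicalize, then apply the tie-break (minimal canonical s, then larger
# minimum overhang); returns a single row or NULL
.pick_split <- function(cands, genome, l) {
  if (is.null(cands) || nrow(cands) == 0L) return(NULL)
  shift <- integer(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    cf <- canonical_fusion(genome, fusion_point(cands$s[i], cands$e[i]))
    shift[i] <- cands$s[i] - cf$s
  }
  cands$s <- cands$s - shift
  cands$e <- cands$e - shift
  cands$x <- cands$x - shift
  cands$min_oh <- pmin(cands$x, l - cands$x)
  ord <- order(cands$total, cands$s, -cands$min_oh)
  cands[ord[1], , drop = FALSE]
}

#' Find the optimal two-segment (split) alignment of a read
#'
#' Searches both orientations of a read for the best split into a prefix
#' `1..x` aligned at genome positions `s - x + 1 .. s` and a suffix
#' `x + 1 .. l` aligned at `e .. e + l - x - 1`, with `e > s + 1`, i.e. a
#' placement consistent with a simple deletion on one strand.  Each segment
#' must have at least `min_overhang` bases and at most
#' `max_mismatch` substitutions.  Among feasible splits the one maximizing
#' total matched bases wins; ties are broken toward the smallest canonical
#' `s`, then the larger minimum overhang, then the `+` orientation.  The
#' search is exhaustive over all genome placements (optionally shortlisted by
#' seed hits with an exhaustive fallback), so the reported split is a true
#' optimum; placements implying an origin-spanning deletion are rejected.
#'
#' @param read Read sequence (original orientation).
#' @param genome An [mt_genome()].
#' @param index Optional [kmer_index()] used to shortlist placements.
#' @param min_overhang Minimum bases on each side of the fusion (default 20).
#' @param max_mismatch Maximum substitutions per segment (default 1).
#' @return `NULL`, or a one-row tibble with `strand`, `x`, `s`, `e`, `mm1`,
#'   `mm2` describing the canonical split.
#' @export
align_split <- function(read, genome, index = NULL, min_overhang = 20,
                        max_mismatch = 1) {
  stopifnot(inherits(genome, "mt_genome"))
  gi <- utf8ToInt(.doubled(genome))
  .align_split_impl(read, genome, gi, index, min_overhang, max_mismatch)
}

.align_split_impl <- function(read, genome, gi, index, min_overhang,
                              max_mismatch) {
  l <- nchar(read)
  L <- genome$length
  if (l < 2 * min_overhang || l > L) return(NULL)
  shortlist_ok <- !is.null(index) && index$k <= min_overhang

  best <- NULL
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") read else .revcomp(read)
    ri <- utf8ToInt(oriented)
    cands <- NULL
    if (shortlist_ok) {
      offsets <- seq(1L, l - index$k + 1L)
      diags <- .seed_diagonals(oriented, index, offsets)
      cands <- .best_split_over(ri, gi, L, diags, min_overhang, max_mismatch)
    }
    # a zero-mismatch split always has both seed anchors (k <= min_overhang),
    # so only fall back to the full placement scan when errors are in play
    if (!shortlist_ok || is.null(cands) || min(cands$total) > 0L) {
      cands <- .best_split_over(ri, gi, L, seq_len(L), min_overhang,
                                max_mismatch)
    }
    pick <- .pick_split(cands, genome, l)
    if (!is.null(pick)) {
      if (is.null(best) || pick$total < best$total ||
          (pick$total == best$total &&
           (pick$s < best$s ||
            (pick$s == best$s && pick$min_oh > best$min_oh)))) {
        pick$strand <- strand
        best <- pick
      }
    }
  }
  if (is.null(best)) return(NULL)
  tibble::tibble(strand = best$strand, x = as.integer(best$x),
                 s = as.integer(best$s), e = as.integer(best$e),
                 mm1 = as.integer(best$mm1), mm2 = as.integer(best$mm2))
}

#' Split-align every candidate read in a pool
#'
#' Routes each candidate through [classify_full_match()] first (full-length
#' matches are intact-genome reads, not deletion evidence) and then
#' [align_split()].  In aligner-free FASTQ mode the number of full-length
#' matches becomes the mitochondrial read count `r`.
#'
#' @param pool A `candidate_pool` from [extract_candidates()] or
#'   [pool_from_fastq()].
#' @param genome An [mt_genome()].
#' @param k Seed length for the index (default 16).
#' @param min_overhang,max_mismatch Passed to [align_split()].
#' @param max_full_mismatches Passed to [classify_full_match()].
#' @return A tibble of split alignments (`id`, `mate`, `strand`, `x`, `s`,
#'   `e`, `mm1`, `mm2`) with counts attached as attributes: `n_candidates`,
#'   `n_full_match`, `n_split`, `n_unaligned`, and `r` (pool `r`, or the
#'   full-match count in FASTQ mode).
#' @export
align_candidates <- function(pool, genome, k = 16, min_overhang = 20,
                             max_mismatch = 1, max_full_mismatches = 3) {
  stopifnot(inherits(pool, "candidate_pool"), inherits(genome, "mt_genome"))
  index <- kmer_index(genome, k)
  gi <- utf8ToInt(.doubled(genome))
  cand <- pool$candidates

  n_full <- 0L
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    read <- cand$sequence[i]
    if (!is.null(classify_full_match(read, index, genome,
                                     max_full_mismatches))) {
      n_full <- n_full + 1L
      next
    }
    hit <- .align_split_impl(read, genome, gi, index, min_overhang,
                             max_mismatch)
    if (!is.null(hit)) {
      hit$id <- cand$id[i]
      hit$mate <- cand$mate[i]
      rows[[i]] <- hit
    }
  }
  splits <- dplyr::bind_rows(rows)
  if (nrow(splits) == 0L) {
    splits <- tibble::tibble(strand = character(0), x = integer(0),
                             s = integer(0), e = integer(0),
                             mm1 = integer(0), mm2 = integer(0),
                             id = character(0), mate = integer(0))
  }
  splits <- splits[, c("id", "mate", "strand", "x", "s", "e", "mm1", "mm2")]
  attr(splits, "n_candidates") <- nrow(cand)
  attr(splits, "n_full_match") <- n_full
  attr(splits, "n_split") <- nrow(splits)
  attr(splits, "n_unaligned") <- nrow(cand) - n_full - nrow(splits)
  attr(splits, "r") <- if (identical(pool$mode, "fastq")) n_full else pool$r
  attr(splits, "l") <- pool$l
  splits
}
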