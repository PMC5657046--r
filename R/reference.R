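#' Construct a circular mitochondrial reference genome
#'
#' The human mitochondrial chromosome is a circle of 16,569 bases whose
#' positions are numbered 1-based along the light strand.  `mt_genome()` wraps
#' a nucleotide string together with this coordinate convention; all other
#' functions in the package take one of these objects wherever a reference is
#' needed.
#'
#' @param sequence Single nucleotide string over the IUPAC alphabet.
#' @param name Contig name used in SAM/FASTA output (default `"chrM"`).
#' @param circular Should position arithmetic wrap past the end? Mitochondrial
#'   genomes are circular; this is `TRUE` by default.
#' @return An object of class `mt_genome` with fields `name`, `sequence`,
#'   `length` and `circular`.
#' @examples
#' g <- mt_genome("ACGTACGTAC", name = "toy")
#' g$length
#' @export
mt_genome <- function(sequence, name = "chrM", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) {
    stop("reference sequence is empty", call. = FALSE)
  }
  alphabet <- strsplit("ACGTNRYSWKMBDHV", "")[[1]]
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), alphabet)
  if (length(bad) > 0L) {
    stop("reference contains non-IUPAC characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         circular = circular),
    class = "mt_genome"
  )
}

#' @export
print.mt_genome <- function(x, ...) {
  cat(sprintf("<mt_genome> %s: %s bp%s\n", x$name,
              format(x$length, big.mark = ","),
              if (x$circular) ", circular" else ""))
  invisible(x)
}

#' Read a mitochondrial reference from FASTA
#'
#' Reads the first record of a (possibly gzipped) FASTA file, uppercases it,
#' and returns an [mt_genome()].  Intended for the rCRS (NC_012920.1,
#' 16,569 bp) but any single-contig reference works.
#'
#' @param path Path to a FASTA file.
#' @param circular Passed to [mt_genome()].
#' @return An `mt_genome`.
#' @export
read_mito_reference <- function(path, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("no FASTA records found in ", path, call. = FALSE)
  }
  name <- sub("\\s.*$", "", names(seqs)[1])
  mt_genome(as.character(seqs[[1]]), name = name, circular = circular)
}

# wrap a 1-based position onto 1..L
.wrap_pos <- function(p, L) ((p - 1L) %% L) + 1L

# doubled sequence for wraparound substring extraction
.doubled <- function(genome) paste0(genome$sequence, genome$sequence)

# single base at (possibly wrapped) position
.base_at <- function(genome, p) {
  p <- .wrap_pos(p, genome$length)
  substr(genome$sequence, p, p)
}

#' Describe a deletion by its fusion point
#'
#' A deletion removes bases `s + 1 .. e - 1`, fusing the last retained base
#' before the gap (`s`) to the first retained base after it (`e`).  The pair
#' `(s, e)` is the *fusion point*; a sequencing read spanning it is a split
#' (fusion) read.  At least one base must be deleted (`e >= s + 2`), and the
#' deleted segment may not span the origin, so `s >= 1` and `e <= L` when a
#' genome length is known.
#'
#' @param s Position of the last retained base 5' of the fusion.
#' @param e Position of the first retained base 3' of the fusion.
#' @return An object of class `fusion_point` with fields `s`, `e`,
#'   `deleted_start`, `deleted_end` and `deleted_length`.
#' @examples
#' fusion_point(8482, 13460)   # the "common deletion", 4977 bp
#' @export
fusion_point <- function(s, e) {
  s <- as.integer(s); e <- as.integer(e)
  stopifnot(length(s) == 1L, length(e) == 1L, !is.na(s), !is.na(e))
  if (s < 1L) stop("fusion point s must be >= 1", call. = FALSE)
  if (e < s + 2L) {
    stop("fusion point requires e >= s + 2 (at least one deleted base); ",
         "origin-spanning deletions are not representable", call. = FALSE)
  }
  structure(
    list(s = s, e = e, deleted_start = s + 1L, deleted_end = e - 1L,
         deleted_length = e - s - 1L),
    class = "fusion_point"
  )
}

#' @export
print.fusion_point <- function(x, ...) {
  cat(sprintf("<fusion_point> s=%d, e=%d (%s)\n", x$s, x$e,
              format_deletion_notation(x)))
  invisible(x)
}

#' Canonicalize a fusion point against a reference
#'
#' When a deletion breakpoint is flanked by repeated sequence (as the common
#' deletion is, by a 13-bp direct repeat), several `(s, e)` pairs describe the
#' same deleted molecule.  The canonical representative shifts the fusion as
#' far 5' as possible (minimal `s`), stopping at the origin.  Deterministic
#' clustering of split reads requires all placements to be reduced to this
#' form.
#'
#' @param genome An [mt_genome()].
#' @param fp A [fusion_point()].
#' @return A `fusion_point` with minimal `s` among equivalent placements.
#' @export
canonical_fusion <- function(genome, fp) {
  stopifnot(inherits(genome, "mt_genome"), inherits(fp, "fusion_point"))
  s <- fp$s; e <- fp$e
  while (s > 1L && .base_at(genome, s) == .base_at(genome, e - 1L)) {
    s <- s - 1L
    e <- e - 1L
  }
  fusion_point(s, e)
}

#' Excise a deletion from a reference sequence
#'
#' Returns the reference sequence with bases `s + 1 .. e - 1` removed — the
#' deleted haplotype used, e.g., as simulation input.  The excision is linear:
#' the fusion-point representation cannot express an origin-spanning deletion,
#' and coordinates must lie within the genome.
#'
#' @inheritParams canonical_fusion
#' @return A nucleotide string of length `L - deleted_length`.
#' @examples
#' g <- mt_genome("ACGTACGTAC", name = "toy")
#' apply_deletion(g, fusion_point(3, 7))  # "ACGGTAC"
#' @export
apply_deletion <- function(genome, fp) {
  stopifnot(inherits(genome, "mt_genome"), inherits(fp, "fusion_point"))
  L <- genome$length
  if (fp$e > L) {
    stop("fusion point (s=", fp$s, ", e=", fp$e, ") extends past the ",
         L, "-bp reference; origin-spanning deletions are unsupported",
         call. = FALSE)
  }
  paste0(substr(genome$sequence, 1L, fp$s),
         substr(genome$sequence, fp$e, L))
}

#' Extract a subsequence from a circular genome
#'
#' Returns `length` bases starting at `start`, wrapping past the last position
#' back to position 1.  Needed to simulate and align reads that cross the
#' origin of the circular chromosome.
#'
#' @param genome An [mt_genome()].
#' @param start 1-based start position (wrapped into range if outside `1..L`).
#' @param length Number of bases to return; must not exceed the genome length.
#' @return A nucleotide string.
#' @export
circular_subsequence <- function(genome, start, length) {
  stopifnot(inherits(genome, "mt_genome"))
  L <- genome$length
  if (length > L) {
    stop("requested ", length, " bases from a ", L, "-bp genome",
         call. = FALSE)
  }
  if (length == 0L) return("")
  start <- .wrap_pos(as.integer(start), L)
  substr(.doubled(genome), start, start + as.integer(length) - 1L)
}

#' Parse and format deletion notation
#'
#' Deletions are conventionally named `m.<A>_<B>del<len>`, where `A..B` is the
#' deleted segment, inclusive (HGVS style), so that `m.8483_13459del4977`
#' deletes 4977 bases and corresponds to fusion point `(8482, 13460)`.  Some
#' published names state `B - A` rather than `B - A + 1` as the length; the
#' parser trusts the coordinates and warns when a stated length disagrees with
#' the span.
#'
#' @param text A string of the form `m.<A>_<B>del[<len>]`.
#' @return `parse_deletion_notation()` returns a [fusion_point()];
#'   `format_deletion_notation()` returns a string.
#' @examples
#' parse_deletion_notation("m.8483_13459del4977")
#' format_deletion_notation(fusion_point(3, 7))  # "m.4_6del3"
#' @export
parse_deletion_notation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regexec("^m\\.([0-9]+)_([0-9]+)del([0-9]+)?$", text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) == 0L) {
    stop("cannot parse deletion notation: '", text,
         "' (expected m.<start>_<end>del[<length>])", call. = FALSE)
  }
  a <- as.integer(parts[2]); b <- as.integer(parts[3])
  if (b < a) {
    stop("deletion notation '", text, "' has end before start", call. = FALSE)
  }
  if (a < 2L) {
    stop("deleted segment may not include position 1 ",
         "(origin-adjacent deletions are unsupported)", call. = FALSE)
  }
  if (parts[4] != "" && as.integer(parts[4]) != b - a + 1L) {
    warning("stated length ", parts[4], " differs from inclusive span ",
            b - a + 1L, " in '", text, "'; using the coordinates",
            call. = FALSE)
  }
  fusion_point(a - 1L, b + 1L)
}

#' @rdname parse_deletion_notation
#' @param fp A [fusion_point()].
#' @export
format_deletion_notation <- function(fp) {
  stopifnot(inherits(fp, "fusion_point"))
  sprintf("m.%d_%ddel%d", fp$deleted_start, fp$deleted_end, fp$deleted_length)
}
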