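# Shared fixtures and independent oracles.  Everything is generated in code;
# no stored data files.

random_genome <- function(L, seed, name = "chrM") {
  set.seed(seed)
  mt_genome(paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = ""), name = name)
}

revcomp1 <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Construct an error-free fusion read with offset x for fusion (s, e):
# prefix = genome[s-x+1 .. s], suffix = genome[e .. e+l-x-1]
fusion_read <- function(genome, s, e, x, l) {
  paste0(circular_subsequence(genome, s - x + 1, x),
         circular_subsequence(genome, e, l - x))
}

# Independent brute-force split-alignment oracle: enumerates every split
# point and every pair of genome placements directly from the definition,
# canonicalizes, and applies the documented tie-break (max matched bases,
# then minimal canonical s, then larger minimum overhang, + strand first).
# Returns list(s, e) or NULL.
oracle_split <- function(read, genome, min_overhang = 20, max_mismatch = 1) {
  L <- genome$length
  gch <- strsplit(paste0(genome$sequence, genome$sequence), "")[[1]]
  best <- NULL
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") read else revcomp1(read)
    l <- nchar(oriented)
    if (l < 2 * min_overhang) next
    rch <- strsplit(oriented, "")[[1]]
    for (x in seq(min_overhang, l - min_overhang)) {
      pref <- rch[1:x]
      suff <- rch[(x + 1):l]
      mm1 <- vapply(seq_len(L), function(g1) {
        sum(gch[g1:(g1 + x - 1)] != pref)
      }, integer(1))
      mm2 <- vapply(seq_len(L), function(g2) {
        sum(gch[(g2 + x):(g2 + l - 1)] != suff)
      }, integer(1))
      for (g1 in which(mm1 <= max_mismatch)) {
        for (g2 in which(mm2 <= max_mismatch)) {
          s <- ((g1 + x - 2) %% L) + 1
          e <- ((g2 + x - 1) %% L) + 1
          if (e < s + 2) next
          cf <- canonical_fusion(genome, fusion_point(s, e))
          x_c <- x - (s - cf$s)
          cand <- list(score = l - mm1[g1] - mm2[g2], s = cf$s, e = cf$e,
                       minoh = min(x_c, l - x_c), strand = strand)
          if (is.null(best) ||
              cand$score > best$score ||
              (cand$score == best$score &&
               (cand$s < best$s ||
                (cand$s == best$s && cand$minoh > best$minoh)))) {
            best <- cand
          }
        }
      }
    }
  }
  if (is.null(best)) NULL else list(s = best$s, e = best$e)
}

# Independent Clopper-Pearson oracle: invert the binomial tail equations
# P(X >= n | q_low) = alpha/2 and P(X <= n | q_high) = alpha/2 by root
# finding on the cumulative distribution itself.
cp_bisect <- function(n, r, alpha = 0.05) {
  low <- if (n == 0) {
    0
  } else {
    stats::uniroot(function(q) {
      stats::pbinom(n - 1, r, q, lower.tail = FALSE) - alpha / 2
    }, c(1e-15, 1 - 1e-15), tol = 1e-14)$root
  }
  high <- if (n == r) {
    1
  } else {
    stats::uniroot(function(q) {
      stats::pbinom(n, r, q) - alpha / 2
    }, c(1e-15, 1 - 1e-15), tol = 1e-14)$root
  }
  c(low, high)
}

# One simulated experiment written as a pseudo-alignment SAM in tempdir
sim_to_sam <- function(genome, ...) {
  sim <- simulate_reads(genome, ...)
  sam <- tempfile(fileext = ".sam")
  write_pseudo_sam(sim, genome, sam)
  list(sim = sim, sam = sam)
}
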