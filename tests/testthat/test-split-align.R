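test_that("the k-mer index covers every circular position", {
  g <- mt_genome("ACGTACGTAC", name = "toy")
  idx <- kmer_index(g, k = 4)
  counts <- sum(vapply(ls(idx$env), function(k) length(kmer_hits(idx, k)),
                       integer(1)))
  expect_equal(counts, 10L)
  expect_identical(kmer_hits(idx, "AAAA"), integer(0))
  expect_error(kmer_index(g, k = 11))
  # repeated k-mers return all positions (multimap)
  gt <- mt_genome("ATATATATAT")
  it <- kmer_index(gt, 4)
  expect_equal(sort(kmer_hits(it, "ATAT")), c(1L, 3L, 5L, 7L, 9L))
})

test_that("full-length matches are classified on both strands, across the origin", {
  g <- random_genome(2000, seed = 20)
  idx <- kmer_index(g, 16)
  read <- circular_subsequence(g, 500, 80)
  hit <- classify_full_match(read, idx, g)
  expect_equal(hit$pos, 500L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$mismatches, 0L)
  # reverse-complement reported in light-strand coordinates on -
  hit_rc <- classify_full_match(revcomp1(read), idx, g)
  expect_equal(hit_rc$pos, 500L)
  expect_equal(hit_rc$strand, "-")
  # origin-crossing read still matches
  wrap <- circular_subsequence(g, 1980, 60)
  expect_equal(classify_full_match(wrap, idx, g)$pos, 1980L)
  # a read with a substitution matches with 1 mismatch
  mut <- read
  substr(mut, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                 substr(read, 40, 40))[1]
  expect_equal(classify_full_match(mut, idx, g)$mismatches, 1L)
  # a fusion read across a 200-bp deletion has no full match
  fus <- fusion_read(g, 800, 1001, 40, 80)
  expect_null(classify_full_match(fus, idx, g))
})

test_that("split alignment recovers the textbook fusion geometry", {
  g <- random_genome(300, seed = 21)
  # deletion (s=100, e=201); error-free 60-nt read with x = 30
  read <- fusion_read(g, 100, 201, 30, 60)
  hit <- align_split(read, g)
  cf <- canonical_fusion(g, fusion_point(100, 201))
  expect_equal(hit$s, cf$s)
  expect_equal(hit$e, cf$e)
  expect_equal(hit$x + (100L - cf$s), 30L)  # offset shifts with canonical s
  expect_equal(hit$strand, "+")
  expect_equal(hit$mm1 + hit$mm2, 0L)
  # the reported segments really match the reference
  expect_equal(substr(read, 1, hit$x),
               circular_subsequence(g, hit$s - hit$x + 1, hit$x))
  expect_equal(substr(read, hit$x + 1, 60),
               circular_subsequence(g, hit$e, 60 - hit$x))
})

test_that("overhang and deletion-consistency constraints are enforced", {
  g <- random_genome(300, seed = 21)
  # junction too close to the read end
  expect_null(align_split(fusion_read(g, 100, 201, 5, 60), g))
  # a clean full-length read yields no split
  expect_null(align_split(circular_subsequence(g, 10, 60), g))
  # reads shorter than 2 * min_overhang cannot be split
  expect_null(align_split(fusion_read(g, 100, 201, 15, 30), g,
                          min_overhang = 20))
})

test_that("strand symmetry: the reverse complement maps to the same fusion", {
  g <- random_genome(500, seed = 22)
  read <- fusion_read(g, 200, 351, 25, 60)
  fwd <- align_split(read, g)
  rev <- align_split(revcomp1(read), g)
  expect_equal(fwd$s, rev$s)
  expect_equal(fwd$e, rev$e)
  expect_equal(fwd$x, rev$x)
  expect_setequal(c(fwd$strand, rev$strand), c("+", "-"))
})

test_that("one substitution per segment is tolerated, two are not", {
  g <- random_genome(500, seed = 23)
  read <- fusion_read(g, 200, 351, 30, 60)
  flip <- function(s, i) {
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), substr(s, i, i))[1]
    s
  }
  one_each <- flip(flip(read, 10), 50)
  hit <- align_split(one_each, g)
  cf <- canonical_fusion(g, fusion_point(200, 351))
  expect_equal(hit$s, cf$s)
  expect_equal(hit$mm1, 1L)
  expect_equal(hit$mm2, 1L)
  two_one_side <- flip(flip(read, 8), 12)
  expect_null(align_split(two_one_side, g))
})

test_that("split alignment equals the brute-force oracle on simulated fusion reads", {
  g <- random_genome(400, seed = 24)
  fp <- fusion_point(150, 251)
  sim <- simulate_reads(g, fp, coverage_deleted = 12, coverage_intact = 4,
                        read_length = 60, gap_mean = 40, gap_sd = 15,
                        error_rate = 0.005, seed = 25)
  fus <- sim[sim$harbors_fusion, ]
  expect_gt(nrow(fus), 5)
  idx <- kmer_index(g, 16)
  for (i in seq_len(nrow(fus))) {
    read <- fus$sequence[i]
    impl <- align_split(read, g, index = idx)
    orac <- oracle_split(read, g)
    if (is.null(orac)) {
      expect_null(impl)
    } else {
      expect_equal(impl$s, orac$s)
      expect_equal(impl$e, orac$e)
    }
  }
  # a couple of non-fusion reads agree too (both find nothing or full-match
  # routing applies upstream)
  non <- head(sim[!sim$harbors_fusion, ], 3)
  for (read in non$sequence) {
    impl <- align_split(read, g, index = idx)
    orac <- oracle_split(read, g)
    expect_equal(is.null(impl), is.null(orac))
  }
})
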