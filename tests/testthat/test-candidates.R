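test_that("candidate extraction recovers the simulated fusion reads and r", {
  g <- random_genome(4000, seed = 10)
  out <- sim_to_sam(g, deletion = fusion_point(1500, 1701),
                    coverage_deleted = 25, coverage_intact = 50,
                    read_length = 100, seed = 11)
  pool <- extract_candidates(out$sam, clip_min = 20)
  truth <- out$sim[out$sim$harbors_fusion, ]
  key <- function(id, mate) paste(id, mate)
  # every fusion read is in the pool (clipped origin-crossers may join it)
  expect_true(all(key(truth$id, truth$mate) %in%
                  key(pool$candidates$id, pool$candidates$mate)))
  # unmapped candidates are exactly the fusion reads
  unm <- pool$candidates[pool$candidates$source == "unmapped", ]
  expect_setequal(key(unm$id, unm$mate), key(truth$id, truth$mate))
  expect_equal(pool$r, sum(!out$sim$harbors_fusion))
  expect_equal(pool$l, 100L)
  # candidate sequences are in original read orientation
  m <- match(key(truth$id, truth$mate), key(unm$id, unm$mate))
  expect_equal(unm$sequence[m], truth$sequence)
})

test_that("extraction is order-independent", {
  g <- random_genome(3000, seed = 12)
  out <- sim_to_sam(g, deletion = fusion_point(1200, 1401),
                    coverage_deleted = 20, coverage_intact = 30,
                    read_length = 80, seed = 13)
  lines <- readLines(out$sam)
  hdr <- grepl("^@", lines)
  set.seed(14)
  shuffled <- c(lines[hdr], sample(lines[!hdr]))
  sam2 <- tempfile(fileext = ".sam")
  writeLines(shuffled, sam2)
  p1 <- extract_candidates(out$sam)
  p2 <- extract_candidates(sam2)
  expect_equal(p1$r, p2$r)
  o1 <- dplyr::arrange(p1$candidates, id, mate)
  o2 <- dplyr::arrange(p2$candidates, id, mate)
  expect_equal(as.data.frame(o1), as.data.frame(o2))
})

test_that("CIGAR and flag rules decide pool membership", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrM\tLN:16569",
    # unmapped -> candidate
    paste("u1", 4, "*", 0, 0, "*", "*", 0, 0,
          strrep("ACGT", 30), strrep("I", 120), sep = "\t"),
    # mapped with a long soft clip -> candidate
    paste("c1", 0, "chrM", 100, 60, "75M45S", "*", 0, 0,
          strrep("ACGT", 30), strrep("I", 120), sep = "\t"),
    # mapped, reverse strand, clipped -> candidate, orientation restored
    paste("c2", 16, "chrM", 200, 60, "60M60S", "*", 0, 0,
          strrep("ACGT", 30), strrep("I", 120), sep = "\t"),
    # mapped perfectly -> counted in r only
    paste("p1", 0, "chrM", 300, 60, "120M", "*", 0, 0,
          strrep("ACGT", 30), strrep("I", 120), sep = "\t"),
    # short clip below threshold -> not a candidate
    paste("p2", 0, "chrM", 400, 60, "110M10S", "*", 0, 0,
          strrep("ACGT", 30), strrep("I", 120), sep = "\t"),
    # long CIGAR deletion -> candidate via indel rule
    paste("i1", 0, "chrM", 500, 60, "60M30D60M", "*", 0, 0,
          strrep("ACGT", 30), strrep("I", 120), sep = "\t")
  ), sam)
  pool <- extract_candidates(sam, clip_min = 20, indel_min = 5)
  expect_setequal(pool$candidates$id, c("u1", "c1", "c2", "i1"))
  expect_equal(pool$r, 5L)  # all mapped primary records on chrM
  src <- setNames(pool$candidates$source, pool$candidates$id)
  expect_equal(src[["u1"]], "unmapped")
  expect_equal(src[["c1"]], "clipped")
  expect_equal(src[["i1"]], "indel")
  # reverse-strand candidate restored to original read orientation
  expect_equal(pool$candidates$sequence[pool$candidates$id == "c2"],
               revcomp1(strrep("ACGT", 30)))
})

test_that("a missing mitochondrial contig is an error", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:1000"), sam)
  expect_error(extract_candidates(sam), "contig")
  expect_error(extract_candidates(tempfile(fileext = ".bam")), "not found")
})

test_that("FASTQ pools require matched pair files", {
  g <- random_genome(2000, seed = 15)
  sim <- simulate_reads(g, coverage_intact = 20, read_length = 70, seed = 16)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(sim, f1, f2)
  short <- readLines(f2)[1:4]
  f3 <- tempfile(fileext = ".fastq")
  writeLines(short, f3)
  expect_error(pool_from_fastq(f1, f3), "different read counts")
  pool <- pool_from_fastq(f1, f2)
  expect_true(is.na(pool$r))
  expect_equal(nrow(pool$candidates), nrow(sim))
})
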