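test_that("coverage converts to pair counts", {
  expect_equal(coverage_to_pair_count(70, 16569, 150), 3866L)
  expect_equal(coverage_to_pair_count(0, 16569, 150), 0L)
  expect_equal(coverage_to_pair_count(2 * 150 / 1000, 1000, 150), 1L)
})

test_that("simulation is deterministic given a seed", {
  g <- random_genome(4000, seed = 2)
  fp <- fusion_point(1500, 1701)
  a <- simulate_reads(g, fp, coverage_deleted = 30, coverage_intact = 60,
                      read_length = 100, seed = 42)
  b <- simulate_reads(g, fp, coverage_deleted = 30, coverage_intact = 60,
                      read_length = 100, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_reads(g, fp, coverage_deleted = 30, coverage_intact = 60,
                       read_length = 100, seed = 43)
  expect_false(identical(a$sequence, c2$sequence))
})

test_that("heteroplasmy zero yields only intact reads with no fusion truth", {
  g <- random_genome(4000, seed = 2)
  sim <- simulate_reads(g, fusion_point(1500, 1701), coverage_total = 50,
                        p = 0, read_length = 100, seed = 1)
  expect_true(all(sim$haplotype == "intact"))
  expect_false(any(sim$harbors_fusion))
})

test_that("read sampling is uniform and matches the requested coverage", {
  g <- random_genome(16569, seed = 3)
  cov <- 100
  sim <- simulate_reads(g, coverage_intact = cov, read_length = 150,
                        seed = 9, error_rate = 0)
  n_reads <- nrow(sim)
  expect_equal(n_reads, 2 * coverage_to_pair_count(cov, 16569, 150))
  # realized fold-coverage equals the request up to pair-count rounding
  expect_lt(abs(n_reads * 150 / 16569 - cov) / cov, 0.01)
  # read starts uniform on the circle: first-half count within 3 SE
  n_half <- sum(sim$start <= 16569 / 2)
  expect_lt(abs(n_half - n_reads / 2), 3 * sqrt(n_reads * 0.25))
})

test_that("fusion-spanning reads appear at the expected rate with correct truth", {
  g <- random_genome(16569, seed = 4)
  fp <- fusion_point(5000, 5201)
  l <- 150
  sim <- simulate_reads(g, fp, coverage_deleted = 60, coverage_intact = 0,
                        read_length = l, seed = 5, error_rate = 0)
  n_fus <- sum(sim$harbors_fusion)
  expected <- 60 * (l - 1) / l      # junction captured by l-1 start positions
  expect_lt(abs(n_fus - expected), 4 * sqrt(expected))
  expect_true(all(sim$fusion_offset[sim$harbors_fusion] >= 1))
  expect_true(all(sim$fusion_offset[sim$harbors_fusion] <= l - 1))
  # error-free fusion reads are exactly prefix-at-s + suffix-from-e
  fus <- sim[sim$harbors_fusion, ]
  cf <- attr(sim, "fusion")
  for (i in seq_len(nrow(fus))) {
    oriented <- if (fus$strand[i] == "+") fus$sequence[i] else
      revcomp1(fus$sequence[i])
    x <- fus$fusion_offset[i]
    expect_equal(oriented, fusion_read(g, cf$s, cf$e, x, l))
  }
})

test_that("FASTQ output round-trips through a standard reader", {
  g <- random_genome(3000, seed = 6)
  sim <- simulate_reads(g, fusion_point(1000, 1201), coverage_deleted = 20,
                        coverage_intact = 40, read_length = 80, seed = 7)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(sim, f1, f2)
  pool <- pool_from_fastq(f1, f2)
  expect_equal(nrow(pool$candidates), nrow(sim))
  expect_setequal(
    paste(pool$candidates$id, pool$candidates$mate),
    paste(sim$id, sim$mate)
  )
  m <- match(paste(sim$id, sim$mate),
             paste(pool$candidates$id, pool$candidates$mate))
  expect_equal(pool$candidates$sequence[m], sim$sequence)
})

test_that("pseudo-SAM parses under Rsamtools and flags match the truth", {
  g <- random_genome(3000, seed = 6)
  out <- sim_to_sam(g, deletion = fusion_point(1000, 1201),
                    coverage_deleted = 20, coverage_intact = 40,
                    read_length = 80, seed = 7)
  bam <- Rsamtools::asBam(out$sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  b <- Rsamtools::scanBam(bam)[[1]]
  unmapped <- bitwAnd(b$flag, 4L) > 0L
  expect_equal(sum(unmapped), sum(out$sim$harbors_fusion))
  expect_equal(sum(!unmapped), sum(!out$sim$harbors_fusion))
  expect_equal(length(b$flag), nrow(out$sim))
  # intact-only experiment: all records mapped
  out0 <- sim_to_sam(random_genome(2000, seed = 8), coverage_intact = 30,
                     read_length = 70, seed = 9)
  b0 <- Rsamtools::scanBam(Rsamtools::asBam(out0$sam, tempfile(),
                                            overwrite = TRUE,
                                            indexDestination = FALSE))[[1]]
  expect_true(all(bitwAnd(b0$flag, 4L) == 0L))
})
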