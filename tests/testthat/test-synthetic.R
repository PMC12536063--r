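test_that("synthetic germline set is deterministic and structurally sound", {
  db1 <- syntheticGermlineDb(seed = 7)
  db2 <- syntheticGermlineDb(seed = 7)
  expect_identical(as.character(alleleSeqs(db1)), as.character(alleleSeqs(db2)))
  vs <- alleleSeqs(db1, "V")
  # Cys104 codon (TGT) is the penultimate codon of every V allele
  expect_true(all(substr(as.character(vs), 286, 288) == "TGT"))
  js <- as.character(alleleSeqs(db1, "J"))
  expect_true(all(grepl("TGGGGC", js)))  # Trp118 W-G anchor
})

test_that("simulated rearrangements follow the V + n1 + D' + n2 + J model", {
  db <- fxDb()
  rr <- simulateRearrangement(db, shmRate = 0, seed = 3)
  expect_identical(rr$v_mutated, rr$v_germline)  # no SHM at rate 0
  expect_identical(rr$true_sequence,
                   paste0(rr$v_mutated, rr$n1, rr$d_frag, rr$n2,
                          rr$j_sequence))
  expect_lte(nchar(rr$n1), 10)
  expect_lte(nchar(rr$n2), 10)
  # productive by construction: CDR3 anchored C...W
  expect_match(rr$true_cdr3_aa, "^C.*W$")
  expect_false(grepl("*", rr$true_cdr3_aa, fixed = TRUE))
  # deterministic under a fixed seed
  expect_identical(simulateRearrangement(db, shmRate = 0.03, seed = 9),
                   simulateRearrangement(db, shmRate = 0.03, seed = 9))
  # missing segment class errors
  vOnly <- syntheticGermlineDb(nV = 2, nJ = 1, nD = 1, seed = 1)
  vOnly@sequences <- vOnly@sequences[vOnly@info$segment != "D"]
  vOnly@info <- vOnly@info[vOnly@info$segment != "D", ]
  expect_error(simulateRearrangement(vOnly), "no D alleles")
})

test_that("SHM substitution counts match the binomial model", {
  db <- fxDb()
  counts <- vapply(1:200, function(s)
    simulateRearrangement(db, shmRate = 0.05, seed = 4000 + s)$n_mutations,
    numeric(1))
  lo <- qbinom(0.005, 291, 0.05); hi <- qbinom(0.995, 291, 0.05)
  expect_gte(mean(counts >= lo & counts <= hi), 0.95)
  # mean within 4 standard errors of the binomial mean
  se <- sqrt(291 * 0.05 * 0.95 / 200)
  expect_lt(abs(mean(counts) - 291 * 0.05), 4 * se)
})

test_that("simulated profiles meet their MAX_DIFF design bounds", {
  for (s in 1:25) {
    p1 <- simulateProfile("one_clone", seed = 100 + s)
    expect_equal(sum(p1), 1, tolerance = 1e-9)
    pr1 <- computeProfile(100 * p1)
    expect_gte(pr1@maxDiff, 8)
    expect_equal(pr1@maxDiffPosition, 1L)
    expect_gte(pr1@clonePcts[1], 20)

    p0 <- simulateProfile("polyclonal", seed = 200 + s)
    expect_lte(computeProfile(100 * p0)@maxDiff, 4)

    p2 <- simulateProfile("two_clone", seed = 300 + s)
    pr2 <- computeProfile(100 * p2)
    expect_gte(pr2@maxDiff, 8)
    expect_equal(pr2@maxDiffPosition, 2L)
    expect_lt(pr2@clonePcts[1] / pr2@clonePcts[2], 8)
  }
  expect_error(simulateProfile("polyclonal", nBackground = 5), ">= 10")
})

test_that("read simulation produces exact substrings at zero error", {
  db <- fxDb()
  rr <- simulateRearrangement(db, shmRate = 0, seed = 3)
  rd <- simulateReads(rr, nReads = 1000, errorRate = 0, seed = 5)
  # equal split over the three FR amplicons
  expect_setequal(unname(table(rd$info$amplicon)), c(334, 333, 333))
  r1 <- as.character(as(rd$R1, "DNAStringSet"))
  expect_true(all(vapply(r1, grepl, TRUE, x = rr$true_sequence,
                         fixed = TRUE)))
  # R2 is the reverse complement of the 3' end
  r2 <- as.character(Biostrings::reverseComplement(as(rd$R2, "DNAStringSet")))
  expect_true(all(vapply(unique(r2), grepl, TRUE, x = rr$true_sequence,
                         fixed = TRUE)))
  expect_identical(simulateReads(rr, nReads = 10, seed = 8)$R1,
                   simulateReads(rr, nReads = 10, seed = 8)$R1)
})

test_that("whole-sample simulation keeps truth bookkeeping consistent", {
  db <- fxDb()
  sim <- simulateSample(db, abundances = c(0.6, 0.4), totalReads = 50,
                        shmRate = 0, errorRate = 0, seed = 12)
  expect_equal(nrow(sim$truth), 2)
  expect_equal(sum(sim$truth$n_reads), 50)
  expect_equal(length(sim$R1), 50)
  expect_equal(sum(sim$truth$abundance), 1, tolerance = 1e-9)
  # distinct V-J combinations per clone
  expect_equal(anyDuplicated(paste(sim$truth$v, sim$truth$j)), 0)
  # FASTQ round trip
  pre <- tempfile()
  writeFastqPair(sim, pre)
  back <- readFastqPair(paste0(pre, "_R1.fastq"), paste0(pre, "_R2.fastq"))
  expect_identical(as.character(as(back$R1, "DNAStringSet")),
                   as.character(as(sim$R1, "DNAStringSet")))
})
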