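test_that("germline V identity counts mismatches over aligned columns", {
  set.seed(9)
  ref <- randDna(300)
  r <- vIdentity(ref, ref)
  expect_equal(r$identity_pct, 100)
  expect_equal(nrow(r$mutations), 0)
  # exactly 6 substitutions over 300 aligned columns -> 98.0
  pos <- c(40, 90, 140, 190, 240, 280)
  mut <- substituteBases(ref, 6, pos)
  r6 <- vIdentity(mut, ref)
  expect_equal(r6$identity_pct, 98)
  expect_equal(sort(r6$mutations$position), pos - 1L)  # 0-based
  expect_equal(nrow(r6$mutations), 6)
  # adding substitutions never increases identity
  prev <- 100
  for (k in c(3, 9, 15, 30)) {
    idn <- vIdentity(substituteBases(ref, k, seq(20, 290, by = 9)),
                     ref)$identity_pct
    expect_lte(idn, prev)
    prev <- idn
  }
  # failed alignment is flagged as an artifact candidate
  set.seed(10)
  expect_true(vIdentity(randDna(80), ref)$artifact)
})

test_that("pipeline identity tracks the simulated SHM load", {
  shm <- fxShm()
  tab <- rearrangementTable(shm$res$rearrangements)
  j <- which(tab$v_allele == shm$rearr$v_name)
  trueIdentity <- 100 * (1 - shm$rearr$n_mutations / 291)
  expect_equal(tab$identity_pct[j], trueIdentity, tolerance = 1)
  expect_equal(tab$identity_pct[j], 100 * (1 - 0.05), tolerance = 1.5)
  expect_equal(tab$n_mutations[j], shm$rearr$n_mutations)
})

test_that("mutational status thresholds put 98.0 in UM and 97.x borderline", {
  st <- callMutationalStatus(c(100, 98, 97.92, 97.59, 97.57, 96.99, 50))
  expect_equal(st$status,
               c("UM", "UM", "borderline", "borderline", "borderline",
                 "MM", "MM"))
  expect_match(st$note[3], "borderline")
  expect_equal(st$note[1], "")
  # pure function of identity, monotone in the identity value
  ids <- seq(100, 90, by = -0.25)
  lev <- c(UM = 3, borderline = 2, MM = 1)
  codes <- lev[callMutationalStatus(ids)$status]
  expect_true(all(diff(codes) <= 0))
  expect_error(callMutationalStatus(101))
})

test_that("CDR3 extraction recovers truth on productive clones", {
  zn <- fxZeroNoise()
  db <- fxDb()
  tab <- rearrangementTable(zn$res$rearrangements)
  for (i in seq_len(3)) {
    truth <- zn$sim$rearrangements[[i]]
    j <- which(tab$v_allele == truth$v_name & tab$j_allele == truth$j_name)
    expect_identical(tab$cdr3_aa[j], truth$true_cdr3_aa)
    expect_identical(tab$cdr3_nt[j], truth$true_cdr3_nt)
    expect_match(tab$cdr3_aa[j], "^C.*W$")
  }
})

test_that("CDR3 is absent for unproductive or motif-less consensuses", {
  db <- fxDb()
  rr <- simulateRearrangement(db, shmRate = 0, seed = 41)
  vSeq <- rr$v_germline
  # in-frame stop codons inside the junction: anchors exist but CDR3 has *
  bad <- paste0(vSeq, "TAATAA", rr$j_sequence)
  cd <- extractCdr3(bad, vSeq)
  expect_false(isTRUE(cd$productive))
  expect_true(is.na(cd$cdr3_aa))
  # no W-G-x-G downstream motif at all (V region only)
  cd2 <- extractCdr3(vSeq, vSeq)
  expect_true(is.na(cd2$cdr3_aa))
})

test_that("IGHD inference needs a long, near-identical aligned core", {
  db <- fxDb()
  dInfo <- alleleInfo(db, "D")
  dName <- dInfo$name[1]
  dSeq <- as.character(getAllele(db, dName))
  set.seed(12)
  junc <- paste0(randDna(5), dSeq, randDna(4))  # untruncated D core
  r <- inferD(junc, db)
  expect_equal(r$d_allele, dName)
  expect_gte(r$d_identity, 80)
  expect_gte(r$d_aligned_len, 8)
  expect_true(is.na(inferD("ACACACACAC", db)$d_allele))
  expect_true(is.na(inferD("", db)$d_allele))
  # truncated-D simulation round trip when the surviving core is long enough
  zn <- fxZeroNoise()
  tab <- rearrangementTable(zn$res$rearrangements)
  for (i in seq_len(3)) {
    truth <- zn$sim$rearrangements[[i]]
    if (nchar(truth$d_frag) >= 10) {
      j <- which(tab$v_allele == truth$v_name & tab$j_allele == truth$j_name)
      expect_equal(tab$d_allele[j], truth$d_name)
    }
  }
})

test_that("mutation tables flatten across rearrangements", {
  shm <- fxShm()
  mt <- mutationTable(shm$res$rearrangements)
  expect_equal(nrow(mt), shm$rearr$n_mutations)
  expect_true(all(mt$ref != mt$alt))
  expect_true(all(mt$position >= 0 & mt$position < 291))
})
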