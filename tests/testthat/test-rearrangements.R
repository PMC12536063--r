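test_that("pairing inference links V and J through mate pairs with a threshold", {
  mkRow <- function(id, mate, v, j) data.frame(
    read_id = id, mate = mate, orientation = "fwd", assigned = TRUE,
    v_allele = v, j_allele = j, stringsAsFactors = FALSE)
  # 4 pairs: R1 carries V, R2 carries V + J
  asg <- do.call(rbind, lapply(1:4, function(i) rbind(
    mkRow(paste0("p", i), "R1", "IGHV1-2*04", NA),
    mkRow(paste0("p", i), "R2", "IGHV1-2*04", "IGHJ6*02"))))
  pr <- inferPairings(asg, minLinkReads = 3L)
  expect_equal(nrow(pr$pairings), 1)
  expect_equal(pr$pairings$v_allele, "IGHV1-2*04")
  expect_equal(pr$pairings$j_allele, "IGHJ6*02")
  expect_equal(pr$pairings$n_link, 4)
  expect_setequal(pr$reads[[1]], paste0("p", 1:4))
  # 2 linking pairs below the default threshold: no pairing
  pr2 <- inferPairings(asg[1:4, ], minLinkReads = 3L)
  expect_equal(nrow(pr2$pairings), 0)
  # V-only pairs attach to an unambiguous pairing
  asg3 <- rbind(asg, mkRow("vonly", "R1", "IGHV1-2*04", NA))
  pr3 <- inferPairings(asg3)
  expect_true("vonly" %in% pr3$reads[[1]])
})

test_that("two clones sharing a V but differing in J give two pairings", {
  db <- fxDb()
  vs <- alleleInfo(db, "V")$name
  js <- alleleInfo(db, "J")$name
  rr1 <- rr2 <- NULL
  for (s in 1:100) {  # find two truths with same V, different J
    r <- simulateRearrangement(db, shmRate = 0, seed = 500 + s)
    if (is.null(rr1)) { rr1 <- r; next }
    if (r$v_name == rr1$v_name && r$j_name != rr1$j_name) { rr2 <- r; break }
  }
  expect_false(is.null(rr2))
  rd1 <- simulateReads(rr1, nReads = 30, errorRate = 0, seed = 1,
                       idPrefix = "a")
  rd2 <- simulateReads(rr2, nReads = 30, errorRate = 0, seed = 2,
                       idPrefix = "b")
  asg <- assignSample(append(rd1$R1, rd2$R1), append(rd1$R2, rd2$R2), db)
  pr <- inferPairings(asg$assignments)
  expect_equal(nrow(pr$pairings), 2)
  expect_setequal(pr$pairings$j_allele, c(rr1$j_name, rr2$j_name))
  expect_equal(unique(pr$pairings$v_allele), rr1$v_name)
})

test_that("zero-noise simulation round-trips V, J, consensus and abundance", {
  zn <- fxZeroNoise()
  tab <- rearrangementTable(zn$res$rearrangements)
  truth <- zn$sim$truth
  expect_equal(nrow(tab), 3)
  for (i in seq_len(3)) {
    j <- which(tab$v_allele == truth$v[i] & tab$j_allele == truth$j[i])
    expect_length(j, 1)
    expect_identical(tab$consensus[j],
                     zn$sim$rearrangements[[i]]$true_sequence)
    expect_identical(tab$junction[j], zn$sim$rearrangements[[i]]$junction)
    expect_equal(tab$clonal_pct[j], 100 * truth$abundance[i],
                 tolerance = 0.02)
  }
  expect_equal(sum(tab$clonal_pct), 100, tolerance = 1e-6)
  # read conservation: every attributed read pair counted exactly once
  expect_equal(sum(tab$read_count), 300)
})

test_that("consensus building is idempotent and majority-votes columns", {
  zn <- fxZeroNoise()
  db <- fxDb()
  asg <- assignSample(zn$sim$R1, zn$sim$R2, db)
  a <- labelFragments(asg$assignments, db)
  rs1 <- buildRearrangements(a, asg$trimmedR1, asg$trimmedR2, db,
                             sampleId = "zn")
  rs2 <- buildRearrangements(a, asg$trimmedR1, asg$trimmedR2, db,
                             sampleId = "zn")
  expect_identical(rearrangementTable(rs1)$consensus,
                   rearrangementTable(rs2)$consensus)

  # majority and tie rules on a synthetic tally
  counts <- matrix(0L, 5, 3, dimnames = list(c("A", "C", "G", "T", "-"),
                                             NULL))
  counts["A", 1] <- 60L; counts["G", 1] <- 40L   # majority A
  counts["A", 2] <- 50L; counts["G", 2] <- 50L   # tie -> reference (G)
  counts["T", 3] <- 1L                           # below min depth -> ref
  cons <- IGHclonal:::.majorityConsensus(counts, "GGA", minDepth = 2L)
  expect_equal(cons$seq, "AGA")
  expect_equal(cons$depth, c(100L, 100L, 1L))
})

test_that("consensus corrects sequencing errors at modest depth", {
  db <- fxDb()
  amp <- defaultAmplicons(leader = TRUE)
  rr <- simulateRearrangement(db, shmRate = 0, seed = 61)
  rd <- simulateReads(rr, amplicons = amp, nReads = 200, errorRate = 0.01,
                      seed = 62, idPrefix = "e")
  asg <- assignSample(rd$R1, rd$R2, db)
  a <- labelFragments(asg$assignments, db, amp)
  rs <- buildRearrangements(a, asg$trimmedR1, asg$trimmedR2, db)
  tab <- rearrangementTable(rs)
  j <- which(tab$v_allele == rr$v_name & tab$j_allele == rr$j_name)
  # per-base consensus error < 1e-4 at depth >= 100 means zero errors here
  expect_identical(tab$consensus[j], rr$true_sequence)
})

test_that("coverage breadth and clonal percentages follow their formulas", {
  expect_equal(coverageBreadth(c(600, 600, 400, 600), depthFloor = 500), 75)
  expect_equal(coverageBreadth(rep(501, 40), depthFloor = 500), 100)
  expect_error(coverageBreadth(numeric(0)), "empty")
  zn <- fxZeroNoise()
  br <- coverageBreadth(zn$res$rearrangements, depthFloor = 100)
  expect_true(all(br >= 0 & br <= 100))

  rset <- makeRset(list(
    list(v_allele = "IGHV1-2*04", j_allele = "IGHJ6*02", consensus = "ACGT",
         frag_FR1 = 900L),
    list(v_allele = "IGHV3-7*04", j_allele = "IGHJ6*02", consensus = "TTTT",
         frag_FR1 = 100L)))
  expect_equal(rearrangementTable(rset)$clonal_pct, c(90, 10))
  one <- makeRset(list(list(v_allele = "IGHV1-2*04", j_allele = "IGHJ6*02",
                            consensus = "ACGT", frag_FR1 = 7L)))
  expect_equal(rearrangementTable(one)$clonal_pct, 100)
})
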