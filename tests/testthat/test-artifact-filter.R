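test_that("rearrangements sharing >= 95% consensus identity are merged", {
  set.seed(21)
  base <- randDna(350)
  shadow97 <- substituteBases(base, 10)  # ~97.1% identity
  shadow90 <- substituteBases(base, 35)  # ~90% identity
  rset <- makeRset(list(
    list(v_allele = "IGHV1-69*09", j_allele = "IGHJ6*02", consensus = base,
         frag_FR1 = 500L, frag_FR2 = 400L, cdr3_aa = "CARW"),
    list(v_allele = "IGHV1-69*01", j_allele = "IGHJ6*02",
         consensus = shadow97, frag_FR1 = 60L, frag_FR2 = 40L,
         cdr3_aa = "CARW")))
  m <- mergeByIdentity(rset)
  tab <- rearrangementTable(m$rearrangements)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$v_allele, "IGHV1-69*09")  # higher-read member absorbs
  expect_equal(tab$read_count, 1000L)        # counts summed
  expect_equal(m$events$rule, "allele_identity95")
  expect_gte(m$events$identity, 95)

  # below the threshold nothing merges
  rset2 <- makeRset(list(
    list(v_allele = "IGHV1-69*09", j_allele = "IGHJ6*02", consensus = base,
         frag_FR1 = 900L),
    list(v_allele = "IGHV1-69*01", j_allele = "IGHJ6*02",
         consensus = shadow90, frag_FR1 = 100L)))
  m2 <- mergeByIdentity(rset2)
  expect_equal(nrow(rearrangementTable(m2$rearrangements)), 2)
  expect_equal(nrow(m2$events), 0)
})

test_that("second merge pass joins near-identical consensuses across genes", {
  set.seed(22)
  base <- randDna(350)
  rset <- makeRset(list(
    list(v_allele = "IGHV1-2*04", j_allele = "IGHJ6*02", consensus = base,
         frag_FR1 = 800L),
    list(v_allele = "IGHV3-7*04", j_allele = "IGHJ6*02",
         consensus = substituteBases(base, 8), frag_FR1 = 90L)))
  m <- mergeByIdentity(rset)
  expect_equal(nrow(rearrangementTable(m$rearrangements)), 1)
  expect_equal(m$events$rule, "gene_identity95")
})

test_that("identity merging is order-independent and idempotent", {
  set.seed(23)
  base <- randDna(350)
  rows <- list(
    list(v_allele = "IGHV1-69*09", j_allele = "IGHJ6*02", consensus = base,
         frag_FR1 = 500L),
    list(v_allele = "IGHV1-69*01", j_allele = "IGHJ6*02",
         consensus = substituteBases(base, 9), frag_FR1 = 70L),
    list(v_allele = "IGHV4-34*01", j_allele = "IGHJ6*02",
         consensus = randDna(350), frag_FR1 = 200L))
  m1 <- mergeByIdentity(makeRset(rows))
  m2 <- mergeByIdentity(makeRset(rev(rows)))
  t1 <- rearrangementTable(m1$rearrangements)
  t2 <- rearrangementTable(m2$rearrangements)
  expect_setequal(t1$id, t2$id)
  expect_equal(t1$read_count[order(t1$id)], t2$read_count[order(t2$id)])
  # rerunning the filter changes nothing
  m3 <- mergeByIdentity(m1$rearrangements)
  expect_equal(nrow(m3$events), 0)
  expect_identical(rearrangementTable(m3$rearrangements)$read_count,
                   t1$read_count)
})

test_that("low-support rearrangements fold into their same-family major", {
  set.seed(24)
  major <- randDna(350)
  rset <- makeRset(list(
    list(v_allele = "IGHV1-2*04", j_allele = "IGHJ6*02", consensus = major,
         frag_leader = 0L, frag_FR1 = 400L, frag_FR2 = 300L,
         frag_FR3 = 300L, cdr3_aa = "CARDW"),
    # FR3 share 0.95 with a same-family, same-CDR3 major -> absorbed
    list(v_allele = "IGHV1-69*09", j_allele = "IGHJ6*02",
         consensus = randDna(350), frag_FR1 = 5L, frag_FR3 = 95L,
         cdr3_aa = "CARDW"),
    # FR3 share 0.80 with three-fragment support -> untouched
    list(v_allele = "IGHV3-7*04", j_allele = "IGHJ6*02",
         consensus = randDna(350), frag_FR1 = 10L, frag_FR2 = 10L,
         frag_FR3 = 80L, cdr3_aa = "CTTW")))
  m <- mergeLowSupport(rset)
  tab <- rearrangementTable(m$rearrangements)
  expect_equal(nrow(tab), 2)
  expect_equal(m$events$rule, "fr3_dominant")
  expect_equal(tab$read_count[tab$v_allele == "IGHV1-2*04"], 1100L)
  expect_false(any(tab$low_support))

  # single-fragment rearrangement with no matching major: flagged, kept
  rset2 <- makeRset(list(
    list(v_allele = "IGHV1-2*04", j_allele = "IGHJ6*02",
         consensus = randDna(350), frag_FR1 = 400L, frag_FR2 = 300L,
         cdr3_aa = "CARDW"),
    list(v_allele = "IGHV3-7*04", j_allele = "IGHJ6*02",
         consensus = randDna(350), frag_FR3 = 50L, cdr3_aa = "CQQW")))
  m2 <- mergeLowSupport(rset2)
  tab2 <- rearrangementTable(m2$rearrangements)
  expect_equal(nrow(tab2), 2)
  expect_equal(nrow(m2$events), 0)
  expect_true(tab2$low_support[tab2$v_allele == "IGHV3-7*04"])
})

test_that("an injected 96%-identity shadow clone collapses onto the truth", {
  zn <- fxZeroNoise()
  db <- fxDb()
  rset <- zn$res$rearrangements
  tab <- rset@table
  top <- which.max(tab$read_count)
  set.seed(25)
  shadowCons <- substituteBases(tab$consensus[top],
                                round(0.04 * nchar(tab$consensus[top])))
  shadow <- tab[top, ]
  vs <- alleleInfo(db, "V")$name
  shadow$v_allele <- setdiff(vs, tab$v_allele)[1]
  shadow$id <- paste0(shadow$v_allele, "_", shadow$j_allele)
  shadow$consensus <- shadowCons
  for (cl in c("read_count", "frag_leader", "frag_FR1", "frag_FR2",
               "frag_FR3", "frag_unknown"))
    shadow[[cl]] <- as.integer(ceiling(shadow[[cl]] / 10))
  shadow$read_count <- shadow$frag_leader + shadow$frag_FR1 +
    shadow$frag_FR2 + shadow$frag_FR3 + shadow$frag_unknown
  rset@table <- rbind(tab, shadow)
  rset@depth <- c(rset@depth, rset@depth[top])
  rset <- clonalPercentages(rset)
  before <- sum(rset@table$read_count)
  f <- filterArtifacts(rset)
  after <- rearrangementTable(f$rearrangements)
  expect_equal(nrow(after), nrow(tab))  # exactly one survivor of the pair
  expect_true(tab$id[top] %in% after$id)
  expect_false(shadow$id %in% after$id)
  # read conservation through the whole filter stage
  expect_equal(sum(after$read_count), before)
  expect_equal(sum(after$clonal_pct), 100, tolerance = 1e-6)
})

test_that("gene-level summary nests alleles and recomputes percentages", {
  set.seed(26)
  rset <- makeRset(list(
    list(v_allele = "IGHV1-69*09", j_allele = "IGHJ6*02",
         consensus = randDna(300), frag_FR1 = 700L, cdr3_aa = "CARW"),
    list(v_allele = "IGHV1-69*01", j_allele = "IGHJ6*02",
         consensus = randDna(300), frag_FR1 = 200L, cdr3_aa = "CARW"),
    list(v_allele = "IGHV3-7*04", j_allele = "IGHJ4*02",
         consensus = randDna(300), frag_FR1 = 100L, cdr3_aa = "CSSW")))
  g <- summarizeGeneLevel(rset)
  expect_equal(nrow(g), 2)
  r69 <- g[g$v_gene == "IGHV1-69", ]
  expect_equal(r69$read_count, 900L)
  expect_match(r69$alleles, "IGHV1-69\\*09")
  expect_match(r69$alleles, "IGHV1-69\\*01")
  expect_equal(sum(g$clonal_pct), 100, tolerance = 1e-6)
  empty <- rset
  empty@table <- rset@table[0, ]
  empty@depth <- list()
  expect_equal(nrow(summarizeGeneLevel(empty)), 0)
})

test_that("sample QC applies strict read floors per track", {
  expect_true(sampleQc("clonal", majorReads = 1001)$pass)
  qc <- sampleQc("clonal", majorReads = 1000)
  expect_false(qc$pass)
  expect_match(qc$reason, "1000")
  expect_false(sampleQc("polyclonal", trimmedReads = 999)$pass)
  expect_true(sampleQc("polyclonal", trimmedReads = 1000)$pass)
  expect_error(sampleQc("clonal"), "majorReads")
})
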