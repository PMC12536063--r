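# shared fixtures, computed once per test run; the database is small
# (4 V / 2 J / 4 D) so local alignment stays cheap on one CPU
.fx <- new.env(parent = emptyenv())

fxDb <- function() {
  if (is.null(.fx$db)) .fx$db <- syntheticGermlineDb(nV = 4, nJ = 2, nD = 4,
                                                     seed = 42)
  .fx$db
}

# zero-noise three-clone sample (50/30/20 %) run through the pipeline
fxZeroNoise <- function() {
  if (is.null(.fx$zn)) {
    db <- fxDb()
    sim <- simulateSample(db, abundances = c(0.5, 0.3, 0.2),
                          totalReads = 300, shmRate = 0, errorRate = 0,
                          seed = 11, sampleId = "zn")
    res <- runSample(sim$R1, sim$R2, db, sampleId = "zn")
    .fx$zn <- list(sim = sim, res = res)
  }
  .fx$zn
}

# one clone at 5% SHM with 1% sequencing error, leader-inclusive amplicons
# so the whole V region is covered
fxShm <- function() {
  if (is.null(.fx$shm)) {
    db <- fxDb()
    amp <- defaultAmplicons(leader = TRUE)
    rr <- simulateRearrangement(db, shmRate = 0.05, seed = 21)
    rd <- simulateReads(rr, amplicons = amp, nReads = 300, errorRate = 0.01,
                        seed = 22, idPrefix = "shm:c1")
    res <- runSample(rd$R1, rd$R2, db, sampleId = "shm", amplicons = amp)
    .fx$shm <- list(rearr = rr, res = res)
  }
  .fx$shm
}

# constant-quality paired reads with given Phred values per position
makeQualReads <- function(seqs, quals) {
  q <- vapply(quals, function(v)
    paste(rawToChar(as.raw(as.integer(v) + 33L)), collapse = ""), "")
  Biostrings::QualityScaledDNAStringSet(
    setNames(Biostrings::DNAStringSet(seqs),
             paste0("r", seq_along(seqs))),
    Biostrings::PhredQuality(q))
}

# hand-built rearrangement set for filter tests
makeRset <- function(rows, sampleId = "t") {
  defaults <- list(junction = "", frag_leader = 0L, frag_FR1 = 0L,
                   frag_FR2 = 0L, frag_FR3 = 0L, frag_unknown = 0L,
                   clonal_pct = NA_real_, cdr3_aa = NA_character_)
  rows <- lapply(rows, function(r) {
    miss <- setdiff(names(defaults), names(r))
    r[miss] <- defaults[miss]
    if (is.null(r$read_count))
      r$read_count <- r$frag_leader + r$frag_FR1 + r$frag_FR2 +
        r$frag_FR3 + r$frag_unknown
    r$id <- paste0(r$v_allele, "_", r$j_allele)
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[, c("id", "v_allele", "j_allele", "consensus", "junction",
                 "read_count", "frag_leader", "frag_FR1", "frag_FR2",
                 "frag_FR3", "frag_unknown", "clonal_pct", "cdr3_aa")]
  rset <- new("RearrangementSet", sampleId = sampleId,
              table = S4Vectors::DataFrame(tab),
              depth = rep(list(integer(0)), nrow(tab)))
  clonalPercentages(rset)
}

# random DNA of length n under the current RNG state
randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# substitute exactly k bases of a sequence at given (or random) positions
substituteBases <- function(seq, k, positions = NULL) {
  ch <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(seq_along(ch), k)
  for (p in positions[seq_len(k)])
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# exact two-sided permutation p-value for the Mann-Whitney U statistic
exactMannWhitneyP <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  uStat <- function(a, b) {
    sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b), 0))
  }
  obs <- uStat(x, y)
  us <- apply(idx, 2, function(ix) uStat(pooled[ix], pooled[-ix]))
  mu <- nx * (length(pooled) - nx) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
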