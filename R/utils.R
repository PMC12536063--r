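#' @importFrom Biostrings DNAString DNAStringSet pairwiseAlignment
#'   reverseComplement subject pattern alignedPattern alignedSubject
#'   nucleotideSubstitutionMatrix width subseq PhredQuality
#'   QualityScaledDNAStringSet quality pid nindel score GENETIC_CODE
#' @importFrom withr with_seed
NULL

# alignment scoring used throughout: match +1 / mismatch -2 / gap open -4 /
# gap extend -1 (penalties passed positive to pairwiseAlignment). The
# base-only matrix keeps nmatch()/pid() exact, so inputs are sanitized to
# A/C/G/T first (ambiguity codes are rare and carry no signal here).
.subMat <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = TRUE)
    m
  }
})

# replace IUPAC ambiguity codes (incl. N) by A so base-only scoring applies
.sanitizeSeqs <- function(x) {
  ch <- as.character(x)
  bad <- grepl("[^ACGT]", ch)
  if (any(bad)) {
    ch[bad] <- gsub("[^ACGT]", "A", ch[bad])
    x <- Biostrings::DNAStringSet(setNames(ch, names(x)))
  }
  as(x, "DNAStringSet")
}

.alignLocal <- function(patterns, subject) {
  Biostrings::pairwiseAlignment(patterns, subject, type = "local",
                                substitutionMatrix = .subMat(),
                                gapOpening = 4, gapExtension = 1)
}

# matches / aligned columns (gaps included in the denominator)
.alnIdentity <- function(aln) {
  Biostrings::pid(aln, type = "PID1")
}

# per-alignment walk: for every subject (reference) position covered, the
# pattern base (NA at deletions); insertions are dropped
.alnRefBases <- function(ps, ss, sstart) {
  a <- strsplit(ps, "")[[1]]
  b <- strsplit(ss, "")[[1]]
  keep <- b != "-"
  pos <- sstart + cumsum(keep) - 1L
  data.frame(pos = pos[keep],
             base = ifelse(a[keep] == "-", NA_character_, a[keep]),
             stringsAsFactors = FALSE)
}

# restore-on-exit seeded evaluation; all package randomness funnels through
# this so a single integer seed reproduces any simulation
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

.randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases i.i.d. at `rate`; a drawn position always changes base
.mutateSeq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(alt, b), 1L), "")
  }
  paste(ch, collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# plain codon-table translation (standard genetic code, X for ambiguous)
.translate <- function(nt) {
  n <- nchar(nt) %/% 3
  if (n == 0) return("")
  starts <- 3 * (seq_len(n) - 1) + 1
  aa <- Biostrings::GENETIC_CODE[substring(nt, starts, starts + 2)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
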