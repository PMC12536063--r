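#' Quality-trim reads from both ends
#'
#' Strips bases from each end of every read while the terminal base quality
#' is below \code{qFloor} (Phred), then drops reads shorter than
#' \code{minLen}. Trimming is idempotent: once both terminal bases meet the
#' floor, nothing more is removed.
#'
#' @param reads a \code{QualityScaledDNAStringSet}.
#' @param qFloor Phred floor for terminal bases (default 30).
#' @param minLen minimum retained length (default 50); shorter reads are
#'   dropped.
#' @return list with \code{reads} (trimmed \code{QualityScaledDNAStringSet})
#'   and \code{dropped} (character vector of dropped read names).
#' @examples
#' db <- syntheticGermlineDb(seed = 1)
#' rr <- simulateRearrangement(db, seed = 1)
#' rd <- simulateReads(rr, nReads = 5, seed = 1, lowQualTail = 10)
#' qualityTrim(rd$R1)$reads
#' @export
qualityTrim <- function(reads, qFloor = 30L, minLen = 50L) {
  if (length(reads) == 0L)
    return(list(reads = reads, dropped = character(0)))
  if (!all(Biostrings::width(reads) ==
           Biostrings::width(Biostrings::quality(reads))))
    stop("malformed record: sequence and quality lengths differ at index ",
         which(Biostrings::width(reads) !=
               Biostrings::width(Biostrings::quality(reads)))[1])
  qint <- as(Biostrings::quality(reads), "IntegerList")
  n <- length(reads)
  starts <- integer(n); ends <- integer(n)
  for (i in seq_len(n)) {
    q <- qint[[i]]
    s <- 1L
    while (s <= length(q) && q[s] < qFloor) s <- s + 1L
    e <- length(q)
    while (e >= s && q[e] < qFloor) e <- e - 1L
    starts[i] <- s; ends[i] <- e
  }
  len <- pmax(ends - starts + 1L, 0L)
  keep <- len >= minLen
  dropped <- names(reads)[!keep]
  if (!any(keep)) {
    empty <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0)))
    return(list(reads = empty, dropped = dropped))
  }
  sq <- Biostrings::subseq(as(reads, "DNAStringSet")[keep],
                           start = starts[keep], end = ends[keep])
  qq <- Biostrings::PhredQuality(Biostrings::subseq(
    as(Biostrings::quality(reads), "BStringSet")[keep],
    start = starts[keep], end = ends[keep]))
  out <- Biostrings::QualityScaledDNAStringSet(sq, qq)
  names(out) <- names(reads)[keep]
  list(reads = out, dropped = dropped)
}
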