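#' Germline V identity of a consensus sequence
#'
#' Locally aligns a rearrangement consensus against its assigned germline V
#' allele and reports identity as 100 x matches / aligned columns. Because
#' the germline V is the alignment subject, the junction and J portions of
#' the consensus cannot enter the alignment, so identity reflects the V
#' region only -- the somatic hypermutation load. Mismatches are returned
#' with 0-based V-allele coordinates.
#'
#' @param consensus character(1) consensus nucleotide sequence.
#' @param vSeq germline V allele sequence (\code{DNAString} or character).
#' @return list with \code{identity_pct}, \code{mutations} (data.frame:
#'   \code{position} 0-based on the V allele, \code{ref}, \code{alt}), and
#'   \code{artifact} (\code{TRUE} when the alignment fails: identity below
#'   60 percent, or fewer than 100 aligned V columns -- a local alignment of
#'   unrelated sequence always finds some short high-identity stretch, so
#'   the span requirement is part of the failure criterion).
#' @examples
#' vIdentity("ACGTACGTAC", "ACGTACGTAC")
#' @export
vIdentity <- function(consensus, vSeq) {
  aln <- .alignLocal(Biostrings::DNAStringSet(as.character(consensus)),
                     Biostrings::DNAString(as.character(vSeq)))
  ps <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ss <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  id <- 100 * sum(ps == ss) / length(ps)
  refPos <- Biostrings::start(Biostrings::subject(aln)) - 1L +
    cumsum(ss != "-") - 1L
  mm <- which(ps != ss & ps != "-" & ss != "-")
  mutations <- data.frame(position = refPos[mm], ref = ss[mm], alt = ps[mm],
                          stringsAsFactors = FALSE)
  list(identity_pct = id, mutations = mutations,
       artifact = id < 60 || length(ps) < 100)
}

#' Call mutational status from germline identity
#'
#' Unmutated (\code{"UM"}) at or above \code{umThreshold} (98 percent
#' identity, the boundary itself counting as UM), \code{"borderline"} in
#' [\code{borderlineFloor}, \code{umThreshold}), and mutated (\code{"MM"})
#' below. A free-text note accompanies borderline calls since reporting
#' conventions differ.
#'
#' @param identityPct numeric vector of identities in [0, 100].
#' @param umThreshold UM boundary (default 98).
#' @param borderlineFloor lower edge of the borderline band (default 97).
#' @return data.frame with \code{status} and \code{note}.
#' @examples
#' callMutationalStatus(c(100, 98, 97.92, 96.5))$status
#' @export
callMutationalStatus <- function(identityPct, umThreshold = 98,
                                 borderlineFloor = 97) {
  stopifnot(all(identityPct >= 0 & identityPct <= 100))
  status <- ifelse(identityPct >= umThreshold, "UM",
                   ifelse(identityPct >= borderlineFloor, "borderline",
                          "MM"))
  note <- ifelse(status == "borderline",
                 sprintf("MM with note: identity %.2f%% in borderline band [%g, %g)",
                         identityPct, borderlineFloor, umThreshold), "")
  data.frame(status = status, note = note, stringsAsFactors = FALSE)
}

#' Extract the CDR3 from a consensus sequence
#'
#' Translates the consensus in the three forward frames and accepts a frame
#' containing (a) a cysteine homologous to V position 104 -- located via the
#' germline V alignment, falling back to the last Cys encoded within the
#' final 36 nt of the aligned V region -- and (b) downstream, a tryptophan
#' whose following residues match W-G-x-G (the J-region motif; that W is
#' Trp118). The CDR3 spans Cys104 to Trp118 inclusive. A frame whose anchors
#' exist but whose CDR3 contains a stop codon is reported unproductive; if
#' no frame carries both anchors the CDR3 is absent.
#'
#' @param consensus character(1) consensus sequence (must span the junction).
#' @param vSeq germline V allele sequence of the assigned V.
#' @return list with \code{cdr3_aa}, \code{cdr3_nt} (NA when absent),
#'   \code{productive} (\code{NA} when no anchors), \code{frame} (0-2 or NA).
#' @export
extractCdr3 <- function(consensus, vSeq) {
  consensus <- as.character(consensus); vSeq <- as.character(vSeq)
  aln <- .alignLocal(Biostrings::DNAStringSet(consensus),
                     Biostrings::DNAString(vSeq))
  # consensus coordinate of the germline V 3' end (extrapolated when the
  # local alignment stops short)
  cVend <- Biostrings::end(Biostrings::pattern(aln)) +
    (nchar(vSeq) - Biostrings::end(Biostrings::subject(aln)))
  absent <- list(cdr3_aa = NA_character_, cdr3_nt = NA_character_,
                 productive = NA, frame = NA_integer_)
  best <- NULL
  for (f in 0:2) {
    nt <- substr(consensus, 1 + f, nchar(consensus))
    aa <- .translate(nt)
    if (!nzchar(aa)) next
    aaStart <- function(i) f + 3 * (i - 1) + 1  # nt start of codon i
    cysIdx <- which(strsplit(aa, "")[[1]] == "C")
    cysIdx <- cysIdx[aaStart(cysIdx) >= cVend - 35 & aaStart(cysIdx) <= cVend]
    if (!length(cysIdx)) next
    cys <- cysIdx[length(cysIdx)]
    rest <- substr(aa, cys, nchar(aa))
    w <- regexpr("WG.G", rest)
    if (w < 0) next
    cdr3 <- substr(rest, 1, w)
    prod <- !grepl("*", cdr3, fixed = TRUE)
    hit <- list(cdr3_aa = if (prod) cdr3 else NA_character_,
                cdr3_nt = if (prod)
                  substr(consensus, aaStart(cys),
                         aaStart(cys) + 3 * nchar(cdr3) - 1)
                else NA_character_,
                productive = prod, frame = f)
    if (prod) return(hit)
    if (is.null(best)) best <- hit  # remember an unproductive frame
  }
  if (!is.null(best)) return(best)
  absent
}

#' Infer the IGHD allele from the junction insert
#'
#' The junction insert (consensus bases spanning the V-J reference gap) is
#' locally aligned against all germline D alleles; the best hit is reported
#' when the aligned stretch is at least \code{minMatch} nt with identity at
#' least \code{minIdentity} percent (N-nucleotides are expected to flank the
#' D core). Absent otherwise.
#'
#' @param junction character(1) junction insert (may be empty).
#' @param db a [GermlineDb-class].
#' @param minMatch minimum aligned length in nt (default 8).
#' @param minIdentity minimum identity percent (default 80).
#' @return list with \code{d_allele} (NA when absent), \code{d_identity},
#'   \code{d_aligned_len}.
#' @export
inferD <- function(junction, db, minMatch = 8L, minIdentity = 80) {
  absent <- list(d_allele = NA_character_, d_identity = NA_real_,
                 d_aligned_len = NA_integer_)
  junction <- as.character(junction)
  if (is.na(junction) || nchar(junction) == 0L) return(absent)
  dInfo <- alleleInfo(db, "D")
  if (nrow(dInfo) == 0L) return(absent)
  best <- absent; bestScore <- -Inf
  for (a in sort(dInfo$name)) {
    aln <- .alignLocal(Biostrings::DNAStringSet(junction), getAllele(db, a))
    sc <- Biostrings::score(aln)
    if (sc > bestScore) {
      len <- Biostrings::end(Biostrings::pattern(aln)) -
        Biostrings::start(Biostrings::pattern(aln)) + 1L
      idn <- .alnIdentity(aln)
      if (len >= minMatch && idn >= minIdentity) {
        best <- list(d_allele = a, d_identity = idn, d_aligned_len = len)
        bestScore <- sc
      }
    }
  }
  best
}

#' Annotate a rearrangement set
#'
#' Adds germline V identity and the mutation list, mutational status, CDR3
#' (amino acid and nucleotide) and the inferred IGHD allele to every
#' rearrangement of a sample.
#'
#' @param rset a [RearrangementSet-class].
#' @param db a [GermlineDb-class].
#' @param umThreshold,borderlineFloor mutational status thresholds.
#' @param minDMatch,minDIdentity IGHD inference thresholds.
#' @return the [RearrangementSet-class] with columns \code{identity_pct},
#'   \code{status}, \code{status_note}, \code{cdr3_aa}, \code{cdr3_nt},
#'   \code{productive}, \code{d_allele}, \code{n_mutations},
#'   \code{artifact_candidate} added, and a \code{mutations} list-column of
#'   per-rearrangement mutation tables.
#' @export
annotateRearrangements <- function(rset, db, umThreshold = 98,
                                   borderlineFloor = 97, minDMatch = 8L,
                                   minDIdentity = 80) {
  tab <- rset@table
  n <- nrow(tab)
  idp <- numeric(n); nm <- integer(n); art <- logical(n)
  c3a <- character(n); c3n <- character(n); prod <- logical(n)
  dal <- character(n); muts <- vector("list", n)
  for (i in seq_len(n)) {
    vSeq <- getAllele(db, tab$v_allele[i])
    vid <- vIdentity(tab$consensus[i], vSeq)
    idp[i] <- vid$identity_pct
    nm[i] <- nrow(vid$mutations)
    art[i] <- vid$artifact
    muts[[i]] <- vid$mutations
    cd <- extractCdr3(tab$consensus[i], vSeq)
    c3a[i] <- cd$cdr3_aa; c3n[i] <- cd$cdr3_nt
    prod[i] <- isTRUE(cd$productive)
    dal[i] <- inferD(tab$junction[i], db, minDMatch, minDIdentity)$d_allele
  }
  st <- callMutationalStatus(idp, umThreshold, borderlineFloor)
  tab$identity_pct <- idp
  tab$status <- if (n) st$status else character(0)
  tab$status_note <- if (n) st$note else character(0)
  tab$cdr3_aa <- c3a; tab$cdr3_nt <- c3n; tab$productive <- prod
  tab$d_allele <- dal; tab$n_mutations <- nm
  tab$artifact_candidate <- art
  tab$mutations <- muts
  rset@table <- tab
  validObject(rset)
  rset
}

#' Per-rearrangement mutation table
#'
#' Flattens the mutation lists of an annotated set into one data.frame
#' (rearrangement id, 0-based V position, ref, alt).
#'
#' @param rset an annotated [RearrangementSet-class].
#' @return data.frame with \code{id}, \code{position}, \code{ref}, \code{alt}.
#' @export
mutationTable <- function(rset) {
  tab <- rset@table
  if (!"mutations" %in% colnames(tab))
    stop("rearrangements are not annotated; run annotateRearrangements()")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    m <- tab$mutations[[i]]
    if (!NROW(m)) return(NULL)
    cbind(id = tab$id[i], m)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(id = character(0), position = integer(0),
                      ref = character(0), alt = character(0))
  out
}
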