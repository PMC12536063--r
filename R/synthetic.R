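#' @include utils.R germlineDb.R
NULL

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# random stop-free codons, optionally excluding further codons (e.g. Cys/Trp)
.randCodons <- function(n, exclude = character()) {
  bad <- c(.STOP_CODONS, exclude)
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cd <- .randSeq(3)
      if (!cd %in% bad) break
    }
    out[i] <- cd
  }
  paste(out, collapse = "")
}

#' Deterministic synthetic germline IGH allele set
#'
#' Builds a small, fully synthetic germline database with the structural
#' hallmarks the pipeline relies on, under IMGT-style names. V alleles are 291
#' nt (97 codons) of stop-free sequence whose penultimate codon is the
#' conserved Cys104 (\code{TGT}) followed by \code{GCG}; no other cysteine is
#' encoded in the last 12 codons, so motif-based CDR3 anchoring is
#' unambiguous. J alleles carry a variable-length 5' region followed by the
#' canonical Trp118 motif \code{TGG GGC xxx GGA} (W-G-x-G) and a fixed
#' 3' tail. D alleles are short random segments. Sequences are synthetic:
#' only the naming follows real IGH nomenclature.
#'
#' @param nV,nJ,nD how many V/J/D alleles (at most 8/4/6 distinct names).
#' @param seed integer seed; the same seed always yields the same database.
#' @return a [GermlineDb-class].
#' @examples
#' db <- syntheticGermlineDb(seed = 1)
#' alleleInfo(db, "V")$name
#' @export
syntheticGermlineDb <- function(nV = 8, nJ = 4, nD = 6, seed = 42) {
  vNames <- c("IGHV1-2*04", "IGHV1-69*09", "IGHV1-69D*01", "IGHV3-7*04",
              "IGHV3-11*06", "IGHV4-34*01", "IGHV5-10-1*03", "IGHV6-1*01")
  jNames <- c("IGHJ4*02", "IGHJ6*02", "IGHJ5*02", "IGHJ1*01")
  dNames <- c("IGHD3-10*01", "IGHD2-2*01", "IGHD6-19*01", "IGHD1-26*01",
              "IGHD3-22*01", "IGHD5-12*01")
  stopifnot(nV <= length(vNames), nJ <= length(jNames), nD <= length(dNames))
  .withSeed(seed, {
    vSeqs <- vapply(seq_len(nV), function(i) {
      body <- .randCodons(83)                       # codons 1-83
      tail12 <- .randCodons(12, exclude = c("TGT", "TGC"))  # codons 84-95
      paste0(body, tail12, "TGT", "GCG")            # Cys104 + Ala, 97 codons
    }, "")
    jPref <- c(15L, 18L, 21L, 24L)
    jSeqs <- vapply(seq_len(nJ), function(i) {
      pref <- .randCodons(jPref[i] / 3L, exclude = c("TGG", "TGT", "TGC"))
      paste0(pref, "TGGGGC", .randCodons(1, exclude = "TGG"), "GGA",
             "ACCCTGGTCACCGTCTCCTCA")
    }, "")
    dSeqs <- vapply(seq_len(nD), function(i) .randSeq(sample(16:31, 1)), "")
    seqs <- Biostrings::DNAStringSet(c(vSeqs, jSeqs, dSeqs))
    names(seqs) <- c(vNames[seq_len(nV)], jNames[seq_len(nJ)],
                     dNames[seq_len(nD)])
    parsed <- lapply(names(seqs), parseAlleleName)
    db <- .makeGermlineDb(seqs, parsed)
    validObject(db)
    db
  })
}

#' Amplicon anchor definitions
#'
#' The simulator (and fragment labelling) anchor each amplicon's forward
#' primer at a fraction of the V-allele length: leader at 0, FR1/FR2/FR3 at
#' 0.25/0.5/0.75, so the three FR amplicons tile the V region with overlap
#' and every amplicon shares the reverse anchor at the 3' end of J.
#'
#' @param leader include the leader amplicon (cDNA-style protocol).
#' @return data.frame with columns \code{label}, \code{frac}.
#' @export
defaultAmplicons <- function(leader = FALSE) {
  amp <- data.frame(label = c("leader", "FR1", "FR2", "FR3"),
                    frac = c(0, 0.25, 0.5, 0.75),
                    stringsAsFactors = FALSE)
  if (!leader) amp <- amp[amp$label != "leader", , drop = FALSE]
  rownames(amp) <- NULL
  amp
}

.ampliconOffsets <- function(amplicons, vLen) {
  setNames(as.integer(round(amplicons$frac * vLen)), amplicons$label)
}

# truth CDR3 of a full rearranged sequence, using the germline-frame Cys and
# the first downstream W-G-x-G; NA when anchors are missing or a stop
# intervenes
.truthCdr3 <- function(fullSeq, cysNtStart) {
  sub <- substr(fullSeq, cysNtStart, nchar(fullSeq))
  aa <- .translate(sub)
  if (!nzchar(aa) || substr(aa, 1, 1) != "C") return(list(aa = NA, nt = NA))
  w <- regexpr("WG.G", aa)
  if (w < 0) return(list(aa = NA, nt = NA))
  cdr3 <- substr(aa, 1, w)
  if (grepl("*", cdr3, fixed = TRUE)) return(list(aa = NA, nt = NA))
  list(aa = cdr3, nt = substr(fullSeq, cysNtStart,
                              cysNtStart + 3 * nchar(cdr3) - 1))
}

# frame-0 start (1-based) of the last Cys codon in the final 36 nt of a V
.cysPosition <- function(vSeq) {
  n <- nchar(vSeq) %/% 3
  starts <- 3 * (seq_len(n) - 1) + 1
  codons <- substring(vSeq, starts, starts + 2)
  hit <- starts[codons %in% c("TGT", "TGC") & starts >= nchar(vSeq) - 35]
  if (!length(hit)) return(NA_integer_)
  hit[length(hit)]
}

#' Simulate one ground-truth VDJ rearrangement
#'
#' Draws V, D and J alleles uniformly, truncates the D segment at both ends
#' by 0-5 nt, inserts random N-nucleotide stretches of 0-10 nt on either side
#' of it, and applies somatic hypermutation as independent per-base
#' substitutions in the V portion. The rearranged sequence is
#' \code{mutated(V) + n1 + D' + n2 + J}. With \code{productive = TRUE}
#' (default) the junction is resampled until the sequence encodes an intact
#' Cys104...Trp118 CDR3 in frame with no stop codon and no spurious upstream
#' W-G-x-G, emulating the productive rearrangements selected by allelic
#' exclusion.
#'
#' @param db a [GermlineDb-class] with at least one allele per segment.
#' @param shmRate per-base substitution probability in the V region.
#' @param seed optional integer seed.
#' @param productive resample the junction until the CDR3 is productive.
#' @return list of class \code{"SimulatedRearrangement"}: allele names,
#'   junction parts (\code{n1}, \code{d_frag}, \code{n2}), mutated and
#'   germline V, \code{true_sequence}, \code{true_cdr3_aa}/\code{_nt},
#'   \code{n_mutations}, \code{shm_rate}.
#' @export
simulateRearrangement <- function(db, shmRate = 0, seed = NULL,
                                  productive = TRUE) {
  info <- db@info
  for (sg in c("V", "D", "J"))
    if (!any(info$segment == sg))
      stop("germline database has no ", sg, " alleles")
  .withSeed(seed, {
    vName <- sample(info$name[info$segment == "V"], 1)
    dName <- sample(info$name[info$segment == "D"], 1)
    jName <- sample(info$name[info$segment == "J"], 1)
    vSeq <- as.character(getAllele(db, vName))
    dSeq <- as.character(getAllele(db, dName))
    jSeq <- as.character(getAllele(db, jName))
    vMut <- .mutateSeq(vSeq, shmRate)
    nMut <- sum(strsplit(vMut, "")[[1]] != strsplit(vSeq, "")[[1]])
    cys <- .cysPosition(vSeq)
    for (attempt in seq_len(500)) {
      tl <- sample(0:5, 1); tr <- sample(0:5, 1)
      dFrag <- if (tl + tr >= nchar(dSeq)) "" else
        substr(dSeq, tl + 1, nchar(dSeq) - tr)
      n1 <- .randSeq(sample(0:10, 1))
      n2 <- .randSeq(sample(0:10, 1))
      if (!productive) break
      if (is.na(cys)) stop("V allele lacks a terminal Cys codon; ",
                           "cannot build a productive rearrangement")
      # productive selection happens before SHM: check against germline V
      germFull <- paste0(vSeq, n1, dFrag, n2, jSeq)
      cdr3g <- .truthCdr3(germFull, cys)
      # demand the anchor Trp to come from J, not from junction chance
      jW <- !is.na(cdr3g$aa) &&
        (cys + 3 * nchar(cdr3g$aa) - 1) > nchar(vSeq) + nchar(n1) +
          nchar(dFrag) + nchar(n2)
      if (jW) break
      if (attempt == 500) stop("failed to sample a productive junction")
    }
    full <- paste0(vMut, n1, dFrag, n2, jSeq)
    cdr3 <- if (is.na(cys)) list(aa = NA, nt = NA) else .truthCdr3(full, cys)
    structure(list(v_name = vName, d_name = dName, j_name = jName,
                   n1 = n1, d_frag = dFrag, n2 = n2,
                   junction = paste0(n1, dFrag, n2),
                   v_germline = vSeq, v_mutated = vMut,
                   j_sequence = jSeq,
                   true_sequence = full,
                   true_cdr3_aa = cdr3$aa, true_cdr3_nt = cdr3$nt,
                   n_mutations = nMut, shm_rate = shmRate),
              class = "SimulatedRearrangement")
  })
}

#' Simulate a repertoire abundance profile
#'
#' Emulates the three repertoire structures: \code{"polyclonal"} (healthy
#' donor): near-flat Dirichlet abundances over many clones with maximum
#' consecutive ratio at most 4; \code{"one_clone"}: a single dominant clone
#' (20-100 percent) whose ratio to the next clone is at least 8 over a scaled
#' polyclonal background; \code{"two_clone"}: two dominant clones with mutual
#' ratio below 8 and a ratio of at least 8 between the second and third.
#' Profiles are drawn by rejection so the stated MAX_DIFF bounds hold after
#' the 0.1 percent noise filter.
#'
#' @param kind \code{"polyclonal"}, \code{"one_clone"} or \code{"two_clone"}.
#' @param nBackground number of background clones (>= 10).
#' @param seed optional integer seed.
#' @return numeric vector of clone abundances, descending, summing to 1.
#' @examples
#' p <- simulateProfile("one_clone", seed = 7)
#' maxDiff(100 * p)
#' @export
simulateProfile <- function(kind = c("polyclonal", "one_clone", "two_clone"),
                            nBackground = 50, seed = NULL) {
  kind <- match.arg(kind)
  if (nBackground < 10) stop("nBackground must be >= 10")
  .withSeed(seed, {
    repeat {
      # bounds are checked on the filtered profile (clones < 0.1% dropped),
      # matching what the classifier will see downstream
      if (kind == "polyclonal") {
        x <- stats::rgamma(nBackground, shape = 5)
        x <- sort(x / sum(x), decreasing = TRUE)
        pr <- computeProfile(100 * x)
        if (!is.na(pr@maxDiff) && pr@maxDiff <= 4) return(x)
      } else if (kind == "one_clone") {
        r <- 10^stats::runif(1, 1, log10(500))
        bg <- stats::rgamma(nBackground, shape = 3)
        bg <- bg / max(bg) / r
        x <- sort(c(1, bg), decreasing = TRUE)
        x <- x / sum(x)
        pr <- computeProfile(100 * x)
        if (!is.na(pr@maxDiff) && pr@maxDiff >= 8 &&
            identical(pr@maxDiffPosition, 1L) && x[1] >= 0.2)
          return(x)
      } else {
        u <- stats::runif(1, 1.3, 4)
        r <- 10^stats::runif(1, 1, log10(300))
        bg <- stats::rgamma(nBackground, shape = 3)
        bg <- bg / max(bg) / (u * r)
        x <- sort(c(1, 1 / u, bg), decreasing = TRUE)
        x <- x / sum(x)
        pr <- computeProfile(100 * x)
        if (!is.na(pr@maxDiff) && pr@maxDiff >= 8 &&
            identical(pr@maxDiffPosition, 2L) &&
            pr@clonePcts[1] / pr@clonePcts[2] < 8) return(x)
      }
    }
  })
}

.phredString <- function(q, n) {
  paste(rep(rawToChar(as.raw(q + 33L)), n), collapse = "")
}

.splitEqually <- function(n, k) {
  base <- n %/% k
  extra <- n - base * k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' Simulate paired 150 bp amplicon reads for one rearrangement
#'
#' Each amplicon yields read pairs: R1 starts at the amplicon's forward
#' anchor inside the V allele and runs 150 bp; R2 is the reverse complement
#' of the final 150 bp of the rearrangement (the shared reverse anchor at the
#' 3' end of J), so R2 always spans J, the junction and the 3' V. Reads are
#' split across amplicons as equally as possible; substitution errors are
#' i.i.d. at \code{errorRate}; qualities are a constant Phred score with an
#' optional low-quality 3' tail to exercise trimming.
#'
#' @param rearr a \code{SimulatedRearrangement}.
#' @param amplicons data.frame from [defaultAmplicons()].
#' @param nReads number of read pairs.
#' @param errorRate per-base substitution error probability.
#' @param seed optional integer seed.
#' @param readLen read length (150).
#' @param baseQ constant Phred quality for read bases.
#' @param lowQualTail length of a Phred-2 tail at the 3' end of each read
#'   (0 = none), for exercising quality trimming.
#' @param idPrefix prefix for read names.
#' @return list with \code{R1}, \code{R2}
#'   (\code{QualityScaledDNAStringSet}s) and \code{info} (read_id, amplicon).
#' @export
simulateReads <- function(rearr, amplicons = defaultAmplicons(),
                          nReads = 300, errorRate = 0.002, seed = NULL,
                          readLen = 150L, baseQ = 37L, lowQualTail = 0L,
                          idPrefix = "read") {
  L <- nchar(rearr$true_sequence)
  vLen <- nchar(rearr$v_mutated)
  offs <- .ampliconOffsets(amplicons, vLen)
  if (any(offs + 50L > L))
    stop("amplicon does not fit within the rearrangement (length ", L, ")")
  .withSeed(seed, {
    counts <- .splitEqually(nReads, length(offs))
    r2t <- .revcomp(substr(rearr$true_sequence, max(1L, L - readLen + 1), L))
    ids <- character(0); amps <- character(0)
    r1 <- character(0); r2 <- character(0)
    for (a in seq_along(offs)) {
      if (counts[a] == 0) next
      # a fragment shorter than the read length yields a truncated read
      r1t <- substr(rearr$true_sequence, offs[a] + 1,
                    min(offs[a] + readLen, L))
      idx <- seq_len(counts[a])
      ids <- c(ids, paste0(idPrefix, ":", names(offs)[a], ":", idx))
      amps <- c(amps, rep(names(offs)[a], counts[a]))
      r1 <- c(r1, vapply(idx, function(i) .mutateSeq(r1t, errorRate), ""))
      r2 <- c(r2, vapply(idx, function(i) .mutateSeq(r2t, errorRate), ""))
    }
    qual <- function(n) {
      if (lowQualTail > 0 && n > lowQualTail)
        paste0(.phredString(baseQ, n - lowQualTail),
               .phredString(2L, lowQualTail))
      else .phredString(baseQ, n)
    }
    qs1 <- Biostrings::PhredQuality(vapply(nchar(r1), qual, ""))
    qs2 <- Biostrings::PhredQuality(vapply(nchar(r2), qual, ""))
    R1 <- Biostrings::QualityScaledDNAStringSet(
      setNames(Biostrings::DNAStringSet(r1), ids), qs1)
    R2 <- Biostrings::QualityScaledDNAStringSet(
      setNames(Biostrings::DNAStringSet(r2), ids), qs2)
    list(R1 = R1, R2 = R2,
         info = data.frame(read_id = ids, amplicon = amps,
                           stringsAsFactors = FALSE))
  })
}

#' Simulate a complete sample: clones, abundances and paired reads
#'
#' Draws (or accepts) a clone abundance vector, simulates one ground-truth
#' rearrangement per clone with a distinct V-J combination, splits
#' \code{totalReads} read pairs across clones by abundance
#' (largest-remainder rounding), and pools the reads.
#'
#' @param db a [GermlineDb-class].
#' @param kind profile kind for [simulateProfile()]; ignored when
#'   \code{abundances} is given.
#' @param abundances optional explicit abundance vector (normalized to 1).
#' @param totalReads total read pairs in the sample.
#' @param shmRate per-clone SHM rate, recycled across clones.
#' @param errorRate sequencing substitution error rate.
#' @param amplicons amplicon definitions.
#' @param seed optional integer seed.
#' @param nBackground background clone count for simulated profiles.
#' @param sampleId sample name used in read ids and truth rows.
#' @return list with \code{R1}, \code{R2}, \code{truth} (data.frame: clone,
#'   v, d, j, cdr3_aa, abundance, n_reads, shm_rate) and \code{rearrangements}
#'   (list of \code{SimulatedRearrangement}).
#' @export
simulateSample <- function(db, kind = "one_clone", abundances = NULL,
                           totalReads = 1200, shmRate = 0, errorRate = 0.002,
                           amplicons = defaultAmplicons(), seed = NULL,
                           nBackground = 50, sampleId = "sample1") {
  .withSeed(seed, {
    if (is.null(abundances))
      abundances <- simulateProfile(kind, nBackground = nBackground)
    abundances <- sort(abundances / sum(abundances), decreasing = TRUE)
    k <- length(abundances)
    shm <- rep_len(shmRate, k)
    # distinct V-J combinations so clones stay separable, until the
    # database's combination space is exhausted
    nCombos <- sum(db@info$segment == "V") * sum(db@info$segment == "J")
    rearrs <- vector("list", k); seen <- character(0)
    for (i in seq_len(k)) {
      for (try in seq_len(50)) {
        rr <- simulateRearrangement(db, shmRate = shm[i])
        key <- paste(rr$v_name, rr$j_name)
        if (!key %in% seen || length(seen) >= nCombos) break
      }
      seen <- c(seen, key)
      rearrs[[i]] <- rr
    }
    nr <- floor(abundances * totalReads)
    rem <- totalReads - sum(nr)
    if (rem > 0) {
      frac <- abundances * totalReads - nr
      nr[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
        nr[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
    }
    R1 <- NULL; R2 <- NULL; infos <- list()
    for (i in seq_len(k)) {
      if (nr[i] == 0) next
      rd <- simulateReads(rearrs[[i]], amplicons = amplicons,
                          nReads = nr[i], errorRate = errorRate,
                          idPrefix = paste0(sampleId, ":c", i))
      R1 <- if (is.null(R1)) rd$R1 else append(R1, rd$R1)
      R2 <- if (is.null(R2)) rd$R2 else append(R2, rd$R2)
      infos[[i]] <- cbind(rd$info, clone = i)
    }
    truth <- data.frame(
      sample = sampleId, clone = seq_len(k),
      v = vapply(rearrs, `[[`, "", "v_name"),
      d = vapply(rearrs, `[[`, "", "d_name"),
      j = vapply(rearrs, `[[`, "", "j_name"),
      cdr3_aa = vapply(rearrs, function(r)
        as.character(r$true_cdr3_aa %||% NA), ""),
      abundance = abundances, n_reads = nr,
      shm_rate = shm, stringsAsFactors = FALSE)
    list(R1 = R1, R2 = R2, truth = truth, rearrangements = rearrs,
         readInfo = do.call(rbind, infos))
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Write simulated paired reads to FASTQ
#'
#' @param reads list with \code{R1}/\code{R2} quality-scaled read sets.
#' @param prefix output path prefix; writes \code{<prefix>_R1.fastq} and
#'   \code{<prefix>_R2.fastq}.
#' @return character(2) of the paths written, invisibly.
#' @export
writeFastqPair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  Biostrings::writeXStringSet(reads$R1, paths[1], format = "fastq",
                              qualities = Biostrings::quality(reads$R1))
  Biostrings::writeXStringSet(reads$R2, paths[2], format = "fastq",
                              qualities = Biostrings::quality(reads$R2))
  invisible(paths)
}

#' Read a paired FASTQ sample
#'
#' @param r1,r2 paths to the R1 and R2 FASTQ files.
#' @return list with \code{R1}, \code{R2} quality-scaled read sets.
#' @export
readFastqPair <- function(r1, r2) {
  # Biostrings warns about dropping its own internal metadata columns here
  rd <- function(p) suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(p))
  list(R1 = rd(r1), R2 = rd(r2))
}
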