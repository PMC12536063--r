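#' Assign reads to their best germline V and J alleles
#'
#' Aligns every read, in both orientations, locally against all germline V
#' alleles and all germline J alleles (match +1, mismatch -2, gap open -4,
#' gap extend -1). Per segment, the best-scoring hit is retained when its
#' score reaches \code{minScore}; ties are broken by higher identity, then by
#' lexicographic allele name. The orientation maximizing the combined V + J
#' score is used, so a read spanning the V-J junction carries both hits.
#' Reads with no hit are returned flagged unassigned rather than dropped.
#'
#' @param reads a \code{DNAStringSet} or \code{QualityScaledDNAStringSet}
#'   of (already trimmed) reads.
#' @param db a [GermlineDb-class].
#' @param minScore minimum local alignment score for a hit (default 40).
#' @param mate label stored in the \code{mate} column (\code{"R1"}/\code{"R2"}).
#' @return data.frame with one row per read: \code{read_id}, \code{mate},
#'   \code{orientation} (\code{"fwd"}/\code{"rev"}), \code{assigned},
#'   \code{v_allele}, \code{v_score}, \code{v_identity}, \code{v_ref_start},
#'   \code{v_ref_end}, \code{v_read_start}, \code{v_read_end} and the same
#'   block for J. Coordinates are 0-based half-open; read coordinates refer
#'   to the read in its aligned (forward) orientation.
#' @export
assignReads <- function(reads, db, minScore = 40, mate = "R1") {
  seqs <- .sanitizeSeqs(as(reads, "DNAStringSet"))
  n <- length(seqs)
  ids <- names(seqs) %||% as.character(seq_len(n))
  empty <- function() data.frame(
    read_id = character(0), mate = character(0), orientation = character(0),
    assigned = logical(0),
    v_allele = character(0), v_score = numeric(0), v_identity = numeric(0),
    v_ref_start = integer(0), v_ref_end = integer(0),
    v_read_start = integer(0), v_read_end = integer(0),
    j_allele = character(0), j_score = numeric(0), j_identity = numeric(0),
    j_ref_start = integer(0), j_ref_end = integer(0),
    j_read_start = integer(0), j_read_end = integer(0),
    stringsAsFactors = FALSE)
  if (n == 0L) return(empty())

  oriSeqs <- list(fwd = seqs, rev = Biostrings::reverseComplement(seqs))
  segNames <- list(V = sort(alleleInfo(db, "V")$name),
                   J = sort(alleleInfo(db, "J")$name))
  # per (orientation, segment, allele): vectorized score/identity/coords
  hits <- list()
  for (o in names(oriSeqs)) {
    for (sg in names(segNames)) {
      nm <- segNames[[sg]]
      k <- length(nm)
      sc <- idn <- matrix(0, n, k, dimnames = list(NULL, nm))
      rs <- re <- ps <- pe <- matrix(0L, n, k, dimnames = list(NULL, nm))
      for (a in nm) {
        aln <- .alignLocal(oriSeqs[[o]], getAllele(db, a))
        sc[, a] <- Biostrings::score(aln)
        idn[, a] <- .alnIdentity(aln)
        rs[, a] <- Biostrings::start(Biostrings::subject(aln)) - 1L
        re[, a] <- Biostrings::end(Biostrings::subject(aln))
        ps[, a] <- Biostrings::start(Biostrings::pattern(aln)) - 1L
        pe[, a] <- Biostrings::end(Biostrings::pattern(aln))
      }
      hits[[paste(o, sg)]] <- list(score = sc, identity = idn,
                                   ref_start = rs, ref_end = re,
                                   read_start = ps, read_end = pe)
    }
  }

  bestOf <- function(h, i) {
    sc <- h$score[i, ]
    top <- max(sc)
    if (top < minScore) return(NULL)
    cand <- names(sc)[sc == top]
    if (length(cand) > 1) {
      ii <- h$identity[i, cand]
      cand <- sort(cand[ii == max(ii)])
    }
    a <- cand[1]
    list(allele = a, score = unname(top), identity = h$identity[i, a],
         ref_start = h$ref_start[i, a], ref_end = h$ref_end[i, a],
         read_start = h$read_start[i, a], read_end = h$read_end[i, a])
  }

  bestScore <- function(o, sg) {
    apply(hits[[paste(o, sg)]]$score, 1, max)
  }
  totFwd <- pmax(bestScore("fwd", "V"), 0) + pmax(bestScore("fwd", "J"), 0)
  totRev <- pmax(bestScore("rev", "V"), 0) + pmax(bestScore("rev", "J"), 0)
  oriChoice <- ifelse(totRev > totFwd, "rev", "fwd")

  out <- empty()[rep(1L, 0), ]
  col <- function(default) rep(default, n)
  out <- data.frame(
    read_id = ids, mate = col(mate), orientation = oriChoice,
    assigned = col(FALSE),
    v_allele = col(NA_character_), v_score = col(NA_real_),
    v_identity = col(NA_real_), v_ref_start = col(NA_integer_),
    v_ref_end = col(NA_integer_), v_read_start = col(NA_integer_),
    v_read_end = col(NA_integer_),
    j_allele = col(NA_character_), j_score = col(NA_real_),
    j_identity = col(NA_real_), j_ref_start = col(NA_integer_),
    j_ref_end = col(NA_integer_), j_read_start = col(NA_integer_),
    j_read_end = col(NA_integer_), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    o <- oriChoice[i]
    vh <- bestOf(hits[[paste(o, "V")]], i)
    jh <- bestOf(hits[[paste(o, "J")]], i)
    if (!is.null(vh)) {
      out$v_allele[i] <- vh$allele; out$v_score[i] <- vh$score
      out$v_identity[i] <- vh$identity
      out$v_ref_start[i] <- vh$ref_start; out$v_ref_end[i] <- vh$ref_end
      out$v_read_start[i] <- vh$read_start; out$v_read_end[i] <- vh$read_end
    }
    if (!is.null(jh)) {
      out$j_allele[i] <- jh$allele; out$j_score[i] <- jh$score
      out$j_identity[i] <- jh$identity
      out$j_ref_start[i] <- jh$ref_start; out$j_ref_end[i] <- jh$ref_end
      out$j_read_start[i] <- jh$read_start; out$j_read_end[i] <- jh$read_end
    }
    out$assigned[i] <- !is.null(vh) || !is.null(jh)
  }
  out
}

#' Trim and assign a paired sample
#'
#' Convenience wrapper: quality-trims R1 and R2, assigns each mate, and
#' row-binds the assignment tables (mate column distinguishes them).
#'
#' @param R1,R2 \code{QualityScaledDNAStringSet}s of paired reads (same
#'   names in both).
#' @inheritParams assignReads
#' @inheritParams qualityTrim
#' @return list with \code{assignments} (data.frame), \code{trimmedR1},
#'   \code{trimmedR2}, \code{dropped}, \code{n_trimmed_reads}.
#' @export
assignSample <- function(R1, R2, db, qFloor = 30L, minLen = 50L,
                         minScore = 40) {
  t1 <- qualityTrim(R1, qFloor, minLen)
  t2 <- qualityTrim(R2, qFloor, minLen)
  a1 <- assignReads(t1$reads, db, minScore, mate = "R1")
  a2 <- assignReads(t2$reads, db, minScore, mate = "R2")
  list(assignments = rbind(a1, a2), trimmedR1 = t1$reads,
       trimmedR2 = t2$reads,
       dropped = union(t1$dropped, t2$dropped),
       n_trimmed_reads = length(t1$reads) + length(t2$reads))
}

#' Label the amplicon fragment of origin for assigned reads
#'
#' A forward (R1) read with a V hit is labelled with the amplicon whose
#' forward anchor lies nearest its V-reference start, within
#' \code{tolerance}; equidistant anchors resolve to the earlier amplicon.
#' Reverse (R2) reads share one reverse anchor across amplicons, so they
#' inherit the label of their mate; reads that match no anchor (or whose
#' mate does not) are labelled \code{"unknown"}.
#'
#' @param assignments data.frame from [assignReads()]/[assignSample()].
#' @param db a [GermlineDb-class] (for V-allele lengths).
#' @param amplicons amplicon definitions ([defaultAmplicons()]).
#' @param tolerance maximum anchor distance in nt (default 25).
#' @return the assignment data.frame with a \code{fragment} column added.
#' @export
labelFragments <- function(assignments, db, amplicons = defaultAmplicons(),
                           tolerance = 25L) {
  frag <- rep("unknown", nrow(assignments))
  vlen <- setNames(db@info$length, db@info$name)
  r1 <- which(assignments$mate == "R1" & !is.na(assignments$v_allele))
  for (i in r1) {
    offs <- .ampliconOffsets(amplicons, vlen[[assignments$v_allele[i]]])
    d <- abs(assignments$v_ref_start[i] - offs)
    if (min(d) <= tolerance)
      frag[i] <- names(offs)[which.min(d)]  # which.min: earliest on ties
  }
  assignments$fragment <- frag
  # R2 inherits its mate's label
  r1lab <- assignments$fragment[assignments$mate == "R1"]
  names(r1lab) <- assignments$read_id[assignments$mate == "R1"]
  r2 <- which(assignments$mate == "R2")
  hit <- assignments$read_id[r2] %in% names(r1lab)
  assignments$fragment[r2[hit]] <- unname(r1lab[assignments$read_id[r2[hit]]])
  assignments
}

#' Per-allele, per-fragment read counts
#'
#' Counts retained (assigned) reads by allele and fragment of origin. Each
#' assigned read contributes one count, keyed to its V allele when present,
#' otherwise its J allele, so the table total equals the number of assigned
#' reads.
#'
#' @param assignments data.frame from [labelFragments()] (a missing
#'   \code{fragment} column is treated as \code{"unknown"}).
#' @return data.frame with columns \code{allele}, \code{fragment}, \code{n}.
#' @export
alleleReadCounts <- function(assignments) {
  if (nrow(assignments) == 0L)
    return(data.frame(allele = character(0), fragment = character(0),
                      n = integer(0), stringsAsFactors = FALSE))
  a <- assignments[assignments$assigned, , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(allele = character(0), fragment = character(0),
                      n = integer(0), stringsAsFactors = FALSE))
  allele <- ifelse(!is.na(a$v_allele), a$v_allele, a$j_allele)
  fragment <- if ("fragment" %in% names(a)) a$fragment else
    rep("unknown", nrow(a))
  agg <- stats::aggregate(list(n = rep(1L, length(allele))),
                          by = list(allele = allele, fragment = fragment),
                          FUN = sum)
  agg[order(agg$allele, agg$fragment), , drop = FALSE]
}
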