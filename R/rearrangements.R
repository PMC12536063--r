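#' Infer V-J allele pairings from read assignments
#'
#' A read pair links a V allele to a J allele when its mates together carry
#' both hits (a single junction-spanning read carrying both also links). A
#' pairing is created when at least \code{minLinkReads} read pairs link the
#' same combination. Every read pair is then attributed to exactly one
#' pairing: linking pairs go to the retained pairing they support (pairs
#' consistent with several go to the one with more linking reads; exact ties
#' are dropped), and V-only pairs are attached to the pairing of their V
#' allele when that V occurs in exactly one retained pairing.
#'
#' @param assignments data.frame from [assignSample()]/[labelFragments()].
#' @param minLinkReads minimum linking read pairs (default 3).
#' @return list with \code{pairings} (data.frame: \code{v_allele},
#'   \code{j_allele}, \code{n_link}) and \code{reads} (list of read-id
#'   vectors, parallel to the rows of \code{pairings}).
#' @export
inferPairings <- function(assignments, minLinkReads = 3L) {
  a <- assignments[assignments$assigned, , drop = FALSE]
  emptyOut <- list(pairings = data.frame(v_allele = character(0),
                                         j_allele = character(0),
                                         n_link = integer(0),
                                         stringsAsFactors = FALSE),
                   reads = list())
  if (nrow(a) == 0L) return(emptyOut)
  byRead <- split(a, a$read_id)
  combos <- lapply(byRead, function(rows) {
    v <- unique(stats::na.omit(rows$v_allele))
    j <- unique(stats::na.omit(rows$j_allele))
    if (length(v) && length(j))
      expand.grid(v_allele = v, j_allele = j, stringsAsFactors = FALSE)
    else NULL
  })
  linkTab <- do.call(rbind, combos)
  if (is.null(linkTab) || nrow(linkTab) == 0L) return(emptyOut)
  linkTab$read_id <- rep(names(combos),
                         vapply(combos, function(x) NROW(x) %||% 0L, 0L))
  key <- paste(linkTab$v_allele, linkTab$j_allele, sep = "\r")
  cnt <- table(key)
  keep <- names(cnt)[cnt >= minLinkReads]
  if (!length(keep)) return(emptyOut)
  keep <- sort(keep)
  pairings <- data.frame(
    v_allele = vapply(strsplit(keep, "\r"), `[`, "", 1),
    j_allele = vapply(strsplit(keep, "\r"), `[`, "", 2),
    n_link = as.integer(cnt[keep]), stringsAsFactors = FALSE)
  # attribute each linking read pair to one retained pairing
  readAssign <- setNames(vector("list", nrow(pairings)), keep)
  linkKept <- linkTab[key %in% keep, , drop = FALSE]
  linkKept$key <- paste(linkKept$v_allele, linkKept$j_allele, sep = "\r")
  for (id in unique(linkKept$read_id)) {
    ks <- unique(linkKept$key[linkKept$read_id == id])
    if (length(ks) > 1L) {
      n <- as.integer(cnt[ks])
      if (sum(n == max(n)) > 1L) next  # ambiguous tie: drop the read
      ks <- ks[which.max(n)]
    }
    readAssign[[ks]] <- c(readAssign[[ks]], id)
  }
  # V-only read pairs attach when their V is in exactly one pairing
  linkedIds <- unique(linkKept$read_id)
  vOnly <- vapply(byRead, function(rows) {
    any(!is.na(rows$v_allele)) && !any(!is.na(rows$j_allele))
  }, logical(1))
  vOf <- vapply(byRead, function(rows)
    stats::na.omit(rows$v_allele)[1] %||% NA_character_, "")
  for (id in names(byRead)[vOnly & !(names(byRead) %in% linkedIds)]) {
    hits <- which(pairings$v_allele == vOf[[id]])
    if (length(hits) == 1L) {
      k <- keep[hits]
      readAssign[[k]] <- c(readAssign[[k]], id)
    }
  }
  list(pairings = pairings, reads = unname(readAssign))
}

# oriented read sequences (forward-strand of the rearrangement) for a set of
# read ids, using the orientation recorded at assignment
.orientedReads <- function(ids, R1, R2, assignments) {
  a <- assignments[assignments$read_id %in% ids & assignments$assigned, ,
                   drop = FALSE]
  if (!"fragment" %in% names(a)) a$fragment <- "unknown"
  s1 <- .sanitizeSeqs(as(R1, "DNAStringSet"))
  s2 <- .sanitizeSeqs(as(R2, "DNAStringSet"))
  idx1 <- match(a$read_id, names(s1))
  idx2 <- match(a$read_id, names(s2))
  found <- ifelse(a$mate == "R1", !is.na(idx1), !is.na(idx2))
  a <- a[found, , drop = FALSE]
  seqs <- character(nrow(a))
  isR1 <- a$mate == "R1"
  seqs[isR1] <- as.character(s1[idx1[found][isR1]])
  seqs[!isR1] <- as.character(s2[idx2[found][!isR1]])
  rev <- a$orientation == "rev"
  if (any(rev))
    seqs[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rev])))
  list(seqs = Biostrings::DNAStringSet(seqs),
       meta = a[, c("read_id", "mate", "fragment")])
}

# per-position base tally against one reference from a vector of local
# alignments; returns list(counts = 5 x L matrix (A,C,G,T,-), and per-read
# ref/read interval table). Reads without indels (the vast majority under an
# Illumina substitution-error model) are read off by coordinate arithmetic;
# indel reads fall back to an aligned-string walk.
.tallyAlignments <- function(aln, seqs, refLen, minScore) {
  lv <- c("A", "C", "G", "T", "-")
  sc <- Biostrings::score(aln)
  keep <- which(sc >= minScore)
  rs <- Biostrings::start(Biostrings::subject(aln))
  re <- Biostrings::end(Biostrings::subject(aln))
  qs <- Biostrings::start(Biostrings::pattern(aln))
  qe <- Biostrings::end(Biostrings::pattern(aln))
  iv <- data.frame(idx = keep, ref_start = rs[keep] - 1L,
                   ref_end = re[keep], read_start = qs[keep] - 1L,
                   read_end = qe[keep])
  if (!length(keep))
    return(list(counts = matrix(0L, 5, refLen, dimnames = list(lv, NULL)),
                intervals = iv))
  ni <- Biostrings::nindel(aln)
  hasIndel <- (ni@insertion[, "WidthSum"] + ni@deletion[, "WidthSum"]) > 0L
  plain <- keep[!hasIndel[keep]]
  posAll <- integer(0); baseAll <- character(0)
  if (length(plain)) {
    chunks <- substring(as.character(seqs)[plain], qs[plain], qe[plain])
    posAll <- unlist(Map(seq.int, rs[plain], re[plain]), use.names = FALSE)
    baseAll <- unlist(strsplit(chunks, ""), use.names = FALSE)
  }
  for (i in keep[hasIndel[keep]]) {
    a1 <- aln[i]
    cb <- .alnRefBases(as.character(Biostrings::alignedPattern(a1)),
                       as.character(Biostrings::alignedSubject(a1)), rs[i])
    posAll <- c(posAll, cb$pos)
    baseAll <- c(baseAll, ifelse(is.na(cb$base), "-", cb$base))
  }
  ok <- posAll >= 1L & posAll <= refLen & baseAll %in% lv
  counts <- unclass(table(factor(baseAll[ok], levels = lv),
                          factor(posAll[ok], levels = seq_len(refLen))))
  dimnames(counts) <- list(lv, NULL)
  storage.mode(counts) <- "integer"
  list(counts = counts, intervals = iv)
}

# majority call per column; below minDepth or ties including the reference
# fall back to the reference base
.majorityConsensus <- function(counts, refSeq, minDepth) {
  refCh <- strsplit(refSeq, "")[[1]]
  L <- length(refCh)
  out <- refCh
  baseCounts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  depth <- colSums(baseCounts)
  for (p in seq_len(L)) {
    if (depth[p] < minDepth) next
    col <- baseCounts[, p]
    top <- max(col)
    cand <- rownames(baseCounts)[col == top]
    out[p] <- if (refCh[p] %in% cand) refCh[p] else sort(cand)[1]
  }
  list(seq = paste(out, collapse = ""), depth = as.integer(depth))
}

#' Build the consensus sequence for one V-J pairing
#'
#' The pairing's reads are realigned against its V and J germline alleles
#' (the two halves of the concatenated V-J reference; the N-gap between them
#' is never aligned across). Each reference column is called by majority
#' vote with a minimum depth (ties and under-covered columns keep the
#' germline base). The junction insert -- the read bases between the end of V
#' and the start of J -- is taken from junction-spanning reads as the most
#' frequent full junction string (ties: longest, then lexicographic), since
#' column voting cannot represent length variation inside the gap. The
#' consensus is reported 5'V to 3'J as V-consensus + junction + J-consensus.
#'
#' @param vName,jName the pairing's allele names.
#' @param readIds read ids attributed to the pairing.
#' @param R1,R2 trimmed read sets.
#' @param assignments assignment table (for orientations and fragments).
#' @param db a [GermlineDb-class].
#' @param minDepth minimum column depth for a majority call (default 2).
#' @param minScore minimum realignment score for a read to contribute.
#' @return one-row list: consensus, junction, depth vector, fragment
#'   support, read count; \code{NULL} when no read realigns.
#' @export
buildConsensus <- function(vName, jName, readIds, R1, R2, assignments, db,
                           minDepth = 2L, minScore = 40) {
  orc <- .orientedReads(readIds, R1, R2, assignments)
  if (length(orc$seqs) == 0L) return(NULL)
  vSeq <- as.character(getAllele(db, vName))
  jSeq <- as.character(getAllele(db, jName))
  vAln <- .alignLocal(orc$seqs, getAllele(db, vName))
  jAln <- .alignLocal(orc$seqs, getAllele(db, jName))
  vT <- .tallyAlignments(vAln, orc$seqs, nchar(vSeq), minScore)
  jT <- .tallyAlignments(jAln, orc$seqs, nchar(jSeq), minScore)
  if (sum(vT$counts) + sum(jT$counts) == 0L) return(NULL)
  vC <- .majorityConsensus(vT$counts, vSeq, minDepth)
  jC <- .majorityConsensus(jT$counts, jSeq, minDepth)

  # junction: reads whose V alignment reaches (nearly) the V 3' end and
  # whose J alignment starts at (nearly) the J 5' end
  juncs <- character(0)
  vi <- vT$intervals; ji <- jT$intervals
  both <- intersect(vi$idx, ji$idx)
  for (i in both) {
    v <- vi[vi$idx == i, ]; j <- ji[ji$idx == i, ]
    if (nchar(vSeq) - v$ref_end > 3L || j$ref_start > 3L) next
    jStart <- v$read_end + (nchar(vSeq) - v$ref_end) + 1L
    jEnd <- j$read_start - j$ref_start
    if (jEnd < jStart - 1L) next
    js <- if (jEnd < jStart) "" else
      substr(as.character(orc$seqs[[i]]), jStart, jEnd)
    juncs <- c(juncs, js)
  }
  junction <- ""
  nJunc <- 0L
  if (length(juncs)) {
    tab <- table(juncs)
    top <- names(tab)[tab == max(tab)]
    top <- top[nchar(top) == max(nchar(top))]
    junction <- sort(top)[1]
    nJunc <- as.integer(max(tab))
  }
  consensus <- paste0(vC$seq, junction, jC$seq)
  depth <- c(vC$depth, rep(nJunc, nchar(junction)), jC$depth)

  frag <- orc$meta$fragment %||% rep("unknown", nrow(orc$meta))
  pairFrag <- tapply(frag, orc$meta$read_id, function(f) {
    f <- f[f != "unknown"]
    if (length(f)) f[1] else "unknown"
  })
  fragCount <- function(lbl) sum(pairFrag == lbl)
  list(v_allele = vName, j_allele = jName, consensus = consensus,
       junction = junction, depth = depth,
       read_count = length(pairFrag),
       frag_leader = fragCount("leader"), frag_FR1 = fragCount("FR1"),
       frag_FR2 = fragCount("FR2"), frag_FR3 = fragCount("FR3"),
       frag_unknown = fragCount("unknown"))
}

#' Build all rearrangements for a sample
#'
#' Runs [inferPairings()] and [buildConsensus()] over a sample's assigned
#' reads and assembles a [RearrangementSet-class], with clonal percentages
#' computed over the reads assigned to IGH rearrangements. Pairings whose
#' reads fail to realign are discarded with a message.
#'
#' @param assignments assignment table with fragment labels.
#' @param R1,R2 trimmed read sets.
#' @param db a [GermlineDb-class].
#' @param sampleId sample name.
#' @param minLinkReads,minDepth,minScore see [inferPairings()] and
#'   [buildConsensus()].
#' @return a [RearrangementSet-class].
#' @export
buildRearrangements <- function(assignments, R1, R2, db,
                                sampleId = "sample", minLinkReads = 3L,
                                minDepth = 2L, minScore = 40) {
  pr <- inferPairings(assignments, minLinkReads)
  rows <- list(); depths <- list()
  for (i in seq_len(nrow(pr$pairings))) {
    cs <- buildConsensus(pr$pairings$v_allele[i], pr$pairings$j_allele[i],
                         pr$reads[[i]], R1, R2, assignments, db,
                         minDepth, minScore)
    if (is.null(cs)) {
      message("pairing ", pr$pairings$v_allele[i], "_",
              pr$pairings$j_allele[i], " discarded: no read realigned")
      next
    }
    depths[[length(rows) + 1L]] <- cs$depth
    cs$depth <- NULL
    rows[[length(rows) + 1L]] <- cs
  }
  tab <- if (length(rows)) {
    d <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    d$id <- paste0(d$v_allele, "_", d$j_allele)
    d$read_count <- as.integer(d$read_count)
    d$clonal_pct <- NA_real_
    DataFrame(d[, c("id", "v_allele", "j_allele", "consensus", "junction",
                    "read_count", "frag_leader", "frag_FR1", "frag_FR2",
                    "frag_FR3", "frag_unknown", "clonal_pct")])
  } else {
    DataFrame(id = character(0), v_allele = character(0),
              j_allele = character(0), consensus = character(0),
              junction = character(0), read_count = integer(0),
              frag_leader = integer(0), frag_FR1 = integer(0),
              frag_FR2 = integer(0), frag_FR3 = integer(0),
              frag_unknown = integer(0), clonal_pct = numeric(0))
  }
  rs <- new("RearrangementSet", sampleId = sampleId, table = tab,
            depth = depths)
  if (nrow(tab)) rs <- clonalPercentages(rs)
  validObject(rs)
  rs
}

#' Recompute clonal percentages
#'
#' Sets each rearrangement's \code{clonal_pct} to 100 x its read count over
#' the total reads assigned to the sample's IGH rearrangements.
#'
#' @param rset a [RearrangementSet-class].
#' @return the updated [RearrangementSet-class].
#' @export
clonalPercentages <- function(rset) {
  tab <- rset@table
  if (nrow(tab) == 0L) return(rset)
  tot <- sum(tab$read_count)
  tab$clonal_pct <- 100 * tab$read_count / tot
  rset@table <- tab
  validObject(rset)
  rset
}

#' Coverage breadth of a rearrangement consensus
#'
#' Percentage of consensus positions whose read depth is at or above
#' \code{depthFloor} (default 500).
#'
#' @param x a [RearrangementSet-class] (vectorized over rearrangements) or a
#'   numeric depth vector.
#' @param depthFloor depth threshold.
#' @return numeric percentage(s).
#' @examples
#' coverageBreadth(c(600, 600, 400, 600), depthFloor = 500)
#' @export
coverageBreadth <- function(x, depthFloor = 500L) {
  if (is(x, "RearrangementSet"))
    return(vapply(x@depth, coverageBreadth, numeric(1),
                  depthFloor = depthFloor))
  if (!length(x)) stop("empty depth profile")
  100 * sum(x >= depthFloor) / length(x)
}

#' @export
setMethod("show", "RearrangementSet", function(object) {
  cat("RearrangementSet for sample", object@sampleId, "with",
      nrow(object@table), "rearrangement(s)\n")
  if (nrow(object@table)) {
    cols <- intersect(c("id", "read_count", "clonal_pct", "identity_pct",
                        "status", "cdr3_aa"), colnames(object@table))
    print(utils::head(as.data.frame(object@table[, cols, drop = FALSE]), 10))
  }
})

#' Rearrangement table as a data.frame
#'
#' @param rset a [RearrangementSet-class].
#' @return base data.frame of the per-rearrangement table.
#' @export
rearrangementTable <- function(rset) {
  as.data.frame(rset@table)
}

#' @rdname rearrangementTable
#' @export
sampleId <- function(rset) rset@sampleId
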