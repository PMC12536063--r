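.vGene <- function(names) {
  vapply(names, function(n) {
    p <- parseAlleleName(n)
    if (is.null(p)) NA_character_ else p$gene
  }, "", USE.NAMES = FALSE)
}

.vFamily <- function(names) {
  vapply(names, function(n) {
    p <- parseAlleleName(n)
    if (is.null(p)) NA_character_ else p$family
  }, "", USE.NAMES = FALSE)
}

# identity between two consensuses: global alignment, identity over the
# mutual overlap (terminal gap runs excluded, so length differences at the
# ends are not penalized but the shared region is compared end to end)
.consensusIdentity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = .subMat(),
    gapOpening = 4, gapExtension = 1)
  ps <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ss <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  inner <- which(ps != "-" & ss != "-")
  if (!length(inner)) return(0)
  span <- seq(min(inner), max(inner))
  100 * sum(ps[span] == ss[span]) / length(span)
}

.absorb <- function(tab, depth, absorbed, absorber) {
  for (cl in c("read_count", "frag_leader", "frag_FR1", "frag_FR2",
               "frag_FR3", "frag_unknown"))
    if (cl %in% colnames(tab))
      tab[[cl]][absorber] <- tab[[cl]][absorber] + tab[[cl]][absorbed]
  list(table = tab, depth = depth)
}

#' Merge mapping artifacts by consensus identity
#'
#' Two-stage collapse of rearrangements whose consensus sequences share at
#' least \code{threshold} percent identity (computed by global alignment
#' over the mutual overlap of the two consensuses). Stage one merges
#' rearrangements that differ only in the V allele of the same V gene; stage
#' two repeats the sweep across V genes. The member with more reads absorbs
#' the other: read counts and fragment support are summed, and the
#' absorber's consensus and annotation are retained. Sweeps repeat until no
#' pair merges, making the operation idempotent and independent of input
#' order for a fixed abundance ranking.
#'
#' @param rset a [RearrangementSet-class].
#' @param threshold identity threshold in percent (default 95).
#' @return list with \code{rearrangements} (merged set) and \code{events}
#'   (data.frame: \code{absorbed_id}, \code{absorber_id}, \code{rule},
#'   \code{identity}).
#' @export
mergeByIdentity <- function(rset, threshold = 95) {
  events <- data.frame(absorbed_id = character(0),
                       absorber_id = character(0), rule = character(0),
                       identity = numeric(0), stringsAsFactors = FALSE)
  tab <- rset@table; depth <- rset@depth
  if (nrow(tab) < 2)
    return(list(rearrangements = rset, events = events))
  for (pass in 1:2) {
    rule <- if (pass == 1) "allele_identity95" else "gene_identity95"
    repeat {
      merged <- FALSE
      ord <- order(-tab$read_count, tab$id)
      for (ii in rev(seq_along(ord))) {   # smallest first
        i <- ord[ii]
        for (jj in seq_len(ii - 1L)) {    # absorbers, largest first
          j <- ord[jj]
          sameGene <- identical(.vGene(tab$v_allele[i]),
                                .vGene(tab$v_allele[j]))
          sameAllele <- tab$v_allele[i] == tab$v_allele[j]
          okPair <- if (pass == 1)
            sameGene && !sameAllele && tab$j_allele[i] == tab$j_allele[j]
          else TRUE
          if (!okPair) next
          idn <- .consensusIdentity(tab$consensus[i], tab$consensus[j])
          if (idn >= threshold) {
            events <- rbind(events, data.frame(
              absorbed_id = tab$id[i], absorber_id = tab$id[j],
              rule = rule, identity = idn, stringsAsFactors = FALSE))
            upd <- .absorb(tab, depth, i, j)
            tab <- upd$table[-i, , drop = FALSE]
            depth <- depth[-i]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  rset@table <- tab; rset@depth <- depth
  rset <- clonalPercentages(rset)
  list(rearrangements = rset, events = events)
}

#' Merge low-support rearrangements into their major clone
#'
#' A rearrangement supported by only one amplicon fragment class, or whose
#' FR3 fragment carries at least \code{fr3Frac} of its reads, is absorbed
#' into the largest rearrangement sharing its V family and CDR3 amino acid
#' sequence. When no such major rearrangement exists it is retained but
#' flagged \code{low_support}. Requires an annotated set (CDR3 available).
#'
#' @param rset an annotated [RearrangementSet-class].
#' @param fr3Frac FR3 read share triggering the rule (default 0.92).
#' @return list with \code{rearrangements} and \code{events} as in
#'   [mergeByIdentity()].
#' @export
mergeLowSupport <- function(rset, fr3Frac = 0.92) {
  tab <- rset@table; depth <- rset@depth
  if (!"cdr3_aa" %in% colnames(tab))
    stop("rearrangements are not annotated; run annotateRearrangements()")
  events <- data.frame(absorbed_id = character(0),
                       absorber_id = character(0), rule = character(0),
                       identity = numeric(0), stringsAsFactors = FALSE)
  tab$low_support <- if (nrow(tab)) FALSE else logical(0)
  if (nrow(tab) >= 1) {
    repeat {
      merged <- FALSE
      tab$low_support <- FALSE
      fragClasses <- with(as.data.frame(tab[, c("frag_leader", "frag_FR1",
                                                "frag_FR2", "frag_FR3")]),
                          (frag_leader > 0) + (frag_FR1 > 0) +
                          (frag_FR2 > 0) + (frag_FR3 > 0))
      fr3Share <- ifelse(tab$read_count > 0,
                         tab$frag_FR3 / tab$read_count, 0)
      fam <- .vFamily(tab$v_allele)
      for (i in order(tab$read_count, tab$id)) {
        single <- fragClasses[i] <= 1L
        fr3dom <- fr3Share[i] >= fr3Frac
        if (!single && !fr3dom) next
        cand <- which(fam == fam[i] &
                      !is.na(tab$cdr3_aa) & !is.na(tab$cdr3_aa[i]) &
                      tab$cdr3_aa == tab$cdr3_aa[i] &
                      seq_len(nrow(tab)) != i &
                      tab$read_count >= tab$read_count[i])
        if (length(cand)) {
          j <- cand[order(-tab$read_count[cand], tab$id[cand])][1]
          events <- rbind(events, data.frame(
            absorbed_id = tab$id[i], absorber_id = tab$id[j],
            rule = if (single) "single_fragment" else "fr3_dominant",
            identity = NA_real_, stringsAsFactors = FALSE))
          upd <- .absorb(tab, depth, i, j)
          tab <- upd$table[-i, , drop = FALSE]
          depth <- depth[-i]
          merged <- TRUE
          break
        } else {
          tab$low_support[i] <- TRUE
        }
      }
      if (!merged) break
    }
  }
  rset@table <- tab; rset@depth <- depth
  if (nrow(tab)) rset <- clonalPercentages(rset)
  list(rearrangements = rset, events = events)
}

#' Run the full artifact filter
#'
#' [mergeByIdentity()] followed by [mergeLowSupport()], with the merge
#' events of both stages concatenated.
#'
#' @inheritParams mergeByIdentity
#' @inheritParams mergeLowSupport
#' @return list with \code{rearrangements} and \code{events}.
#' @export
filterArtifacts <- function(rset, threshold = 95, fr3Frac = 0.92) {
  s1 <- mergeByIdentity(rset, threshold)
  s2 <- mergeLowSupport(s1$rearrangements, fr3Frac)
  list(rearrangements = s2$rearrangements,
       events = rbind(s1$events, s2$events))
}

#' Gene-level summary report
#'
#' Collapses the (filtered, annotated) allele-level detail to one row per
#' (V gene, J gene, CDR3), keeping the allele names nested as a
#' comma-separated list and recomputing clonal percentages after merging.
#'
#' @param rset an annotated [RearrangementSet-class].
#' @return data.frame with \code{v_gene}, \code{j_gene}, \code{cdr3_aa},
#'   \code{alleles}, \code{read_count}, \code{clonal_pct}, \code{status}.
#' @export
summarizeGeneLevel <- function(rset) {
  tab <- as.data.frame(rset@table)
  if (nrow(tab) == 0L)
    return(data.frame(v_gene = character(0), j_gene = character(0),
                      cdr3_aa = character(0), alleles = character(0),
                      read_count = integer(0), clonal_pct = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  if (!"cdr3_aa" %in% colnames(tab)) tab$cdr3_aa <- NA_character_
  if (!"status" %in% colnames(tab)) tab$status <- NA_character_
  key <- paste(.vGene(tab$v_allele),
               vapply(tab$j_allele, function(x) parseAlleleName(x)$gene, ""),
               ifelse(is.na(tab$cdr3_aa), "", tab$cdr3_aa), sep = "\r")
  rows <- lapply(split(seq_len(nrow(tab)), key), function(ix) {
    main <- ix[which.max(tab$read_count[ix])]
    data.frame(v_gene = .vGene(tab$v_allele[main]),
               j_gene = parseAlleleName(tab$j_allele[main])$gene,
               cdr3_aa = tab$cdr3_aa[main],
               alleles = paste(sort(unique(
                 paste0(tab$v_allele[ix], "_", tab$j_allele[ix]))),
                 collapse = ","),
               read_count = sum(tab$read_count[ix]),
               clonal_pct = NA_real_, status = tab$status[main],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$clonal_pct <- 100 * out$read_count / sum(out$read_count)
  out <- out[order(-out$read_count, out$v_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample-level quality control
#'
#' Clonal-track samples require more than \code{readFloor} reads assigned to
#' the major IG rearrangement (strict inequality); polyclonal-track samples
#' require at least \code{readFloor} reads surviving trimming. Failures are
#' reported with a reason, never silently dropped.
#'
#' @param track \code{"clonal"} or \code{"polyclonal"}.
#' @param majorReads reads assigned to the major rearrangement (clonal track).
#' @param trimmedReads reads surviving trimming (polyclonal track).
#' @param readFloor threshold (default 1000).
#' @return list with \code{pass} and \code{reason}.
#' @examples
#' sampleQc("clonal", majorReads = 1001)$pass
#' @export
sampleQc <- function(track = c("clonal", "polyclonal"), majorReads = NULL,
                     trimmedReads = NULL, readFloor = 1000L) {
  track <- match.arg(track)
  if (track == "clonal") {
    if (is.null(majorReads)) stop("majorReads required for the clonal track")
    if (majorReads > readFloor) return(list(pass = TRUE, reason = ""))
    return(list(pass = FALSE,
                reason = sprintf("major rearrangement has %d reads (> %d required)",
                                 majorReads, readFloor)))
  }
  if (is.null(trimmedReads)) stop("trimmedReads required for the polyclonal track")
  if (trimmedReads >= readFloor) return(list(pass = TRUE, reason = ""))
  list(pass = FALSE,
       reason = sprintf("%d trimmed reads (>= %d required)", trimmedReads,
                        readFloor))
}
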