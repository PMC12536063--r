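#' Parse an IMGT-style allele name
#'
#' Splits a name such as \code{"IGHV1-69*09"} into gene (\code{"IGHV1-69"}),
#' family (\code{"IGHV1"}), segment (\code{"V"}) and allele number
#' (\code{"09"}). Returns \code{NULL} when the name does not parse.
#'
#' @param name character(1) allele name.
#' @return list with \code{name}, \code{segment}, \code{family}, \code{gene},
#'   \code{allele_num}, or \code{NULL}.
#' @examples
#' parseAlleleName("IGHV1-69*09")
#' @export
parseAlleleName <- function(name) {
  if (length(name) != 1L || is.na(name)) return(NULL)
  if (!grepl("^IGH[VDJ]", name) || !grepl("*", name, fixed = TRUE)) return(NULL)
  parts <- strsplit(name, "*", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[2])) return(NULL)
  gene <- parts[1]
  fam <- regmatches(gene, regexpr("^IGH[VDJ][0-9]+", gene))
  if (!length(fam)) return(NULL)
  list(name = name, segment = substr(gene, 4, 4), family = fam,
       gene = gene, allele_num = parts[2])
}

.makeGermlineDb <- function(seqs, parsed) {
  info <- DataFrame(
    name = vapply(parsed, `[[`, "", "name"),
    segment = vapply(parsed, `[[`, "", "segment"),
    family = vapply(parsed, `[[`, "", "family"),
    gene = vapply(parsed, `[[`, "", "gene"),
    allele_num = vapply(parsed, `[[`, "", "allele_num"),
    length = Biostrings::width(seqs))
  names(seqs) <- info$name
  new("GermlineDb", sequences = seqs, info = info)
}

#' Load a germline V/D/J allele database from FASTA
#'
#' Reads a (possibly multi-line) FASTA of germline IGH alleles. The allele
#' name is taken from the first header token that contains \code{"IGH"} and a
#' \code{"*"}, splitting on pipes and whitespace, so plain
#' (\code{>IGHJ6*02}) and IMGT/GENE-DB-style
#' (\code{>X92343|IGHV1-69*09|Homo sapiens|...}) headers both work. Records
#' whose header yields no parseable allele name are skipped with a message.
#'
#' @param path path to a FASTA file.
#' @return a [GermlineDb-class] object.
#' @examples
#' fa <- system.file("extdata", "synthetic_igh_germline.fasta",
#'                   package = "IGHclonal")
#' db <- readGermlineDb(fa)
#' db
#' @export
readGermlineDb <- function(path) {
  if (!file.exists(path))
    stop("germline FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L)
    stop("no FASTA records in germline database: ", path)
  parsed <- lapply(names(seqs), function(h) {
    toks <- strsplit(h, "[|[:space:]]+")[[1]]
    toks <- toks[grepl("IGH", toks) & grepl("*", toks, fixed = TRUE)]
    for (t in toks) {
      p <- parseAlleleName(t)
      if (!is.null(p)) return(p)
    }
    NULL
  })
  keep <- !vapply(parsed, is.null, logical(1))
  if (!any(keep))
    stop("no parseable IGH allele names in germline database: ", path)
  if (any(!keep))
    message(sum(!keep), " record(s) with unparseable allele names skipped")
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs[keep])))
  if (any(grepl("[^ACGT]", as.character(seqs))))
    message("ambiguity codes in germline sequences replaced by A")
  seqs <- .sanitizeSeqs(seqs)
  db <- .makeGermlineDb(seqs, parsed[keep])
  validObject(db)
  db
}

#' Write a germline database back to FASTA
#'
#' Headers are the bare allele names; sequences are wrapped at 60 columns, so
#' a database round-trips through [readGermlineDb()] unchanged.
#'
#' @param db a [GermlineDb-class].
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeGermlineDb <- function(db, path) {
  Biostrings::writeXStringSet(db@sequences, path, width = 60L)
  invisible(path)
}

#' @describeIn readGermlineDb Summary table of the database (one row per
#'   allele: name, segment, family, gene, length), suitable for CSV export.
#' @export
dbSummary <- function(db) {
  as.data.frame(db@info)
}

#' Access alleles of a germline database
#'
#' \code{alleleInfo} returns the annotation table, \code{alleleSeqs} the
#' sequences (optionally restricted to one segment class), and
#' \code{getAllele} a single named allele as a \code{DNAString}.
#'
#' @param db a [GermlineDb-class].
#' @param segment optional \code{"V"}, \code{"D"} or \code{"J"}.
#' @return see each description.
#' @export
alleleInfo <- function(db, segment = NULL) {
  info <- db@info
  if (!is.null(segment)) info <- info[info$segment == segment, , drop = FALSE]
  info
}

#' @rdname alleleInfo
#' @export
alleleSeqs <- function(db, segment = NULL) {
  if (is.null(segment)) return(db@sequences)
  db@sequences[db@info$segment == segment]
}

#' @rdname alleleInfo
#' @param name allele name, e.g. \code{"IGHJ6*02"}.
#' @export
getAllele <- function(db, name) {
  if (!name %in% db@info$name)
    stop("allele not in database: ", name)
  db@sequences[[name]]
}

#' @export
setMethod("show", "GermlineDb", function(object) {
  tab <- table(factor(object@info$segment, levels = c("V", "D", "J")))
  cat("GermlineDb with", length(object@sequences), "alleles (",
      paste0(names(tab), ":", as.integer(tab), collapse = " "), ")\n")
  fams <- sort(unique(object@info$family))
  cat("families:", paste(fams, collapse = ", "), "\n")
})

#' Concatenate a V and a J allele into a rearrangement mapping reference
#'
#' Builds the joined reference used for per-rearrangement consensus mapping:
#' the V allele, a stretch of \code{gapLen} \code{N} bases standing in for the
#' unrepresented D/junction region, then the J allele. Coordinates of the gap
#' are returned 0-based, half-open, on the forward strand.
#'
#' @param v,j \code{DNAString}/character germline V and J sequences, or a
#'   [GermlineDb-class] plus allele names via \code{vName}/\code{jName}.
#' @param gapLen number of \code{N} placeholder bases (default 30).
#' @return list with \code{seq} (\code{DNAString}), \code{gap_start},
#'   \code{gap_end} (0-based half-open interval of the gap).
#' @examples
#' concatVJReference("ACGT", "TTAA", gapLen = 3)
#' @export
concatVJReference <- function(v, j, gapLen = 30L) {
  if (gapLen < 0) stop("gapLen must be >= 0")
  v <- as.character(v); j <- as.character(j)
  seq <- paste0(v, strrep("N", gapLen), j)
  list(seq = Biostrings::DNAString(seq),
       gap_start = nchar(v), gap_end = nchar(v) + as.integer(gapLen))
}

#' @rdname concatVJReference
#' @param db a [GermlineDb-class].
#' @param vName,jName allele names; segments are checked.
#' @export
concatVJAlleles <- function(db, vName, jName, gapLen = 30L) {
  info <- db@info
  segOf <- function(n) info$segment[match(n, info$name)]
  if (is.na(segOf(vName)) || segOf(vName) != "V")
    stop(vName, " is not a V allele")
  if (is.na(segOf(jName)) || segOf(jName) != "J")
    stop(jName, " is not a J allele")
  concatVJReference(getAllele(db, vName), getAllele(db, jName), gapLen)
}
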