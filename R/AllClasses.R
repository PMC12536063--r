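#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Germline V/D/J allele database
#'
#' Container for a set of germline IGH alleles: the allele sequences as a
#' \link[Biostrings]{DNAStringSet} plus a parsed annotation table with one row
#' per allele (name, segment, family, gene, allele number, length).
#'
#' Allele names follow the IMGT convention \code{<gene>*<allele>}, e.g.
#' \code{"IGHV1-69*09"}: the family is the leading \code{IGH<segment><digits>}
#' prefix (\code{"IGHV1"}) and the gene is everything before the \code{"*"}
#' (\code{"IGHV1-69"}).
#'
#' @slot sequences \code{DNAStringSet} of allele sequences, named by allele.
#' @slot info \code{DataFrame} with columns \code{name}, \code{segment}
#'   (one of \code{"V"}, \code{"D"}, \code{"J"}), \code{family}, \code{gene},
#'   \code{allele_num}, \code{length}.
#'
#' @seealso [readGermlineDb()], [syntheticGermlineDb()], [getAllele()]
#' @exportClass GermlineDb
setClass("GermlineDb",
         representation(sequences = "DNAStringSet", info = "DataFrame"))

setValidity("GermlineDb", function(object) {
  msgs <- character()
  info <- object@info
  need <- c("name", "segment", "family", "gene", "allele_num", "length")
  if (!all(need %in% colnames(info)))
    msgs <- c(msgs, paste("info must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(info$name))
      msgs <- c(msgs, "duplicate allele names")
    if (!all(info$segment %in% c("V", "D", "J")))
      msgs <- c(msgs, "segment must be V, D or J")
    if (length(object@sequences) != nrow(info))
      msgs <- c(msgs, "sequences and info disagree in length")
    else if (!identical(names(object@sequences), info$name))
      msgs <- c(msgs, "sequence names must match info$name")
    if (any(Biostrings::width(object@sequences) == 0L))
      msgs <- c(msgs, "empty allele sequence")
    ok <- startsWith(info$gene, info$family) & startsWith(info$name, info$gene)
    if (!all(ok))
      msgs <- c(msgs, "family must prefix gene and gene must prefix name")
  }
  if (length(msgs)) msgs else TRUE
})

#' Set of reconstructed IGH rearrangements for one sample
#'
#' One row per V-J rearrangement: the consensus sequence, junction insert,
#' read support broken down by amplicon fragment, and (once annotated)
#' germline V identity, mutational status, CDR3 and inferred IGHD.
#' Per-consensus-position read depths are kept in a parallel list.
#'
#' @slot sampleId sample identifier.
#' @slot table \code{DataFrame}, one row per rearrangement, with at least
#'   \code{id}, \code{v_allele}, \code{j_allele}, \code{consensus},
#'   \code{junction}, \code{read_count}, \code{frag_leader}, \code{frag_FR1},
#'   \code{frag_FR2}, \code{frag_FR3}, \code{clonal_pct}.
#' @slot depth list of integer vectors, one per rearrangement, giving the read
#'   depth at each consensus position.
#'
#' @seealso [buildRearrangements()], [annotateRearrangements()],
#'   [mergeByIdentity()], [computeProfile()]
#' @exportClass RearrangementSet
setClass("RearrangementSet",
         representation(sampleId = "character", table = "DataFrame",
                        depth = "list"))

setValidity("RearrangementSet", function(object) {
  msgs <- character()
  tab <- object@table
  need <- c("id", "v_allele", "j_allele", "consensus", "junction",
            "read_count", "frag_leader", "frag_FR1", "frag_FR2", "frag_FR3",
            "clonal_pct")
  if (!all(need %in% colnames(tab)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tab) > 0) {
    fr <- tab$frag_leader + tab$frag_FR1 + tab$frag_FR2 + tab$frag_FR3
    if ("frag_unknown" %in% colnames(tab)) fr <- fr + tab$frag_unknown
    if (!all(tab$read_count == fr))
      msgs <- c(msgs, "read_count must equal the sum of fragment support")
    if (length(object@depth) != nrow(tab))
      msgs <- c(msgs, "depth list must parallel the table")
    if (!all(is.na(tab$clonal_pct) | (tab$clonal_pct > 0 & tab$clonal_pct <= 100)))
      msgs <- c(msgs, "clonal_pct must lie in (0, 100]")
    if (!all(is.na(tab$clonal_pct)) &&
        sum(tab$clonal_pct, na.rm = TRUE) > 100 + 1e-6)
      msgs <- c(msgs, "clonal percentages exceed 100")
    bad <- grepl("-", tab$consensus, fixed = TRUE)
    if (any(bad))
      msgs <- c(msgs, "consensus must not contain gap characters")
    has_j <- nchar(tab$junction) == 0L |
      mapply(grepl, tab$junction, tab$consensus, MoreArgs = list(fixed = TRUE))
    if (!all(has_j))
      msgs <- c(msgs, "junction must be a substring of its consensus")
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-sample repertoire abundance profile
#'
#' Clone percentages ordered by decreasing abundance (clones below the noise
#' floor removed), the ratios between consecutive clones, and the MAX_DIFF
#' statistic: the maximum consecutive ratio, whose position is the candidate
#' clonal/subclonal cut-off. A profile reduced to a single clone has no
#' consecutive pair; its MAX_DIFF is \code{Inf}.
#'
#' @slot sampleId sample identifier.
#' @slot clonePcts numeric, descending clone percentages after filtering.
#' @slot cloneIds character, rearrangement ids parallel to \code{clonePcts}
#'   (may be empty placeholders for bare numeric profiles).
#' @slot ratios numeric, \code{clonePcts[i] / clonePcts[i + 1]}.
#' @slot maxDiff maximum of \code{ratios} (\code{Inf} for one clone,
#'   \code{NA} for an empty, unclassifiable profile).
#' @slot maxDiffPosition 1-based index of the first maximal ratio.
#'
#' @seealso [computeProfile()], [maxDiff()], [classifySample()]
#' @exportClass RepertoireProfile
setClass("RepertoireProfile",
         representation(sampleId = "character", clonePcts = "numeric",
                        cloneIds = "character", ratios = "numeric",
                        maxDiff = "numeric", maxDiffPosition = "integer"))

setValidity("RepertoireProfile", function(object) {
  msgs <- character()
  p <- object@clonePcts
  if (is.unsorted(rev(p)) && is.unsorted(-p))
    msgs <- c(msgs, "clonePcts must be in descending order")
  if (length(p) >= 2) {
    if (length(object@ratios) != length(p) - 1L)
      msgs <- c(msgs, "ratios must have length(clonePcts) - 1")
    else if (any(object@ratios < 1 - 1e-9))
      msgs <- c(msgs, "consecutive ratios must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted k-nearest-neighbour repertoire classifier
#'
#' Lazy KNN model over standardized per-sample features (by default
#' \code{log10(MAX_DIFF)} and the top-clone percentage). Prediction keeps the
#' training points and standardization parameters.
#'
#' @slot train numeric matrix of standardized training features.
#' @slot labels factor of training labels (\code{"clonal"}/\code{"polyclonal"}).
#' @slot center,scale per-feature standardization parameters.
#' @slot k number of neighbours.
#' @slot accuracy named numeric: train/test accuracy and cross-validated
#'   F1 summaries.
#'
#' @seealso [trainKnn()], [classifySample()]
#' @exportClass KnnClassifier
setClass("KnnClassifier",
         representation(train = "matrix", labels = "factor",
                        center = "numeric", scale = "numeric",
                        k = "integer", accuracy = "numeric"))

#' Repertoire structure call for one sample
#'
#' The verdict for a sample: \code{"polyclonal"}, \code{"<N>CLONE"} (N
#' rearrangements above the MAX_DIFF gap are clonal, the rest subclonal), or
#' \code{"unclassifiable"} when no clone survives the noise filter.
#'
#' @slot sampleId sample identifier.
#' @slot label \code{"polyclonal"}, \code{"1CLONE"}, \code{"2CLONE"}, ... or
#'   \code{"unclassifiable"}.
#' @slot nClones number of clonal rearrangements (0 when polyclonal).
#' @slot clonalIds,subclonalIds rearrangement ids above/below the cut-off.
#' @slot maxDiff the sample's MAX_DIFF value.
#' @slot features the feature vector given to the classifier.
#' @slot k neighbours used.
#' @slot nearThreshold TRUE when MAX_DIFF falls in the zone where the clonal
#'   groups overlap the decision boundary (flagged for manual review).
#'
#' @seealso [classifySample()]
#' @exportClass ClonalityCall
setClass("ClonalityCall",
         representation(sampleId = "character", label = "character",
                        nClones = "integer", clonalIds = "character",
                        subclonalIds = "character", maxDiff = "numeric",
                        features = "numeric", k = "integer",
                        nearThreshold = "logical"))

setValidity("ClonalityCall", function(object) {
  msgs <- character()
  if (grepl("^[0-9]+CLONE$", object@label)) {
    n <- as.integer(sub("CLONE$", "", object@label))
    if (n != object@nClones)
      msgs <- c(msgs, "label N must equal nClones")
    if (length(object@clonalIds) && length(object@clonalIds) != n)
      msgs <- c(msgs, "clonalIds must have length N")
  } else if (object@label == "polyclonal") {
    if (length(object@clonalIds))
      msgs <- c(msgs, "polyclonal call cannot carry clonal ids")
  }
  if (length(msgs)) msgs else TRUE
})
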