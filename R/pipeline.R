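#' Default pipeline configuration
#'
#' All thresholds the pipeline consults, in one flat list: quality floor and
#' minimum read length for trimming, minimum alignment score, minimum V-J
#' linking reads, consensus column depth, artifact-merge identity, FR3
#' dominance fraction, clone noise floor, sample read floor, coverage depth
#' floor, mutational-status thresholds, IGHD inference thresholds, KNN k,
#' the V-J reference gap length, the fragment anchor tolerance and the RNG
#' seed. Every key appears in the run manifest.
#'
#' @param ... overrides for any default key; unknown keys are rejected.
#' @return named list of configuration values.
#' @examples
#' cfg <- pipelineConfig(min_pct = 0.5)
#' cfg$q_floor
#' @export
pipelineConfig <- function(...) {
  cfg <- list(q_floor = 30L, min_len = 50L, min_score = 40,
              min_link_reads = 3L, min_depth = 2L,
              merge_identity = 95, fr3_frac = 0.92, min_pct = 0.1,
              read_floor = 1000L, depth_floor = 500L,
              um_threshold = 98, borderline_floor = 97,
              min_d_match = 8L, min_d_identity = 80,
              k = 3L, gap_len = 30L, fragment_tolerance = 25L,
              seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, dots)
}

#' Run the pipeline on one sample
#'
#' Executes trimming, V/J assignment, fragment labelling, V-J pairing,
#' consensus building, annotation, artifact filtering and profile
#' computation for one paired read set, and collects per-stage read counts
#' for the run manifest.
#'
#' @param R1,R2 \code{QualityScaledDNAStringSet}s of paired reads.
#' @param db a [GermlineDb-class].
#' @param config list from [pipelineConfig()].
#' @param sampleId sample name.
#' @param amplicons amplicon definitions for fragment labelling.
#' @return list with \code{rearrangements} (filtered, annotated
#'   [RearrangementSet-class]), \code{geneReport}, \code{profile},
#'   \code{alleleCounts}, \code{mergeEvents}, \code{qc}, \code{stageCounts}.
#' @export
runSample <- function(R1, R2, db, config = pipelineConfig(),
                      sampleId = "sample", amplicons = defaultAmplicons()) {
  asg <- assignSample(R1, R2, db, qFloor = config$q_floor,
                      minLen = config$min_len, minScore = config$min_score)
  asg$assignments <- labelFragments(asg$assignments, db, amplicons,
                                    tolerance = config$fragment_tolerance)
  counts <- alleleReadCounts(asg$assignments)
  rset <- buildRearrangements(asg$assignments, asg$trimmedR1, asg$trimmedR2,
                              db, sampleId = sampleId,
                              minLinkReads = config$min_link_reads,
                              minDepth = config$min_depth,
                              minScore = config$min_score)
  rset <- annotateRearrangements(rset, db,
                                 umThreshold = config$um_threshold,
                                 borderlineFloor = config$borderline_floor,
                                 minDMatch = config$min_d_match,
                                 minDIdentity = config$min_d_identity)
  flt <- filterArtifacts(rset, threshold = config$merge_identity,
                         fr3Frac = config$fr3_frac)
  rset <- flt$rearrangements
  profile <- computeProfile(rset, minPct = config$min_pct)
  majorReads <- if (nrow(rset@table)) max(rset@table$read_count) else 0L
  qc <- sampleQc("clonal", majorReads = majorReads,
                 readFloor = config$read_floor)
  stageCounts <- c(input_pairs = length(R1),
                   trimmed_reads = asg$n_trimmed_reads,
                   assigned_reads = sum(asg$assignments$assigned),
                   rearrangement_reads = sum(rset@table$read_count),
                   rearrangements = nrow(rset@table))
  list(rearrangements = rset, geneReport = summarizeGeneLevel(rset),
       profile = profile, alleleCounts = counts,
       mergeEvents = flt$events, qc = qc, stageCounts = stageCounts)
}

#' Run the pipeline over a batch of samples
#'
#' Applies [runSample()] to each sample; a hard error in one sample aborts
#' that sample only and is reported as a failure row while the batch
#' continues. Optionally classifies each sample's profile and writes the
#' report bundle to \code{outDir}.
#'
#' @param samples named list; each element a list with \code{R1}, \code{R2}
#'   (read sets) or \code{r1}, \code{r2} (FASTQ paths).
#' @param db a [GermlineDb-class] or path to a germline FASTA.
#' @param config list from [pipelineConfig()].
#' @param classifier optional [KnnClassifier-class] for clonality calls.
#' @param outDir optional output directory for CSV reports.
#' @param amplicons amplicon definitions.
#' @return named list of per-sample results (each as in [runSample()], plus
#'   \code{call} when a classifier is given); failed samples carry
#'   \code{error} instead.
#' @export
runPipeline <- function(samples, db, config = pipelineConfig(),
                        classifier = NULL, outDir = NULL,
                        amplicons = defaultAmplicons()) {
  if (is.character(db)) db <- readGermlineDb(db)
  results <- list()
  for (nm in names(samples)) {
    s <- samples[[nm]]
    res <- tryCatch({
      if (!is.null(s$r1)) {
        rd <- readFastqPair(s$r1, s$r2)
        s$R1 <- rd$R1; s$R2 <- rd$R2
      }
      out <- runSample(s$R1, s$R2, db, config, sampleId = nm,
                       amplicons = amplicons)
      if (!is.null(classifier))
        out$call <- classifySample(out$profile, classifier)
      out
    }, error = function(e) list(error = conditionMessage(e)))
    results[[nm]] <- res
  }
  if (!is.null(outDir)) writeReports(results, outDir, config)
  results
}

.profileTable <- function(profile) {
  n <- length(profile@clonePcts)
  data.frame(sample = profile@sampleId, rank = seq_len(n),
             id = profile@cloneIds, clone_pct = profile@clonePcts,
             ratio_to_next = c(profile@ratios, NA_real_)[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Write the per-batch report bundle
#'
#' Emits, per sample, the consensus FASTA (records named
#' \code{sample|Vallele_Jallele}) and CSVs for rearrangements, gene-level
#' summary, allele counts, profile, merge events and (when present)
#' classification, plus a run manifest listing every configuration value
#' and per-stage read counts. Column order is fixed so reruns with the same
#' seed and config are byte-identical.
#'
#' @param results list from [runPipeline()].
#' @param outDir output directory (created if needed).
#' @param config the configuration used (recorded in the manifest).
#' @return \code{outDir}, invisibly.
#' @export
writeReports <- function(results, outDir, config = pipelineConfig()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(outDir, f),
                                          row.names = FALSE, quote = TRUE)
  manifest <- c(paste0("package_version: ",
                       as.character(utils::packageVersion("IGHclonal"))),
               paste0(names(config), ": ",
                      vapply(config, function(x)
                        paste(format(x), collapse = ","), "")))
  rearr <- list(); gene <- list(); prof <- list(); calls <- list()
  merges <- list(); counts <- list()
  for (nm in names(results)) {
    res <- results[[nm]]
    if (!is.null(res$error)) {
      manifest <- c(manifest, paste0("sample_failed: ", nm, " -- ",
                                     res$error))
      next
    }
    tab <- as.data.frame(res$rearrangements@table)
    tab$mutations <- NULL
    tab$coverage_breadth <- coverageBreadth(res$rearrangements,
                                            config$depth_floor)
    rearr[[nm]] <- cbind(sample = nm, tab)
    if (nrow(tab)) {
      fa <- Biostrings::DNAStringSet(tab$consensus)
      names(fa) <- paste0(nm, "|", tab$id)
      Biostrings::writeXStringSet(fa, file.path(outDir,
                                                paste0(nm, "_consensus.fasta")),
                                  width = 60L)
    }
    gene[[nm]] <- cbind(sample = nm, res$geneReport)
    prof[[nm]] <- .profileTable(res$profile)
    if (nrow(res$mergeEvents))
      merges[[nm]] <- cbind(sample = nm, res$mergeEvents)
    if (nrow(res$alleleCounts))
      counts[[nm]] <- cbind(sample = nm, res$alleleCounts)
    if (!is.null(res$call)) {
      cl <- res$call
      calls[[nm]] <- data.frame(sample = nm, label = cl@label,
                                n_clones = cl@nClones,
                                max_diff = cl@maxDiff,
                                log10_max_diff = unname(cl@features[1]),
                                top_clone_pct = unname(cl@features[2]),
                                near_threshold = cl@nearThreshold,
                                stringsAsFactors = FALSE)
    }
    manifest <- c(manifest, paste0("sample: ", nm, " stages: ",
                                   paste(names(res$stageCounts),
                                         res$stageCounts, sep = "=",
                                         collapse = " ")))
  }
  bind <- function(l) if (length(l)) do.call(rbind, unname(l)) else NULL
  if (!is.null(d <- bind(rearr))) wcsv(d, "rearrangements.csv")
  if (!is.null(d <- bind(gene))) wcsv(d, "gene_report.csv")
  if (!is.null(d <- bind(prof))) wcsv(d, "profiles.csv")
  if (!is.null(d <- bind(merges))) wcsv(d, "merge_events.csv")
  if (!is.null(d <- bind(counts))) wcsv(d, "allele_counts.csv")
  if (!is.null(d <- bind(calls))) wcsv(d, "classification.csv")
  writeLines(manifest, file.path(outDir, "run_manifest.txt"))
  invisible(outDir)
}
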