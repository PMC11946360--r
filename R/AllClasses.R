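#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

VARIANT_CATEGORIES <- c("CDS_1BP", "NONCODING_1BP", "LARGER")

INHERITANCE_MODES <- c("AUTOSOMAL_RECESSIVE", "AUTOSOMAL_DOMINANT",
                       "X_LINKED", "MITOCHONDRIAL", "COMPLEX", "UNKNOWN")

CALL_STATUSES <- c("WILDTYPE", "CARRIER", "HOMOZYGOUS_ALT", "HEMIZYGOUS_ALT",
                   "MITO_PRESENT", "NOT_ASSESSABLE")

EXCLUSION_REASONS <- c("NO_GENOMIC_LOCATION", "WRONG_BUILD",
                       "BAD_GENE_SYMBOL", "SIZE_GT_MAX")

#' CurationReport: bookkeeping for catalogue curation
#'
#' Records how many raw catalogue entries were excluded at each curation
#' stage and why. Stage 1 collects annotation failures (no parseable
#' genomic/mitochondrial location, wrong reference build, missing or
#' malformed gene symbol); stage 2 collects size failures (indels larger
#' than the panel's size cutoff). Every excluded record carries exactly one
#' primary reason code, and \code{nInput = nExcludedStage1 +
#' nExcludedStage2 + nRetained} always holds (enforced by the validity
#' method).
#'
#' @slot nInput Number of raw records read.
#' @slot nExcludedStage1 Records failing the annotation criteria.
#' @slot nExcludedStage2 Records failing the size criterion.
#' @slot nRetained Records converted to curated panel variants.
#' @slot exclusions \code{data.frame} with columns \code{record_id},
#'   \code{reason} (one of \code{NO_GENOMIC_LOCATION}, \code{WRONG_BUILD},
#'   \code{BAD_GENE_SYMBOL}, \code{SIZE_GT_MAX}).
#' @export
setClass("CurationReport",
  representation(nInput = "integer", nExcludedStage1 = "integer",
                 nExcludedStage2 = "integer", nRetained = "integer",
                 exclusions = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (object@nInput !=
        object@nExcludedStage1 + object@nExcludedStage2 + object@nRetained)
      msg <- c(msg, "counts do not reconcile: nInput != stage1 + stage2 + retained")
    if (nrow(object@exclusions) !=
        object@nExcludedStage1 + object@nExcludedStage2)
      msg <- c(msg, "exclusion table length does not match exclusion counts")
    if (nrow(object@exclusions) &&
        !all(object@exclusions$reason %in% EXCLUSION_REASONS))
      msg <- c(msg, "unknown exclusion reason code")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "CurationReport", function(object) {
  cat("CurationReport\n")
  cat("  raw records:           ", object@nInput, "\n")
  cat("  excluded (annotation): ", object@nExcludedStage1, "\n")
  cat("  excluded (size):       ", object@nExcludedStage2, "\n")
  cat("  retained:              ", object@nRetained, "\n")
  if (nrow(object@exclusions)) {
    tab <- table(object@exclusions$reason)
    for (r in names(tab)) cat("    ", r, ": ", tab[[r]], "\n", sep = "")
  }
})

#' @describeIn CurationReport Number of raw input records.
#' @param object A \code{CurationReport}.
#' @export
setGeneric("nInput", function(object) standardGeneric("nInput"))
#' @export
setMethod("nInput", "CurationReport", function(object) object@nInput)

#' @describeIn CurationReport Number of retained (curated) records.
#' @export
setGeneric("nRetained", function(object) standardGeneric("nRetained"))
#' @export
setMethod("nRetained", "CurationReport", function(object) object@nRetained)

#' @describeIn CurationReport Exclusion table (record_id, reason).
#' @export
setGeneric("exclusions", function(object) standardGeneric("exclusions"))
#' @export
setMethod("exclusions", "CurationReport", function(object) object@exclusions)

#' DepthTrack: per-base sequencing depth for one sample
#'
#' Sparse map from (chromosome, 1-based position) to read depth. Positions
#' absent from the track have depth 0, so lookups never fail and loci that
#' received no reads at all ("range: 0x") are representable without
#' sentinels.
#'
#' @slot sampleId Sample identifier.
#' @slot depth Named integer vector; names are \code{"chrom:pos"} keys.
#' @export
setClass("DepthTrack",
  representation(sampleId = "character", depth = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
      msg <- c(msg, "sampleId must be a single non-empty string")
    if (length(object@depth) && any(object@depth < 0L))
      msg <- c(msg, "depths must be non-negative")
    if (length(object@depth) && is.null(names(object@depth)))
      msg <- c(msg, "depth vector must be named by chrom:pos")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "DepthTrack", function(object) {
  cat("DepthTrack for sample", object@sampleId, "-",
      length(object@depth), "positions\n")
})

#' @describeIn DepthTrack Sample identifier of a track.
#' @param object A \code{DepthTrack}.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @export
setMethod("sampleId", "DepthTrack", function(object) object@sampleId)

#' QualificationMatrix: sample x variant x threshold depth qualification
#'
#' A \linkS4class{SummarizedExperiment} with variants as rows, samples as
#' columns, and one logical assay per depth threshold (named
#' \code{"ge<threshold>"}). A cell is \code{TRUE} when every base of the
#' variant span reached the threshold in that sample. The validity method
#' enforces threshold monotonicity: qualification at 30x implies 20x
#' implies 10x.
#'
#' @export
setClass("QualificationMatrix", contains = "SummarizedExperiment",
  validity = function(object) {
    th <- qualThresholds(object)
    if (!length(th)) return("no threshold assays (expected names like 'ge10')")
    th <- sort(th)
    for (i in seq_along(th)[-1]) {
      hi <- SummarizedExperiment::assay(object, paste0("ge", th[i]))
      lo <- SummarizedExperiment::assay(object, paste0("ge", th[i - 1]))
      if (any(hi & !lo, na.rm = TRUE))
        return(sprintf("monotonicity violated: qualified at %dx but not %dx",
                       th[i], th[i - 1]))
    }
    TRUE
  })

#' @describeIn QualificationMatrix Depth thresholds covered by the matrix.
#' @param object A \code{QualificationMatrix}.
#' @export
setGeneric("qualThresholds", function(object) standardGeneric("qualThresholds"))
#' @export
setMethod("qualThresholds", "QualificationMatrix", function(object) {
  nm <- SummarizedExperiment::assayNames(object)
  sort(as.integer(sub("^ge", "", nm[grepl("^ge[0-9]+$", nm)])))
})

#' @describeIn QualificationMatrix Logical variant x sample matrix at one
#'   threshold.
#' @param threshold Depth cutoff (must be one of \code{qualThresholds}).
#' @export
setGeneric("isQualified", function(object, threshold) standardGeneric("isQualified"))
#' @export
setMethod("isQualified", "QualificationMatrix", function(object, threshold) {
  nm <- paste0("ge", as.integer(threshold))
  if (!nm %in% SummarizedExperiment::assayNames(object))
    stop("no qualification assay at threshold ", threshold)
  SummarizedExperiment::assay(object, nm)
})

setMethod("show", "QualificationMatrix", function(object) {
  cat("QualificationMatrix:", nrow(object), "variants x", ncol(object),
      "samples; thresholds:",
      paste0(">=", qualThresholds(object), "x", collapse = ", "), "\n")
})

#' DetectionMatrix: screened genotypes for every sample x panel variant
#'
#' A \linkS4class{SummarizedExperiment} with panel variants as rows
#' (rowData carries the curated catalogue columns) and samples as columns
#' (colData carries sex and breed). Assays: \code{altCount} — matched
#' alternate-allele dosage (\code{NA} when the call is not assessable) —
#' and \code{status} — interpreted zygosity (\code{WILDTYPE},
#' \code{CARRIER}, \code{HOMOZYGOUS_ALT}, \code{HEMIZYGOUS_ALT},
#' \code{MITO_PRESENT}, \code{NOT_ASSESSABLE}).
#'
#' @export
setClass("DetectionMatrix", contains = "SummarizedExperiment",
  validity = function(object) {
    an <- SummarizedExperiment::assayNames(object)
    msg <- NULL
    if (!all(c("altCount", "status") %in% an))
      msg <- c(msg, "assays 'altCount' and 'status' are required")
    else {
      st <- SummarizedExperiment::assay(object, "status")
      ac <- SummarizedExperiment::assay(object, "altCount")
      if (!all(st %in% CALL_STATUSES))
        msg <- c(msg, "unknown call status")
      if (any(is.na(ac) != (st == "NOT_ASSESSABLE")))
        msg <- c(msg, "altCount must be NA exactly for NOT_ASSESSABLE calls")
    }
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn DetectionMatrix Integer alt-allele dosage matrix
#'   (variants x samples, NA = not assessable).
#' @param object A \code{DetectionMatrix}.
#' @export
setGeneric("altCounts", function(object) standardGeneric("altCounts"))
#' @export
setMethod("altCounts", "DetectionMatrix", function(object)
  SummarizedExperiment::assay(object, "altCount"))

#' @describeIn DetectionMatrix Character matrix of interpreted zygosity
#'   statuses.
#' @export
setGeneric("callStatus", function(object) standardGeneric("callStatus"))
#' @export
setMethod("callStatus", "DetectionMatrix", function(object)
  SummarizedExperiment::assay(object, "status"))

setMethod("show", "DetectionMatrix", function(object) {
  ac <- altCounts(object)
  cat("DetectionMatrix:", nrow(object), "panel variants x", ncol(object),
      "samples\n")
  cat("  assessable calls:", sum(!is.na(ac)), "/", length(ac), "\n")
  cat("  non-reference calls:", sum(ac >= 1L, na.rm = TRUE), "\n")
})

#' ScreeningReport: clinical-style screening summary for one sample
#'
#' Captures the reportable range (fraction of the panel whose variant span
#' qualified at the reporting depth threshold), the loci that could not be
#' assessed (below-threshold depth or failed variant filters) and the
#' non-wildtype findings grouped by inheritance mode.
#'
#' @slot sampleId Sample identifier.
#' @slot threshold Reporting depth threshold (x coverage).
#' @slot reportableRange Fraction of panel variants qualified at the
#'   threshold, in [0, 1].
#' @slot unassessable \code{data.frame(record_id, reason)} with reasons
#'   \code{BELOW_DEPTH} or \code{FILTER_FAIL} (or \code{NO_CALL}).
#' @slot findings \code{data.frame} of calls with status other than
#'   \code{WILDTYPE} / \code{NOT_ASSESSABLE}, one row per panel variant.
#' @slot breakdown per-category qualification counts underlying the
#'   reportable range.
#' @export
setClass("ScreeningReport",
  representation(sampleId = "character", threshold = "integer",
                 reportableRange = "numeric", unassessable = "data.frame",
                 findings = "data.frame", breakdown = "data.frame"),
  validity = function(object) {
    if (object@reportableRange < 0 || object@reportableRange > 1)
      return("reportableRange must lie in [0, 1]")
    TRUE
  })

setMethod("show", "ScreeningReport", function(object) {
  cat("ScreeningReport -- sample", object@sampleId, "\n")
  cat(sprintf("  reportable range at >=%dx: %.2f%% of panel\n",
              object@threshold, 100 * object@reportableRange))
  cat("  loci not assessable:", nrow(object@unassessable), "\n")
  cat("  findings:", nrow(object@findings), "\n")
  if (nrow(object@findings)) {
    f <- object@findings
    for (mode in unique(f$inheritance)) {
      sub <- f[f$inheritance == mode, , drop = FALSE]
      cat("   ", mode, ":\n")
      for (i in seq_len(nrow(sub)))
        cat("      ", sub$gene[i], " (", sub$record_id[i], ") ",
            sub$status[i], "\n", sep = "")
    }
  }
})

#' @describeIn ScreeningReport Reportable-range fraction of a report.
#' @param object A \code{ScreeningReport}.
#' @export
setGeneric("reportableRange", function(object) standardGeneric("reportableRange"))
#' @export
setMethod("reportableRange", "ScreeningReport", function(object)
  object@reportableRange)

#' @describeIn ScreeningReport Non-wildtype findings table.
#' @export
setGeneric("findings", function(object) standardGeneric("findings"))
#' @export
setMethod("findings", "ScreeningReport", function(object) object@findings)

#' @describeIn ScreeningReport Table of loci that could not be assessed.
#' @export
setGeneric("unassessableLoci", function(object) standardGeneric("unassessableLoci"))
#' @export
setMethod("unassessableLoci", "ScreeningReport", function(object)
  object@unassessable)
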