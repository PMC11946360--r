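## Clinical-style screening reports and the end-to-end pipeline driver.
##
## A screening report for one sample states the reportable range (the
## fraction of the panel for which a reliable genotype could be
## generated at the reporting depth threshold), enumerates the loci that
## could not be assessed — below-threshold depth or failed variant
## filters — and lists the non-wildtype findings grouped by inheritance
## mode, so recessive carrier results (usable in breeding) stand apart
## from dominant/X-linked/mitochondrial findings.

#' Build the screening report for one sample
#'
#' @param sample Sample identifier (must be a column of both matrices).
#' @param variants Curated catalogue \code{data.frame}.
#' @param qm \linkS4class{QualificationMatrix} for the cohort.
#' @param dm \linkS4class{DetectionMatrix} from \code{\link{scanVcf}}.
#' @param threshold Reporting depth threshold (default 10; there is no
#'   field-wide consensus on a minimal depth, so this is a parameter,
#'   not a constant).
#' @return A \linkS4class{ScreeningReport}. Its unassessable-locus list
#'   is exactly the panel variants whose span did not qualify at the
#'   threshold plus the variants sitting in filter-failed or uncalled
#'   VCF records, so \code{|panel| = |qualified| + |below-depth loci|}
#'   always reconciles.
#' @export
buildReport <- function(sample, variants, qm, dm, threshold = 10) {
  stopifnot(is(qm, "QualificationMatrix"), is(dm, "DetectionMatrix"))
  if (!sample %in% colnames(qm) || !sample %in% colnames(dm))
    stop("unknown sample: ", sample)
  qual <- isQualified(qm, threshold)[variants$record_id, sample]
  status <- callStatus(dm)[variants$record_id, sample]
  ac <- altCounts(dm)[variants$record_id, sample]
  fp <- SummarizedExperiment::assay(dm, "filterPass")[variants$record_id,
                                                      sample]

  reason <- rep(NA_character_, nrow(variants))
  reason[!qual] <- "BELOW_DEPTH"
  reason[is.na(reason) & status == "NOT_ASSESSABLE" & !is.na(fp) & !fp] <-
    "FILTER_FAIL"
  reason[is.na(reason) & status == "NOT_ASSESSABLE"] <- "NO_CALL"
  unassessable <- data.frame(
    record_id = variants$record_id[!is.na(reason)],
    reason = reason[!is.na(reason)], stringsAsFactors = FALSE)

  isFinding <- !status %in% c("WILDTYPE", "NOT_ASSESSABLE")
  findings <- data.frame(
    record_id = variants$record_id[isFinding],
    gene = variants$gene[isFinding],
    phene = variants$phene[isFinding],
    inheritance = variants$inheritance[isFinding],
    status = status[isFinding],
    alt_count = ac[isFinding], stringsAsFactors = FALSE)
  findings <- findings[order(findings$inheritance, findings$gene), ,
                       drop = FALSE]
  rownames(findings) <- NULL

  breakdown <- do.call(rbind, lapply(split(seq_len(nrow(variants)),
                                           variants$category),
    function(idx) data.frame(category = variants$category[idx[1]],
                             n_variants = length(idx),
                             n_qualified = sum(qual[idx]),
                             pct_qualified = asPct(sum(qual[idx]),
                                                   length(idx)))))
  rownames(breakdown) <- NULL

  rep <- new("ScreeningReport", sampleId = sample,
             threshold = as.integer(threshold),
             reportableRange = sum(qual) / nrow(variants),
             unassessable = unassessable, findings = findings,
             breakdown = breakdown)
  validObject(rep)
  rep
}

#' Run the whole screening pipeline from a configuration
#'
#' Executes catalogue curation, depth qualification, VCF screening,
#' accumulation analysis and per-sample reporting, writing every output
#' as TSV/JSON into the configured output directory. The configuration
#' is a list (or path to a YAML file) with entries:
#' \describe{
#'   \item{catalogue}{path to the raw catalogue TSV (mandatory)}
#'   \item{depth_dir}{directory of per-sample \code{<sample>.depth.tsv}
#'     files (mandatory)}
#'   \item{vcf}{path to the multi-sample VCF (mandatory)}
#'   \item{metadata}{path to the sample metadata TSV (mandatory)}
#'   \item{out_dir}{output directory (mandatory)}
#'   \item{accepted_build, max_size, design_year, thresholds,
#'     reporting_threshold, accumulation (list: step, n_replicates,
#'     seed, mode)}{optional overrides of the documented defaults}
#' }
#'
#' @param config List or path to a YAML configuration file.
#' @return Invisible list with the main in-memory results (curated
#'   catalogue, qualification matrix, detection matrix, accumulation
#'   curve, report objects) and the written paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (must in c("catalogue", "depth_dir", "vcf", "metadata", "out_dir"))
    if (is.null(config[[must]]))
      stop("configuration error: '", must, "' is required")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  thresholds <- config$thresholds %||% c(10L, 20L, 30L)
  repThr <- config$reporting_threshold %||% 10L
  accCfg <- config$accumulation %||% list()

  .msg("curating catalogue")
  raw <- readCatalogue(config$catalogue)
  cur <- curateCatalogue(raw,
                         acceptedBuild = config$accepted_build %||% "CanFam3.1",
                         maxSize = config$max_size %||% 20)
  variants <- cur$variants
  writeCatalogue(variants, file.path(out, "catalogue_curated.tsv"))
  writeCurationReport(cur$report,
                      jsonPath = file.path(out, "curation_report.json"),
                      txtPath = file.path(out, "curation_report.txt"))

  .msg("reading metadata and depth tracks")
  metadata <- read.delim(config$metadata, colClasses = "character")
  tracks <- lapply(metadata$sample_id, function(s) {
    p <- file.path(config$depth_dir, paste0(s, ".depth.tsv"))
    if (!file.exists(p)) stop("depth track missing for sample ", s)
    readDepthTrack(p, sampleId = s)
  })
  names(tracks) <- metadata$sample_id

  .msg("qualifying panel loci by depth")
  qm <- qualifyPanel(tracks, variants, thresholds)
  writeQualification(qm, file.path(out, "qualification.tsv"))
  write.table(categoryTable(qm),
              file.path(out, "per_sample_performance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pvd <- perVariantDepth(tracks, variants)
  write.table(categoryDepthSummary(pvd),
              file.path(out, "per_variant_depth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## post-design-year reanalysis
  post <- splitByYear(variants, config$design_year %||% 2014)$post
  if (nrow(post)) {
    qmPost <- qm[post$record_id, ]
    qmPost <- new("QualificationMatrix", qmPost)
    write.table(categoryTable(qmPost),
                file.path(out, "per_sample_performance_post_design.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  .msg("screening VCF for panel variants")
  dm <- scanVcf(config$vcf, variants, metadata, qualification = qm,
                threshold = repThr)
  write.table(genotypeCalls(dm), file.path(out, "genotype_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (diseaseOnly in c(FALSE, TRUE)) {
    s <- perDogSummary(dm, diseaseOnly = diseaseOnly)
    write.table(s$histogram,
                file.path(out, paste0("per_dog_histogram",
                                      if (diseaseOnly) "_disease",
                                      ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  .msg("computing accumulation curve")
  curve <- accumulationCurve(dm,
                             sizes = accCfg$sizes %||% NULL,
                             nReplicates = accCfg$n_replicates %||% 100,
                             seed = accCfg$seed %||% 1,
                             mode = accCfg$mode %||% "NESTED",
                             diseaseOnly = TRUE)
  write.table(curve, file.path(out, "accumulation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  grDevices::pdf(file.path(out, "accumulation.pdf"), width = 6, height = 5)
  plotAccumulation(curve)
  grDevices::dev.off()

  .msg("building per-sample reports")
  reports <- lapply(metadata$sample_id, function(s)
    buildReport(s, variants, qm, dm, threshold = repThr))
  names(reports) <- metadata$sample_id
  repJson <- lapply(reports, function(r)
    list(sample_id = r@sampleId, threshold = r@threshold,
         reportable_range = r@reportableRange,
         unassessable = r@unassessable, findings = r@findings))
  jsonlite::write_json(repJson, file.path(out, "screening_reports.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  .msg("pipeline finished; outputs in ", out)
  invisible(list(variants = variants, report = cur$report, qm = qm,
                 dm = dm, curve = curve, reports = reports,
                 out_dir = out))
}
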