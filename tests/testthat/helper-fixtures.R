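# Shared fixture builders. Everything is generated in code; no data files.

# minimal raw catalogue row with every field valid; override via ...
rawRecord <- function(record_id = "R1", ...) {
  rec <- data.frame(
    record_id = record_id, gene = "MYGENE", location = "g.1000",
    build = "CanFam3.1", ref = "A", alt = "G", chromosome = "chr1",
    location_class = "CDS", inheritance = "autosomal recessive",
    year = "2010", phene = "test trait", is_disease = "yes",
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

writeRawTsv <- function(records) {
  path <- tempfile(fileext = ".tsv")
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# curated variant row (as curateCatalogue would emit)
curatedVariant <- function(record_id = "V1", chromosome = "chr1",
                           position = 1000L, ref = "A", alt = "G",
                           category = "CDS_1BP",
                           inheritance = "AUTOSOMAL_RECESSIVE",
                           year = 2010L, is_disease = TRUE,
                           gene = "MYGENE") {
  data.frame(record_id = record_id, gene = gene, chromosome = chromosome,
             position = position, ref = ref, alt = alt,
             size_bp = max(nchar(ref), nchar(alt)),
             category = category, inheritance = inheritance,
             year = year, phene = "trait", is_disease = is_disease,
             stringsAsFactors = FALSE)
}

# flat-depth track covering positions around the fixture variants
flatTrack <- function(sampleId, depth, chrom = "chr1",
                      pos = 990:1030) {
  DepthTrack(sampleId, rep(chrom, length(pos)), pos,
             rep(depth, length(pos)))
}

# DetectionMatrix built directly from a dosage matrix (variants x samples)
makeDetectionMatrix <- function(dosage, variants = NULL, sex = NULL) {
  nV <- nrow(dosage); nS <- ncol(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("V%02d", seq_len(nV))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("s%02d", seq_len(nS))
  if (is.null(variants))
    variants <- do.call(rbind, lapply(seq_len(nV), function(i)
      curatedVariant(rownames(dosage)[i], position = 1000L + 100L * i)))
  if (is.null(sex)) sex <- rep("female", nS)
  status <- matrix("NOT_ASSESSABLE", nV, nS, dimnames = dimnames(dosage))
  for (j in seq_len(nV)) for (s in seq_len(nS))
    status[j, s] <- interpretZygosity(dosage[j, s],
                                      variants$inheritance[j], sex[s],
                                      variants$chromosome[j])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(altCount = dosage, status = status,
                  filterPass = !is.na(dosage)),
    rowData = S4Vectors::DataFrame(variants,
                                   row.names = rownames(dosage)),
    colData = S4Vectors::DataFrame(
      sample_id = colnames(dosage), sex = sex,
      row.names = colnames(dosage)))
  new("DetectionMatrix", se)
}

# a small cohort used by several end-to-end tests (cached per session)
smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "small_cohort")
      meta <- defaultMetadata()[1:12, ]
      cache <<- simulateCohort(
        dir, seed = 42, metadata = meta,
        nCds = 30, nNoncoding = 4, nLarger = 10, nDisease = 38,
        postDesignMix = c(CDS_1BP = 12, NONCODING_1BP = 2, LARGER = 4),
        nXLinked = 3, nMito = 1,
        nInvalidPerReason = c(NO_GENOMIC_LOCATION = 2, WRONG_BUILD = 2,
                              BAD_GENE_SYMBOL = 2, SIZE_GT_MAX = 2))
    }
    cache
  }
})
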