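## Catalogue parsing, curation and classification.
##
## The raw input is an OMIA-style delimited table of phenotype-associated
## variants. Entries are retained only when (1) they carry a parseable
## genomic ("g.<pos>") or mitochondrial ("m.<pos>") location, (2) they are
## annotated on the accepted reference build, (3) the gene symbol is
## present and well-formed, and (4) the variant is at most 20 bp. Retained
## entries are classified into three categories driving all downstream
## summaries: 1 bp variants in coding sequence, 1 bp variants in
## intronic/UTR/promoter context, and larger (2-20 bp) variants.

.CATALOGUE_COLUMNS <- c("record_id", "gene", "location", "build", "ref",
                        "alt", "chromosome", "location_class",
                        "inheritance", "year", "phene", "is_disease")

#' Read a raw variant catalogue
#'
#' Parses a delimited OMIA-style table into raw records without any
#' validation beyond column presence; malformed rows are the business of
#' \code{\link{curateCatalogue}}, not of the parser. Row order is
#' preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect List with \code{sep} (field delimiter, default tab) and
#'   optionally \code{columns}, a named character vector mapping canonical
#'   column names (\code{record_id}, \code{gene}, \code{location},
#'   \code{build}, \code{ref}, \code{alt}, \code{chromosome},
#'   \code{location_class}, \code{inheritance}, \code{year}, \code{phene},
#'   \code{is_disease}) to the header names actually used in the file.
#' @return \code{data.frame} of raw records with canonical column names,
#'   one row per input data row. Missing optional fields become \code{NA};
#'   only \code{record_id} and \code{location} are mandatory columns.
#' @export
readCatalogue <- function(path, dialect = list(sep = "\t")) {
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  sep <- if (is.null(dialect$sep)) "\t" else dialect$sep
  raw <- read.delim(path, sep = sep, header = TRUE,
                    colClasses = "character", na.strings = character(),
                    check.names = FALSE, quote = "")
  map <- dialect$columns
  if (!is.null(map)) {
    for (canon in names(map)) {
      if (!map[[canon]] %in% names(raw))
        stop("configured column '", map[[canon]], "' (", canon,
             ") absent from catalogue header")
      names(raw)[names(raw) == map[[canon]]] <- canon
    }
  }
  for (must in c("record_id", "location"))
    if (!must %in% names(raw))
      stop("mandatory column '", must, "' absent from catalogue header")
  for (col in .CATALOGUE_COLUMNS)
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  if (anyDuplicated(raw$record_id))
    stop("record_id values are not unique")
  raw[, .CATALOGUE_COLUMNS, drop = FALSE]
}

#' Classify a curated variant into a depth-analysis category
#'
#' Variants of size 1 bp are split by location into coding-sequence
#' (\code{CDS_1BP}) versus intronic/UTR/promoter (\code{NONCODING_1BP});
#' anything larger than 1 bp (up to the 20 bp panel cutoff) is
#' \code{LARGER} regardless of location.
#'
#' @param sizeBp Integer variant size in [1, 20].
#' @param locationClass Free-text location class ("CDS", "intron", "UTR",
#'   "promoter", ...). Only coding annotations map to \code{CDS_1BP}; any
#'   other (or missing) annotation of a 1 bp variant is treated as
#'   non-coding.
#' @return One of \code{"CDS_1BP"}, \code{"NONCODING_1BP"}, \code{"LARGER"}.
#' @export
classifyVariant <- function(sizeBp, locationClass) {
  stopifnot(length(sizeBp) == 1L, !is.na(sizeBp))
  sizeBp <- as.integer(sizeBp)
  if (sizeBp < 1L || sizeBp > 20L)
    stop("variant size ", sizeBp, " outside the supported 1-20 bp range")
  if (sizeBp > 1L) return("LARGER")
  cls <- tolower(trimws(as.character(locationClass %||% "")))
  if (length(cls) == 0L || is.na(cls)) cls <- ""
  if (cls %in% c("cds", "exon", "exonic", "coding")) "CDS_1BP" else "NONCODING_1BP"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parseInheritance <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("UNKNOWN", length(x))
  out[grepl("recessive", x) & grepl("autosom", x)] <- "AUTOSOMAL_RECESSIVE"
  out[grepl("dominant", x) & grepl("autosom", x)]  <- "AUTOSOMAL_DOMINANT"
  out[grepl("x.?link", x)] <- "X_LINKED"
  out[grepl("mito", x)] <- "MITOCHONDRIAL"
  out[grepl("complex|multifactor", x)] <- "COMPLEX"
  canon <- toupper(x)   # already-canonical tokens pass through
  out[canon %in% INHERITANCE_MODES] <- canon[canon %in% INHERITANCE_MODES]
  out
}

.parseLogical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  ifelse(x %in% c("true", "t", "yes", "y", "1"), TRUE,
         ifelse(x %in% c("false", "f", "no", "n", "0"), FALSE, NA))
}

.validAllele <- function(x) grepl("^[ACGT]*$", x)

#' Curate a raw variant catalogue
#'
#' Applies the four inclusion criteria to raw records and converts the
#' survivors to curated panel variants. A record is retained iff its
#' location is of the form \code{g.<digits>} or \code{m.<digits>} with a
#' usable chromosome annotation, its build tag equals \code{acceptedBuild},
#' its gene symbol is a well-formed alphanumeric token, and its size
#' (\code{max(nchar(ref), nchar(alt))}, alleles in minimal representation)
#' does not exceed \code{maxSize}. Exclusion is never fatal: each dropped
#' record is reported with a single primary reason code, checked in
#' criterion order. Annotation failures (criteria 1-3) form stage 1 of the
#' report and size failures stage 2, mirroring the two-pass narrative of
#' manual catalogue curation.
#'
#' @param records Raw records from \code{\link{readCatalogue}}.
#' @param acceptedBuild Reference build tag retained records must carry
#'   (default \code{"CanFam3.1"}).
#' @param maxSize Maximum variant size in bp (default 20).
#' @return List with \code{variants} (curated \code{data.frame}: columns
#'   \code{record_id, gene, chromosome, position, ref, alt, size_bp,
#'   category, inheritance, year, phene, is_disease}) and \code{report}
#'   (a \linkS4class{CurationReport}).
#' @export
curateCatalogue <- function(records, acceptedBuild = "CanFam3.1",
                            maxSize = 20) {
  stopifnot(is.data.frame(records), nzchar(acceptedBuild))
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  loc <- trimws(records$location)
  locOk <- grepl("^[gm]\\.[0-9]+$", loc)
  isMito <- grepl("^m\\.", loc)
  chromRaw <- trimws(records$chromosome)
  chrom <- ifelse(isMito, "MT", chromRaw)
  ref <- toupper(trimws(records$ref)); ref[is.na(ref)] <- ""
  alt <- toupper(trimws(records$alt)); alt[is.na(alt)] <- ""
  annotOk <- locOk & (isMito | (!is.na(chrom) & nzchar(chrom))) &
    .validAllele(ref) & .validAllele(alt) & (ref != alt) &
    (nzchar(ref) | nzchar(alt))
  reason[!annotOk] <- "NO_GENOMIC_LOCATION"

  buildOk <- trimws(records$build) == acceptedBuild
  reason[is.na(reason) & !buildOk] <- "WRONG_BUILD"

  gene <- trimws(records$gene)
  geneOk <- !is.na(gene) & grepl("^[A-Za-z][A-Za-z0-9_.-]*$", gene)
  reason[is.na(reason) & !geneOk] <- "BAD_GENE_SYMBOL"

  sizeBp <- pmax(nchar(ref), nchar(alt))
  reason[is.na(reason) & sizeBp > maxSize] <- "SIZE_GT_MAX"

  keep <- is.na(reason)
  kept <- records[keep, , drop = FALSE]
  variants <- data.frame(
    record_id = kept$record_id,
    gene = gene[keep],
    chromosome = chrom[keep],
    position = as.integer(sub("^[gm]\\.", "", loc[keep])),
    ref = ref[keep],
    alt = alt[keep],
    size_bp = as.integer(sizeBp[keep]),
    category = vapply(which(keep), function(i)
      classifyVariant(sizeBp[i], records$location_class[i]), character(1)),
    inheritance = .parseInheritance(kept$inheritance),
    year = suppressWarnings(as.integer(kept$year)),
    phene = as.character(kept$phene),
    is_disease = .parseLogical(kept$is_disease),
    stringsAsFactors = FALSE
  )
  rownames(variants) <- variants$record_id

  excl <- data.frame(record_id = records$record_id[!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  report <- new("CurationReport",
    nInput = n,
    nExcludedStage1 = sum(excl$reason != "SIZE_GT_MAX"),
    nExcludedStage2 = sum(excl$reason == "SIZE_GT_MAX"),
    nRetained = nrow(variants),
    exclusions = excl)
  validObject(report)
  list(variants = variants, report = report)
}

#' Split a curated catalogue at the capture-design year
#'
#' Partitions curated variants into those published up to and including
#' the year the capture design was frozen, and those published after it.
#' The post-design subset measures how well a fixed exome design keeps up
#' with newly discovered variants. Variants with no publication year fall
#' in neither part and are returned separately.
#'
#' @param variants Curated catalogue \code{data.frame}.
#' @param designYear Design freeze year (default 2014).
#' @return List with \code{pre}, \code{post} and \code{missing}
#'   \code{data.frame}s; \code{pre}/\code{post} partition the dated
#'   variants exhaustively and disjointly.
#' @export
splitByYear <- function(variants, designYear = 2014) {
  stopifnot(is.data.frame(variants), "year" %in% names(variants))
  missing <- variants[is.na(variants$year), , drop = FALSE]
  dated <- variants[!is.na(variants$year), , drop = FALSE]
  list(pre = dated[dated$year <= designYear, , drop = FALSE],
       post = dated[dated$year > designYear, , drop = FALSE],
       missing = missing)
}

#' Write a curated catalogue as TSV
#'
#' @param variants Curated catalogue \code{data.frame}.
#' @param path Output path.
#' @export
writeCatalogue <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a curation report as JSON and/or plain text
#'
#' @param report A \linkS4class{CurationReport}.
#' @param jsonPath Optional path for a machine-readable JSON report.
#' @param txtPath Optional path for a human-readable text report.
#' @export
writeCurationReport <- function(report, jsonPath = NULL, txtPath = NULL) {
  stopifnot(is(report, "CurationReport"))
  if (!is.null(jsonPath)) {
    obj <- list(n_input = report@nInput,
                n_excluded_stage1 = report@nExcludedStage1,
                n_excluded_stage2 = report@nExcludedStage2,
                n_retained = report@nRetained,
                exclusions = report@exclusions)
    jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(txtPath)) {
    con <- file(txtPath, "w"); on.exit(close(con))
    sink(con); show(report); sink()
  }
  invisible(report)
}
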