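## Panel screening of a multi-sample VCF.
##
## Each curated panel variant is looked up in the VCF by its normalized
## (chrom, pos, ref, alt) key, multi-allelic records being split per
## alternate allele. Genotypes are translated to alternate-allele dosages
## and interpreted per inheritance context: autosomal dosage 1 is a
## carrier, any dose on the male X is hemizygous, any dose on MT is
## reported as present (homoplasmic assumption). Sites that failed the
## caller's hard filter, uncalled genotypes, and absent sites without
## adequate depth are not assessable.

#' Interpret an alternate-allele dosage as a zygosity status
#'
#' Autosomes (and the female X): dosage 0 is \code{WILDTYPE}, 1 is
#' \code{CARRIER}, 2 is \code{HOMOZYGOUS_ALT}. Male X: any alternate
#' dose is \code{HEMIZYGOUS_ALT} (a dose of 2 is inconsistent with a
#' single X and raises a warning, but is still reported hemizygous).
#' Mitochondrial sites are present/absent: any dose is
#' \code{MITO_PRESENT}. A missing dosage (\code{NA}) is
#' \code{NOT_ASSESSABLE}.
#'
#' @param altCount Integer dosage (0-2, or \code{NA}).
#' @param inheritance Inheritance mode of the variant (one of
#'   \code{AUTOSOMAL_RECESSIVE}, \code{AUTOSOMAL_DOMINANT},
#'   \code{X_LINKED}, \code{MITOCHONDRIAL}, \code{COMPLEX},
#'   \code{UNKNOWN}); dosage interpretation is keyed on the chromosome,
#'   the mode is carried through for reporting.
#' @param sex \code{"male"} or \code{"female"}.
#' @param chromosome Chromosome of the variant ("X" and "MT" trigger the
#'   special rules).
#' @return One of the zygosity status strings.
#' @export
interpretZygosity <- function(altCount, inheritance, sex, chromosome) {
  stopifnot(length(altCount) == 1L)
  sex <- match.arg(tolower(sex), c("male", "female"))
  if (is.na(altCount)) return("NOT_ASSESSABLE")
  altCount <- as.integer(altCount)
  if (chromosome == "MT")
    return(if (altCount >= 1L) "MITO_PRESENT" else "WILDTYPE")
  if (chromosome == "X" && sex == "male") {
    if (altCount == 0L) return("WILDTYPE")
    if (altCount >= 2L)
      warning("dosage 2 on the male X is inconsistent with hemizygosity; ",
              "reporting HEMIZYGOUS_ALT")
    return("HEMIZYGOUS_ALT")
  }
  switch(as.character(min(altCount, 2L)),
         "0" = "WILDTYPE", "1" = "CARRIER", "2" = "HOMOZYGOUS_ALT")
}

## dosage of allele index `a` in a GT string like "0/1", "1|2", "1", "./1"
.gtDosage <- function(gt, a) {
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".") || !length(alleles)) return(NA_integer_)
  sum(alleles == as.character(a))
}

#' Scan a multi-sample VCF for curated panel variants
#'
#' Matches every panel variant against the VCF by normalized allele key
#' (\code{\link{normalizeAllele}}), splitting multi-allelic records, and
#' builds the sample x variant dosage matrix with interpreted zygosity.
#' Records failing the hard filter (FILTER other than \code{PASS} or
#' \code{.}) are not assessable. A panel variant absent from the VCF is
#' wildtype in a sample only when its span qualified at
#' \code{threshold} in that sample (callers emit variant sites only, so
#' absence is evidence of the reference genotype only where there was
#' coverage); without a qualification matrix all absent sites are taken
#' as covered.
#'
#' @param vcfPath Path to a VCF 4.x file (plain or bgzipped) with GT.
#' @param variants Curated catalogue \code{data.frame}.
#' @param metadata \code{data.frame} with \code{sample_id}, \code{sex}
#'   and optionally \code{breed}; every sample listed must be present in
#'   the VCF (a missing one is a configuration error).
#' @param qualification Optional \linkS4class{QualificationMatrix} used
#'   to depth-gate absent sites.
#' @param threshold Reporting depth threshold for the gate (default 10).
#' @return A \linkS4class{DetectionMatrix} with assays \code{altCount},
#'   \code{status} and \code{filterPass}.
#' @export
scanVcf <- function(vcfPath, variants, metadata, qualification = NULL,
                    threshold = 10) {
  stopifnot(is.data.frame(variants), is.data.frame(metadata),
            all(c("sample_id", "sex") %in% names(metadata)))
  vcf <- VariantAnnotation::readVcf(vcfPath, genome = "panel")
  vcfSamples <- colnames(vcf)
  missing <- setdiff(metadata$sample_id, vcfSamples)
  if (length(missing))
    stop("samples in metadata but absent from VCF: ",
         paste(missing, collapse = ", "))
  samples <- metadata$sample_id
  sex <- setNames(tolower(metadata$sex), samples)

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refA <- as.character(VariantAnnotation::ref(vcf))
  altA <- VariantAnnotation::alt(vcf)
  filt <- as.character(VariantAnnotation::fixed(vcf)$FILTER)
  gt <- VariantAnnotation::geno(vcf)$GT[, samples, drop = FALSE]

  ## index every (record, alt allele) pair by its normalized key
  keyRec <- list()
  for (i in seq_along(rr)) {
    alts <- as.character(altA[[i]])
    for (a in seq_along(alts)) {
      if (!grepl("^[ACGT]+$", alts[a])) next  # symbolic/spanning alleles
      k <- normalizeAllele(chrom[i], pos[i], refA[i], alts[a])$key
      keyRec[[k]] <- c(keyRec[[k]], list(c(rec = i, alt = a)))
    }
  }

  nV <- nrow(variants); nS <- length(samples)
  altCount <- matrix(NA_integer_, nV, nS,
                     dimnames = list(variants$record_id, samples))
  filterPass <- matrix(NA, nV, nS,
                       dimnames = list(variants$record_id, samples))
  keys <- .panelKeys(variants)
  qual <- if (!is.null(qualification))
    isQualified(qualification, threshold)[variants$record_id, samples,
                                          drop = FALSE]

  for (j in seq_len(nV)) {
    hits <- keyRec[[keys[j]]]
    if (is.null(hits)) {
      ## absent from the VCF: wildtype only where coverage supports it
      covered <- if (is.null(qual)) rep(TRUE, nS) else qual[j, ]
      altCount[j, covered] <- 0L
      filterPass[j, ] <- TRUE
      next
    }
    if (length(hits) > 1L) {
      ord <- order(vapply(hits, function(h) pos[h[["rec"]]], numeric(1)))
      hits <- hits[ord]
      warning("panel variant ", variants$record_id[j],
              " matches ", length(hits),
              " VCF records; using the first by position")
    }
    i <- hits[[1]][["rec"]]; a <- hits[[1]][["alt"]]
    pass <- filt[i] %in% c("PASS", ".")
    filterPass[j, ] <- pass
    if (!pass) next  # hard-filtered: not assessable for any sample
    altCount[j, ] <- vapply(gt[i, ], .gtDosage, integer(1), a = a)
  }

  status <- matrix("NOT_ASSESSABLE", nV, nS,
                   dimnames = dimnames(altCount))
  for (j in seq_len(nV)) for (s in seq_len(nS))
    status[j, s] <- interpretZygosity(altCount[j, s],
                                      variants$inheritance[j],
                                      sex[[samples[s]]],
                                      variants$chromosome[j])

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(altCount = altCount, status = status,
                  filterPass = filterPass),
    rowData = S4Vectors::DataFrame(variants, row.names = variants$record_id),
    colData = S4Vectors::DataFrame(metadata, row.names = samples))
  dm <- new("DetectionMatrix", se)
  validObject(dm)
  dm
}

#' Per-dog summary of distinct detected variants
#'
#' Counts, per sample, the distinct panel variants with at least one
#' alternate allele (zygosity-agnostic) and tabulates the distribution
#' over samples.
#'
#' @param dm A \linkS4class{DetectionMatrix}.
#' @param diseaseOnly Restrict to disease-associated panel variants
#'   (\code{is_disease} in the catalogue).
#' @return List with \code{perSample} (named integer vector),
#'   \code{histogram} (\code{data.frame}: n_variants, n_samples),
#'   \code{nWithAtLeastOne} and \code{pctWithAtLeastOne} (percentage of
#'   samples, rounded half-up to 1 decimal).
#' @export
perDogSummary <- function(dm, diseaseOnly = FALSE) {
  stopifnot(is(dm, "DetectionMatrix"))
  ac <- altCounts(dm)
  if (diseaseOnly) {
    dis <- SummarizedExperiment::rowData(dm)$is_disease
    dis[is.na(dis)] <- FALSE
    ac <- ac[dis, , drop = FALSE]
  }
  detected <- !is.na(ac) & ac >= 1L
  perSample <- colSums(detected)
  hist <- as.data.frame(table(perSample), stringsAsFactors = FALSE)
  names(hist) <- c("n_variants", "n_samples")
  hist$n_variants <- as.integer(hist$n_variants)
  hist$n_samples <- as.integer(hist$n_samples)
  nPos <- sum(perSample >= 1L)
  list(perSample = perSample, histogram = hist,
       nWithAtLeastOne = nPos,
       pctWithAtLeastOne = roundHalfUp(100 * nPos / length(perSample), 1))
}

#' Long-format genotype call table
#'
#' @param dm A \linkS4class{DetectionMatrix}.
#' @return \code{data.frame}: \code{sample}, \code{record_id},
#'   \code{alt_count}, \code{status}, \code{filter_pass}.
#' @export
genotypeCalls <- function(dm) {
  ac <- altCounts(dm); st <- callStatus(dm)
  fp <- SummarizedExperiment::assay(dm, "filterPass")
  data.frame(sample = rep(colnames(ac), each = nrow(ac)),
             record_id = rep(rownames(ac), times = ncol(ac)),
             alt_count = as.vector(ac), status = as.vector(st),
             filter_pass = as.vector(fp))
}
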