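## Synthetic-data generators.
##
## Every stage of the pipeline is testable without sequencing data: the
## generators emit a raw catalogue with planted curation violations, per
## sample per-base depth tracks with category-specific coverage models,
## and a multi-sample VCF with planted genotype dosages — each alongside
## a ground-truth table. Variants live on an artificial mini-genome
## (chr1..chr10, X, MT at kilobase scale) so no reference download is
## ever needed. All generators are seed-deterministic.

.SIM_AUTOSOMES <- paste0("chr", 1:10)

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

.otherBase <- function(exclude) sample(setdiff(c("A", "C", "G", "T"),
                                               exclude), 1L)

#' Default 49-dog cohort metadata
#'
#' The breed and sex composition used by the simulators: 49 dogs, 22
#' male and 27 female, across 14 breeds (Labrador Retrievers,
#' Deerhounds, Malinois, Bloodhounds, crossbreeds, Dutch Partridge dogs
#' and eight singleton breeds).
#'
#' @return \code{data.frame} with \code{sample_id}, \code{sex},
#'   \code{breed}.
#' @export
defaultMetadata <- function() {
  grp <- function(breed, m, f)
    data.frame(breed = breed, sex = c(rep("male", m), rep("female", f)))
  x <- rbind(grp("Labrador Retriever", 7, 9), grp("Deerhound", 2, 5),
             grp("Malinois", 3, 1), grp("Bloodhound", 1, 4),
             grp("Crossbreed", 3, 2), grp("Dutch Partridge dog", 1, 3),
             grp("Belgian Shepherd", 1, 0),
             grp("English Cocker Spaniel", 0, 1), grp("Pitbull", 1, 0),
             grp("Irish Setter", 0, 1), grp("American Staffordshire", 1, 0),
             grp("Chesapeake Bay Retriever", 1, 0),
             grp("French Bulldog", 1, 0), grp("Jack Russell Terrier", 0, 1))
  data.frame(sample_id = sprintf("dog%02d", seq_len(nrow(x))),
             sex = x$sex, breed = x$breed)
}

#' Simulate a raw variant catalogue with planted curation violations
#'
#' Generates a raw OMIA-style table containing \code{nCds + nNoncoding +
#' nLarger} fully valid records plus, per curation criterion, a planted
#' set of invalid records each violating exactly one criterion
#' (unparseable location, wrong reference build, malformed gene symbol,
#' size above 20 bp). Valid records carry consistent coordinates and
#' minimal-representation alleles on the artificial mini-genome;
#' X-linked records sit on "X" and mitochondrial ones on "MT".
#' Publication years are assigned so that exactly
#' \code{postDesignMix[category]} records per category postdate
#' \code{designYear}, and exactly \code{nDisease} records are flagged as
#' disease-associated.
#'
#' @param nCds,nNoncoding,nLarger Category sizes (defaults 251 / 7 / 94).
#' @param nDisease Number of disease-flagged valid records (default 323).
#' @param postDesignMix Named counts of post-design-year records per
#'   category (defaults 118 / 6 / 46).
#' @param designYear Capture-design freeze year (default 2014).
#' @param nInvalidPerReason Named counts of planted invalid records.
#' @param nXLinked,nMito Valid records placed on X / MT (defaults 6 / 2).
#' @param build Reference build tag written on valid records.
#' @param seed Integer seed.
#' @return List with \code{records} (raw catalogue \code{data.frame},
#'   rows shuffled) and \code{truth} (valid-variant table plus planted
#'   exclusions with reason codes).
#' @export
simulateCatalogue <- function(nCds = 251, nNoncoding = 7, nLarger = 94,
                              nDisease = 323,
                              postDesignMix = c(CDS_1BP = 118,
                                                NONCODING_1BP = 6,
                                                LARGER = 46),
                              designYear = 2014,
                              nInvalidPerReason = c(NO_GENOMIC_LOCATION = 3,
                                                    WRONG_BUILD = 3,
                                                    BAD_GENE_SYMBOL = 3,
                                                    SIZE_GT_MAX = 3),
                              nXLinked = 6, nMito = 2,
                              build = "CanFam3.1", seed = 1) {
  set.seed(as.integer(seed))
  nValid <- nCds + nNoncoding + nLarger
  stopifnot(nDisease <= nValid, nMito <= nCds, nXLinked <= nValid - nMito)

  category <- c(rep("CDS_1BP", nCds), rep("NONCODING_1BP", nNoncoding),
                rep("LARGER", nLarger))
  locClass <- c(rep("CDS", nCds),
                rep(c("intron", "promoter", "UTR"),
                    length.out = nNoncoding),
                rep("CDS", nLarger))

  ## inheritance: mitochondrial records are CDS SNVs on MT; X-linked
  ## records sit on X; a handful are dominant/complex; the rest follow
  ## the autosomal-recessive majority seen in Mendelian trait catalogues
  inheritance <- rep("AUTOSOMAL_RECESSIVE", nValid)
  mitoIdx <- seq_len(nMito)                       # first CDS records
  xIdx <- nMito + seq_len(nXLinked)
  inheritance[mitoIdx] <- "MITOCHONDRIAL"
  inheritance[xIdx] <- "X_LINKED"
  rest <- setdiff(seq_len(nValid), c(mitoIdx, xIdx))
  domIdx <- rest[seq_len(min(5L, length(rest)))]
  cplxIdx <- rest[5L + seq_len(min(4L, length(rest) - 5L))]
  inheritance[domIdx] <- "AUTOSOMAL_DOMINANT"
  inheritance[cplxIdx] <- "COMPLEX"

  chrom <- character(nValid)
  chrom[mitoIdx] <- "MT"
  chrom[xIdx] <- "X"
  chrom[-c(mitoIdx, xIdx)] <- sample(.SIM_AUTOSOMES,
                                     nValid - nMito - nXLinked,
                                     replace = TRUE)
  ## distinct, well-separated slots per chromosome
  position <- integer(nValid)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    position[idx] <- 1000L + 200L * (seq_along(idx) - 1L)
  }

  ref <- character(nValid); alt <- character(nValid)
  sizeBp <- integer(nValid)
  for (i in seq_len(nValid)) {
    if (category[i] != "LARGER") {
      ref[i] <- .randSeq(1L); alt[i] <- .otherBase(ref[i]); sizeBp[i] <- 1L
    } else {
      k <- sample(2:20, 1L)
      kind <- sample(c("del", "ins", "delins"), 1L,
                     prob = c(0.45, 0.35, 0.2))
      if (kind == "del") { ref[i] <- .randSeq(k); alt[i] <- "" }
      else if (kind == "ins") { ref[i] <- ""; alt[i] <- .randSeq(k) }
      else { ref[i] <- .randSeq(k)
             alt[i] <- .otherBase(substr(ref[i], 1L, 1L)) }
      sizeBp[i] <- k
    }
  }

  year <- integer(nValid)
  for (cat in names(postDesignMix)) {
    idx <- which(category == cat)
    nPost <- postDesignMix[[cat]]
    stopifnot(nPost <= length(idx))
    post <- sample(idx, nPost)
    year[post] <- sample((designYear + 1L):2021L, nPost, replace = TRUE)
    pre <- setdiff(idx, post)
    year[pre] <- sample(1990L:designYear, length(pre), replace = TRUE)
  }

  isDisease <- rep(TRUE, nValid)
  isDisease[sample(nValid, nValid - nDisease)] <- FALSE

  validId <- sprintf("VAR%04d", seq_len(nValid))
  valid <- data.frame(
    record_id = validId, gene = sprintf("GENE%04d", seq_len(nValid)),
    location = paste0(ifelse(chrom == "MT", "m.", "g."), position),
    build = build, ref = ref, alt = alt, chromosome = chrom,
    location_class = locClass, inheritance = tolower(gsub(
      "_", " ", inheritance)), year = as.character(year),
    phene = sprintf("trait %d", seq_len(nValid)),
    is_disease = ifelse(isDisease, "yes", "no"),
    stringsAsFactors = FALSE)

  ## planted invalid records: one violated criterion each
  invalid <- list(); inv <- 0L
  mkInvalid <- function(reason, i) {
    r <- .randSeq(1L)
    rec <- data.frame(
      record_id = sprintf("INV_%s_%02d", reason, i), gene = "GENEBAD",
      location = "g.5000", build = build, ref = r, alt = .otherBase(r),
      chromosome = sample(.SIM_AUTOSOMES, 1L), location_class = "CDS",
      inheritance = "autosomal recessive", year = "2010",
      phene = "planted invalid", is_disease = "yes",
      stringsAsFactors = FALSE)
    rec$gene <- sprintf("GENEX%s%02d", substr(reason, 1, 2), i)
    if (reason == "NO_GENOMIC_LOCATION") rec$location <- "c.76del"
    if (reason == "WRONG_BUILD") rec$build <- "CanFam2.0"
    if (reason == "BAD_GENE_SYMBOL") rec$gene <- ""
    if (reason == "SIZE_GT_MAX") {
      k <- sample(21:30, 1L); rec$ref <- .randSeq(k); rec$alt <- ""
    }
    rec
  }
  for (reason in names(nInvalidPerReason))
    for (i in seq_len(nInvalidPerReason[[reason]])) {
      inv <- inv + 1L
      invalid[[inv]] <- mkInvalid(reason, i)
    }
  invalid <- if (inv) do.call(rbind, invalid) else valid[0, ]

  records <- rbind(valid, invalid)
  records <- records[sample(nrow(records)), , drop = FALSE]
  rownames(records) <- NULL

  truthValid <- data.frame(
    record_id = validId, chromosome = chrom, position = position,
    ref = ref, alt = alt, size_bp = sizeBp, category = category,
    inheritance = inheritance, year = year, is_disease = isDisease,
    stringsAsFactors = FALSE)
  truthInvalid <- if (inv)
    data.frame(record_id = invalid$record_id,
               reason = sub("^INV_(.*)_[0-9]+$", "\\1",
                            invalid$record_id),
               stringsAsFactors = FALSE)
  else data.frame(record_id = character(), reason = character())

  list(records = records,
       truth = list(valid = truthValid, invalid = truthInvalid,
                    design_year = designYear, n_disease = nDisease))
}

#' Write a raw catalogue table as TSV
#'
#' @param records Raw catalogue \code{data.frame}
#'   (\code{\link{simulateCatalogue}} output).
#' @param path Output path.
#' @export
writeRawCatalogue <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate per-sample depth tracks over the panel loci
#'
#' Coverage at each variant locus follows a zero-inflated
#' gamma-Poisson (negative binomial) model with category-specific
#' parameters: on-target coding loci are deep (default mean 35x),
#' off-target intronic/UTR/promoter loci shallow (default mean 5x with a
#' larger zero mass, so fully unsequenced loci occur). Within a locus a
#' single gamma-distributed rate drives all span (and flank) positions,
#' mimicking the local correlation of real coverage.
#'
#' @param sampleIds Character vector of sample identifiers.
#' @param variants Curated catalogue \code{data.frame} (or the
#'   generator's truth table).
#' @param mu Named per-category mean depths.
#' @param size Named per-category negative-binomial size (dispersion).
#' @param zeroInflation Named per-category probability that a locus got
#'   no coverage at all in a sample.
#' @param flank Flanking bases covered on each side of a span (default 2).
#' @param seed Integer seed.
#' @return List with \code{tracks} (named list of
#'   \linkS4class{DepthTrack}) and \code{truth} (model parameters and
#'   the implied marginal mean \code{(1 - zeroInflation) * mu} per
#'   category).
#' @export
simulateDepth <- function(sampleIds, variants,
                          mu = c(CDS_1BP = 35, NONCODING_1BP = 5,
                                 LARGER = 37),
                          size = c(CDS_1BP = 3, NONCODING_1BP = 0.6,
                                   LARGER = 3),
                          zeroInflation = c(CDS_1BP = 0.02,
                                            NONCODING_1BP = 0.15,
                                            LARGER = 0.02),
                          flank = 2L, seed = 1) {
  set.seed(as.integer(seed))
  nV <- nrow(variants)
  spans <- lapply(seq_len(nV), function(i) {
    sp <- variantSpan(variants$position[i], variants$ref[i],
                      variants$alt[i])
    seq(max(1L, min(sp) - flank), max(sp) + flank)
  })
  tracks <- lapply(sampleIds, function(s) {
    chromAll <- integer(0); posAll <- integer(0); depthAll <- integer(0)
    chromV <- character(0)
    for (i in seq_len(nV)) {
      cat <- variants$category[i]
      n <- length(spans[[i]])
      if (runif(1) < zeroInflation[[cat]]) {
        d <- rep(0L, n)
      } else {
        lam <- stats::rgamma(1, shape = size[[cat]],
                             rate = size[[cat]] / mu[[cat]])
        d <- rpois(n, lam)
      }
      chromV <- c(chromV, rep(variants$chromosome[i], n))
      posAll <- c(posAll, spans[[i]])
      depthAll <- c(depthAll, d)
    }
    DepthTrack(s, chromV, posAll, depthAll)
  })
  names(tracks) <- sampleIds
  list(tracks = tracks,
       truth = list(mu = as.list(mu), size = as.list(size),
                    zero_inflation = as.list(zeroInflation),
                    expected_mean = as.list((1 - zeroInflation) * mu)))
}

#' Write depth tracks as per-sample 3-column TSVs
#'
#' @param tracks Named list of \linkS4class{DepthTrack}s.
#' @param dir Output directory (created if absent).
#' @return Named vector of written paths.
#' @export
writeDepthTracks <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(tracks, function(tr) {
    key <- strsplit(names(tr@depth), ":", fixed = TRUE)
    df <- data.frame(chrom = vapply(key, `[`, character(1), 1L),
                     pos = as.integer(vapply(key, `[`, character(1), 2L)),
                     depth = unname(tr@depth))
    p <- file.path(dir, paste0(sampleId(tr), ".depth.tsv"))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  paths
}

#' Simulate a multi-sample VCF with planted genotypes
#'
#' Draws per-sample alternate-allele dosages for every panel variant
#' respecting inheritance context and sex (males never carry two X
#' alleles; mitochondrial plants are present/absent, emitted haploid),
#' then writes a VCF 4.2 in which indels appear in anchored caller
#' representation — deliberately different from the catalogue's minimal
#' form so allele normalization is exercised — a configurable fraction
#' of sites carries a failing FILTER, some single-nucleotide sites are
#' emitted multi-allelic with a decoy alternate allele, and one site
#' carries a half-missing genotype. Deterministic plants guarantee at
#' least one hemizygous male-X carrier, mitochondrial presence in two
#' samples, and one indel carrier regardless of the random rates.
#'
#' @param variants Curated catalogue \code{data.frame}.
#' @param metadata Cohort metadata (default \code{\link{defaultMetadata}}).
#' @param carrierProb Per-variant probability that a sample carries at
#'   least one alternate allele. Default: calibrated so the expected
#'   fraction of samples with >=1 disease-variant detection is 0.8 for
#'   the panel's disease-variant count.
#' @param filterFailRate Fraction of emitted sites given FILTER
#'   \code{LowQual} (default 0.02).
#' @param multiAllelicFraction Fraction of emitted SNV sites augmented
#'   with a decoy alternate allele (default 0.05).
#' @param seed Integer seed.
#' @return List with \code{vcfLines} (character vector; write with
#'   \code{writeLines}), \code{metadata}, and \code{truth} (dosage
#'   matrix variants x samples with \code{NA} for the planted missing
#'   genotype, plus the record ids of filter-failed and emitted sites).
#' @export
simulateVcf <- function(variants, metadata = defaultMetadata(),
                        carrierProb = NULL, filterFailRate = 0.02,
                        multiAllelicFraction = 0.05, seed = 1) {
  set.seed(as.integer(seed))
  nV <- nrow(variants); samples <- metadata$sample_id
  nS <- length(samples)
  sex <- setNames(tolower(metadata$sex), samples)
  isDis <- variants$is_disease
  isDis[is.na(isDis)] <- FALSE
  nDis <- max(sum(isDis), 1L)
  if (is.null(carrierProb)) carrierProb <- 1 - 0.2^(1 / nDis)
  stopifnot(carrierProb >= 0, carrierProb <= 1)
  f <- 1 - sqrt(1 - carrierProb)   # per-allele frequency under HWE

  dosage <- matrix(0L, nV, nS, dimnames = list(variants$record_id, samples))
  for (j in seq_len(nV)) {
    ch <- variants$chromosome[j]
    for (s in seq_len(nS)) {
      dosage[j, s] <- if (ch == "MT") rbinom(1, 1, carrierProb)
      else if (ch == "X" && sex[[samples[s]]] == "male") rbinom(1, 1, f)
      else rbinom(1, 2, f)
    }
  }

  ## deterministic plants (skipped for a zero carrier rate): hemizygous
  ## male X, mitochondrial presence, an indel carrier
  if (carrierProb > 0) {
    males <- which(sex[samples] == "male")
    xVars <- which(variants$chromosome == "X")
    if (length(xVars) && length(males)) dosage[xVars[1], males[1]] <- 1L
    mtVars <- which(variants$chromosome == "MT")
    if (length(mtVars)) dosage[mtVars[1], seq_len(min(2L, nS))] <- 1L
    indels <- which(variants$size_bp > 1L)
    if (length(indels)) dosage[indels[1], min(3L, nS)] <- 1L
  }

  emitted <- which(rowSums(dosage) > 0L)
  filterFail <- emitted[runif(length(emitted)) < filterFailRate]
  snvEmitted <- emitted[variants$size_bp[emitted] == 1L &
                          nchar(variants$ref[emitted]) == 1L]
  multi <- snvEmitted[runif(length(snvEmitted)) < multiAllelicFraction]

  ## one planted half-missing genotype at an emitted autosomal site
  missTarget <- emitted[!variants$chromosome[emitted] %in% c("X", "MT")]
  missJ <- if (length(missTarget)) missTarget[1] else NA_integer_
  missS <- if (!is.na(missJ)) which(dosage[missJ, ] > 0L)[1] else NA_integer_

  gtString <- function(dose, a, ploidy, half = FALSE) {
    if (half) return(paste0(".", "/", a))
    if (ploidy == 1L) as.character(ifelse(dose >= 1L, a, 0L))
    else paste(c(rep(0L, 2L - min(dose, 2L)),
                 rep(a, min(dose, 2L))), collapse = "/")
  }

  lines <- c("##fileformat=VCFv4.2",
             "##source=ExomeScreenSimulator",
             "##FILTER=<ID=LowQual,Description=\"Low quality\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste0("##contig=<ID=", c(.SIM_AUTOSOMES, "X", "MT"), ">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples),
                   collapse = "\t"))

  ord <- emitted[order(match(variants$chromosome[emitted],
                             c(.SIM_AUTOSOMES, "X", "MT")),
                       variants$position[emitted])]
  body <- character(0)
  for (j in ord) {
    ch <- variants$chromosome[j]
    refC <- variants$ref[j]; altC <- variants$alt[j]
    pos <- variants$position[j]
    if (nzchar(refC) && nzchar(altC) && nchar(refC) == 1L &&
        nchar(altC) == 1L) {            # SNV: emitted as-is
      posV <- pos; refV <- refC; altV <- altC
    } else if (nzchar(refC) && nzchar(altC)) {  # delins: legal unanchored
      posV <- pos; refV <- refC; altV <- altC
    } else {                             # pure indel: anchored caller form
      anchor <- .otherBase(c(substr(refC, nchar(refC), nchar(refC)),
                             substr(altC, nchar(altC), nchar(altC))))
      posV <- pos - 1L
      refV <- paste0(anchor, refC)
      altV <- paste0(anchor, altC)
    }
    alts <- altV; aIdx <- 1L
    decoyCarrier <- NA_integer_
    if (j %in% multi) {
      decoy <- .otherBase(c(refV, altV))
      if (runif(1) < 0.5) { alts <- c(decoy, altV); aIdx <- 2L }
      else alts <- c(altV, decoy)
      zeros <- which(dosage[j, ] == 0L)
      if (length(zeros)) decoyCarrier <- zeros[1]
    }
    dIdx <- setdiff(seq_along(alts), aIdx)
    filt <- if (j %in% filterFail) "LowQual" else "PASS"
    ploidy <- if (ch == "MT" ) 1L else 2L
    gts <- vapply(seq_len(nS), function(s) {
      pl <- if (ch == "X" && sex[[samples[s]]] == "male") 1L else ploidy
      if (!is.na(missJ) && j == missJ && s == missS)
        return(gtString(NA, aIdx, 2L, half = TRUE))
      if (!is.na(decoyCarrier) && s == decoyCarrier)
        return(paste0("0/", dIdx))
      gtString(dosage[j, s], aIdx, pl)
    }, character(1))
    body <- c(body, paste(c(ch, posV, variants$record_id[j], refV,
                            paste(alts, collapse = ","), "100", filt,
                            ".", "GT", gts), collapse = "\t"))
  }

  truthDosage <- dosage
  if (!is.na(missJ)) truthDosage[missJ, missS] <- NA_integer_
  list(vcfLines = c(lines, body), metadata = metadata,
       truth = list(dosage = truthDosage,
                    filter_failed = variants$record_id[filterFail],
                    emitted = variants$record_id[emitted],
                    carrier_prob = carrierProb,
                    missing_gt = if (!is.na(missJ))
                      c(record_id = variants$record_id[missJ],
                        sample = samples[missS]) else NULL))
}

#' Generate a complete synthetic study cohort on disk
#'
#' Orchestrates the three generators and writes every pipeline input
#' into \code{dir}: raw catalogue TSV, per-sample depth TSVs, a
#' multi-sample VCF, cohort metadata TSV and a ground-truth JSON.
#'
#' @param dir Output directory.
#' @param seed Integer seed driving all three generators.
#' @param metadata Cohort metadata (default \code{\link{defaultMetadata}}).
#' @param ... Further arguments passed to \code{\link{simulateCatalogue}}.
#' @return Invisible list with the written paths and the in-memory
#'   truth objects.
#' @export
simulateCohort <- function(dir, seed = 1, metadata = defaultMetadata(),
                           ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cata <- simulateCatalogue(seed = seed, ...)
  cataPath <- file.path(dir, "catalogue_raw.tsv")
  writeRawCatalogue(cata$records, cataPath)

  curated <- curateCatalogue(readCatalogue(cataPath))
  dep <- simulateDepth(metadata$sample_id, curated$variants,
                       seed = seed + 1L)
  depthDir <- file.path(dir, "depth")
  writeDepthTracks(dep$tracks, depthDir)

  sim <- simulateVcf(curated$variants, metadata, seed = seed + 2L)
  vcfPath <- file.path(dir, "cohort.vcf")
  writeLines(sim$vcfLines, vcfPath)
  metaPath <- file.path(dir, "metadata.tsv")
  write.table(metadata, metaPath, sep = "\t", quote = FALSE,
              row.names = FALSE)

  truth <- list(catalogue = cata$truth, depth = dep$truth,
                genotypes = list(
                  dosage = sim$truth$dosage,
                  filter_failed = sim$truth$filter_failed,
                  emitted = sim$truth$emitted,
                  carrier_prob = sim$truth$carrier_prob,
                  missing_gt = sim$truth$missing_gt))
  truthPath <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(list(catalogue = cataPath, depth_dir = depthDir,
                 vcf = vcfPath, metadata = metaPath, truth_json = truthPath,
                 truth = truth, variants = curated$variants,
                 tracks = dep$tracks))
}
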