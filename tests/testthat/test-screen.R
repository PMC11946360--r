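# exhaustive trimming oracle: enumerate every (suffix, prefix) trim that
# keeps the pair a valid description of the same change, take the minimal
brutalNormalize <- function(chrom, pos, ref, alt) {
  repeat {
    n <- nchar(ref); m <- nchar(alt)
    if (n > 0 && m > 0 &&
        substr(ref, n, n) == substr(alt, m, m)) {
      ref <- substr(ref, 1, n - 1); alt <- substr(alt, 1, m - 1)
      next
    }
    if (n > 0 && m > 0 && substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, n); alt <- substr(alt, 2, m); pos <- pos + 1
      next
    }
    break
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

test_that("allele normalization reduces equivalent descriptions to one key", {
  # SNVs are fixed points
  snv <- normalizeAllele("chr5", 100, "A", "G")
  expect_equal(snv$key, "chr5:100:A:G")
  # anchored caller form and minimal catalogue form share a key
  expect_equal(normalizeAllele("chr5", 100, "ATG", "A")$key,
               normalizeAllele("chr5", 101, "TG", "")$key)
  expect_equal(normalizeAllele("chr5", 100, "C", "CTTAG")$key,
               normalizeAllele("chr5", 101, "", "TTAG")$key)
  # degenerate and malformed input
  expect_error(normalizeAllele("chr5", 100, "A", "A"), "degenerate")
  expect_error(normalizeAllele("chr5", 100, "AN", "A"), "A/C/G/T")
  # randomized agreement with the exhaustive trimming oracle + idempotence
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  for (i in 1:300) {
    core <- paste(sample(bases, sample(1:6, 1), TRUE), collapse = "")
    alt0 <- paste(sample(bases, sample(0:6, 1), TRUE), collapse = "")
    if (core == alt0) next
    pre <- paste(sample(bases, sample(0:3, 1), TRUE), collapse = "")
    suf <- paste(sample(bases, sample(0:3, 1), TRUE), collapse = "")
    ref <- paste0(pre, core, suf); alt <- paste0(pre, alt0, suf)
    if (ref == alt) next
    got <- normalizeAllele("chr2", 500, ref, alt)
    expect_equal(got$key, brutalNormalize("chr2", 500, ref, alt))
    again <- normalizeAllele(got$chrom, got$position,
                             if (nzchar(got$ref)) got$ref else "",
                             if (nzchar(got$alt)) got$alt else "")
    expect_equal(again$key, got$key)
  }
})

test_that("dosages are interpreted per chromosome context and sex", {
  cases <- list(
    list(0, "AUTOSOMAL_RECESSIVE", "female", "chr12", "WILDTYPE"),
    list(1, "AUTOSOMAL_RECESSIVE", "female", "chr12", "CARRIER"),
    list(2, "AUTOSOMAL_RECESSIVE", "male", "chr12", "HOMOZYGOUS_ALT"),
    list(1, "AUTOSOMAL_DOMINANT", "male", "chr3", "CARRIER"),
    list(1, "X_LINKED", "male", "X", "HEMIZYGOUS_ALT"),
    list(0, "X_LINKED", "male", "X", "WILDTYPE"),
    list(1, "X_LINKED", "female", "X", "CARRIER"),
    list(2, "X_LINKED", "female", "X", "HOMOZYGOUS_ALT"),
    list(1, "MITOCHONDRIAL", "male", "MT", "MITO_PRESENT"),
    list(0, "MITOCHONDRIAL", "female", "MT", "WILDTYPE"),
    list(NA, "AUTOSOMAL_RECESSIVE", "female", "chr1", "NOT_ASSESSABLE"))
  for (cs in cases)
    expect_equal(interpretZygosity(cs[[1]], cs[[2]], cs[[3]], cs[[4]]),
                 cs[[5]], info = paste(unlist(cs), collapse = "/"))
  # dosage 2 on the male X: flagged as inconsistent, still hemizygous
  expect_warning(st <- interpretZygosity(2, "X_LINKED", "male", "X"),
                 "inconsistent")
  expect_equal(st, "HEMIZYGOUS_ALT")
})

# hand-written five-sites/two-samples VCF exercising the scan rules
writeTinyVcf <- function() {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=LowQual,Description=\"Low quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=chr1>", "##contig=<ID=chr2>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "dogA", "dogB"), collapse = "\t"),
    "chr1\t1000\t.\tA\tG\t99\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t1100\t.\tC\tT\t99\tLowQual\t.\tGT\t1/1\t0/1",
    # multi-allelic: panel allele is index 2, decoy index 1
    "chr1\t1200\t.\tG\tC,A\t99\tPASS\t.\tGT\t0/2\t0/1",
    # anchored deletion of TG at 1301-1302
    "chr1\t1300\t.\tCTG\tC\t99\tPASS\t.\tGT\t1/1\t0/1",
    # half-called genotype
    "chr2\t2000\t.\tT\tA\t99\tPASS\t.\tGT\t./1\t0/0")
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

tinyPanel <- function() rbind(
  curatedVariant("P1", position = 1000L, ref = "A", alt = "G"),
  curatedVariant("P2", position = 1100L, ref = "C", alt = "T"),
  curatedVariant("P3", position = 1200L, ref = "G", alt = "A"),
  curatedVariant("P4", position = 1301L, ref = "TG", alt = "",
                 category = "LARGER"),
  curatedVariant("P5", chromosome = "chr2", position = 2000L,
                 ref = "T", alt = "A"),
  curatedVariant("P6", position = 1400L, ref = "A", alt = "C"))

tinyMeta <- data.frame(sample_id = c("dogA", "dogB"),
                       sex = c("male", "female"),
                       breed = "Crossbreed")

test_that("the VCF scan matches, splits, filters and depth-gates", {
  vcf <- writeTinyVcf()
  panel <- tinyPanel()
  dm <- scanVcf(vcf, panel, tinyMeta)
  ac <- altCounts(dm); st <- callStatus(dm)
  # planted heterozygous SNV -> carrier
  expect_equal(unname(ac["P1", ]), c(1L, 0L))
  expect_equal(unname(st["P1", ]), c("CARRIER", "WILDTYPE"))
  # hard-filtered site is not assessable for anyone
  expect_true(all(is.na(ac["P2", ])))
  expect_true(all(st["P2", ] == "NOT_ASSESSABLE"))
  # multi-allelic: dosage of the matching allele only
  expect_equal(unname(ac["P3", ]), c(1L, 0L))
  # anchored indel matches the minimal catalogue form
  expect_equal(unname(ac["P4", ]), c(2L, 1L))
  expect_equal(unname(st["P4", "dogA"]), "HOMOZYGOUS_ALT")
  # half-called genotype is not assessable; the called sample is
  expect_true(is.na(ac["P5", "dogA"]))
  expect_equal(unname(ac["P5", "dogB"]), 0L)
  # absent site without a qualification matrix: assumed covered
  expect_equal(unname(ac["P6", ]), c(0L, 0L))

  # with a qualification matrix, absent sites are gated by depth
  tracks <- list(dogA = flatTrack("dogA", 50L, pos = 900:1450),
                 dogB = flatTrack("dogB", 0L, pos = 900:1450))
  qm <- qualifyPanel(tracks, panel[panel$record_id != "P5", ])
  dm2 <- scanVcf(vcf, panel[panel$record_id != "P5", ], tinyMeta,
                 qualification = qm, threshold = 10)
  expect_equal(unname(altCounts(dm2)["P6", "dogA"]), 0L)
  expect_true(is.na(altCounts(dm2)["P6", "dogB"]))
  expect_equal(unname(callStatus(dm2)["P6", "dogB"]), "NOT_ASSESSABLE")

  # sample in metadata but absent from the VCF is fatal
  badMeta <- rbind(tinyMeta,
                   data.frame(sample_id = "dogC", sex = "male",
                              breed = "Pitbull"))
  expect_error(scanVcf(vcf, panel, badMeta), "dogC")
})

test_that("per-dog summaries count distinct variants, zygosity-agnostic", {
  # 6 samples x 4 variants; V1/V2 disease, V3/V4 not
  dos <- matrix(0L, 4, 6,
                dimnames = list(paste0("V", 1:4), paste0("s", 1:6)))
  dos["V1", 1] <- 1L; dos["V1", 2] <- 2L     # hom counts once
  dos["V3", 2] <- 1L; dos["V4", 3] <- 1L
  vars <- do.call(rbind, lapply(1:4, function(i)
    curatedVariant(paste0("V", i), position = 1000L + 100L * i,
                   is_disease = i <= 2)))
  dm <- makeDetectionMatrix(dos, vars)
  all <- perDogSummary(dm, diseaseOnly = FALSE)
  dis <- perDogSummary(dm, diseaseOnly = TRUE)
  expect_equal(unname(all$perSample), c(1L, 2L, 1L, 0L, 0L, 0L))
  expect_equal(all$nWithAtLeastOne, 3L)
  expect_equal(unname(dis$perSample), c(1L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(dis$nWithAtLeastOne, 2L)
  # disease counts never exceed all-variant counts
  expect_true(all(dis$perSample <= all$perSample))
  expect_equal(sum(all$histogram$n_samples), 6L)
  # zero case: histogram mass entirely at 0
  none <- perDogSummary(makeDetectionMatrix(matrix(0L, 2, 3)))
  expect_equal(none$nWithAtLeastOne, 0L)
  expect_equal(none$histogram$n_variants, 0L)
  expect_equal(none$histogram$n_samples, 3L)
})

test_that("splitting a multi-allelic site changes no call", {
  vcfA <- tempfile(fileext = ".vcf"); vcfB <- tempfile(fileext = ".vcf")
  head <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
            "##contig=<ID=chr1>",
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                    "FILTER", "INFO", "FORMAT", "dogA", "dogB"),
                  collapse = "\t"))
  writeLines(c(head,
               "chr1\t1000\t.\tA\tG,T\t99\tPASS\t.\tGT\t0/1\t0/2"),
             vcfA)
  # the same genotypes with the site split into biallelic records
  writeLines(c(head,
               "chr1\t1000\t.\tA\tG\t99\tPASS\t.\tGT\t0/1\t0/0",
               "chr1\t1000\t.\tA\tT\t99\tPASS\t.\tGT\t0/0\t0/1"),
             vcfB)
  panel <- curatedVariant("M1", position = 1000L, ref = "A", alt = "G")
  a <- scanVcf(vcfA, panel, tinyMeta)
  b <- scanVcf(vcfB, panel, tinyMeta)
  expect_identical(altCounts(a), altCounts(b))
  expect_identical(callStatus(a), callStatus(b))
})
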