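test_that("parsing preserves rows verbatim and tolerates blank fields", {
  recs <- rbind(rawRecord("A1"),
                rawRecord("A2", gene = "", location = "g.1234"),
                rawRecord("A3", location = "c.76del"))
  got <- readCatalogue(writeRawTsv(recs))
  expect_equal(nrow(got), 3L)
  expect_equal(got$record_id, c("A1", "A2", "A3"))   # row order preserved
  expect_equal(got$location[2], "g.1234")
  expect_equal(got$gene[2], "")                      # blank, not an error
  # empty data section -> empty record list
  empty <- readCatalogue(writeRawTsv(rawRecord()[0, ]))
  expect_equal(nrow(empty), 0L)
})

test_that("parser errors name missing mandatory columns", {
  recs <- rawRecord()
  bad <- recs[, setdiff(names(recs), "location")]
  expect_error(readCatalogue(writeRawTsv(bad)), "location")
  expect_error(readCatalogue(tempfile()), "not found")
})

test_that("column remapping via the dialect works and is checked", {
  recs <- rawRecord("B1")
  names(recs)[names(recs) == "gene"] <- "gene_symbol"
  path <- writeRawTsv(recs)
  got <- readCatalogue(path, dialect = list(
    sep = "\t", columns = c(gene = "gene_symbol")))
  expect_equal(got$gene, "MYGENE")
  expect_error(readCatalogue(path, dialect = list(
    columns = c(gene = "no_such_column"))), "no_such_column")
})

test_that("each inclusion criterion excludes with its own reason code", {
  recs <- rbind(
    rawRecord("ok1"),
    rawRecord("ok2", location = "m.404", chromosome = "",
              location_class = "CDS"),
    rawRecord("x_loc", location = "c.76del"),
    rawRecord("x_build", build = "CanFam2.0"),
    rawRecord("x_gene", gene = ""),
    rawRecord("x_size", ref = strrep("A", 21), alt = ""))
  cur <- curateCatalogue(readCatalogue(writeRawTsv(recs)))
  expect_equal(nRetained(cur$report), 2L)
  ex <- exclusions(cur$report)
  expect_equal(ex$reason[ex$record_id == "x_loc"], "NO_GENOMIC_LOCATION")
  expect_equal(ex$reason[ex$record_id == "x_build"], "WRONG_BUILD")
  expect_equal(ex$reason[ex$record_id == "x_gene"], "BAD_GENE_SYMBOL")
  expect_equal(ex$reason[ex$record_id == "x_size"], "SIZE_GT_MAX")
  # mitochondrial location implies chromosome MT
  expect_equal(cur$variants["ok2", "chromosome"], "MT")
  # 20 bp sits exactly on the inclusive size boundary
  atMax <- curateCatalogue(readCatalogue(writeRawTsv(
    rawRecord("b20", ref = strrep("A", 20), alt = ""))))
  expect_equal(nRetained(atMax$report), 1L)
  expect_equal(atMax$variants$size_bp, 20L)
})

test_that("curation report always reconciles and is idempotent", {
  sim <- simulateCatalogue(nCds = 20, nNoncoding = 3, nLarger = 7,
                           nDisease = 25,
                           postDesignMix = c(CDS_1BP = 8,
                                             NONCODING_1BP = 1,
                                             LARGER = 3),
                           nXLinked = 2, nMito = 1, seed = 5)
  cur <- curateCatalogue(readCatalogue(writeRawTsv(sim$records)))
  rep <- cur$report
  expect_equal(nInput(rep),
               rep@nExcludedStage1 + rep@nExcludedStage2 + nRetained(rep))
  # category partition: exactly one category each, sums to retained
  expect_true(all(cur$variants$category %in%
                    c("CDS_1BP", "NONCODING_1BP", "LARGER")))
  expect_equal(sum(table(cur$variants$category)), nRetained(rep))
  # curating the curated set excludes nothing
  recur <- curateCatalogue(readCatalogue(writeRawTsv(rawRecord(
    cur$variants$record_id[1], gene = cur$variants$gene[1],
    location = paste0("g.", cur$variants$position[1]),
    ref = cur$variants$ref[1], alt = cur$variants$alt[1]))))
  expect_equal(nrow(exclusions(recur$report)), 0L)
})

test_that("variants are classified by size then location", {
  expect_equal(classifyVariant(1, "CDS"), "CDS_1BP")
  expect_equal(classifyVariant(1, "promoter"), "NONCODING_1BP")
  expect_equal(classifyVariant(1, "intron"), "NONCODING_1BP")
  expect_equal(classifyVariant(1, "UTR"), "NONCODING_1BP")
  expect_equal(classifyVariant(5, "CDS"), "LARGER")
  expect_equal(classifyVariant(20, "intron"), "LARGER")
  expect_error(classifyVariant(21, "CDS"), "1-20")
  expect_error(classifyVariant(0, "CDS"), "1-20")
})

test_that("design-year split is exhaustive, disjoint, boundary-inclusive", {
  v <- do.call(rbind, lapply(1:3, function(i)
    curatedVariant(paste0("Y", i), year = c(2010L, 2014L, 2015L)[i])))
  sp <- splitByYear(v, designYear = 2014)
  expect_equal(sp$pre$record_id, c("Y1", "Y2"))   # 2014 itself is pre
  expect_equal(sp$post$record_id, "Y3")
  expect_equal(nrow(sp$pre) + nrow(sp$post) + nrow(sp$missing), nrow(v))
  # all pre-design -> empty post list
  allPre <- splitByYear(v[v$year <= 2014, ], 2014)
  expect_equal(nrow(allPre$post), 0L)
  # missing years fall in neither part but are reported
  v$year[2] <- NA
  sp2 <- splitByYear(v, 2014)
  expect_equal(sp2$missing$record_id, "Y2")
  expect_equal(nrow(sp2$pre) + nrow(sp2$post), 2L)
})
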