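test_that("variant spans cover the affected reference bases", {
  expect_equal(variantSpan(100, "A", "G"), 100L)            # SNV
  expect_equal(variantSpan(100, "TGA", ""), c(100L, 101L, 102L))
  expect_equal(variantSpan(100, "ACG", "T"), c(100L, 101L, 102L))
  # insertion between 100 and 101: both flanking anchors
  expect_equal(variantSpan(101, "", "ACGT"), c(100L, 101L))
  expect_equal(variantSpan(1, "", "AC"), 1L)                # clipped at 1
  expect_error(variantSpan(100, "", ""), "empty")
  expect_true(all(lengths(lapply(2:20, function(k)
    variantSpan(50, strrep("A", k), ""))) <= 21))
})

test_that("qualification requires every span base to reach the cutoff", {
  tr <- DepthTrack("s1", rep("chr1", 3), 100:102, c(12L, 9L, 15L))
  expect_false(qualifySpan(tr, "chr1", 100:102, 10))  # one base below
  expect_true(qualifySpan(tr, "chr1", c(100L, 102L), 10))
  # the cutoff is inclusive
  tr10 <- DepthTrack("s1", "chr1", 100L, 10L)
  expect_true(qualifySpan(tr10, "chr1", 100L, 10))
  expect_false(qualifySpan(tr10, "chr1", 100L, 11))
  # absent positions count as depth 0: all-zero track never qualifies
  empty <- DepthTrack("s1")
  for (th in c(10, 20, 30))
    expect_false(qualifySpan(empty, "chr1", 100:105, th))
  expect_equal(depthAt(empty, "chr1", 1:3), c(0L, 0L, 0L))
})

test_that("qualifyPanel agrees with a per-position brute force and is monotone", {
  set.seed(11)
  variants <- do.call(rbind, lapply(1:20, function(i) {
    k <- sample(1:5, 1)
    if (k == 1) curatedVariant(sprintf("Q%02d", i),
                               position = 500L + 50L * i)
    else curatedVariant(sprintf("Q%02d", i), position = 500L + 50L * i,
                        ref = strrep("A", k), alt = "", category = "LARGER")
  }))
  tracks <- lapply(1:4, function(s) {
    pos <- 480:1550
    DepthTrack(paste0("s", s), rep("chr1", length(pos)), pos,
               sample(0:40, length(pos), replace = TRUE))
  })
  names(tracks) <- paste0("s", 1:4)
  qm <- qualifyPanel(tracks, variants)
  for (th in c(10L, 20L, 30L)) {
    q <- isQualified(qm, th)
    for (i in seq_len(nrow(variants))) for (s in names(tracks)) {
      span <- variantSpan(variants$position[i], variants$ref[i],
                          variants$alt[i])
      ok <- TRUE                              # explicit per-position loop
      for (p in span)
        if (depthAt(tracks[[s]], "chr1", p) < th) ok <- FALSE
      expect_identical(unname(q[variants$record_id[i], s]), ok)
    }
  }
  expect_true(all(isQualified(qm, 30) <= isQualified(qm, 20)))
  expect_true(all(isQualified(qm, 20) <= isQualified(qm, 10)))
})

test_that("per-variant depth summarises per-sample span means", {
  v <- curatedVariant("D1", position = 1000L)
  one <- perVariantDepth(list(s1 = flatTrack("s1", 46L)), v)
  expect_equal(one$mean_depth, 46)
  expect_equal(c(one$min_depth, one$max_depth), c(46, 46))
  zeros <- perVariantDepth(list(s1 = DepthTrack("s1"),
                                s2 = DepthTrack("s2")), v)
  expect_equal(c(zeros$mean_depth, zeros$min_depth, zeros$max_depth),
               c(0, 0, 0))
  # span mean, not span min: 3 bp deletion with depths 10/20/30
  v3 <- curatedVariant("D3", position = 1000L, ref = "AAA", alt = "",
                       category = "LARGER")
  tr <- DepthTrack("s1", rep("chr1", 3), 1000:1002, c(10L, 20L, 30L))
  expect_equal(perVariantDepth(list(s1 = tr), v3)$mean_depth, 20)
})

test_that("category summaries reproduce counts, order statistics and pcts", {
  # counts engineered to hit min 178 / median 215 / max 238 out of 251
  counts <- c(178L, rep(215L, 47L), 238L)
  s <- summarizeCategory(counts, 251)
  expect_equal(s$min_pct, 70.92)
  expect_equal(s$median_pct, 85.66)
  expect_equal(s$max_pct, 94.82)
  expect_true(s$min <= s$median && s$median <= s$max)
  # all samples at the panel size -> 100.00 everywhere
  full <- summarizeCategory(rep(94L, 10L), 94)
  expect_true(all(unlist(full[paste0(c("min", "max", "median", "mean"),
                                     "_pct")]) == 100))
  # even sample count -> midpoint median
  expect_equal(summarizeCategory(c(1L, 2L), 10)$median, 1.5)
  # pct reconstruction holds for every cell of a random table
  set.seed(3)
  cnt <- sample(0:60, 30, replace = TRUE)
  s2 <- summarizeCategory(cnt, 60)
  for (nm in c("min", "max", "median", "mean"))
    expect_equal(s2[[paste0(nm, "_pct")]],
                 roundHalfUp(100 * s2[[nm]] / 60, 2))
})

test_that("per-sample counts are per category and fall with the cutoff", {
  sim <- smallCohort()
  qm <- qualifyPanel(sim$tracks, sim$variants)
  psc <- perSampleCounts(qm)
  # identity case: all qualified -> count equals category size
  dense <- qualifyPanel(list(sAll = flatTrack("sAll", 99L)),
                        curatedVariant("D1", position = 1000L))
  expect_equal(perSampleCounts(dense)$count, rep(1L, 3))
  # counts non-increasing in threshold for every sample x category
  wide <- reshape(psc, idvar = c("sample", "category"),
                  timevar = "threshold", direction = "wide")
  expect_true(all(wide$count.30 <= wide$count.20 &
                    wide$count.20 <= wide$count.10))
  # table layout reconciles with the long counts
  tab <- categoryTable(qm)
  cell <- psc[psc$category == "CDS_1BP" & psc$threshold == 10, ]
  row <- tab[tab$category == "CDS_1BP" & tab$threshold == 10, ]
  expect_equal(row$median, median(cell$count))
  expect_equal(row$median_pct, asPct(median(cell$count), row$n_variants))
})

test_that("GATK-style per-locus depth tables are readable", {
  df <- data.frame(Locus = paste0("chr1:", 100:104),
                   Total_Depth = 5L, Average_Depth = 2.5,
                   check.names = FALSE)
  df[["Depth_for_dogA"]] <- c(10L, 11L, 12L, 13L, 14L)
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- readDepthTrack(path, sampleId = "dogA", format = "gatk")
  expect_equal(depthAt(tr, "chr1", c(100L, 104L, 105L)), c(10L, 14L, 0L))
  expect_error(readDepthTrack(path, sampleId = "dogB", format = "gatk"),
               "Depth_for_dogB")
})
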