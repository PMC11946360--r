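## Per-base depth qualification.
##
## A variant locus counts as successfully sequenced in a sample at a depth
## cutoff only when EVERY base of its span reaches that cutoff — one
## shallow base fails the whole variant. Qualification is computed at
## >=10x, >=20x and >=30x; per-sample counts per category feed the
## performance summary tables.

#' Construct a DepthTrack from chromosome/position/depth vectors
#'
#' @param sampleId Sample identifier.
#' @param chrom,pos,depth Parallel vectors of per-base depth observations.
#'   Positions not listed are depth 0.
#' @return A \linkS4class{DepthTrack}.
#' @export
DepthTrack <- function(sampleId, chrom = character(), pos = integer(),
                       depth = integer()) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(depth))
  d <- as.integer(depth)
  names(d) <- .lockey(chrom, as.integer(pos))
  if (anyDuplicated(names(d)))
    d <- d[!duplicated(names(d))]
  new("DepthTrack", sampleId = as.character(sampleId), depth = d)
}

#' Read a per-sample depth track
#'
#' Two dialects are supported: a plain 3-column TSV (\code{chrom},
#' \code{pos}, \code{depth}; header optional but recommended) and the
#' GATK DepthOfCoverage per-locus table, whose first column is
#' \code{Locus} ("chrom:pos") and whose per-sample depths sit in
#' \code{Depth_for_<sample>} columns.
#'
#' @param path Path to the depth file.
#' @param sampleId Sample identifier. For the GATK dialect this selects
#'   the \code{Depth_for_<sampleId>} column; for the TSV dialect it just
#'   labels the track (default: file base name).
#' @param format \code{"tsv"} or \code{"gatk"}.
#' @return A \linkS4class{DepthTrack}.
#' @export
readDepthTrack <- function(path, sampleId = NULL, format = c("tsv", "gatk")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("depth file not found: ", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.(tsv|txt|depth)$", "", basename(path))
  if (format == "tsv") {
    first <- readLines(path, n = 1L)
    hasHeader <- !grepl("^\\S+\t[0-9]+\t[0-9]+$", first)
    d <- read.delim(path, header = hasHeader, colClasses = "character")
    if (ncol(d) < 3L) stop("depth TSV needs >=3 columns (chrom, pos, depth)")
    DepthTrack(sampleId, d[[1]], as.integer(d[[2]]), as.integer(d[[3]]))
  } else {
    d <- read.delim(path, header = TRUE, check.names = FALSE)
    col <- paste0("Depth_for_", sampleId)
    if (!col %in% names(d))
      stop("column '", col, "' absent from DepthOfCoverage table")
    locus <- strsplit(as.character(d$Locus), ":", fixed = TRUE)
    DepthTrack(sampleId,
               vapply(locus, `[`, character(1), 1L),
               as.integer(vapply(locus, `[`, character(1), 2L)),
               as.integer(d[[col]]))
  }
}

#' Depth at given positions (absent positions are 0)
#'
#' @param track A \linkS4class{DepthTrack}.
#' @param chrom Chromosome name.
#' @param pos Integer vector of 1-based positions.
#' @return Integer vector of depths, 0 where no observation exists.
#' @export
depthAt <- function(track, chrom, pos) {
  stopifnot(is(track, "DepthTrack"))
  d <- unname(track@depth[.lockey(chrom, as.integer(pos))])
  d[is.na(d)] <- 0L
  d
}

#' Positions whose depth must qualify for a variant
#'
#' Span conventions, driven by which reference bases the variant touches:
#' a substitution covers its own base; a deletion (or delins) covers every
#' deleted reference base; a pure insertion has no reference bases of its
#' own, so the two flanking anchor bases must qualify instead. Alleles are
#' expected in minimal representation; an insertion's \code{position} is
#' the base immediately after the insertion point, so its span is
#' \code{{position - 1, position}}.
#'
#' @param position 1-based position of the first affected reference base
#'   (for insertions: the base after the insertion point).
#' @param ref,alt Minimal-representation alleles (empty \code{ref} for a
#'   pure insertion, empty \code{alt} for a pure deletion).
#' @return Sorted integer vector of 1-based positions (length <= 21).
#' @export
variantSpan <- function(position, ref, alt) {
  position <- as.integer(position)
  stopifnot(length(position) == 1L, position >= 1L)
  if (!nzchar(ref)) {
    if (!nzchar(alt)) stop("ref and alt cannot both be empty")
    return(unique(c(max(1L, position - 1L), position)))
  }
  position:(position + nchar(ref) - 1L)
}

#' Is a variant span adequately sequenced at a depth cutoff?
#'
#' \code{TRUE} iff the depth at every position of the span is at least
#' \code{threshold} (the cutoff is inclusive).
#'
#' @param track A \linkS4class{DepthTrack}.
#' @param chrom Chromosome of the span.
#' @param span Integer positions from \code{\link{variantSpan}}.
#' @param threshold Positive depth cutoff.
#' @return Single logical.
#' @export
qualifySpan <- function(track, chrom, span, threshold) {
  stopifnot(threshold > 0, length(span) >= 1L)
  all(depthAt(track, chrom, span) >= threshold)
}

#' Qualify a whole panel across samples and thresholds
#'
#' @param tracks Named list of \linkS4class{DepthTrack}s (one per sample);
#'   names default to each track's \code{sampleId}.
#' @param variants Curated catalogue \code{data.frame}
#'   (\code{\link{curateCatalogue}}).
#' @param thresholds Integer depth cutoffs (default \code{c(10, 20, 30)}).
#' @return A \linkS4class{QualificationMatrix} with variants as rows,
#'   samples as columns and one logical assay per threshold.
#' @export
qualifyPanel <- function(tracks, variants, thresholds = c(10L, 20L, 30L)) {
  stopifnot(length(tracks) >= 1L, nrow(variants) >= 1L)
  if (is.null(names(tracks)))
    names(tracks) <- vapply(tracks, sampleId, character(1))
  thresholds <- sort(as.integer(thresholds))
  spans <- lapply(seq_len(nrow(variants)), function(i)
    variantSpan(variants$position[i], variants$ref[i], variants$alt[i]))
  minDepth <- vapply(tracks, function(tr)
    vapply(seq_len(nrow(variants)), function(i)
      min(depthAt(tr, variants$chromosome[i], spans[[i]])), integer(1)),
    integer(nrow(variants)))
  minDepth <- matrix(minDepth, nrow = nrow(variants),
                     dimnames = list(variants$record_id, names(tracks)))
  assays <- lapply(thresholds, function(th) minDepth >= th)
  names(assays) <- paste0("ge", thresholds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(variants, row.names = variants$record_id),
    colData = S4Vectors::DataFrame(sample_id = names(tracks),
                                   row.names = names(tracks)))
  qm <- new("QualificationMatrix", se)
  validObject(qm)
  qm
}

#' Per-variant depth summary across samples
#'
#' For each variant, the depth of its span in one sample is the mean depth
#' over the span's positions; the summary gives the mean, minimum and
#' maximum of that quantity over samples.
#'
#' @param tracks Named list of \linkS4class{DepthTrack}s.
#' @param variants Curated catalogue \code{data.frame}.
#' @return \code{data.frame} with \code{record_id}, \code{category},
#'   \code{mean_depth}, \code{min_depth}, \code{max_depth}.
#' @export
perVariantDepth <- function(tracks, variants) {
  stopifnot(length(tracks) >= 1L)
  if (is.null(names(tracks)))
    names(tracks) <- vapply(tracks, sampleId, character(1))
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    span <- variantSpan(variants$position[i], variants$ref[i],
                        variants$alt[i])
    per <- vapply(tracks, function(tr)
      mean(depthAt(tr, variants$chromosome[i], span)), numeric(1))
    data.frame(record_id = variants$record_id[i],
               category = variants$category[i],
               mean_depth = mean(per), min_depth = min(per),
               max_depth = max(per))
  })
  do.call(rbind, rows)
}

#' Category-level depth aggregates
#'
#' Averages the per-variant mean depths within each category and reports
#' the extremes of per-(variant, sample) mean span depth, the scale on
#' which a "range: 0x-..." statement is made.
#'
#' @param pvd Output of \code{\link{perVariantDepth}}.
#' @return \code{data.frame} with one row per category.
#' @export
categoryDepthSummary <- function(pvd) {
  stopifnot(all(c("category", "mean_depth") %in% names(pvd)))
  do.call(rbind, lapply(split(pvd, pvd$category), function(g)
    data.frame(category = g$category[1], n_variants = nrow(g),
               mean_depth = mean(g$mean_depth),
               min_depth = min(g$min_depth),
               max_depth = max(g$max_depth))))
}

#' Per-sample qualified-variant counts by category and threshold
#'
#' @param qm A \linkS4class{QualificationMatrix}.
#' @return Long \code{data.frame}: \code{sample}, \code{category},
#'   \code{threshold}, \code{count}, \code{n_variants}.
#' @export
perSampleCounts <- function(qm) {
  stopifnot(is(qm, "QualificationMatrix"))
  cats <- SummarizedExperiment::rowData(qm)$category
  out <- list()
  for (th in qualThresholds(qm)) {
    q <- isQualified(qm, th)
    for (cat in unique(cats)) {
      sel <- cats == cat
      counts <- colSums(q[sel, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        sample = colnames(qm), category = cat, threshold = th,
        count = as.integer(counts), n_variants = sum(sel))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise per-sample qualified counts for one category/threshold cell
#'
#' Produces the min / max / median / mean of the per-sample counts and the
#' same statistics as percentages of the category size, rounded half-up to
#' 2 decimals (\code{pct = 100 * statistic / nVariants}). The median uses
#' the standard midpoint rule for even sample numbers.
#'
#' @param counts Integer vector of per-sample qualified counts.
#' @param nVariants Number of variants in the category.
#' @return One-row \code{data.frame} with \code{min}, \code{max},
#'   \code{median}, \code{mean} and matching \code{*_pct} columns.
#' @export
summarizeCategory <- function(counts, nVariants) {
  stopifnot(length(counts) >= 1L, nVariants >= 1L)
  s <- c(min = min(counts), max = max(counts),
         median = median(counts), mean = mean(counts))
  out <- as.data.frame(as.list(s))
  for (nm in names(s)) out[[paste0(nm, "_pct")]] <- asPct(s[[nm]], nVariants)
  out
}

#' Per-sample performance table across categories and thresholds
#'
#' The analogue of a "per sample performance" summary table: one row per
#' (category, threshold) with min/max/median/mean qualified counts and
#' percentages.
#'
#' @param qm A \linkS4class{QualificationMatrix}.
#' @return \code{data.frame} ordered by category then threshold.
#' @export
categoryTable <- function(qm) {
  psc <- perSampleCounts(qm)
  cells <- split(psc, list(psc$category, psc$threshold))
  rows <- lapply(cells, function(cell) {
    cbind(data.frame(category = cell$category[1],
                     threshold = cell$threshold[1],
                     n_variants = cell$n_variants[1]),
          summarizeCategory(cell$count, cell$n_variants[1]))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$category, res$threshold), ]
  rownames(res) <- NULL
  res
}

#' Write a qualification matrix as long-format TSV
#'
#' @param qm A \linkS4class{QualificationMatrix}.
#' @param path Output path.
#' @export
writeQualification <- function(qm, path) {
  rows <- list()
  for (th in qualThresholds(qm)) {
    q <- isQualified(qm, th)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = rep(colnames(q), each = nrow(q)),
      record_id = rep(rownames(q), times = ncol(q)),
      threshold = th, qualified = as.vector(q))
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
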