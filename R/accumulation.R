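## Carrier accumulation over growing panel subsets.
##
## The question answered here: as the screened panel grows by random
## 50-variant increments, what fraction of the cohort has at least one
## detected variant? The last point always uses the full panel and is
## therefore seed-independent.

#' Carrier-accumulation curve over random panel subsets
#'
#' For each subset size, draws random variant subsets without replacement
#' and records the proportion of samples with at least one detected
#' variant in the subset, averaged over replicates. \code{NESTED} mode
#' grows one subset per replicate incrementally (each size extends the
#' previous draw), making every replicate's curve non-decreasing;
#' \code{INDEPENDENT} mode draws each size afresh. With \code{exact =
#' TRUE} the \code{INDEPENDENT} expectation is computed in closed form:
#' for a sample with \code{d} detected variants out of a panel of
#' \code{m}, the probability that a random size-\code{k} subset hits at
#' least one is \code{1 - choose(m - d, k) / choose(m, k)}.
#'
#' @param dm A \linkS4class{DetectionMatrix}.
#' @param sizes Increasing subset sizes; default a 50-variant-step grid
#'   up to the panel size. The full panel is always appended as the last
#'   point.
#' @param nReplicates Number of random replicates (default 100).
#' @param seed Integer seed (default 1).
#' @param mode \code{"NESTED"} (default) or \code{"INDEPENDENT"}.
#' @param diseaseOnly Restrict the panel to disease-associated variants.
#' @param exact Compute the expectation analytically instead of by Monte
#'   Carlo (\code{INDEPENDENT} mode only).
#' @return \code{data.frame} with \code{size}, \code{proportion} (mean
#'   over replicates), \code{min_prop}, \code{max_prop} (replicate
#'   spread; equal to \code{proportion} when \code{exact}). Attributes
#'   \code{mode}, \code{seed}, \code{n_replicates} record the draw
#'   settings.
#' @export
accumulationCurve <- function(dm, sizes = NULL, nReplicates = 100,
                              seed = 1, mode = c("NESTED", "INDEPENDENT"),
                              diseaseOnly = FALSE, exact = FALSE) {
  mode <- match.arg(mode)
  ac <- altCounts(dm)
  if (diseaseOnly) {
    dis <- SummarizedExperiment::rowData(dm)$is_disease
    dis[is.na(dis)] <- FALSE
    ac <- ac[dis, , drop = FALSE]
  }
  detected <- t(!is.na(ac) & ac >= 1L)  # samples x variants
  m <- ncol(detected); nS <- nrow(detected)
  stopifnot(m >= 1L, nS >= 1L)
  if (is.null(sizes))
    sizes <- if (m >= 50L) seq(50L, m, by = 50L) else integer(0)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes > m)) stop("subset size exceeds panel size ", m)
  if (!m %in% sizes) sizes <- c(sizes, m)

  propAtLeastOne <- function(cols)
    mean(rowSums(detected[, cols, drop = FALSE]) >= 1L)

  if (exact) {
    if (mode != "INDEPENDENT")
      stop("exact computation is defined for INDEPENDENT mode")
    d <- rowSums(detected)
    prop <- vapply(sizes, function(k)
      mean(1 - exp(lchoose(m - d, k) - lchoose(m, k))), numeric(1))
    res <- data.frame(size = sizes, proportion = prop,
                      min_prop = prop, max_prop = prop)
    nReplicates <- NA_integer_
  } else {
    set.seed(as.integer(seed))
    reps <- matrix(NA_real_, nReplicates, length(sizes))
    for (r in seq_len(nReplicates)) {
      if (mode == "NESTED") {
        perm <- sample.int(m)
        reps[r, ] <- vapply(sizes, function(k)
          propAtLeastOne(perm[seq_len(k)]), numeric(1))
      } else {
        reps[r, ] <- vapply(sizes, function(k)
          propAtLeastOne(sample.int(m, k)), numeric(1))
      }
    }
    res <- data.frame(size = sizes, proportion = colMeans(reps),
                      min_prop = apply(reps, 2, min),
                      max_prop = apply(reps, 2, max))
  }
  ## the full panel point never depends on the draw
  res[res$size == m, c("proportion", "min_prop", "max_prop")] <-
    propAtLeastOne(seq_len(m))
  attr(res, "mode") <- mode
  attr(res, "seed") <- as.integer(seed)
  attr(res, "n_replicates") <- nReplicates
  res
}

#' Plot a carrier-accumulation curve
#'
#' Base-graphics plot of the mean proportion against subset size, with
#' the replicate min/max band when available.
#'
#' @param curve Output of \code{\link{accumulationCurve}}.
#' @param ... Further arguments to \code{plot}.
#' @export
plotAccumulation <- function(curve, ...) {
  plot(curve$size, curve$proportion, type = "b", pch = 19,
       ylim = c(0, 1), xlab = "Number of variants screened",
       ylab = "Proportion of samples with >=1 detected variant", ...)
  if (any(curve$min_prop != curve$max_prop)) {
    graphics::arrows(curve$size, curve$min_prop, curve$size,
                     curve$max_prop, angle = 90, code = 3,
                     length = 0.03, col = "grey50")
  }
  invisible(curve)
}
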