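## Reference-free allele normalization.
##
## Catalogue entries describe indels in minimal (HGVS-like) form while
## variant callers emit anchored VCF records; both must reduce to one key
## before they can be compared. Trimming is purely string-based (no
## reference sequence): the shared suffix is removed first, then the
## shared prefix (advancing the position), leaving a minimal pair in which
## at most one allele may be empty.

#' Normalize an allele pair to a minimal comparable key
#'
#' Trims the common suffix, then the common prefix (advancing
#' \code{position} one base per trimmed prefix base). SNVs are fixed
#' points. Anchored indels reduce to the same key as their minimal
#' catalogue form, e.g. \code{(100, "ATG", "A")} and \code{(101, "TG",
#' "")} both become \code{(101, "TG", "")}. For a resulting pure
#' insertion, \code{position} is the reference base immediately after the
#' insertion point (matching \code{\link{variantSpan}}'s convention).
#' Trimming is idempotent.
#'
#' @param chrom Chromosome name.
#' @param position 1-based position of the first \code{ref} base.
#' @param ref,alt Allele strings over A/C/G/T (one may be empty, not
#'   both; they must differ).
#' @return List with \code{chrom}, \code{position}, \code{ref},
#'   \code{alt} and \code{key} (a single string
#'   \code{"chrom:pos:ref:alt"} usable for matching).
#' @export
normalizeAllele <- function(chrom, position, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!grepl("^[ACGT]*$", ref) || !grepl("^[ACGT]*$", alt))
    stop("alleles must consist of A/C/G/T only: ", ref, "/", alt)
  if (ref == alt)
    stop("degenerate allele pair (ref == alt): ", ref)
  position <- as.integer(position)
  # shared suffix
  while (nzchar(ref) && nzchar(alt) &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # shared prefix, advancing the anchor
  while (nzchar(ref) && nzchar(alt) &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    position <- position + 1L
  }
  list(chrom = as.character(chrom), position = position, ref = ref,
       alt = alt, key = paste(chrom, position, ref, alt, sep = ":"))
}

## vectorised key helper for catalogue data.frames
.panelKeys <- function(variants) {
  vapply(seq_len(nrow(variants)), function(i)
    normalizeAllele(variants$chromosome[i], variants$position[i],
                    variants$ref[i], variants$alt[i])$key,
    character(1))
}
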