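#' Construct a GenomeMap
#'
#' @param chrom character vector of chromosome names.
#' @param length integer vector of chromosome lengths in bp.
#' @param centromere integer vector of centromere midpoints in bp.
#' @return A [GenomeMap-class] object.
#' @examples
#' GenomeMap("chrI", 230218L, 151523L)
#' @export
GenomeMap <- function(chrom, length, centromere) {
  new("GenomeMap", chrom = as.character(chrom),
      length = as.integer(length), centromere = as.integer(centromere))
}

#' The S. cerevisiae R64-1-1 genome map
#'
#' Sixteen nuclear chromosomes with their R64-1-1 (sacCer3, 2011) physical
#' lengths and centromere midpoints.
#'
#' @return A [GenomeMap-class] with 16 chromosomes.
#' @examples
#' g <- sgdGenome()
#' sum(chromLengths(g))  # ~12.07 Mb
#' @export
sgdGenome <- function() {
  GenomeMap(
    chrom = paste0("chr", c("I", "II", "III", "IV", "V", "VI", "VII",
                            "VIII", "IX", "X", "XI", "XII", "XIII", "XIV",
                            "XV", "XVI")),
    length = c(230218L, 813184L, 316620L, 1531933L, 576874L, 270161L,
               1090940L, 562643L, 439888L, 745751L, 666816L, 1078177L,
               924431L, 784333L, 1091291L, 948066L),
    centromere = c(151523L, 238265L, 114443L, 449770L, 152045L, 148568L,
                   496979L, 105644L, 355687L, 436366L, 440187L, 150887L,
                   268090L, 628816L, 326643L, 556015L))
}

#' @describeIn GenomeMap-class chromosome names
#' @param x,object a GenomeMap
#' @export
chromNames <- function(x) x@chrom

#' @describeIn GenomeMap-class named chromosome lengths (bp)
#' @export
chromLengths <- function(x) stats::setNames(x@length, x@chrom)

#' @describeIn GenomeMap-class named centromere midpoints (bp)
#' @export
centromeres <- function(x) stats::setNames(x@centromere, x@chrom)

setMethod("show", "GenomeMap", function(object) {
  cat("GenomeMap with", length(object@chrom), "chromosomes,",
      sprintf("%.2f Mb total\n", sum(object@length) / 1e6))
  cat("  ", paste(utils::head(object@chrom, 4), collapse = ", "),
      if (length(object@chrom) > 4) "..." else "", "\n")
})

setMethod("show", "TetradGenotypes", function(object) {
  nm <- sum(vapply(object@positions, length, 1L))
  cat("TetradGenotypes", object@tetradId, "-", length(object@positions),
      "chromosomes,", nm, "markers\n")
})

setMethod("show", "GammaFit", function(object) {
  cat(sprintf(
    "One-pathway gamma fit: shape = %.3f, rate = %.4f /cM (n = %d, logLik = %.1f, %s)\n",
    object@shape, object@rate, object@nDistances, object@logLik,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "TwoPathwayFit", function(object) {
  cat(sprintf(
    "Two-pathway gamma mixture: p = %.3f, shape1 = %.3f, rate1 = %.4f, rate2 = %.4f\n",
    object@p, object@shape1, object@rate1, object@rate2))
  cat(sprintf("  %d EM iterations, logLik = %.2f%s%s\n", object@nIter,
      object@logLikTrace[length(object@logLikTrace)],
      if (object@converged) ", converged" else ", NOT converged",
      if (object@degenerate) ", DEGENERATE (component collapsed)" else ""))
})

setMethod("show", "CoCProfile", function(object) {
  cat(sprintf(
    "CoCProfile: %d kb bins, %d tetrads, %d separation classes\n",
    as.integer(object@binSize / 1000), object@nTetrads, nrow(object@table)))
  cat(sprintf("  adjacent-class CoC = %.3f, interference (1 - CoC) = %.3f\n",
      1 - object@interferenceAdjacent, object@interferenceAdjacent))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: %d tetrads, %.1f COs/meiosis (Class I fraction %.2f, shape %.2f), %.1f NCOs/meiosis, %d markers\n",
    object@nTetrads, sum(object@meanCoPerChrom), object@classIFraction,
    object@gammaShape, sum(object@ncoRatePerChrom), object@markerCount))
})
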