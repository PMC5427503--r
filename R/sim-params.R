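#' Default per-chromosome crossover allocation weights
#'
#' Allocates a genome-wide event mean over chromosomes proportionally to
#' physical length plus a fixed per-chromosome baseline. The baseline gives
#' small chromosomes the mild excess of events per kb seen in budding-yeast
#' recombination maps (chrI receives about 2.2 crossovers per meiosis at a
#' wild-type genome total of 93, roughly twice its share by length alone).
#'
#' @param genome a [GenomeMap-class].
#' @param baselineBp per-chromosome baseline added to the physical length
#'   before normalization (default 1e5 bp).
#' @return named numeric weights summing to 1.
#' @export
defaultCoWeights <- function(genome, baselineBp = 1e5) {
  L <- chromLengths(genome)
  w <- L + baselineBp
  w / sum(w)
}

#' Construct simulation parameters
#'
#' Builds a [SimParams-class] holding the conditions of a synthetic tetrad
#' dataset. Per-chromosome means may be given directly or derived from
#' genome-wide totals via [defaultCoWeights()].
#'
#' @param genome a [GenomeMap-class].
#' @param nTetrads tetrads per dataset.
#' @param totalCo genome-wide mean crossovers per meiosis (ignored when
#'   `meanCoPerChrom` is supplied).
#' @param meanCoPerChrom optional named vector of per-chromosome crossover
#'   means (lambda_c).
#' @param totalNco genome-wide mean noncrossover conversions per meiosis.
#' @param ncoRatePerChrom optional named per-chromosome noncrossover means.
#' @param classIFraction fraction of crossovers from the interfering Class I
#'   pathway.
#' @param gammaShape Class I renewal shape (1 = no interference).
#' @param coGcProb probability a crossover has a detectable associated
#'   conversion tract.
#' @param coGcTractMedianBp,ncoGcTractMedianBp median conversion-tract
#'   lengths (bp).
#' @param complexRate genome-wide mean of complex two-chromatid conversions
#'   (default 0).
#' @param markerCount total SNP markers on the genome.
#' @return A [SimParams-class].
#' @examples
#' p <- simParams(sgdGenome(), nTetrads = 10, totalCo = 93.4)
#' sum(meanCoPerChrom(p))
#' @export
simParams <- function(genome, nTetrads = 1L, totalCo = 93.4,
                      meanCoPerChrom = NULL, totalNco = 46,
                      ncoRatePerChrom = NULL, classIFraction = 1,
                      gammaShape = 1.83, coGcProb = 0.7,
                      coGcTractMedianBp = 2000, ncoGcTractMedianBp = 1500,
                      complexRate = 0, markerCount = 59215L) {
  w <- defaultCoWeights(genome)
  if (is.null(meanCoPerChrom)) meanCoPerChrom <- totalCo * w
  if (is.null(ncoRatePerChrom)) ncoRatePerChrom <- totalNco * w
  if (!identical(sort(names(meanCoPerChrom)), sort(chromNames(genome))))
    stop("meanCoPerChrom must be named by the genome's chromosomes")
  new("SimParams",
      meanCoPerChrom = meanCoPerChrom[chromNames(genome)],
      classIFraction = classIFraction, gammaShape = gammaShape,
      ncoRatePerChrom = ncoRatePerChrom[chromNames(genome)],
      coGcProb = coGcProb, coGcTractMedianBp = coGcTractMedianBp,
      ncoGcTractMedianBp = ncoGcTractMedianBp, complexRate = complexRate,
      markerCount = as.integer(markerCount), nTetrads = as.integer(nTetrads))
}

#' Genotype presets for the four strains of the study system
#'
#' Returns [simParams()] preconfigured with the published genome-wide
#' crossover/noncrossover means, one-pathway interference shapes and
#' conversion-tract medians of the S288c/YJM789 hybrid genotypes.
#'
#' @param genotype one of "wild_type", "mlh3", "pch2", "mlh3_pch2".
#' @param genome a [GenomeMap-class].
#' @param nTetrads tetrads per dataset; defaults to the number of sequenced
#'   tetrads of that genotype (66, 19, 15, 20).
#' @param ... further arguments passed to [simParams()] (override defaults).
#' @return A [SimParams-class].
#' @examples
#' presetParams("wild_type")
#' @export
presetParams <- function(genotype = c("wild_type", "mlh3", "pch2",
                                      "mlh3_pch2"),
                         genome = sgdGenome(), nTetrads = NULL, ...) {
  genotype <- match.arg(genotype)
  tab <- list(
    wild_type = list(co = 93.4, nco = 46.0, shape = 1.83, n = 66L,
                     coTract = 2000, ncoTract = 1500),
    mlh3      = list(co = 64.4, nco = 49.5, shape = 1.29, n = 19L,
                     coTract = 2400, ncoTract = 1700),
    pch2      = list(co = 136.5, nco = 85.9, shape = 1.33, n = 15L,
                     coTract = 2700, ncoTract = 1800),
    mlh3_pch2 = list(co = 99.8, nco = 93.6, shape = 1.13, n = 20L,
                     coTract = 3900, ncoTract = 2200))[[genotype]]
  if (is.null(nTetrads)) nTetrads <- tab$n
  args <- list(genome = genome, nTetrads = nTetrads, totalCo = tab$co,
               totalNco = tab$nco, gammaShape = tab$shape,
               coGcTractMedianBp = tab$coTract,
               ncoGcTractMedianBp = tab$ncoTract)
  args[names(list(...))] <- list(...)
  do.call(simParams, args)
}

#' @describeIn simParams per-chromosome crossover means of a SimParams
#' @param params a [SimParams-class]
#' @export
meanCoPerChrom <- function(params) params@meanCoPerChrom
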