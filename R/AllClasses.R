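#' @import methods
NULL

#' GenomeMap: the physical coordinate frame
#'
#' Chromosome names, physical lengths and centromere positions for a
#' 16-chromosome budding-yeast genome (or any custom genome). All positions
#' are 1-based bp.
#'
#' @slot chrom character vector of unique chromosome names.
#' @slot length integer vector of chromosome lengths (bp).
#' @slot centromere integer vector of centromere midpoints (bp), strictly
#'   inside each chromosome.
#' @seealso [sgdGenome()] for the S. cerevisiae R64-1-1 default.
#' @exportClass GenomeMap
setClass("GenomeMap",
  representation(chrom = "character", length = "integer",
                 centromere = "integer"))

setValidity("GenomeMap", function(object) {
  n <- length(object@chrom)
  if (length(object@length) != n || length(object@centromere) != n)
    return("chrom, length and centromere must have equal length")
  if (anyDuplicated(object@chrom))
    return("chromosome names must be unique")
  if (any(object@length <= 0L))
    return("chromosome lengths must be positive")
  if (any(object@centromere <= 0L | object@centromere >= object@length))
    return("centromeres must satisfy 0 < centromere < length")
  TRUE
})

#' SimParams: simulation parameters for synthetic tetrads
#'
#' Holds the study conditions for the synthetic tetrad generator: the
#' per-chromosome mean crossover counts (Poisson means lambda_c), the fraction
#' of crossovers placed by the interfering (Class I) gamma-renewal pathway and
#' its shape, the per-chromosome noncrossover rates, gene-conversion tract
#' medians, and the marker count.
#'
#' @slot meanCoPerChrom named numeric, mean crossovers per chromosome per
#'   meiosis (lambda_c >= 0); the genome-wide mean is `sum(meanCoPerChrom)`.
#' @slot classIFraction fraction p of crossovers from the interfering Class I
#'   pathway (gamma renewal); the remaining (1-p) are Poisson (Class II).
#' @slot gammaShape renewal shape nu (>= 1) for Class I inter-crossover
#'   distances; nu = 1 makes Class I itself a Poisson process.
#' @slot ncoRatePerChrom named numeric, mean noncrossover gene-conversion
#'   tracts per chromosome per meiosis.
#' @slot coGcProb probability that a crossover carries a detectable associated
#'   conversion tract.
#' @slot coGcTractMedianBp,ncoGcTractMedianBp median tract lengths (bp) of the
#'   geometric tract-length law for crossover-associated and noncrossover
#'   conversions.
#' @slot complexRate mean per-chromosome rate of complex (two-chromatid)
#'   conversion events; 0 by default.
#' @slot markerCount total number of SNP markers placed on the genome.
#' @slot nTetrads default number of tetrads generated per dataset.
#' @exportClass SimParams
setClass("SimParams",
  representation(meanCoPerChrom = "numeric", classIFraction = "numeric",
                 gammaShape = "numeric", ncoRatePerChrom = "numeric",
                 coGcProb = "numeric", coGcTractMedianBp = "numeric",
                 ncoGcTractMedianBp = "numeric", complexRate = "numeric",
                 markerCount = "integer", nTetrads = "integer"))

setValidity("SimParams", function(object) {
  if (is.null(names(object@meanCoPerChrom)) ||
      is.null(names(object@ncoRatePerChrom)))
    return("meanCoPerChrom and ncoRatePerChrom must be named by chromosome")
  if (any(object@meanCoPerChrom < 0) || any(object@ncoRatePerChrom < 0))
    return("per-chromosome rates must be nonnegative")
  if (object@classIFraction < 0 || object@classIFraction > 1)
    return("classIFraction must lie in [0, 1]")
  if (object@gammaShape < 1)
    return("gammaShape must be >= 1")
  if (object@coGcProb < 0 || object@coGcProb > 1)
    return("coGcProb must lie in [0, 1]")
  if (object@coGcTractMedianBp <= 0 || object@ncoGcTractMedianBp <= 0)
    return("tract medians must be positive")
  if (object@complexRate < 0)
    return("complexRate must be nonnegative")
  if (object@nTetrads < 1L)
    return("nTetrads must be >= 1")
  TRUE
})

#' TetradGenotypes: four spore genotype vectors along a genome
#'
#' One sequenced (or simulated) tetrad: per chromosome, sorted marker
#' positions and a 4 x M genotype matrix over {0, 1, NA}, where 0 is the
#' S288c allele, 1 the YJM789 allele and NA a missing call.
#'
#' @slot tetradId single character identifier.
#' @slot positions named list (by chromosome) of strictly increasing integer
#'   marker positions (bp, 1-based).
#' @slot genotypes named list (by chromosome) of 4 x M integer matrices.
#' @exportClass TetradGenotypes
setClass("TetradGenotypes",
  representation(tetradId = "character", positions = "list",
                 genotypes = "list"))

setValidity("TetradGenotypes", function(object) {
  if (length(object@tetradId) != 1L)
    return("tetradId must be a single string")
  if (!identical(names(object@positions), names(object@genotypes)))
    return("positions and genotypes must be parallel named lists")
  for (chrom in names(object@positions)) {
    pos <- object@positions[[chrom]]
    g <- object@genotypes[[chrom]]
    if (!is.matrix(g) || nrow(g) != 4L || ncol(g) != length(pos))
      return(sprintf("genotypes[['%s']] must be a 4 x %d matrix",
                     chrom, length(pos)))
    if (is.unsorted(pos, strictly = TRUE))
      return(sprintf("positions on %s must be strictly increasing", chrom))
    if (!all(g %in% c(0L, 1L, NA)))
      return("genotypes must be 0, 1 or NA")
  }
  TRUE
})

#' GammaFit: one-pathway gamma interference fit
#'
#' Maximum-likelihood two-parameter gamma fit to pooled inter-crossover
#' distances (cM). Shape 1 corresponds to no interference; shape > 1 to
#' positive interference.
#'
#' @slot shape fitted gamma shape (dimensionless).
#' @slot rate fitted gamma rate (per cM).
#' @slot nDistances number of distances used.
#' @slot logLik maximized log-likelihood.
#' @slot converged logical convergence flag of the score solve.
#' @exportClass GammaFit
setClass("GammaFit",
  representation(shape = "numeric", rate = "numeric", nDistances = "integer",
                 logLik = "numeric", converged = "logical"))

setValidity("GammaFit", function(object) {
  if (object@shape <= 0 || object@rate <= 0)
    return("shape and rate must be positive")
  if (!is.finite(object@logLik)) return("log-likelihood must be finite")
  TRUE
})

#' TwoPathwayFit: two-component gamma-mixture interference fit
#'
#' EM fit of p * Gamma(nu, rate1) + (1 - p) * Gamma(1, rate2) to
#' inter-crossover distances; the second (Class II) component has its shape
#' fixed at 1, so it is the no-interference exponential pathway.
#'
#' @slot p mixing proportion of the interfering component.
#' @slot shape1,rate1 gamma parameters of the interfering component.
#' @slot rate2 rate of the shape-1 component.
#' @slot nIter EM iterations run.
#' @slot logLikTrace per-iteration log-likelihood (non-decreasing).
#' @slot converged,degenerate status flags; degenerate marks p collapsed to
#'   0 or 1 (component unidentifiable).
#' @exportClass TwoPathwayFit
setClass("TwoPathwayFit",
  representation(p = "numeric", shape1 = "numeric", rate1 = "numeric",
                 rate2 = "numeric", nIter = "integer",
                 logLikTrace = "numeric", converged = "logical",
                 degenerate = "logical"))

#' CoCProfile: coefficient-of-coincidence profile on genome bins
#'
#' The genome is partitioned into fixed-size bins (default 25 kb); for every
#' same-chromosome bin pair the observed and expected double-crossover counts
#' across tetrads are accumulated by separation class. Interference at the
#' adjacent (0-25 kb) class is 1 - CoC.
#'
#' @slot binSize bin size in bp.
#' @slot nTetrads number of tetrads profiled.
#' @slot table data.frame with columns separation_kb, coc, observed,
#'   expected, n_pairs (one row per separation class).
#' @slot interferenceAdjacent 1 - mean CoC at the adjacent class.
#' @exportClass CoCProfile
setClass("CoCProfile",
  representation(binSize = "numeric", nTetrads = "integer",
                 table = "data.frame", interferenceAdjacent = "numeric"))
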