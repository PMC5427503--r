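## Classical marker-based tetrad genetics: PD/NPD/TT classification, Perkins
## map distances, spore-based distances and spore-viability tests.

#' Classify a two-locus tetrad as PD, NPD or TT
#'
#' Standard ditype classification: parental ditype when only the two
#' parental two-locus classes occur, nonparental ditype when only the two
#' recombinant classes occur, tetratype when all four occur. Alleles are
#' coded 0/1; the parental combinations are (0,0) and (1,1).
#'
#' @param locus1,locus2 integer vectors of the 4 spores' genotypes at the
#'   two loci.
#' @return "PD", "NPD", "TT", or "unscorable" when either locus does not
#'   segregate 2:2. Invariant under spore permutation.
#' @examples
#' classifyDitype(c(0, 0, 1, 1), c(0, 0, 1, 1))  # "PD"
#' @export
classifyDitype <- function(locus1, locus2) {
  if (anyNA(locus1) || anyNA(locus2) ||
      sum(locus1 == 0) != 2L || sum(locus2 == 0) != 2L)
    return("unscorable")
  recomb <- locus1 != locus2
  nRec <- sum(recomb)
  if (nRec == 0L) "PD" else if (nRec == 4L) "NPD" else "TT"
}

#' Perkins map distance from tetrad class counts
#'
#' cM = 100 * (TT/2 + 3 * NPD) / (PD + NPD + TT); additive over intervals.
#'
#' @param pd,npd,tt nonnegative tetrad class counts (vectorized; one element
#'   per interval).
#' @return map distance(s) in cM.
#' @examples
#' perkinsDistance(50, 0, 50)  # 25 cM
#' @export
perkinsDistance <- function(pd, npd, tt) {
  n <- pd + npd + tt
  if (any(n == 0)) stop("no tetrads in at least one interval")
  100 * (tt / 2 + 3 * npd) / n
}

#' Spore-based map distance
#'
#' cM = 100 * recombinant / (recombinant + parental); no mapping-function
#' correction.
#'
#' @param parental,recombinant nonnegative spore counts (vectorized).
#' @return map distance(s) in cM.
#' @examples
#' sporeDistance(90, 10)  # 10 cM
#' @export
sporeDistance <- function(parental, recombinant) {
  tot <- parental + recombinant
  if (any(tot == 0)) stop("no spores in at least one interval")
  100 * recombinant / tot
}

#' Spore-viability comparison and MI-nondisjunction signature
#'
#' Compares two viability tables (counts of tetrads with 0-4 viable spores)
#' with a 2 x 2 Fisher exact test on total (viable, dead) spores, and scores
#' the Meiosis I nondisjunction signature: the excess of the even
#' (4, 2, 0 viable) tetrad classes over the odd (3, 1) classes,
#' (f4 + f2 + f0) - (f3 + f1); positive scores are flagged as
#' MI-nondisjunction-like.
#'
#' @param countsA,countsB numeric vectors of length 5: tetrads with 4, 3, 2,
#'   1 and 0 viable spores, in that order.
#' @return list(fisherP, viabilityPctA, viabilityPctB, signatureA,
#'   signatureB, flaggedA, flaggedB).
#' @export
viabilityTests <- function(countsA, countsB) {
  summarize <- function(counts) {
    if (length(counts) != 5L || any(counts < 0))
      stop("counts must be 5 nonnegative values (4,3,2,1,0 viable spores)")
    N <- sum(counts)
    if (N == 0) stop("empty viability table")
    viable <- sum(counts * c(4, 3, 2, 1, 0))
    f <- counts / N
    list(viable = viable, dead = 4 * N - viable,
         pct = 100 * viable / (4 * N),
         signature = (f[1] + f[3] + f[5]) - (f[2] + f[4]))
  }
  a <- summarize(countsA)
  b <- summarize(countsB)
  ft <- stats::fisher.test(matrix(c(a$viable, a$dead, b$viable, b$dead),
                                  nrow = 2, byrow = TRUE))
  list(fisherP = ft$p.value, viabilityPctA = a$pct,
       viabilityPctB = b$pct, signatureA = a$signature,
       signatureB = b$signature, flaggedA = a$signature > 0,
       flaggedB = b$signature > 0)
}

#' Score a marker pair across tetrads and sum Perkins distances
#'
#' Convenience wrapper: classifies every tetrad at two marker positions and
#' returns the class counts and Perkins distance.
#'
#' @param tetrads list of [TetradGenotypes-class].
#' @param chrom chromosome name.
#' @param pos1,pos2 marker positions (must exist in every tetrad's map).
#' @return list(PD, NPD, TT, unscorable, cM).
#' @export
tetradClassCounts <- function(tetrads, chrom, pos1, pos2) {
  classes <- vapply(tetrads, function(tt) {
    pos <- tt@positions[[chrom]]
    i1 <- match(pos1, pos); i2 <- match(pos2, pos)
    if (is.na(i1) || is.na(i2)) return("unscorable")
    classifyDitype(tt@genotypes[[chrom]][, i1],
                   tt@genotypes[[chrom]][, i2])
  }, character(1))
  pd <- sum(classes == "PD"); npd <- sum(classes == "NPD")
  tt <- sum(classes == "TT")
  list(PD = pd, NPD = npd, TT = tt,
       unscorable = sum(classes == "unscorable"),
       cM = perkinsDistance(pd, npd, tt))
}
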