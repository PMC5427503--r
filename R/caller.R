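## Event caller: annotates crossovers, noncrossovers and gene-conversion
## tracts from four-spore genotype tables, working on maximal blocks of
## identical 4-spore genotype vectors.

#' Classify the segregation of one marker column
#'
#' @param column integer vector of 4 genotypes over {0, 1, NA}.
#' @return one of "2:2", "3:1", "1:3", "4:0", "0:4", "missing"; the class is
#'   the count of allele 0 vs allele 1 among the four spores, "missing" if
#'   any spore call is NA.
#' @examples
#' classifySegregation(c(0L, 0L, 1L, 1L))  # "2:2"
#' @export
classifySegregation <- function(column) {
  if (anyNA(column)) return("missing")
  c("0:4", "1:3", "2:2", "3:1", "4:0")[sum(column == 0L) + 1L]
}

#' Segment a chromosome into blocks of constant 4-spore genotype
#'
#' Markers with any missing call are excluded from block boundaries (treated
#' as uninformative). Blocks are maximal runs of consecutive informative
#' markers with identical genotype vectors.
#'
#' @param tetrad a [TetradGenotypes-class].
#' @param chrom chromosome name.
#' @return list with `blocks` (data.frame: start_bp, end_bp, n_markers,
#'   class), `geno` (4 x nBlocks matrix of the block genotype vectors) and
#'   `nMissing` (count of excluded markers).
#' @export
segmentBlocks <- function(tetrad, chrom) {
  pos <- tetrad@positions[[chrom]]
  g <- tetrad@genotypes[[chrom]]
  ok <- colSums(is.na(g)) == 0L
  pos <- pos[ok]
  g <- g[, ok, drop = FALSE]
  if (!length(pos))
    return(list(blocks = data.frame(start_bp = numeric(0),
                                    end_bp = numeric(0),
                                    n_markers = integer(0),
                                    class = character(0)),
                geno = matrix(integer(0), 4, 0), nMissing = sum(!ok)))
  key <- g[1, ] + 2L * g[2, ] + 4L * g[3, ] + 8L * g[4, ]
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  geno <- g[, starts, drop = FALSE]
  cls <- vapply(seq_along(starts),
                function(i) classifySegregation(geno[, i]), character(1))
  list(blocks = data.frame(start_bp = pos[starts], end_bp = pos[ends],
                           n_markers = r$lengths, class = cls,
                           stringsAsFactors = FALSE),
       geno = geno, nMissing = sum(!ok))
}

.emptyEvents <- function() {
  data.frame(tetrad_id = character(0), chrom = character(0),
             class = character(0), start = numeric(0), end = numeric(0),
             midpoint = numeric(0), chromatids = character(0),
             gc_type = integer(0), co_associated = logical(0),
             direction = integer(0), tract_start = numeric(0),
             tract_end = numeric(0), tract_min = numeric(0),
             tract_mid = numeric(0), tract_max = numeric(0),
             stringsAsFactors = FALSE)
}

.eventRow <- function(tetradId, chrom, class, start, end, chromatids,
                      gcType = NA_integer_, coAssociated = FALSE,
                      direction = NA_integer_, tractStart = NA_real_,
                      tractEnd = NA_real_, tractMin = NA_real_,
                      tractMid = NA_real_, tractMax = NA_real_) {
  data.frame(tetrad_id = tetradId, chrom = chrom, class = class,
             start = start, end = end, midpoint = (start + end) / 2,
             chromatids = chromatids, gc_type = gcType,
             co_associated = coAssociated, direction = direction,
             tract_start = tractStart, tract_end = tractEnd,
             tract_min = tractMin, tract_mid = tractMid,
             tract_max = tractMax, stringsAsFactors = FALSE)
}

#' Conversion-tract length estimates
#'
#' Minimum estimate: span of the converted markers; maximum estimate:
#' distance between the nearest non-converted flanking markers; mid
#' estimate: their average (the default reported length). Missing flanks
#' (tract at a chromosome end) fall back on the converted span.
#'
#' @param firstBp,lastBp positions of the first and last converted marker.
#' @param leftFlankBp,rightFlankBp positions of the nearest non-converted
#'   markers (NA if none).
#' @return numeric c(min, mid, max) in bp.
#' @examples
#' tractLengths(10000, 11000, 9000, 12500)  # 1000 2250 3500
#' @export
tractLengths <- function(firstBp, lastBp, leftFlankBp = NA,
                         rightFlankBp = NA) {
  minLen <- lastBp - firstBp
  lo <- if (is.na(leftFlankBp)) firstBp else leftFlankBp
  hi <- if (is.na(rightFlankBp)) lastBp else rightFlankBp
  maxLen <- hi - lo
  c(min = minLen, mid = (minLen + maxLen) / 2, max = maxLen)
}

## Decide which chromatids a non-2:2 block converts, judged against the
## flanking 2:2 genotype vectors (either may be NULL at chromosome ends).
## Returns list(conv = chromatid indices, gained = allele gained).
.convertedChromatids <- function(vb, vl, vr) {
  convL <- if (is.null(vl)) NULL else which(vb != vl)
  convR <- if (is.null(vr)) NULL else which(vb != vr)
  conv <-
    if (is.null(convL)) convR
    else if (is.null(convR)) convL
    else if (identical(vl, vr)) convL
    else if (length(convL) < length(convR)) convL
    else convR                              # tie -> right flank
  list(conv = conv, gained = vb[conv])
}

## Annotate the conversion tracts lying between (or outside) 2:2 blocks.
## innerIdx: block indices of a maximal run of non-2:2 blocks;
## vl/vr: flanking 2:2 genotype vectors (NULL at ends); coChromatids:
## chromatids of crossovers called across this gap (integer vector).
.tractEvents <- function(tetradId, chrom, seg, innerIdx, vl, vr,
                         coChromatids, mergeGapBp = 5000) {
  blocks <- seg$blocks
  out <- list()
  i <- 1L
  while (i <= length(innerIdx)) {
    j <- i
    b <- innerIdx[i]
    cc <- .convertedChromatids(seg$geno[, b], vl, vr)
    ## merge consecutive blocks with the same converted set + direction
    while (j < length(innerIdx) && innerIdx[j + 1L] == innerIdx[j] + 1L) {
      cc2 <- .convertedChromatids(seg$geno[, innerIdx[j + 1L]], vl, vr)
      if (identical(cc2$conv, cc$conv) &&
          identical(cc2$gained, cc$gained)) j <- j + 1L else break
    }
    bLast <- innerIdx[j]
    firstBp <- blocks$start_bp[b]
    lastBp <- blocks$end_bp[bLast]
    leftFlank <- if (b > 1L) blocks$end_bp[b - 1L] else NA
    rightFlank <- if (bLast < nrow(blocks)) blocks$start_bp[bLast + 1L]
                  else NA
    tl <- tractLengths(firstBp, lastBp, leftFlank, rightFlank)
    nConv <- length(cc$conv)
    gcType <- if (nConv == 1L) 0L
              else if (nConv == 2L && length(unique(cc$gained)) == 1L) 2L
              else if (nConv == 2L) 3L
              else 4L
    coAssoc <- length(coChromatids) > 0L && any(cc$conv %in% coChromatids)
    cls <- if (nConv == 0L || nConv > 2L) "GC_complex" else "NCO"
    out[[length(out) + 1L]] <- .eventRow(
      tetradId, chrom, cls, firstBp, lastBp,
      chromatids = paste(cc$conv, collapse = ","), gcType = gcType,
      coAssociated = coAssoc,
      direction = if (nConv == 1L) cc$gained else NA_integer_,
      tractStart = firstBp, tractEnd = lastBp,
      tractMin = tl[["min"]], tractMid = tl[["mid"]], tractMax = tl[["max"]])
    i <- j + 1L
  }
  out
}

#' Call recombination events in one tetrad
#'
#' Between consecutive 2:2 blocks, the set of spores whose genotype changes
#' determines the crossovers: two spores switching in opposite directions
#' give one crossover (breakpoint interval spanning the gap, position
#' reported at its midpoint); four spores switching give two crossovers
#' (4-strand double) on the same interval. Non-2:2 blocks become conversion
#' tracts; a tract inside a crossover gap whose converted chromatid is a
#' crossover chromatid is attached to that crossover (co_associated). A
#' flank change that admits no chromatid assignment is flagged "GC_complex",
#' never dropped silently.
#'
#' @param tetrad a [TetradGenotypes-class].
#' @param mergeGapBp crossover-tract association window (bp, default 5000).
#' @return list with `events` (data.frame, one row per event; see
#'   [.eventRow] columns) and `summary` (data.frame: tetrad_id, chrom, co,
#'   nco, e0).
#' @export
callEvents <- function(tetrad, mergeGapBp = 5000) {
  allEvents <- list()
  sumRows <- list()
  tid <- tetrad@tetradId
  for (chrom in names(tetrad@positions)) {
    seg <- segmentBlocks(tetrad, chrom)
    blocks <- seg$blocks
    nb <- nrow(blocks)
    events <- list()
    twoTwo <- which(blocks$class == "2:2")
    if (nb > 0L && length(twoTwo) == 0L) {
      ## no 2:2 anchor at all: unresolvable, flag and move on
      events[[1L]] <- .eventRow(tid, chrom, "GC_complex",
                                blocks$start_bp[1], blocks$end_bp[nb],
                                chromatids = "", gcType = 4L)
    } else if (nb > 0L) {
      ## leading tracts before the first 2:2 block
      if (twoTwo[1] > 1L)
        events <- c(events, .tractEvents(tid, chrom, seg,
                                         seq_len(twoTwo[1] - 1L),
                                         NULL, seg$geno[, twoTwo[1]],
                                         integer(0), mergeGapBp))
      ## gaps between consecutive 2:2 blocks
      if (length(twoTwo) > 1L) {
        for (q in seq_len(length(twoTwo) - 1L)) {
          i1 <- twoTwo[q]; i2 <- twoTwo[q + 1L]
          v1 <- seg$geno[, i1]; v2 <- seg$geno[, i2]
          diffS <- which(v1 != v2)
          gapL <- blocks$end_bp[i1]
          gapR <- blocks$start_bp[i2]
          coChromatids <- integer(0)
          coRows <- list()
          if (length(diffS) == 2L) {
            if (sum(v2[diffS] - v1[diffS]) == 0L) {
              coChromatids <- diffS
              coRows[[1L]] <- .eventRow(tid, chrom, "CO", gapL, gapR,
                                        paste(diffS, collapse = ","))
            } else {
              coRows[[1L]] <- .eventRow(tid, chrom, "GC_complex", gapL,
                                        gapR,
                                        paste(diffS, collapse = ","),
                                        gcType = 4L)
            }
          } else if (length(diffS) == 4L) {
            up <- diffS[v2[diffS] > v1[diffS]]
            down <- diffS[v2[diffS] < v1[diffS]]
            if (length(up) == 2L && length(down) == 2L) {
              coChromatids <- diffS
              for (k in 1:2)
                coRows[[k]] <- .eventRow(tid, chrom, "CO", gapL, gapR,
                                         paste(c(up[k], down[k]),
                                               collapse = ","))
            } else {
              coRows[[1L]] <- .eventRow(tid, chrom, "GC_complex", gapL,
                                        gapR,
                                        paste(diffS, collapse = ","),
                                        gcType = 4L)
            }
          } else if (length(diffS) != 0L) {
            coRows[[1L]] <- .eventRow(tid, chrom, "GC_complex", gapL, gapR,
                                      paste(diffS, collapse = ","),
                                      gcType = 4L)
          }
          ## conversion tracts inside this gap
          inner <- if (i2 > i1 + 1L) seq(i1 + 1L, i2 - 1L) else integer(0)
          tractRows <- .tractEvents(tid, chrom, seg, inner, v1, v2,
                                    coChromatids, mergeGapBp)
          ## attach co-associated tracts to their crossover
          if (length(coRows) && length(tractRows)) {
            for (t in seq_along(tractRows)) {
              tr <- tractRows[[t]]
              if (!tr$co_associated) next
              trChr <- as.integer(strsplit(tr$chromatids, ",")[[1]])
              near <- abs(tr$midpoint - (gapL + gapR) / 2) <=
                (gapR - gapL) / 2 + mergeGapBp
              for (k in seq_along(coRows)) {
                coChr <- as.integer(strsplit(coRows[[k]]$chromatids,
                                             ",")[[1]])
                if (coRows[[k]]$class == "CO" && near &&
                    any(trChr %in% coChr) &&
                    !coRows[[k]]$co_associated) {
                  coRows[[k]]$co_associated <- TRUE
                  coRows[[k]]$gc_type <- tr$gc_type
                  coRows[[k]]$direction <- tr$direction
                  coRows[[k]]$tract_start <- tr$tract_start
                  coRows[[k]]$tract_end <- tr$tract_end
                  coRows[[k]]$tract_min <- tr$tract_min
                  coRows[[k]]$tract_mid <- tr$tract_mid
                  coRows[[k]]$tract_max <- tr$tract_max
                  tractRows[[t]] <- NA
                  break
                }
              }
            }
            tractRows <- tractRows[!vapply(tractRows,
                                           function(x) all(is.na(x)),
                                           logical(1))]
          }
          events <- c(events, coRows, tractRows)
        }
      }
      ## trailing tracts after the last 2:2 block
      lastTT <- twoTwo[length(twoTwo)]
      if (lastTT < nb)
        events <- c(events, .tractEvents(tid, chrom, seg,
                                         seq(lastTT + 1L, nb),
                                         seg$geno[, lastTT], NULL,
                                         integer(0), mergeGapBp))
    }
    ev <- if (length(events)) do.call(rbind, events) else .emptyEvents()
    allEvents[[chrom]] <- ev
    sumRows[[chrom]] <- data.frame(
      tetrad_id = tid, chrom = chrom,
      co = sum(ev$class == "CO"), nco = sum(ev$class == "NCO"),
      e0 = sum(ev$class == "CO") == 0L, stringsAsFactors = FALSE)
  }
  list(events = do.call(rbind, c(allEvents, list(make.row.names = FALSE))),
       summary = do.call(rbind, c(sumRows, list(make.row.names = FALSE))))
}

#' Call events across a list of tetrads
#'
#' @param tetrads list of [TetradGenotypes-class] (e.g.
#'   `simulateTetrads(...)$tetrads`).
#' @param mergeGapBp see [callEvents()].
#' @return list with combined `events` and `summary` data.frames. Calling is
#'   idempotent and never mutates its input.
#' @export
callTetrads <- function(tetrads, mergeGapBp = 5000) {
  res <- lapply(tetrads, callEvents, mergeGapBp = mergeGapBp)
  list(events = do.call(rbind, c(lapply(res, `[[`, "events"),
                                 list(make.row.names = FALSE))),
       summary = do.call(rbind, c(lapply(res, `[[`, "summary"),
                                  list(make.row.names = FALSE))))
}

#' Flag ambiguous nonexchange (E0) chromosomes
#'
#' An E0 chromosome is flagged ambiguous when it carries two or more
#' single-chromatid noncrossover tracts on complementary (nonsister)
#' chromatids, converted in opposite directions, within `windowBp` of each
#' other -- a configuration that admits re-annotation as a closely spaced
#' double crossover. Also reports whether the E0 chromosome carries any
#' gene-conversion event at all.
#'
#' @param summary per-tetrad/chromosome summary from [callEvents()].
#' @param events event table from [callEvents()].
#' @param windowBp ambiguity window (default 10 kb).
#' @return data.frame: tetrad_id, chrom, has_gc, ambiguous (one row per E0
#'   chromosome).
#' @export
flagAmbiguousE0 <- function(summary, events, windowBp = 10000) {
  e0 <- summary[summary$e0, , drop = FALSE]
  if (!nrow(e0))
    return(data.frame(tetrad_id = character(0), chrom = character(0),
                      has_gc = logical(0), ambiguous = logical(0)))
  out <- lapply(seq_len(nrow(e0)), function(i) {
    ev <- events[events$tetrad_id == e0$tetrad_id[i] &
                 events$chrom == e0$chrom[i], , drop = FALSE]
    hasGc <- any(ev$class %in% c("NCO", "GC_complex") | ev$co_associated)
    nco <- ev[ev$class == "NCO" & ev$gc_type == 0L, , drop = FALSE]
    amb <- FALSE
    if (nrow(nco) >= 2L) {
      cid <- as.integer(nco$chromatids)
      for (a in seq_len(nrow(nco) - 1L)) {
        for (b in seq(a + 1L, nrow(nco))) {
          if (abs(nco$midpoint[a] - nco$midpoint[b]) <= windowBp &&
              ((cid[a] <= 2L) != (cid[b] <= 2L)) &&
              nco$direction[a] != nco$direction[b]) {
            amb <- TRUE
          }
        }
      }
    }
    data.frame(tetrad_id = e0$tetrad_id[i], chrom = e0$chrom[i],
               has_gc = hasGc, ambiguous = amb, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
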