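## Structural-variant breakpoint characterization: inversion length from the
## two breakpoints, junction classification (microhomology / duplication /
## deletion and the implied repair mechanism), dotplot word matching of
## breakpoint windows, and read-depth window profiles with a copy-number
## neutrality check.

#' Create a breakpoint
#'
#' A breakpoint "between positions p and p+1" is stored as \code{leftPos =
#' p}: the 1-based position of the last reference base before the break.
#'
#' @param chrom chromosome name.
#' @param leftPos 1-based position of the last base before the break.
#' @return a \code{Breakpoint} object.
#' @export
Breakpoint <- function(chrom, leftPos) {
  stopifnot(is.character(chrom), length(chrom) == 1L, leftPos >= 1)
  structure(list(chrom = chrom, leftPos = as.numeric(leftPos)),
            class = "Breakpoint")
}

#' @export
print.Breakpoint <- function(x, ...) {
  cat(sprintf("Breakpoint %s: between %s and %s\n", x$chrom,
              format(x$leftPos, big.mark = ","),
              format(x$leftPos + 1, big.mark = ",")))
  invisible(x)
}

.roundHalfUp <- function(x, digits = 0) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Inversion length from its two breakpoints
#'
#' Length in bp between the two breakpoints on the same chromosome, plus the
#' Mb value rounded half-up to one decimal. The result does not depend on
#' strand or orientation of the inverted segment.
#'
#' @param bp1,bp2 [Breakpoint()] objects; \code{bp2} must lie after
#'   \code{bp1} on the same chromosome.
#' @return list with \code{bp} (integer length) and \code{mb} (1-decimal Mb).
#' @examples
#' inversionLength(Breakpoint("X", 82271052), Breakpoint("X", 86034441))
#' @export
inversionLength <- function(bp1, bp2) {
  stopifnot(inherits(bp1, "Breakpoint"), inherits(bp2, "Breakpoint"))
  if (bp1$chrom != bp2$chrom)
    stop("breakpoints on different chromosomes: a translocation, not an inversion")
  if (bp2$leftPos <= bp1$leftPos)
    stop("bp2 must lie after bp1 on the chromosome")
  len <- bp2$leftPos - bp1$leftPos
  list(bp = len, mb = .roundHalfUp(len / 1e6, 1))
}

.asSeqChar <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  if (length(x) > 1L) x <- x[[1L]]
  toupper(as.character(x))
}

#' Classify a structural-variant junction
#'
#' Anchors the junction-spanning sequence onto its two reference flanks with
#' an exact 20-bp seed, extends each anchor base by base, and reads off the
#' repair signature at the join: an overlap of the two anchor matches is a
#' shared microhomologous segment; a gap whose leading bases copy the
#' left-flank suffix is a (partial) duplication inserted at the join; any
#' remaining gap bases are untemplated insertions; reference bases not
#' covered by either anchor are deletions. The flanks must be oriented as
#' they appear in the derivative allele (for an inversion junction the
#' distal flank is supplied already reverse-complemented).
#'
#' Mechanism label: \code{MMBIR_like} iff the duplicated/microhomologous
#' length reaches \code{minMicrohomology}; otherwise \code{NHEJ_like} when
#' any deletion, insertion or sub-threshold homology is present, and
#' \code{blunt} for an exact end join. When ties exist among (prefix,
#' suffix) decompositions, the call maximizes the duplicated overlap and is
#' leftmost, which the seed-and-extend procedure realizes deterministically.
#'
#' @param refLeftFlank reference sequence ending at the left side of the
#'   break (character or Biostrings object).
#' @param refRightFlank reference sequence starting at the right side of the
#'   break, in derivative orientation.
#' @param junctionSeq sequence spanning the novel join, with at least 20
#'   bases matching each flank.
#' @param minMicrohomology minimum duplicated length for an
#'   \code{MMBIR_like} call (default 2, so a single shared or lost base
#'   stays \code{NHEJ_like}).
#' @return a [JunctionCall-class].
#' @examples
#' jx <- simulateJunction(motif = "GTACAAGAAACT", microhomologyLength = 12,
#'                        seed = 7)
#' classifyJunction(jx$refLeftFlank, jx$refRightFlank, jx$junctionSeq)
#' @export
classifyJunction <- function(refLeftFlank, refRightFlank, junctionSeq,
                             minMicrohomology = 2) {
  L <- .asSeqChar(refLeftFlank)
  R <- .asSeqChar(refRightFlank)
  J <- .asSeqChar(junctionSeq)
  w <- 20L
  unresolved <- function(msg)
    new("JunctionCall", duplicatedSegment = "", deletedBases = "",
        insertedBases = "", mechanism = "unresolved", diagnostics = msg)
  if (nchar(J) < 2L * w)
    return(unresolved("junction sequence shorter than two 20-bp anchors"))

  ## left anchor: first occurrence of the junction's leading 20-mer in L,
  ## extended rightwards
  seedL <- substr(J, 1L, w)
  posL <- regexpr(seedL, L, fixed = TRUE)[1L]
  if (posL < 0L)
    return(unresolved("junction start fails to anchor in the left flank"))
  pL <- w; eL <- posL + w - 1L
  while (pL < nchar(J) && eL < nchar(L) &&
         substr(J, pL + 1L, pL + 1L) == substr(L, eL + 1L, eL + 1L)) {
    pL <- pL + 1L; eL <- eL + 1L
  }

  ## right anchor: last occurrence of the junction's trailing 20-mer in R,
  ## extended leftwards
  seedR <- substr(J, nchar(J) - w + 1L, nchar(J))
  posR <- gregexpr(seedR, R, fixed = TRUE)[[1L]]
  if (posR[1L] < 0L)
    return(unresolved("junction end fails to anchor in the right flank"))
  posR <- posR[length(posR)]
  qR <- nchar(J) - w + 1L; sR <- posR
  while (qR > 1L && sR > 1L &&
         substr(J, qR - 1L, qR - 1L) == substr(R, sR - 1L, sR - 1L)) {
    qR <- qR - 1L; sR <- sR - 1L
  }

  deleted <- paste0(substr(L, eL + 1L, nchar(L)), substr(R, 1L, sR - 1L))
  if (pL >= qR) {
    dup <- substr(J, qR, pL)
    inserted <- ""
  } else {
    gap <- if (qR - pL > 1L) substr(J, pL + 1L, qR - 1L) else ""
    dupLen <- 0L
    if (nchar(gap)) {
      for (t in nchar(gap):1L) {
        if (eL - t + 1L >= 1L &&
            substr(gap, 1L, t) == substr(L, eL - t + 1L, eL)) {
          dupLen <- as.integer(t)
          break
        }
      }
    }
    dup <- substr(gap, 1L, dupLen)
    inserted <- substr(gap, dupLen + 1L, nchar(gap))
  }
  mech <- if (nchar(dup) >= minMicrohomology) "MMBIR_like"
    else if (nchar(dup) > 0L || nchar(deleted) > 0L || nchar(inserted) > 0L)
      "NHEJ_like"
    else "blunt"
  new("JunctionCall", duplicatedSegment = dup, deletedBases = deleted,
      insertedBases = inserted, mechanism = mech, diagnostics = "")
}

#' @describeIn JunctionCall length of the duplicated/microhomologous segment
#' @param x a [JunctionCall-class].
#' @export
duplicatedLength <- function(x) nchar(x@duplicatedSegment)

#' @describeIn JunctionCall number of deleted reference bases
#' @export
deletedLength <- function(x) nchar(x@deletedBases)

#' @describeIn JunctionCall repair-mechanism label
#' @export
mechanism <- function(x) x@mechanism

setMethod("show", "JunctionCall", function(object) {
  cat("JunctionCall:", object@mechanism, "\n")
  if (object@mechanism == "unresolved") {
    cat("  ", object@diagnostics, "\n")
    return(invisible(NULL))
  }
  cat(sprintf("  duplicated: %d bp%s\n", nchar(object@duplicatedSegment),
              if (nchar(object@duplicatedSegment))
                paste0(" (5'-", object@duplicatedSegment, "-3')") else ""))
  cat(sprintf("  deleted: %d bp%s\n", nchar(object@deletedBases),
              if (nchar(object@deletedBases))
                paste0(" (", object@deletedBases, ")") else ""))
  cat(sprintf("  inserted: %d bp\n", nchar(object@insertedBases)))
})

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Exact-word dotplot matches between two sequences
#'
#' All exact matches of length \code{wordSize} between \code{a} and \code{b}
#' (and, when \code{bothStrands}, between \code{a} and the reverse
#' complement of \code{b}), reported as 1-based start coordinates in the
#' original sequences. For a reverse-strand hit, \code{j} is the start in
#' the original \code{b} of the word whose reverse complement matches
#' \code{a} at \code{i}. Words containing N never match. Rows are ordered by
#' \code{i}, then \code{j}, then strand (\code{"+"} before \code{"-"}).
#'
#' @param a,b sequences over A/C/G/T/N (character or Biostrings objects).
#' @param wordSize exact word length (default 10, minimum 4).
#' @param bothStrands also scan the reverse complement of \code{b}
#'   (default TRUE).
#' @return data.frame with columns \code{i}, \code{j}, \code{strand}; empty
#'   (with a warning) when either sequence is shorter than \code{wordSize}.
#' @export
dotplotMatches <- function(a, b, wordSize = 10, bothStrands = TRUE) {
  stopifnot(wordSize >= 4)
  a <- .asSeqChar(a); b <- .asSeqChar(b)
  empty <- data.frame(i = integer(0), j = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (nchar(a) < wordSize || nchar(b) < wordSize) {
    warning("sequence shorter than wordSize; no matches possible")
    return(empty)
  }
  w <- as.integer(wordSize)
  words <- function(s) {
    n <- nchar(s)
    substring(s, seq_len(n - w + 1L), seq.int(w, n))
  }
  wa <- words(a)
  hits <- function(wb, mapJ) {
    lut <- split(seq_along(wb), wb)
    ok <- which(!grepl("N", wa, fixed = TRUE))
    res <- lapply(ok, function(i) {
      js <- lut[[wa[i]]]
      if (is.null(js)) return(NULL)
      js <- js[!grepl("N", wb[js], fixed = TRUE)]
      if (!length(js)) return(NULL)
      data.frame(i = i, j = mapJ(js), stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  fwd <- hits(words(b), identity)
  if (!is.null(fwd) && nrow(fwd)) fwd$strand <- "+"
  rev <- NULL
  if (bothStrands) {
    nb <- nchar(b)
    rev <- hits(words(.revcomp(b)), function(jr) nb - jr - w + 2L)
    if (!is.null(rev) && nrow(rev)) rev$strand <- "-"
  }
  out <- rbind(fwd, rev)
  if (is.null(out) || !nrow(out)) return(empty)
  out <- out[order(out$i, out$j, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Windowed read-depth profile
#'
#' Tiles the chromosome into non-overlapping windows anchored at position 1
#' and computes the mean depth per window, from either a per-base table
#' (columns \code{chrom}, \code{pos}, \code{depth}) or a per-window table
#' (columns \code{chrom}, \code{start}, \code{mean}, with starts on the
#' window grid). Windows intersecting any mask interval are flagged masked
#' and excluded from downstream statistics. Mask intervals follow the BED
#' convention (0-based, half-open) and are converted internally to 1-based
#' inclusive coordinates.
#'
#' @param depth input data.frame (single chromosome).
#' @param window window size in bp (default 10,000).
#' @param mask optional data.frame with columns \code{chrom}, \code{start},
#'   \code{end} in BED coordinates.
#' @return a [DepthProfile-class].
#' @export
depthProfile <- function(depth, window = 10000, mask = NULL) {
  stopifnot(is.data.frame(depth))
  window <- as.integer(window)
  if (all(c("chrom", "pos", "depth") %in% names(depth))) {
    if (length(unique(depth$chrom)) > 1L)
      stop("depth table must cover a single chromosome")
    if (any(depth$depth < 0)) stop("depth values must be non-negative")
    chrom <- depth$chrom[1L]
    win <- (depth$pos - 1L) %/% window
    means <- tapply(depth$depth, win, mean)
    starts <- as.integer(names(means)) * window + 1L
    meanDepth <- as.numeric(means)
  } else if (all(c("chrom", "start", "mean") %in% names(depth))) {
    if (length(unique(depth$chrom)) > 1L)
      stop("depth table must cover a single chromosome")
    if (any((depth$start - 1L) %% window != 0L))
      stop("per-window starts must lie on the ", window, "-bp grid")
    if (any(depth$mean < 0)) stop("depth values must be non-negative")
    chrom <- depth$chrom[1L]
    starts <- as.integer(depth$start)
    meanDepth <- as.numeric(depth$mean)
  } else {
    stop("depth must have columns chrom/pos/depth (per base) or ",
         "chrom/start/mean (per window)")
  }
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = starts, width = window))
  gr$meanDepth <- meanDepth
  gr$masked <- FALSE
  if (!is.null(mask) && nrow(mask)) {
    mgr <- GenomicRanges::GRanges(as.character(mask$chrom),
             IRanges::IRanges(start = mask$start + 1L, end = mask$end))
    gr$masked <- IRanges::overlapsAny(gr, mgr)
  }
  new("DepthProfile", windows = gr, windowSize = as.numeric(window))
}

#' @describeIn DepthProfile the windows as a GRanges
#' @param x a [DepthProfile-class].
#' @export
profileWindows <- function(x) x@windows

setMethod("show", "DepthProfile", function(object) {
  gr <- object@windows
  cat("DepthProfile:", length(gr), "windows of", object@windowSize, "bp (",
      sum(gr$masked), "masked )\n")
  um <- gr$meanDepth[!gr$masked]
  if (length(um))
    cat(sprintf("  unmasked mean depth: %.2f (range %.2f-%.2f)\n",
                mean(um), min(um), max(um)))
})

#' Copy-number neutrality of an interval
#'
#' Compares the mean depth of unmasked windows fully inside the interval
#' with the mean of unmasked windows entirely outside it. The interval is
#' called copy-neutral when the ratio lies within
#' [1/foldThreshold, foldThreshold].
#'
#' @param profile a [DepthProfile-class].
#' @param interval \code{c(start, end)} in 1-based inclusive coordinates.
#' @param foldThreshold fold-change cutoff (default 1.5, flagging a
#'   heterozygous deletion at ~0.5x or a duplication at ~1.5x).
#' @return list with \code{neutral} (logical) and \code{ratio}.
#' @export
copyNumberFlag <- function(profile, interval, foldThreshold = 1.5) {
  stopifnot(is(profile, "DepthProfile"), length(interval) == 2L,
            foldThreshold > 1)
  gr <- profile@windows
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  inside <- !gr$masked & st >= interval[1L] & en <= interval[2L]
  outside <- !gr$masked & (en < interval[1L] | st > interval[2L])
  if (!any(inside))
    stop("no unmasked window inside the interval")
  if (!any(outside))
    stop("no unmasked window outside the interval to compare against")
  ratio <- mean(gr$meanDepth[inside]) / mean(gr$meanDepth[outside])
  list(neutral = ratio >= 1 / foldThreshold && ratio <= foldThreshold,
       ratio = ratio)
}
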