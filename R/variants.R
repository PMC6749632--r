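## Small-variant candidate prioritization: heterozygous in the case, absent
## from a control panel, quality above threshold, protein-altering
## consequence. Coordinates are 1-based inclusive throughout (VCF
## convention). Panel absence is an exact site+allele key match.

.PROTEIN_ALTERING <- c("missense", "frameshift", "inframe_insertion",
                       "inframe_deletion", "stop_gained", "stop_lost")

.variantKey <- function(chrom, pos, ref, alt)
  paste(chrom, pos, ref, alt, sep = ":")

## trim shared trailing bases of an unnormalized indel (keeping at least one
## base of each allele); position is unchanged by right-trimming
.normalizeAlleles <- function(ref, alt) {
  trimmed <- FALSE
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 1L && na > 1L &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      trimmed <- TRUE
    } else break
  }
  list(ref = ref, alt = alt, trimmed = trimmed)
}

.normalizeVariants <- function(variants, label = "variant") {
  trimmedAny <- FALSE
  for (k in seq_len(nrow(variants))) {
    nm <- .normalizeAlleles(variants$ref[k], variants$alt[k])
    if (nm$trimmed) {
      trimmedAny <- TRUE
      variants$ref[k] <- nm$ref
      variants$alt[k] <- nm$alt
    }
  }
  if (trimmedAny)
    warning("unnormalized ", label, " allele(s) with shared trailing base ",
            "detected; trimmed on the fly")
  variants
}

#' Read the case sample's variants from a VCF
#'
#' Reads a single-sample VCF (4.2; optionally bgzipped) and returns one row
#' per (site, alternate allele): multi-allelic records are split before any
#' filtering. Genotypes are reduced per alternate allele to
#' \code{hom_ref} / \code{het} / \code{hom_alt} / \code{missing}.
#'
#' @param file path to the VCF.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{genotype}, \code{qual}.
#' @export
readCaseVariants <- function(file) {
  vcf <- VariantAnnotation::readVcf(file)
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT[, 1L]
  alts <- rr$ALT
  out <- vector("list", length(rr))
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  qual <- rr$QUAL
  for (k in seq_along(rr)) {
    av <- as.character(alts[[k]])
    gAll <- strsplit(gt[k], "[/|]")[[1L]]
    rows <- lapply(seq_along(av), function(j) {
      g <- if (any(gAll == ".")) "missing" else {
        copies <- sum(gAll == as.character(j))
        others <- sum(gAll != "0" & gAll != as.character(j))
        if (copies == 2L) "hom_alt"
        else if (copies == 1L) "het"
        else if (others > 0L) "missing" else "hom_ref"
      }
      data.frame(chrom = chrom[k], pos = pos[k], ref = ref[k], alt = av[j],
                 genotype = g, qual = if (is.na(qual[k])) 0 else qual[k],
                 stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read control-panel sites
#'
#' Accepts either a VCF (all alternate alleles become panel keys) or a
#' delimited table with columns \code{chrom}, \code{pos}, \code{ref},
#' \code{alt}.
#'
#' @param file path to the panel file.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @export
readPanelSites <- function(file) {
  first <- readLines(file, n = 1L)
  if (startsWith(first, "##fileformat")) {
    vcf <- VariantAnnotation::readVcf(file)
    rr <- SummarizedExperiment::rowRanges(vcf)
    alts <- rr$ALT
    n <- lengths(alts)
    data.frame(chrom = rep(as.character(GenomicRanges::seqnames(rr)), n),
               pos = rep(GenomicRanges::start(rr), n),
               ref = rep(as.character(rr$REF), n),
               alt = as.character(unlist(alts)),
               stringsAsFactors = FALSE)
  } else {
    sep <- if (grepl("\t", first)) "\t" else ","
    d <- utils::read.table(file, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(d)))
    d$pos <- as.integer(d$pos)
    d[c("chrom", "pos", "ref", "alt")]
  }
}

#' Read a consequence-annotation table
#'
#' Delimited table keyed by \code{(chrom, pos, ref, alt)} with columns
#' \code{consequence} and optionally \code{sift_score}. Consequence classes
#' in \code{missense, frameshift, inframe_insertion, inframe_deletion,
#' stop_gained, stop_lost} count as protein-altering; anything else is
#' \code{other}; absent records are \code{unannotated}.
#'
#' @param file path to the annotation table.
#' @return data.frame.
#' @export
readVariantAnnotations <- function(file) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "consequence") %in% names(d)))
  d$chrom <- as.character(d$chrom)
  d$pos <- as.integer(d$pos)
  d
}

#' Attach consequence annotations to a variant table
#'
#' Left join on the exact \code{(chrom, pos, ref, alt)} key; variants with
#' no annotation record get consequence \code{"unannotated"}.
#'
#' @param variants variant data.frame (as from [readCaseVariants()]).
#' @param annotations annotation data.frame (as from
#'   [readVariantAnnotations()]).
#' @return \code{variants} with added \code{consequence} (and
#'   \code{sift_score} if present) columns.
#' @export
annotateVariants <- function(variants, annotations) {
  key <- .variantKey(variants$chrom, variants$pos, variants$ref, variants$alt)
  akey <- .variantKey(annotations$chrom, annotations$pos, annotations$ref,
                      annotations$alt)
  m <- match(key, akey)
  variants$consequence <- ifelse(is.na(m), "unannotated",
                                 annotations$consequence[m])
  if ("sift_score" %in% names(annotations))
    variants$sift_score <- annotations$sift_score[m]
  variants
}

#' Filter to private heterozygous high-quality variants
#'
#' Retains exactly the records that are heterozygous in the case, have a
#' quality score strictly greater than \code{qualThreshold}, and whose
#' \code{(chrom, pos, ref, alt)} key is absent from the control panel.
#' Input order is preserved. Variants (and panel sites) with a shared
#' trailing base in ref/alt are normalized on the fly with a warning, so
#' that the key comparison is on parsimonious alleles.
#'
#' @param variants variant data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{genotype}, \code{qual}.
#' @param panel panel data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (as from [readPanelSites()]).
#' @param qualThreshold quality cutoff, strict (default 30).
#' @return the surviving subset of \code{variants}, order preserved.
#' @export
filterPrivateHet <- function(variants, panel, qualThreshold = 30) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "genotype", "qual") %in%
                  names(variants)))
  variants <- .normalizeVariants(variants)
  panel <- .normalizeVariants(panel, label = "panel site")
  key <- .variantKey(variants$chrom, variants$pos, variants$ref, variants$alt)
  pkey <- .variantKey(panel$chrom, panel$pos, panel$ref, panel$alt)
  keep <- variants$genotype == "het" &
    variants$qual > qualThreshold &
    !(key %in% pkey)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count protein-altering candidates
#'
#' Tallies how many records carry a protein-altering consequence
#' (missense, frameshift, inframe insertion/deletion, stop gained/lost),
#' with a per-class breakdown; unannotated records are counted separately.
#'
#' @param variants annotated variant data.frame with a \code{consequence}
#'   column.
#' @return list with \code{n_total}, \code{n_protein_altering},
#'   \code{n_unannotated} and the named integer \code{breakdown} over
#'   consequence classes present.
#' @export
countProteinAltering <- function(variants) {
  if (!nrow(variants))
    return(list(n_total = 0L, n_protein_altering = 0L, n_unannotated = 0L,
                breakdown = integer(0)))
  stopifnot("consequence" %in% names(variants))
  cons <- variants$consequence
  pa <- cons %in% .PROTEIN_ALTERING
  breakdown <- table(cons[pa])
  list(n_total = nrow(variants),
       n_protein_altering = sum(pa),
       n_unannotated = sum(cons == "unannotated"),
       breakdown = setNames(as.integer(breakdown), names(breakdown)))
}
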