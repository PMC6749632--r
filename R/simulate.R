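## Synthetic-data generators. Every generator is deterministic given its
## seed and returns a machine-readable ground-truth record so each pipeline
## stage has a planted-truth recovery test.

.randSeq <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

.drawOffspring <- function(spec) {
  if (is.numeric(spec)) return(as.integer(spec))
  if (is.list(spec) && identical(spec$dist, "poisson"))
    return(stats::rpois(1L, spec$lambda))
  stop("offspringPerMating must be an integer or list(dist='poisson', lambda=)")
}

#' Simulate a looped multi-generation pedigree
#'
#' Generates a multi-generation random-mating pedigree of the kind found in
#' intensively selected dairy cattle populations, with (optionally) a
#' designated proband whose paternal and maternal lineages share exactly
#' \code{loopAncestors} planted common ancestors. The common ancestors are
#' founders re-used on both sides through side-specific descent chains, so
#' the set of ancestors present in both lineages is exactly the planted set.
#' Every animal receives a birth year (one generation every
#' \code{yearsPerGeneration} years) and an age at death in months: death in
#' the 0-6-month window with probability \code{windowDeathProb} (default
#' 0.1093, a realistic calf-mortality rate for the breed), later otherwise.
#' The first planted common ancestor is designated the carrier ancestor.
#'
#' @param nFounders number of founders.
#' @param nGenerations number of background random-mating generations.
#' @param offspringPerMating integer, or \code{list(dist = "poisson",
#'   lambda = )}.
#' @param loopAncestors number of ancestors to plant in both proband
#'   lineages (0 for none).
#' @param birthYearStart founder birth year.
#' @param yearsPerGeneration years between generations (default 3).
#' @param proband build a proband with planted loops (default TRUE).
#' @param windowDeathProb probability of death within 0-6 months.
#' @param seed integer RNG seed (required).
#' @return list with \code{pedigree} (a [Pedigree-class]) and \code{truth}
#'   (list with \code{proband}, \code{loopAncestors}, \code{carrier},
#'   \code{contributions}: the exact recursion-based contributions of the
#'   carrier, or NULL).
#' @export
simulatePedigree <- function(nFounders = 60, nGenerations = 4,
                             offspringPerMating = list(dist = "poisson",
                                                       lambda = 2),
                             loopAncestors = 10, birthYearStart = 2000,
                             yearsPerGeneration = 3, proband = TRUE,
                             windowDeathProb = 0.1093, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(nFounders >= 2, nGenerations >= 1, loopAncestors >= 0)
  if (proband && loopAncestors > nFounders - 4L)
    stop("infeasible loop count: need at least loopAncestors + 4 founders")
  set.seed(seed)

  id <- sprintf("F%04d", seq_len(nFounders))
  sire <- rep(NA_character_, nFounders)
  dam <- rep(NA_character_, nFounders)
  ## balanced founder sex ratio: a breeding nucleus has both sires and dams
  sex <- rep_len(c("male", "female"), nFounders)
  year <- rep(birthYearStart, nFounders)

  addRow <- function(i, s, d, sx, y) {
    id <<- c(id, i); sire <<- c(sire, s); dam <<- c(dam, d)
    sex <<- c(sex, sx); year <<- c(year, y)
  }

  probandId <- NA_character_
  loopIds <- character(0)
  if (proband) {
    perm <- sample(id[seq_len(nFounders)])
    loopIds <- if (loopAncestors > 0) perm[seq_len(loopAncestors)] else character(0)
    side <- perm[loopAncestors + seq_len(4L)]
    fp <- side[1:2]; fm <- side[3:4]
    sex[match(fp, id)] <- c("male", "female")
    sex[match(fm, id)] <- c("male", "female")
    buildChain <- function(first2, commons, prefix, headSex) {
      chain <- c(first2, if (length(commons)) sample(commons) else character(0))
      cur <- NULL
      g <- 0L
      for (k in seq.int(2L, length(chain))) {
        g <- g + 1L
        nxt <- if (k < length(chain)) chain[k + 1L] else NA_character_
        newSex <- if (is.na(nxt)) headSex else
          if (sex[match(nxt, id)] == "male") "female" else "male"
        mateA <- if (k == 2L) chain[1L] else cur
        mateB <- chain[k]
        sxA <- if (k == 2L) sex[match(mateA, id)] else sxCur
        sxB <- sex[match(mateB, id)]
        child <- sprintf("%s%03d", prefix, g)
        addRow(child,
               s = if (sxA == "male") mateA else mateB,
               d = if (sxA == "male") mateB else mateA,
               sx = newSex,
               y = birthYearStart + g * yearsPerGeneration)
        cur <- child
        sxCur <- newSex
      }
      cur
    }
    sireHead <- buildChain(fp, loopIds, "P", "male")
    damHead <- buildChain(fm, loopIds, "M", "female")
    chainLen <- 1L + length(loopIds)
    probandId <- "CASE"
    addRow(probandId, sireHead, damHead, "female",
           birthYearStart + (chainLen + 1L) * yearsPerGeneration)
  }

  ## background random-mating generations (founders are generation 0)
  prev <- id[seq_len(nFounders)]
  for (g in seq_len(nGenerations)) {
    males <- prev[sex[match(prev, id)] == "male"]
    females <- prev[sex[match(prev, id)] == "female"]
    nMat <- min(length(males), length(females))
    if (nMat == 0L) break
    males <- sample(males)[seq_len(nMat)]
    females <- sample(females)[seq_len(nMat)]
    newGen <- character(0)
    cnt <- 0L
    for (m in seq_len(nMat)) {
      for (o in seq_len(max(.drawOffspring(offspringPerMating), 0L))) {
        cnt <- cnt + 1L
        child <- sprintf("G%02d_%04d", g, cnt)
        addRow(child, males[m], females[m],
               sample(c("male", "female"), 1L),
               birthYearStart + g * yearsPerGeneration)
        newGen <- c(newGen, child)
      }
    }
    prev <- newGen
  }

  n <- length(id)
  diedEarly <- stats::runif(n) < windowDeathProb
  death <- ifelse(diedEarly, round(stats::runif(n, 0, 6), 1),
                  round(stats::runif(n, 7, 120), 1))
  pheno <- rep("unaffected", n)
  if (!is.na(probandId)) {
    i <- match(probandId, id)
    pheno[i] <- "affected"
    death[i] <- 0.5
  }
  ped <- Pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                             birth_year = year, death_age_months = death,
                             phenotype = pheno, stringsAsFactors = FALSE))
  carrier <- if (length(loopIds)) loopIds[1L] else NA_character_
  truth <- list(proband = probandId, loopAncestors = loopIds,
                carrier = carrier,
                contributions = if (!is.na(carrier))
                  contributions(expectedContribution(ped, carrier)) else NULL)
  list(pedigree = ped, truth = truth)
}

#' Plant a heterozygous carrier and drop alleles forward
#'
#' One Mendelian forward simulation: the ancestor is heterozygous for the
#' mutant allele, every other founder carries zero copies, and each meiosis
#' transmits one uniformly random parental allele. Individuals with two
#' mutant copies are flagged affected (fully penetrant recessive model).
#'
#' @param ped a [Pedigree-class].
#' @param ancestor carrier ancestor identifier.
#' @param seed integer RNG seed (required).
#' @return list with named integer \code{genotype} (0/1/2 mutant copies)
#'   and named logical \code{affected}.
#' @export
plantCarrierAndDrop <- function(ped, ancestor, seed) {
  if (missing(seed)) stop("a seed is required")
  a <- .idIndex(ped, ancestor, "ancestor")
  arg <- .cppArgs(ped)
  set.seed(seed)
  g <- .mendelian_drop_cpp(arg$order, arg$sire, arg$dam, a - 1L)
  g <- setNames(as.integer(g), ped@data$id)
  list(genotype = g, affected = g == 2L)
}

#' Simulate a case variant table with planted private candidates
#'
#' Generates a single-sample variant table in which
#' \code{nPlantedPrivateHet} records are heterozygous, absent from the
#' control panel and have quality strictly above 30 (the planted truth a
#' private-variant filter must recover exactly), surrounded by distractors:
#' panel-shared het and hom variants, low-quality private hets (one pinned
#' at quality exactly 30.00, on the filter boundary), private homozygotes
#' and hom-ref records. A consequence-annotation table covers the planted
#' records and a random share of the distractors.
#'
#' @param nSites number of case variant records.
#' @param nPlantedPrivateHet number of planted private candidates.
#' @param chrom chromosome name (default "1").
#' @param nPanelExtra panel-only sites not seen in the case (default 300).
#' @param seed integer RNG seed (required).
#' @return list with \code{variants}, \code{panel}, \code{annotations}
#'   (data.frames) and \code{truth} (list with \code{plantedKeys}).
#' @export
simulateVariantTable <- function(nSites = 1000, nPlantedPrivateHet = 12,
                                 chrom = "1", nPanelExtra = 300, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(nPlantedPrivateHet <= nSites)
  set.seed(seed)
  allPos <- sample.int(5e6, nSites + nPanelExtra)
  pos <- sort(allPos[seq_len(nSites)])
  extraPos <- sort(allPos[nSites + seq_len(nPanelExtra)])
  bases <- c("A", "C", "G", "T")

  drawAlleles <- function(n) {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    kind <- stats::runif(n)
    del <- kind < 0.1
    ins <- kind >= 0.1 & kind < 0.2
    ref[del] <- paste0(ref[del], sample(bases, sum(del), replace = TRUE))
    alt[del] <- substr(ref[del], 1L, 1L)
    alt[ins] <- paste0(ref[ins], sample(bases, sum(ins), replace = TRUE))
    list(ref = ref, alt = unname(alt))
  }
  al <- drawAlleles(nSites)

  cat_ <- rep(NA_character_, nSites)
  planted <- sample.int(nSites, nPlantedPrivateHet)
  cat_[planted] <- "planted"
  rest <- which(is.na(cat_))
  cat_[rest] <- sample(c("panel_het", "panel_hom", "private_lowq_het",
                         "private_hom", "private_homref"),
                       length(rest), replace = TRUE,
                       prob = c(0.30, 0.15, 0.25, 0.20, 0.10))
  qual <- round(stats::runif(nSites, 1, 200), 2)
  qual[cat_ == "planted"] <- round(stats::runif(nPlantedPrivateHet, 31, 200), 2)
  qual[qual <= 30 & cat_ == "planted"] <- 31
  lowq <- which(cat_ == "private_lowq_het")
  qual[lowq] <- round(stats::runif(length(lowq), 1, 30), 2)
  if (length(lowq)) qual[lowq[1L]] <- 30  # exact boundary distractor
  geno <- c(planted = "het", panel_het = "het", panel_hom = "hom_alt",
            private_lowq_het = "het", private_hom = "hom_alt",
            private_homref = "hom_ref")[cat_]

  variants <- data.frame(chrom = chrom, pos = pos, ref = al$ref,
                         alt = al$alt, genotype = unname(geno), qual = qual,
                         stringsAsFactors = FALSE)

  inPanel <- cat_ %in% c("panel_het", "panel_hom")
  alx <- drawAlleles(nPanelExtra)
  panel <- rbind(variants[inPanel, c("chrom", "pos", "ref", "alt")],
                 data.frame(chrom = chrom, pos = extraPos, ref = alx$ref,
                            alt = alx$alt, stringsAsFactors = FALSE))
  panel <- panel[order(panel$pos), , drop = FALSE]
  rownames(panel) <- NULL

  annIdx <- sort(unique(c(planted, sample(rest, ceiling(length(rest) * 0.3)))))
  consequence <- sample(c(.PROTEIN_ALTERING, "other"), length(annIdx),
                        replace = TRUE,
                        prob = c(rep(0.05, length(.PROTEIN_ALTERING)), 0.7))
  annotations <- data.frame(chrom = chrom, pos = pos[annIdx],
                            ref = al$ref[annIdx], alt = al$alt[annIdx],
                            consequence = consequence,
                            sift_score = ifelse(consequence == "missense",
                                                round(stats::runif(length(annIdx)), 2),
                                                NA_real_),
                            stringsAsFactors = FALSE)

  truth <- list(plantedKeys = .variantKey(chrom, pos[planted],
                                          al$ref[planted], al$alt[planted]),
                plantedRows = sort(planted))
  list(variants = variants, panel = panel, annotations = annotations,
       truth = truth)
}

#' Write a minimal single-sample VCF 4.2
#'
#' Deterministic text writer for the simulated case variant table: the same
#' table always produces byte-identical output. Biallelic records only.
#'
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{genotype}, \code{qual}.
#' @param file output path.
#' @param sample sample name in the header (default "CASE").
#' @export
writeCaseVcf <- function(variants, file, sample = "CASE") {
  gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
          missing = "./.")[variants$genotype]
  if (any(is.na(gt))) stop("unknown genotype code in variant table")
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(variants$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
          sprintf("%.2f", variants$qual), ".", ".", "GT", gt, sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}

#' Simulate a junction with a specified repair signature
#'
#' Builds two random reference flanks and a junction sequence embedding
#' exactly the configured repair signature: a duplicated motif (the
#' left-flank suffix re-appearing at the join, the reconstruction of a
#' microhomology-mediated template switch), deleted reference bases taken
#' from the start of the right flank, and/or untemplated inserted bases.
#' Flanks are guaranteed non-repetitive at the join by construction
#' followed by an internal classification check; on a collision the flanks
#' are regenerated (bounded retries).
#'
#' @param flankLength flank length in bp (default 500; must be at least
#'   motif length + 50).
#' @param motif nucleotide string to duplicate at the join (planted as the
#'   left-flank suffix); if NULL and \code{microhomologyLength} > 0 a
#'   random motif of that length is used.
#' @param microhomologyLength duplicated length (defaults to the motif
#'   length, or 0).
#' @param deletionLength number of reference bases deleted at the join.
#' @param deletedBases optional explicit deleted bases (length must equal
#'   \code{deletionLength}), e.g. \code{"T"}.
#' @param insertion untemplated inserted bases (default none).
#' @param minMicrohomology classification threshold used for the internal
#'   verification (default 2).
#' @param maxRetries flank regeneration attempts (default 50).
#' @param seed integer RNG seed (required).
#' @return list with \code{refLeftFlank}, \code{refRightFlank},
#'   \code{junctionSeq} (character) and \code{truth} (list mirroring the
#'   junction-call fields).
#' @export
simulateJunction <- function(flankLength = 500, motif = NULL,
                             microhomologyLength = NULL, deletionLength = 0,
                             deletedBases = NULL, insertion = "",
                             minMicrohomology = 2, maxRetries = 50, seed) {
  if (missing(seed)) stop("a seed is required")
  if (!is.null(motif)) {
    motif <- toupper(motif)
    stopifnot(grepl("^[ACGT]+$", motif))
    if (is.null(microhomologyLength)) microhomologyLength <- nchar(motif)
    if (microhomologyLength != nchar(motif))
      stop("microhomologyLength must equal the motif length")
  }
  m <- if (is.null(microhomologyLength)) 0L else as.integer(microhomologyLength)
  d <- as.integer(deletionLength)
  insertion <- toupper(insertion)
  if (!is.null(deletedBases)) {
    deletedBases <- toupper(deletedBases)
    stopifnot(nchar(deletedBases) == d)
  }
  if (flankLength < m + 50)
    stop("flankLength must be at least motif length + 50")
  set.seed(seed)
  expectMech <- if (m >= minMicrohomology) "MMBIR_like"
    else if (m + d + nchar(insertion) > 0L) "NHEJ_like" else "blunt"
  for (try in seq_len(maxRetries)) {
    L <- .randSeq(flankLength)
    mot <- if (m > 0L) { if (is.null(motif)) .randSeq(m) else motif } else ""
    if (m > 0L)
      L <- paste0(substr(L, 1L, flankLength - m), mot)
    R <- .randSeq(flankLength)
    if (d > 0L) {
      db <- if (is.null(deletedBases)) substr(R, 1L, d) else deletedBases
      R <- paste0(db, substr(R, d + 1L, flankLength))
    } else db <- ""
    J <- paste0(L, mot, insertion, substr(R, d + 1L, flankLength))
    call <- classifyJunction(L, R, J, minMicrohomology)
    ok <- identical(call@duplicatedSegment, mot) &&
      identical(call@deletedBases, db) &&
      identical(call@insertedBases, insertion) &&
      identical(call@mechanism, expectMech)
    if (ok) {
      truth <- list(duplicatedSegment = mot, duplicatedLength = m,
                    deletedBases = db, deletedLength = d,
                    insertedBases = insertion, mechanism = expectMech)
      return(list(refLeftFlank = L, refRightFlank = R, junctionSeq = J,
                  truth = truth))
    }
  }
  stop("could not generate non-repetitive flanks for the requested ",
       "junction signature in ", maxRetries, " attempts")
}

#' Simulate a windowed read-depth profile
#'
#' Per-window mean depths are Poisson: the window total is drawn as
#' Poisson(baseMean * fold * window) and divided by the window size,
#' emulating per-base Poisson coverage. Inside a CNV interval the rate is
#' scaled by the interval's fold (partially overlapping windows get an
#' overlap-weighted rate). The default base mean of 13.8x matches a typical
#' single-genome short-read sequencing depth.
#'
#' @param chromLength chromosome (or region) length in bp.
#' @param window window size in bp (default 10,000).
#' @param baseMean copy-neutral mean depth (default 13.8).
#' @param cnv optional data.frame with columns \code{start}, \code{end}
#'   (1-based inclusive) and \code{fold} (> 0).
#' @param perBase emit a per-base \code{chrom/pos/depth} table instead of
#'   per-window means (only sensible for short regions).
#' @param chrom chromosome name (default "X").
#' @param seed integer RNG seed (required).
#' @return list with \code{depth} (data.frame) and \code{truth} (the CNV
#'   table).
#' @export
simulateDepth <- function(chromLength = 6e6, window = 10000,
                          baseMean = 13.8, cnv = NULL, perBase = FALSE,
                          chrom = "X", seed) {
  if (missing(seed)) stop("a seed is required")
  if (!is.null(cnv)) stopifnot(all(cnv$fold > 0))
  set.seed(seed)
  if (perBase) {
    pos <- seq_len(chromLength)
    fold <- rep(1, chromLength)
    if (!is.null(cnv)) for (k in seq_len(nrow(cnv)))
      fold[pos >= cnv$start[k] & pos <= cnv$end[k]] <- cnv$fold[k]
    depth <- data.frame(chrom = chrom, pos = pos,
                        depth = stats::rpois(chromLength, baseMean * fold),
                        stringsAsFactors = FALSE)
  } else {
    nwin <- chromLength %/% window
    start <- (seq_len(nwin) - 1L) * window + 1L
    end <- start + window - 1L
    fold <- rep(1, nwin)
    if (!is.null(cnv)) for (k in seq_len(nrow(cnv))) {
      ov <- pmax(0, pmin(end, cnv$end[k]) - pmax(start, cnv$start[k]) + 1L)
      fold <- fold * (1 + (cnv$fold[k] - 1) * ov / window)
    }
    depth <- data.frame(chrom = chrom, start = start,
                        mean = stats::rpois(nwin, baseMean * fold * window) / window,
                        stringsAsFactors = FALSE)
  }
  list(depth = depth, truth = list(cnv = cnv))
}
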