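## Independent oracles, deliberately implemented with different algorithms
## than the package: Wright's path-counting kinship, exhaustive enumeration
## of Mendelian transmission outcomes, and a streaming mean.

## Wright path counting: phi(i,j) = sum over common ancestors A and pairs of
## ancestral paths (i -> A, j -> A) sharing only A of
## (1/2)^(n1 + n2 + 1) * (1 + F_A), with F_A = phi(sire_A, dam_A).
oracleKinship <- function(ped, aId, bId) {
  d <- pedigreeTable(ped)
  si <- match(d$sire, d$id)
  di <- match(d$dam, d$id)
  pathCache <- new.env(parent = emptyenv())
  pathsUp <- function(i) {
    key <- as.character(i)
    v <- pathCache[[key]]
    if (!is.null(v)) return(v)
    res <- list(i)
    for (p in c(si[i], di[i])) if (!is.na(p))
      for (pp in pathsUp(p)) res <- c(res, list(c(i, pp)))
    pathCache[[key]] <- res
    res
  }
  Fo <- function(i) {
    if (is.na(si[i]) || is.na(di[i])) return(0)
    phiO(si[i], di[i])
  }
  phiO <- function(i, j) {
    if (i == j) return(0.5 * (1 + Fo(i)))
    tot <- 0
    for (P1 in pathsUp(i)) for (P2 in pathsUp(j)) {
      A <- P1[length(P1)]
      if (A != P2[length(P2)]) next
      if (length(intersect(P1[-length(P1)], P2[-length(P2)])) > 0) next
      tot <- tot + 0.5^(length(P1) + length(P2) - 1) * (1 + Fo(A))
    }
    tot
  }
  phiO(match(aId, d$id), match(bId, d$id))
}

## Exact joint homozygosity probability by brute-force enumeration of every
## Mendelian transmission outcome (one of the ancestor's alleles mutant).
## Only feasible for pedigrees with few meioses.
oracleJointHomozygosity <- function(ped, ancestor, proband) {
  d <- pedigreeTable(ped)
  si <- match(d$sire, d$id)
  di <- match(d$dam, d$id)
  ord <- ped@topo
  anc <- match(ancestor, d$id)
  pro <- match(proband, d$id)
  ## meioses in processing order: (individual, parent) with a known parent;
  ## transmissions into the ancestor itself are irrelevant and skipped
  meio <- list()
  for (i in ord) {
    if (i == anc) next
    if (!is.na(si[i])) meio[[length(meio) + 1L]] <- c(i, si[i])
    if (!is.na(di[i])) meio[[length(meio) + 1L]] <- c(i, di[i])
  }
  m <- length(meio)
  stopifnot(m <= 16)  # 2^m outcomes
  n <- nrow(d)
  hom <- 0L
  for (mask in 0:(2^m - 1L)) {
    bits <- as.integer(intToBits(mask))[seq_len(max(m, 1L))]
    a1 <- character(n)
    a2 <- character(n)
    bi <- 0L
    for (i in ord) {
      if (i == anc) {
        a1[i] <- "MUT"; a2[i] <- "wt"
        next
      }
      pickFrom <- function(p) {
        bi <<- bi + 1L
        if (bits[bi] == 1L) a1[p] else a2[p]
      }
      a1[i] <- if (is.na(si[i])) paste0("u", i, "s") else pickFrom(si[i])
      a2[i] <- if (is.na(di[i])) paste0("u", i, "d") else pickFrom(di[i])
    }
    if (a1[pro] == "MUT" && a2[pro] == "MUT") hom <- hom + 1L
  }
  hom / 2^m
}

## streaming (running) mean, numerically independent of base::mean
streamingMean <- function(x) {
  m <- 0
  for (k in seq_along(x)) m <- m + (x[k] - m) / k
  m
}
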