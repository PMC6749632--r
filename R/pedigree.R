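## Pedigree construction, validation, kinship and lineage operations.
## Kinship uses the standard tabular recursion in topological order, which is
## equivalent to the diagonal-first construction of the Cholesky factor of
## the kinship matrix used by classic livestock pedigree software.

.SEX_LEVELS <- c("male", "female", "unknown")
.PHENO_LEVELS <- c("affected", "unaffected", "unknown")

.normParent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

## Stable Kahn topological sort; ties broken by input order.
## Returns row indices; stops with the id of an individual on a cycle.
.topoSort <- function(id, si, di) {
  n <- length(id)
  nLeft <- as.integer(!is.na(si)) + as.integer(!is.na(di))
  eFrom <- c(si[!is.na(si)], di[!is.na(di)])
  eTo <- c(which(!is.na(si)), which(!is.na(di)))
  children <- split(eTo, factor(eFrom, levels = seq_len(n)))
  ready <- which(nLeft == 0L)
  ord <- integer(n)
  k <- 0L
  while (length(ready)) {
    i <- ready[1L]
    ready <- ready[-1L]
    k <- k + 1L
    ord[k] <- i
    ch <- children[[i]]
    for (c_ in ch) {
      nLeft[c_] <- nLeft[c_] - 1L
      if (nLeft[c_] == 0L) ready <- sort(c(ready, c_))
    }
  }
  if (k < n) {
    ## walk parent links inside the unresolved set until a repeat: that
    ## individual provably lies on a parentage cycle
    left <- setdiff(seq_len(n), ord[seq_len(k)])
    cur <- left[1L]
    seen <- integer(0)
    while (!(cur %in% seen)) {
      seen <- c(seen, cur)
      nxt <- c(si[cur], di[cur])
      nxt <- nxt[!is.na(nxt) & nxt %in% left]
      cur <- nxt[1L]
    }
    stop("parentage cycle detected involving individual '", id[cur], "'")
  }
  ord
}

setValidity("Pedigree", function(object) {
  d <- object@data
  need <- c("id", "sire", "dam", "sex", "birth_year", "death_age_months",
            "phenotype", "cause")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$id)) return("duplicate individual id")
  if (any(is.na(d$id) | d$id == "")) return("empty individual id")
  if (any(!is.na(d$sire) & d$sire == d$id) || any(!is.na(d$dam) & d$dam == d$id))
    return("individual listed as its own parent")
  if (!all(stats::na.omit(c(d$sire, d$dam)) %in% d$id))
    return("parent id referenced but absent from the pedigree")
  sx <- d$sex[match(stats::na.omit(d$sire), d$id)]
  if (any(sx == "female")) return("an individual recorded as female is listed as a sire")
  dx <- d$sex[match(stats::na.omit(d$dam), d$id)]
  if (any(dx == "male")) return("an individual recorded as male is listed as a dam")
  rank <- integer(nrow(d)); rank[object@topo] <- seq_len(nrow(d))
  si <- match(d$sire, d$id); di <- match(d$dam, d$id)
  ok <- (is.na(si) | rank[si] < rank) & (is.na(di) | rank[di] < rank)
  if (!all(ok)) return("topological order inconsistent with parentage")
  TRUE
})

#' Construct a validated Pedigree
#'
#' Builds a [Pedigree-class] from a table of individual records, normalizes
#' unknown parents ("0", empty string and \code{NA} all mean unknown),
#' optionally auto-creates referenced-but-absent parents as founders, and
#' computes a topological order (stable by input order). A parentage cycle
#' is a structural error naming one individual on the cycle.
#'
#' @param data data.frame with columns \code{id}, \code{sire}, \code{dam} and
#'   optionally \code{sex}, \code{birth_year}, \code{death_age_months},
#'   \code{phenotype}, \code{cause}.
#' @param addMissingFounders if \code{TRUE} (default), a parent id that never
#'   appears in \code{id} is appended as a founder with unknown attributes;
#'   if \code{FALSE} this is an error.
#' @return a [Pedigree-class] object.
#' @examples
#' ped <- Pedigree(data.frame(id = c("A", "B", "C"),
#'                            sire = c("0", "0", "A"),
#'                            dam  = c("0", "0", "B")))
#' pedIds(ped)
#' @export
Pedigree <- function(data, addMissingFounders = TRUE) {
  stopifnot(is.data.frame(data), all(c("id", "sire", "dam") %in% names(data)))
  d <- data.frame(id = as.character(data$id),
                  sire = .normParent(data$sire),
                  dam = .normParent(data$dam),
                  stringsAsFactors = FALSE)
  d$sex <- if ("sex" %in% names(data)) {
    s <- as.character(data$sex)
    s[is.na(s) | !(s %in% .SEX_LEVELS)] <- "unknown"
    s
  } else rep("unknown", nrow(d))
  d$birth_year <- if ("birth_year" %in% names(data))
    as.integer(data$birth_year) else rep(NA_integer_, nrow(d))
  d$death_age_months <- if ("death_age_months" %in% names(data))
    as.numeric(data$death_age_months) else rep(NA_real_, nrow(d))
  d$phenotype <- if ("phenotype" %in% names(data)) {
    p <- as.character(data$phenotype)
    p[is.na(p) | !(p %in% .PHENO_LEVELS)] <- "unknown"
    p
  } else rep("unknown", nrow(d))
  d$cause <- if ("cause" %in% names(data))
    as.character(data$cause) else rep(NA_character_, nrow(d))

  if (anyDuplicated(d$id))
    stop("duplicate individual id: '", d$id[duplicated(d$id)][1L], "'")
  missing <- setdiff(stats::na.omit(c(d$sire, d$dam)), d$id)
  if (length(missing)) {
    if (!addMissingFounders)
      stop("parent id(s) referenced but absent: ",
           paste(missing, collapse = ", "))
    asSire <- missing %in% d$sire
    asDam <- missing %in% d$dam
    sex <- ifelse(asSire & !asDam, "male", ifelse(asDam & !asSire, "female", "unknown"))
    d <- rbind(d, data.frame(id = missing, sire = NA_character_,
                             dam = NA_character_, sex = sex,
                             birth_year = NA_integer_,
                             death_age_months = NA_real_,
                             phenotype = "unknown", cause = NA_character_,
                             stringsAsFactors = FALSE))
  }
  rownames(d) <- NULL
  si <- match(d$sire, d$id)
  di <- match(d$dam, d$id)
  topo <- .topoSort(d$id, si, di)
  new("Pedigree", data = d, topo = topo)
}

#' Read a pedigree from delimited text
#'
#' Comma or tab delimiter is auto-detected from the header line; a header is
#' required. Unknown parents may be encoded as \code{"0"} or an empty field.
#'
#' @param file path to the pedigree file.
#' @inheritParams Pedigree
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(file, addMissingFounders = TRUE) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         colClasses = "character",
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  Pedigree(d, addMissingFounders = addMissingFounders)
}

#' Write a pedigree to delimited text
#'
#' Inverse of [readPedigree()]: writes the individual table (input order,
#' unknown parents as \code{"0"}) so that reading it back reproduces the
#' same structure.
#'
#' @param ped a [Pedigree-class].
#' @param file output path.
#' @param sep field delimiter (default comma).
#' @export
writePedigree <- function(ped, file, sep = ",") {
  d <- ped@data
  d$sire[is.na(d$sire)] <- "0"
  d$dam[is.na(d$dam)] <- "0"
  utils::write.table(d, file, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(file)
}

#' @describeIn Pedigree individual identifiers, in input order
#' @param ped a [Pedigree-class].
#' @export
pedIds <- function(ped) ped@data$id

#' @describeIn Pedigree the individual table as a data.frame
#' @export
pedigreeTable <- function(ped) ped@data

#' @describeIn Pedigree number of individuals
#' @export
nIndividuals <- function(ped) nrow(ped@data)

setMethod("show", "Pedigree", function(object) {
  d <- object@data
  cat("Pedigree with", nrow(d), "individuals (",
      sum(is.na(d$sire) & is.na(d$dam)), "founders )\n")
  cat("  birth years:", if (all(is.na(d$birth_year))) "none recorded" else
      paste(range(d$birth_year, na.rm = TRUE), collapse = "-"), "\n")
  cat("  affected:", sum(d$phenotype == "affected"), "\n")
})

.parentIdx <- function(ped) {
  d <- ped@data
  list(si = match(d$sire, d$id), di = match(d$dam, d$id))
}

.idIndex <- function(ped, id, what = "individual") {
  i <- match(id, ped@data$id)
  if (is.na(i)) stop("unknown ", what, " id: '", id, "'")
  i
}

#' Kinship matrix by the tabular recursion
#'
#' Computes the full dense matrix of pairwise kinship coefficients phi by the
#' standard tabular recursion in topological order: phi(i,i) = 0.5 * (1 +
#' phi(sire_i, dam_i)) and phi(i,j) = 0.5 * (phi(sire_i, j) + phi(dam_i, j))
#' for j preceding i, with unknown-parent terms contributing 0. This is
#' algebraically identical to building the Cholesky factor of the kinship
#' matrix row by row. The dense matrix is restricted to pedigrees of at most
#' 20,000 individuals; beyond that use [kinshipPair()] on demand.
#'
#' @param ped a [Pedigree-class].
#' @return a [KinshipMatrix-class] with ids as dimnames, in input order.
#' @examples
#' ped <- Pedigree(data.frame(id = c("A", "B", "C"), sire = c(0, 0, "A"),
#'                            dam = c(0, 0, "B")))
#' kinshipMatrix(ped)["A", "C"]   # parent-offspring: 0.25
#' @export
kinshipMatrix <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- nIndividuals(ped)
  if (n > 20000L)
    stop("dense kinship matrix is limited to 20,000 individuals; ",
         "use kinshipPair() for per-pair values")
  p <- .parentIdx(ped)
  K <- matrix(0, n, n, dimnames = list(ped@data$id, ped@data$id))
  ord <- ped@topo
  for (k in seq_len(n)) {
    i <- ord[k]
    s <- p$si[i]; d <- p$di[i]
    if (k > 1L) {
      prev <- ord[seq_len(k - 1L)]
      v <- numeric(k - 1L)
      if (!is.na(s)) v <- v + K[s, prev]
      if (!is.na(d)) v <- v + K[d, prev]
      v <- 0.5 * v
      K[i, prev] <- v
      K[prev, i] <- v
    }
    K[i, i] <- 0.5 * (1 + if (!is.na(s) && !is.na(d)) K[s, d] else 0)
  }
  new("KinshipMatrix", K)
}

## memoized pairwise kinship closure over one pedigree
.phiFun <- function(ped) {
  p <- .parentIdx(ped)
  rank <- integer(nIndividuals(ped))
  rank[ped@topo] <- seq_along(ped@topo)
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (rank[i] < rank[j]) { t <- i; i <- j; j <- t }
    key <- paste0(i, ":", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      0.5 * (1 + phi(p$si[i], p$di[i]))
    } else {
      0.5 * (phi(p$si[i], j) + phi(p$di[i], j))
    }
    memo[[key]] <- v
    v
  }
  phi
}

#' Kinship coefficient for one pair of individuals
#'
#' Memoized pairwise recursion; suitable for pedigrees too large for the
#' dense [kinshipMatrix()].
#'
#' @param ped a [Pedigree-class].
#' @param a,b individual identifiers.
#' @return kinship coefficient in [0, 1].
#' @export
kinshipPair <- function(ped, a, b) {
  i <- .idIndex(ped, a); j <- .idIndex(ped, b)
  .phiFun(ped)(i, j)
}

#' Inbreeding coefficient
#'
#' F equals the kinship coefficient of the individual's parents; 0 when
#' either parent is unknown.
#'
#' @param ped a [Pedigree-class].
#' @param id individual identifier.
#' @return F in [0, 1].
#' @export
inbreedingCoefficient <- function(ped, id) {
  i <- .idIndex(ped, id)
  p <- .parentIdx(ped)
  if (is.na(p$si[i]) || is.na(p$di[i])) return(0)
  .phiFun(ped)(p$si[i], p$di[i])
}

#' Mean inbreeding coefficient of a birth cohort
#'
#' Arithmetic mean of F over individuals born in a given year, optionally
#' restricted to one sex.
#'
#' @param ped a [Pedigree-class].
#' @param birthYear integer year.
#' @param sex optional \code{"male"} or \code{"female"} filter.
#' @return mean F of the cohort.
#' @export
cohortMeanInbreeding <- function(ped, birthYear, sex = NULL) {
  d <- ped@data
  keep <- !is.na(d$birth_year) & d$birth_year == birthYear
  if (!is.null(sex)) keep <- keep & d$sex == sex
  if (!any(keep))
    stop("empty cohort: no individual born in ", birthYear,
         if (!is.null(sex)) paste0(" with sex ", sex) else "")
  p <- .parentIdx(ped)
  phi <- .phiFun(ped)
  f <- vapply(which(keep), function(i) {
    if (is.na(p$si[i]) || is.na(p$di[i])) 0 else phi(p$si[i], p$di[i])
  }, numeric(1))
  mean(f)
}

#' Ancestor identifiers of one individual
#'
#' All ancestors reachable through recorded parent links (the individual
#' itself excluded).
#'
#' @param ped a [Pedigree-class].
#' @param id individual identifier.
#' @return character vector of ancestor ids.
#' @export
ancestorIds <- function(ped, id) {
  i <- .idIndex(ped, id)
  p <- .parentIdx(ped)
  seen <- logical(nIndividuals(ped))
  queue <- c(p$si[i], p$di[i])
  queue <- queue[!is.na(queue)]
  while (length(queue)) {
    j <- queue[[1L]]
    queue <- queue[-1L]
    if (seen[j]) next
    seen[j] <- TRUE
    nxt <- c(p$si[j], p$di[j])
    queue <- c(queue, nxt[!is.na(nxt)])
  }
  ped@data$id[seen]
}

#' Ancestors common to both parental lineages of a proband
#'
#' Returns the intersection of the ancestor set of the proband's sire
#' (including the sire itself) and that of its dam (including the dam). Each
#' returned ancestor implies at least one pedigree loop through the proband,
#' i.e. a path structure enabling autozygosity in the proband.
#'
#' @param ped a [Pedigree-class].
#' @param proband proband identifier; both parents must be recorded.
#' @return character vector of common-lineage ancestor ids (possibly empty).
#' @export
commonLineageAncestors <- function(ped, proband) {
  i <- .idIndex(ped, proband, "proband")
  d <- ped@data
  if (is.na(d$sire[i]) || is.na(d$dam[i]))
    stop("proband '", proband, "' must have both parents recorded")
  pat <- c(d$sire[i], ancestorIds(ped, d$sire[i]))
  mat <- c(d$dam[i], ancestorIds(ped, d$dam[i]))
  intersect(pat, mat)
}
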