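## Quadrat-based skin morphometry: per-group means of hair count, pilary
## canal diameter and hair-covered area in fixed 1-mm^2 quadrats, and
## case/control fold changes. Rounding is half-up at the precision the
## measurements are reported at (1 decimal for counts and diameters,
## integer for areas).

#' Read a quadrat morphometry table
#'
#' Delimited table with columns \code{group} (\code{control} or
#' \code{affected}), \code{quadrat_id}, \code{hair_count},
#' \code{mean_diameter_um}, \code{total_area_um2}. Quadrat area is fixed at
#' 1 mm^2.
#'
#' @param file path to the table.
#' @return data.frame.
#' @export
readQuadrats <- function(file) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("group", "quadrat_id", "hair_count", "mean_diameter_um",
            "total_area_um2")
  stopifnot(all(need %in% names(d)))
  if (any(d$hair_count < 0) || any(d$mean_diameter_um <= 0) ||
      any(d$total_area_um2 <= 0))
    stop("hair counts must be >= 0 and diameters/areas positive")
  d
}

#' Per-group quadrat summary
#'
#' Arithmetic means per group, rounded half-up: hair count and diameter to
#' one decimal, total area to the nearest integer.
#'
#' @param quadrats data.frame as from [readQuadrats()].
#' @return data.frame with one row per group and columns
#'   \code{mean_hair_count}, \code{mean_diameter_um},
#'   \code{mean_total_area_um2}.
#' @export
quadratSummary <- function(quadrats) {
  groups <- unique(quadrats$group)
  if (!length(groups)) stop("empty quadrat table")
  rows <- lapply(groups, function(g) {
    q <- quadrats[quadrats$group == g, , drop = FALSE]
    if (!nrow(q)) stop("empty group: ", g)
    data.frame(group = g,
               mean_hair_count = .roundHalfUp(mean(q$hair_count), 1),
               mean_diameter_um = .roundHalfUp(mean(q$mean_diameter_um), 1),
               mean_total_area_um2 = .roundHalfUp(mean(q$total_area_um2), 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Case/control fold changes of the quadrat summary
#'
#' Hair-count fold is affected/control (an increase in the affected
#' animal); diameter fold is control/affected (the affected canals are
#' narrower, and the fold expresses how many times smaller). Both are
#' reported rounded half-up to one decimal and to the nearest integer fold.
#'
#' @param summary data.frame from [quadratSummary()] containing both
#'   groups.
#' @return list with \code{hair_count_fold}, \code{hair_count_fold_int},
#'   \code{diameter_fold}, \code{diameter_fold_int}.
#' @export
foldChanges <- function(summary) {
  need <- c("affected", "control")
  if (!all(need %in% summary$group))
    stop("summary must contain both an 'affected' and a 'control' group")
  aff <- summary[summary$group == "affected", , drop = FALSE]
  ctl <- summary[summary$group == "control", , drop = FALSE]
  if (ctl$mean_hair_count == 0 || aff$mean_diameter_um == 0)
    stop("zero denominator in fold change")
  hairFold <- aff$mean_hair_count / ctl$mean_hair_count
  diamFold <- ctl$mean_diameter_um / aff$mean_diameter_um
  list(hair_count_fold = .roundHalfUp(hairFold, 1),
       hair_count_fold_int = .roundHalfUp(hairFold, 0),
       diameter_fold = .roundHalfUp(diamFold, 1),
       diameter_fold_int = .roundHalfUp(diamFold, 0))
}
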