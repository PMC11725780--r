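#' @title Chromosomal sex and maternal-lineage consistency
#' @name uniparental
#' @description Sex calls from Y-chromosome read proportions (Ry) and
#'   X-normalised coverage (Rx), and consistency checks of mtDNA lineage
#'   labels along maternal paths of a pedigree.
NULL

#' Chromosomal sex from the Y-read proportion Ry
#'
#' Ry = nY / (nX + nY) with an exact binomial 95% CI. XX when the CI upper
#' bound is below `xx_max` (0.016), XY when the lower bound is above
#' `xy_min` (0.075), undetermined otherwise.
#'
#' @param nY,nX read counts mapped to Y and X.
#' @param xx_max,xy_min decision thresholds.
#' @return list with `ry`, `ry_ci`, `call`.
#' @export
ry_sex <- function(nY, nX, xx_max = 0.016, xy_min = 0.075) {
  tot <- nX + nY
  if (tot <= 0) return(list(ry = NA_real_, ry_ci = c(NA, NA),
                            call = "undetermined"))
  ci <- stats::binom.test(nY, tot)$conf.int
  ry <- nY / tot
  call <- if (ci[2] < xx_max) "XX" else if (ci[1] > xy_min) "XY"
    else "undetermined"
  list(ry = ry, ry_ci = as.numeric(ci), call = call)
}

#' Chromosomal sex from X-normalised coverage Rx
#'
#' Rx is the mean over autosomes of X coverage divided by that autosome's
#' coverage; its CI uses the across-autosome variability. XX when the CI
#' lies within [0.8, 1.2], XY when within [0.3, 0.7], else undetermined.
#'
#' @param coverages named numeric vector of mean per-chromosome coverages;
#'   must contain an element named "X" and at least two autosomes.
#' @return list with `rx`, `rx_ci`, `call`.
#' @export
rx_sex <- function(coverages) {
  if (!"X" %in% names(coverages) || is.na(coverages["X"]))
    return(list(rx = NA_real_, rx_ci = c(NA, NA), call = "undetermined"))
  aut <- coverages[setdiff(names(coverages), c("X", "Y"))]
  aut <- aut[!is.na(aut) & aut > 0]
  if (length(aut) < 2) stop("need coverage for at least two autosomes")
  ratios <- coverages[["X"]] / aut
  rx <- mean(ratios)
  se <- stats::sd(ratios) / sqrt(length(ratios))
  ci <- rx + c(-1.96, 1.96) * se
  call <- if (ci[1] >= 0.8 && ci[2] <= 1.2) "XX"
    else if (ci[1] >= 0.3 && ci[2] <= 0.7) "XY"
    else "undetermined"
  list(rx = rx, rx_ci = ci, call = call)
}

#' Combine Ry and Rx sex calls
#'
#' Both statistics are reported; the combined call is their shared value, or
#' the single determined one; a conflict yields undetermined.
#'
#' @param ry_call,rx_call calls from [ry_sex()] and [rx_sex()].
#' @return "XX", "XY" or "undetermined".
#' @export
combine_sex_calls <- function(ry_call, rx_call) {
  det <- setdiff(unique(c(ry_call, rx_call)), "undetermined")
  if (length(det) == 1) det else "undetermined"
}

# matriline root of an individual: follow mother links upward
matriline_root <- function(ped, id) {
  while (TRUE) {
    m <- ped$mother[ped$id == id]
    if (length(m) == 0 || is.na(m)) return(id)
    id <- m
  }
}

#' Check mtDNA lineage labels against a pedigree's maternal paths
#'
#' Every pair of labelled individuals connected by a maternal path (same
#' matriline) must carry the same lineage label.
#'
#' @param lineages data.frame with columns `id` and `lineage`.
#' @param ped pedigree data.frame.
#' @return data.frame of violations (id1, id2, lineage1, lineage2); zero
#'   rows when consistent.
#' @export
maternal_consistency <- function(lineages, ped) {
  lab <- stats::setNames(lineages$lineage, lineages$id)
  ids <- intersect(names(lab), ped$id)
  roots <- vapply(ids, function(i) matriline_root(ped, i), "")
  out <- data.frame(id1 = character(0), id2 = character(0),
                    lineage1 = character(0), lineage2 = character(0),
                    stringsAsFactors = FALSE)
  if (length(ids) < 2) return(out)
  cmb <- utils::combn(ids, 2)
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    if (roots[i] == roots[j] && lab[i] != lab[j])
      out <- rbind(out, data.frame(id1 = i, id2 = j, lineage1 = lab[i],
                                   lineage2 = lab[j],
                                   stringsAsFactors = FALSE))
  }
  out
}
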