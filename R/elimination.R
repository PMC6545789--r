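#' Eliminate a sacrificial cell population
#'
#' Converts every site of the given cell type to cell culture medium
#' (\eqn{\sigma = 0}), modeling the on-command removal of sensitized
#' (sacrificial) cells. The intervention is instantaneous and leaves every
#' other site untouched; applying it twice equals applying it once.
#'
#' @param lat An [mmc_lattice()].
#' @param sacrificial Type name or sigma index of the population to remove.
#'   Must be a cell type: medium cannot be eliminated and hydrogel removal is
#'   not a biological elimination.
#' @return List with the updated `lattice`, the number of sites `removed`,
#'   and `vacated`, the 1-based linear indices of the converted sites.
#' @export
eliminate_type <- function(lat, sacrificial) {
  stopifnot(inherits(lat, "mmc_lattice"))
  s <- sigma_of(lat, sacrificial)
  stopifnot(length(s) == 1L)
  kind <- lat$types$kind[lat$types$sigma == s]
  if (kind != "cell")
    stop("only cell types can be eliminated, not ", kind)
  idx <- which(lat$sites == s)
  out <- lat
  out$sites[idx] <- 0L
  list(lattice = out, removed = length(idx), vacated = idx)
}
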