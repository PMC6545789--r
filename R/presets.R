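#' Adhesion-parameter presets of the three study scenarios
#'
#' Returns the works-of-adhesion table and type registry used by each
#' simulated construct. All medium contacts have zero work of adhesion, so
#' the energy is purely interfacial between condensed phases.
#'
#' \describe{
#'   \item{`"single_tube"`}{medium / wall cells / sacrificial cells with
#'     identical adhesivities (all cell-cell works 1.4): the wall and the
#'     sacrificial population come from the same cell type, so their mutual
#'     interfacial tension vanishes and only the medium interface is active.}
#'   \item{`"two_type_sorting"`}{medium / smooth muscle / endothelial /
#'     sacrificial with the tension hierarchy that drives endothelial cells
#'     to spread over the sacrificial core (works 1.6, 1.4, 1.0, 2.0, 1.8,
#'     2.4 for the pairs 11, 12, 13, 22, 23, 33).}
#'   \item{`"two_type_scrambled"`}{same except the smooth-muscle/endothelial
#'     work drops to 1.0, breaking the hierarchy; sorting then fails to
#'     produce an endothelial lining.}
#'   \item{`"branched_hydrogel"`}{medium / hydrogel / endothelial /
#'     sacrificial (works 2.4, 2.0, 2.0, 1.6, 2.0, 4.0 for 11, 12, 13, 22,
#'     23, 33): endothelial cells wet the hydrogel-sacrificial interface.}
#' }
#'
#' @param name Preset name.
#' @return List with `types` (a [type_registry()]) and `table` (an
#'   [adhesion_table()] with `E_T = 1`).
#' @export
adhesion_preset <- function(name = c("single_tube", "two_type_sorting",
                                     "two_type_scrambled", "branched_hydrogel")) {
  name <- match.arg(name)
  sym <- function(n, vals) {
    e <- matrix(0, n, n)
    k <- 1L
    for (i in 2:n) for (j in i:n) {
      e[i, j] <- e[j, i] <- vals[k]
      k <- k + 1L
    }
    e
  }
  if (name == "single_tube") {
    types <- type_registry(c("medium", "wall", "sacrificial"),
                           c("medium", "cell", "cell"))
    eps <- sym(3, c(1.4, 1.4, 1.4)) # 11, 12, 22
  } else if (name == "two_type_sorting") {
    types <- type_registry(c("medium", "smooth_muscle", "endothelial", "sacrificial"),
                           c("medium", "cell", "cell", "cell"))
    eps <- sym(4, c(1.6, 1.4, 1.0, 2.0, 1.8, 2.4)) # 11, 12, 13, 22, 23, 33
  } else if (name == "two_type_scrambled") {
    types <- type_registry(c("medium", "smooth_muscle", "endothelial", "sacrificial"),
                           c("medium", "cell", "cell", "cell"))
    eps <- sym(4, c(1.6, 1.0, 1.0, 2.0, 1.8, 2.4))
  } else {
    types <- type_registry(c("medium", "hydrogel", "endothelial", "sacrificial"),
                           c("medium", "hydrogel", "cell", "cell"))
    eps <- sym(4, c(2.4, 2.0, 2.0, 1.6, 2.0, 4.0))
  }
  list(types = types, table = adhesion_table(eps, E_T = 1, type_names = types$name))
}
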