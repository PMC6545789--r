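phase_mask <- function(lat, phase) {
  s <- sigma_of(lat, phase)
  if (!length(s)) stop("phase must name at least one type")
  mask <- rep(FALSE, nrow(lat$types))
  mask[s + 1L] <- TRUE
  mask
}

#' Connected components of a phase
#'
#' Standard connected-component labeling of the indicator volume of a set of
#' types. The default 26-connectivity matches the interaction neighborhood;
#' 6-connectivity is the stricter choice for perfusability questions, where a
#' fluid path through a cube-diagonal contact is physically dubious.
#'
#' @param lat An [mmc_lattice()].
#' @param phase Type names or sigma indices forming the phase.
#' @param connectivity 6, 18 or 26.
#' @return List with `labels` (integer array, 0 outside the phase),
#'   `n_components`, and `sizes` (component site counts, decreasing).
#' @export
phase_components <- function(lat, phase, connectivity = 26) {
  stopifnot(inherits(lat, "mmc_lattice"))
  mask <- phase_mask(lat, phase)
  lab <- cpp_label_components(as.vector(lat$sites), dim(lat$sites), mask,
                              as.integer(connectivity))
  n <- max(lab, 0L)
  sizes <- if (n > 0) sort(tabulate(lab, nbins = n), decreasing = TRUE) else integer(0)
  list(labels = array(lab, dim(lat$sites)), n_components = n, sizes = sizes)
}

cavity_shell_pairs <- function(lat, cavity_sigma) {
  d <- dim(lat$sites)
  cav_lin <- which(array(lat$sites %in% cavity_sigma, d))
  if (!length(cav_lin)) stop("cavity phase is empty")
  xyz <- arrayInd(cav_lin, d)
  off <- neighbor_offsets()
  nb_val <- integer(0)
  for (j in seq_len(nrow(off))) {
    p <- sweep(xyz, 2, off[j, ], "+")
    inb <- p[, 1] >= 1L & p[, 1] <= d[1] & p[, 2] >= 1L & p[, 2] <= d[2] &
      p[, 3] >= 1L & p[, 3] <= d[3]
    if (!any(inb)) next
    q <- p[inb, , drop = FALSE]
    nb_val <- c(nb_val, lat$sites[q[, 1] + d[1] * (q[, 2] - 1L) + d[1] * d[2] * (q[, 3] - 1L)])
  }
  nb_val[!nb_val %in% cavity_sigma]
}

#' Endothelial lining coverage of a cavity
#'
#' Over all 26-neighbors of cavity sites that are not themselves cavity,
#' returns the fraction held by the lining type. A value of 1 means the
#' cavity is completely wrapped in lining cells.
#'
#' @param lat An [mmc_lattice()].
#' @param lining Lining type (name or sigma).
#' @param cavity Cavity phase (names or sigmas), e.g. the sacrificial
#'   population before elimination or the lumen medium after.
#' @return Fraction in `[0, 1]`.
#' @export
lining_coverage <- function(lat, lining, cavity) {
  stopifnot(inherits(lat, "mmc_lattice"))
  lin_s <- sigma_of(lat, lining)
  cav_s <- sigma_of(lat, cavity)
  stopifnot(length(lin_s) == 1L)
  if (lin_s %in% cav_s) stop("the lining type cannot be part of the cavity phase")
  shell <- cavity_shell_pairs(lat, cav_s)
  if (!length(shell)) stop("the cavity has an empty interface")
  mean(shell == lin_s)
}

#' Boundary-pair count between two phases
#'
#' The number of unordered 26-neighbor pairs with one site in each phase.
#' For a fixed enclosed volume, a decreasing count indicates surface
#' smoothing (a digital sphere exposes fewer boundary pairs than an
#' elongated shape of the same volume).
#'
#' @param lat An [mmc_lattice()].
#' @param a,b Disjoint phases (type names or sigma indices).
#' @return Pair count (numeric).
#' @export
interface_roughness <- function(lat, a, b) {
  sa <- sigma_of(lat, a)
  sb <- sigma_of(lat, b)
  if (length(intersect(sa, sb))) stop("phases must be disjoint")
  N <- bond_counts(lat)
  sum(N[sa + 1L, sb + 1L, drop = FALSE])
}

#' Lining coverage across the checkpoints of a run
#'
#' Evaluates [lining_coverage()] on every recorded snapshot that still
#' contains the cavity phase; used to compare adhesion-parameter hierarchies.
#'
#' @param run An [run_schedule()] result with snapshots.
#' @param lining,cavity Passed to [lining_coverage()].
#' @return Data frame with columns `mcs` and `coverage`.
#' @export
sorting_trajectory <- function(run, lining, cavity) {
  stopifnot(inherits(run, "mmc_run"))
  if (!length(run$snapshots)) stop("the run recorded no snapshots")
  mcs <- as.numeric(names(run$snapshots))
  cov <- vapply(run$snapshots, function(sn) {
    cav <- sigma_of(sn, cavity)
    if (!any(sn$sites %in% cav)) return(NA_real_)
    lining_coverage(sn, lining, cavity)
  }, numeric(1))
  data.frame(mcs = mcs, coverage = unname(cov))
}

#' Enclosed (interior) medium mask
#'
#' Classifies each medium site by ray casting along the six lattice axes: a
#' site is interior when at least `min_blocked` of the six rays meet a
#' non-medium site before leaving the box. This separates channel/lumen
#' medium (wrapped transversally by cells or gel, but open along the channel
#' axis) from the exterior bath.
#'
#' @param lat An [mmc_lattice()].
#' @param min_blocked Minimum number of blocked axial rays (default 4: a
#'   straight open channel has two open axial rays).
#' @return Logical array, `TRUE` for interior medium sites.
#' @export
enclosed_medium <- function(lat, min_blocked = 4) {
  stopifnot(inherits(lat, "mmc_lattice"))
  blocked <- cpp_blocked_directions(as.vector(lat$sites), dim(lat$sites))
  array(blocked >= min_blocked, dim(lat$sites))
}

#' Locate and measure the lumen of a construct
#'
#' The lumen is operationalized as the connected component of interior
#' medium ([enclosed_medium()]) that contains the largest share of the sites
#' vacated by sacrificial-cell elimination. (A naive labeling of all medium
#' would merge the lumen with the exterior bath through the open channel
#' ends.)
#'
#' @param lat An [mmc_lattice()], typically after [eliminate_type()] plus
#'   further relaxation.
#' @param vacated 1-based linear indices of the sites the elimination
#'   vacated, as returned by [eliminate_type()] / stored in an `mmc_run`.
#' @param connectivity Connectivity for the component labeling.
#' @param min_blocked Passed to [enclosed_medium()].
#' @return List: `exists`, `size` (sites in the lumen component),
#'   `overlap` (share of the lumen inside the vacated set),
#'   `vacated_recovered` (share of vacated sites inside the lumen),
#'   `n_interior_components`, and `lumen_sites` (linear indices).
#' @export
lumen_report <- function(lat, vacated, connectivity = 26, min_blocked = 4) {
  stopifnot(inherits(lat, "mmc_lattice"))
  mask <- enclosed_medium(lat, min_blocked = min_blocked)
  ind <- array(as.integer(mask), dim(lat$sites))
  lab <- cpp_label_components(as.vector(ind), dim(lat$sites), c(FALSE, TRUE),
                              as.integer(connectivity))
  n <- max(lab, 0L)
  if (n == 0L)
    return(list(exists = FALSE, size = 0L, overlap = NA_real_,
                vacated_recovered = 0, n_interior_components = 0L,
                lumen_sites = integer(0)))
  overlap_cnt <- tabulate(lab[vacated], nbins = n)
  best <- which.max(overlap_cnt)
  sizes <- tabulate(lab, nbins = n)
  lumen_sites <- which(lab == best)
  list(exists = overlap_cnt[best] > 0L, size = sizes[best],
       overlap = overlap_cnt[best] / sizes[best],
       vacated_recovered = overlap_cnt[best] / length(vacated),
       n_interior_components = n, lumen_sites = lumen_sites)
}
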