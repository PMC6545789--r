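#' Metropolis acceptance rule
#'
#' A proposed swap with energy change `dE` is accepted outright when
#' `dE <= 0`; otherwise it is accepted with probability
#' \eqn{\exp(-\Delta E / E_T)}.
#'
#' @param dE Numeric vector of energy changes.
#' @param E_T Positive fluctuation energy scale.
#' @return Logical vector of accept/reject decisions (one uniform deviate is
#'   consumed per energy-raising proposal).
#' @export
metropolis_accept <- function(dE, E_T = 1) {
  if (!is.numeric(E_T) || length(E_T) != 1L || E_T <= 0) stop("E_T must be positive")
  acc <- dE <= 0
  pos <- which(!acc)
  if (length(pos)) acc[pos] <- runif(length(pos)) < exp(-dE[pos] / E_T)
  acc
}

check_coord <- function(lat, p, what) {
  d <- dim(lat$sites)
  p <- as.integer(p)
  if (length(p) != 3L || any(p < 1L) || any(p > d))
    stop(what, " must be a within-bounds (x, y, z) coordinate triple")
  p
}

lin0 <- function(p, d) (p[1] - 1L) + d[1] * ((p[2] - 1L) + d[2] * (p[3] - 1L))

#' Energy change of a neighbor swap
#'
#' Computes \eqn{\Delta E} for exchanging the contents of two neighboring
#' sites from their two 26-neighborhoods only; by construction it equals the
#' global energy difference between the swapped and unswapped configurations.
#'
#' @param lat An [mmc_lattice()].
#' @param table An [adhesion_table()].
#' @param a,b 1-based (x, y, z) coordinates of two distinct sites within the
#'   26-neighborhood of one another, holding different types.
#' @return Energy scalar.
#' @export
delta_energy <- function(lat, table, a, b) {
  stopifnot(inherits(lat, "mmc_lattice"))
  check_table_covers(lat, table)
  d <- dim(lat$sites)
  a <- check_coord(lat, a, "a"); b <- check_coord(lat, b, "b")
  ch <- max(abs(a - b))
  if (ch != 1L || any(abs(a - b) > 1L)) stop("a and b must be distinct 26-neighbors")
  if (lat$sites[a[1], a[2], a[3]] == lat$sites[b[1], b[2], b[3]])
    stop("sites hold identical types: the swap is a no-op and is not a valid move")
  cpp_delta_energy(as.vector(lat$sites), d, gamma_matrix(table), lin0(a, d), lin0(b, d))
}

#' Mobility policy of the swap dynamics
#'
#' Only cell-type sites initiate moves. A move exchanges a cell with a
#' neighboring site of a different type: another cell, medium, or (when
#' `allow_gel_swap` is `TRUE`, the default, modeling a hydrogel that cells can
#' invade and remodel) hydrogel. Medium and hydrogel never exchange with one
#' another, so the gel does not diffuse through the medium.
#'
#' @param lat An [mmc_lattice()].
#' @param allow_gel_swap Allow cell/hydrogel exchanges?
#' @return List with `mobile` (logical by type) and `swap_ok` (logical
#'   type-by-type matrix).
#' @export
mobility_policy <- function(lat, allow_gel_swap = TRUE) {
  kind <- lat$types$kind
  n <- length(kind)
  mobile <- kind == "cell"
  ok <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ki <- kind[i]; kj <- kind[j]
    if (ki == "cell" && kj == "cell") ok[i, j] <- TRUE
    else if ((ki == "cell" && kj == "medium") || (ki == "medium" && kj == "cell")) ok[i, j] <- TRUE
    else if ((ki == "cell" && kj == "hydrogel") || (ki == "hydrogel" && kj == "cell"))
      ok[i, j] <- isTRUE(allow_gel_swap)
  }
  list(mobile = mobile, swap_ok = ok)
}

#' Run Monte Carlo steps
#'
#' One Monte Carlo step (MCS) is `M` attempted swaps, where `M` is the current
#' number of mobile (cell-type) sites. Each attempt picks a mobile site
#' uniformly, then one of its in-bounds 26-neighbors uniformly; the swap is
#' attempted if the two types differ and the pair is allowed by the mobility
#' policy, and accepted by the Metropolis rule. Uses R's global RNG stream:
#' call `set.seed()` (or use [run_schedule()]) for reproducibility.
#'
#' @param lat An [mmc_lattice()].
#' @param table An [adhesion_table()].
#' @param n_mcs Number of Monte Carlo steps.
#' @param allow_gel_swap Passed to [mobility_policy()].
#' @return List with the updated `lattice` and the `attempted` / `accepted`
#'   swap counters.
#' @export
run_mcs <- function(lat, table, n_mcs, allow_gel_swap = TRUE) {
  stopifnot(inherits(lat, "mmc_lattice"))
  check_table_covers(lat, table)
  n_mcs <- as.integer(n_mcs)
  stopifnot(length(n_mcs) == 1L, n_mcs >= 0L)
  pol <- mobility_policy(lat, allow_gel_swap)
  if (!any(pol$mobile[lat$sites + 1L])) stop("no mobile sites: nothing to move")
  if (n_mcs == 0L)
    return(list(lattice = lat, attempted = 0, accepted = 0))
  res <- cpp_run_mcs(as.vector(lat$sites), dim(lat$sites), gamma_matrix(table),
                     table$E_T, pol$mobile, pol$swap_ok, n_mcs)
  out <- lat
  out$sites <- array(res$sites, dim(lat$sites))
  list(lattice = out, attempted = res$attempted, accepted = res$accepted)
}
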