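#' Works-of-adhesion table
#'
#' The energetics of a configuration are set by the symmetric matrix of works
#' of adhesion \eqn{\epsilon_{\sigma\sigma'}}: the energy needed to break the
#' bond between two neighboring particles of types \eqn{\sigma} and
#' \eqn{\sigma'}. All values are dimensionless, in units of the fluctuation
#' energy scale \eqn{E_T}.
#'
#' @param eps Square, symmetric, non-negative, finite numeric matrix; row/
#'   column `i` corresponds to \eqn{\sigma = i - 1}.
#' @param E_T Fluctuation energy scale (> 0). Defaults to 1; all `eps` entries
#'   are interpreted in these units.
#' @param type_names Optional character vector of type names used for dimnames.
#' @return An object of class `adhesion_table`.
#' @export
adhesion_table <- function(eps, E_T = 1, type_names = NULL) {
  eps <- as.matrix(eps)
  if (nrow(eps) != ncol(eps)) stop("eps must be square")
  if (!all(is.finite(eps))) stop("all works of adhesion must be finite")
  if (any(eps < 0)) stop("works of adhesion must be non-negative")
  if (!isTRUE(all.equal(eps, t(eps)))) stop("eps must be symmetric")
  if (!is.numeric(E_T) || length(E_T) != 1L || E_T <= 0) stop("E_T must be a positive scalar")
  if (!is.null(type_names)) {
    stopifnot(length(type_names) == nrow(eps))
    dimnames(eps) <- list(type_names, type_names)
  }
  structure(list(eps = eps, E_T = E_T, n_types = nrow(eps)), class = "adhesion_table")
}

#' @export
print.adhesion_table <- function(x, ...) {
  cat(sprintf("adhesion_table: %d types, E_T = %g\n", x$n_types, x$E_T))
  print(x$eps)
  invisible(x)
}

#' Interfacial tension between two particle types
#'
#' \eqn{\gamma_{\sigma\sigma'} = 0.5(\epsilon_{\sigma\sigma} +
#' \epsilon_{\sigma'\sigma'}) - \epsilon_{\sigma\sigma'}}. Positive tension
#' drives demixing and compaction of the two phases; zero tension makes their
#' interface energetically neutral.
#'
#' @param table An [adhesion_table()].
#' @param a,b Type indices \eqn{\sigma} (0-based).
#' @return Energy scalar; 0 whenever `a == b`.
#' @export
interfacial_tension <- function(table, a, b) {
  stopifnot(inherits(table, "adhesion_table"))
  a <- as.integer(a); b <- as.integer(b)
  if (any(c(a, b) < 0L) || any(c(a, b) >= table$n_types))
    stop("type index out of range")
  e <- table$eps
  0.5 * (e[a + 1L, a + 1L] + e[b + 1L, b + 1L]) - e[a + 1L, b + 1L]
}

#' Full interfacial-tension matrix of a table
#' @param table An [adhesion_table()].
#' @return Symmetric matrix of \eqn{\gamma_{\sigma\sigma'}} with zero diagonal.
#' @export
gamma_matrix <- function(table) {
  stopifnot(inherits(table, "adhesion_table"))
  e <- table$eps
  d <- diag(e)
  0.5 * outer(d, d, "+") - e
}

check_table_covers <- function(lat, table) {
  mx <- max(lat$types$sigma)
  if (table$n_types <= mx)
    stop(sprintf("adhesion table has %d types but the lattice registers sigma up to %d",
                 table$n_types, mx))
}

#' Neighbor-pair (bond) counts per type pair
#'
#' Counts every unordered pair of 26-neighborhood neighbors once, classified
#' by the two types involved. Sites outside the finite box contribute no
#' bonds.
#'
#' @param lat An [mmc_lattice()].
#' @param n_types Number of types to tabulate; defaults to the lattice
#'   registry size.
#' @return Symmetric matrix `N` where `N[a + 1, b + 1]` is the number of
#'   \eqn{\sigma = a} / \eqn{\sigma = b} neighbor pairs.
#' @export
bond_counts <- function(lat, n_types = NULL) {
  stopifnot(inherits(lat, "mmc_lattice"))
  if (is.null(n_types)) n_types <- nrow(lat$types)
  N <- cpp_bond_counts(as.vector(lat$sites), dim(lat$sites), as.integer(n_types))
  dimnames(N) <- list(seq_len(n_types) - 1L, seq_len(n_types) - 1L)
  N
}

#' Interfacial adhesion energy of a configuration
#'
#' \eqn{E = \sum_{\sigma < \sigma'} \gamma_{\sigma\sigma'} N_{\sigma\sigma'}}:
#' the interfacial part of the total energy of adhesion (the configuration-
#' independent constant term is dropped). Same-type bonds contribute nothing
#' because \eqn{\gamma_{\sigma\sigma} = 0}.
#'
#' @param lat An [mmc_lattice()].
#' @param table An [adhesion_table()] covering every type on the lattice.
#' @return Energy scalar in units of \eqn{E_T}.
#' @export
total_energy <- function(lat, table) {
  stopifnot(inherits(lat, "mmc_lattice"))
  check_table_covers(lat, table)
  cpp_total_energy(as.vector(lat$sites), dim(lat$sites), gamma_matrix(table))
}
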