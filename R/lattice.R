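#' Register the particle types of a simulation
#'
#' Each lattice site holds a particle-type index \eqn{\sigma}. By convention
#' \eqn{\sigma = 0} is cell culture medium; a hydrogel phase (if present) and
#' the cell types take the following indices, in the order given here.
#'
#' @param names Character vector of type names. The first entry is the medium.
#' @param kinds Character vector, same length, each one of `"medium"`,
#'   `"hydrogel"`, `"cell"`. Only `"cell"` sites are mobile in the dynamics.
#' @return A data frame with columns `sigma`, `name`, `kind`.
#' @examples
#' type_registry(c("medium", "wall", "sacrificial"), c("medium", "cell", "cell"))
#' @export
type_registry <- function(names, kinds) {
  stopifnot(is.character(names), is.character(kinds), length(names) == length(kinds))
  if (anyDuplicated(names)) stop("type names must be unique")
  kinds <- match.arg(kinds, c("medium", "hydrogel", "cell"), several.ok = TRUE)
  if (kinds[1] != "medium") stop("the first registered type (sigma = 0) must be the medium")
  if (sum(kinds == "medium") != 1) stop("exactly one medium type is required")
  data.frame(sigma = seq_along(names) - 1L, name = names, kind = kinds,
             stringsAsFactors = FALSE)
}

#' Construct a lattice state
#'
#' Wraps a dense 3-D array of particle-type indices together with the type
#' registry and the physical size of one lattice site.
#'
#' @param sites Integer 3-D array of type indices \eqn{\sigma}.
#' @param types Type registry from [type_registry()]. If missing, a generic
#'   registry (medium plus anonymous cell types) is derived from the values
#'   present.
#' @param lattice_unit Physical edge length of one site in micrometers.
#'   Defaults to 10, one cell diameter.
#' @return An object of class `mmc_lattice` with elements `sites`, `types`,
#'   `lattice_unit`.
#' @export
mmc_lattice <- function(sites, types = NULL, lattice_unit = 10) {
  if (length(dim(sites)) != 3L) stop("sites must be a 3-D array")
  if (any(dim(sites) < 1L)) stop("all lattice dimensions must be positive")
  storage.mode(sites) <- "integer"
  if (anyNA(sites)) stop("sites must not contain NA")
  mx <- max(sites)
  if (min(sites) < 0L) stop("type indices must be non-negative")
  if (is.null(types)) {
    nm <- c("medium", if (mx >= 1L) paste0("cell", seq_len(mx)))
    types <- type_registry(nm, c("medium", rep("cell", mx)))
  }
  if (mx > max(types$sigma)) stop("lattice contains a type index outside the registry")
  structure(list(sites = sites, types = types, lattice_unit = lattice_unit),
            class = "mmc_lattice")
}

#' @export
print.mmc_lattice <- function(x, ...) {
  d <- dim(x$sites)
  cat(sprintf("mmc_lattice %d x %d x %d (%s sites, %g um/site)\n",
              d[1], d[2], d[3], format(prod(d), big.mark = ","), x$lattice_unit))
  cts <- site_counts(x)
  for (i in seq_len(nrow(x$types)))
    cat(sprintf("  sigma=%d %-14s %-8s %s\n", x$types$sigma[i], x$types$name[i],
                x$types$kind[i], format(cts[i], big.mark = ",")))
  invisible(x)
}

#' @export
dim.mmc_lattice <- function(x) dim(x$sites)

#' Per-type site census
#'
#' @param lat An [mmc_lattice()].
#' @return Named integer vector of site counts, one entry per registered type
#'   (zeros included).
#' @export
site_counts <- function(lat) {
  stopifnot(inherits(lat, "mmc_lattice"))
  n <- tabulate(as.vector(lat$sites) + 1L, nbins = nrow(lat$types))
  names(n) <- lat$types$name
  n
}

#' Resolve a type name or index to its sigma value
#' @param lat An [mmc_lattice()].
#' @param type Type name (character) or sigma index (numeric).
#' @return Integer sigma index.
#' @export
sigma_of <- function(lat, type) {
  stopifnot(inherits(lat, "mmc_lattice"))
  if (is.character(type)) {
    i <- match(type, lat$types$name)
    if (anyNA(i)) stop("unknown type name: ", paste(type[is.na(i)], collapse = ", "))
    return(lat$types$sigma[i])
  }
  type <- as.integer(type)
  if (any(!type %in% lat$types$sigma)) stop("unknown type index")
  type
}

#' The 26-site interaction neighborhood
#'
#' Every lattice site interacts with 6 nearest (axis), 12 next-nearest
#' (face-diagonal) and 8 second-nearest (cube-diagonal) neighbors; the same
#' neighborhood is used for energy evaluation, swap moves and (by default)
#' connectivity analysis.
#'
#' @return Integer matrix of 26 displacement rows with a `shell` attribute
#'   (1 = axis, 2 = face diagonal, 3 = cube diagonal).
#' @export
neighbor_offsets <- function() {
  off <- cpp_offsets()
  colnames(off) <- c("dx", "dy", "dz")
  attr(off, "shell") <- rep(1:3, times = c(6L, 12L, 8L))
  off
}
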