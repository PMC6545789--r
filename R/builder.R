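#' Digital sphere of a multicellular spheroid
#'
#' Digitizes a spheroid of the given diameter (in lattice units, i.e. cell
#' diameters) as the integer lattice points inside the closed Euclidean ball
#' of radius `diameter / 2` about a lattice site, excluding surface points
#' lying exactly on the coordinate axes. This calibration makes a diameter-10
#' spheroid hold exactly 509 cells (the 515-point closed ball minus its six
#' axial surface points).
#'
#' @param diameter Spheroid diameter in lattice units (>= 2).
#' @return Integer matrix (n x 3) of site offsets centered on the origin.
#' @export
make_spheroid <- function(diameter) {
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter < 2)
    stop("diameter must be a single number >= 2")
  r <- floor(diameter / 2)
  r2 <- (diameter / 2)^2
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  n2 <- rowSums(g^2)
  axial_surface <- n2 == r2 & rowSums(g != 0) == 1L
  m <- g[n2 <= r2 & !axial_surface, , drop = FALSE]
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

#' Exact-count apportionment by the largest-remainder method
#'
#' Splits `n` items over groups proportionally to `fractions`, rounding so
#' that the counts sum exactly to `n`: each group gets the floor of its quota
#' and the leftover items go to the largest fractional remainders (ties to
#' the earlier group).
#'
#' @param n Total count.
#' @param fractions Non-negative weights summing to 1.
#' @return Integer vector of group counts summing to `n`.
#' @export
largest_remainder <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  quota <- n * fractions
  base <- floor(quota)
  left <- round(n - sum(base))
  if (left > 0) {
    ord <- order(quota - base, seq_along(fractions), decreasing = c(TRUE, FALSE),
                 method = "radix")
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Heterotypic spheroid with randomly intermixed cell types
#'
#' Same geometric support as [make_spheroid()]; site labels are assigned by
#' an exact-count random permutation: group sizes come from
#' [largest_remainder()] and positions from a single `sample()` draw, so the
#' composition is exact and reproducible under `set.seed()`.
#'
#' @param diameter Spheroid diameter in lattice units.
#' @param fractions Type fractions summing to 1 (e.g. `c(0.9, 0.1)` for a
#'   90/10 smooth-muscle/endothelial mix).
#' @return List with `coords` (as [make_spheroid()]) and `group`, an integer
#'   vector assigning each site to a fraction index (1-based).
#' @export
make_heterotypic_spheroid <- function(diameter, fractions) {
  coords <- make_spheroid(diameter)
  n <- nrow(coords)
  if (length(fractions) > n) stop("more types than spheroid sites")
  counts <- largest_remainder(n, fractions)
  group <- sample(rep.int(seq_along(fractions), counts))
  list(coords = coords, group = group)
}

# ---- spheroid placement utilities -------------------------------------------

coord_key <- function(m) (m[, 1] + 512) * 2^20 + (m[, 2] + 512) * 2^10 + (m[, 3] + 512)

spheres_disjoint <- function(coords_a, coords_b, off) {
  b <- sweep(coords_b, 2, as.integer(round(off)), "+")
  !any(coord_key(coords_a) %in% coord_key(b))
}

# Smallest integer center offset along `dir` at which two digital spheres are
# disjoint (optionally also disjoint from previously placed neighbors given
# as a list of (coords, offset) pairs). Deterministic: candidates are scanned
# by increasing distance from the contact distance (dA + dB) / 2.
find_touching_offset <- function(dA, dB, dir, placed = list()) {
  A <- make_spheroid(dA)
  B <- make_spheroid(dB)
  dir <- dir / sqrt(sum(dir^2))
  target <- (dA + dB) / 2
  svals <- seq(max(1, target - 3), target + 6, by = 0.25)
  cand <- unique(t(vapply(svals, function(s) as.integer(round(s * dir)), integer(3))))
  ord <- order(sqrt(rowSums(cand^2)))
  for (i in ord) {
    off <- cand[i, ]
    if (!spheres_disjoint(A, B, off)) next
    ok <- TRUE
    for (p in placed) {
      if (!spheres_disjoint(p$coords, B, off - p$off)) { ok <- FALSE; break }
    }
    if (ok) return(off)
  }
  stop("no disjoint placement found along the requested direction")
}

# Center spacing along a lattice axis at which two equal spheroids touch
# without sharing sites (d - 1 for even diameters, d for odd ones).
chain_spacing <- function(diameter) {
  find_touching_offset(diameter, diameter, c(1, 0, 0))[1]
}

# Transverse (y, z) offsets of a ring of wall spheroids around an axial core
# spheroid. Wall centers sit at the given angles, at the smallest lattice
# offsets disjoint from the core and from one another.
ring_offsets <- function(d_wall, d_core, angles_deg) {
  placed <- list()
  wall <- make_spheroid(d_wall)
  out <- matrix(0L, length(angles_deg), 2)
  for (i in seq_along(angles_deg)) {
    th <- angles_deg[i] * pi / 180
    off3 <- find_touching_offset(d_core, d_wall, c(0, cos(th), sin(th)), placed = placed)
    placed[[length(placed) + 1L]] <- list(coords = wall, off = off3)
    out[i, ] <- off3[2:3]
  }
  out
}

# Stamp a spheroid into the site array, refusing to overwrite anything other
# than the allowed background types.
stamp <- function(sites, coords, center, sigma_values, background = 0L) {
  d <- dim(sites)
  abs_xyz <- sweep(coords, 2, as.integer(round(center)), "+")
  if (any(abs_xyz < 1L) || any(abs_xyz[, 1] > d[1]) || any(abs_xyz[, 2] > d[2]) ||
      any(abs_xyz[, 3] > d[3]))
    stop("spheroid extends outside the lattice bounds")
  idx <- abs_xyz[, 1] + d[1] * (abs_xyz[, 2] - 1L) + d[1] * d[2] * (abs_xyz[, 3] - 1L)
  if (any(!sites[idx] %in% background))
    stop("spheroid placement collides with previously placed sites")
  sites[idx] <- sigma_values
  sites
}

#' Per-voxel seeding probability of dispersed cells
#'
#' Converts a volumetric seeding density into the probability that one
#' hydrogel voxel holds a cell: `density * (lattice_unit in cm)^3`. At
#' 10^6 cells/mL and a 10 um lattice unit this is 10^-3.
#'
#' @param density_per_ml Cells per milliliter.
#' @param lattice_unit_um Lattice unit in micrometers.
#' @return Probability per voxel.
#' @export
seeding_probability <- function(density_per_ml, lattice_unit_um) {
  p <- density_per_ml * (lattice_unit_um * 1e-4)^3
  if (p > 1) stop("seeding density exceeds one cell per voxel")
  p
}

# ---- construct specifications -----------------------------------------------

#' Geometric recipe for an initial bioprinted construct
#'
#' Captures the printed geometry of one of the three study scenarios:
#' `"single_type_tube"` (wall spheroids of one cell type wrapping a
#' contiguous axial chain of sacrificial spheroids), `"two_type_tube"` (the
#' same geometry with heterotypic 10% endothelial / 90% smooth-muscle wall
#' spheroids) and `"branched_hydrogel"` (an endothelial-cell-laden hydrogel
#' slab holding a branched chain of large and small sacrificial spheroids).
#'
#' @param scenario One of the three scenario names.
#' @param ... Overrides of the scenario defaults, among:
#' \describe{
#'   \item{spheroid_diameter}{Wall and core spheroid diameter for the tubes
#'     (default 10 lattice units).}
#'   \item{chain_length}{Sacrificial spheroids along the axis (tubes: 5;
#'     branched main chain: 6).}
#'   \item{ring_count}{Wall spheroids per cross-sectional ring (default 6;
#'     consecutive rings are staggered by half the angular pitch).}
#'   \item{composition}{Wall-spheroid type fractions for the two-type tube,
#'     ordered as (smooth muscle, endothelial); default `c(0.9, 0.1)`.}
#'   \item{large_diameter, small_diameter}{Main-chain and side-branch
#'     sacrificial spheroid diameters for the branched scenario (30 and 16).}
#'   \item{branch_layout}{List of branches, each
#'     `list(attach =, direction =, diameter =, count =)`: chain index the
#'     branch starts from, its axis (a unit 3-vector perpendicular to the
#'     main chain), spheroid diameter and spheroid count.}
#'   \item{hydrogel_dims}{Slab size in lattice units (default
#'     `c(210, 145, 124)`, i.e. 2.1 mm x 1.45 mm x 1.24 mm at 10 um/site).}
#'   \item{seeding_density}{Endothelial cells per mL of hydrogel (10^6).}
#'   \item{lattice_unit}{Micrometers per site (10).}
#'   \item{padding}{Medium margin around the construct (tubes: 3; the
#'     branched slab fills its lattice, padding 0).}
#'   \item{seed}{Optional RNG seed consumed by [build_construct()].}
#' }
#' @return An object of class `construct_spec`.
#' @export
construct_spec <- function(scenario = c("single_type_tube", "two_type_tube",
                                        "branched_hydrogel"), ...) {
  scenario <- match.arg(scenario)
  spec <- switch(scenario,
    single_type_tube = list(spheroid_diameter = 10, chain_length = 5, ring_count = 6,
                            padding = 3, lattice_unit = 10, seed = NULL),
    two_type_tube = list(spheroid_diameter = 10, chain_length = 5, ring_count = 6,
                         composition = c(smooth_muscle = 0.9, endothelial = 0.1),
                         padding = 3, lattice_unit = 10, seed = NULL),
    branched_hydrogel = list(large_diameter = 30, small_diameter = 16, chain_length = 6,
                             branch_layout = NULL, hydrogel_dims = c(210, 145, 124),
                             seeding_density = 1e6, padding = 0, lattice_unit = 10,
                             seed = NULL))
  spec$scenario <- scenario
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(spec)))
  if (length(unknown)) stop("unknown spec fields: ", paste(unknown, collapse = ", "))
  spec[names(dots)] <- dots
  if (scenario == "branched_hydrogel" && is.null(spec$branch_layout)) {
    n <- spec$chain_length
    at1 <- min(2, n); at2 <- max(n - 1, 1)
    spec$branch_layout <- list(
      list(attach = at1, direction = c(0, 1, 0), diameter = spec$small_diameter, count = 3),
      list(attach = at2, direction = c(0, -1, 0), diameter = spec$small_diameter, count = 3))
  }
  validate_spec(spec)
  structure(spec, class = "construct_spec")
}

validate_spec <- function(spec) {
  dia <- c(spec$spheroid_diameter, spec$large_diameter, spec$small_diameter)
  if (any(dia < 2)) stop("spheroid diameters must be >= 2")
  if (!is.null(spec$composition)) {
    if (abs(sum(spec$composition) - 1) > 1e-8) stop("composition fractions must sum to 1")
    if (any(spec$composition < 0)) stop("composition fractions must be non-negative")
  }
  if (!is.null(spec$seeding_density) && spec$seeding_density < 0)
    stop("seeding_density must be >= 0")
  if (spec$padding < 0) stop("padding must be >= 0")
  if (spec$scenario != "branched_hydrogel" && spec$padding < 2)
    stop("tube constructs need a medium padding of at least 2 layers")
  if (spec$chain_length < 1) stop("chain_length must be >= 1")
  invisible(spec)
}

#' Build the initial lattice of a construct
#'
#' Dispatches on the scenario of a [construct_spec()] and returns the printed
#' (pre-rearrangement) configuration. If the spec carries a `seed` it is
#' applied first; label permutations (heterotypic spheroids) and hydrogel
#' seeding are the only stochastic elements.
#'
#' @param spec A [construct_spec()].
#' @return An [mmc_lattice()] with a `manifest` attribute: a data frame with
#'   one row per placed spheroid (role, center, diameter, site count).
#' @export
build_construct <- function(spec) {
  stopifnot(inherits(spec, "construct_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  switch(spec$scenario,
         single_type_tube = make_single_type_tube(spec),
         two_type_tube = make_two_type_tube(spec),
         branched_hydrogel = make_branched_construct(spec))
}

# Shared geometry of the tubular constructs: chain centers along x and wall
# ring offsets in the (y, z) plane, staggered between consecutive rings.
tube_geometry <- function(spec) {
  d <- spec$spheroid_diameter
  sp <- chain_spacing(d)
  n <- spec$chain_length
  angles0 <- seq(0, 360 - 360 / spec$ring_count, by = 360 / spec$ring_count)
  ring0 <- ring_offsets(d, d, angles0)
  ring1 <- ring_offsets(d, d, angles0 + 180 / spec$ring_count)
  chain_x <- (seq_len(n) - 1L) * sp
  list(d = d, sp = sp, chain_x = chain_x, rings = list(ring0, ring1))
}

assemble_tube <- function(spec, wall_sigma_fun, core_sigma, types) {
  geo <- tube_geometry(spec)
  d <- geo$d
  sph <- make_spheroid(d)
  r <- max(abs(sph))
  ring_r <- max(abs(unlist(geo$rings))) + r
  pad <- spec$padding
  dims <- c(max(geo$chain_x) + 2L * r + 1L + 2L * pad,
            2L * ring_r + 1L + 2L * pad,
            2L * ring_r + 1L + 2L * pad)
  origin <- c(r + pad + 1L, ring_r + pad + 1L, ring_r + pad + 1L)
  sites <- array(0L, dims)
  manifest <- NULL
  for (i in seq_along(geo$chain_x)) {
    ctr <- c(origin[1] + geo$chain_x[i], origin[2], origin[3])
    sites <- stamp(sites, sph, ctr, core_sigma)
    manifest <- rbind(manifest, data.frame(role = "sacrificial", diameter = d,
                                           x = ctr[1], y = ctr[2], z = ctr[3],
                                           sites = nrow(sph)))
    ring <- geo$rings[[(i - 1L) %% 2L + 1L]]
    for (j in seq_len(nrow(ring))) {
      wctr <- c(ctr[1], origin[2] + ring[j, 1], origin[3] + ring[j, 2])
      lab <- wall_sigma_fun(nrow(sph))
      sites <- stamp(sites, sph, wctr, lab)
      manifest <- rbind(manifest, data.frame(role = "wall", diameter = d,
                                             x = wctr[1], y = wctr[2], z = wctr[3],
                                             sites = nrow(sph)))
    }
  }
  lat <- mmc_lattice(sites, types = types, lattice_unit = spec$lattice_unit)
  attr(lat, "manifest") <- manifest
  lat
}

#' Single-cell-type tube with a sacrificial core
#'
#' Wall spheroids of one cell type (sigma = 1) arranged in staggered rings
#' around a contiguous axial chain of sacrificial spheroids (sigma = 2); the
#' whole construct is padded with medium. Under the matched-adhesion
#' parameter set the two populations have identical adhesivities and only
#' their medium interface is energetically active.
#'
#' @param spec A [construct_spec()] with scenario `"single_type_tube"`.
#' @return An [mmc_lattice()]; see [build_construct()].
#' @export
make_single_type_tube <- function(spec) {
  stopifnot(spec$scenario == "single_type_tube")
  types <- type_registry(c("medium", "wall", "sacrificial"),
                         c("medium", "cell", "cell"))
  assemble_tube(spec, wall_sigma_fun = function(n) rep(1L, n),
                core_sigma = 2L, types = types)
}

#' Two-cell-type tube with heterotypic wall spheroids
#'
#' Same geometry as [make_single_type_tube()], but each wall spheroid is an
#' exact-count random mix of smooth muscle cells (sigma = 1) and endothelial
#' cells (sigma = 2); the sacrificial core spheroids are homotypic
#' (sigma = 3).
#'
#' @param spec A [construct_spec()] with scenario `"two_type_tube"`.
#' @return An [mmc_lattice()]; see [build_construct()].
#' @export
make_two_type_tube <- function(spec) {
  stopifnot(spec$scenario == "two_type_tube")
  types <- type_registry(c("medium", "smooth_muscle", "endothelial", "sacrificial"),
                         c("medium", "cell", "cell", "cell"))
  frac <- spec$composition
  wall_fun <- function(n) {
    counts <- largest_remainder(n, frac)
    sample(rep.int(c(1L, 2L), counts))
  }
  assemble_tube(spec, wall_sigma_fun = wall_fun, core_sigma = 3L, types = types)
}

#' Branched sacrificial chain in a cell-laden hydrogel slab
#'
#' A hydrogel slab (sigma = 1) holds a main axial chain of large sacrificial
#' spheroids (sigma = 3) with perpendicular side branches of small
#' sacrificial spheroids whose first member touches the main chain. Hydrogel
#' voxels are then converted to endothelial cells (sigma = 2) by independent
#' per-voxel sampling at the probability implied by the seeding density
#' ([seeding_probability()]).
#'
#' @param spec A [construct_spec()] with scenario `"branched_hydrogel"`.
#' @return An [mmc_lattice()]; see [build_construct()].
#' @export
make_branched_construct <- function(spec) {
  stopifnot(spec$scenario == "branched_hydrogel")
  types <- type_registry(c("medium", "hydrogel", "endothelial", "sacrificial"),
                         c("medium", "hydrogel", "cell", "cell"))
  pad <- spec$padding
  hd <- as.integer(spec$hydrogel_dims)
  dims <- hd + 2L * pad
  sites <- array(0L, dims)
  slab <- c(pad + 1L, pad + 1L, pad + 1L)
  sites[slab[1]:(slab[1] + hd[1] - 1L), slab[2]:(slab[2] + hd[2] - 1L),
        slab[3]:(slab[3] + hd[3] - 1L)] <- 1L

  dL <- spec$large_diameter
  spL <- chain_spacing(dL)
  sphL <- make_spheroid(dL)
  rL <- max(abs(sphL))
  n <- spec$chain_length
  span <- (n - 1L) * spL
  x0 <- slab[1] + floor((hd[1] - 1L - span) / 2)
  ctr_y <- slab[2] + floor((hd[2] - 1L) / 2)
  ctr_z <- slab[3] + floor((hd[3] - 1L) / 2)
  if (x0 - rL < slab[1] || x0 + span + rL > slab[1] + hd[1] - 1L)
    stop("main chain does not fit inside the hydrogel slab")

  manifest <- NULL
  chain_ctr <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    ctr <- c(x0 + (i - 1L) * spL, ctr_y, ctr_z)
    chain_ctr[i, ] <- ctr
    sites <- stamp(sites, sphL, ctr, 3L, background = 1L)
    manifest <- rbind(manifest, data.frame(role = "main_chain", diameter = dL,
                                           x = ctr[1], y = ctr[2], z = ctr[3],
                                           sites = nrow(sphL)))
  }
  for (br in spec$branch_layout) {
    dS <- br$diameter
    sphS <- make_spheroid(dS)
    spS <- chain_spacing(dS)
    dirv <- br$direction / sqrt(sum(br$direction^2))
    if (br$attach < 1 || br$attach > n) stop("branch attach index outside the main chain")
    base <- chain_ctr[br$attach, ]
    off0 <- find_touching_offset(dL, dS, dirv)
    for (k in seq_len(br$count)) {
      ctr <- base + off0 + as.integer(round((k - 1L) * spS * dirv))
      inside <- all(ctr - max(abs(sphS)) >= slab) &&
        all(ctr + max(abs(sphS)) <= slab + hd - 1L)
      if (!inside) stop("branch extends outside the hydrogel slab")
      sites <- stamp(sites, sphS, ctr, 3L, background = 1L)
      manifest <- rbind(manifest, data.frame(role = "branch", diameter = dS,
                                             x = ctr[1], y = ctr[2], z = ctr[3],
                                             sites = nrow(sphS)))
    }
  }

  p <- seeding_probability(spec$seeding_density, spec$lattice_unit)
  gel <- which(sites == 1L)
  if (p > 0 && length(gel)) {
    seeded <- gel[runif(length(gel)) < p]
    sites[seeded] <- 2L
  }
  lat <- mmc_lattice(sites, types = types, lattice_unit = spec$lattice_unit)
  attr(lat, "manifest") <- manifest
  lat
}
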