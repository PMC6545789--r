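test_that("the calibrated digitization reproduces the 509-cell spheroid", {
  sph <- make_spheroid(10)
  expect_equal(nrow(sph), 509L)
  # centrosymmetric and invariant under all 48 cube symmetries
  key <- function(m) sort(m[, 1] * 1e6 + m[, 2] * 1e3 + m[, 3])
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  for (p in perms) for (i in seq_len(nrow(signs))) {
    tr <- sweep(sph[, p, drop = FALSE], 2, signs[i, ], "*")
    expect_equal(key(tr), key(sph))
  }
  # connected under 26-connectivity
  d <- c(13, 13, 13)
  arr <- array(0L, d)
  idx <- sweep(sph, 2, c(7L, 7L, 7L), "+")
  arr[idx[, 1] + d[1] * (idx[, 2] - 1L) + d[1] * d[2] * (idx[, 3] - 1L)] <- 1L
  expect_equal(oracle_components(arr, 1L)$n_components, 1L)
  expect_error(make_spheroid(1), ">= 2")
})

test_that("heterotypic spheroids get exact-count random labels on a fixed support", {
  set.seed(1)
  het <- make_heterotypic_spheroid(10, c(0.10, 0.90))
  expect_equal(sum(het$group == 1L), 51L) # endothelial share of 509
  expect_equal(sum(het$group == 2L), 458L)
  expect_equal(het$coords, make_spheroid(10))
  set.seed(2)
  het2 <- make_heterotypic_spheroid(10, c(0.10, 0.90))
  expect_equal(het2$coords, het$coords)
  expect_false(identical(het2$group, het$group))
  # degenerate single-type composition
  homo <- make_heterotypic_spheroid(4, 1)
  expect_true(all(homo$group == 1L))
  expect_error(make_heterotypic_spheroid(2, rep(0.5, 2)), "more types")
})

test_that("largest-remainder apportionment is exact and reproducible", {
  expect_equal(largest_remainder(509, c(0.10, 0.90)), c(51L, 458L))
  expect_error(largest_remainder(10, c(0.5, 0.4)), "sum to 1")
  set.seed(4)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    f <- runif(k)
    f <- f / sum(f)
    n <- sample(0:500, 1)
    cts <- largest_remainder(n, f)
    expect_equal(sum(cts), n)
    expect_true(all(abs(cts - n * f) < 1))
  }
})

test_that("the single-type tube is made of touching, non-overlapping spheroids", {
  spec <- construct_spec("single_type_tube", spheroid_diameter = 5, chain_length = 3)
  lat <- build_construct(spec)
  man <- attr(lat, "manifest")
  n_sph <- nrow(man)
  expect_equal(n_sph, 3L * (1L + spec$ring_count))
  # census equals spheroid count x per-spheroid size: no overlaps anywhere
  cts <- site_counts(lat)
  expect_equal(unname(cts["wall"] + cts["sacrificial"]), sum(man$sites))
  expect_equal(unname(cts["sacrificial"]), sum(man$sites[man$role == "sacrificial"]))
  # the sacrificial chain is one 26-connected component
  expect_equal(phase_components(lat, "sacrificial")$n_components, 1L)
  # outermost layers are pure medium (boundary never energetically visible)
  d <- dim(lat$sites)
  for (p in 1:2) {
    shell <- c(lat$sites[c(p, d[1] - p + 1L), , ], lat$sites[, c(p, d[2] - p + 1L), ],
               lat$sites[, , c(p, d[3] - p + 1L)])
    expect_true(all(shell == 0L))
  }
})

test_that("every wall spheroid of a minimal ring touches the sacrificial core", {
  lat <- build_construct(construct_spec("single_type_tube", chain_length = 1))
  man <- attr(lat, "manifest")
  expect_equal(nrow(man), 7L)
  sph <- make_spheroid(10)
  key <- function(m) (m[, 1] + 512) * 2^20 + (m[, 2] + 512) * 2^10 + (m[, 3] + 512)
  core <- sweep(sph, 2, as.integer(unlist(man[man$role == "sacrificial", c("x", "y", "z")])), "+")
  core_keys <- key(core)
  dil <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in which(man$role == "wall")) {
    wall <- sweep(sph, 2, as.integer(unlist(man[i, c("x", "y", "z")])), "+")
    touches <- FALSE
    for (k in seq_len(nrow(dil))) {
      if (any(key(sweep(wall, 2, dil[k, ], "+")) %in% core_keys)) { touches <- TRUE; break }
    }
    expect_true(touches)
  }
})

test_that("the two-type tube carries the exact 10/90 endothelial composition", {
  spec <- construct_spec("two_type_tube", chain_length = 1)
  set.seed(6)
  lat <- build_construct(spec)
  cts <- site_counts(lat)
  expect_equal(unname(cts["endothelial"]), 6L * 51L)
  expect_equal(unname(cts["smooth_muscle"]), 6L * 458L)
  expect_equal(unname(cts["sacrificial"]), 509L)
  # fully reproducible from the spec seed
  l1 <- build_construct(construct_spec("two_type_tube", chain_length = 1, seed = 9))
  l2 <- build_construct(construct_spec("two_type_tube", chain_length = 1, seed = 9))
  expect_identical(l1$sites, l2$sites)
  # degenerate composition reduces to a single-type wall
  l3 <- build_construct(construct_spec("two_type_tube", chain_length = 1,
                                       composition = c(1, 0), seed = 1))
  expect_equal(unname(site_counts(l3)["endothelial"]), 0L)
})

test_that("the branched construct fills its slab and seeds the gel binomially", {
  spec <- construct_spec("branched_hydrogel", large_diameter = 15, small_diameter = 8,
                         chain_length = 3, hydrogel_dims = c(70, 55, 46),
                         branch_layout = list(
                           list(attach = 2, direction = c(0, 1, 0), diameter = 8, count = 2),
                           list(attach = 2, direction = c(0, -1, 0), diameter = 8, count = 2)),
                         seed = 5)
  lat <- build_construct(spec)
  cts <- site_counts(lat)
  expect_equal(sum(cts), prod(c(70, 55, 46)))
  expect_equal(unname(cts["medium"]), 0L) # the slab fills the lattice
  man <- attr(lat, "manifest")
  expect_equal(unname(cts["sacrificial"]), sum(man$sites))
  expect_equal(phase_components(lat, "sacrificial")$n_components, 1L)
  # per-voxel seeding probability: 10^6 cells/mL at 10 um/site is 1e-3
  expect_equal(seeding_probability(1e6, 10), 1e-3)
  n_gel_before <- sum(cts[c("hydrogel", "endothelial")])
  expect_lt(abs(cts["endothelial"] - 1e-3 * n_gel_before),
            4 * sqrt(n_gel_before * 1e-3 * (1 - 1e-3)))
  # zero density seeds nothing
  l0 <- build_construct(construct_spec("branched_hydrogel", large_diameter = 15,
                                       small_diameter = 8, chain_length = 3,
                                       hydrogel_dims = c(70, 55, 46),
                                       branch_layout = list(),
                                       seeding_density = 0, seed = 1))
  expect_equal(unname(site_counts(l0)["endothelial"]), 0L)
  # branches must stay inside the slab
  expect_error(build_construct(
    construct_spec("branched_hydrogel", large_diameter = 15, small_diameter = 8,
                   chain_length = 3, hydrogel_dims = c(70, 55, 46),
                   branch_layout = list(list(attach = 2, direction = c(0, 1, 0),
                                             diameter = 8, count = 10)),
                   seed = 1)), "outside the hydrogel slab")
})

test_that("construct specs validate their geometric parameters", {
  expect_error(construct_spec("single_type_tube", spheroid_diameter = 1), ">= 2")
  expect_error(construct_spec("single_type_tube", padding = 1), "at least 2")
  expect_error(construct_spec("two_type_tube", composition = c(0.5, 0.4)), "sum to 1")
  expect_error(construct_spec("single_type_tube", wings = 3), "unknown spec fields")
  expect_error(construct_spec("branched_hydrogel", seeding_density = -1), ">= 0")
  expect_error(construct_spec("single_type_tube", chain_length = 0), ">= 1")
})
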