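make_two_spheroid_lattice <- function(gap) {
  sph <- make_spheroid(5)
  d <- c(20 + gap, 9, 9)
  arr <- array(0L, d)
  for (cx in c(4L, 4L + 5L + gap)) {
    idx <- sweep(sph, 2, c(cx, 5L, 5L), "+")
    arr[idx[, 1] + d[1] * (idx[, 2] - 1L) + d[1] * d[2] * (idx[, 3] - 1L)] <- 1L
  }
  as_cell_lattice(arr, 2)
}

test_that("phase component labeling agrees with a flood-fill oracle", {
  touching <- make_two_spheroid_lattice(0L) # centers at the touching spacing
  expect_equal(phase_components(touching, "cell1")$n_components, 1L)
  separated <- make_two_spheroid_lattice(3L)
  expect_equal(phase_components(separated, "cell1")$n_components, 2L)
  # sizes always partition the phase census
  set.seed(31)
  for (conn in c(6, 18, 26)) {
    sites <- random_sites(c(7, 7, 7), 2, p = c(0.8, 0.2))
    lat <- as_cell_lattice(sites, 2)
    pc <- phase_components(lat, "cell1", connectivity = conn)
    or <- oracle_components(sites, 1L, connectivity = conn)
    expect_equal(pc$n_components, or$n_components)
    expect_equal(sum(pc$sizes), sum(sites == 1L))
    # same partition: component sizes agree as multisets
    expect_equal(sort(pc$sizes),
                 sort(tabulate(or$labels[or$labels > 0])))
  }
  expect_error(phase_components(touching, "nope"), "unknown")
})

shell_of_cube <- function() {
  # 7^3 box: 3^3 cavity of sigma 3 at the center, wrapped by a one-site shell
  arr <- array(0L, c(9, 9, 9))
  arr[3:7, 3:7, 3:7] <- 1L
  arr[4:6, 4:6, 4:6] <- 3L
  arr
}

test_that("lining coverage counts the lining share of the cavity shell", {
  types <- type_registry(c("medium", "muscle", "endothelial", "sacrificial"),
                         c("medium", "cell", "cell", "cell"))
  # cavity fully enclosed in lining cells
  arr <- shell_of_cube()
  arr[arr == 1L] <- 2L
  lat <- mmc_lattice(arr, types = types)
  expect_equal(lining_coverage(lat, "endothelial", "sacrificial"), 1)
  # lining type absent
  arr2 <- shell_of_cube()
  lat2 <- mmc_lattice(arr2, types = types)
  expect_equal(lining_coverage(lat2, "endothelial", "sacrificial"), 0)
  # partial shell: expected value from direct enumeration of neighbor pairs
  arr3 <- shell_of_cube()
  sel <- which(arr3 == 1L, arr.ind = TRUE)
  upper <- sel[, 3] >= 6L # top slab of the shell becomes endothelial
  arr3[sel[upper, , drop = FALSE]] <- 2L
  lat3 <- mmc_lattice(arr3, types = types)
  cav <- which(arr3 == 3L, arr.ind = TRUE)
  off <- oracle_offsets()
  lin_pairs <- tot_pairs <- 0
  for (i in seq_len(nrow(cav))) for (k in seq_len(nrow(off))) {
    q <- cav[i, ] + off[k, ]
    v <- arr3[q[1], q[2], q[3]]
    if (v != 3L) {
      tot_pairs <- tot_pairs + 1
      if (v == 2L) lin_pairs <- lin_pairs + 1
    }
  }
  expect_equal(lining_coverage(lat3, "endothelial", "sacrificial"),
               lin_pairs / tot_pairs)
  # mirror symmetry: relabeling the two shell halves swaps their coverages
  arr4 <- shell_of_cube()
  sel4 <- which(arr4 == 1L, arr.ind = TRUE)
  arr4[sel4[sel4[, 3] > 5L, , drop = FALSE]] <- 2L
  lat4 <- mmc_lattice(arr4, types = types)
  cov_top <- lining_coverage(lat4, "endothelial", "sacrificial")
  cov_bot <- lining_coverage(lat4, "muscle", "sacrificial")
  expect_equal(cov_top + cov_bot, 1)
  expect_error(lining_coverage(lat, "sacrificial", "sacrificial"), "cannot be part")
  expect_error(lining_coverage(lat2, "muscle", "endothelial"), "empty")
})

test_that("lining coverage is invariant under cube symmetries of the volume", {
  set.seed(41)
  arr <- shell_of_cube()
  sel <- which(arr == 1L)
  arr[sample(sel, 40)] <- 2L
  types <- type_registry(c("medium", "muscle", "endothelial", "sacrificial"),
                         c("medium", "cell", "cell", "cell"))
  base <- lining_coverage(mmc_lattice(arr, types = types), "endothelial", "sacrificial")
  rotations <- list(
    function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE],
    function(a) aperm(a, c(3, 2, 1))[, , dim(a)[1]:1, drop = FALSE],
    function(a) a[dim(a)[1]:1, , , drop = FALSE])
  for (rot in rotations) {
    lat_r <- mmc_lattice(array(rot(arr), dim(arr)), types = types)
    expect_equal(lining_coverage(lat_r, "endothelial", "sacrificial"), base)
  }
})

test_that("interface roughness is symmetric and ranks sphere below bar", {
  # digital sphere vs an equal-volume bar: the sphere exposes fewer pairs
  sph <- make_spheroid(8)
  v <- nrow(sph)
  d <- c(max(v + 4L, 15L), 15L, 15L)
  sphere_arr <- array(0L, d)
  idx <- sweep(sph, 2, c(8L, 8L, 8L), "+")
  sphere_arr[idx[, 1] + d[1] * (idx[, 2] - 1L) + d[1] * d[2] * (idx[, 3] - 1L)] <- 1L
  bar_arr <- array(0L, d)
  bar_arr[3:(2L + v), 8L, 8L] <- 1L
  sphere <- as_cell_lattice(sphere_arr, 2)
  bar <- as_cell_lattice(bar_arr, 2)
  expect_equal(sum(sphere$sites), sum(bar$sites))
  expect_lt(interface_roughness(sphere, "cell1", "medium"),
            interface_roughness(bar, "cell1", "medium"))
  # symmetry, consistency with bond counts, and empty phases
  expect_equal(interface_roughness(sphere, "medium", "cell1"),
               interface_roughness(sphere, "cell1", "medium"))
  expect_equal(interface_roughness(sphere, "cell1", "medium"),
               bond_counts(sphere)[1, 2])
  empty <- as_cell_lattice(array(0L, c(3, 3, 3)), 2)
  expect_equal(interface_roughness(empty, "cell1", "medium"), 0)
  expect_error(interface_roughness(sphere, "cell1", "cell1"), "disjoint")
})

test_that("enclosed-medium ray casting isolates a channel lumen", {
  # hollow tube of cells along x, open at both ends, in a medium bath
  d <- c(16, 11, 11)
  arr <- array(0L, d)
  for (x in 3:14) for (y in 4:8) for (z in 4:8) {
    r2 <- (y - 6)^2 + (z - 6)^2
    if (r2 >= 2 && r2 <= 6) arr[x, y, z] <- 1L
  }
  core <- which(arr == 0L & slice.index(arr, 1) %in% 3:14 &
                  (slice.index(arr, 2) - 6)^2 + (slice.index(arr, 3) - 6)^2 < 2)
  lat <- as_cell_lattice(arr, 2)
  enc <- enclosed_medium(lat)
  expect_true(all(enc[core])) # channel medium is interior
  expect_false(enc[1, 1, 1]) # bath corner is exterior
  expect_false(enc[1, 6, 6]) # on-axis bath site ahead of the opening
  rep <- lumen_report(lat, vacated = core)
  expect_true(rep$exists)
  expect_gte(rep$vacated_recovered, 1)
  expect_equal(rep$overlap, 1)
})

test_that("sorting trajectories track lining coverage across checkpoints", {
  set.seed(51)
  lat <- build_construct(construct_spec("two_type_tube", spheroid_diameter = 5,
                                        chain_length = 2))
  tab <- adhesion_preset("two_type_sorting")$table
  run0 <- run_schedule(lat, tab, mmc_schedule(0, seed = 1))
  tr0 <- sorting_trajectory(run0, "endothelial", "sacrificial")
  expect_equal(nrow(tr0), 1L)
  expect_equal(tr0$mcs, 0)
  run <- run_schedule(lat, tab, mmc_schedule(40, seed = 2, checkpoints = c(20)))
  tr <- sorting_trajectory(run, "endothelial", "sacrificial")
  expect_equal(tr$mcs, c(0, 20, 40))
  expect_true(all(tr$coverage >= 0 & tr$coverage <= 1))
  expect_equal(tr$coverage[1],
               lining_coverage(lat, "endothelial", "sacrificial"))
})
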