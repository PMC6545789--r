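#' Settings of the three study protocols
#'
#' Returns the construct spec, adhesion preset name and schedule parameters
#' for a named protocol at full or reduced scale. Full scale reproduces the
#' printed study conditions (diameter-10 tube spheroids, 5e3 + 1e3 MCS for
#' the single-type tube; 5e4 MCS for the two-type tube; the 210 x 145 x 124
#' slab with diameter-30/16 spheroids and 1e5 MCS for the branched
#' construct). Reduced scale halves the spheroid diameters, shortens the
#' chains to three spheroids and divides the MCS budgets by ten so each
#' protocol completes in minutes on one CPU while preserving the morphology
#' being tested.
#'
#' @param protocol `"single_tube"`, `"two_type_tube"` or `"branched_channel"`.
#' @param scale `"reduced"` or `"full"`.
#' @param variant For the two-type tube: `"sorting"` (the tension hierarchy
#'   that yields an endothelial lining) or `"scrambled"`.
#' @return List with `spec`, `preset`, `sacrificial` (type name), and the
#'   schedule skeleton (`n_mcs`, `checkpoints`, `eliminate_at`,
#'   `post_elim_mcs`).
#' @export
protocol_settings <- function(protocol = c("single_tube", "two_type_tube",
                                           "branched_channel"),
                              scale = c("reduced", "full"),
                              variant = c("sorting", "scrambled")) {
  protocol <- match.arg(protocol)
  scale <- match.arg(scale)
  variant <- match.arg(variant)
  reduced <- scale == "reduced"
  if (protocol == "single_tube") {
    spec <- construct_spec("single_type_tube",
                           spheroid_diameter = if (reduced) 5 else 10,
                           chain_length = if (reduced) 3 else 5)
    list(spec = spec, preset = "single_tube", sacrificial = "sacrificial",
         n_mcs = if (reduced) 600 else 6000,
         eliminate_at = if (reduced) 500 else 5000,
         checkpoints = if (reduced) c(100, 500) else c(1000, 5000))
  } else if (protocol == "two_type_tube") {
    spec <- construct_spec("two_type_tube",
                           spheroid_diameter = if (reduced) 5 else 10,
                           chain_length = if (reduced) 3 else 5)
    n_mcs <- if (reduced) 5000 else 50000
    list(spec = spec,
         preset = if (variant == "sorting") "two_type_sorting" else "two_type_scrambled",
         sacrificial = "sacrificial", n_mcs = n_mcs, eliminate_at = n_mcs,
         checkpoints = seq(n_mcs / 5, n_mcs, by = n_mcs / 5))
  } else {
    spec <- if (reduced)
      construct_spec("branched_hydrogel", large_diameter = 15, small_diameter = 8,
                     chain_length = 3, hydrogel_dims = c(70, 55, 46),
                     branch_layout = list(
                       list(attach = 2, direction = c(0, 1, 0), diameter = 8, count = 2),
                       list(attach = 2, direction = c(0, -1, 0), diameter = 8, count = 2)))
    else construct_spec("branched_hydrogel")
    n_mcs <- if (reduced) 10000 else 100000
    list(spec = spec, preset = "branched_hydrogel", sacrificial = "sacrificial",
         n_mcs = n_mcs, eliminate_at = n_mcs,
         checkpoints = if (reduced) c(500, 5000) else c(5000, 50000))
  }
}

#' Run one study protocol end to end
#'
#' Builds the construct, runs its Monte Carlo schedule (with the scheduled
#' sacrificial-cell elimination), and assembles a morphology report with one
#' row per recorded state: adhesion energy, sacrificial-phase component
#' count, construct/medium boundary-pair count (roughness), endothelial
#' lining coverage of the sacrificial cavity (where an endothelial type
#' exists), and — for states after the elimination — the lumen size and its
#' overlap with the vacated region.
#'
#' @param protocol,scale,variant See [protocol_settings()].
#' @param seed Integer seed controlling construct randomness and dynamics.
#' @param snapshots Keep lattice snapshots in the result?
#' @return List with `protocol`, `scale`, `variant`, `settings`,
#'   `construct`, `run` (an `mmc_run`) and `report` (data frame).
#' @export
run_protocol <- function(protocol = c("single_tube", "two_type_tube",
                                      "branched_channel"),
                         scale = c("reduced", "full"), seed = 1,
                         variant = c("sorting", "scrambled"), snapshots = TRUE) {
  protocol <- match.arg(protocol)
  scale <- match.arg(scale)
  variant <- match.arg(variant)
  st <- protocol_settings(protocol, scale, variant)
  set.seed(seed)
  lat <- build_construct(st$spec)
  preset <- adhesion_preset(st$preset)
  sched <- mmc_schedule(st$n_mcs, seed = NULL, checkpoints = st$checkpoints,
                        events = list(list(mcs = st$eliminate_at,
                                           eliminate = st$sacrificial)))
  run <- run_schedule(lat, preset$table, sched, snapshots = TRUE)
  report <- protocol_report(run, lat)
  if (!snapshots) run$snapshots <- list()
  list(protocol = protocol, scale = scale, variant = variant, settings = st,
       construct = lat, run = run, report = report)
}

protocol_report <- function(run, lat0) {
  has_endo <- "endothelial" %in% lat0$types$name
  elim_mcs <- as.numeric(names(run$vacated))
  vac <- if (length(run$vacated)) run$vacated[[1]] else integer(0)
  cell_sigmas <- lat0$types$sigma[lat0$types$kind == "cell"]
  rows <- lapply(names(run$snapshots), function(key) {
    sn <- run$snapshots[[key]]
    mcs <- as.numeric(key)
    sacr_present <- any(sn$sites == sigma_of(sn, "sacrificial"))
    comp <- if (sacr_present)
      phase_components(sn, "sacrificial")$n_components else NA_integer_
    rough <- interface_roughness(sn, lat0$types$name[lat0$types$kind != "medium"],
                                 "medium")
    covg <- if (has_endo && sacr_present)
      lining_coverage(sn, "endothelial", "sacrificial") else NA_real_
    data.frame(mcs = mcs,
               energy = run$trace$energy[match(mcs, run$trace$mcs)],
               sacrificial_components = comp, boundary_pairs = rough,
               lining_coverage = covg)
  })
  report <- do.call(rbind, rows)
  if (length(vac)) {
    lum <- lumen_report(run$final, vac)
    attr(report, "lumen") <- lum
  }
  report
}
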