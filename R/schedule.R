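#' Simulation schedule
#'
#' Bundles the Monte Carlo budget, the RNG seed, the checkpoints at which
#' snapshots and energies are recorded, and scheduled events (currently:
#' elimination of a sacrificial cell type).
#'
#' @param n_mcs Total Monte Carlo steps (>= 0).
#' @param seed Optional integer RNG seed; if `NULL` the current RNG state is
#'   used.
#' @param checkpoints Strictly increasing MCS indices in `[1, n_mcs]` at which
#'   snapshots are emitted (the initial state and the final state are always
#'   recorded).
#' @param events List of `list(mcs =, eliminate =)` entries, ordered by
#'   strictly increasing `mcs <= n_mcs`; `eliminate` names the cell type to
#'   convert to medium once that MCS completes. Checkpoint snapshots at the
#'   same MCS are taken before the event fires.
#' @return An object of class `mmc_schedule`.
#' @export
mmc_schedule <- function(n_mcs, seed = NULL, checkpoints = integer(0), events = list()) {
  n_mcs <- as.numeric(n_mcs)
  stopifnot(length(n_mcs) == 1L, n_mcs >= 0, n_mcs == floor(n_mcs))
  checkpoints <- as.numeric(checkpoints)
  if (length(checkpoints)) {
    if (any(diff(checkpoints) <= 0)) stop("checkpoints must be strictly increasing")
    if (any(checkpoints < 1) || any(checkpoints > n_mcs))
      stop("checkpoints must lie in [1, n_mcs]")
  }
  if (length(events)) {
    ev_mcs <- vapply(events, function(e) as.numeric(e$mcs), numeric(1))
    if (any(diff(ev_mcs) <= 0)) stop("event MCS indices must be strictly increasing")
    if (any(ev_mcs < 1) || any(ev_mcs > n_mcs)) stop("event MCS indices must lie in [1, n_mcs]")
    ok <- vapply(events, function(e) !is.null(e$eliminate), logical(1))
    if (!all(ok)) stop("each event must name a type to eliminate")
  }
  structure(list(n_mcs = n_mcs, seed = seed, checkpoints = checkpoints, events = events),
            class = "mmc_schedule")
}

#' Execute a simulation schedule
#'
#' Runs the Metropolis swap dynamics for `schedule$n_mcs` MCS, firing
#' elimination events and emitting snapshots/energies at their MCS indices.
#' Fully reproducible: the same lattice, table and schedule (with a seed)
#' give a bit-identical result.
#'
#' @param lat An [mmc_lattice()].
#' @param table An [adhesion_table()].
#' @param schedule An [mmc_schedule()].
#' @param allow_gel_swap Passed to [mobility_policy()].
#' @param snapshots Record lattice snapshots at checkpoints? (Energies are
#'   always recorded.)
#' @return An object of class `mmc_run`: list with `final` (lattice), `trace`
#'   (data frame `mcs`, `energy`, `attempted`, `accepted`, cumulative),
#'   `snapshots` (named by MCS; includes `"0"` and the final state),
#'   `vacated` (per elimination event, the 1-based linear indices of the
#'   sites converted to medium), `eliminated` (named removal counts),
#'   `schedule` and `table`.
#' @export
run_schedule <- function(lat, table, schedule, allow_gel_swap = TRUE, snapshots = TRUE) {
  stopifnot(inherits(lat, "mmc_lattice"), inherits(schedule, "mmc_schedule"))
  check_table_covers(lat, table)
  if (!is.null(schedule$seed)) set.seed(schedule$seed)

  ev_mcs <- vapply(schedule$events, function(e) as.numeric(e$mcs), numeric(1))
  breaks <- sort(unique(c(schedule$checkpoints, ev_mcs,
                          if (schedule$n_mcs > 0) schedule$n_mcs)))
  cur <- lat
  attempted <- accepted <- 0
  trace <- data.frame(mcs = 0, energy = total_energy(lat, table),
                      attempted = 0, accepted = 0)
  snaps <- list()
  if (snapshots) snaps[["0"]] <- lat
  vacated <- list()
  eliminated <- numeric(0)

  pos <- 0
  for (bp in breaks) {
    if (bp > pos) {
      step <- run_mcs(cur, table, bp - pos, allow_gel_swap = allow_gel_swap)
      cur <- step$lattice
      attempted <- attempted + step$attempted
      accepted <- accepted + step$accepted
      pos <- bp
    }
    is_cp <- bp %in% schedule$checkpoints || bp == schedule$n_mcs
    if (is_cp && snapshots) snaps[[as.character(bp)]] <- cur
    if (is_cp)
      trace <- rbind(trace, data.frame(mcs = bp, energy = total_energy(cur, table),
                                       attempted = attempted, accepted = accepted))
    # events fire after the checkpoint snapshot at the same MCS, so a
    # snapshot at an elimination index shows the state right before removal
    for (e in schedule$events[ev_mcs == bp]) {
      el <- eliminate_type(cur, e$eliminate)
      cur <- el$lattice
      key <- as.character(bp)
      vacated[[key]] <- el$vacated
      eliminated[key] <- el$removed
    }
  }
  structure(list(final = cur, trace = trace, snapshots = snaps, vacated = vacated,
                 eliminated = eliminated, attempted = attempted, accepted = accepted,
                 schedule = schedule, table = table),
            class = "mmc_run")
}

#' @export
print.mmc_run <- function(x, ...) {
  cat(sprintf("mmc_run: %g MCS, %g attempted / %g accepted swaps (%.1f%%)\n",
              x$schedule$n_mcs, x$attempted, x$accepted,
              if (x$attempted > 0) 100 * x$accepted / x$attempted else 0))
  cat(sprintf("  energy %0.2f -> %0.2f over %d trace points\n",
              x$trace$energy[1], x$trace$energy[nrow(x$trace)], nrow(x$trace)))
  if (length(x$eliminated))
    cat(sprintf("  eliminated %s sites at MCS %s\n",
                paste(x$eliminated, collapse = ", "),
                paste(names(x$eliminated), collapse = ", ")))
  invisible(x)
}
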