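default_elements <- c("C", "N", "O", "P", "S", "F", "K", "B")

#' Export a lattice snapshot as an XYZ point cloud
#'
#' Writes the standard XYZ text format readable by molecular viewers (VMD,
#' OVITO, PyMOL): a record count, a comment line, then one
#' `element x y z` row per non-medium site, with coordinates in lattice
#' units.
#'
#' @param lat An [mmc_lattice()].
#' @param path Output file path.
#' @param type_map Optional character vector mapping sigma = 1, 2, ... to
#'   element symbols; defaults to C, N, O, P, S, ...
#' @return The path, invisibly.
#' @export
export_xyz <- function(lat, path, type_map = NULL) {
  stopifnot(inherits(lat, "mmc_lattice"))
  n_cell_types <- max(lat$types$sigma)
  if (is.null(type_map))
    type_map <- rep_len(default_elements, max(n_cell_types, 1L))
  d <- dim(lat$sites)
  idx <- which(lat$sites != 0L)
  xyz <- arrayInd(idx, d) - 1L
  sig <- lat$sites[idx]
  lines <- c(as.character(length(idx)),
             sprintf("sacrosim snapshot dims=%d,%d,%d unit=%gum", d[1], d[2], d[3],
                     lat$lattice_unit),
             sprintf("%s %d %d %d", type_map[sig], xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ point cloud written by [export_xyz()]
#' @param path File path.
#' @return Data frame with columns `element`, `x`, `y`, `z` (lattice units).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  if (n == 0L)
    return(data.frame(element = character(0), x = integer(0), y = integer(0),
                      z = integer(0)))
  rec <- strsplit(lines[3:(2 + n)], "[[:space:]]+")
  data.frame(element = vapply(rec, `[`, "", 1L),
             x = as.integer(vapply(rec, `[`, "", 2L)),
             y = as.integer(vapply(rec, `[`, "", 3L)),
             z = as.integer(vapply(rec, `[`, "", 4L)))
}

#' Save a lattice as a plain-text label volume
#'
#' Self-describing text container: a format tag, a JSON metadata line (dims,
#' lattice unit, type table) and the run-length-encoded site labels in
#' column-major order. Round-trips exactly through [read_volume()].
#'
#' @param lat An [mmc_lattice()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_volume <- function(lat, path) {
  stopifnot(inherits(lat, "mmc_lattice"))
  meta <- jsonlite::toJSON(list(dims = dim(lat$sites), lattice_unit = lat$lattice_unit,
                                types = lat$types), auto_unbox = FALSE)
  r <- rle(as.vector(lat$sites))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#sacrosim-volume 1", as.character(meta),
               paste(r$values, r$lengths)), con)
  invisible(path)
}

#' Load a lattice from a plain-text label volume
#' @param path File written by [write_volume()].
#' @return An [mmc_lattice()].
#' @export
read_volume <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "#sacrosim-volume 1") stop("not a sacrosim volume file")
  meta <- jsonlite::fromJSON(lines[2])
  rl <- do.call(rbind, strsplit(lines[-(1:2)], " ", fixed = TRUE))
  sites <- inverse.rle(structure(list(lengths = as.integer(rl[, 2]),
                                      values = as.integer(rl[, 1])), class = "rle"))
  types <- as.data.frame(meta$types)
  types$sigma <- as.integer(types$sigma)
  mmc_lattice(array(sites, meta$dims), types = types, lattice_unit = meta$lattice_unit)
}

#' Write a run configuration file
#'
#' Persists the adhesion table, type registry and schedule of a simulation as
#' human-readable YAML so any run can be reproduced from its configuration
#' plus seed.
#'
#' @param path Output file path.
#' @param types A [type_registry()].
#' @param table An [adhesion_table()].
#' @param schedule An [mmc_schedule()].
#' @return The path, invisibly.
#' @export
write_run_config <- function(path, types, table, schedule) {
  cfg <- list(
    types = lapply(seq_len(nrow(types)), function(i)
      list(sigma = types$sigma[i], name = types$name[i], kind = types$kind[i])),
    eps = apply(unname(table$eps), 1, as.numeric, simplify = FALSE),
    E_T = table$E_T,
    n_mcs = schedule$n_mcs,
    seed = schedule$seed,
    checkpoints = as.numeric(schedule$checkpoints),
    events = lapply(schedule$events, function(e)
      list(mcs = as.numeric(e$mcs), eliminate = e$eliminate)))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a run configuration file
#' @param path YAML file written by [write_run_config()].
#' @return List with `types`, `table` and `schedule`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  types <- type_registry(vapply(cfg$types, `[[`, "", "name"),
                         vapply(cfg$types, `[[`, "", "kind"))
  eps <- do.call(rbind, lapply(cfg$eps, as.numeric))
  table <- adhesion_table(eps, E_T = cfg$E_T, type_names = types$name)
  schedule <- mmc_schedule(cfg$n_mcs, seed = cfg$seed,
                           checkpoints = as.numeric(unlist(cfg$checkpoints)),
                           events = cfg$events)
  list(types = types, table = table, schedule = schedule)
}
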