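#' Trajectory frames container
#'
#' Ordered coordinate snapshots with a constant atom set, as produced by
#' [read_multimodel_pdb()] or [gen_toy_trajectory()]. Coordinates are in
#' Angstrom; the snapshot interval is carried in picoseconds.
#'
#' @param atoms Data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resid`, `element` (one row per atom).
#' @param coords Numeric array `n_atoms x 3 x n_frames`.
#' @param interval_ps Snapshot interval in ps (> 0).
#' @return Object of class `trajectory_frames`.
#' @export
trajectory_frames <- function(atoms, coords, interval_ps) {
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3L,
            dim(coords)[1] == nrow(atoms), dim(coords)[2] == 3L,
            interval_ps > 0)
  structure(list(atoms = atoms, coords = coords, interval_ps = interval_ps),
            class = "trajectory_frames")
}

#' @export
print.trajectory_frames <- function(x, ...) {
  cat(sprintf("<trajectory_frames> %d atoms x %d frames @ %g ps\n",
              nrow(x$atoms), dim(x$coords)[3], x$interval_ps))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

#' Read a multi-model PDB file as a toy trajectory
#'
#' Minimal fixed-width parser for `MODEL`/`ATOM`/`HETATM`/`ENDMDL` records
#' (toy-scale trajectories only; binary trajectory formats are out of scope).
#' The atom set must be identical across models.
#'
#' @param path PDB file.
#' @param interval_ps Snapshot interval to attach (ps), default 10.
#' @return A [trajectory_frames()] object.
#' @export
read_multimodel_pdb <- function(path, interval_ps = 10) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_id <- cumsum(rec == "MODEL ")
  if (max(model_id) == 0L) model_id <- model_id + 1L  # single unlabelled model
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]
  f <- function(from, to) sub("^\\s+|\\s+$", "", substr(atom_lines, from, to), perl = TRUE)
  parsed <- data.frame(
    serial = as.integer(f(7, 11)), name = f(13, 16), resname = f(18, 20),
    chain = f(22, 22), resid = as.integer(f(23, 26)),
    x = as.numeric(f(31, 38)), y = as.numeric(f(39, 46)), z = as.numeric(f(47, 54)),
    element = f(77, 78), stringsAsFactors = FALSE)
  # fall back on the first character of the atom name when the element
  # column is blank (common in hand-made files)
  blank <- !nzchar(parsed$element)
  parsed$element[blank] <- substr(gsub("[0-9]", "", parsed$name[blank]), 1, 1)
  models <- unique(atom_model)
  per <- tabulate(atom_model)[models]
  if (length(unique(per)) != 1L)
    stop("models differ in atom count; constant atom set required")
  n_at <- per[1]
  atoms <- parsed[atom_model == models[1],
                  c("serial", "name", "resname", "chain", "resid", "element")]
  coords <- array(NA_real_, c(n_at, 3, length(models)))
  for (i in seq_along(models)) {
    m <- parsed[atom_model == models[i], c("x", "y", "z")]
    coords[, , i] <- as.matrix(m)
  }
  trajectory_frames(atoms, coords, interval_ps)
}

#' Write a toy trajectory as a multi-model PDB file
#'
#' @param traj A [trajectory_frames()] object.
#' @param path Output file.
#' @export
write_multimodel_pdb <- function(traj, path) {
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- traj$coords[, , k]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      at$serial, at$name, at$resname, at$chain, at$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
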