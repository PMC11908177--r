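# LAMMPS interchange: tabulated pair potentials, data files, dump/XYZ
# trajectories. Tabulated numbers are printed with 15 significant digits so
# energies and forces survive a parse round trip to well below 1e-8
# kcal/mol even near the repulsive core; coordinates use 10 digits.

#' @keywords internal
#' @noRd
.fmt10 <- function(x) formatC(x, digits = 10, format = "g")

#' @keywords internal
#' @noRd
.fmt15 <- function(x) formatC(x, digits = 15, format = "g")

#' @keywords internal
#' @noRd
.pair_keyword <- function(i, j) paste("WF", min(i, j), max(i, j), sep = "_")

#' Write LAMMPS pair_style table files
#'
#' Tabulates the full pair interaction (short-range branch plus screened
#' electrostatics) for every residue pair at each requested temperature;
#' one file per temperature, one section per pair with keyword
#' `WF_<I>_<J>`. The `r` grid is uniform from `r_min` to the largest
#' cutoff. Format: `index r energy force` under an `N <points>` header, as
#' consumed by `pair_style table linear`.
#'
#' @param ff a [forcefield()] object.
#' @param temperatures temperatures in K (one output file each).
#' @param dir output directory.
#' @param codes residue codes to tabulate (default: all in the force
#'   field).
#' @param n_points table resolution (default 1001).
#' @param r_min smallest tabulated distance in Angstrom; default
#'   0.8 x the smallest pair sigma, where the repulsive core is already
#'   several hundred kcal/mol.
#' @return invisible character vector of file paths written.
#' @export
write_pair_tables <- function(ff, temperatures, dir,
                              codes = ff$residues$code, n_points = 1001,
                              r_min = NULL) {
  stopifnot(inherits(ff, "cg_forcefield"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(r_min)) r_min <- 0.8 * min(ff$pairs$sigma_ij)
  r_max <- max(ff$pairs$r_cut, ff$electrostatics$yukawa_cutoff)
  r <- seq(r_min, r_max, length.out = n_points)
  paths <- character(0)
  for (T in temperatures) {
    path <- file.path(dir, sprintf("pair_table_%gK.table", T))
    con <- file(path, "w")
    writeLines(sprintf(
      "# cgphase tabulated pair potentials at T = %g K (kcal/mol, Angstrom)",
      T), con)
    for (a in seq_along(codes)) for (b in a:length(codes)) {
      i <- codes[a]; j <- codes[b]
      u <- pair_energy(r, i, j, T, ff)
      f <- pair_force(r, i, j, T, ff)
      writeLines(c("", .pair_keyword(i, j), sprintf("N %d", n_points), ""),
                 con)
      writeLines(sprintf("%d %s %s %s", seq_len(n_points), .fmt15(r),
                         .fmt15(u), .fmt15(f)), con)
    }
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a LAMMPS pair table file
#'
#' @param path file written by [write_pair_tables()] (or compatible).
#' @return named list of data.frames with columns `r`, `energy`, `force`;
#'   names are the section keywords.
#' @export
read_pair_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  out <- list()
  k <- 1
  while (k <= length(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || grepl("^\\d", ln)) { k <- k + 1; next }
    keyword <- ln
    k <- k + 1
    while (trimws(lines[k]) == "") k <- k + 1
    npt <- as.integer(sub("^N\\s+(\\d+).*", "\\1", trimws(lines[k])))
    k <- k + 1
    while (k <= length(lines) && trimws(lines[k]) == "") k <- k + 1
    block <- lines[k:(k + npt - 1)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"),
                               function(x) as.numeric(x[2:4])))
    out[[keyword]] <- data.frame(r = m[, 1], energy = m[, 2], force = m[, 3])
    k <- k + npt
  }
  out
}

#' Write a LAMMPS data file (atom_style full)
#'
#' @param sys a `particle_system`.
#' @param ff a [forcefield()] object (bond constants recorded in header
#'   comments).
#' @param path output path.
#' @return invisible `path`.
#' @export
write_lammps_data <- function(sys, ff, path) {
  types <- sort(unique(sys$codes))
  tmap <- stats::setNames(seq_along(types), types)
  n <- nrow(sys$positions)
  pos <- wrap_positions(sys$positions, sys$box)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("LAMMPS data file (cgphase; bond: harmonic k=%g r0=%g)",
            ff$bond$k, ff$bond$r0),
    "",
    sprintf("%d atoms", n),
    sprintf("%d bonds", nrow(sys$bonds)),
    sprintf("%d atom types", length(types)),
    "1 bond types",
    "",
    sprintf("0.0 %s xlo xhi", .fmt10(sys$box[1])),
    sprintf("0.0 %s ylo yhi", .fmt10(sys$box[2])),
    sprintf("0.0 %s zlo zhi", .fmt10(sys$box[3])),
    "",
    "Masses",
    ""), con)
  writeLines(sprintf("%d %s  # %s", seq_along(types),
                     .fmt10(ff$residues[types, "mass"]), types), con)
  writeLines(c("", "Atoms  # full", ""), con)
  writeLines(sprintf("%d %d %d %s %s %s %s", seq_len(n), sys$chain_id,
                     tmap[sys$codes], .fmt10(sys$charge),
                     .fmt10(pos[, 1]), .fmt10(pos[, 2]), .fmt10(pos[, 3])),
             con)
  if (nrow(sys$bonds) > 0) {
    writeLines(c("", "Bonds", ""), con)
    writeLines(sprintf("%d 1 %d %d", seq_len(nrow(sys$bonds)),
                       sys$bonds[, 1], sys$bonds[, 2]), con)
  }
  invisible(path)
}

#' Write a LAMMPS input-script template
#'
#' Emits a minimal NVT (Langevin) input script wired to the table and data
#' files produced by [write_pair_tables()] and [write_lammps_data()].
#' Values in `real` units; the user supplies run lengths at production
#' scale.
#'
#' @param ff a [forcefield()] object.
#' @param data_file,table_file file names to reference.
#' @param path output path.
#' @param temperature run temperature (K).
#' @param codes residue codes in type order (default all).
#' @param n_points table resolution used when writing the tables.
#' @return invisible `path`.
#' @export
write_lammps_input_template <- function(ff, data_file, table_file, path,
                                        temperature = 300,
                                        codes = ff$residues$code,
                                        n_points = 1001) {
  codes <- sort(codes)
  lines <- c(
    "# cgphase coarse-grained slab protocol (template)",
    "units real",
    "atom_style full",
    "boundary p p p",
    sprintf("read_data %s", data_file),
    sprintf("bond_style harmonic"),
    sprintf("bond_coeff 1 %g %g", ff$bond$k, ff$bond$r0),
    sprintf("pair_style table linear %d", n_points))
  for (a in seq_along(codes)) for (b in a:length(codes)) {
    lines <- c(lines, sprintf("pair_coeff %d %d %s %s", a, b, table_file,
                              .pair_keyword(codes[a], codes[b])))
  }
  lines <- c(lines,
    "neighbor 2.0 bin",
    "timestep 10",
    sprintf("velocity all create %g 12345", temperature),
    sprintf("fix nvt all nve"),
    sprintf("fix lang all langevin %g %g 5000.0 12345", temperature,
            temperature),
    "dump traj all custom 100000 slab.dump id type x y z",
    "# run 5000000   # 50 ns equilibration",
    "# run 40000000  # 400 ns production")
  writeLines(lines, path)
  invisible(path)
}

#' Write an XYZ trajectory
#'
#' @param traj a `cg_trajectory`, or a `particle_system` (single frame).
#' @param path output path.
#' @param codes element column; defaults to residue codes.
#' @return invisible `path`.
#' @export
write_xyz <- function(traj, path, codes = NULL) {
  frames <- if (inherits(traj, "particle_system")) {
    if (is.null(codes)) codes <- traj$codes
    list(wrap_positions(traj$positions, traj$box))
  } else {
    if (is.null(codes)) codes <- rep("C", nrow(traj$frames[[1]]))
    traj$frames
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    p <- frames[[k]]
    writeLines(c(sprintf("%d", nrow(p)), sprintf("frame %d", k)), con)
    writeLines(sprintf("%s %s %s %s", codes, .fmt10(p[, 1]),
                       .fmt10(p[, 2]), .fmt10(p[, 3])), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file.
#' @return list of frames, each a list with `codes` and `positions`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  k <- 1
  while (k <= length(lines)) {
    n <- as.integer(trimws(lines[k]))
    block <- strsplit(trimws(lines[(k + 2):(k + 1 + n)]), "\\s+")
    codes <- vapply(block, `[`, character(1), 1)
    pos <- do.call(rbind, lapply(block, function(x) as.numeric(x[2:4])))
    out[[length(out) + 1]] <- list(codes = codes, positions = pos)
    k <- k + 2 + n
  }
  out
}

#' Write a LAMMPS-style custom dump
#'
#' Plain-text dump with `ITEM: ATOMS id type x y z` records, one entry per
#' trajectory frame.
#'
#' @param traj a `cg_trajectory`.
#' @param path output path.
#' @param types integer type per bead (default 1).
#' @return invisible `path`.
#' @export
write_dump <- function(traj, path, types = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  n <- nrow(traj$frames[[1]])
  if (is.null(types)) types <- rep(1L, n)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    p <- traj$frames[[k]]
    writeLines(c("ITEM: TIMESTEP", sprintf("%d", k),
                 "ITEM: NUMBER OF ATOMS", sprintf("%d", n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0.0 %s", .fmt10(traj$box[1])),
                 sprintf("0.0 %s", .fmt10(traj$box[2])),
                 sprintf("0.0 %s", .fmt10(traj$box[3])),
                 "ITEM: ATOMS id type x y z"), con)
    writeLines(sprintf("%d %d %s %s %s", seq_len(n), types,
                       .fmt10(p[, 1]), .fmt10(p[, 2]), .fmt10(p[, 3])), con)
  }
  invisible(path)
}

#' Read a LAMMPS-style custom dump
#'
#' Supports `ITEM: ATOMS id type x y z` records with `pp pp pp` box
#' bounds.
#'
#' @param path dump file.
#' @return list of frames, each with `timestep`, `box`, `types`,
#'   `positions` (ordered by atom id).
#' @export
read_dump <- function(path) {
  lines <- readLines(path)
  out <- list()
  k <- 1
  while (k <= length(lines)) {
    stopifnot(grepl("^ITEM: TIMESTEP", lines[k]))
    ts <- as.numeric(lines[k + 1])
    n <- as.integer(lines[k + 3])
    bounds <- do.call(rbind, lapply(strsplit(trimws(
      lines[(k + 5):(k + 7)]), "\\s+"), as.numeric))
    box <- bounds[, 2] - bounds[, 1]
    block <- strsplit(trimws(lines[(k + 9):(k + 8 + n)]), "\\s+")
    m <- do.call(rbind, lapply(block, as.numeric))
    ord <- order(m[, 1])
    out[[length(out) + 1]] <- list(timestep = ts, box = box,
                                   types = as.integer(m[ord, 2]),
                                   positions = m[ord, 3:5, drop = FALSE])
    k <- k + 9 + n
  }
  out
}
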