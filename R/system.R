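#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that validates every
#' record against the 20-residue one-letter alphabet.
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase sequences (possibly empty,
#'   with a warning).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    warning("FASTA file contains no records: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  seqs <- toupper(as.character(set))
  bad <- vapply(strsplit(seqs, ""),
                function(s) any(!s %in% AA_ALPHABET), logical(1))
  if (any(bad)) {
    stop("unknown residue code(s) in record(s): ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  if (is.null(names(sequences))) {
    names(set) <- paste0("seq", seq_along(sequences))
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Number of chain replicates for a slab build
#'
#' 64 (4 x 4 x 4) replicates for chains shorter than 190 residues, 27
#' (3 x 3 x 3) for chains of 190 residues or more.
#'
#' @param sequence_length chain length in residues (>= 1).
#' @return 64 or 27.
#' @export
replicate_count <- function(sequence_length) {
  stopifnot(sequence_length >= 1)
  ifelse(sequence_length < 190, 64L, 27L)
}

#' Construct a particle system
#'
#' Low-level constructor; most users should call [build_single_chain()] or
#' [build_slab()].
#'
#' @param positions N x 3 matrix of coordinates (Angstrom).
#' @param codes length-N character vector of residue codes.
#' @param chains list of integer index vectors, one per chain, each
#'   consecutive in order along the backbone.
#' @param box orthorhombic box lengths `c(lx, ly, lz)` in Angstrom
#'   (periodic).
#' @param ff a [forcefield()] object supplying masses, charges and bond
#'   constants.
#' @param velocities optional N x 3 matrix (Angstrom/fs); zero if omitted.
#' @return object of class `particle_system`.
#' @export
particle_system <- function(positions, codes, chains, box, ff,
                            velocities = NULL) {
  stopifnot(inherits(ff, "cg_forcefield"))
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, length(codes) == n, length(box) == 3,
            all(box > 0))
  if (!setequal(sort(unlist(chains)), seq_len(n)) ||
      length(unlist(chains)) != n) {
    stop("chain indices must partition 1..N", call. = FALSE)
  }
  if (any(!codes %in% ff$residues$code)) {
    stop("residue code(s) not present in force field: ",
         paste(unique(codes[!codes %in% ff$residues$code]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  bonds <- do.call(rbind, lapply(chains, function(idx) {
    if (length(idx) < 2) return(NULL)
    cbind(idx[-length(idx)], idx[-1])
  }))
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  chain_id <- integer(n)
  for (k in seq_along(chains)) chain_id[chains[[k]]] <- k
  structure(list(
    positions = positions,
    velocities = as.matrix(velocities),
    codes = codes,
    mass = unname(ff$residues[codes, "mass"]),
    charge = unname(ff$residues[codes, "charge"]),
    chains = chains,
    chain_id = chain_id,
    bonds = bonds,
    box = as.numeric(box)),
    class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat("<particle_system>", nrow(x$positions), "beads,",
      length(x$chains), "chain(s), box",
      paste(signif(x$box, 5), collapse = " x "), "A\n")
  invisible(x)
}

#' Total mass of a system in amu
#' @param sys a `particle_system`.
#' @return total mass (amu).
#' @export
total_mass <- function(sys) sum(sys$mass)

#' Overall mass density of a system
#' @param sys a `particle_system`.
#' @return density in g/cm^3.
#' @export
system_density <- function(sys) {
  total_mass(sys) * .const$amu_g / (prod(sys$box) * 1e-24)
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards.
#' @keywords internal
#' @noRd
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Self-avoiding-ish random walk with fixed bond length, optionally confined
# to a sphere. Returns an n x 3 matrix starting at `origin`.
#' @keywords internal
#' @noRd
.random_walk <- function(n, r0, origin = c(0, 0, 0), confine_r = Inf,
                         center = origin, min_sep = 0.8 * r0) {
  pos <- matrix(0, n, 3)
  pos[1, ] <- origin
  for (i in seq_len(n)[-1]) {
    placed <- FALSE
    for (try in 1:60) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- pos[i - 1, ] + r0 * u
      if (sqrt(sum((cand - center)^2)) > confine_r) next
      if (i > 2) {
        prev <- pos[seq_len(i - 2), , drop = FALSE]
        d2 <- rowSums(sweep(prev, 2, cand)^2)
        if (min(d2) < min_sep^2) next
      }
      pos[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) {
      # fold back toward the confinement centre; relaxation fixes overlaps
      u <- center - pos[i - 1, ] + 0.3 * stats::rnorm(3)
      nu <- sqrt(sum(u^2))
      u <- if (nu > 0) u / nu else c(1, 0, 0)
      pos[i, ] <- pos[i - 1, ] + r0 * u
    }
  }
  pos
}

#' Build a single-chain system for scaling-exponent runs
#'
#' One self-avoiding random-walk chain with fixed bond length in a cubic
#' periodic box large enough that the chain can never interact with its
#' own periodic images.
#'
#' @param sequence one-letter sequence string.
#' @param ff a [forcefield()] object.
#' @param box_margin extra clearance in Angstrom added on each side of the
#'   fully extended chain (default 50).
#' @param seed integer seed (placement is deterministic given the seed).
#' @return a `particle_system` with one chain, centred in the box.
#' @export
build_single_chain <- function(sequence, ff, box_margin = 50, seed = 1) {
  stopifnot(nchar(sequence) >= 1)
  codes <- strsplit(toupper(sequence), "")[[1]]
  n <- length(codes)
  r0 <- ff$bond$r0
  edge <- (n - 1) * r0 + 2 * box_margin
  pos <- .with_seed(seed, .random_walk(n, r0))
  # centre the chain in the box
  pos <- sweep(pos, 2, colMeans(pos))
  pos <- sweep(pos, 2, rep(edge / 2, 3), "+")
  particle_system(pos, codes, list(seq_len(n)), rep(edge, 3), ff)
}

#' Build a slab system at a target solution concentration
#'
#' Implements the finite-size slab preparation: the chain is replicated
#' (64 copies below 190 residues, 27 at or above), packed on a cubic
#' lattice, compressed by staged affine box rescaling (with optional short
#' Langevin relaxation bursts between stages, standing in for an NPT
#' compression) until the requested dense density is reached, and the box
#' is then extended along z so that total mass / volume equals the target
#' solution concentration, with the dense slab centred at z = Lz/2.
#'
#' @param sequence one-letter sequence string.
#' @param ff a [forcefield()] object.
#' @param target_concentration overall solution concentration in g/L.
#' @param dense_density density of the compressed slab in g/cm^3 (default
#'   0.9, the midpoint of the conventional 0.8-1.0 range).
#' @param seed integer seed.
#' @param n_replicates override the replicate rule (default
#'   [replicate_count()] of the sequence length).
#' @param stages number of affine compression stages (default 4).
#' @param relax_steps Langevin steps between stages (default 100; 0
#'   disables relaxation).
#' @param relax_temperature temperature of the relaxation bursts (K).
#' @return a `particle_system` in an elongated box (z is the long axis).
#' @export
build_slab <- function(sequence, ff, target_concentration,
                       dense_density = 0.9, seed = 1,
                       n_replicates = NULL, stages = 4, relax_steps = 100,
                       relax_temperature = 300) {
  stopifnot(target_concentration > 0, dense_density > 0)
  codes <- strsplit(toupper(sequence), "")[[1]]
  len <- length(codes)
  n_rep <- if (is.null(n_replicates)) replicate_count(len) else n_replicates
  n_side <- round(n_rep^(1 / 3))
  if (n_side^3 != n_rep) {
    stop("n_replicates must be a perfect cube", call. = FALSE)
  }
  chain_mass <- sum(ff$residues[codes, "mass"])
  mass <- n_rep * chain_mass
  # dense cubic box edge from mass / density
  v_dense <- mass * 1.66053906660 / dense_density     # Angstrom^3
  l_dense <- v_dense^(1 / 3)
  start_scale <- 1.6
  l0 <- l_dense * start_scale
  cell <- l0 / n_side
  r0 <- ff$bond$r0

  pos <- .with_seed(seed, {
    out <- matrix(0, n_rep * len, 3)
    k <- 0
    for (ix in seq_len(n_side) - 1) for (iy in seq_len(n_side) - 1)
      for (iz in seq_len(n_side) - 1) {
        ctr <- (c(ix, iy, iz) + 0.5) * cell
        walk <- .random_walk(len, r0, origin = ctr,
                             confine_r = 0.45 * cell, center = ctr)
        out[k * len + seq_len(len), ] <- walk
        k <- k + 1
      }
    out
  })
  chains <- split(seq_len(n_rep * len), rep(seq_len(n_rep), each = len))
  sys <- particle_system(pos, rep(codes, n_rep), unname(chains),
                         rep(l0, 3), ff)

  # staged affine compression toward the dense cube; a short minimisation
  # before each burst removes packing overlaps so the 2 fs relaxation
  # dynamics stay stable
  scales <- start_scale^(-seq_len(stages) / stages)  # cumulative factors
  for (s in seq_along(scales)) {
    target_l <- l0 * scales[s]
    f <- target_l / sys$box[1]
    sys$positions <- sys$positions * f
    sys$box <- rep(target_l, 3)
    if (relax_steps > 0) {
      sys <- minimize_system(sys, ff, relax_temperature,
                             max_steps = 50)$system
      sys$velocities[] <- 0
      sys <- run_steps(sys, ff, temperature = relax_temperature,
                       n_steps = relax_steps, dt = 2,
                       seed = seed + 1000L + s)
    }
  }
  sys <- minimize_system(sys, ff, relax_temperature, max_steps = 100)$system
  sys$velocities[] <- 0

  # extend z to reach the target solution concentration
  conc_gcm3 <- target_concentration / 1000
  v_target <- mass * 1.66053906660 / conc_gcm3
  lz <- v_target / (sys$box[1] * sys$box[2])
  if (lz < sys$box[3]) {
    stop("infeasible geometry: target concentration denser than the slab",
         call. = FALSE)
  }
  # centre the dense slab at z = lz/2
  sys$positions[, 3] <- sys$positions[, 3] - sys$box[3] / 2 + lz / 2
  sys$box[3] <- lz
  sys$positions <- wrap_positions(sys$positions, sys$box)
  sys
}

#' Wrap coordinates into the primary periodic cell
#'
#' @param positions N x 3 matrix.
#' @param box box lengths `c(lx, ly, lz)`.
#' @return wrapped N x 3 matrix with every coordinate in \[0, box).
#' @export
wrap_positions <- function(positions, box) {
  for (d in 1:3) {
    positions[, d] <- positions[, d] - floor(positions[, d] / box[d]) * box[d]
  }
  positions
}
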