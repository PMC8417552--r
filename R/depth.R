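# Residue depth: distance to the nearest bulk water after explicit lattice
# solvation.  The structure is immersed in a randomly rotated and translated
# cubic water lattice; waters clashing with protein heavy atoms are removed,
# then non-bulk waters (too few water neighbours, e.g. trapped in cavities or
# grooves) are removed iteratively.  Atom depth is the distance to the nearest
# surviving water, averaged over several independent solvation cycles.

#' Depth computation parameters
#'
#' @param water_spacing Lattice spacing of the solvent box, in Angstrom.  The
#'   default 2.8 gives bulk-water-like density.
#' @param clash_distance Minimum allowed water-to-protein-heavy-atom distance
#'   (Angstrom); closer waters are removed.
#' @param bulk_neighbor_radius Radius (Angstrom) within which water neighbours
#'   are counted for the bulk criterion.
#' @param min_water_neighbors A kept water must have at least this many other
#'   waters within `bulk_neighbor_radius`; waters failing the criterion are
#'   removed iteratively until the set is stable.
#' @param n_cycles Number of independent solvation cycles averaged.
#' @param seed Base random seed; cycle `k` uses a seed derived from it, so the
#'   whole computation is deterministic.
#' @return A `cp_depth_params` list.
#' @export
depth_params <- function(water_spacing = 2.8, clash_distance = 2.6,
                         bulk_neighbor_radius = 4.2, min_water_neighbors = 2L,
                         n_cycles = 5L, seed = 17L) {
  stopifnot(water_spacing > 0, clash_distance > 0, bulk_neighbor_radius > 0,
            min_water_neighbors >= 0, n_cycles >= 1)
  structure(list(water_spacing = water_spacing,
                 clash_distance = clash_distance,
                 bulk_neighbor_radius = bulk_neighbor_radius,
                 min_water_neighbors = as.integer(min_water_neighbors),
                 n_cycles = as.integer(n_cycles),
                 seed = as.integer(seed)),
            class = "cp_depth_params")
}

# deterministic 3x3 rotation + in-cell translation from a seed
lattice_pose <- function(seed) {
  with_seed(seed, {
    M <- matrix(stats::rnorm(9), 3, 3)
    Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    list(rot = Q, shift = stats::runif(3))
  })
}

#' Solvate a structure with a bulk-water lattice
#'
#' Places a cubic lattice of candidate water positions around the protein,
#' randomly rotated and translated according to `cycle_seed`, removes waters
#' clashing with protein heavy atoms, and then iteratively removes non-bulk
#' waters until every kept water has at least `min_water_neighbors` water
#' neighbours within `bulk_neighbor_radius`.
#'
#' @param structure A `cp_structure`.
#' @param params A [depth_params()] object.
#' @param cycle_seed Integer seed for this solvation cycle.
#' @param model Model index.
#' @return Numeric matrix (n x 3) of surviving bulk-water coordinates.
#' @export
solvate <- function(structure, params = depth_params(), cycle_seed = params$seed,
                    model = 1L) {
  co <- model_coords(structure, model = model, heavy_only = TRUE)
  if (nrow(co) == 0L) stop("structure has no heavy atoms")
  pose <- lattice_pose(cycle_seed)
  # work in the rotated frame: rotate protein, lay an axis-aligned lattice
  pco <- co %*% pose$rot
  sp <- params$water_spacing
  margin <- 2 * params$bulk_neighbor_radius + 2 * sp
  lo <- apply(pco, 2, min) - margin
  hi <- apply(pco, 2, max) + margin
  # lattice anchored at the (shifted) origin of the rotated frame, not at
  # the bounding box, so enlarging a structure only extends the candidate
  # lattice and never moves existing lattice points
  ax <- lapply(1:3, function(k) {
    lo_k <- (floor(lo[k] / sp) - 1) * sp + pose$shift[k] * sp
    seq(lo_k, hi[k] + sp, by = sp)
  })
  waters <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  dimnames(waters) <- NULL

  # clash removal against protein heavy atoms
  keep <- .cp_min_dist(waters, pco) >= params$clash_distance
  waters <- waters[keep, , drop = FALSE]

  # iterative bulk filtering
  repeat {
    if (nrow(waters) == 0L) break
    counts <- .cp_neighbor_counts(waters, params$bulk_neighbor_radius)
    ok <- counts >= params$min_water_neighbors
    if (all(ok)) break
    waters <- waters[ok, , drop = FALSE]
  }
  # return in the original frame
  waters %*% t(pose$rot)
}

#' Compute atom and residue depths
#'
#' Atom depth is the distance (Angstrom) from the atom to the nearest bulk
#' water, averaged over `params$n_cycles` independent solvation cycles.
#' Residue depth is the arithmetic mean over the residue's heavy atoms.
#'
#' @param structure A `cp_structure`.
#' @param params A [depth_params()] object.
#' @param model Model index.
#' @return A `cp_depth` object: list with `atom_depth` (numeric vector
#'   aligned with the heavy-atom rows of the model; the `atoms` data frame
#'   has `key` and `elety` columns identifying them), `residues` (data frame
#'   `key`, `chain`, `resno`, `insert`, `aa`, `depth`, `zone`) and `params`.
#' @export
compute_depth <- function(structure, params = depth_params(), model = 1L) {
  a <- structure$atoms
  sel <- a$model == model & a$heavy
  if (!any(sel)) stop("structure has no heavy atoms")
  co <- as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
  acc <- numeric(nrow(co))
  for (k in seq_len(params$n_cycles)) {
    waters <- solvate(structure, params,
                      cycle_seed = params$seed + 7919L * (k - 1L),
                      model = model)
    acc <- acc + .cp_min_dist(co, waters)
  }
  atom_depth <- acc / params$n_cycles

  atoms <- a[sel, c("key", "chain", "resno", "insert", "aa", "elety"),
             drop = FALSE]
  atoms$depth <- atom_depth
  ukey <- unique(atoms$key)
  rdepth <- vapply(split(atom_depth, factor(atoms$key, levels = ukey)),
                   mean, numeric(1))
  ridx <- match(ukey, atoms$key)
  residues <- data.frame(
    key = ukey, chain = atoms$chain[ridx], resno = atoms$resno[ridx],
    insert = atoms$insert[ridx], aa = atoms$aa[ridx],
    depth = unname(rdepth), stringsAsFactors = FALSE)
  residues$zone <- depth_zone(residues$depth)
  rownames(residues) <- NULL
  structure(list(atoms = atoms, residues = residues, params = params,
                 model = model), class = "cp_depth")
}

#' @export
print.cp_depth <- function(x, ...) {
  cat(sprintf("<cp_depth> %d residues; depth %.2f-%.2f A; zones: %s\n",
              nrow(x$residues), min(x$residues$depth), max(x$residues$depth),
              paste(names(table(x$residues$zone)),
                    table(x$residues$zone), sep = "=", collapse = " ")))
  invisible(x)
}

#' Depth zone assignment
#'
#' Partitions residue depth into the three burial zones: exposed to solvent
#' (depth < 5 A), intermediate (5 A <= depth <= 8 A) and buried
#' (depth > 8 A).
#'
#' @param depth Numeric vector of residue depths (Angstrom), all positive.
#' @return Character vector: `"exposed"`, `"intermediate"` or `"buried"`.
#' @export
depth_zone <- function(depth) {
  if (any(!is.finite(depth) | depth <= 0))
    stop("depth must be positive and finite")
  ifelse(depth < 5, "exposed", ifelse(depth <= 8, "intermediate", "buried"))
}
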