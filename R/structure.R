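# Structure parsing and residue-level atom accounting.
#
# PDB I/O is delegated to bio3d; this layer applies the filtering rules the
# downstream geometry needs (altloc resolution, hydrogen flagging, HETATM and
# water removal, non-standard residue flagging) and exposes residue-level
# side-chain heavy-atom accounting.

res_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste(chain, resno, insert, sep = ":")
}

infer_heavy <- function(elesy, elety) {
  el <- toupper(ifelse(is.na(elesy) | elesy == "", NA, elesy))
  # fall back to the atom name when the element column is absent
  miss <- is.na(el)
  if (any(miss)) {
    nm <- gsub("[0-9']", "", toupper(elety[miss]))
    el[miss] <- ifelse(substr(nm, 1, 1) == "H", "H", substr(nm, 1, 1))
  }
  !(el %in% c("H", "D"))
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records into a `cp_structure` object.  HETATM records (ligands,
#' waters) are dropped; hydrogens are kept but flagged; alternate locations
#' are resolved by keeping the highest-occupancy altloc (ties resolved
#' alphabetically, so 'A' wins); residues with non-standard names are kept but
#' flagged non-standard and excluded from scoring.
#'
#' @param file Path to a PDB file (ATOM/MODEL/ENDMDL records).
#' @param model_policy `"first"` keeps only the first model, `"all"` keeps
#'   every model (multi-model NMR-style input).  All models must share the
#'   same residue identity sequence.
#' @param id Structure identifier; defaults to the file name.
#' @return A `cp_structure`: list with `id`, `atoms` (data frame with one row
#'   per atom per model: `model`, `chain`, `resno`, `insert`, `aa`, `resid`,
#'   `elety`, `x`, `y`, `z`, `heavy`, `side_chain`, `standard`), `residues`
#'   (per-residue accounting for one model: `key`, `chain`, `resno`, `insert`,
#'   `aa`, `standard`, `n_side_heavy`, `has_side_chain`), and `nmodels`.
#' @export
read_structure <- function(file, model_policy = c("first", "all"), id = NULL) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(file)) stop("no such file: ", file)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = (model_policy == "all"),
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error: ", conditionMessage(e)))
  build_structure(pdb, id = id %||% sub("\\.(pdb|ent)$", "", basename(file)),
                  model_policy = model_policy)
}

#' @rdname read_structure
#' @param text Character vector (or single string) of PDB-format text.
#' @export
parse_structure <- function(text, model_policy = c("first", "all"),
                            id = "structure") {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!any(grepl("^ATOM", text)))
    stop("PDB parse error: no ATOM records found")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(text, tf)
  read_structure(tf, model_policy = model_policy, id = id)
}

build_structure <- function(pdb, id, model_policy) {
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (!any(keep)) stop("PDB parse error: no ATOM records found")
  nmodels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_policy == "first") nmodels <- 1L

  at <- at[keep, , drop = FALSE]
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1L)
  # column indices of the kept atoms within the flat xyz vector
  ci <- as.vector(t(outer(which(keep) - 1L, 1:3, function(i, k) 3L * i + k)))

  per_model <- vector("list", nmodels)
  for (m in seq_len(nmodels)) {
    co <- matrix(xyz[m, ci], ncol = 3L, byrow = TRUE)
    df <- data.frame(
      model = m, chain = at$chain, resno = at$resno,
      insert = ifelse(is.na(at$insert), "", at$insert),
      resid = at$resid, elety = at$elety,
      elesy = if ("elesy" %in% names(at)) at$elesy else NA_character_,
      alt = ifelse(is.na(at$alt), "", at$alt),
      o = ifelse(is.na(at$o), 1, at$o),
      x = co[, 1], y = co[, 2], z = co[, 3],
      stringsAsFactors = FALSE)
    per_model[[m]] <- df
  }
  atoms <- do.call(rbind, per_model)

  # altloc resolution: within (model, residue, atom name) keep the
  # highest-occupancy record; ties go to the alphabetically first altloc
  atoms <- atoms[order(atoms$model, atoms$chain, atoms$resno, atoms$insert,
                       atoms$elety, -atoms$o, atoms$alt), , drop = FALSE]
  akey <- paste(atoms$model, atoms$chain, atoms$resno, atoms$insert,
                atoms$elety, sep = "\r")
  atoms <- atoms[!duplicated(akey), , drop = FALSE]

  atoms$aa <- unname(AA_THREE_TO_ONE[atoms$resid])
  atoms$standard <- !is.na(atoms$aa)
  if (any(!atoms$standard)) {
    bad <- unique(atoms$resid[!atoms$standard])
    warning("non-standard residue name(s) excluded from scoring: ",
            paste(bad, collapse = ", "))
  }
  atoms$heavy <- infer_heavy(atoms$elesy, atoms$elety)

  atoms$side_chain <- !(atoms$elety %in% BACKBONE_ATOMS)
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$insert)
  # restore file order within model
  atoms <- atoms[order(atoms$model, match(atoms$key, unique(atoms$key)),
                       atoms$elety), , drop = FALSE]
  rownames(atoms) <- NULL

  # per-residue accounting from model 1 (models must agree on identity)
  m1 <- atoms[atoms$model == 1L, , drop = FALSE]
  ukey <- unique(m1$key)
  ridx <- match(ukey, m1$key)
  residues <- data.frame(
    key = ukey, chain = m1$chain[ridx], resno = m1$resno[ridx],
    insert = m1$insert[ridx], aa = m1$aa[ridx],
    standard = m1$standard[ridx], stringsAsFactors = FALSE)
  residues$n_side_heavy <- vapply(ukey, function(k) {
    sum(m1$key == k & m1$heavy & m1$side_chain)
  }, integer(1))
  # glycine: CA stands in for the side chain
  gly_ca <- vapply(ukey, function(k) {
    any(m1$key == k & m1$elety == "CA")
  }, logical(1))
  is_gly <- !is.na(residues$aa) & residues$aa == "G"
  residues$n_side_heavy[is_gly] <- as.integer(gly_ca[is_gly])
  residues$has_side_chain <- residues$n_side_heavy > 0L
  if (any(residues$standard & !residues$has_side_chain))
    warning("residue(s) with no side-chain heavy atoms excluded from ",
            "contact graph: ",
            paste(residues$key[residues$standard & !residues$has_side_chain],
                  collapse = ", "))
  rownames(residues) <- NULL

  if (nmodels > 1L) {
    for (m in 2:nmodels) {
      mm <- atoms[atoms$model == m, , drop = FALSE]
      if (!identical(unique(mm$key), ukey))
        stop("models disagree on residue identity sequence")
    }
  }

  structure(list(id = id, atoms = atoms, residues = residues,
                 nmodels = nmodels), class = "cp_structure")
}

#' @export
print.cp_structure <- function(x, ...) {
  cat(sprintf("<cp_structure> %s: %d model(s), %d residue(s), %d atom(s)\n",
              x$id, x$nmodels, nrow(x$residues),
              sum(x$atoms$model == 1L)))
  invisible(x)
}

# atoms of one residue in one model, as a data frame
residue_atoms <- function(structure, key, model = 1L) {
  a <- structure$atoms
  a[a$model == model & a$key == key, , drop = FALSE]
}

#' Side-chain heavy atoms of a residue
#'
#' Returns the non-hydrogen atoms beyond the backbone (N, CA, C, O, OXT) of a
#' residue.  For glycine, the CA atom is returned in lieu of the side chain.
#'
#' @param structure A `cp_structure`.
#' @param chain,resno,insert Residue selection (author numbering).
#' @param model Model index (default 1).
#' @return Data frame of atom rows (subset of `structure$atoms`).
#' @export
side_chain_heavy_atoms <- function(structure, chain, resno, insert = "",
                                   model = 1L) {
  key <- res_key(chain, resno, insert)
  ra <- residue_atoms(structure, key, model)
  if (nrow(ra) == 0L) stop("no such residue: ", key)
  if (!ra$standard[1]) stop("residue ", key, " is non-standard")
  if (ra$aa[1] == "G") {
    out <- ra[ra$elety == "CA", , drop = FALSE]
  } else {
    out <- ra[ra$side_chain & ra$heavy, , drop = FALSE]
  }
  out
}

#' Chain sequence of a structure
#'
#' @param structure A `cp_structure`.
#' @param chain Chain identifier.
#' @return One-letter amino-acid string in residue order ('X' for
#'   non-standard residues).
#' @export
chain_sequence <- function(structure, chain) {
  r <- structure$residues[structure$residues$chain == chain, , drop = FALSE]
  if (nrow(r) == 0L) stop("no such chain: ", chain)
  paste(ifelse(is.na(r$aa), "X", r$aa), collapse = "")
}

#' Write a structure back to PDB format
#'
#' Writes one model of a `cp_structure` as PDB ATOM records via
#' [bio3d::write.pdb()].
#'
#' @param structure A `cp_structure`.
#' @param file Output path.
#' @param model Model index to write.
#' @export
write_structure <- function(structure, file, model = 1L) {
  a <- structure$atoms[structure$atoms$model == model, , drop = FALSE]
  if (nrow(a) == 0L) stop("no such model: ", model)
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   elety = a$elety, o = a$o)
  invisible(file)
}

# coordinate matrix for a model (optionally heavy atoms / standard residues)
model_coords <- function(structure, model = 1L, heavy_only = TRUE,
                         standard_only = FALSE) {
  a <- structure$atoms
  sel <- a$model == model
  if (heavy_only) sel <- sel & a$heavy
  if (standard_only) sel <- sel & a$standard
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}
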