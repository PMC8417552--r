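# Depth-stratified amino-acid substitution matrices.
#
# A matrix set holds one 20x20 likelihood table per burial region (exposed /
# intermediate / buried); lookups route through the depth-zone rule shared
# with the depth module.  Matrices are directional (wild-type row, mutant
# column) and are not required to be symmetric.  The file format is a plain
# TSV with one header line per region block.

SUBST_REGIONS <- c("exposed", "intermediate", "buried")

#' Construct a substitution matrix set
#'
#' @param exposed,intermediate,buried 20x20 numeric matrices with the 20
#'   standard amino acids (one-letter codes) as row and column names; rows
#'   are the wild-type amino acid, columns the mutant.
#' @param name Free-text name stored as metadata.
#' @return A `cp_subst` object.
#' @export
substitution_matrix_set <- function(exposed, intermediate, buried,
                                    name = "unnamed") {
  tabs <- list(exposed = exposed, intermediate = intermediate,
               buried = buried)
  for (r in SUBST_REGIONS) {
    m <- tabs[[r]]
    if (!is.matrix(m) || !identical(dim(m), c(20L, 20L)))
      stop("region '", r, "' must be a 20x20 matrix")
    if (!identical(rownames(m), AA_CODES) ||
        !identical(colnames(m), AA_CODES))
      stop("region '", r, "' must have the 20 amino acids (alphabetical) ",
           "as row and column names")
    if (any(!is.finite(m)))
      stop("region '", r, "' contains non-finite entries")
  }
  structure(list(tables = tabs, name = name), class = "cp_subst")
}

#' @export
print.cp_subst <- function(x, ...) {
  cat(sprintf("<cp_subst> '%s': 3 regions x 20x20\n", x$name))
  invisible(x)
}

#' Write / read a substitution matrix set
#'
#' TSV schema: a `# cliquepred-substitution-matrices v1` header, a
#' `# name: ...` line, then for each region a `# region: <name>` line, a
#' header row `wt<TAB>A<TAB>C...` and 20 data rows.
#'
#' @param set A `cp_subst` object.
#' @param path File path.
#' @return `read_matrix_set` returns a validated `cp_subst`.
#' @export
write_matrix_set <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cliquepred-substitution-matrices v1",
               paste0("# name: ", set$name)), con)
  for (r in SUBST_REGIONS) {
    writeLines(paste0("# region: ", r), con)
    writeLines(paste(c("wt", AA_CODES), collapse = "\t"), con)
    m <- set$tables[[r]]
    for (i in seq_len(20)) {
      writeLines(paste(c(AA_CODES[i],
                         formatC(m[i, ], format = "g", digits = 10)),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_matrix_set
#' @export
read_matrix_set <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# cliquepred-substitution-matrices", lines[1]))
    stop("not a cliquepred substitution matrix file: ", path)
  name <- sub("^# name: ", "", grep("^# name: ", lines, value = TRUE)[1])
  if (is.na(name)) name <- "unnamed"
  tabs <- list()
  region_at <- grep("^# region: ", lines)
  if (length(region_at) == 0L) stop("no region blocks found")
  for (k in seq_along(region_at)) {
    r <- sub("^# region: ", "", lines[region_at[k]])
    if (!r %in% SUBST_REGIONS) stop("unknown region '", r, "'")
    hdr <- strsplit(lines[region_at[k] + 1L], "\t")[[1]]
    if (!identical(hdr, c("wt", AA_CODES)))
      stop("region '", r, "': bad header row")
    block <- lines[(region_at[k] + 2L):(region_at[k] + 21L)]
    m <- matrix(NA_real_, 20, 20, dimnames = list(AA_CODES, AA_CODES))
    for (ln in block) {
      f <- strsplit(ln, "\t")[[1]]
      if (length(f) != 21L)
        stop("region '", r, "', row '", f[1], "': expected 20 values, got ",
             length(f) - 1L)
      m[f[1], ] <- as.numeric(f[-1])
    }
    if (any(is.na(m))) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("region '", r, "': missing cell (", AA_CODES[bad[1]], ", ",
           AA_CODES[bad[2]], ")")
    }
    tabs[[r]] <- m
  }
  missing_r <- setdiff(SUBST_REGIONS, names(tabs))
  if (length(missing_r))
    stop("missing region block(s): ", paste(missing_r, collapse = ", "))
  substitution_matrix_set(tabs$exposed, tabs$intermediate, tabs$buried,
                          name = name)
}

#' Depth-routed substitution score
#'
#' Looks up the wild-type to mutant substitution likelihood in the matrix of
#' the burial region selected by [depth_zone()] (exposed < 5 A,
#' intermediate 5-8 A, buried > 8 A).
#'
#' @param set A `cp_subst` object.
#' @param wt,mut Wild-type and mutant amino acids (one-letter codes).
#' @param residue_depth Residue depth in Angstrom (> 0).
#' @return Numeric score (vectorised over wt/mut/depth).
#' @export
substitution_score <- function(set, wt, mut, residue_depth) {
  if (any(!wt %in% AA_CODES) || any(!mut %in% AA_CODES))
    stop("wt and mut must be standard amino acids")
  zone <- depth_zone(residue_depth)
  n <- max(length(wt), length(mut), length(zone))
  wt <- rep_len(wt, n); mut <- rep_len(mut, n); zone <- rep_len(zone, n)
  vapply(seq_len(n), function(i) set$tables[[zone[i]]][wt[i], mut[i]],
         numeric(1))
}

#' Synthetic substitution matrix set
#'
#' Generates a deterministic, clearly synthetic matrix set for testing and
#' examples: identity substitutions score highest, substitutions within a
#' physicochemical group score mildly positive, cross-group substitutions
#' negative, with the penalty growing from the exposed to the buried region
#' (buried substitutions are less tolerated).  These are stand-in values,
#' not likelihoods estimated from structural alignments.
#'
#' @param seed Seed for the small deterministic jitter.
#' @param jitter Amplitude of the jitter added to each cell.
#' @return A `cp_subst` object named `"synthetic-v1"`.
#' @export
synthetic_matrix_set <- function(seed = 1L, jitter = 0.1) {
  groups <- list(hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C"),
                 polar = c("S", "T", "N", "Q", "Y", "G"),
                 positive = c("K", "R", "H"),
                 negative = c("D", "E"),
                 special = "P")
  grp <- stats::setNames(rep(names(groups), lengths(groups)),
                         unlist(groups))[AA_CODES]
  with_seed(seed, {
    mk <- function(penalty) {
      m <- matrix(0, 20, 20, dimnames = list(AA_CODES, AA_CODES))
      same_grp <- outer(grp, grp, "==")
      m[] <- ifelse(same_grp, 0.5, -penalty)
      diag(m) <- 2
      m + matrix(stats::runif(400, -jitter, jitter), 20, 20)
    }
    substitution_matrix_set(mk(1.0), mk(1.5), mk(2.0),
                            name = "synthetic-v1")
  })
}
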