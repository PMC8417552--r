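# Depth-stratified clique statistical potential.
#
# Observed clique-composition counts are collected from a structure corpus at
# five (overlapping) depth strata; expected counts come from a quasi-chemical
# reference state (composition-multinomial under corpus amino-acid
# frequencies, per stratum); the pseudo-energy is the Sippl-style log ratio
#   E^c = kT * log((P_obs + alpha * P_exp) / (P_exp + alpha * P_exp)),
# with natural log, alpha = 0 and kT = +1 by default, so positive E means an
# enriched (favourably packed) composition.  A clique is scored by Gaussian
# re-weighting of the stratum energies around its depth mean and sd.

#' Depth strata for the potential
#'
#' The five depth levels at which the potential is built:
#' 2.80-5.25, 4.25-6.25, 5.25-7.25, 6.25-8.25 and 7.25-Inf Angstrom.  The
#' levels deliberately overlap; a clique is counted in every stratum whose
#' half-open interval `[d_i, d_f)` contains its depth mean.  The unbounded
#' last stratum uses an effective width (default 2.0 A, matching the other
#' strata) for the `1/(d_f - d_i)` normaliser of the clique score.
#'
#' @param d_i,d_f Lower/upper bounds (Angstrom) of each level.
#' @param last_width Effective width of the unbounded last level.
#' @return A `cp_strata` data frame with columns `d_i`, `d_f`, `width`.
#' @export
depth_strata <- function(d_i = c(2.80, 4.25, 5.25, 6.25, 7.25),
                         d_f = c(5.25, 6.25, 7.25, 8.25, Inf),
                         last_width = 2.0) {
  stopifnot(length(d_i) == length(d_f), all(d_i < d_f))
  width <- d_f - d_i
  width[!is.finite(width)] <- last_width
  structure(data.frame(d_i = d_i, d_f = d_f, width = width),
            class = c("cp_strata", "data.frame"))
}

# indices of strata whose [d_i, d_f) interval contains mu
strata_containing <- function(mu, strata) {
  which(mu >= strata$d_i & mu < strata$d_f)
}

#' Count clique compositions over a structure corpus
#'
#' Enumerates (N, d_cut) cliques in every model of every corpus structure,
#' computes each clique's depth mean, and adds a count of one to every depth
#' stratum containing that mean.  Multi-model structures contribute each
#' model with weight one.  Corpus amino-acid counts (over standard residues,
#' per model) are accumulated for the reference state.
#'
#' @param corpus List of `cp_structure` objects.
#' @param params A [clique_params()] object.
#' @param depth_params A [depth_params()] object.
#' @param strata A [depth_strata()] object.
#' @return List: `observed` (matrix, composition x stratum), `totals`
#'   (per-stratum clique counts), `aa_counts` (named vector over the 20
#'   amino acids), `n_structures`, `n_models`.
#' @export
count_cliques <- function(corpus, params = clique_params(),
                          depth_params = cliquepred::depth_params(),
                          strata = depth_strata()) {
  if (length(corpus) == 0L) stop("corpus is empty")
  nlev <- nrow(strata)
  obs <- list()
  aa_counts <- stats::setNames(numeric(length(AA_CODES)), AA_CODES)
  n_models <- 0L
  for (s in corpus) {
    for (m in seq_len(s$nmodels)) {
      n_models <- n_models + 1L
      cl <- tryCatch(
        find_residue_cliques(s, params, depth_params = depth_params,
                             model = m),
        error = function(e) NULL)
      res <- s$residues[s$residues$standard, , drop = FALSE]
      tab <- table(res$aa)
      aa_counts[names(tab)] <- aa_counts[names(tab)] + as.numeric(tab)
      if (is.null(cl) || nrow(cl) == 0L) {
        warning("structure ", s$id, " model ", m, " contributed no cliques")
        next
      }
      for (i in seq_len(nrow(cl))) {
        lev <- strata_containing(cl$mu[i], strata)
        comp <- cl$composition[i]
        if (is.null(obs[[comp]])) obs[[comp]] <- numeric(nlev)
        obs[[comp]][lev] <- obs[[comp]][lev] + 1
      }
    }
  }
  observed <- do.call(rbind, obs)
  if (is.null(observed)) stop("no cliques found anywhere in the corpus")
  rownames(observed) <- names(obs)
  observed <- observed[order(rownames(observed)), , drop = FALSE]
  colnames(observed) <- paste0("L", seq_len(nlev))
  list(observed = observed, totals = colSums(observed),
       aa_counts = aa_counts, n_structures = length(corpus),
       n_models = n_models)
}

#' Expected clique count under the reference state
#'
#' Multinomial reference: for a composition `c = {r_1, ..., r_N}` with
#' multiplicities `m_1, ..., m_k`, the expected count in a stratum with total
#' clique count `T` is `T * N! / (m_1! ... m_k!) * prod(f(r_i))`, where `f`
#' are the corpus amino-acid frequencies.
#'
#' @param composition Composition string (sorted amino-acid letters, e.g.
#'   `"AAW"`).
#' @param total Total clique count of the stratum.
#' @param aa_freq Named frequency vector over the 20 amino acids, summing
#'   to 1.
#' @return Expected count (numeric).
#' @export
expected_count <- function(composition, total, aa_freq) {
  if (abs(sum(aa_freq) - 1) > 1e-8) stop("aa_freq must sum to 1")
  letters <- strsplit(composition, "")[[1]]
  if (!all(letters %in% AA_CODES)) stop("bad composition: ", composition)
  mult <- table(letters)
  coef <- factorial(length(letters)) / prod(factorial(mult))
  total * coef * prod(aa_freq[letters])
}

#' Sippl-style clique pseudo-energy
#'
#' `E = kT * log((obs + alpha * exp) / (exp + alpha * exp))` (natural log).
#' With `alpha = 0` and `obs = 0` the ratio degenerates; such entries are
#' floored at `floor` and flagged by the caller.
#'
#' @param obs,exp Observed and expected counts (`exp > 0`).
#' @param alpha Pseudo-count ratio (default 0).
#' @param kT Energy prefactor (default +1: positive E = enriched/favourable).
#' @param floor Value used when `alpha = 0` and `obs = 0`.
#' @return Energy (vectorised over `obs`/`exp`).
#' @export
clique_energy <- function(obs, exp, alpha = 0, kT = 1, floor = -Inf) {
  if (any(exp <= 0)) stop("expected count must be > 0")
  e <- kT * log((obs + alpha * exp) / (exp + alpha * exp))
  e[!is.finite(e)] <- floor
  e
}

#' Build the potential from observed counts
#'
#' @param counts Output of [count_cliques()] (or a compatible list with
#'   `observed` and optionally `aa_counts`).
#' @param aa_freq Amino-acid frequencies; derived from `counts$aa_counts`
#'   when NULL.
#' @param params,strata Clique parameters and depth strata stored with the
#'   table.
#' @param alpha Pseudo-count ratio of the energy formula.
#' @param kT Energy prefactor.
#' @param floor Energy assigned to unobserved compositions when `alpha = 0`;
#'   defaults to (minimum finite energy - 1), which keeps scores finite while
#'   preserving their ordering.
#' @return A `cp_potential` object.
#' @export
potential_from_counts <- function(counts, aa_freq = NULL,
                                  params = clique_params(),
                                  strata = depth_strata(),
                                  alpha = 0, kT = 1, floor = NULL) {
  observed <- counts$observed
  if (is.null(aa_freq)) {
    ac <- counts$aa_counts
    if (sum(ac) == 0) stop("empty amino-acid counts")
    aa_freq <- ac / sum(ac)
  }
  aa_freq <- aa_freq[AA_CODES]
  aa_freq[is.na(aa_freq)] <- 0
  names(aa_freq) <- AA_CODES
  totals <- colSums(observed)
  expected <- observed * 0
  for (comp in rownames(observed)) {
    for (l in seq_along(totals)) {
      if (totals[l] > 0)
        expected[comp, l] <- expected_count(comp, totals[l], aa_freq)
    }
  }
  ok <- expected > 0
  energies <- observed * NA_real_
  energies[ok] <- clique_energy(observed[ok], expected[ok], alpha, kT,
                                floor = -Inf)
  finite <- energies[is.finite(energies)]
  if (length(finite) == 0L) stop("no finite energies; corpus too small")
  if (is.null(floor)) floor <- min(finite) - 1
  floored <- is.finite(energies) & FALSE
  floored[!is.finite(energies) | is.na(energies)] <- TRUE
  energies[!is.finite(energies) | is.na(energies)] <- floor
  structure(list(params = params, strata = strata, observed = observed,
                 expected = expected, energies = energies,
                 floored = floored, totals = totals, aa_freq = aa_freq,
                 alpha = alpha, kT = kT, floor = floor),
            class = "cp_potential")
}

#' Build the clique statistical potential from a corpus
#'
#' @inheritParams count_cliques
#' @inheritParams potential_from_counts
#' @return A `cp_potential` object.
#' @export
build_potential <- function(corpus, params = clique_params(),
                            depth_params = cliquepred::depth_params(),
                            strata = depth_strata(), alpha = 0, kT = 1,
                            floor = NULL) {
  counts <- count_cliques(corpus, params, depth_params, strata)
  potential_from_counts(counts, params = params, strata = strata,
                        alpha = alpha, kT = kT, floor = floor)
}

#' @export
print.cp_potential <- function(x, ...) {
  cat(sprintf(
    "<cp_potential> N=%d d_cut=%.1f A; %d compositions x %d strata; floor=%.3f\n",
    x$params$N, x$params$d_cut, nrow(x$energies), ncol(x$energies), x$floor))
  invisible(x)
}

row_list <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))

# energy of a composition at one stratum (floor when unknown)
energy_lookup <- function(potential, composition, level) {
  if (composition %in% rownames(potential$energies)) {
    potential$energies[composition, level]
  } else {
    potential$floor
  }
}

#' Score a clique under the potential
#'
#' The clique score is the weighted sum over depth levels of the level energy
#' times the Gaussian mass of the clique's depth distribution in that level:
#' `S = sum_l E_l(c) / (d_f - d_i) * integral_{d_i}^{d_f} N(x | mu, sigma) dx`.
#' The Gaussian integral is a normal-CDF difference; `sigma = 0` is treated
#' as a point mass at `mu` (with the same half-open `[d_i, d_f)` containment
#' convention as stratum counting); the unbounded last level integrates to
#' infinity via the survival function and uses its effective width.
#'
#' @param potential A `cp_potential`.
#' @param composition Composition string; compositions absent from the table
#'   use the floor energy (flagged in the `"floored"` attribute).
#' @param mu,sigma Depth mean and standard deviation of the clique (A).
#' @return Numeric score, with attribute `floored` (TRUE when any level used
#'   the floor energy).
#' @export
clique_score <- function(potential, composition, mu, sigma) {
  stopifnot(sigma >= 0)
  st <- potential$strata
  s <- 0
  floored_any <- FALSE
  for (l in seq_len(nrow(st))) {
    if (sigma > 0) {
      hi <- if (is.finite(st$d_f[l])) stats::pnorm(st$d_f[l], mu, sigma) else 1
      mass <- hi - stats::pnorm(st$d_i[l], mu, sigma)
    } else {
      mass <- as.numeric(mu >= st$d_i[l] && mu < st$d_f[l])
    }
    if (mass == 0) next
    e <- energy_lookup(potential, composition, l)
    if (!(composition %in% rownames(potential$energies)) ||
        isTRUE(potential$floored[composition, l])) floored_any <- TRUE
    s <- s + e * mass / st$width[l]
  }
  attr(s, "floored") <- floored_any
  s
}

#' Score every residue of a structure
#'
#' Scores each clique of the structure under the potential; the score of a
#' residue is the mean over all cliques it participates in, and the protein
#' score is the mean over residue scores.
#'
#' @param structure A `cp_structure`.
#' @param potential A `cp_potential`.
#' @param depth Optional precomputed `cp_depth`.
#' @param depth_params Used when `depth` is NULL.
#' @param model Model index.
#' @return List: `cliques` (clique table with `score` column), `residues`
#'   (data frame `key`, `aa`, `n_cliques`, `score`; residues in no clique
#'   have `NA` score), `protein_score`, `depth`.
#' @export
score_structure <- function(structure, potential, depth = NULL,
                            depth_params = cliquepred::depth_params(),
                            model = 1L) {
  if (is.null(depth)) depth <- compute_depth(structure, depth_params, model)
  cl <- find_residue_cliques(structure, potential$params, depth = depth,
                             model = model)
  if (nrow(cl)) {
    cl$score <- vapply(seq_len(nrow(cl)), function(i) {
      as.numeric(clique_score(potential, cl$composition[i], cl$mu[i],
                              cl$sigma[i]))
    }, numeric(1))
  } else cl$score <- numeric(0)

  res <- structure$residues[structure$residues$standard, , drop = FALSE]
  rsc <- vapply(res$key, function(k) {
    idx <- vapply(cl$members, function(m) k %in% m, logical(1))
    if (!any(idx)) return(NA_real_)
    mean(cl$score[idx])
  }, numeric(1))
  ncl <- vapply(res$key, function(k) {
    sum(vapply(cl$members, function(m) k %in% m, logical(1)))
  }, numeric(1))
  residues <- data.frame(key = res$key, aa = res$aa,
                         n_cliques = as.integer(ncl),
                         score = unname(rsc), stringsAsFactors = FALSE)
  list(cliques = cl, residues = residues,
       protein_score = mean(rsc, na.rm = TRUE), depth = depth)
}

#' Residue clique score
#'
#' @param scored Output of [score_structure()].
#' @param key Residue key.
#' @return Mean clique score of the residue (`NA` if it is in no clique).
#' @export
residue_score <- function(scored, key) {
  i <- match(key, scored$residues$key)
  if (is.na(i)) stop("no such residue: ", key)
  scored$residues$score[i]
}

#' Protein clique score
#'
#' @param scored Output of [score_structure()].
#' @return Mean over residue scores.
#' @export
protein_score <- function(scored) scored$protein_score

#' Serialise / load a potential
#'
#' JSON round-trip of the full table (parameters, strata, observed and
#' expected counts, energies, frequencies), with deterministic ordering.
#'
#' @param potential A `cp_potential`.
#' @param path Output / input path.
#' @return `read_potential` returns a `cp_potential`.
#' @export
write_potential <- function(potential, path) {
  obj <- list(
    format = "cliquepred-potential-v1",
    params = list(N = potential$params$N, d_cut = potential$params$d_cut),
    strata = list(d_i = potential$strata$d_i, d_f = potential$strata$d_f,
                  width = potential$strata$width),
    alpha = potential$alpha, kT = potential$kT, floor = potential$floor,
    aa_freq = as.list(potential$aa_freq),
    totals = as.numeric(potential$totals),
    compositions = rownames(potential$observed),
    observed = row_list(potential$observed),
    expected = row_list(potential$expected),
    energies = row_list(potential$energies),
    floored = row_list(potential$floored))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cliquepred-potential-v1"))
    stop("not a cliquepred potential file: ", path)
  strata <- depth_strata(d_i = obj$strata$d_i,
                         d_f = ifelse(is.na(obj$strata$d_f), Inf,
                                      obj$strata$d_f))
  strata$width <- obj$strata$width
  comp <- obj$compositions
  nlev <- nrow(strata)
  mk <- function(x, mode = "double") {
    m <- if (is.list(x)) do.call(rbind, x) else as.matrix(x)
    storage.mode(m) <- mode
    dimnames(m) <- list(comp, paste0("L", seq_len(nlev)))
    m
  }
  structure(list(params = clique_params(obj$params$N, obj$params$d_cut),
                 strata = strata, observed = mk(obj$observed),
                 expected = mk(obj$expected), energies = mk(obj$energies),
                 floored = mk(obj$floored, "logical"),
                 totals = stats::setNames(obj$totals,
                                          paste0("L", seq_len(nlev))),
                 aa_freq = unlist(obj$aa_freq), alpha = obj$alpha,
                 kT = obj$kT, floor = obj$floor),
            class = "cp_potential")
}
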