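# Combined mutation-effect score and classification.
#
# For a mutation the three components are: S, the clique statistical
# potential score of the mutant residue (the mutation is introduced by
# swapping the amino-acid type inside every clique containing the position,
# with the mutant inheriting the wild-type residue's geometry and depths);
# H, the positional Shannon entropy; and F, the depth-routed substitution
# likelihood.  The combined score is the trained linear combination
# PS = w_S * S + w_H * H + w_F * F, and a mutation is called neutral when
# PS exceeds the trained threshold, destabilizing otherwise.

#' Score weights and classification threshold
#'
#' Defaults are the trained values: `w_S = 1.5`, `w_H = 1.75`, `w_F = 0.5`,
#' threshold `1.6`.
#'
#' @param w_s,w_h,w_f Coefficients of the clique-potential, entropy and
#'   substitution components.
#' @param threshold Classification cut-off: scores strictly above it are
#'   neutral.
#' @return A `cp_weights` list.
#' @export
score_weights <- function(w_s = 1.5, w_h = 1.75, w_f = 0.5,
                          threshold = 1.6) {
  stopifnot(is.finite(w_s), is.finite(w_h), is.finite(w_f),
            is.finite(threshold))
  structure(list(w_s = w_s, w_h = w_h, w_f = w_f, threshold = threshold),
            class = "cp_weights")
}

#' Combined score
#'
#' `PS = w_S * S + w_H * H + w_F * F` (exact weighted sum, vectorised).
#'
#' @param S,H,F Component scores.
#' @param weights A [score_weights()] object.
#' @return Numeric combined score.
#' @export
combined_score <- function(S, H, F, weights = score_weights()) {
  weights$w_s * S + weights$w_h * H + weights$w_f * F
}

#' Classify a combined score
#'
#' Scores strictly greater than the threshold are neutral; scores less than
#' or equal to it (including the boundary) are destabilizing.
#'
#' @param PS Combined score (finite, vectorised).
#' @param threshold Cut-off (default 1.6).
#' @return Character vector: `"neutral"` or `"destabilizing"`.
#' @export
classify_score <- function(PS, threshold = 1.6) {
  if (any(!is.finite(PS))) stop("PS must be finite")
  ifelse(PS > threshold, "neutral", "destabilizing")
}

#' Read a mutation list
#'
#' TSV with a required header and columns `chain`, `position`, `wt`, `mut`
#' (author residue numbering; one-letter amino-acid codes).
#'
#' @param path File path.
#' @return Data frame of mutations.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("chain", "position", "wt", "mut")
  if (!all(need %in% names(df)))
    stop("mutation file must have header columns: ",
         paste(need, collapse = ", "))
  df$position <- as.integer(df$position)
  df$wt <- toupper(df$wt)
  df$mut <- toupper(df$mut)
  df
}

# mutant residue score: mean clique score over the same geometric cliques
# with the position's amino acid replaced (depths and (mu, sigma) unchanged)
mutant_residue_score_at <- function(scored, potential, key, wt, mut,
                                    s_mode = "mutant") {
  cl <- scored$cliques
  idx <- which(vapply(cl$members, function(m) key %in% m, logical(1)))
  if (length(idx) == 0L)
    return(list(S = 0, flags = "no_clique"))
  flags <- character(0)
  mut_scores <- vapply(idx, function(i) {
    comp <- cl$composition[i]
    letters <- strsplit(comp, "")[[1]]
    # replace one occurrence of the wild-type amino acid
    pos <- match(wt, letters)
    letters[pos] <- mut
    newcomp <- paste(sort(letters), collapse = "")
    s <- clique_score(potential, newcomp, cl$mu[i], cl$sigma[i])
    if (isTRUE(attr(s, "floored"))) flags <<- union(flags, "floored_energy")
    as.numeric(s)
  }, numeric(1))
  S <- mean(mut_scores)
  if (s_mode == "delta") S <- S - mean(cl$score[idx])
  list(S = S, flags = flags)
}

#' Mutant residue clique score
#'
#' Recomputes the residue clique score with the mutation's position carrying
#' the mutant amino-acid type in every clique it participates in; the clique
#' geometry, atom depths and (mu, sigma) are those of the wild-type
#' structure (the mutant inherits all properties of the wild-type residue).
#'
#' @param scored Output of [score_structure()].
#' @param potential The `cp_potential` used for scoring.
#' @param chain,position,insert Residue selection (author numbering).
#' @param mut Mutant amino acid.
#' @param s_mode `"mutant"` (default) returns the mutant's absolute score;
#'   `"delta"` returns mutant minus wild-type.
#' @return Numeric score with attribute `flags` (e.g. `"no_clique"`, in
#'   which case the score falls back to 0, or `"floored_energy"`).
#' @export
mutant_residue_score <- function(scored, potential, chain, position, mut,
                                 insert = "", s_mode = c("mutant", "delta")) {
  s_mode <- match.arg(s_mode)
  key <- res_key(chain, position, insert)
  i <- match(key, scored$residues$key)
  if (is.na(i)) stop("no such residue: ", key)
  wt <- scored$residues$aa[i]
  out <- mutant_residue_score_at(scored, potential, key, wt, mut, s_mode)
  structure(out$S, flags = out$flags)
}

#' Predict the effect of a mutation list
#'
#' Runs the full pipeline for a batch of mutations on one structure: residue
#' depth, contact graph and clique enumeration, clique-potential scoring of
#' each mutant composition, positional entropy, and the depth-routed
#' substitution score, combined with the trained weights.  Failures are
#' reported per row (in the `error` column), never fatally.
#'
#' @param structure A `cp_structure`.
#' @param potential A `cp_potential`.
#' @param mutations Data frame with columns `chain`, `position`, `wt`,
#'   `mut` (and optional `insert`), as from [read_mutations()].
#' @param msa Optional `cp_msa`; without it H is 0 and flagged `no_msa`.
#' @param matrices Optional `cp_subst`; without it F is 0 and flagged
#'   `no_matrix`.
#' @param weights A [score_weights()] object.
#' @param depth_params,model Passed to [compute_depth()].
#' @param msa_query,msa_mapping Passed to [map_entropy_to_structure()].
#' @param s_mode Convention for S, see [mutant_residue_score()].
#' @return A `cp_predictions` data frame: one row per mutation with `S`,
#'   `H`, `F`, `PS`, `call`, `depth`, `zone`, `flags`, `error`.
#' @export
predict_mutations <- function(structure, potential, mutations, msa = NULL,
                              matrices = NULL, weights = score_weights(),
                              depth_params = cliquepred::depth_params(),
                              model = 1L, msa_query = 1L, msa_mapping = NULL,
                              s_mode = c("mutant", "delta")) {
  s_mode <- match.arg(s_mode)
  if (!all(c("chain", "position", "wt", "mut") %in% names(mutations)))
    stop("mutations must have columns chain, position, wt, mut")
  n <- nrow(mutations)
  out <- cbind(as.data.frame(mutations, stringsAsFactors = FALSE),
               data.frame(S = rep(NA_real_, n), H = rep(NA_real_, n),
                          F = rep(NA_real_, n), PS = rep(NA_real_, n),
                          call = rep(NA_character_, n),
                          depth = rep(NA_real_, n),
                          zone = rep(NA_character_, n),
                          flags = rep("", n),
                          error = rep(NA_character_, n),
                          stringsAsFactors = FALSE))
  if (n == 0L) {
    class(out) <- c("cp_predictions", "data.frame")
    return(out)
  }
  ins <- if ("insert" %in% names(mutations)) mutations$insert else
    rep("", n)

  depth <- compute_depth(structure, depth_params, model)
  scored <- score_structure(structure, potential, depth = depth,
                            model = model)
  entropy <- NULL
  if (!is.null(msa)) {
    ent_by_chain <- list()
  }

  for (i in seq_len(n)) {
    chain <- mutations$chain[i]
    key <- res_key(chain, mutations$position[i], ins[i])
    ri <- match(key, structure$residues$key)
    if (is.na(ri)) {
      out$error[i] <- paste0("no residue ", key, " in structure")
      next
    }
    wt_actual <- structure$residues$aa[ri]
    if (is.na(wt_actual)) {
      out$error[i] <- paste0("residue ", key, " is non-standard")
      next
    }
    if (wt_actual != mutations$wt[i]) {
      out$error[i] <- sprintf("expected %s at position %s, found %s",
                              mutations$wt[i], key, wt_actual)
      next
    }
    if (!mutations$mut[i] %in% AA_CODES) {
      out$error[i] <- paste0("mutant '", mutations$mut[i],
                             "' is not a standard amino acid")
      next
    }
    if (mutations$mut[i] == mutations$wt[i]) {
      out$error[i] <- "wt and mut are identical"
      next
    }
    flags <- character(0)

    di <- match(key, depth$residues$key)
    d <- depth$residues$depth[di]
    out$depth[i] <- d
    out$zone[i] <- depth$residues$zone[di]

    sres <- mutant_residue_score_at(scored, potential, key, wt_actual,
                                    mutations$mut[i], s_mode)
    out$S[i] <- sres$S
    flags <- union(flags, sres$flags)

    if (is.null(msa)) {
      out$H[i] <- 0
      flags <- union(flags, "no_msa")
    } else {
      if (is.null(ent_by_chain[[chain]])) {
        ent_by_chain[[chain]] <- map_entropy_to_structure(
          msa, structure, chain, query = msa_query, mapping = msa_mapping)
      }
      ei <- match(key, ent_by_chain[[chain]]$key)
      h <- ent_by_chain[[chain]]$H[ei]
      if (is.na(h)) {
        out$H[i] <- 0
        flags <- union(flags, "no_msa_column")
      } else out$H[i] <- h
    }

    if (is.null(matrices)) {
      out$F[i] <- 0
      flags <- union(flags, "no_matrix")
    } else {
      out$F[i] <- substitution_score(matrices, wt_actual, mutations$mut[i], d)
    }

    out$PS[i] <- combined_score(out$S[i], out$H[i], out$F[i], weights)
    out$call[i] <- classify_score(out$PS[i], weights$threshold)
    out$flags[i] <- paste(flags, collapse = ";")
  }
  class(out) <- c("cp_predictions", "data.frame")
  attr(out, "weights") <- weights
  out
}

#' @export
print.cp_predictions <- function(x, ...) {
  ok <- sum(is.na(x$error))
  cat(sprintf("<cp_predictions> %d mutation(s), %d scored, %d error(s)\n",
              nrow(x), ok, nrow(x) - ok))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  invisible(x)
}
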