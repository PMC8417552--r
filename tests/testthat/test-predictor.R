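# shared pipeline fixture: one structure, a small corpus potential, an MSA
# over the structure's sequence, and the synthetic matrix set
local_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    s <- parse_structure(make_structure(25, "globule", seed = 91))
    corpus <- lapply(make_corpus(4, n_residues = 22, seed = 101),
                     parse_structure)
    pot <- build_potential(corpus, clique_params(3, 8.0), fast_depth())
    msa <- msa_from_sequences(
      make_msa(consensus = chain_sequence(s, "A"), conservation = 0.8,
               n_seqs = 60, seed = 111)[c(FALSE, TRUE)])
    set <- synthetic_matrix_set(seed = 3)
    cache <<- list(s = s, pot = pot, msa = msa, set = set)
    cache
  }
})

test_that("the combined score is the exact weighted sum with trained defaults", {
  w <- score_weights()
  expect_equal(unlist(w), c(w_s = 1.5, w_h = 1.75, w_f = 0.5,
                            threshold = 1.6))
  expect_equal(combined_score(0, 0, 0, w), 0)
  expect_equal(combined_score(1, 0.4, 0.5, w), 2.45)
  expect_equal(combined_score(3, -2, 7, score_weights(0, 0, 0, 1)), 0)
  # monotone in every component for positive weights
  base <- combined_score(0.3, 1.2, -0.5, w)
  expect_gt(combined_score(0.4, 1.2, -0.5, w), base)
  expect_gt(combined_score(0.3, 1.3, -0.5, w), base)
  expect_gt(combined_score(0.3, 1.2, -0.4, w), base)
})

test_that("classification is neutral strictly above the 1.6 threshold", {
  expect_equal(classify_score(2.45), "neutral")
  expect_equal(classify_score(1.6), "destabilizing")
  expect_equal(classify_score(1.61), "neutral")
  expect_equal(classify_score(-1), "destabilizing")
  expect_equal(classify_score(c(0, 1.7)), c("destabilizing", "neutral"))
  expect_error(classify_score(NaN), "finite")
})

test_that("mutant scores re-use wild-type geometry with swapped composition", {
  fx <- local_pipeline()
  d <- compute_depth(fx$s, fast_depth())
  sc <- score_structure(fx$s, fx$pot, depth = d)
  res <- sc$residues[sc$residues$n_cliques > 0, ]
  k <- res$key[which.max(res$n_cliques)]
  aa <- res$aa[which.max(res$n_cliques)]
  chain <- sub(":.*", "", k)
  pos <- as.integer(strsplit(k, ":")[[1]][2])

  # identity substitution returns the wild-type residue score
  expect_equal(as.numeric(mutant_residue_score(sc, fx$pot, chain, pos, aa)),
               residue_score(sc, k))

  # oracle: recompute by hand over the cliques containing the residue
  for (mut in c("W", "G", "E")) {
    if (mut == aa) next
    idx <- which(vapply(sc$cliques$members, function(m) k %in% m,
                        logical(1)))
    hand <- mean(vapply(idx, function(i) {
      comp <- strsplit(sc$cliques$composition[i], "")[[1]]
      comp[match(aa, comp)] <- mut
      as.numeric(clique_score(fx$pot, paste(sort(comp), collapse = ""),
                              sc$cliques$mu[i], sc$cliques$sigma[i]))
    }, numeric(1)))
    expect_equal(as.numeric(mutant_residue_score(sc, fx$pot, chain, pos, mut)),
                 hand)
  }
  # delta mode subtracts the wild-type mean
  expect_equal(
    as.numeric(mutant_residue_score(sc, fx$pot, chain, pos, "W",
                                    s_mode = "delta")),
    as.numeric(mutant_residue_score(sc, fx$pot, chain, pos, "W")) -
      residue_score(sc, k))
})

test_that("batch prediction composes the components row by row", {
  fx <- local_pipeline()
  res <- fx$s$residues
  muts <- data.frame(chain = "A",
                     position = c(res$resno[2], res$resno[5], res$resno[5],
                                  res$resno[9]),
                     wt = res$aa[c(2, 5, 5, 9)],
                     mut = c("W", "E", "K", "G"),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(muts)))  # ensure wt != mut and rows 2/3 differ
    if (muts$mut[i] == muts$wt[i])
      muts$mut[i] <- setdiff(AA_CODES, c(muts$wt[i], muts$mut))[1]
  pred <- predict_mutations(fx$s, fx$pot, muts, msa = fx$msa,
                            matrices = fx$set, depth_params = fast_depth())
  expect_true(all(is.na(pred$error)))
  expect_equal(pred$PS, combined_score(pred$S, pred$H, pred$F))
  expect_equal(pred$call, classify_score(pred$PS))
  # H depends only on the position, not the mutant amino acid
  expect_equal(pred$H[2], pred$H[3])
  # F matches a direct matrix lookup at the residue depth
  for (i in seq_len(nrow(pred)))
    expect_equal(pred$F[i], substitution_score(fx$set, pred$wt[i],
                                               pred$mut[i], pred$depth[i]))
  # calls are invariant under re-ordering of the mutation list
  perm <- c(3, 1, 4, 2)
  pred2 <- predict_mutations(fx$s, fx$pot, muts[perm, ], msa = fx$msa,
                             matrices = fx$set, depth_params = fast_depth())
  expect_equal(pred2$call, pred$call[perm])

  # empty list and row-level failure handling
  empty <- predict_mutations(fx$s, fx$pot, muts[0, ], msa = fx$msa,
                             matrices = fx$set, depth_params = fast_depth())
  expect_equal(nrow(empty), 0L)
  bad <- muts
  bad$wt[1] <- setdiff(AA_CODES, bad$wt[1])[1]
  predb <- predict_mutations(fx$s, fx$pot, bad, msa = fx$msa,
                             matrices = fx$set, depth_params = fast_depth())
  expect_match(predb$error[1], "expected")
  expect_true(all(is.na(predb$error[-1])))
  expect_equal(predb$PS[-1], pred$PS[-1])
})

test_that("positions without cliques or inputs degrade gracefully with flags", {
  # structure with one residue far from everything: no cliques there
  helix <- make_structure(10, "helix", seed = 121)
  lone <- c(atom_line(900, "N", "ALA", "A", 50, 39, 0, 0),
            atom_line(901, "CA", "ALA", "A", 50, 40, 0, 0),
            atom_line(902, "C", "ALA", "A", 50, 41, 0.5, 0),
            atom_line(903, "O", "ALA", "A", 50, 41, 1.7, 0),
            atom_line(904, "CB", "ALA", "A", 50, 40, -1.5, 0))
  s <- parse_structure(c(helix[helix != "END"], lone, "END"))
  corpus <- lapply(make_corpus(3, n_residues = 20, seed = 131),
                   parse_structure)
  pot <- build_potential(corpus, clique_params(3, 8.0), fast_depth())
  muts <- data.frame(chain = "A", position = 50, wt = "A", mut = "W",
                     stringsAsFactors = FALSE)
  pred <- predict_mutations(s, pot, muts, depth_params = fast_depth())
  expect_true(is.na(pred$error[1]))
  expect_equal(pred$S[1], 0)
  expect_match(pred$flags[1], "no_clique")
  # no MSA and no matrices: H and F fall back to zero with flags
  expect_equal(pred$H[1], 0)
  expect_equal(pred$F[1], 0)
  expect_match(pred$flags[1], "no_msa")
  expect_match(pred$flags[1], "no_matrix")
})

test_that("mutation lists read from TSV with a mandatory header", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("chain\tposition\twt\tmut", "A\t5\tL\tP", "A\t7\tg\tw"), tf)
  m <- read_mutations(tf)
  expect_equal(m$position, c(5L, 7L))
  expect_equal(m$wt, c("L", "G"))
  writeLines(c("A\t5\tL\tP"), tf)
  expect_error(read_mutations(tf), "header")
})
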