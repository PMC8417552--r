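test_that("clique counting distributes over overlapping strata and is linear", {
  s <- parse_structure(make_structure(20, "globule", seed = 41))
  cp <- clique_params(3, 8.0)
  dp <- fast_depth()
  st <- depth_strata()
  counts <- count_cliques(list(s), cp, dp, st)

  # oracle: recount from the clique table directly
  cl <- find_residue_cliques(s, cp, depth_params = dp)
  want <- matrix(0, nrow = length(unique(cl$composition)), ncol = nrow(st),
                 dimnames = list(sort(unique(cl$composition)),
                                 paste0("L", 1:nrow(st))))
  for (i in seq_len(nrow(cl))) {
    lev <- which(cl$mu[i] >= st$d_i & cl$mu[i] < st$d_f)
    want[cl$composition[i], lev] <- want[cl$composition[i], lev] + 1
  }
  expect_equal(counts$observed, want)

  # each clique lands in every stratum containing its depth mean
  n_strata_per_clique <- vapply(cl$mu, function(m)
    sum(m >= st$d_i & m < st$d_f), numeric(1))
  expect_equal(sum(counts$observed), sum(n_strata_per_clique))

  # doubling the corpus doubles every observed count
  counts2 <- count_cliques(list(s, s), cp, dp, st)
  expect_equal(counts2$observed, 2 * counts$observed)
  expect_equal(counts2$aa_counts, 2 * counts$aa_counts)
})

test_that("reference-state expectations follow the multinomial closed form", {
  unif <- stats::setNames(rep(1 / 20, 20), AA_CODES)
  expect_equal(expected_count("AA", 400, unif), 1.0)
  expect_equal(expected_count("AC", 400, unif), 2.0)
  expect_equal(expected_count("AAA", 8000, unif), 1.0)
  expect_equal(expected_count("ACD", 8000, unif), 6.0)

  # multinomial normalisation: expectations sum to the stratum total
  comps2 <- apply(utils::combn(rep(AA_CODES, 2), 2), 2, function(x)
    paste(sort(x), collapse = ""))
  comps2 <- unique(c(comps2, paste0(AA_CODES, AA_CODES)))
  tot <- sum(vapply(comps2, expected_count, numeric(1), total = 400,
                    aa_freq = unif))
  expect_equal(tot, 400)
  expect_error(expected_count("AA", 10, unif * 0.5), "sum to 1")
})

test_that("clique energies follow the log-odds form with flooring of zeros", {
  expect_equal(clique_energy(10, 10), 0)
  expect_equal(clique_energy(exp(1) * 7, 7), 1)
  expect_equal(clique_energy(5, 10, alpha = 1), log((5 + 10) / 20))
  expect_error(clique_energy(1, 0), "> 0")

  pot <- toy_potential()
  # AAW has observed 0 in strata 1 and 5: floored at min(E) - 1
  expect_true(pot$floored["AAW", 1] && pot$floored["AAW", 5])
  finite_e <- pot$energies[!pot$floored]
  expect_equal(pot$floor, min(finite_e) - 1)
  expect_equal(pot$energies["AAW", 1], pot$floor)
  # observed > 0 entries reproduce log(obs/exp)
  expect_equal(pot$energies["ACD", 2],
               log(pot$observed["ACD", 2] / pot$expected["ACD", 2]))
})

test_that("clique score matches the point-mass limit and numerical quadrature", {
  pot <- toy_potential()
  st <- pot$strata
  # sigma -> 0 with mu interior to only the first stratum: E / width
  s0 <- clique_score(pot, "AAA", mu = 3.0, sigma = 0)
  expect_equal(as.numeric(s0), pot$energies["AAA", 1] / 2.45)
  # unknown composition uses the floor and is flagged
  sx <- clique_score(pot, "CDE", mu = 3.0, sigma = 0)
  expect_true(attr(sx, "floored"))
  expect_equal(as.numeric(sx), pot$floor / 2.45)

  # all-zero energies score zero for any (mu, sigma)
  obs0 <- pot$expected  # obs == exp everywhere -> E == 0
  pot0 <- potential_from_counts(list(observed = obs0),
                                aa_freq = pot$aa_freq)
  # force energies to zero exactly (counts are already self-consistent only
  # approximately, so zero them explicitly)
  pot0$energies[] <- 0
  expect_equal(as.numeric(clique_score(pot0, "AAA", 6, 1.2)), 0)

  # quadrature oracle for sigma > 0
  quad <- function(comp, mu, sigma) {
    sum(vapply(seq_len(nrow(st)), function(l) {
      up <- if (is.finite(st$d_f[l])) st$d_f[l] else Inf
      v <- stats::integrate(function(x) stats::dnorm(x, mu, sigma),
                            st$d_i[l], up, rel.tol = 1e-12)$value
      pot$energies[comp, l] / st$width[l] * v
    }, numeric(1)))
  }
  for (mu in c(3.0, 6.0, 9.5)) for (sigma in c(0.25, 0.5, 1.5)) {
    expect_equal(as.numeric(clique_score(pot, "AAA", mu, sigma)),
                 quad("AAA", mu, sigma), tolerance = 1e-6)
  }
})

test_that("residue and protein scores are means over cliques and residues", {
  s <- parse_structure(make_structure(18, "helix", seed = 51))
  corpus <- lapply(make_corpus(3, n_residues = 20, seed = 61),
                   parse_structure)
  pot <- build_potential(corpus, clique_params(3, 8.0), fast_depth())
  sc <- score_structure(s, pot, depth_params = fast_depth())

  cl <- sc$cliques
  for (k in sample(sc$residues$key, 5)) {
    idx <- vapply(cl$members, function(m) k %in% m, logical(1))
    want <- if (any(idx)) mean(cl$score[idx]) else NA_real_
    expect_equal(residue_score(sc, k), want)
  }
  expect_equal(protein_score(sc),
               mean(sc$residues$score, na.rm = TRUE))
  # a residue in exactly one clique scores exactly that clique
  n_in <- vapply(sc$residues$key, function(k)
    sum(vapply(cl$members, function(m) k %in% m, logical(1))), numeric(1))
  if (any(n_in == 1)) {
    k1 <- sc$residues$key[which(n_in == 1)[1]]
    idx <- which(vapply(cl$members, function(m) k1 %in% m, logical(1)))
    expect_equal(residue_score(sc, k1), cl$score[idx])
  }
})

test_that("a planted composition enrichment is recovered from sampled cliques", {
  beta <- 1.0
  fr <- stats::setNames(rep(0.7 / 19, 20), AA_CODES)
  fr["A"] <- 0.3
  comps <- unique(apply(expand.grid(AA_CODES, AA_CODES, AA_CODES), 1,
                        function(x) paste(sort(x), collapse = "")))
  pref <- vapply(comps, function(cc) {
    l <- strsplit(cc, "")[[1]]
    m <- table(l)
    factorial(3) / prod(factorial(m)) * prod(fr[l])
  }, numeric(1))
  expect_equal(sum(pref), 1)  # multinomial sanity
  q <- pref
  q["AAA"] <- q["AAA"] * exp(beta)
  Z <- sum(q)
  q <- q / Z
  set.seed(2024)
  draws <- sample(comps, 10000, replace = TRUE, prob = q)
  tab <- table(draws)
  obs <- matrix(0, length(tab), 5,
                dimnames = list(names(tab), paste0("L", 1:5)))
  obs[, 2] <- obs[, 3] <- as.numeric(tab)  # all cliques at depth mean 6 A
  pot <- potential_from_counts(list(observed = obs), aa_freq = fr)
  # the fitted energy estimates beta - log Z (Z is the planted normaliser)
  p_aaa <- q[["AAA"]]
  mc_sd <- sqrt((1 - p_aaa) / (10000 * p_aaa))
  expect_lt(abs(pot$energies["AAA", 2] - (beta - log(Z))), 4 * mc_sd)
})

test_that("potentials survive a JSON round trip bit for bit", {
  corpus <- lapply(make_corpus(2, n_residues = 18, seed = 71),
                   parse_structure)
  pot <- build_potential(corpus, clique_params(3, 8.0), fast_depth())
  tf <- tempfile(fileext = ".json")
  write_potential(pot, tf)
  pot2 <- read_potential(tf)
  expect_equal(pot2$energies, pot$energies)
  expect_equal(pot2$observed, pot$observed)
  expect_equal(pot2$expected, pot$expected)
  expect_equal(pot2$aa_freq, pot$aa_freq)
  expect_equal(pot2$floor, pot$floor)
  expect_equal(pot2$strata, pot$strata)
  expect_equal(pot2$params$N, pot$params$N)
  # scoring is identical through the round trip
  expect_equal(as.numeric(clique_score(pot2, rownames(pot$energies)[1], 6, 0.7)),
               as.numeric(clique_score(pot, rownames(pot$energies)[1], 6, 0.7)))
})
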