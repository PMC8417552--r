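# Deterministic synthetic generators: structures, structure corpora,
# alignments and labeled mutation feature sets.  All generators are pure
# functions of their arguments (fixed seed => byte-identical output), so
# every module of the package is testable without external data.  The
# structures are geometric stand-ins -- ideal backbones with centroid
# side-chain pseudo-atom clusters carrying the canonical heavy-atom count
# per amino acid -- sufficient for the contact, clique and depth logic but
# not physically realistic proteins.

format_atom_name <- function(name) {
  if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
}

pdb_atom_line <- function(serial, name, res3, chain, resno, x, y, z) {
  sprintf("ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, format_atom_name(name), res3, chain, resno, x, y, z,
          substr(gsub("[0-9]", "", name), 1, 1))
}

unit <- function(v) v / sqrt(sum(v^2))

# two unit vectors orthogonal to u
perp_pair <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- unit(pracma_cross(u, a))
  p2 <- unit(pracma_cross(u, p1))
  list(p1, p2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# side-chain pseudo-atom offsets (relative to CA) for n atoms along
# direction u: a compact cluster extending 1.5-4 A from the backbone
side_chain_offsets <- function(n, u, jitter) {
  pp <- perp_pair(u)
  lapply(seq_len(n), function(k) {
    reach <- 1.5 + 0.55 * ((k - 1) %/% 3)
    side <- (k - 1) %% 3
    off <- u * reach
    if (side == 1) off <- off + pp[[1]] * 1.2
    if (side == 2) off <- off + pp[[2]] * 1.2
    off + jitter[k, ]
  })
}

#' Generate a synthetic PDB structure
#'
#' Ideal-geometry backbone (helix, extended sheet strand, or compact
#' globule) with side-chain pseudo-atom clusters carrying the canonical
#' heavy-atom count of each amino acid.  Glycine gets no side-chain atoms
#' (its CA stands in), per the contact rule.
#'
#' @param n_residues Number of residues (>= 2).
#' @param geometry `"helix"`, `"sheet"` or `"globule"`.
#' @param seed Seed controlling sequence sampling and jitter.
#' @param sequence Optional one-letter sequence (overrides sampling).
#' @param aa_freq Optional sampling frequencies over [AA_CODES] (uniform by
#'   default).
#' @param chain Chain identifier.
#' @return Character vector of PDB-format lines.
#' @export
make_structure <- function(n_residues = 20L,
                           geometry = c("helix", "sheet", "globule"),
                           seed = 1L, sequence = NULL, aa_freq = NULL,
                           chain = "A") {
  geometry <- match.arg(geometry)
  if (is.null(sequence) && n_residues < 2L) stop("need n_residues >= 2")
  with_seed(seed, {
    if (is.null(sequence)) {
      p <- aa_freq %||% stats::setNames(rep(1 / 20, 20), AA_CODES)
      sequence <- paste(sample(AA_CODES, n_residues, replace = TRUE,
                               prob = p[AA_CODES]), collapse = "")
    }
    aas <- strsplit(sequence, "")[[1]]
    n <- length(aas)
    if (n < 2L) stop("need at least 2 residues")

    ca <- matrix(0, n, 3)
    udir <- matrix(0, n, 3)
    if (geometry == "helix") {
      t <- (seq_len(n) - 1) * 100 * pi / 180
      ca <- cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(n) - 1))
      udir <- cbind(cos(t), sin(t), 0)
    } else if (geometry == "sheet") {
      ca <- cbind(3.3 * (seq_len(n) - 1),
                  0.5 * (-1)^(seq_len(n)), 0)
      udir <- cbind(0, 0, (-1)^(seq_len(n)))
    } else {
      # compact globule: CA points rejection-sampled in a ball whose volume
      # allots ~85 A^3 per residue (tight packing, so the solvent cannot
      # percolate into the core), minimum CA-CA separation 3.4 A
      R <- (3 * n * 85 / (4 * pi))^(1 / 3)
      pts <- matrix(NA_real_, 0, 3)
      tries <- 0L
      while (nrow(pts) < n && tries < 50000L) {
        tries <- tries + 1L
        p <- stats::runif(3, -R, R)
        if (sum(p^2) > R^2) next
        if (nrow(pts) && min(colSums((t(pts) - p)^2)) < 3.4^2) next
        pts <- rbind(pts, p)
      }
      if (nrow(pts) < n)
        stop("could not place ", n, " residues in the globule ball")
      ca <- pts
      # side chains point inward for surface residues half the time, else
      # random; a random direction keeps the interior packed
      udir <- t(apply(ca, 1, function(p) unit(stats::rnorm(3))))
    }

    lines <- character(0)
    serial <- 0L
    for (i in seq_len(n)) {
      aa <- aas[i]
      if (!aa %in% AA_CODES) stop("bad amino acid: ", aa)
      res3 <- AA_ONE_TO_THREE[[aa]]
      u <- udir[i, ]
      pp <- perp_pair(u)
      npos <- ca[i, ] - pp[[1]] * 1.46
      cpos <- ca[i, ] + pp[[1]] * 1.52
      opos <- cpos + pp[[2]] * 1.23
      emit <- function(name, xyz) {
        serial <<- serial + 1L
        lines <<- c(lines, pdb_atom_line(serial, name, res3, chain, i,
                                         xyz[1], xyz[2], xyz[3]))
      }
      emit("N", npos); emit("CA", ca[i, ]); emit("C", cpos); emit("O", opos)
      sc_names <- SIDE_CHAIN_ATOMS[[aa]]
      if (length(sc_names)) {
        jit <- matrix(stats::runif(3 * length(sc_names), -0.35, 0.35),
                      ncol = 3)
        offs <- side_chain_offsets(length(sc_names), u, jit)
        for (k in seq_along(sc_names)) emit(sc_names[k], ca[i, ] + offs[[k]])
      }
    }
    c(lines, "END")
  })
}

#' Generate a synthetic structure corpus
#'
#' @param n_proteins Number of structures.
#' @param n_residues Residues per structure.
#' @param seed Base seed; protein `i` uses `seed + i`.
#' @param aa_freq Amino-acid sampling frequencies (controls the corpus
#'   composition, e.g. for reference-state tests).
#' @param geometry Geometry passed to [make_structure()].
#' @return List of PDB text character vectors.
#' @export
make_corpus <- function(n_proteins, n_residues = 30L, seed = 1L,
                        aa_freq = NULL, geometry = "globule") {
  if (n_proteins < 1L) stop("n_proteins must be >= 1")
  lapply(seq_len(n_proteins), function(i) {
    make_structure(n_residues = n_residues, geometry = geometry,
                   seed = seed + i, aa_freq = aa_freq)
  })
}

#' Generate a synthetic multiple sequence alignment
#'
#' The first row is the consensus (query) sequence.  At column `j`, every
#' other sequence carries the consensus letter with probability
#' `conservation[j]` and otherwise a letter sampled uniformly from
#' `noise_alphabet`.
#'
#' @param length Alignment length (ignored when `consensus` is given).
#' @param conservation Per-column conservation in `[0, 1]` (recycled).
#' @param n_seqs Number of sequences including the query.
#' @param seed Seed.
#' @param consensus Optional consensus sequence.
#' @param noise_alphabet Letters used for non-consensus draws.
#' @return Character vector of aligned-FASTA lines.
#' @export
make_msa <- function(length = 30L, conservation = 0.8, n_seqs = 100L,
                     seed = 1L, consensus = NULL,
                     noise_alphabet = AA_CODES) {
  if (any(conservation < 0 | conservation > 1))
    stop("conservation must be in [0, 1]")
  with_seed(seed, {
    if (is.null(consensus))
      consensus <- paste(sample(AA_CODES, length, replace = TRUE),
                         collapse = "")
    cons <- strsplit(consensus, "")[[1]]
    L <- base::length(cons)
    cvec <- rep_len(conservation, L)
    rows <- matrix(rep(cons, n_seqs), nrow = n_seqs, byrow = TRUE)
    for (j in seq_len(L)) {
      flip <- stats::runif(n_seqs - 1L) > cvec[j]
      if (any(flip))
        rows[1L + which(flip), j] <- sample(noise_alphabet, sum(flip),
                                            replace = TRUE)
    }
    fasta <- character(0)
    for (i in seq_len(n_seqs)) {
      fasta <- c(fasta, paste0(">seq", i),
                 paste(rows[i, ], collapse = ""))
    }
    fasta
  })
}

#' Generate labeled mutation features with a planted linear rule
#'
#' Samples component features (S, H, F) uniformly over realistic ranges,
#' labels each mutation by thresholding the planted linear combination at
#' `threshold`, discards points within `margin` of the decision boundary,
#' and optionally flips a fraction of labels.  Supports weight-recovery
#' tests of the grid-search trainer.
#'
#' The component ranges span what the pipeline actually produces: clique
#' scores roughly in `[-2, 2]`, entropies over the full `[0, log2(20)]`
#' range, substitution likelihoods in `[-3, 3]`.  The default margin (0.05)
#' is kept below the trainer's threshold grid step so that the planted rule
#' is the unique best grid point once a few thousand mutations are sampled.
#'
#' @param n Number of mutations.
#' @param weights Planted coefficient vector `c(w_s, w_h, w_f)`.
#' @param threshold Planted decision threshold.
#' @param margin Half-width of the excluded band around the boundary.
#' @param flip_rate Fraction of labels flipped at random.
#' @param seed Seed.
#' @return List: `features` (data frame `S`, `H`, `F`), `truth` (labels),
#'   `ps` (planted combined scores).
#' @export
make_labeled_mutations <- function(n = 2000L, weights = c(1.5, 1.75, 0.5),
                                   threshold = 1.6, margin = 0.05,
                                   flip_rate = 0, seed = 1L) {
  stopifnot(margin >= 0, n >= 1)
  with_seed(seed, {
    S <- numeric(0); H <- numeric(0); F <- numeric(0)
    while (base::length(S) < n) {
      m <- 2L * (n - base::length(S)) + 16L
      s <- stats::runif(m, -2, 2)
      h <- stats::runif(m, 0, log2(20))
      f <- stats::runif(m, -3, 3)
      ps <- weights[1] * s + weights[2] * h + weights[3] * f
      keep <- abs(ps - threshold) > margin
      S <- c(S, s[keep]); H <- c(H, h[keep]); F <- c(F, f[keep])
    }
    S <- S[seq_len(n)]; H <- H[seq_len(n)]; F <- F[seq_len(n)]
    ps <- weights[1] * S + weights[2] * H + weights[3] * F
    truth <- ifelse(ps > threshold, "neutral", "destabilizing")
    if (flip_rate > 0) {
      flip <- stats::runif(n) < flip_rate
      truth[flip] <- ifelse(truth[flip] == "neutral", "destabilizing",
                            "neutral")
    }
    list(features = data.frame(S = S, H = H, F = F), truth = truth,
         ps = ps)
  })
}
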