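# Shared fixtures and independent oracles, built in code at test time.

# hand-written PDB ATOM line with correct column layout
atom_line <- function(serial, name, res3, chain, resno, x, y, z,
                      occ = 1, alt = " ", element = NULL, record = "ATOM  ") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%s%5d %s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
          record, serial, nm, alt, res3, chain, resno, x, y, z, occ, element)
}

# minimal glycine residue: 4 backbone heavy atoms + terminal OXT (5 atoms)
gly5_pdb <- function() {
  c(atom_line(1, "N",   "GLY", "A", 1, 0.0, 0.0, 0.0),
    atom_line(2, "CA",  "GLY", "A", 1, 1.45, 0.0, 0.0),
    atom_line(3, "C",   "GLY", "A", 1, 2.0, 1.4, 0.0),
    atom_line(4, "O",   "GLY", "A", 1, 1.3, 2.4, 0.0),
    atom_line(5, "OXT", "GLY", "A", 1, 3.2, 1.5, 0.0),
    "END")
}

# two glycine residues whose CA atoms are `sep` apart along x, with all
# other backbone atoms placed outside the CA-CA gap
two_gly_pdb <- function(sep = 6.0) {
  c(atom_line(1, "N",  "GLY", "A", 1, -1.46, 0, 0),
    atom_line(2, "CA", "GLY", "A", 1, 0, 0, 0),
    atom_line(3, "C",  "GLY", "A", 1, -1.0, 1.2, 0),
    atom_line(4, "O",  "GLY", "A", 1, -1.0, 2.4, 0),
    atom_line(5, "N",  "GLY", "A", 2, sep + 1.46, 0, 0),
    atom_line(6, "CA", "GLY", "A", 2, sep, 0, 0),
    atom_line(7, "C",  "GLY", "A", 2, sep + 1.0, 1.2, 0),
    atom_line(8, "O",  "GLY", "A", 2, sep + 1.0, 2.4, 0),
    "END")
}

# closed alanine shell: residues whose atoms tile a sphere of radius r,
# enclosing a small empty cavity
shell_pdb <- function(n_res = 48, r = 5.0) {
  lines <- character(0)
  serial <- 0
  # Fibonacci sphere directions
  golden <- pi * (3 - sqrt(5))
  for (i in seq_len(n_res)) {
    zf <- 1 - 2 * (i - 0.5) / n_res
    rad <- sqrt(1 - zf^2)
    th <- golden * i
    u <- c(rad * cos(th), rad * sin(th), zf)
    p1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- p1 - sum(p1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    ca <- u * r
    emit <- function(nm, xyz) {
      serial <<- serial + 1
      lines <<- c(lines, atom_line(serial, nm, "ALA", "A", i,
                                   xyz[1], xyz[2], xyz[3]))
    }
    emit("N", ca + e1 * 1.4)
    emit("CA", ca)
    emit("C", ca - e1 * 1.4)
    emit("O", ca - e1 * 1.4 + e2 * 1.2)
    emit("CB", ca + u * 1.5)
  }
  c(lines, "END")
}

# brute-force clique oracle: every N-subset of vertices checked against the
# adjacency matrix
cliques_bruteforce <- function(adj, N) {
  n <- nrow(adj)
  if (N > n) return(list())
  out <- list()
  for (idx in utils::combn(n, N, simplify = FALSE)) {
    pairs <- utils::combn(idx, 2)
    if (all(adj[cbind(pairs[1, ], pairs[2, ])])) out[[length(out) + 1]] <- idx
  }
  out
}

# igraph from a 0/1 adjacency matrix with arbitrary aa labels
graph_from_adj <- function(adj, names = NULL) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  nm <- names %||% paste0("A:", seq_len(nrow(adj)), ":")
  g <- igraph::set_vertex_attr(g, "name", value = nm)
  igraph::set_vertex_attr(g, "aa", value = rep_len(cliquepred::AA_CODES,
                                                   nrow(adj)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a fabricated depth profile for clique_depth_stats tests
fake_depth <- function(keys, depths_per_residue) {
  atoms <- do.call(rbind, lapply(seq_along(keys), function(i) {
    d <- depths_per_residue[[i]]
    data.frame(key = keys[i], chain = "A", resno = i, insert = "",
               aa = "A", elety = paste0("X", seq_along(d)), depth = d,
               stringsAsFactors = FALSE)
  }))
  residues <- data.frame(
    key = keys, chain = "A", resno = seq_along(keys), insert = "", aa = "A",
    depth = vapply(depths_per_residue, mean, numeric(1)),
    stringsAsFactors = FALSE)
  residues$zone <- cliquepred::depth_zone(residues$depth)
  structure(list(atoms = atoms, residues = residues,
                 params = cliquepred::depth_params(), model = 1L),
            class = "cp_depth")
}

# small potential with hand-set counts, shared by scoring tests
toy_potential <- function() {
  obs <- matrix(c(5, 3, 2, 1, 4,
                  2, 2, 2, 2, 2,
                  0, 1, 1, 1, 0),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("AAA", "ACD", "AAW"), paste0("L", 1:5)))
  potential_from_counts(list(observed = obs,
                             aa_counts = stats::setNames(rep(5, 20),
                                                         cliquepred::AA_CODES)))
}

# fast depth parameters for tests
fast_depth <- function(n_cycles = 1L, seed = 17L)
  depth_params(n_cycles = n_cycles, seed = seed)
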