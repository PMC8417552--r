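# Residue contact graph and (N, d_cut) clique enumeration.
#
# Two residues are linked when at least four, or more than half, of the
# side-chain non-hydrogen atoms of one (whichever is smaller) lie within
# d_cut of any atom of the other.  Glycine's CA stands in for its side chain.
# The rule as stated is one-directional; we call a pair linked when either
# direction satisfies it, which guarantees an undirected graph.

#' Clique parameters
#'
#' @param N Clique size (number of residues, >= 2; sizes 2-4 are the
#'   supported sweep range).
#' @param d_cut Linkage distance cut-off in Angstrom (7.0-10.5 is the
#'   conventional sweep range).
#' @return A `cp_clique_params` list.
#' @export
clique_params <- function(N = 3L, d_cut = 8.0) {
  stopifnot(N >= 2, d_cut > 0)
  structure(list(N = as.integer(N), d_cut = d_cut),
            class = "cp_clique_params")
}

#' Contact-count threshold for the linkage rule
#'
#' Number of side-chain heavy atoms of a residue that must lie within `d_cut`
#' of the partner residue for the pair to count as linked from this side:
#' at least four or more than half of the side-chain heavy atoms, whichever
#' is smaller, i.e. `min(4, floor(n/2) + 1)`.
#'
#' @param n_side_chain_heavy Number of side-chain heavy atoms (glycine counts
#'   its CA, so n = 1).
#' @return Integer threshold.
#' @export
contact_threshold <- function(n_side_chain_heavy) {
  if (any(n_side_chain_heavy < 1)) stop("side-chain heavy-atom count must be >= 1")
  pmin(4L, n_side_chain_heavy %/% 2L + 1L)
}

# side-chain heavy-atom coordinates (glycine -> CA) for one residue
side_chain_coords <- function(structure, key, model = 1L) {
  ra <- residue_atoms(structure, key, model)
  if (nrow(ra) == 0L || !isTRUE(ra$standard[1])) return(NULL)
  if (ra$aa[1] == "G") ra <- ra[ra$elety == "CA", , drop = FALSE]
  else ra <- ra[ra$side_chain & ra$heavy, , drop = FALSE]
  if (nrow(ra) == 0L) return(NULL)
  as.matrix(ra[, c("x", "y", "z"), drop = FALSE])
}

# all heavy-atom coordinates for one residue
heavy_coords <- function(structure, key, model = 1L) {
  ra <- residue_atoms(structure, key, model)
  ra <- ra[ra$heavy, , drop = FALSE]
  as.matrix(ra[, c("x", "y", "z"), drop = FALSE])
}

#' Residue linkage test
#'
#' @param structure A `cp_structure`.
#' @param key_a,key_b Residue keys (`"chain:resno:insert"`, see
#'   `structure$residues$key`).
#' @param d_cut Distance cut-off (Angstrom).
#' @param model Model index.
#' @return `TRUE` if the pair is linked in either direction.  A residue with
#'   no side-chain heavy atoms yields `FALSE` with a warning; a residue is
#'   never linked to itself.
#' @export
residue_linked <- function(structure, key_a, key_b, d_cut, model = 1L) {
  if (identical(key_a, key_b)) return(FALSE)
  sa <- side_chain_coords(structure, key_a, model)
  sb <- side_chain_coords(structure, key_b, model)
  if (is.null(sa) || is.null(sb)) {
    warning("residue without usable side-chain heavy atoms: ",
            if (is.null(sa)) key_a else key_b)
    return(FALSE)
  }
  ha <- heavy_coords(structure, key_a, model)
  hb <- heavy_coords(structure, key_b, model)
  fwd <- .cp_count_within(sa, hb, d_cut) >= contact_threshold(nrow(sa))
  if (fwd) return(TRUE)
  .cp_count_within(sb, ha, d_cut) >= contact_threshold(nrow(sb))
}

#' Build the residue contact graph
#'
#' Undirected simple graph over the standard residues of a model, with an
#' edge wherever [residue_linked()] holds.  Candidate pairs are pre-screened
#' with a centroid-plus-radius bound before the exact atom-level test, so the
#' result equals the all-pairs computation exactly.
#'
#' @param structure A `cp_structure`.
#' @param d_cut Distance cut-off (Angstrom).
#' @param model Model index.
#' @return An [igraph] graph whose vertex names are residue keys, with
#'   vertex attribute `aa`.
#' @export
build_contact_graph <- function(structure, d_cut, model = 1L) {
  res <- structure$residues
  res <- res[res$standard & res$has_side_chain, , drop = FALSE]
  keys <- res$key
  n <- length(keys)
  if (n < 2L) stop("need at least 2 usable standard residues")

  # centroid and reach of each residue's heavy atoms for the exact pre-screen
  cents <- matrix(0, n, 3)
  reach <- numeric(n)
  hc <- vector("list", n)
  sc <- vector("list", n)
  for (i in seq_len(n)) {
    hc[[i]] <- heavy_coords(structure, keys[i], model)
    sc[[i]] <- side_chain_coords(structure, keys[i], model)
    cents[i, ] <- colMeans(hc[[i]])
    reach[i] <- sqrt(max(rowSums(sweep(hc[[i]], 2, cents[i, ])^2)))
  }

  edges <- integer(0)
  for (i in seq_len(n - 1L)) {
    dc <- sqrt(colSums((t(cents[(i + 1L):n, , drop = FALSE]) - cents[i, ])^2))
    cand <- which(dc <= d_cut + reach[i] + reach[(i + 1L):n]) + i
    for (j in cand) {
      ti <- contact_threshold(nrow(sc[[i]]))
      tj <- contact_threshold(nrow(sc[[j]]))
      hit <- .cp_count_within(sc[[i]], hc[[j]], d_cut) >= ti ||
        .cp_count_within(sc[[j]], hc[[i]], d_cut) >= tj
      if (hit) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = keys)
  g <- igraph::set_vertex_attr(g, "aa", value = res$aa)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

#' Enumerate residue cliques of exact size N
#'
#' All complete subgraphs on exactly `N` vertices (not only maximal ones),
#' each emitted once, ordered deterministically by sorted residue keys.
#'
#' @param graph Contact graph from [build_contact_graph()].
#' @param N Clique size (>= 2).
#' @return Data frame with one row per clique: `members` (list column of
#'   residue-key vectors, each sorted) and `composition` (sorted amino-acid
#'   multiset as a string, e.g. `"AAW"`).
#' @export
enumerate_cliques <- function(graph, N) {
  stopifnot(N >= 2)
  aa <- igraph::vertex_attr(graph, "aa")
  names(aa) <- igraph::V(graph)$name
  if (N > igraph::vcount(graph)) {
    return(data.frame(members = I(list()), composition = character(0)))
  }
  cl <- igraph::cliques(graph, min = N, max = N)
  members <- lapply(cl, function(v) sort(igraph::V(graph)$name[v]))
  ord <- order(vapply(members, paste, character(1), collapse = "|"))
  members <- members[ord]
  comp <- vapply(members, function(m) {
    paste(sort(unname(aa[m])), collapse = "")
  }, character(1))
  out <- data.frame(composition = comp, stringsAsFactors = FALSE)
  out$members <- members
  out[, c("members", "composition")]
}

#' Depth statistics of a residue clique
#'
#' Mean and population standard deviation of the depths of all heavy atoms of
#' all member residues.
#'
#' @param depth A `cp_depth` object from [compute_depth()].
#' @param members Character vector of residue keys.
#' @return Named numeric vector `c(mu =, sigma =)`, in Angstrom.
#' @export
clique_depth_stats <- function(depth, members) {
  d <- depth$atoms$depth[depth$atoms$key %in% members]
  if (length(d) == 0L || !all(members %in% depth$atoms$key))
    stop("some clique members have no depth values")
  mu <- mean(d)
  sigma <- sqrt(mean((d - mu)^2))
  c(mu = mu, sigma = sigma)
}

#' Enumerate cliques with composition and depth statistics
#'
#' Convenience wrapper: builds the contact graph, enumerates (N, d_cut)
#' cliques and annotates each with its depth mean and standard deviation.
#'
#' @param structure A `cp_structure`.
#' @param params A [clique_params()] object.
#' @param depth Optional `cp_depth`; computed with `depth_params` if omitted.
#' @param depth_params Parameters for [compute_depth()] when `depth` is NULL.
#' @param model Model index.
#' @return Data frame: `members` (list column), `composition`, `mu`, `sigma`.
#' @export
find_residue_cliques <- function(structure, params = clique_params(),
                                 depth = NULL,
                                 depth_params = cliquepred::depth_params(),
                                 model = 1L) {
  g <- build_contact_graph(structure, params$d_cut, model = model)
  cl <- enumerate_cliques(g, params$N)
  if (is.null(depth)) depth <- compute_depth(structure, depth_params, model)
  if (nrow(cl)) {
    st <- t(vapply(cl$members, function(m) clique_depth_stats(depth, m),
                   c(mu = 0, sigma = 0)))
    cl$mu <- st[, "mu"]
    cl$sigma <- st[, "sigma"]
  } else {
    cl$mu <- numeric(0)
    cl$sigma <- numeric(0)
  }
  cl
}
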