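# Positional Shannon entropy from a multiple sequence alignment.
#
# H = -sum_i P_i log2 P_i over the 20 amino acids, where P_i is the fraction
# of amino acid i at the column.  Gaps and X are excluded and the remaining
# fractions renormalised under the default gap policy; a "gap as 21st symbol"
# policy is available.  No sequence weighting or pseudo-counts are applied.

#' Read a multiple sequence alignment
#'
#' @param path Aligned FASTA or Stockholm file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return A `cp_msa`: character matrix (rows = sequences, columns =
#'   alignment positions, upper case; `-` and `.` are gaps).
#' @export
read_msa <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::unmasked(aln))
  m <- do.call(rbind, unname(strsplit(toupper(seqs), "")))
  rownames(m) <- names(seqs)
  m[m == "."] <- "-"
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  structure(m, class = c("cp_msa", class(m)))
}

#' @rdname read_msa
#' @param sequences Named character vector of equal-length aligned sequences.
#' @export
msa_from_sequences <- function(sequences) {
  if (length(unique(nchar(sequences))) != 1L)
    stop("aligned sequences must have equal length")
  m <- do.call(rbind, unname(strsplit(toupper(sequences), "")))
  rownames(m) <- names(sequences) %||% paste0("seq", seq_along(sequences))
  m[m == "."] <- "-"
  structure(m, class = c("cp_msa", class(m)))
}

#' Column amino-acid frequencies
#'
#' @param msa A `cp_msa` matrix.
#' @param column Column index.
#' @param gap_policy `"exclude"` drops gaps and X then renormalises over the
#'   20 amino acids; `"gap21"` keeps the gap as a 21st symbol.
#' @return Named frequency vector (20 amino acids, plus `"-"` under
#'   `"gap21"`).  An all-gap column returns all-NA with attribute
#'   `all_gap = TRUE`.
#' @export
column_frequencies <- function(msa, column,
                               gap_policy = c("exclude", "gap21")) {
  gap_policy <- match.arg(gap_policy)
  if (column < 1 || column > ncol(msa)) stop("column out of bounds")
  col <- msa[, column]
  symbols <- if (gap_policy == "gap21") c(AA_CODES, "-") else AA_CODES
  col <- col[col %in% symbols]
  p <- stats::setNames(numeric(length(symbols)), symbols)
  if (length(col) == 0L) {
    p[] <- NA_real_
    attr(p, "all_gap") <- TRUE
    return(p)
  }
  tab <- table(col)
  p[names(tab)] <- as.numeric(tab) / length(col)
  attr(p, "all_gap") <- FALSE
  p
}

#' Shannon entropy of a frequency vector
#'
#' `H = -sum_i P_i log2 P_i` in bits, with `0 * log 0 = 0`.
#'
#' @param p Frequency vector summing to 1, entries >= 0.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("empty distribution")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("malformed distribution: entries must be >= 0 and sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

# alignment columns of the non-gap positions of one row
query_columns <- function(msa, query) which(msa[query, ] != "-")

#' Map alignment entropy onto structure positions
#'
#' Maps every residue of a chain to an alignment column through the query
#' row (structure position i corresponds to the i-th non-gap column of the
#' query row) and reports the per-position entropy.  The gap-stripped query
#' must match the chain sequence at >= 95% identity unless an explicit
#' `mapping` is supplied.
#'
#' @param msa A `cp_msa` matrix.
#' @param structure A `cp_structure`.
#' @param chain Chain identifier.
#' @param query Row index of the query sequence in the alignment.
#' @param mapping Optional integer vector: alignment column per structure
#'   position (NA = unmapped).
#' @param gap_policy Passed to [column_frequencies()].
#' @return A `cp_entropy` data frame: `key`, `chain`, `resno`, `insert`,
#'   `aa`, `column`, `H` (bits), `coverage` (non-gap fraction of the
#'   column).  Unmapped or all-gap positions carry `NA` entropy.
#' @export
map_entropy_to_structure <- function(msa, structure, chain, query = 1L,
                                     mapping = NULL,
                                     gap_policy = c("exclude", "gap21")) {
  gap_policy <- match.arg(gap_policy)
  res <- structure$residues[structure$residues$chain == chain, , drop = FALSE]
  if (nrow(res) == 0L) stop("no such chain: ", chain)
  npos <- nrow(res)
  if (is.null(mapping)) {
    cols <- query_columns(msa, query)
    if (length(cols) != npos)
      stop("gap-stripped query length (", length(cols),
           ") does not match chain length (", npos,
           "); supply an explicit mapping")
    qseq <- msa[query, cols]
    sseq <- ifelse(is.na(res$aa), "X", res$aa)
    ident <- mean(qseq == sseq)
    if (ident < 0.95) {
      mism <- which(qseq != sseq)
      stop(sprintf(
        "query/structure identity %.0f%% < 95%%; mismatches at positions: %s",
        100 * ident,
        paste(utils::head(mism, 10), collapse = ", ")))
    }
    mapping <- cols
  }
  if (length(mapping) != npos)
    stop("mapping length must equal chain length")
  H <- rep(NA_real_, npos)
  cov <- rep(NA_real_, npos)
  for (i in seq_len(npos)) {
    if (is.na(mapping[i])) next
    p <- column_frequencies(msa, mapping[i], gap_policy)
    cov[i] <- mean(msa[, mapping[i]] != "-")
    if (!isTRUE(attr(p, "all_gap"))) H[i] <- shannon_entropy(p)
  }
  out <- data.frame(key = res$key, chain = res$chain, resno = res$resno,
                    insert = res$insert, aa = res$aa, column = mapping,
                    H = H, coverage = cov, stringsAsFactors = FALSE)
  class(out) <- c("cp_entropy", "data.frame")
  out
}
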