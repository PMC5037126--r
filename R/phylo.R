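#' Pairwise alignment-derived distance matrix
#'
#' For each pair, the fractional identity `p` of the Smith-Waterman
#' local alignment is converted to an evolutionary distance
#' `d = -ln(max(p - 0.05, eps) / 0.95)`, where 0.05 is the random
#' identity floor of a 20-letter alphabet; identities at or below the
#' floor are capped at the finite ceiling `-ln(eps / 0.95)`.  This is a
#' deliberately simple companion to the network — distances come from
#' pairwise alignments, not a multiple sequence alignment — so trees
#' built from it are approximations, suitable for sketching the
#' within-cluster structure of a subfamily.
#'
#' @param records a [protein_records] table with at least 3 rows.
#' @param scheme a [scoring_scheme()].
#' @param eps positive floor inside the log (default 1e-3, giving a
#'   distance ceiling of about 6.86).
#' @return A symmetric numeric matrix with zero diagonal, dimnames =
#'   record ids.
#' @export
distance_matrix <- function(records, scheme = scoring_scheme(),
                            eps = 1e-3) {
  stopifnot(is_protein_records(records))
  n <- nrow(records)
  if (n < 3L) stop("distance_matrix needs at least 3 records")
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      aln <- smith_waterman(records$sequence[[i]], records$sequence[[j]],
                            scheme)
      p <- aln$pct_identity / 100
      d[i, j] <- d[j, i] <- -log(max(p - 0.05, eps) / 0.95)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]) with
#' negative branch lengths clamped to zero (a warning reports how many;
#' additive inputs produce none).
#'
#' @param D symmetric distance matrix with ids as dimnames (n >= 3).
#' @return An unrooted `phylo` tree (2n-3 edges).
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 3L,
            isTRUE(all.equal(D, t(D))), all(diag(D) == 0),
            all(is.finite(D)))
  tree <- ape::nj(stats::as.dist(D))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    warning(sum(neg), " negative branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Sum of branch lengths along the path between two leaves
#'
#' Used to verify that a tree reproduces additive input distances.
#'
#' @param tree a `phylo`.
#' @param a,b leaf labels.
#' @return Path length (numeric).
#' @export
tree_path_length <- function(tree, a, b) {
  d <- ape::cophenetic.phylo(tree)
  d[a, b]
}

#' Write / read a distance matrix as square TSV
#'
#' Writes a labelled square table (first column ids, remaining columns
#' distances).  `read_distance_matrix` also accepts the PHYLIP square
#' dialect, where the first line holds only the taxon count and rows are
#' whitespace-separated.
#'
#' @param D distance matrix.
#' @param path file path.
#' @return `read_distance_matrix` returns the matrix.
#' @export
write_distance_matrix <- function(D, path) {
  tab <- data.frame(id = rownames(D), D, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*[0-9]+\\s*$", first)) {
    # PHYLIP square: count line, then "<id> <d1> <d2> ..." rows
    n <- as.integer(trimws(first))
    tab <- read.table(path, skip = 1L, stringsAsFactors = FALSE)
    stopifnot(nrow(tab) == n, ncol(tab) == n + 1L)
    D <- as.matrix(tab[, -1, drop = FALSE])
    rownames(D) <- colnames(D) <- tab[[1]]
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    D <- as.matrix(tab[, -1, drop = FALSE])
    rownames(D) <- tab[[1]]
  }
  storage.mode(D) <- "double"
  D
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
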