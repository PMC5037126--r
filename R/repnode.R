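#' Greedy collapse into representative nodes
#'
#' Reproduces the representative-node granularity of an SSN: sequences
#' sharing at least `identity_threshold` percent identity (default 60)
#' with a representative are collapsed into one node.  Records are
#' processed in order of decreasing length (ties broken by accession);
#' each record joins the first existing node whose *representative*
#' aligns to it at or above the threshold, otherwise it founds a new
#' node with itself as representative (CD-HIT-style linear-scan greedy
#' clustering).  Identity here follows the CD-HIT convention: identical
#' columns of the local alignment divided by the *shorter* full sequence
#' length.  (The BLAST-style aligned-column identity reported on network
#' edges is unsuitable for collapsing: two unrelated proteins typically
#' share a short local alignment of high column identity.)  Sequences
#' are compared full-length, before any cytochrome-b5 trimming.
#'
#' @param records a [protein_records] table.
#' @param identity_threshold percent identity in (0, 100].
#' @param scheme a [scoring_scheme()].
#' @return A data.frame of class `rep_nodes`: `rep_id`, `size`, and a
#'   `member_ids` list-column (each includes its `rep_id`).
#' @export
greedy_cluster <- function(records, identity_threshold = 60,
                           scheme = scoring_scheme()) {
  stopifnot(is_protein_records(records),
            identity_threshold > 0, identity_threshold <= 100)
  ord <- order(-records$length, records$id)
  reps <- character()     # representative ids, in founding order
  rep_seq <- character()
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (r in seq_along(reps)) {
      if (cluster_identity(rep_seq[[r]], records$sequence[[i]], scheme) >=
          identity_threshold) {
        members[[r]] <- c(members[[r]], records$id[[i]])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, records$id[[i]])
      rep_seq <- c(rep_seq, records$sequence[[i]])
      members <- c(members, list(records$id[[i]]))
    }
  }
  out <- data.frame(rep_id = reps, size = lengths(members),
                    stringsAsFactors = FALSE)
  out$member_ids <- members
  class(out) <- c("rep_nodes", "data.frame")
  out
}

#' Clustering identity between two sequences
#'
#' CD-HIT-style percent identity used by [greedy_cluster()]: identical
#' columns of the optimal local alignment divided by the length of the
#' shorter sequence.
#'
#' @param a,b amino-acid strings.
#' @param scheme a [scoring_scheme()].
#' @return Percent identity in [0, 100].
#' @export
cluster_identity <- function(a, b, scheme = scoring_scheme()) {
  aln <- smith_waterman(a, b, scheme)
  100 * aln$n_ident / min(nchar(a), nchar(b))
}

#' @export
`[.rep_nodes` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "member_ids" %in% names(out))
    class(out) <- c("rep_nodes", "data.frame")
  out
}

#' Annotation summary of one representative node
#'
#' @param node a single-row `rep_nodes` table.
#' @param records the [protein_records] table resolving all member ids.
#' @return A list: `has_characterized`, `kingdoms` (table over members),
#'   `substrates` (table over characterized members only),
#'   `all_fused_b5` (TRUE when every member carries a cytb5 domain).
#' @export
node_effective_annotation <- function(node, records) {
  stopifnot(nrow(node) == 1L)
  ids <- node$member_ids[[1]]
  idx <- match(ids, records$id)
  if (anyNA(idx))
    stop("unknown member id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  mem <- records[idx, ]
  chr <- mem[mem$characterized, ]
  list(has_characterized = nrow(chr) > 0L,
       kingdoms = table(mem$kingdom),
       substrates = table(chr$substrate),
       all_fused_b5 = all(has_cytb5(mem)))
}

#' Write / read a representative-node table
#'
#' TSV with columns `rep_id`, `size`, `member_ids` (semicolon-joined).
#'
#' @param repnodes a `rep_nodes` table.
#' @param path file path.
#' @return `read_repnodes` returns the `rep_nodes` table.
#' @export
write_repnodes <- function(repnodes, path) {
  tab <- data.frame(rep_id = repnodes$rep_id, size = repnodes$size,
                    member_ids = vapply(repnodes$member_ids, paste,
                                        "", collapse = ";"),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_repnodes
#' @export
read_repnodes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "character"))
  out <- data.frame(rep_id = tab$rep_id, size = tab$size,
                    stringsAsFactors = FALSE)
  out$member_ids <- strsplit(tab$member_ids, ";", fixed = TRUE)
  class(out) <- c("rep_nodes", "data.frame")
  out
}
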