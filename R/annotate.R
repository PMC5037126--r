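#' Residue charge classes
#'
#' Fixed partition of the 20-residue alphabet used for the binding-site
#' substitution report: positive \{K, R, H\}, negative \{D, E\},
#' polar-uncharged \{S, T, N, Q, Y, C\}, hydrophobic
#' \{A, V, L, I, M, F, W, G, P\}; X is classed `special`.  Histidine is
#' conventionally classed positive here; desaturase His-box residues are
#' catalytic, so an alternative table can be supplied where that
#' matters.
#'
#' @param residue character vector of single residues.
#' @param table optional named character vector residue -> class
#'   overriding the default.
#' @return Character vector of classes.
#' @export
charge_class <- function(residue, table = NULL) {
  if (is.null(table)) table <- default_charge_table()
  out <- table[residue]
  if (anyNA(out))
    stop("unclassified residue(s): ",
         paste(unique(residue[is.na(out)]), collapse = ", "))
  unname(out)
}

default_charge_table <- function() {
  c(K = "positive", R = "positive", H = "positive",
    D = "negative", E = "negative",
    S = "polar-uncharged", T = "polar-uncharged", N = "polar-uncharged",
    Q = "polar-uncharged", Y = "polar-uncharged", C = "polar-uncharged",
    A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
    I = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
    W = "hydrophobic", G = "hydrophobic", P = "hydrophobic",
    X = "special")
}

#' Summarize the clusters of a partition
#'
#' Per cluster: node and protein counts, kingdom composition, and the
#' consensus substrate head-group over *characterized* members only
#' (uncharacterized members carry no vote).  The consensus is the strict
#' majority label; a tie gives `"ambiguous"`, no characterized members
#' give `"unknown"` with support 0.
#'
#' @param partition an `ssn_partition`.
#' @param records the [protein_records] table resolving all members.
#' @return A data.frame of class `cluster_summaries`: `label`,
#'   `node_count`, `protein_count`, `characterized_count`,
#'   `consensus_substrate`, `consensus_support`, `family_name` (NA until
#'   [name_families()]), plus list-columns `kingdom_counts` and
#'   `substrate_counts`.
#' @export
summarize_clusters <- function(partition, records) {
  stopifnot(inherits(partition, "ssn_partition"))
  mem <- member_assignment(partition)
  idx <- match(names(mem), records$id)
  if (anyNA(idx))
    stop("unknown member id(s): ",
         paste(names(mem)[is.na(idx)], collapse = ", "))
  cl <- partition$clusters
  kingdom_counts <- substrate_counts <- vector("list", nrow(cl))
  characterized_count <- integer(nrow(cl))
  consensus <- character(nrow(cl))
  support <- numeric(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    ids <- names(mem)[mem == cl$label[i]]
    r <- records[match(ids, records$id), ]
    kingdom_counts[[i]] <- table(r$kingdom)
    chr <- r[r$characterized, ]
    substrate_counts[[i]] <- table(chr$substrate)
    characterized_count[i] <- nrow(chr)
    if (nrow(chr) == 0L) {
      consensus[i] <- "unknown"; support[i] <- 0
    } else {
      s <- substrate_counts[[i]]
      top <- s[s == max(s)]
      consensus[i] <- if (length(top) > 1L) "ambiguous" else names(top)
      support[i] <- max(s) / nrow(chr)
    }
  }
  out <- data.frame(label = cl$label, node_count = cl$node_count,
                    protein_count = cl$protein_count,
                    characterized_count = characterized_count,
                    consensus_substrate = consensus,
                    consensus_support = support,
                    family_name = NA_character_,
                    stringsAsFactors = FALSE)
  out$kingdom_counts <- kingdom_counts
  out$substrate_counts <- substrate_counts
  class(out) <- c("cluster_summaries", "data.frame")
  out
}

#' Name clusters from curated seed sequences
#'
#' A cluster containing seed accessions of exactly one family takes that
#' family's name (e.g. SCD1-like seeds labelling the first-desaturase
#' cluster "FD"); clusters containing seeds of two or more families are
#' flagged `"conflict"`; seedless clusters get systematic names
#' (`"cluster-01"` by protein-count rank).
#'
#' @param summaries a `cluster_summaries` table.
#' @param partition the `ssn_partition` the summaries came from.
#' @param seed_map named character vector: seed accession -> family name.
#' @return The summaries with `family_name` filled in.
#' @export
name_families <- function(summaries, partition, seed_map) {
  stopifnot(inherits(summaries, "cluster_summaries"),
            inherits(partition, "ssn_partition"))
  mem <- member_assignment(partition)
  missing <- setdiff(names(seed_map), names(mem))
  if (length(missing))
    warning("seed accession(s) absent from the network: ",
            paste(missing, collapse = ", "))
  seed_map <- seed_map[setdiff(names(seed_map), missing)]
  fam <- rep(NA_character_, nrow(summaries))
  for (i in seq_len(nrow(summaries))) {
    seeds_here <- unique(seed_map[names(seed_map)[
      mem[names(seed_map)] == summaries$label[i]]])
    if (length(seeds_here) == 1L) fam[i] <- seeds_here
    else if (length(seeds_here) > 1L) fam[i] <- "conflict"
  }
  rank <- order(-summaries$protein_count, summaries$label)
  sys_names <- character(nrow(summaries))
  sys_names[rank] <- sprintf("cluster-%02d", seq_len(nrow(summaries)))
  fam[is.na(fam)] <- sys_names[is.na(fam)]
  summaries$family_name <- fam
  summaries
}

#' Write cluster summaries as TSV
#'
#' @param summaries a `cluster_summaries` table.
#' @param path output TSV.
#' @export
write_cluster_summaries <- function(summaries, path) {
  tab <- summaries[, c("label", "node_count", "protein_count",
                       "characterized_count", "consensus_substrate",
                       "consensus_support", "family_name")]
  tab$kingdom_counts <- vapply(summaries$kingdom_counts, function(k)
    paste(sprintf("%s:%d", names(k), as.integer(k)), collapse = ";"), "")
  tab$substrate_counts <- vapply(summaries$substrate_counts, function(s)
    if (length(s) == 0L) "" else
      paste(sprintf("%s:%d", names(s), as.integer(s)), collapse = ";"), "")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binding-site substitution report between two sequences
#'
#' Globally aligns a reference to a query (affine-gap Needleman-Wunsch,
#' end gaps charged) and, for each user-supplied 1-based reference
#' position (e.g. the substrate head-group binding residues of a solved
#' structure), reports the aligned query residue (or gap) and the charge
#' class transition.  The kind of comparison behind contrasting an
#' acyl-CoA-binding site with an uncharged lipid-binding one: charged or
#' polar residues in one protein replaced by uncharged residues in the
#' other.
#'
#' @param ref_seq,query_seq amino-acid strings.
#' @param ref_positions integer vector of 1-based positions in `ref_seq`.
#' @param scheme a [scoring_scheme()].
#' @param charge_table optional residue -> class override for
#'   [charge_class()].
#' @return A data.frame (`ref_position`, `ref_residue`, `query_residue`
#'   — `"-"` for a gap —, `ref_class`, `query_class`, `charge_change`),
#'   with attribute `n_charged_to_uncharged`: the number of listed
#'   positions whose charged reference residue aligns to an uncharged
#'   residue or gap.
#' @export
binding_site_substitutions <- function(ref_seq, query_seq, ref_positions,
                                       scheme = scoring_scheme(),
                                       charge_table = NULL) {
  ref_positions <- as.integer(ref_positions)
  if (any(ref_positions < 1L) || any(ref_positions > nchar(ref_seq)))
    stop("ref position(s) out of range 1..", nchar(ref_seq))
  nw <- .nw_align_cpp(encode_seq(ref_seq, scheme),
                      encode_seq(query_seq, scheme),
                      scheme$matrix, scheme$gap_open, scheme$gap_extend)
  # map: reference position -> query position (0 = gap)
  qpos_of <- integer(nchar(ref_seq))
  qpos_of[nw$a_pos[nw$a_pos > 0L]] <- nw$b_pos[nw$a_pos > 0L]
  refc <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  qryc <- strsplit(query_seq, "", fixed = TRUE)[[1]]
  charged <- c("positive", "negative")
  out <- data.frame(ref_position = ref_positions,
                    ref_residue = refc[ref_positions],
                    query_residue = ifelse(qpos_of[ref_positions] > 0L,
                                           qryc[pmax(qpos_of[ref_positions], 1L)],
                                           "-"),
                    stringsAsFactors = FALSE)
  out$ref_class <- charge_class(out$ref_residue, charge_table)
  out$query_class <- ifelse(out$query_residue == "-", NA_character_,
                            charge_class(ifelse(out$query_residue == "-", "A",
                                                out$query_residue),
                                         charge_table))
  ref_chg <- out$ref_class %in% charged
  qry_chg <- !is.na(out$query_class) & out$query_class %in% charged
  opposite <- ref_chg & qry_chg & out$ref_class != out$query_class
  out$charge_change <- xor(ref_chg, qry_chg) | opposite
  attr(out, "n_charged_to_uncharged") <- sum(ref_chg & !qry_chg)
  out
}

#' Write a binding-site substitution report as TSV
#'
#' @param report output of [binding_site_substitutions()].
#' @param path output TSV.
#' @export
write_site_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
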