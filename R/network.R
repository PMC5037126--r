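#' Build a sequence similarity network over representative nodes
#'
#' Nodes are representative nodes; edges carry the logE of the
#' representative-vs-representative alignment.  The SSN is created at an
#' initial stringency (default -5) and can only be made stricter with
#' [apply_threshold()].
#'
#' @param repnodes a `rep_nodes` table from [greedy_cluster()].
#' @param edge_alignments data.frame from [all_vs_all()] run on the
#'   representative records (at most one row per unordered pair).
#' @param records optional [protein_records] table; when given, node
#'   attributes carry the [node_effective_annotation()] summaries.
#' @param stringency the logE cutoff the edges were generated at.
#' @return An object of class `ssn`: list with `nodes` (rep_nodes table
#'   plus annotation columns), `edges` (`node_a`, `node_b`, `logE`,
#'   `pct_identity`), and `stringency`.
#' @export
build_network <- function(repnodes, edge_alignments, records = NULL,
                          stringency = -5) {
  stopifnot(inherits(repnodes, "rep_nodes"))
  e <- edge_alignments
  if (nrow(e) > 0L) {
    unknown <- setdiff(c(e$query_id, e$subject_id), repnodes$rep_id)
    if (length(unknown))
      stop("edge references non-representative id(s): ",
           paste(unknown, collapse = ", "))
    if (any(e$query_id == e$subject_id))
      stop("self-edges are not allowed")
    key <- paste(pmin(e$query_id, e$subject_id),
                 pmax(e$query_id, e$subject_id))
    if (anyDuplicated(key))
      stop("duplicate unordered pair(s) in edge table")
    if (any(e$logE > stringency))
      stop("edge logE above the stated stringency")
  }
  nodes <- repnodes
  if (!is.null(records)) {
    ann <- lapply(seq_len(nrow(nodes)), function(i)
      node_effective_annotation(nodes[i, ], records))
    nodes$has_characterized <- vapply(ann, `[[`, logical(1), "has_characterized")
    nodes$all_fused_b5 <- vapply(ann, `[[`, logical(1), "all_fused_b5")
    nodes$kingdom_major <- vapply(ann, function(a) {
      k <- a$kingdoms
      if (length(k) == 0L) "unknown" else names(k)[which.max(k)]
    }, character(1))
    nodes$substrate_summary <- vapply(ann, function(a) {
      s <- a$substrates
      if (length(s) == 0L) "" else
        paste(sprintf("%s:%d", names(s), as.integer(s)), collapse = ";")
    }, character(1))
  }
  edges <- data.frame(node_a = pmin(e$query_id, e$subject_id),
                      node_b = pmax(e$query_id, e$subject_id),
                      logE = e$logE,
                      pct_identity = e$pct_identity,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, stringency = stringency),
            class = "ssn")
}

#' @export
print.ssn <- function(x, ...) {
  cat("SSN: ", nrow(x$nodes), " representative nodes (",
      sum(x$nodes$size), " proteins), ", nrow(x$edges),
      " edges at logE <= ", x$stringency, "\n", sep = "")
  invisible(x)
}

#' Tighten the stringency of an SSN
#'
#' Retains exactly the edges with `logE <= logE_threshold`; nodes are
#' never removed.  Loosening (a threshold above the current stringency)
#' is an error, so successive partitions always refine each other.
#'
#' @param ssn an `ssn`.
#' @param logE_threshold new stringency, at most the current one.
#' @return The filtered `ssn`.
#' @export
apply_threshold <- function(ssn, logE_threshold) {
  stopifnot(inherits(ssn, "ssn"))
  if (logE_threshold > ssn$stringency)
    stop("cannot loosen an SSN: threshold ", logE_threshold,
         " is above current stringency ", ssn$stringency)
  ssn$edges <- ssn$edges[ssn$edges$logE <= logE_threshold, , drop = FALSE]
  rownames(ssn$edges) <- NULL
  ssn$stringency <- logE_threshold
  ssn
}

#' Connected-component clusters of an SSN
#'
#' Isolated nodes form singleton clusters.  Cluster labels are canonical
#' (the lexicographically smallest rep_id in the cluster), so they are
#' invariant to node input order.
#'
#' @param ssn an `ssn`.
#' @return An object of class `ssn_partition`: list with `threshold`,
#'   `assignment` (named vector: node rep_id -> cluster label),
#'   `clusters` (data.frame `label`, `node_count`, `protein_count`),
#'   and `nodes` (the node table, for downstream summaries).
#' @export
connected_components <- function(ssn) {
  stopifnot(inherits(ssn, "ssn"))
  g <- igraph::graph_from_data_frame(
    ssn$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = ssn$nodes$rep_id, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  ids <- names(comp)
  label_of <- vapply(split(ids, comp), min, character(1))
  assignment <- setNames(label_of[as.character(comp)], ids)
  sizes <- setNames(ssn$nodes$size, ssn$nodes$rep_id)
  cl <- data.frame(label = sort(unique(assignment)), stringsAsFactors = FALSE)
  cl$node_count <- vapply(cl$label, function(l)
    sum(assignment == l), integer(1))
  cl$protein_count <- vapply(cl$label, function(l)
    sum(sizes[names(assignment)[assignment == l]]), integer(1))
  structure(list(threshold = ssn$stringency, assignment = assignment,
                 clusters = cl, nodes = ssn$nodes),
            class = "ssn_partition")
}

#' @export
print.ssn_partition <- function(x, ...) {
  cat("Partition at logE <= ", x$threshold, ": ", nrow(x$clusters),
      " cluster(s) over ", length(x$assignment), " nodes\n", sep = "")
  invisible(x)
}

#' Cluster assignment of every underlying protein
#'
#' Expands a node-level partition to member level: each protein inherits
#' the cluster of its representative node.
#'
#' @param partition an `ssn_partition`.
#' @return Named character vector: protein id -> cluster label.
#' @export
member_assignment <- function(partition) {
  stopifnot(inherits(partition, "ssn_partition"))
  nodes <- partition$nodes
  ids <- unlist(nodes$member_ids, use.names = FALSE)
  reps <- rep(nodes$rep_id, lengths(nodes$member_ids))
  setNames(partition$assignment[reps], ids)
}

#' Stringency sweep over descending logE thresholds
#'
#' @param ssn an `ssn`.
#' @param thresholds strictly decreasing logE values, all at most the
#'   SSN's stringency.  The classic presets (-13, -20, -30, -56, -65)
#'   form a valid sweep from an initial -5 network.
#' @return A list of `ssn_partition`s, one per threshold, in order; each
#'   partition refines the previous one.
#' @export
threshold_sweep <- function(ssn, thresholds) {
  stopifnot(inherits(ssn, "ssn"), length(thresholds) >= 1)
  if (any(diff(thresholds) >= 0))
    stop("thresholds must be strictly decreasing")
  if (any(thresholds > ssn$stringency))
    stop("all thresholds must be at most the SSN stringency")
  out <- vector("list", length(thresholds))
  cur <- ssn
  for (k in seq_along(thresholds)) {
    cur <- apply_threshold(cur, thresholds[k])
    out[[k]] <- connected_components(cur)
  }
  names(out) <- as.character(thresholds)
  out
}

#' Major clusters of a partition
#'
#' A major cluster is a connected component with strictly more than
#' `min_proteins` member sequences (counting all proteins collapsed into
#' its representative nodes).
#'
#' @param partition an `ssn_partition`.
#' @param min_proteins strict lower bound on protein count (default 50).
#' @return Character vector of cluster labels, sorted by protein count
#'   decreasing (ties by label).
#' @export
major_clusters <- function(partition, min_proteins = 50L) {
  stopifnot(inherits(partition, "ssn_partition"), min_proteins >= 1)
  cl <- partition$clusters
  cl <- cl[cl$protein_count > min_proteins, , drop = FALSE]
  cl <- cl[order(-cl$protein_count, cl$label), , drop = FALSE]
  cl$label
}

node_attribute_table <- function(ssn) {
  nodes <- ssn$nodes
  tab <- data.frame(rep_id = nodes$rep_id, size = nodes$size,
                    stringsAsFactors = FALSE)
  for (col in c("has_characterized", "all_fused_b5", "kingdom_major",
                "substrate_summary"))
    tab[[col]] <- if (col %in% names(nodes)) nodes[[col]] else NA
  tab
}

#' Export an SSN for external viewers
#'
#' Supported formats: `"edge-tsv"` (writes `<prefix>.edges.tsv` and
#' `<prefix>.nodes.tsv`; re-importing the edge TSV with [read_edges()]
#' reproduces the edge set exactly), `"graphml"`, and `"xgmml"`
#' (Cytoscape-readable).
#'
#' @param ssn an `ssn`.
#' @param path output path (a prefix for `"edge-tsv"`).
#' @param format one of `"edge-tsv"`, `"graphml"`, `"xgmml"`.
#' @return The path(s) written, invisibly.
#' @export
export_graph <- function(ssn, path, format = c("edge-tsv", "graphml", "xgmml")) {
  stopifnot(inherits(ssn, "ssn"))
  format <- match.arg(format)
  if (format == "edge-tsv") {
    ep <- paste0(path, ".edges.tsv")
    np <- paste0(path, ".nodes.tsv")
    write.table(ssn$edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(node_attribute_table(ssn), np, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(c(ep, np)))
  }
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      ssn$edges, directed = FALSE,
      vertices = node_attribute_table(ssn))
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  # XGMML, the Cytoscape network interchange dialect
  nodes <- node_attribute_table(ssn)
  idx <- setNames(seq_len(nrow(nodes)), nodes$rep_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<graph label="ssn logE<=%s" directed="0" xmlns="http://www.cs.rpi.edu/XGMML">',
            ssn$stringency)), con)
  for (i in seq_len(nrow(nodes))) {
    writeLines(sprintf('  <node id="%d" label="%s">', i, nodes$rep_id[i]), con)
    writeLines(sprintf('    <att name="size" type="integer" value="%d"/>',
                       nodes$size[i]), con)
    for (col in c("has_characterized", "all_fused_b5", "kingdom_major",
                  "substrate_summary"))
      if (!is.na(nodes[[col]][i]))
        writeLines(sprintf('    <att name="%s" type="string" value="%s"/>',
                           col, nodes[[col]][i]), con)
    writeLines('  </node>', con)
  }
  for (i in seq_len(nrow(ssn$edges))) {
    e <- ssn$edges[i, ]
    writeLines(sprintf(
      '  <edge source="%d" target="%d" label="%s-%s"><att name="logE" type="real" value="%.6g"/></edge>',
      idx[[e$node_a]], idx[[e$node_b]], e$node_a, e$node_b, e$logE), con)
  }
  writeLines('</graph>', con)
  invisible(path)
}

#' Persist / restore a built SSN as plain-text files
#'
#' Writes everything needed to classify queries later: representative
#' sequences (FASTA), annotations (TSV), the repnode table, the edge
#' table and the stringency.  `load_ssn` restores the `ssn` plus the
#' representative records.
#'
#' @param ssn an `ssn`.
#' @param records the [protein_records] table the SSN was built from
#'   (representative records are persisted).
#' @param dir directory to create/use.
#' @param summaries optional `cluster_summaries` to persist alongside.
#' @return `save_ssn` the directory; `load_ssn` a list `ssn`, `records`,
#'   `summaries` (NULL when none were saved).
#' @export
save_ssn <- function(ssn, records, dir, summaries = NULL) {
  stopifnot(inherits(ssn, "ssn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reps <- records[match(ssn$nodes$rep_id, records$id), ]
  write_fasta(reps, file.path(dir, "representatives.fasta"))
  write_annotations(reps, file.path(dir, "representatives.tsv"))
  write_repnodes(ssn$nodes[, c("rep_id", "size", "member_ids")],
                 file.path(dir, "repnodes.tsv"))
  write.table(node_attribute_table(ssn), file.path(dir, "nodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ssn$edges, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sprintf("stringency\t%.10g", ssn$stringency),
             file.path(dir, "meta.tsv"))
  if (!is.null(summaries))
    write_cluster_summaries(summaries, file.path(dir, "summaries.tsv"))
  invisible(dir)
}

#' @rdname save_ssn
#' @export
load_ssn <- function(dir) {
  reps <- read_fasta(file.path(dir, "representatives.fasta"))
  reps <- join_annotations(reps, file.path(dir, "representatives.tsv"))
  repnodes <- read_repnodes(file.path(dir, "repnodes.tsv"))
  edges <- read.delim(file.path(dir, "edges.tsv"), stringsAsFactors = FALSE)
  meta <- read.delim(file.path(dir, "meta.tsv"), header = FALSE)
  stringency <- as.numeric(meta$V2[meta$V1 == "stringency"])
  aln <- if (nrow(edges) > 0L)
    data.frame(query_id = edges$node_a, subject_id = edges$node_b,
               logE = edges$logE, pct_identity = edges$pct_identity,
               stringsAsFactors = FALSE)
  else
    data.frame(query_id = character(), subject_id = character(),
               logE = numeric(), pct_identity = numeric())
  ssn <- build_network(repnodes, aln, stringency = stringency)
  attrs <- read.delim(file.path(dir, "nodes.tsv"), stringsAsFactors = FALSE)
  ix <- match(ssn$nodes$rep_id, attrs$rep_id)
  for (col in c("has_characterized", "all_fused_b5", "kingdom_major",
                "substrate_summary"))
    ssn$nodes[[col]] <- attrs[[col]][ix]
  ssn$nodes$substrate_summary[is.na(ssn$nodes$substrate_summary)] <- ""
  sp <- file.path(dir, "summaries.tsv")
  summaries <- if (file.exists(sp)) read.delim(sp, stringsAsFactors = FALSE)
  else NULL
  list(ssn = ssn, records = reps, summaries = summaries)
}
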