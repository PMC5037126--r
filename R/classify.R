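#' Classify a query sequence against a built SSN
#'
#' Nearest-representative (1-NN in logE) assignment: the query is
#' aligned against every representative sequence (the cytochrome-b5 rule
#' applies pairwise — full sequences only when both the query and the
#' representative carry a cytb5 domain), the minimum logE wins, and if
#' it clears the cutoff the query inherits that representative's
#' cluster, family name and consensus substrate.  Confidence is the
#' assigned cluster's consensus support, i.e. the fraction of its
#' characterized members voting for the consensus substrate.
#'
#' @param query a single-row [protein_records] table.
#' @param ssn an `ssn` at the stringency classification should use.
#' @param records [protein_records] table resolving the representative
#'   sequences (and all members, for summaries).
#' @param summaries `cluster_summaries` of the SSN's partition at the
#'   same stringency (see [summarize_clusters()]); pass a family-named
#'   table from [name_families()] to fill `family_name`.
#' @param cutoff_logE assignment cutoff; defaults to the SSN stringency.
#' @param scheme a [scoring_scheme()].
#' @return One-row data.frame: `query_id`, `best_rep_id`, `best_logE`,
#'   `cluster_label`, `family_name`, `predicted_substrate`, `confidence`,
#'   `status` (`"assigned"` or `"unclassified"`).  Ties on logE break by
#'   higher percent identity, then lexicographic rep_id.
#' @export
classify_query <- function(query, ssn, records, summaries,
                           cutoff_logE = ssn$stringency,
                           scheme = scoring_scheme()) {
  stopifnot(inherits(ssn, "ssn"), nrow(query) == 1L)
  if (nrow(ssn$nodes) == 0L) stop("empty SSN")
  reps <- records[match(ssn$nodes$rep_id, records$id), ]
  if (anyNA(reps$id)) stop("representative(s) missing from records")
  q_fused <- has_cytb5(query)
  q_full <- query$sequence[[1]]
  q_trim <- effective_sequence(query, "desaturase-only")
  # node-level b5 rule when node annotations are present
  r_fused <- if ("all_fused_b5" %in% names(ssn$nodes))
    ssn$nodes$all_fused_b5 else has_cytb5(reps)

  best <- NULL
  for (i in seq_len(nrow(reps))) {
    use_full <- q_fused && r_fused[i]
    qs <- if (use_full) q_full else q_trim
    rs <- if (use_full) reps$sequence[[i]] else
      effective_sequence(reps[i, ], "desaturase-only")
    aln <- smith_waterman(qs, rs, scheme)
    cand <- list(rep_id = reps$id[[i]], logE = aln$logE,
                 pct = aln$pct_identity)
    if (is.null(best) ||
        cand$logE < best$logE ||
        (cand$logE == best$logE && cand$pct > best$pct) ||
        (cand$logE == best$logE && cand$pct == best$pct &&
         cand$rep_id < best$rep_id))
      best <- cand
  }

  res <- data.frame(query_id = query$id[[1]], best_rep_id = best$rep_id,
                    best_logE = best$logE, cluster_label = NA_character_,
                    family_name = NA_character_,
                    predicted_substrate = NA_character_,
                    confidence = NA_real_, status = "unclassified",
                    stringsAsFactors = FALSE)
  if (best$logE <= cutoff_logE) {
    part <- connected_components(ssn)
    lab <- part$assignment[[best$rep_id]]
    res$cluster_label <- lab
    res$status <- "assigned"
    row <- summaries[summaries$label == lab, ]
    if (nrow(row) == 1L) {
      res$family_name <- row$family_name
      res$predicted_substrate <- row$consensus_substrate
      res$confidence <- row$consensus_support
    }
  }
  res
}

#' Classify many queries
#'
#' @param queries a [protein_records] table.
#' @inheritParams classify_query
#' @return Data.frame with one [classify_query()] row per query.
#' @export
classify_queries <- function(queries, ssn, records, summaries,
                             cutoff_logE = ssn$stringency,
                             scheme = scoring_scheme()) {
  do.call(rbind, lapply(seq_len(nrow(queries)), function(i)
    classify_query(queries[i, ], ssn, records, summaries,
                   cutoff_logE, scheme)))
}
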