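#' Scoring scheme for pairwise alignment and E-value statistics
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters `lambda` and `K` used to convert raw
#' alignment scores into bit scores and E-values.  The defaults are the
#' standard gapped protein-search settings: BLOSUM62 with gap open 11 /
#' gap extend 1 and the published gapped Karlin-Altschul parameters
#' lambda = 0.267, K = 0.041.  A gap of length k costs
#' `gap_open + k * gap_extend`.
#'
#' @param matrix integer substitution matrix with residue dimnames
#'   (defaults to BLOSUM62 restricted to the 20 canonical residues + X).
#' @param gap_open positive integer gap-opening penalty.
#' @param gap_extend positive integer gap-extension penalty; must not
#'   exceed `gap_open`.
#' @param lambda Karlin-Altschul lambda (nats per score unit), > 0.
#' @param K Karlin-Altschul K (dimensionless), > 0.
#' @return An object of class `scoring_scheme`.
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["A", "A"]
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) {
    matrix <- blosum62()
  }
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must have identical row/column residue names")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (gap_open <= 0L || gap_extend <= 0L)
    stop("gap penalties must be positive")
  if (gap_extend > gap_open)
    stop("gap_extend must not exceed gap_open")
  if (!(lambda > 0) || !(K > 0))
    stop("lambda and K must be positive")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

# BLOSUM62 restricted to the package alphabet, taken from Biostrings
# (cached after the first load).
.blosum_cache <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(.blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    storage.mode(m) <- "integer"
    .blosum_cache$m <- m
  }
  .blosum_cache$m
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("Scoring scheme: ", nrow(x$matrix), "x", ncol(x$matrix),
      " matrix, gap open ", x$gap_open, ", gap extend ", x$gap_extend,
      ", lambda = ", x$lambda, ", K = ", x$K, "\n", sep = "")
  invisible(x)
}

encode_seq <- function(seq, scheme) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], rownames(scheme$matrix))
  if (anyNA(codes))
    stop("sequence contains residues absent from the substitution matrix")
  codes - 1L
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' Exact affine-gap local alignment (Gotoh three-state dynamic
#' programming), as used for every edge of the sequence similarity
#' network.  The raw score is floored at zero; an empty optimal
#' alignment yields score 0, alignment length 0 and percent identity 0.
#' Percent identity is computed over aligned columns including gap
#' columns.
#'
#' @param a,b non-empty amino-acid strings.
#' @param scheme a [scoring_scheme()].
#' @param m,n effective search-space lengths used for the E-value;
#'   default to the lengths of `a` and `b`.
#' @return A list of class `pair_alignment` with elements `raw_score`,
#'   `bit_score`, `logE`, `pct_identity`, `aln_len`, `n_ident` (identical
#'   columns), `m`, `n`.
#' @examples
#' smith_waterman("MKTAY", "MKTAY")$raw_score  # 26 with BLOSUM62
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme(),
                           m = nchar(a), n = nchar(b)) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty")
  res <- .sw_align_cpp(encode_seq(a, scheme), encode_seq(b, scheme),
                       scheme$matrix, scheme$gap_open, scheme$gap_extend)
  bits <- bit_score(res$score, scheme)
  structure(list(
    raw_score = res$score,
    bit_score = bits,
    logE = log_evalue(bits, m, n),
    pct_identity = if (res$aln_len > 0) 100 * res$n_ident / res$aln_len else 0,
    aln_len = res$aln_len,
    n_ident = res$n_ident,
    m = as.integer(m), n = as.integer(n)
  ), class = "pair_alignment")
}

#' Bit score from a raw alignment score
#'
#' Karlin-Altschul normalisation `(lambda * S - ln K) / ln 2`.
#'
#' @param raw_score raw alignment score (local alignment scores are
#'   always >= 0, but the transform is defined for any real value).
#' @param scheme a [scoring_scheme()] supplying `lambda` and `K`.
#' @return Bit score (real).
#' @export
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' Base-10 log E-value of an alignment
#'
#' For a pairwise search space of `m * n` residues,
#' `E = m * n * 2^(-bit_score)`; this returns `log10(E)`.  More negative
#' values are more significant; the network thresholds (-5 ... -65) act
#' on this quantity.
#'
#' @param bit_score bit score.
#' @param m,n lengths (residues) of the two sequences actually aligned.
#' @return `log10` of the expected number of chance alignments.
#' @export
log_evalue <- function(bit_score, m, n) {
  stopifnot(all(m >= 1), all(n >= 1))
  log10(m) + log10(n) - bit_score * log10(2)
}

#' All-vs-all alignment stage of the SSN
#'
#' Aligns every unordered pair of records and keeps pairs whose logE is
#' at or below the initial cutoff (default -5, the standard initial
#' network generation cutoff).  When `b5_rule` is on, a pair is aligned
#' on full sequences only if *both* records carry a fused cytochrome b5
#' domain; any mixed or unfused pair is aligned on the
#' desaturase-only (cytb5-trimmed) sequences.  `m` and `n` record the
#' lengths of the sequences actually aligned, so the rule is auditable
#' from the edge table.
#'
#' @param records a [protein_records] table.
#' @param scheme a [scoring_scheme()].
#' @param initial_cutoff_logE edges with logE above this are dropped.
#' @param b5_rule logical; apply the cytochrome-b5 inclusion rule.
#' @param fused logical vector (one per record) saying which records
#'   count as cytochrome-b5-fused for the rule.  Defaults to the
#'   record's own domain annotation; when the records are node
#'   representatives, pass the node-level "all members fused" flags so
#'   the domain is only included when every protein in both connecting
#'   nodes carries it.
#' @return A data.frame with one row per retained unordered pair:
#'   `query_id`, `subject_id` (lexicographic order), `raw_score`,
#'   `bit_score`, `logE`, `pct_identity`, `aln_len`, `m`, `n`.
#' @export
all_vs_all <- function(records, scheme = scoring_scheme(),
                       initial_cutoff_logE = -5, b5_rule = TRUE,
                       fused = has_cytb5(records)) {
  stopifnot(is_protein_records(records), length(fused) == nrow(records))
  if (nrow(records) < 2L)
    stop("all_vs_all needs at least 2 records")
  ids <- records$id
  full <- setNames(records$sequence, ids)
  trimmed <- setNames(
    vapply(seq_len(nrow(records)),
           function(i) effective_sequence(records[i, ], "desaturase-only"),
           character(1)),
    ids)
  fused <- setNames(fused, ids)

  out <- vector("list", nrow(records) * (nrow(records) - 1L) / 2L)
  k <- 0L
  ord <- order(ids)
  for (ii in seq_along(ord)[-length(ord)]) {
    for (jj in seq((ii + 1L), length(ord))) {
      qi <- ids[ord[ii]]; si <- ids[ord[jj]]
      use_full <- !b5_rule || (fused[[qi]] && fused[[si]])
      sa <- if (use_full) full[[qi]] else trimmed[[qi]]
      sb <- if (use_full) full[[si]] else trimmed[[si]]
      aln <- smith_waterman(sa, sb, scheme)
      if (aln$logE <= initial_cutoff_logE) {
        k <- k + 1L
        out[[k]] <- data.frame(
          query_id = qi, subject_id = si, raw_score = aln$raw_score,
          bit_score = aln$bit_score, logE = aln$logE,
          pct_identity = aln$pct_identity, aln_len = aln$aln_len,
          m = aln$m, n = aln$n, stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      raw_score = integer(), bit_score = numeric(),
                      logE = numeric(), pct_identity = numeric(),
                      aln_len = integer(), m = integer(), n = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(k)])
}

#' Write / read an SSN edge table
#'
#' Tab-separated edge list as produced by [all_vs_all()]; re-reading
#' reproduces the table exactly.
#'
#' @param edges edge data.frame.
#' @param path file path.
#' @return `read_edges` returns the edge data.frame.
#' @export
write_edges <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
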