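# Shared fixtures and the independent alignment oracle.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
          "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Independent exhaustive three-state affine-gap local-alignment oracle,
# written as plain R loops over the textbook recursion.  Deliberately
# separate from the package's compiled implementation; used only to
# check raw scores.  Gap of length k costs go + k * ge.
sw_oracle <- function(a, b, scheme = scoring_scheme()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  mat <- scheme$matrix; go <- scheme$gap_open; ge <- scheme$gap_extend
  H <- matrix(0, n + 1, m + 1)       # match state
  E <- matrix(-Inf, n + 1, m + 1)    # gap in b
  F <- matrix(-Inf, n + 1, m + 1)    # gap in a
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - go - ge, E[i - 1, j] - ge)
      F[i, j] <- max(H[i, j - 1] - go - ge, F[i, j - 1] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) +
        mat[av[i - 1], bv[j - 1]]
      best <- max(best, H[i, j])
    }
  }
  best
}

# Mutate a character-vector sequence at the given positions, replacing
# each residue by a fixed different one (next residue in the alphabet).
mutate_at <- function(x, pos) {
  x[pos] <- AA20[(match(x[pos], AA20) %% 20L) + 1L]
  x
}

# Minimal rep_nodes table for graph-level tests that need no alignment.
make_repnodes <- function(rep_ids, sizes = NULL, member_ids = NULL) {
  if (is.null(member_ids)) member_ids <- as.list(rep_ids)
  if (is.null(sizes)) sizes <- lengths(member_ids)
  out <- data.frame(rep_id = rep_ids, size = as.integer(sizes),
                    stringsAsFactors = FALSE)
  out$member_ids <- member_ids
  class(out) <- c("rep_nodes", "data.frame")
  out
}

# Edge table in the all_vs_all output shape from a simple spec list.
make_edges <- function(a, b, logE, pct = 50) {
  data.frame(query_id = pmin(a, b), subject_id = pmax(a, b),
             logE = logE, pct_identity = rep_len(pct, length(logE)),
             stringsAsFactors = FALSE)
}

# Small annotated corpus used across annotate/classify tests.
toy_records <- function() {
  protein_records(
    id = c("r1", "r2", "r3", "r4", "r5"),
    sequence = vapply(1:5, function(i) {
      set.seed(100 + i); rand_seq(60)
    }, character(1)),
    kingdom = c("animal", "animal", "plant", "fungus", "unknown"),
    characterized = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    substrate = c("acyl-CoA", "acyl-CoA", "acyl-PC", "unknown", "unknown"))
}

# Default scheme shared across tests (avoids re-loading the matrix).
SC <- scoring_scheme()
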