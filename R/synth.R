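AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
          "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Configuration for the synthetic superfamily generator
#'
#' Describes a star-like hierarchy root -> families -> subfamilies ->
#' tips under a uniform 20-state substitution model: each branch mutates
#' every site independently with the stated probability to a uniformly
#' chosen *different* residue.  Defaults plant four families of three
#' subfamilies with 25 tips each (400 aa), with tip/subfamily/family
#' branch substitution probabilities 0.1 / 0.35 / 0.7 — giving the
#' within-subfamily >> within-family >> between-family identity tiers an
#' SSN resolves — plus 50 unrelated background sequences.  Half of one
#' designated family carries a 90-residue fused accessory segment
#' recorded as a `cytb5` domain, and 20% of tips per subfamily are
#' marked characterized with the subfamily's substrate label.
#'
#' @param seed integer RNG seed; the whole corpus is reproducible from it.
#' @param n_families,subfamilies_per_family,seqs_per_subfamily counts.
#' @param seq_len core sequence length in residues (>= 50).
#' @param p_family,p_subfamily,p_tip per-site substitution probabilities
#'   on family / subfamily / tip branches, each in [0, 1).
#' @param frac_fused fraction of the designated family's tips given the
#'   fused accessory segment.
#' @param fused_family index of the family carrying fusions.
#' @param frac_characterized fraction of tips per subfamily exposing the
#'   subfamily substrate label (at least one per subfamily when > 0).
#' @param n_background number of unrelated uniform-random sequences.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_families = 4L,
                         subfamilies_per_family = 3L,
                         seqs_per_subfamily = 25L, seq_len = 400L,
                         p_family = 0.7, p_subfamily = 0.35, p_tip = 0.1,
                         frac_fused = 0.5, fused_family = 1L,
                         frac_characterized = 0.2, n_background = 50L) {
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              subfamilies_per_family = as.integer(subfamilies_per_family),
              seqs_per_subfamily = as.integer(seqs_per_subfamily),
              seq_len = as.integer(seq_len), p_family = p_family,
              p_subfamily = p_subfamily, p_tip = p_tip,
              frac_fused = frac_fused, fused_family = as.integer(fused_family),
              frac_characterized = frac_characterized,
              n_background = as.integer(n_background))
  with(cfg, stopifnot(
    n_families >= 1, subfamilies_per_family >= 1, seqs_per_subfamily >= 1,
    seq_len >= 50,
    p_family >= 0, p_family < 1, p_subfamily >= 0, p_subfamily < 1,
    p_tip >= 0, p_tip < 1,
    frac_fused >= 0, frac_fused <= 1, fused_family >= 1,
    fused_family <= n_families,
    frac_characterized >= 0, frac_characterized <= 1, n_background >= 0))
  structure(cfg, class = "synth_config")
}

# Mutate each site independently with probability p to a uniformly
# chosen different residue (character-vector in, character-vector out).
mutate_seq <- function(x, p) {
  if (p <= 0) return(x)
  hit <- which(runif(length(x)) < p)
  if (length(hit)) {
    off <- sample.int(19L, length(hit), replace = TRUE)
    x[hit] <- AA20[((match(x[hit], AA20) - 1L + off) %% 20L) + 1L]
  }
  x
}

ACCESSORY_LEN <- 90L

#' Generate a synthetic superfamily with planted truth
#'
#' See [synth_config()] for the model.  Substrate labels are drawn per
#' subfamily from the five lipid head-group classes; kingdoms are
#' assigned per family; fused tips get the accessory segment appended at
#' the C-terminus with a `cytb5` domain range recorded; background
#' sequences are fresh uniform draws with no annotations.
#'
#' @param config a [synth_config()].
#' @return A list: `records` (a [protein_records] table) and `truth`
#'   (data.frame `id`, `family`, `subfamily`, `substrate`, `fused`,
#'   `characterized`; background rows have `family = NA`).
#' @export
generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  L <- config$seq_len
  root <- sample(AA20, L, replace = TRUE)
  acc_root <- sample(AA20, ACCESSORY_LEN, replace = TRUE)
  substr_pool <- c("acyl-CoA", "acyl-PC", "MGDG", "sphingolipid",
                   "phospholipid")
  regio_pool <- c("D9", "D12", "D6", "D5", "D4", "D8", "D15")
  kingdom_pool <- c("animal", "plant", "fungus", "protist",
                    "cyanobacteria", "other-prokaryote")

  ids <- seqs <- character()
  kingdom <- organism <- substrate <- regio <- character()
  characterized <- fused <- logical()
  domains <- list()
  t_family <- t_subfamily <- t_substrate <- character()

  for (f in seq_len(config$n_families)) {
    fam_anc <- mutate_seq(root, config$p_family)
    fam_kingdom <- kingdom_pool[((f - 1L) %% length(kingdom_pool)) + 1L]
    for (s in seq_len(config$subfamilies_per_family)) {
      sub_anc <- mutate_seq(fam_anc, config$p_subfamily)
      sub_substrate <- sample(substr_pool, 1L)
      sub_regio <- sample(regio_pool, 1L)
      n_tip <- config$seqs_per_subfamily
      n_chr <- if (config$frac_characterized > 0)
        max(1L, round(config$frac_characterized * n_tip)) else 0L
      chr_idx <- if (n_chr > 0) sort(sample.int(n_tip, n_chr)) else integer()
      for (t in seq_len(n_tip)) {
        tip <- mutate_seq(sub_anc, config$p_tip)
        id <- sprintf("F%dS%dT%02d", f, s, t)
        ids <- c(ids, id)
        seqs <- c(seqs, paste(tip, collapse = ""))
        kingdom <- c(kingdom, fam_kingdom)
        organism <- c(organism, sprintf("synthetic taxon %s", id))
        is_chr <- t %in% chr_idx
        characterized <- c(characterized, is_chr)
        substrate <- c(substrate, if (is_chr) sub_substrate else "unknown")
        regio <- c(regio, if (is_chr) sub_regio else "")
        fused <- c(fused, FALSE)  # decided per family below
        domains <- c(domains, list(data.frame(
          label = "desaturase", start = 1L, end = L,
          stringsAsFactors = FALSE)))
        t_family <- c(t_family, sprintf("F%d", f))
        t_subfamily <- c(t_subfamily, sprintf("F%dS%d", f, s))
        t_substrate <- c(t_substrate, sub_substrate)
      }
    }
    if (f == config$fused_family && config$frac_fused > 0) {
      fam_idx <- which(t_family == sprintf("F%d", f))
      n_fuse <- round(config$frac_fused * length(fam_idx))
      if (n_fuse > 0) {
        fuse_idx <- sort(sample(fam_idx, n_fuse))
        for (i in fuse_idx) {
          acc <- mutate_seq(acc_root, config$p_tip)
          seqs[i] <- paste0(seqs[i], paste(acc, collapse = ""))
          fused[i] <- TRUE
          domains[[i]] <- rbind(domains[[i]], data.frame(
            label = "cytb5", start = L + 1L, end = L + ACCESSORY_LEN,
            stringsAsFactors = FALSE))
        }
      }
    }
  }

  for (k in seq_len(config$n_background)) {
    ids <- c(ids, sprintf("BG%03d", k))
    seqs <- c(seqs, paste(sample(AA20, L, replace = TRUE), collapse = ""))
    kingdom <- c(kingdom, "unknown")
    organism <- c(organism, "synthetic background")
    characterized <- c(characterized, FALSE)
    substrate <- c(substrate, "unknown")
    regio <- c(regio, "")
    fused <- c(fused, FALSE)
    domains <- c(domains, list(empty_domains()))
    t_family <- c(t_family, NA_character_)
    t_subfamily <- c(t_subfamily, NA_character_)
    t_substrate <- c(t_substrate, NA_character_)
  }

  records <- protein_records(ids, seqs, kingdom = kingdom,
                             organism = organism,
                             characterized = characterized,
                             substrate = substrate, regio = regio,
                             domains = domains)
  truth <- data.frame(id = ids, family = t_family, subfamily = t_subfamily,
                      substrate = t_substrate, fused = fused,
                      characterized = characterized,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Expected identity along a chain of substitution events
#'
#' Closed form for the expected per-site identity between two sequences
#' separated by a chain of branches with the given per-site substitution
#' probabilities, under the uniform 20-state model with
#' back-substitution: per step,
#' `P(same) <- P(same) * (1 - p) + (1 - P(same)) * p / 19`.
#'
#' @param path_probs numeric vector of per-branch substitution
#'   probabilities, each in [0, 1); an empty path gives 1.
#' @return Expected fractional identity.
#' @export
expected_identity <- function(path_probs) {
  stopifnot(all(path_probs >= 0), all(path_probs < 1))
  r <- 1
  for (p in path_probs) r <- r * (1 - p) + (1 - r) * p / 19
  r
}

#' Full-pipeline convenience wrapper
#'
#' Length-filter, greedy repnode collapse, all-vs-all alignment of the
#' representatives, and SSN construction at the initial cutoff.
#'
#' @param records a [protein_records] table.
#' @param scheme a [scoring_scheme()].
#' @param identity_threshold repnode collapse threshold (percent).
#' @param initial_cutoff_logE initial network cutoff.
#' @param b5_rule apply the cytochrome-b5 inclusion rule.
#' @param min_len,max_len length filter bounds.
#' @return A list: `records` (filtered), `repnodes`, `edges`, `ssn`.
#' @export
ssn_pipeline <- function(records, scheme = scoring_scheme(),
                         identity_threshold = 60,
                         initial_cutoff_logE = -5, b5_rule = TRUE,
                         min_len = 250L, max_len = 550L) {
  records <- filter_by_length(records, min_len, max_len)
  repnodes <- greedy_cluster(records, identity_threshold, scheme)
  reps <- records[match(repnodes$rep_id, records$id), ]
  # node-level b5 rule: the fused domain enters an edge's E-value only
  # when every member protein of both connecting nodes carries it
  node_fused <- vapply(repnodes$member_ids, function(ids)
    all(has_cytb5(records[match(ids, records$id), ])), logical(1))
  edges <- all_vs_all(reps, scheme, initial_cutoff_logE, b5_rule,
                      fused = node_fused)
  ssn <- build_network(repnodes, edges, records = records,
                       stringency = initial_cutoff_logE)
  list(records = records, repnodes = repnodes, edges = edges, ssn = ssn)
}

#' Planted-structure recovery experiment
#'
#' Runs the whole pipeline on a synthetic corpus and measures how well
#' connected components recover the planted families and subfamilies
#' (adjusted Rand index over planted tips; background sequences carry no
#' planted label and are excluded from the ARI), plus hold-out
#' classification: a fraction of tips is withheld *before* the network
#' is built and classified against the strictest partition.
#'
#' @param config a [synth_config()].
#' @param thresholds strictly decreasing logE thresholds for the sweep
#'   (all below the initial cutoff).  The defaults -13 (family level)
#'   and -100 (subfamily level) were frozen from a pilot sweep of the
#'   default configuration.
#' @param holdout_frac fraction of planted tips withheld for
#'   classification (0 disables the hold-out arm).
#' @param scheme a [scoring_scheme()].
#' @param initial_cutoff_logE initial network cutoff.
#' @return A list of class `recovery_report`: `sweep` (data.frame
#'   `threshold`, `n_components`, `ari_family`, `ari_subfamily`),
#'   `holdout` (list `n`, `accuracy`, `substrate_match`), and the built
#'   `pipeline` objects.
#' @export
recovery_experiment <- function(config = synth_config(),
                                thresholds = c(-13, -100),
                                holdout_frac = 0.2,
                                scheme = scoring_scheme(),
                                initial_cutoff_logE = -5) {
  stopifnot(all(diff(thresholds) < 0),
            all(thresholds <= initial_cutoff_logE))
  gen <- generate(config)
  truth <- gen$truth
  planted_ids <- truth$id[!is.na(truth$family)]

  held <- character()
  if (holdout_frac > 0) {
    n_hold <- max(1L, round(holdout_frac * length(planted_ids)))
    held <- sort(sample(planted_ids, n_hold))
  }
  corpus <- gen$records[!(gen$records$id %in% held), ]

  pipe <- ssn_pipeline(corpus, scheme,
                       initial_cutoff_logE = initial_cutoff_logE)
  parts <- threshold_sweep(pipe$ssn, thresholds)

  sweep <- data.frame(threshold = thresholds,
                      n_components = NA_integer_,
                      ari_family = NA_real_, ari_subfamily = NA_real_)
  for (k in seq_along(parts)) {
    mem <- member_assignment(parts[[k]])
    keep <- intersect(names(mem), planted_ids)
    ti <- match(keep, truth$id)
    sweep$n_components[k] <- nrow(parts[[k]]$clusters)
    sweep$ari_family[k] <-
      mclust::adjustedRandIndex(mem[keep], truth$family[ti])
    sweep$ari_subfamily[k] <-
      mclust::adjustedRandIndex(mem[keep], truth$subfamily[ti])
  }

  holdout <- list(n = length(held), accuracy = NA_real_,
                  substrate_match = NA_real_)
  if (length(held)) {
    strict <- parts[[length(parts)]]
    ssn_strict <- apply_threshold(pipe$ssn, thresholds[length(thresholds)])
    summaries <- summarize_clusters(strict, pipe$records)
    mem <- member_assignment(strict)
    # planted subfamily -> cluster holding the majority of its retained tips
    sub_of <- setNames(truth$subfamily, truth$id)
    retained <- intersect(names(mem), planted_ids)
    sub_cluster <- tapply(mem[retained], sub_of[retained], function(x)
      names(sort(table(x), decreasing = TRUE))[1])
    res <- classify_queries(gen$records[gen$records$id %in% held, ],
                            ssn_strict, pipe$records, summaries,
                            scheme = scheme)
    expected_cluster <- unname(sub_cluster[sub_of[res$query_id]])
    correct <- res$status == "assigned" &
      !is.na(expected_cluster) & res$cluster_label == expected_cluster
    holdout$accuracy <- mean(correct)
    planted_sub <- setNames(truth$substrate, truth$id)
    informative <- correct & !is.na(res$predicted_substrate) &
      !(res$predicted_substrate %in% c("unknown", "ambiguous"))
    holdout$substrate_match <- if (any(informative))
      mean(res$predicted_substrate[informative] ==
             planted_sub[res$query_id[informative]]) else NA_real_
    holdout$results <- res
  }

  structure(list(sweep = sweep, holdout = holdout, pipeline = pipe,
                 truth = truth, held_out = held),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Planted-structure recovery\n")
  cat(sprintf("  corpus: %d records -> %d repnodes, %d initial edges\n",
              nrow(x$pipeline$records), nrow(x$pipeline$repnodes),
              nrow(x$pipeline$edges)))
  for (k in seq_len(nrow(x$sweep)))
    cat(sprintf("  logE <= %g: %d components, family ARI %.3f, subfamily ARI %.3f\n",
                x$sweep$threshold[k], x$sweep$n_components[k],
                x$sweep$ari_family[k], x$sweep$ari_subfamily[k]))
  if (x$holdout$n > 0)
    cat(sprintf("  hold-out: %d queries, accuracy %.3f, substrate match %.3f\n",
                x$holdout$n, x$holdout$accuracy, x$holdout$substrate_match))
  invisible(x)
}

#' Write the recovery report sweep as TSV
#'
#' @param report a `recovery_report`.
#' @param path output TSV.
#' @export
write_recovery_report <- function(report, path) {
  write.table(report$sweep, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
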