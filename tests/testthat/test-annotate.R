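test_that("charge classes partition the alphabet", {
  tab <- fadssn:::default_charge_table()
  expect_setequal(names(tab), c(AA20, "X"))
  expect_equal(anyDuplicated(names(tab)), 0L)
  expect_equal(unname(table(tab)[c("positive", "negative")]),
               c(3L, 2L), ignore_attr = TRUE)
  expect_equal(charge_class(c("K", "D", "S", "L")),
               c("positive", "negative", "polar-uncharged", "hydrophobic"))
  expect_error(charge_class("B"), "unclassified")
})

test_that("cluster summaries compute strict-majority consensus", {
  rec <- protein_records(
    sprintf("p%d", 1:8),
    vapply(1:8, function(i) strrep("MKTAY", 12), ""),
    kingdom = c(rep("animal", 4), rep("plant", 4)),
    characterized = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    substrate = c("acyl-CoA", "acyl-CoA", "acyl-CoA", "unknown",
                  "acyl-PC", "MGDG", "unknown", "unknown"))
  rn <- make_repnodes(c("p1", "p5", "p7"),
                      member_ids = list(c("p1", "p2", "p3", "p4"),
                                        c("p5", "p6"), c("p7", "p8")))
  ssn <- build_network(rn, make_edges(character(), character(), numeric()),
                       records = rec, stringency = -5)
  part <- connected_components(ssn)
  summ <- summarize_clusters(part, rec)
  expect_equal(sum(summ$protein_count), 8L)

  s1 <- summ[summ$label == "p1", ]
  expect_equal(s1$consensus_substrate, "acyl-CoA")
  expect_equal(s1$consensus_support, 1)
  expect_equal(s1$characterized_count, 3L)

  s2 <- summ[summ$label == "p5", ]  # acyl-PC vs MGDG tie
  expect_equal(s2$consensus_substrate, "ambiguous")

  s3 <- summ[summ$label == "p7", ]  # nothing characterized
  expect_equal(s3$consensus_substrate, "unknown")
  expect_equal(s3$consensus_support, 0)

  # consensus is invariant to member order
  rn_r <- make_repnodes(c("p1", "p5", "p7"),
                        member_ids = list(c("p4", "p3", "p2", "p1"),
                                          c("p6", "p5"), c("p8", "p7")))
  ssn_r <- build_network(rn_r, make_edges(character(), character(),
                                          numeric()),
                         records = rec, stringency = -5)
  summ_r <- summarize_clusters(connected_components(ssn_r), rec)
  expect_equal(summ_r$consensus_substrate, summ$consensus_substrate)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_summaries(summ, f)
  expect_equal(read.delim(f)$consensus_substrate, summ$consensus_substrate)
})

test_that("family naming follows seeds, conflicts and size ranks", {
  rec <- protein_records(sprintf("p%d", 1:6),
                         vapply(1:6, function(i) strrep("ACDEF", 12), ""))
  rn <- make_repnodes(c("p1", "p3", "p5"),
                      member_ids = list(c("p1", "p2"), c("p3", "p4"),
                                        c("p5", "p6")))
  ssn <- build_network(rn, make_edges(character(), character(), numeric()),
                       records = rec, stringency = -5)
  part <- connected_components(ssn)
  summ <- summarize_clusters(part, rec)

  named <- name_families(summ, part, c(p1 = "FD", p4 = "FE"))
  expect_equal(named$family_name[named$label == "p1"], "FD")
  expect_equal(named$family_name[named$label == "p3"], "FE")
  # seedless cluster gets a systematic rank name
  expect_match(named$family_name[named$label == "p5"], "^cluster-0[1-3]$")

  conf <- name_families(summ, part, c(p1 = "FD", p2 = "FE"))
  expect_equal(conf$family_name[conf$label == "p1"], "conflict")

  expect_warning(name_families(summ, part, c(p1 = "FD", zz = "ME")), "zz")
})

test_that("binding-site report detects charge transitions", {
  ref <- "MKTAYWLRDEKQSTVNGHPF"
  expect_ident <- binding_site_substitutions(ref, ref, c(2, 9, 11), SC)
  expect_false(any(expect_ident$charge_change))
  expect_equal(attr(expect_ident, "n_charged_to_uncharged"), 0L)

  # K -> L at a listed position: positive -> hydrophobic
  qry <- sub("K", "L", ref)  # first K is position 2
  rep2 <- binding_site_substitutions(ref, qry, 2, SC)
  expect_equal(rep2$ref_residue, "K")
  expect_equal(rep2$query_residue, "L")
  expect_true(rep2$charge_change)
  expect_equal(attr(rep2, "n_charged_to_uncharged"), 1L)

  # D -> K is a charge change too (opposite signs)
  qry2 <- paste0(substr(ref, 1, 8), "K", substr(ref, 10, 20))
  rep3 <- binding_site_substitutions(ref, qry2, 9, SC)
  expect_true(rep3$charge_change)
  expect_equal(attr(rep3, "n_charged_to_uncharged"), 0L)

  expect_error(binding_site_substitutions(ref, ref, 21, SC), "range")
})

test_that("global mapping reports gapped positions", {
  # query lacks residues 11-14 of the reference; the alignment must gap
  # them and map flanking positions one-to-one
  ref <- "MKTAYWLRDECQISHVNGPFWDERLYMKTA"
  qry <- paste0(substr(ref, 1, 10), substr(ref, 15, 30))
  rep <- binding_site_substitutions(ref, qry, c(5, 12, 20), SC)
  expect_equal(rep$query_residue[rep$ref_position == 5], "Y")
  expect_equal(rep$query_residue[rep$ref_position == 12], "-")
  expect_true(is.na(rep$query_class[rep$ref_position == 12]))
  expect_equal(rep$query_residue[rep$ref_position == 20],
               substr(ref, 20, 20))
  # independent check of the global score against Biostrings
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  bs <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref), Biostrings::AAString(qry),
    substitutionMatrix = e$BLOSUM62, gapOpening = 11, gapExtension = 1,
    type = "global")
  nw <- fadssn:::.nw_align_cpp(fadssn:::encode_seq(ref, SC),
                               fadssn:::encode_seq(qry, SC),
                               SC$matrix, SC$gap_open, SC$gap_extend)
  expect_equal(nw$score, Biostrings::score(bs))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_report(rep, f)
  expect_equal(nrow(read.delim(f)), 3L)
})
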