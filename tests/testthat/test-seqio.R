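test_that("read_fasta preserves ids and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKTAY", ">P2", "ACDEF", "GHIKX"), f)
  rec <- read_fasta(f)
  expect_s3_class(rec, "protein_records")
  expect_equal(rec$id, c("P1", "P2"))
  expect_equal(rec$sequence, c("MKTAY", "ACDEFGHIKX"))
  expect_equal(rec$length, c(5L, 10L))
  expect_equal(rec$substrate, c("unknown", "unknown"))

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_equal(nrow(read_fasta(empty)), 0L)

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKTAY", ">P1", "ACDEF"), dup)
  expect_error(read_fasta(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKTAY", ">P9", "MKBZY"), bad)
  expect_error(read_fasta(bad), "P9")
})

test_that("FASTA round trip is byte-identical on sequences", {
  set.seed(11)
  rec <- protein_records(sprintf("S%02d", 1:8),
                         vapply(1:8, function(i) rand_seq(150), ""))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, f)
  back <- read_fasta(f)
  expect_identical(back$id, rec$id)
  expect_identical(back$sequence, rec$sequence)
})

test_that("annotations join onto records and invariants are enforced", {
  rec <- protein_records(c("X", "Y"), c("MKTAYMKTAY", "ACDEFACDEF"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tkingdom\torganism\tsubstrate\tregio\tcharacterized\tdomains",
    "X\tanimal\tHomo sapiens\tacyl-CoA\tD9\ttrue\tdesaturase:1-8;cytb5:9-10",
    "Q\tplant\tArabidopsis\tMGDG\tD7\ttrue\t"), f)
  expect_warning(out <- join_annotations(rec, f), "Q")
  expect_equal(out$kingdom, c("animal", "unknown"))
  expect_equal(out$substrate, c("acyl-CoA", "unknown"))
  expect_true(out$characterized[1])
  expect_equal(out$domains[[1]]$label, c("desaturase", "cytb5"))
  expect_equal(out$domains[[2]], fadssn:::empty_domains())

  # substrate on an uncharacterized record violates the invariant
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tkingdom\torganism\tsubstrate\tregio\tcharacterized\tdomains",
    "X\tanimal\t\tacyl-CoA\t\tfalse\t"), bad)
  expect_error(join_annotations(rec, bad), "uncharacterized")

  # unrecognized substrate degrades to "other" with a warning
  odd <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tkingdom\torganism\tsubstrate\tregio\tcharacterized\tdomains",
    "X\tanimal\t\ttriacylglycerol\t\ttrue\t"), odd)
  expect_warning(tab <- read_annotations(odd), "other")
  expect_equal(tab$substrate, "other")

  # malformed domain encoding names the row
  mal <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tkingdom\torganism\tsubstrate\tregio\tcharacterized\tdomains",
    "X\tanimal\t\tunknown\t\tfalse\tcytb5:10"), mal)
  expect_error(read_annotations(mal), "malformed")
})

test_that("annotation TSV round-trips through write_annotations", {
  rec <- protein_records(
    c("A1", "B2"), c(strrep("MKTAY", 20), strrep("ACDEF", 20)),
    kingdom = c("fungus", "plant"), organism = c("yeast", "moss"),
    characterized = c(TRUE, FALSE), substrate = c("sphingolipid", "unknown"),
    regio = c("D8", ""),
    domains = list(data.frame(label = c("desaturase", "cytb5"),
                              start = c(1L, 81L), end = c(80L, 100L)),
                   fadssn:::empty_domains()))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(rec, f)
  fresh <- protein_records(rec$id, rec$sequence)
  back <- join_annotations(fresh, f)
  expect_equal(back$kingdom, rec$kingdom)
  expect_equal(back$substrate, rec$substrate)
  expect_equal(back$characterized, rec$characterized)
  expect_equal(back$domains, rec$domains)
})

test_that("length filter applies inclusive bounds and is idempotent", {
  lens <- c(249, 250, 550, 551, 400)
  rec <- protein_records(sprintf("L%d", lens),
                         vapply(lens, function(n) strrep("A", n), ""))
  kept <- filter_by_length(rec, 250, 550)
  expect_equal(kept$length, c(250, 550, 400))          # order preserved
  expect_equal(filter_by_length(kept, 250, 550), kept) # idempotent

  strict <- length_preset("strict")
  kept2 <- filter_by_length(rec, strict["min_len"], strict["max_len"])
  expect_equal(sort(kept2$length), c(400, 550))

  none <- filter_by_length(rec[0, ], 250, 550)
  expect_equal(nrow(none), 0L)
})

test_that("effective sequence removes cytb5 ranges only when asked", {
  seq <- paste0(strrep("W", 100), strrep("A", 350))
  rec <- protein_records("F1", seq,
                         domains = list(data.frame(
                           label = "cytb5", start = 1L, end = 100L)))
  expect_equal(effective_sequence(rec, "full"), seq)
  expect_equal(effective_sequence(rec, "desaturase-only"), strrep("A", 350))

  plain <- protein_records("U1", strrep("A", 120))
  expect_equal(effective_sequence(plain, "desaturase-only"), strrep("A", 120))
  expect_equal(effective_sequence(plain, "full"), strrep("A", 120))

  bad <- protein_records("F2", strrep("A", 200),
                         domains = list(data.frame(
                           label = c("cytb5", "cytb5"),
                           start = c(1L, 50L), end = c(100L, 120L))))
  expect_error(effective_sequence(bad, "desaturase-only"), "overlapping")
})

test_that("trimmed length equals full length minus total cytb5 span", {
  set.seed(21)
  for (k in 1:10) {
    L <- sample(200:400, 1)
    s1 <- sample(1:(L - 120), 1); e1 <- s1 + sample(20:60, 1)
    s2 <- e1 + sample(2:10, 1); e2 <- min(L, s2 + sample(10:40, 1))
    rec <- protein_records("T", rand_seq(L), domains = list(data.frame(
      label = c("cytb5", "cytb5"), start = c(s1, s2), end = c(e1, e2))))
    trimmed <- effective_sequence(rec, "desaturase-only")
    expect_equal(nchar(trimmed), L - (e1 - s1 + 1) - (e2 - s2 + 1))
  }
})
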