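#' Protein record tables
#'
#' The package's working container is a data.frame of class
#' `protein_records` with one row per protein: `id`, `sequence`,
#' `length`, `kingdom`, `organism`, `characterized`, `substrate`,
#' `regio`, and a `domains` list-column of data.frames with columns
#' `label`, `start`, `end` (1-based, inclusive).  Annotations default to
#' unknown/empty until joined from a table.
#'
#' @param id character vector of unique accessions.
#' @param sequence amino-acid strings over the 20-letter alphabet plus X.
#' @param kingdom,organism,characterized,substrate,regio optional
#'   annotation vectors, recycled to length 1 defaults when omitted.
#' @param domains optional list of domain data.frames (`label`, `start`,
#'   `end`), one per record.
#' @return A `protein_records` data.frame.
#' @export
protein_records <- function(id, sequence,
                            kingdom = "unknown", organism = "",
                            characterized = FALSE, substrate = "unknown",
                            regio = "", domains = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(id))
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  bad <- vapply(sequence, function(s)
    any(!strsplit(s, "", fixed = TRUE)[[1]] %in% AA_ALPHABET), logical(1))
  if (any(bad))
    stop("non-amino-acid characters in record(s): ",
         paste(id[bad], collapse = ", "))
  n <- length(id)
  if (is.null(domains)) domains <- rep(list(empty_domains()), n)
  df <- data.frame(id = id, sequence = sequence, length = nchar(sequence),
                   kingdom = rep_len(kingdom, n),
                   organism = rep_len(organism, n),
                   characterized = rep_len(characterized, n),
                   substrate = rep_len(substrate, n),
                   regio = rep_len(regio, n),
                   stringsAsFactors = FALSE)
  df$domains <- domains
  class(df) <- c("protein_records", "data.frame")
  validate_records(df)
  df
}

empty_domains <- function() {
  data.frame(label = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

validate_records <- function(records) {
  stopifnot(all(records$length == nchar(records$sequence)))
  for (i in seq_len(nrow(records))) {
    d <- records$domains[[i]]
    if (nrow(d) == 0L) next
    if (any(d$start > d$end) || any(d$start < 1L) ||
        any(d$end > records$length[i]))
      stop("invalid domain range for record ", records$id[i])
  }
  bad <- records$substrate != "unknown" & !records$characterized
  if (any(bad))
    stop("substrate given for uncharacterized record(s): ",
         paste(records$id[bad], collapse = ", "))
  invisible(records)
}

#' @rdname protein_records
#' @param x object to test.
#' @export
is_protein_records <- function(x) inherits(x, "protein_records")

# Subsetting keeps the class (data.frame [ drops it by default).
#' @export
`[.protein_records` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "domains" %in% names(out))
    class(out) <- c("protein_records", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Header text up to the first whitespace is taken as the accession.
#' Duplicate accessions and characters outside the amino-acid alphabet
#' (20 residues + X) are hard errors naming the record.
#'
#' @param path FASTA file.
#' @return A [protein_records] table with default (unknown) annotations.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L)
    return(protein_records(character(), character()))
  ids <- sub("\\s.*$", "", names(aa))
  protein_records(ids, as.character(aa))
}

#' Write protein records to FASTA
#'
#' @param records a [protein_records] table.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Read an annotation table (TSV)
#'
#' Columns: `id`, `kingdom`, `organism`, `substrate`, `regio`,
#' `characterized`, `domains`.  Domains are encoded
#' `"label:start-end;label:start-end"`.  Substrate values outside the
#' controlled vocabulary are mapped to `"other"` with a warning.
#'
#' @param path TSV file.
#' @return A data.frame with a parsed `domains` list-column.
#' @export
read_annotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "kingdom", "organism", "substrate", "regio",
            "characterized", "domains")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  tab$characterized <- tolower(tab$characterized) %in% c("true", "t", "1", "yes")
  bad_sub <- !(tab$substrate %in% SUBSTRATES)
  if (any(bad_sub)) {
    warning("unrecognized substrate value(s) mapped to 'other': ",
            paste(unique(tab$substrate[bad_sub]), collapse = ", "))
    tab$substrate[bad_sub] <- "other"
  }
  tab$domains <- lapply(seq_len(nrow(tab)), function(i)
    parse_domains(tab$domains[i], row = i))
  tab
}

parse_domains <- function(txt, row = NA) {
  if (is.na(txt) || !nzchar(txt)) return(empty_domains())
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([^:]+):([0-9]+)-([0-9]+)$", parts))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("malformed domain range in annotation row ", row, ": ",
         paste(parts[bad], collapse = ", "))
  data.frame(label = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

format_domains <- function(d) {
  if (nrow(d) == 0L) return("")
  paste(sprintf("%s:%d-%d", d$label, d$start, d$end), collapse = ";")
}

#' Join an annotation table onto protein records
#'
#' Matched records take the table's kingdom, organism, substrate, regio,
#' characterized flag and domain ranges; unmatched records keep their
#' defaults.  Table rows whose id is absent from the records are
#' reported with a warning, not an error.
#'
#' @param records a [protein_records] table.
#' @param table data.frame as returned by [read_annotations()], or a
#'   path to such a TSV.
#' @return The annotated [protein_records] table.
#' @export
join_annotations <- function(records, table) {
  stopifnot(is_protein_records(records))
  if (is.character(table)) table <- read_annotations(table)
  idx <- match(table$id, records$id)
  orphans <- sum(is.na(idx))
  if (orphans > 0L)
    warning(orphans, " annotation row(s) with no matching record: ",
            paste(head(table$id[is.na(idx)], 5L), collapse = ", "))
  hit <- which(!is.na(idx))
  for (k in hit) {
    i <- idx[k]
    records$kingdom[i] <- table$kingdom[k]
    records$organism[i] <- table$organism[k]
    records$substrate[i] <- table$substrate[k]
    records$regio[i] <- table$regio[k]
    records$characterized[i] <- table$characterized[k]
    records$domains[[i]] <- table$domains[[k]]
  }
  validate_records(records)
  records
}

#' Write the annotation table for a set of records
#'
#' Inverse of [read_annotations()] for round-tripping synthetic corpora.
#'
#' @param records a [protein_records] table.
#' @param path output TSV.
#' @export
write_annotations <- function(records, path) {
  tab <- data.frame(id = records$id, kingdom = records$kingdom,
                    organism = records$organism,
                    substrate = records$substrate, regio = records$regio,
                    characterized = tolower(as.character(records$characterized)),
                    domains = vapply(records$domains, format_domains, ""),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Length filter for the superfamily corpus
#'
#' Retains records with `min_len <= length <= max_len`, preserving input
#' order.  The default (250, 550) removes partial proteins and
#' multi-domain fusions other than the desaturase-cytochrome-b5 pair; a
#' stricter (350, 550) window is available via `length_preset("strict")`.
#'
#' @param records a [protein_records] table.
#' @param min_len,max_len inclusive bounds in residues.
#' @return The filtered [protein_records] table.
#' @export
filter_by_length <- function(records, min_len = 250L, max_len = 550L) {
  stopifnot(is_protein_records(records), min_len <= max_len)
  records[records$length >= min_len & records$length <= max_len, ]
}

#' @rdname filter_by_length
#' @param preset `"default"` (250-550 aa) or `"strict"` (350-550 aa).
#' @export
length_preset <- function(preset = c("default", "strict")) {
  switch(match.arg(preset),
         default = c(min_len = 250L, max_len = 550L),
         strict = c(min_len = 350L, max_len = 550L))
}

has_cytb5 <- function(records) {
  vapply(records$domains, function(d) any(d$label == "cytb5"), logical(1))
}

#' Effective sequence under the cytochrome-b5 inclusion rule
#'
#' The fused cytochrome b5 domain is only allowed into E-value
#' computation when both partners of a pair carry it; this helper
#' produces the sequence actually aligned.  `mode = "full"` returns the
#' whole sequence; `mode = "desaturase-only"` removes all residues
#' inside `cytb5`-labelled ranges.  Records without a cytb5 domain are
#' returned unchanged in both modes.
#'
#' @param record a single-row [protein_records] table (or a row index
#'   into a larger one via `records[i, ]`).
#' @param mode `"full"` or `"desaturase-only"`.
#' @return The effective amino-acid string.
#' @export
effective_sequence <- function(record, mode = c("full", "desaturase-only")) {
  mode <- match.arg(mode)
  stopifnot(nrow(record) == 1L)
  seq <- record$sequence[[1]]
  d <- record$domains[[1]]
  b5 <- d[d$label == "cytb5", , drop = FALSE]
  if (mode == "full" || nrow(b5) == 0L) return(seq)
  b5 <- b5[order(b5$start), , drop = FALSE]
  if (nrow(b5) > 1L && any(b5$start[-1] <= b5$end[-nrow(b5)]))
    stop("overlapping cytb5 ranges for record ", record$id[[1]])
  keep <- rep(TRUE, nchar(seq))
  for (r in seq_len(nrow(b5))) keep[b5$start[r]:b5$end[r]] <- FALSE
  paste(strsplit(seq, "", fixed = TRUE)[[1]][keep], collapse = "")
}
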