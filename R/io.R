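#' Read kinase sequences from FASTA
#'
#' Headers follow the convention `accession|gene_symbol|group`. A missing or
#' unrecognized group token falls back to `"Other"` with a warning; duplicate
#' accessions are a hard error.
#'
#' @param path FASTA file path.
#' @return data frame with columns accession, gene_symbol, group, sequence;
#'   entry order preserved. Attribute `report` counts fallback events.
#' @export
read_kinome_fasta <- function(path) {
  if (!file.exists(path)) input_error(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    out <- data.frame(accession = character(), gene_symbol = character(),
                      group = character(), sequence = character())
    attr(out, "report") <- c(unknown_group = 0L)
    return(out)
  }
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  accession <- vapply(parts, `[`, "", 1)
  gene <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
  group <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, "")
  if (anyDuplicated(accession)) {
    input_error(sprintf("duplicate accession in FASTA: %s",
                        accession[duplicated(accession)][1]))
  }
  bad <- is.na(group) | !(group %in% KINASE_GROUPS)
  if (any(bad)) {
    warning(sum(bad), " FASTA entries without a recognized group; set to Other",
            call. = FALSE)
    group[bad] <- "Other"
  }
  gene[is.na(gene)] <- accession[is.na(gene)]
  out <- data.frame(accession = accession, gene_symbol = gene, group = group,
                    sequence = as.character(ss))
  rownames(out) <- NULL
  attr(out, "report") <- c(unknown_group = sum(bad))
  out
}

#' Write kinase records to FASTA
#'
#' @param kinases data frame with accession, gene_symbol, group, sequence.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kinome_fasta <- function(kinases, path) {
  ss <- Biostrings::AAStringSet(kinases$sequence)
  names(ss) <- paste(kinases$accession, kinases$gene_symbol, kinases$group,
                     sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# TSV schemas: required columns and their types. Extra columns are ignored.
TABLE_SCHEMAS <- list(
  mutation = list(cols = c(accession = "character", position = "integer",
                           ref_aa = "character", alt_aa = "character",
                           sample_id = "character",
                           genome_wide_screen = "logical")),
  ptm = list(cols = c(accession = "character", position = "integer",
                      residue = "character", mod_type = "character",
                      confidence = "numeric", manually_curated = "logical")),
  domain = list(cols = c(accession = "character", domain_id = "character",
                         start = "integer", end = "integer")),
  nih_metrics = list(cols = c(accession = "character",
                              jensen_score = "numeric",
                              r01_count = "numeric",
                              pubtator_score = "numeric"))
)

#' Read a typed record table from TSV
#'
#' Tab-separated with a header row naming the schema's columns; blank lines
#' and `#` comments are skipped, extra columns ignored. Rows with unparseable
#' numeric fields (or, for domains, `end < start`) are dropped and counted in
#' the `report` attribute; a missing required column is a hard error.
#'
#' @param path TSV file path.
#' @param schema one of "mutation", "ptm", "domain", "annotation_matrix",
#'   "nih_metrics".
#' @return data frame of typed records with a `report` attribute (named
#'   integer vector of dropped-row counts).
#' @export
read_table <- function(path, schema = c("mutation", "ptm", "domain",
                                        "annotation_matrix", "nih_metrics")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) input_error(sprintf("table file not found: %s", path))
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   blank.lines.skip = TRUE, colClasses = "character",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (schema == "annotation_matrix") {
    if (!"accession" %in% names(df)) {
      input_error("annotation_matrix TSV is missing required column: accession")
    }
    vars <- setdiff(names(df), "accession")
    if (!length(vars)) input_error("annotation_matrix TSV has no variable columns")
    out <- data.frame(accession = df$accession, check.names = FALSE)
    dropped <- rep(FALSE, nrow(df))
    for (v in vars) {
      x <- suppressWarnings(as.numeric(df[[v]]))
      dropped <- dropped | (is.na(x) & !is.na(df[[v]]) & nzchar(df[[v]]))
      out[[v]] <- x
    }
    out <- out[!dropped, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "report") <- c(unparseable_row = sum(dropped))
    return(out)
  }
  spec <- TABLE_SCHEMAS[[schema]]$cols
  missing <- setdiff(names(spec), names(df))
  if (length(missing)) {
    input_error(sprintf("%s TSV is missing required column: %s",
                        schema, missing[1]))
  }
  out <- data.frame(row.names = seq_len(nrow(df)))
  bad <- rep(FALSE, nrow(df))
  for (col in names(spec)) {
    raw <- df[[col]]
    x <- switch(spec[[col]],
      character = raw,
      integer = suppressWarnings(as.integer(raw)),
      numeric = suppressWarnings(as.numeric(raw)),
      logical = {
        v <- toupper(trimws(raw))
        ifelse(v %in% c("TRUE", "T", "1", "YES"), TRUE,
               ifelse(v %in% c("FALSE", "F", "0", "NO"), FALSE, NA))
      })
    if (spec[[col]] != "character") bad <- bad | is.na(x)
    out[[col]] <- x
  }
  n_bad <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  report <- c(unparseable_row = n_bad)
  if (schema == "domain") {
    inverted <- out$end < out$start
    report <- c(report, inverted_interval = sum(inverted))
    out <- out[!inverted, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

#' Write a data frame as TSV
#'
#' UTF-8, tab-separated, header row, `.` decimal, no quoting or row names.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write all tables of a kinome dataset to a directory
#'
#' Emits `kinome.fasta`, `mutations.tsv`, `ptms.tsv`, `domains.tsv` in the
#' formats [read_kinome_fasta()] and [read_table()] read back.
#'
#' @param x a list with kinases, mutations, ptms, domains data frames (either
#'   a `kinome_dataset` or the `raw` element of [simulate_kinome()]).
#' @param dir output directory, created if needed.
#' @return named character vector of the written paths, invisibly.
#' @export
write_kinome_tables <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "kinome.fasta"),
             mutations = file.path(dir, "mutations.tsv"),
             ptms = file.path(dir, "ptms.tsv"),
             domains = file.path(dir, "domains.tsv"))
  write_kinome_fasta(x$kinases, paths["fasta"])
  write_tsv(x$mutations, paths["mutations"])
  write_tsv(x$ptms, paths["ptms"])
  write_tsv(x$domains, paths["domains"])
  invisible(paths)
}
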