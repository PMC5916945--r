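#' Assemble and validate a kinome dataset
#'
#' Cross-checks every record against the loaded sequences and applies the
#' ingest filters. Records are never repaired: any contradiction drops the
#' record and increments a named counter in the validation report.
#'
#' Rules applied, in order:
#' \itemize{
#'   \item mutations/PTMs/domains referencing an unknown accession are dropped;
#'   \item positions outside the sequence (or domain intervals not within
#'     `[1, length]`) are dropped;
#'   \item mutations whose `ref_aa` (and PTMs whose `residue`) disagree with
#'     the sequence at that position are dropped — inputs are assumed to be in
#'     canonical coordinates, and this check catches coordinate drift;
#'   \item mutations with `ref_aa == alt_aa` are dropped;
#'   \item with `genome_wide_filter = TRUE` (default), mutations not from a
#'     genome-wide screen are excluded;
#'   \item mutation events are deduplicated on
#'     (sample_id, accession, position, alt_aa) — the same substitution in
#'     different samples is kept as distinct events;
#'   \item PTM rows failing (`manually_curated` AND `confidence >
#'     min_confidence`, strict) are excluded; duplicated
#'     (accession, position, mod_type) rows are collapsed.
#' }
#'
#' The function is idempotent: validating a validated dataset changes nothing.
#'
#' @param kinases data frame from [read_kinome_fasta()].
#' @param mutations data frame with the mutation schema.
#' @param ptms data frame with the ptm schema.
#' @param domains data frame with the domain schema.
#' @param genome_wide_filter drop mutations with `genome_wide_screen = FALSE`?
#' @param min_confidence strict lower bound for PTM confidence (default 1).
#' @return an object of class `kinome_dataset`: list with kinases, mutations,
#'   ptms, domains, and `validation_report` (named integer vector of dropped
#'   or flagged record counts).
#' @export
validate_dataset <- function(kinases, mutations, ptms, domains,
                             genome_wide_filter = TRUE, min_confidence = 1) {
  if (!nrow(kinases)) input_error("dataset has no kinase sequences")
  seqs <- strsplit(kinases$sequence, "", fixed = TRUE)
  names(seqs) <- kinases$accession
  lens <- setNames(lengths(seqs), kinases$accession)
  rep_ <- integer(0)
  bump <- function(name, k) {
    rep_[name] <<- (if (name %in% names(rep_)) rep_[[name]] else 0L) + as.integer(k)
  }
  bump("nonstandard_residue",
       sum(!unlist(seqs, use.names = FALSE) %in% AA_ALPHABET))

  # mutations
  m <- mutations
  known <- m$accession %in% kinases$accession
  bump("mutation_unknown_accession", sum(!known)); m <- m[known, , drop = FALSE]
  inr <- m$position >= 1L & m$position <= lens[m$accession]
  bump("mutation_out_of_range", sum(!inr)); m <- m[inr, , drop = FALSE]
  ref_ok <- mapply(function(a, p) seqs[[a]][p], m$accession, m$position) == m$ref_aa
  ref_ok <- ref_ok & (m$ref_aa %in% AA_ALPHABET)
  bump("mutation_ref_mismatch", sum(!ref_ok)); m <- m[ref_ok, , drop = FALSE]
  silent <- m$ref_aa == m$alt_aa
  bump("mutation_silent", sum(silent)); m <- m[!silent, , drop = FALSE]
  if (genome_wide_filter) {
    gws <- m$genome_wide_screen
    bump("mutation_not_genome_wide", sum(!gws)); m <- m[gws, , drop = FALSE]
  }
  dup <- duplicated(m[, c("sample_id", "accession", "position", "alt_aa")])
  bump("mutation_duplicate_event", sum(dup)); m <- m[!dup, , drop = FALSE]

  # PTMs
  p <- ptms
  known <- p$accession %in% kinases$accession
  bump("ptm_unknown_accession", sum(!known)); p <- p[known, , drop = FALSE]
  inr <- p$position >= 1L & p$position <= lens[p$accession]
  bump("ptm_out_of_range", sum(!inr)); p <- p[inr, , drop = FALSE]
  res_ok <- mapply(function(a, pos) seqs[[a]][pos], p$accession, p$position) ==
    p$residue
  res_ok <- res_ok & (p$residue %in% AA_ALPHABET)
  bump("ptm_residue_mismatch", sum(!res_ok)); p <- p[res_ok, , drop = FALSE]
  pass <- p$manually_curated & p$confidence > min_confidence
  bump("ptm_filtered", sum(!pass)); p <- p[pass, , drop = FALSE]
  dup <- duplicated(p[, c("accession", "position", "mod_type")])
  bump("ptm_duplicate", sum(dup)); p <- p[!dup, , drop = FALSE]

  # domains
  d <- domains
  known <- d$accession %in% kinases$accession
  bump("domain_unknown_accession", sum(!known)); d <- d[known, , drop = FALSE]
  ok <- d$start >= 1L & d$end >= d$start & d$end <= lens[d$accession]
  bump("domain_out_of_bounds", sum(!ok)); d <- d[ok, , drop = FALSE]

  rownames(m) <- rownames(p) <- rownames(d) <- NULL
  structure(list(kinases = kinases, mutations = m, ptms = p, domains = d,
                 validation_report = rep_),
            class = "kinome_dataset")
}

#' @export
print.kinome_dataset <- function(x, ...) {
  cat("kinome_dataset:", nrow(x$kinases), "kinases,",
      nrow(x$mutations), "mutation events,",
      nrow(x$ptms), "PTM rows,",
      nrow(x$domains), "domain intervals\n")
  dropped <- x$validation_report[x$validation_report > 0]
  if (length(dropped)) {
    cat("validation drops/flags:\n")
    for (nm in names(dropped)) cat(sprintf("  %s: %d\n", nm, dropped[[nm]]))
  }
  invisible(x)
}

#' Load a kinome dataset from files
#'
#' Convenience wrapper: reads FASTA + three TSVs and runs [validate_dataset()].
#'
#' @param fasta,mutations,ptms,domains file paths.
#' @param ... passed to [validate_dataset()].
#' @return a `kinome_dataset`.
#' @export
load_kinome_dataset <- function(fasta, mutations, ptms, domains, ...) {
  validate_dataset(read_kinome_fasta(fasta),
                   read_table(mutations, "mutation"),
                   read_table(ptms, "ptm"),
                   read_table(domains, "domain"), ...)
}
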