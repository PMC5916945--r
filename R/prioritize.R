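#' Domains enriched in both cancer variants and PTM sites
#'
#' Inner join of VEA and MEA results on (accession, domain_id), keeping units
#' significant in both analyses. Scores are recomputed from the adjusted
#' p-values via [enrichment_score()]; the reported `average_score` is their
#' mean, rounded to 3 decimals (half away from zero). Rows are sorted by
#' average score descending, ties broken lexicographically by
#' (accession, domain_id).
#'
#' @param vea,mea result data frames from [run_vea()] and [run_mea()],
#'   computed over the same test units (mismatched universes are an error).
#' @param alpha significance level applied to both adjusted p-values.
#' @return data frame: accession, gene_symbol, domain_id, vea_adj_p,
#'   mea_adj_p, vea_score, mea_score, average_score.
#' @export
dual_enriched <- function(vea, mea, alpha = 0.005) {
  kv <- paste(vea$accession, vea$domain_id, sep = "\r")
  km <- paste(mea$accession, mea$domain_id, sep = "\r")
  if (!setequal(kv, km) || length(kv) != length(km)) {
    input_error("VEA and MEA were not computed over the same test units")
  }
  mea <- mea[match(kv, km), , drop = FALSE]
  keep <- vea$adj_p < alpha & mea$adj_p < alpha
  out <- data.frame(
    accession = vea$accession[keep],
    gene_symbol = vea$gene_symbol[keep],
    domain_id = vea$domain_id[keep],
    vea_adj_p = vea$adj_p[keep],
    mea_adj_p = mea$adj_p[keep],
    vea_score = enrichment_score(vea$adj_p[keep]),
    mea_score = enrichment_score(mea$adj_p[keep]))
  out$average_score <- round_half_away(
    (out$vea_score + out$mea_score) / 2, 3)
  out <- out[order(-out$average_score, out$accession, out$domain_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutation-PTM overlapping sites
#'
#' Positions that are both post-translationally modified and mutated in
#' cancer samples: the join of mutation events and curated PTM sites on
#' (accession, position), requiring exact positional identity. When a
#' dual-enrichment table is supplied, each site is flagged as lying inside
#' one of those enriched units.
#'
#' @param dataset a validated `kinome_dataset`.
#' @param restrict_to optional data frame with accession and domain_id
#'   columns (e.g. from [dual_enriched()]); adds/fills the
#'   `within_enriched_domain` flag.
#' @return data frame: accession, position, residue, mutation_event_count,
#'   alt_residues (distinct alternates, "," separated), mod_types (","
#'   separated), within_enriched_domain.
#' @export
overlap_sites <- function(dataset, restrict_to = NULL) {
  m <- dataset$mutations
  p <- dataset$ptms
  mkey <- paste(m$accession, m$position, sep = "\r")
  pkey <- paste(p$accession, p$position, sep = "\r")
  common <- intersect(unique(mkey), unique(pkey))
  if (!length(common)) {
    return(data.frame(accession = character(), position = integer(),
                      residue = character(), mutation_event_count = integer(),
                      alt_residues = character(), mod_types = character(),
                      within_enriched_domain = logical()))
  }
  parts <- strsplit(common, "\r", fixed = TRUE)
  acc <- vapply(parts, `[`, "", 1)
  pos <- as.integer(vapply(parts, `[`, "", 2))
  mut_count <- as.integer(table(mkey)[common])
  alts <- vapply(common, function(k) {
    paste(sort(unique(m$alt_aa[mkey == k])), collapse = ",")
  }, "")
  mods <- vapply(common, function(k) {
    paste(sort(unique(p$mod_type[pkey == k])), collapse = ",")
  }, "")
  res <- vapply(common, function(k) p$residue[pkey == k][1], "")
  within <- rep(NA, length(common))
  if (!is.null(restrict_to)) {
    comp <- compute_composition(dataset)
    up <- comp$unit_positions
    ukeys <- paste(restrict_to$accession, restrict_to$domain_id, sep = "\r")
    inpos <- up[up$unit %in% ukeys, , drop = FALSE]
    within <- paste(acc, pos, sep = "\r") %in%
      paste(inpos$accession, inpos$position, sep = "\r")
  }
  out <- data.frame(accession = acc, position = pos, residue = res,
                    mutation_event_count = mut_count, alt_residues = alts,
                    mod_types = mods, within_enriched_domain = within)
  out <- out[order(out$accession, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position profile of a domain
#'
#' One row per residue position of the pooled interval(s) of a
#' (kinase, domain type) unit: the mutation event count across samples, a
#' logical flag per modification type present in the dataset, and the
#' mutation-PTM overlap flag. Row sums reproduce the observed counts used by
#' [run_vea()] and [run_mea()] for that unit.
#'
#' @param dataset a validated `kinome_dataset`.
#' @param accession kinase accession.
#' @param domain_id domain identifier.
#' @return data frame: accession, domain_id, position, residue,
#'   mutation_events, one logical column per modification type, ptm (any
#'   type), overlap.
#' @export
position_profile <- function(dataset, accession, domain_id) {
  d <- dataset$domains[dataset$domains$accession == accession &
                       dataset$domains$domain_id == domain_id, , drop = FALSE]
  if (!nrow(d)) {
    input_error(sprintf("unknown domain: %s %s", accession, domain_id))
  }
  pos <- sort(unique(unlist(mapply(seq, d$start, d$end, SIMPLIFY = FALSE))))
  seq_chars <- strsplit(dataset$kinases$sequence[
    dataset$kinases$accession == accession], "", fixed = TRUE)[[1]]
  m <- dataset$mutations[dataset$mutations$accession == accession, , drop = FALSE]
  p <- dataset$ptms[dataset$ptms$accession == accession, , drop = FALSE]
  mut <- as.integer(table(factor(m$position, levels = pos)))
  out <- data.frame(accession = accession, domain_id = domain_id,
                    position = pos, residue = seq_chars[pos],
                    mutation_events = mut)
  types <- sort(unique(dataset$ptms$mod_type))
  for (ty in types) {
    out[[ty]] <- pos %in% p$position[p$mod_type == ty]
  }
  out$ptm <- pos %in% p$position
  out$overlap <- out$ptm & out$mutation_events > 0
  out
}
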