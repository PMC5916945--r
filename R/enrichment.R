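#' Amino-acid composition tables for enrichment testing
#'
#' Counts every residue of every kinase sequence (`N_a`, kinome-wide,
#' including regions outside any domain) and the residues of each test unit
#' (`N_ad`). A test unit is one (accession, domain_id) pair; repeated copies
#' of the same domain in one protein are pooled into a single unit (each
#' residue counted once), while distinct overlapping domains are each counted
#' in full. Residues outside the 20-letter standard alphabet (e.g. `X`) are
#' excluded from all counts.
#'
#' @param dataset a validated `kinome_dataset`.
#' @return list of class `composition_table`: `N_a` (named integer vector
#'   over the 20 amino acids), `N_ad` (integer matrix, units x amino acids),
#'   `units` (data frame: accession, domain_id, n_residues), and
#'   `unit_positions` (data frame: unit, accession, position, aa — the pooled
#'   residue membership used to count observed events).
#' @export
compute_composition <- function(dataset) {
  seqs <- strsplit(dataset$kinases$sequence, "", fixed = TRUE)
  names(seqs) <- dataset$kinases$accession
  all_res <- unlist(seqs, use.names = FALSE)
  N_a <- setNames(tabulate(factor(all_res, levels = AA_ALPHABET), nbins = 20),
                  AA_ALPHABET)

  d <- dataset$domains
  if (!nrow(d)) {
    return(structure(list(
      N_a = N_a,
      N_ad = matrix(0L, 0, 20, dimnames = list(NULL, AA_ALPHABET)),
      units = data.frame(accession = character(), domain_id = character(),
                         n_residues = integer()),
      unit_positions = data.frame(unit = character(), accession = character(),
                                  position = integer(), aa = character())),
      class = "composition_table"))
  }
  pos <- data.frame(
    unit = rep(paste(d$accession, d$domain_id, sep = "\r"),
               d$end - d$start + 1L),
    accession = rep(d$accession, d$end - d$start + 1L),
    position = unlist(mapply(seq, d$start, d$end, SIMPLIFY = FALSE),
                      use.names = FALSE))
  # pool copies of the same domain id: each residue belongs to a unit once
  pos <- pos[!duplicated(pos[, c("unit", "position")]), , drop = FALSE]
  seq_offset <- cumsum(c(0L, lengths(seqs)))
  pos$aa <- all_res[seq_offset[match(pos$accession, names(seqs))] + pos$position]
  std <- pos$aa %in% AA_ALPHABET
  pos_std <- pos[std, , drop = FALSE]
  ufac <- factor(pos_std$unit, levels = unique(pos$unit))
  N_ad <- table(ufac, factor(pos_std$aa, levels = AA_ALPHABET))
  N_ad <- matrix(as.integer(N_ad), nrow = nlevels(ufac),
                 dimnames = list(levels(ufac), AA_ALPHABET))
  key <- do.call(rbind, strsplit(levels(ufac), "\r", fixed = TRUE))
  units <- data.frame(accession = key[, 1], domain_id = key[, 2],
                      n_residues = as.integer(rowSums(N_ad)))
  structure(list(N_a = N_a, N_ad = N_ad, units = units,
                 unit_positions = pos[, c("unit", "accession", "position", "aa")]),
            class = "composition_table")
}

#' Per-amino-acid event rates
#'
#' Computes `E_a = O_a / N_a`: the kinome-wide average number of events per
#' residue of each amino-acid type. In `vea` mode `O_a` counts mutation events
#' (with sample multiplicity); in `mea` mode it counts distinct modified
#' positions, and `E_a` is the Bernoulli probability that a residue of type
#' `a` is a curated PTM site, so every `E_a` must be <= 1.
#'
#' @param event_counts named numeric vector of per-amino-acid event counts
#'   (`O_a`); missing amino acids count 0.
#' @param composition a `composition_table`.
#' @param mode `"vea"` or `"mea"`.
#' @return list of class `rate_table`: `E_a`, `O_a`, `mode`.
#' @export
per_residue_rate <- function(event_counts, composition, mode = c("vea", "mea")) {
  mode <- match.arg(mode)
  O_a <- setNames(numeric(20), AA_ALPHABET)
  if (length(event_counts)) {
    keep <- names(event_counts) %in% AA_ALPHABET
    O_a[names(event_counts)[keep]] <- event_counts[keep]
  }
  N_a <- composition$N_a
  if (any(O_a > 0 & N_a == 0)) {
    input_error(sprintf(
      "events observed on amino acid '%s' absent from the kinome",
      names(O_a)[O_a > 0 & N_a == 0][1]))
  }
  E_a <- ifelse(N_a > 0, O_a / N_a, 0)
  if (mode == "mea" && any(E_a > 1)) {
    input_error("MEA per-residue rate exceeds 1; more sites than residues")
  }
  structure(list(E_a = E_a, O_a = O_a, mode = mode), class = "rate_table")
}

#' Composition-weighted expected event count of a test unit
#'
#' `E_d = sum_a E_a * N_ad`: the Poisson null parameter lambda for the unit.
#'
#' @param rates a `rate_table`.
#' @param unit_composition named numeric vector of residue counts for one unit.
#' @return nonnegative scalar.
#' @export
expected_count <- function(rates, unit_composition) {
  if (!length(unit_composition)) return(0)
  a <- names(unit_composition)
  sum(rates$E_a[a] * unit_composition)
}

#' Poisson upper-tail probability
#'
#' `P(X >= observed)` for `X ~ Poisson(lam)`, via the stable survival function
#' (regularized incomplete gamma), not naive term summation.
#'
#' @param observed nonnegative integer count.
#' @param lam nonnegative Poisson mean.
#' @return probability in `[0, 1]`.
#' @export
poisson_upper_p <- function(observed, lam) {
  if (any(observed < 0) || any(lam < 0)) {
    input_error("poisson_upper_p requires nonnegative observed and lam")
  }
  # P(X >= k) = P(X > k - 1); ppois handles lam = 0 (point mass at 0)
  ifelse(observed == 0, 1, ppois(observed - 1, lam, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (`stats::p.adjust(method = "BH")`):
#' ascending `p_(i) * m / i`, monotonized by cumulative minimum from the
#' largest, capped at 1, returned in input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals < 0 | pvals > 1)) input_error("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Enrichment score from an adjusted p-value
#'
#' `-log10(max(adj_p, 1e-14))`: adjusted p-values below the 1e-14 floor all
#' score 14, so vanishingly small p-values do not dominate rankings.
#'
#' @param adj_p numeric vector of adjusted p-values.
#' @return nonnegative scores.
#' @export
enrichment_score <- function(adj_p) {
  -log10(pmax(adj_p, 1e-14))
}

# Shared VEA/MEA engine: given per-unit observed counts and per-aa O_a,
# compute lambda, p-values, BH, scores, flags.
run_enrichment <- function(dataset, mode, alpha) {
  comp <- compute_composition(dataset)
  if (!nrow(comp$units)) {
    return(structure(data.frame(
      accession = character(), gene_symbol = character(),
      domain_id = character(), n_residues = integer(), observed = integer(),
      expected = numeric(), raw_p = numeric(), adj_p = numeric(),
      score = numeric(), significant = logical()),
      mode = mode, alpha = alpha, composition = comp))
  }
  if (mode == "vea") {
    ev <- dataset$mutations
    O_a <- tapply(rep(1L, nrow(ev)), factor(ev$ref_aa, levels = AA_ALPHABET),
                  sum, default = 0L)
    ev_key <- paste(ev$accession, ev$position)
  } else {
    sites <- unique(dataset$ptms[, c("accession", "position")])
    seqs <- strsplit(dataset$kinases$sequence, "", fixed = TRUE)
    names(seqs) <- dataset$kinases$accession
    res <- mapply(function(a, p) seqs[[a]][p], sites$accession, sites$position)
    O_a <- tapply(rep(1L, nrow(sites)), factor(res, levels = AA_ALPHABET),
                  sum, default = 0L)
    ev_key <- paste(sites$accession, sites$position)
  }
  rates <- per_residue_rate(setNames(as.numeric(O_a), AA_ALPHABET), comp, mode)
  lam <- as.numeric(comp$N_ad %*% rates$E_a)

  up <- comp$unit_positions
  up_key <- paste(up$accession, up$position)
  ev_per_key <- table(ev_key)
  up_events <- as.integer(ev_per_key[up_key])
  up_events[is.na(up_events)] <- 0L
  observed <- as.integer(tapply(up_events,
                                factor(up$unit, levels = rownames(comp$N_ad)),
                                sum, default = 0L))

  raw_p <- poisson_upper_p(observed, lam)
  adj_p <- bh_adjust(raw_p)
  res <- data.frame(
    accession = comp$units$accession,
    gene_symbol = dataset$kinases$gene_symbol[
      match(comp$units$accession, dataset$kinases$accession)],
    domain_id = comp$units$domain_id,
    n_residues = comp$units$n_residues,
    observed = observed, expected = lam, raw_p = raw_p, adj_p = adj_p,
    score = enrichment_score(adj_p), significant = adj_p < alpha)
  rownames(res) <- NULL
  structure(res, mode = mode, alpha = alpha, composition = comp)
}

#' Variant enrichment analysis (VEA)
#'
#' Tests every (kinase, domain type) unit for an excess of cancer missense
#' mutation events over the composition-adjusted expectation. Observed counts
#' and the kinome-wide `O_a` keep per-sample multiplicity (one event = one
#' sample carrying one substitution, after the dataset-level deduplication);
#' the null is `Poisson(E_d)` with `E_d = sum_a E_a N_ad`, the p-value is the
#' upper tail `P(X >= observed)`, and BH adjustment runs once across all
#' units.
#'
#' @param dataset a validated `kinome_dataset`.
#' @param alpha significance level on the adjusted p-value (default 0.005).
#' @return data frame: accession, gene_symbol, domain_id, n_residues,
#'   observed, expected, raw_p, adj_p, score, significant. One row per test
#'   unit; attribute `mode` is `"vea"`.
#' @export
run_vea <- function(dataset, alpha = 0.005) {
  run_enrichment(dataset, "vea", alpha)
}

#' Modification enrichment analysis (MEA)
#'
#' Tests every (kinase, domain type) unit for an excess of distinct modified
#' positions. Each residue is an independent Bernoulli trial with probability
#' `E_a` for its amino-acid type; the number modified in a domain follows a
#' Poisson-binomial distribution, approximated by `Poisson(E_d)` (the error is
#' bounded by the Le Cam total-variation bound `sum p_i^2`). A position with
#' several modification types counts once.
#'
#' @inheritParams run_vea
#' @return as [run_vea()], with attribute `mode = "mea"`.
#' @export
run_mea <- function(dataset, alpha = 0.005) {
  run_enrichment(dataset, "mea", alpha)
}
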