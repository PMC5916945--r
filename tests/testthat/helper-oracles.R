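# Independent oracles and fixture builders, deliberately kept naive and
# separate from the package's production code paths.

# Upper-tail P(X >= k) for X ~ Poisson(lam) by direct PMF summation of the
# lower tail (naive, adequate for lam <= ~50 at double precision).
pois_upper_pmf_sum <- function(k, lam) {
  if (k == 0) return(1)
  terms <- vapply(0:(k - 1), function(j) exp(-lam + j * log(lam) - lgamma(j + 1)),
                  0)
  max(0, 1 - sum(terms))
}

# Exact Poisson-binomial upper tail P(S >= k), S = sum of independent
# Bernoulli(p_i), by dynamic-programming convolution.
poisbin_upper <- function(p, k) {
  probs <- 1
  for (pi in p) probs <- c(probs * (1 - pi), 0) + c(0, probs * pi)
  if (k <= 0) return(1)
  if (k > length(p)) return(0)
  sum(probs[(k + 1):length(probs)])
}

# Hand-rolled Benjamini-Hochberg step-up, used as the reference for the
# package's adjustment (which delegates to stats::p.adjust).
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Build a fully specified dataset from plain vectors; bypasses simulation so
# worked examples control every count exactly.
make_dataset <- function(sequences, domains,
                         mutations = NULL, ptms = NULL, ...) {
  kin <- data.frame(accession = names(sequences),
                    gene_symbol = toupper(names(sequences)),
                    group = "Other", sequence = unname(sequences))
  if (is.null(mutations)) {
    mutations <- data.frame(accession = character(), position = integer(),
                            ref_aa = character(), alt_aa = character(),
                            sample_id = character(),
                            genome_wide_screen = logical())
  }
  if (is.null(ptms)) {
    ptms <- data.frame(accession = character(), position = integer(),
                       residue = character(), mod_type = character(),
                       confidence = numeric(), manually_curated = logical())
  }
  validate_dataset(kin, mutations, ptms, domains, ...)
}

# Mutation-event rows at given positions, each in its own sample so that the
# per-sample deduplication keeps every event.
mut_events <- function(accession, positions, ref, alt = NULL) {
  n <- length(positions)
  if (is.null(alt)) alt <- ifelse(ref == "V", "A", "V")
  data.frame(accession = rep(accession, length.out = n), position = positions,
             ref_aa = rep(ref, length.out = n),
             alt_aa = rep(alt, length.out = n),
             sample_id = sprintf("smp%04d", seq_len(n)),
             genome_wide_screen = rep(TRUE, n))
}

ptm_rows <- function(accession, positions, residue, mod = "phosphorylation",
                     confidence = 2, curated = TRUE) {
  n <- length(positions)
  data.frame(accession = rep(accession, length.out = n), position = positions,
             residue = rep(residue, length.out = n),
             mod_type = rep(mod, length.out = n),
             confidence = rep(confidence, length.out = n),
             manually_curated = rep(curated, length.out = n))
}

# One null (no planted signal) replicate of the scaled study conditions:
# returns the dual-enrichment false-discovery proportion and table size.
null_dual_fdp <- function(seed, n_kinases = 50) {
  cfg <- sim_config(n_kinases = n_kinases, seq_length_range = c(400L, 600L),
                    n_domains_per_kinase = c(2L, 2L),
                    domain_length_range = c(90L, 110L),
                    non_gws_fraction = 0, seed = seed)
  sim <- simulate_kinome(cfg)
  d <- dual_enriched(run_vea(sim$dataset), run_mea(sim$dataset))
  c(fdp = if (nrow(d)) 1 else 0, n_disc = nrow(d))
}
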