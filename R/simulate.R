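#' Simulation configuration for a synthetic kinome
#'
#' Builds and validates the configuration driving [simulate_kinome()] and
#' [simulate_annotation_matrix()]. Defaults describe a small kinome in which a
#' typical 100-residue domain expects about two mutation events and about two
#' modified residues under the null, so planted multipliers act against a
#' realistic low background.
#'
#' @param n_kinases number of kinases to generate.
#' @param seq_length_range integer pair, uniform range of sequence lengths.
#' @param aa_frequencies named numeric vector of length 20 over the standard
#'   amino acids; must be nonnegative and sum to 1 (tolerance 1e-9). Default
#'   uniform.
#' @param n_domains_per_kinase integer pair, uniform range of domain counts
#'   per kinase.
#' @param domain_length_range integer pair, uniform range of domain lengths.
#' @param n_samples number of cancer samples in the simulated cohort.
#' @param background_mutation_rate expected mutation events per residue across
#'   the whole cohort (Poisson rate outside planted domains).
#' @param ptm_site_probability named numeric vector: per-residue Bernoulli
#'   probability that a residue of that amino-acid type is a curated PTM site.
#'   Residue types absent from the vector are never modified.
#' @param planted_domains data frame with columns `kinase` (1-based kinase
#'   index), `domain` (1-based domain index within that kinase), `mut_mult`
#'   and `ptm_mult` (rate/probability multipliers, both >= 1). Default none.
#' @param annotation_variables character vector of annotation-count variable
#'   names for the resource matrix; default the 14 federated-query variables.
#' @param annotation_noise log-scale noise sd of the annotation generator;
#'   0 gives deterministic monotone functions of the latent study intensity.
#' @param low_confidence_fraction fraction of generated PTM rows written with
#'   a failing confidence/curation status, to exercise the ingest filter.
#' @param non_gws_fraction fraction of mutation events flagged as not coming
#'   from a genome-wide screen, to exercise the screen filter.
#' @param seed integer root seed; all randomness derives from it via named
#'   substreams per data category.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_kinases = 50,
                       seq_length_range = c(300L, 600L),
                       aa_frequencies = NULL,
                       n_domains_per_kinase = c(1L, 3L),
                       domain_length_range = c(60L, 140L),
                       n_samples = 500,
                       background_mutation_rate = 0.02,
                       ptm_site_probability = c(S = 0.12, T = 0.08, Y = 0.08,
                                                K = 0.08, R = 0.04),
                       planted_domains = NULL,
                       annotation_variables = NULL,
                       annotation_noise = 0.5,
                       low_confidence_fraction = 0.05,
                       non_gws_fraction = 0.1,
                       seed = 1L) {
  if (is.null(aa_frequencies)) {
    aa_frequencies <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  if (is.null(annotation_variables)) {
    annotation_variables <- c(
      "Mutation", "Reaction", "Complex", "Pathway", "PubMed_human",
      "Homologs", "Modifications", "Expression_human", "GO_human", "PPI",
      "GO_mouse", "Phenotype", "Expression_mouse", "PubMed_mouse")
  }
  if (is.null(planted_domains)) {
    planted_domains <- data.frame(kinase = integer(), domain = integer(),
                                  mut_mult = numeric(), ptm_mult = numeric())
  }
  cfg <- list(n_kinases = as.integer(n_kinases),
              seq_length_range = as.integer(seq_length_range),
              aa_frequencies = aa_frequencies,
              n_domains_per_kinase = as.integer(n_domains_per_kinase),
              domain_length_range = as.integer(domain_length_range),
              n_samples = as.integer(n_samples),
              background_mutation_rate = background_mutation_rate,
              ptm_site_probability = ptm_site_probability,
              planted_domains = planted_domains,
              annotation_variables = annotation_variables,
              annotation_noise = annotation_noise,
              low_confidence_fraction = low_confidence_fraction,
              non_gws_fraction = non_gws_fraction,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_kinases < 1L) config_error("n_kinases must be >= 1")
  if (cfg$n_samples < 1L) config_error("n_samples must be >= 1")
  f <- cfg$aa_frequencies
  if (length(f) != 20 || !setequal(names(f), AA_ALPHABET)) {
    config_error("aa_frequencies must name exactly the 20 standard amino acids")
  }
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
    config_error("aa_frequencies must be nonnegative and sum to 1 (+- 1e-9)")
  }
  if (any(cfg$seq_length_range < 1L) || diff(cfg$seq_length_range) < 0) {
    config_error("seq_length_range must be a nondecreasing positive pair")
  }
  if (any(cfg$n_domains_per_kinase < 0L) || diff(cfg$n_domains_per_kinase) < 0) {
    config_error("n_domains_per_kinase must be a nondecreasing nonnegative pair")
  }
  if (any(cfg$domain_length_range < 1L) || diff(cfg$domain_length_range) < 0) {
    config_error("domain_length_range must be a nondecreasing positive pair")
  }
  if (cfg$background_mutation_rate < 0) {
    config_error("background_mutation_rate must be >= 0")
  }
  if (any(cfg$ptm_site_probability < 0) || any(cfg$ptm_site_probability > 1)) {
    config_error("ptm_site_probability values must lie in [0, 1]")
  }
  pd <- cfg$planted_domains
  if (!all(c("kinase", "domain", "mut_mult", "ptm_mult") %in% names(pd))) {
    config_error("planted_domains needs columns kinase, domain, mut_mult, ptm_mult")
  }
  if (nrow(pd) && (any(pd$mut_mult < 1) || any(pd$ptm_mult < 1))) {
    config_error("planted multipliers must be >= 1")
  }
  if (cfg$annotation_noise < 0) config_error("annotation_noise must be >= 0")
  if (cfg$low_confidence_fraction < 0 || cfg$low_confidence_fraction > 1 ||
      cfg$non_gws_fraction < 0 || cfg$non_gws_fraction > 1) {
    config_error("fractions must lie in [0, 1]")
  }
  cfg
}

# Uniform integer draw from [lo, hi]; safe when lo == hi (no sample() scalar
# surprise).
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Pfam-style family-name pool; sampled without replacement within a kinase so
# (accession, domain_id) uniquely identifies one generated domain.
DOMAIN_NAME_POOL <- c(
  "Pkinase", "Pkinase_Tyr", "Pkinase_C", "PH", "SH2", "SH3", "C1_1", "C2",
  "PBD", "EphA2_TM", "fn3", "PPAK", "Bromodomain", "GF_recep_IV",
  "Recep_L_domain", "FERM_M", "RhoGEF", "PDZ", "WD40", "Ig_like",
  "DAG_PE_bind", "SAM_1", "CNH", "UBA")

#' Generate a synthetic kinome dataset with known ground truth
#'
#' Draws sequences i.i.d. from the configured amino-acid frequencies, places
#' non-overlapping domain intervals, generates per-residue Poisson mutation
#' events (rate multiplied inside planted domains) attributed to uniformly
#' drawn cohort samples, and per-residue Bernoulli curated PTM sites (type
#' assigned by residue: phosphorylation on S/T/Y, acetylation/ubiquitination/
#' methylation on K, methylation on R). All draws are deterministic given the
#' config seed; each data category uses its own named substream.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `dataset` (a validated `kinome_dataset`, see
#'   [validate_dataset()]), `raw` (the unvalidated record tables, as written to
#'   disk), and `truth` (list with `enriched_domains`, a data frame of planted
#'   (accession, domain_id) keys and their multipliers, and
#'   `study_intensity`, reserved for [simulate_annotation_matrix()]).
#' @export
simulate_kinome <- function(config) {
  config <- validate_sim_config(config)
  n <- config$n_kinases
  acc <- sprintf("K%04d", seq_len(n))
  gene <- sprintf("GENE%04d", seq_len(n))
  group <- with_substream(config$seed, "groups",
                          sample(KINASE_GROUPS, n, replace = TRUE))

  seqs <- with_substream(config$seed, "sequences", {
    lens <- sample_range(config$seq_length_range[1],
                         config$seq_length_range[2], n)
    lapply(lens, function(L) {
      sample(AA_ALPHABET, L, replace = TRUE, prob = config$aa_frequencies)
    })
  })
  lens <- lengths(seqs)

  domains <- with_substream(config$seed, "domains", {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      k <- sample_range(config$n_domains_per_kinase[1],
                        config$n_domains_per_kinase[2], 1L)
      if (k == 0L) next
      dl <- sample_range(config$domain_length_range[1],
                         config$domain_length_range[2], k)
      # drop trailing domains that cannot fit in this sequence
      while (k > 0 && sum(dl[seq_len(k)]) > lens[i]) k <- k - 1L
      if (k == 0L) next
      dl <- dl[seq_len(k)]
      # distribute free residues into k+1 gaps, then lay domains end to end
      gaps <- as.vector(stats::rmultinom(1, lens[i] - sum(dl), rep(1, k + 1)))
      start <- cumsum(c(1L, dl)) [seq_len(k)] + cumsum(gaps[seq_len(k)])
      ids <- sample(DOMAIN_NAME_POOL, k, replace = FALSE)
      out[[i]] <- data.frame(accession = acc[i], domain_id = ids,
                             start = as.integer(start),
                             end = as.integer(start + dl - 1L),
                             domain_index = seq_len(k))
    }
    do.call(rbind, c(out, list(data.frame(accession = character(),
                                          domain_id = character(),
                                          start = integer(), end = integer(),
                                          domain_index = integer()))))
  })

  # per-residue rate/probability multipliers from planted domains
  pd <- config$planted_domains
  mut_mult <- lapply(lens, function(L) rep(1, L))
  ptm_mult <- lapply(lens, function(L) rep(1, L))
  planted_keys <- data.frame(accession = character(), domain_id = character(),
                             mut_mult = numeric(), ptm_mult = numeric())
  if (nrow(pd)) {
    for (r in seq_len(nrow(pd))) {
      i <- pd$kinase[r]
      if (i < 1 || i > n) config_error("planted kinase index out of range")
      drows <- domains[domains$accession == acc[i] &
                       domains$domain_index == pd$domain[r], , drop = FALSE]
      if (!nrow(drows)) {
        config_error(sprintf("planted domain %d absent in kinase %d (did not fit)",
                             pd$domain[r], i))
      }
      idx <- seq(drows$start[1], drows$end[1])
      mut_mult[[i]][idx] <- mut_mult[[i]][idx] * pd$mut_mult[r]
      ptm_mult[[i]][idx] <- ptm_mult[[i]][idx] * pd$ptm_mult[r]
      planted_keys <- rbind(planted_keys,
                            data.frame(accession = acc[i],
                                       domain_id = drows$domain_id[1],
                                       mut_mult = pd$mut_mult[r],
                                       ptm_mult = pd$ptm_mult[r]))
    }
  }

  mutations <- with_substream(config$seed, "mutations", {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      counts <- rpois(lens[i], config$background_mutation_rate * mut_mult[[i]])
      tot <- sum(counts)
      if (tot == 0L) next
      pos <- rep.int(seq_len(lens[i]), counts)
      ref <- seqs[[i]][pos]
      alt <- vapply(ref, function(a) sample(setdiff(AA_ALPHABET, a), 1), "")
      out[[i]] <- data.frame(
        accession = acc[i], position = pos, ref_aa = ref, alt_aa = alt,
        sample_id = sprintf("S%05d", sample.int(config$n_samples, tot,
                                                replace = TRUE)),
        genome_wide_screen = runif(tot) >= config$non_gws_fraction)
    }
    do.call(rbind, c(out, list(data.frame(
      accession = character(), position = integer(), ref_aa = character(),
      alt_aa = character(), sample_id = character(),
      genome_wide_screen = logical()))))
  })

  ptms <- with_substream(config$seed, "ptms", {
    out <- vector("list", n)
    base_p <- config$ptm_site_probability
    for (i in seq_len(n)) {
      p <- base_p[seqs[[i]]]
      p[is.na(p)] <- 0
      p <- p * ptm_mult[[i]]
      if (any(p > 1)) {
        warning("PTM probability exceeded 1 after planted multiplier; clipped",
                call. = FALSE)
        p <- pmin(p, 1)
      }
      hit <- which(runif(lens[i]) < p)
      if (!length(hit)) next
      res <- seqs[[i]][hit]
      mod <- ifelse(res %in% c("S", "T", "Y"), "phosphorylation",
             ifelse(res == "R", "methylation",
                    sample(c("acetylation", "ubiquitination", "methylation"),
                           length(res), replace = TRUE)))
      df <- data.frame(accession = acc[i], position = hit, residue = res,
                       mod_type = mod)
      # a small fraction of K sites carry a second modification type
      second <- which(res == "K" & runif(length(res)) < 0.05)
      if (length(second)) {
        alt_mod <- vapply(mod[second], function(m) {
          sample(setdiff(c("acetylation", "ubiquitination", "methylation"), m), 1)
        }, "")
        df <- rbind(df, data.frame(accession = acc[i], position = hit[second],
                                   residue = res[second], mod_type = alt_mod))
      }
      m <- nrow(df)
      fail <- runif(m) < config$low_confidence_fraction
      df$confidence <- ifelse(fail, runif(m, 0, 1), runif(m, 1.05, 4))
      df$manually_curated <- TRUE
      # half of the failing rows fail via the curation flag instead
      flip <- fail & runif(m) < 0.5
      df$manually_curated[flip] <- FALSE
      df$confidence[flip] <- runif(sum(flip), 1.05, 4)
      out[[i]] <- df
    }
    do.call(rbind, c(out, list(data.frame(
      accession = character(), position = integer(), residue = character(),
      mod_type = character(), confidence = numeric(),
      manually_curated = logical()))))
  })

  kinases <- data.frame(accession = acc, gene_symbol = gene, group = group,
                        sequence = vapply(seqs, paste0, "", collapse = ""))
  rownames(mutations) <- rownames(ptms) <- rownames(domains) <- NULL
  domains_out <- domains[, c("accession", "domain_id", "start", "end")]
  raw <- list(kinases = kinases, mutations = mutations, ptms = ptms,
              domains = domains_out)
  dataset <- validate_dataset(kinases, mutations, ptms, domains_out)
  truth <- list(enriched_domains = planted_keys, study_intensity = NULL)
  list(dataset = dataset, raw = raw, truth = truth)
}

#' Generate a synthetic annotation-count matrix and NIH metrics
#'
#' Draws a latent per-kinase "study intensity" from a heavy-tailed (lognormal)
#' distribution; every annotation variable and every NIH measurement is a
#' noisy monotone function of that latent, so the omega score and the NIH
#' metrics are positively correlated with tunable strength. With
#' `annotation_noise = 0` all functions are deterministic and strictly
#' monotone, giving Spearman rho of exactly 1.
#'
#' @param config a [sim_config()] object.
#' @return list with `matrix` (data frame: accession + one count column per
#'   annotation variable), `nih` (data frame: accession, jensen_score,
#'   r01_count, pubtator_score), and `truth` (list with `study_intensity`,
#'   a named numeric vector).
#' @export
simulate_annotation_matrix <- function(config) {
  config <- validate_sim_config(config)
  if (!length(config$annotation_variables)) {
    config_error("at least one annotation variable is required")
  }
  n <- config$n_kinases
  acc <- sprintf("K%04d", seq_len(n))
  vars <- config$annotation_variables
  noise <- config$annotation_noise

  res <- with_substream(config$seed, "annotation", {
    lat <- rlnorm(n, meanlog = 0, sdlog = 1)
    V <- sapply(seq_along(vars), function(j) {
      b <- runif(1, 0.7, 1.3)         # per-variable exponent
      sc <- exp(runif(1, 1, 4))       # per-variable abundance scale
      mu <- sc * lat^b
      if (noise > 0) rpois(n, mu * exp(rnorm(n, 0, noise))) else mu
    })
    if (n == 1L) V <- matrix(V, nrow = 1)
    list(lat = lat, V = V)
  })
  nih <- with_substream(config$seed, "nih", {
    lat <- res$lat
    mult <- function() if (noise > 0) exp(rnorm(n, 0, noise)) else 1
    data.frame(accession = acc,
               jensen_score = 50 * lat * mult(),
               r01_count = if (noise > 0) rpois(n, 2 * lat * mult())
                           else 2 * lat,
               pubtator_score = 150 * lat * mult())
  })
  mat <- data.frame(accession = acc, res$V)
  names(mat) <- c("accession", vars)
  list(matrix = mat, nih = nih,
       truth = list(study_intensity = setNames(res$lat, acc)))
}
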