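#' Run the full enrichment pipeline
#'
#' Orchestrates simulate/load, validation, VEA, MEA, dual enrichment,
#' annotation scoring, overlap-site detection and report writing, and records
#' a manifest (config echo, seed, record counts, dropped-record report, and
#' MD5 checksums of every output) so a run is fully reconstructable.
#' Identical config and seed produce byte-identical outputs.
#'
#' @param config either a path to a YAML config file or a named list. Exactly
#'   one of `simulate` (a list of [sim_config()] overrides) or `inputs` (named
#'   paths: fasta, mutations, ptms, domains, optionally annotation_matrix and
#'   nih_metrics) must be present. Optional fields: `alpha` (default 0.005),
#'   `omega_threshold` (default 1.00), `min_confidence` (default 1, strict),
#'   `genome_wide_filter` (default TRUE), `outdir` (required), `seed`
#'   (default 1, simulate mode only).
#' @return invisibly, the manifest list. Outputs written to `outdir`:
#'   `vea.tsv`, `mea.tsv`, `dual_enrichment.tsv`, `overlap_sites.tsv`,
#'   `scores.tsv` (when annotation inputs are available), simulated input
#'   tables in simulate mode, and `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      input_error(sprintf("config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    config_error("config must contain exactly one of 'simulate' or 'inputs'")
  }
  if (is.null(config$outdir)) config_error("config must name an 'outdir'")
  alpha <- config$alpha %||% 0.005
  omega_threshold <- config$omega_threshold %||% 1.00
  min_confidence <- config$min_confidence %||% 1
  gw_filter <- config$genome_wide_filter %||% TRUE
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  scores <- NULL
  if (has_sim) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed %||% 1L
    if (!is.null(sim_args$planted_domains)) {
      sim_args$planted_domains <-
        as.data.frame(do.call(rbind, lapply(sim_args$planted_domains, as.data.frame)))
    }
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_kinome(cfg)
    write_kinome_tables(sim$raw, outdir)
    dataset <- validate_dataset(sim$raw$kinases, sim$raw$mutations,
                                sim$raw$ptms, sim$raw$domains,
                                genome_wide_filter = gw_filter,
                                min_confidence = min_confidence)
    ann <- simulate_annotation_matrix(cfg)
    write_tsv(ann$matrix, file.path(outdir, "annotation_matrix.tsv"))
    write_tsv(ann$nih, file.path(outdir, "nih_metrics.tsv"))
    scores <- classify_kinases(omega_scores(ann$matrix), ann$nih,
                               omega_threshold)
  } else {
    inp <- config$inputs
    for (f in c("fasta", "mutations", "ptms", "domains")) {
      if (is.null(inp[[f]])) config_error(sprintf("inputs must name '%s'", f))
      if (!file.exists(inp[[f]])) {
        input_error(sprintf("input file not found: %s", inp[[f]]))
      }
    }
    dataset <- load_kinome_dataset(inp$fasta, inp$mutations, inp$ptms,
                                   inp$domains,
                                   genome_wide_filter = gw_filter,
                                   min_confidence = min_confidence)
    if (!is.null(inp$annotation_matrix) && !is.null(inp$nih_metrics)) {
      amat <- read_table(inp$annotation_matrix, "annotation_matrix")
      nih <- read_table(inp$nih_metrics, "nih_metrics")
      scores <- classify_kinases(omega_scores(amat), nih, omega_threshold)
    }
  }

  vr <- dataset$validation_report
  dropped <- vr[vr > 0]
  if (length(dropped)) {
    warning("validation dropped/flagged records: ",
            paste(names(dropped), dropped, sep = "=", collapse = ", "),
            call. = FALSE)
  }

  vea <- run_vea(dataset, alpha)
  mea <- run_mea(dataset, alpha)
  dual <- dual_enriched(vea, mea, alpha)
  overlaps <- overlap_sites(dataset, restrict_to = dual)

  fmt <- function(x) {
    for (cl in names(x)) if (is.numeric(x[[cl]]) && !is.integer(x[[cl]])) {
      x[[cl]] <- signif(x[[cl]], 7)
    }
    x
  }
  write_tsv(fmt(vea), file.path(outdir, "vea.tsv"))
  write_tsv(fmt(mea), file.path(outdir, "mea.tsv"))
  write_tsv(fmt(dual), file.path(outdir, "dual_enrichment.tsv"))
  write_tsv(overlaps, file.path(outdir, "overlap_sites.tsv"))
  if (!is.null(scores)) write_tsv(fmt(scores), file.path(outdir, "scores.tsv"))

  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    config = config,
    counts = list(kinases = nrow(dataset$kinases),
                  mutation_events = nrow(dataset$mutations),
                  ptm_rows = nrow(dataset$ptms),
                  domain_intervals = nrow(dataset$domains),
                  test_units = nrow(vea),
                  dual_enriched = nrow(dual),
                  overlap_sites = nrow(overlaps)),
    validation_report = as.list(vr),
    checksums = as.list(tools::md5sum(sort(outputs))))
  names(manifest$checksums) <- basename(sort(outputs))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
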