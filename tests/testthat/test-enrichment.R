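test_that("composition tables count residues kinome-wide and per pooled unit", {
  ds <- make_dataset(c(k1 = "SSSAA"),
                     data.frame(accession = "k1", domain_id = "dom",
                                start = 1L, end = 3L))
  comp <- compute_composition(ds)
  expect_equal(comp$N_a[["S"]], 3L)
  expect_equal(comp$N_a[["A"]], 2L)
  expect_equal(sum(comp$N_a), 5L)
  expect_equal(comp$N_ad["k1\rdom", "S"], 3L)
  expect_equal(sum(comp$N_ad), 3L)

  # two copies of one domain id pool into a single unit with summed counts
  ds2 <- make_dataset(c(k1 = "SSSAASSS"),
                      data.frame(accession = "k1", domain_id = "fn3",
                                 start = c(1L, 6L), end = c(3L, 8L)))
  comp2 <- compute_composition(ds2)
  expect_equal(nrow(comp2$units), 1L)
  expect_equal(comp2$N_ad[1, "S"], 6L)

  # nonstandard residues are excluded from all counts and reported
  kin <- data.frame(accession = "k1", gene_symbol = "K1", group = "Other",
                    sequence = "SSXAA")
  ds3 <- validate_dataset(kin,
                          mut_events("k1", integer(0), character(0)),
                          ptm_rows("k1", integer(0), character(0)),
                          data.frame(accession = "k1", domain_id = "d",
                                     start = 1L, end = 5L))
  expect_equal(ds3$validation_report[["nonstandard_residue"]], 1L)
  comp3 <- compute_composition(ds3)
  expect_equal(sum(comp3$N_a), 4L)
  expect_equal(comp3$units$n_residues, 4L)
})

test_that("per-residue rates divide event counts by composition", {
  ds <- make_dataset(c(k1 = strrep("S", 100)),
                     data.frame(accession = "k1", domain_id = "d",
                                start = 1L, end = 10L))
  comp <- compute_composition(ds)
  r <- per_residue_rate(c(S = 10), comp, "vea")
  expect_equal(r$E_a[["S"]], 0.1)
  expect_true(all(r$E_a[setdiff(names(r$E_a), "S")] == 0))
  expect_equal(per_residue_rate(c(S = 0), comp, "vea")$E_a[["S"]], 0)
  # MEA: 6 modified S among 30 S residues -> Bernoulli p 0.2
  ds30 <- make_dataset(c(k1 = strrep("S", 30)),
                       data.frame(accession = "k1", domain_id = "d",
                                  start = 1L, end = 30L))
  expect_equal(per_residue_rate(c(S = 6), compute_composition(ds30),
                                "mea")$E_a[["S"]], 0.2)
  # events on an amino acid absent from the kinome are contradictory
  expect_error(per_residue_rate(c(W = 3), comp, "vea"), "absent")
})

test_that("expected counts follow E_d = sum_a E_a N_ad", {
  ds <- make_dataset(c(k1 = paste0(strrep("A", 50), strrep("S", 50))),
                     data.frame(accession = "k1", domain_id = "d",
                                start = 1L, end = 10L))
  r <- per_residue_rate(c(A = 5, S = 10), compute_composition(ds), "vea")
  expect_equal(expected_count(r, c(A = 5, S = 3)), 5 * 0.1 + 3 * 0.2)
  expect_equal(expected_count(r, numeric(0)), 0)
  # uniform rate: lambda = r * L
  r2 <- per_residue_rate(setNames(rep(5, 20), names(r$E_a)),
                         compute_composition(make_dataset(
                           c(k1 = paste(rep(names(r$E_a), 5), collapse = "")),
                           data.frame(accession = "k1", domain_id = "d",
                                      start = 1L, end = 100L))), "vea")
  expect_equal(expected_count(r2, setNames(rep(1, 20), names(r2$E_a))), 20)
})

test_that("poisson_upper_p is an exact, monotone upper tail", {
  expect_equal(poisson_upper_p(0, 3.7), 1)
  expect_equal(poisson_upper_p(1, 0), 0)
  expect_equal(poisson_upper_p(3, 1), 0.0803014, tolerance = 1e-6)
  expect_error(poisson_upper_p(-1, 1), "nonnegative")
  expect_error(poisson_upper_p(1, -1), "nonnegative")
  for (lam in c(0.3, 2, 9)) {
    p <- poisson_upper_p(0:30, lam)
    expect_true(all(diff(p) <= 0))        # nonincreasing in observed
    expect_true(all(p >= 0 & p <= 1))
  }
  for (k in c(1L, 4L, 12L)) {
    p <- vapply(c(0.1, 1, 2, 5, 10), function(l) poisson_upper_p(k, l), 0)
    expect_true(all(diff(p) >= 0))        # nondecreasing in lam
  }
})

test_that("BH adjustment matches the hand-rolled step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.9)), c(0.015, 0.06, 0.9))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_stepup_oracle(p))
    expect_true(all(adj >= p) && all(adj <= 1))
    o <- sample(seq_along(p))             # order-equivariance
    expect_equal(bh_adjust(p[o]), adj[o])
  }
})

test_that("enrichment scores floor the adjusted p-value at 1e-14", {
  expect_equal(enrichment_score(1e-20), 14)
  expect_equal(enrichment_score(6.70e-6), 5.1739, tolerance = 1e-4)
  expect_equal(enrichment_score(1), 0)
})

test_that("VEA reproduces the composition-adjusted Poisson worked example", {
  # kinome: 100 A residues, 10 A-mutation events -> E_A = 0.1;
  # unit of 20 A residues -> lambda = 2; 6 observed events
  muts <- mut_events("k1", c(2, 5, 7, 11, 15, 19, 30, 55, 70, 90), "A")
  ds <- make_dataset(c(k1 = strrep("A", 100)),
                     data.frame(accession = "k1", domain_id = "d",
                                start = 1L, end = 20L),
                     mutations = muts)
  res <- run_vea(ds)
  expect_equal(res$observed, 6L)
  expect_equal(res$expected, 2)
  expect_equal(res$raw_p, 0.016564, tolerance = 1e-4)
  expect_equal(res$raw_p, pois_upper_pmf_sum(6, 2), tolerance = 1e-12)
  expect_equal(res$adj_p, res$raw_p)      # single unit: BH with m = 1
  expect_false(res$significant)

  # zero events everywhere -> p = 1, nothing significant
  res0 <- run_vea(make_dataset(c(k1 = strrep("A", 100)),
                               data.frame(accession = "k1", domain_id = "d",
                                          start = 1L, end = 20L)))
  expect_equal(res0$raw_p, 1)
  expect_false(any(res0$significant))

  # no domains -> empty result
  expect_equal(nrow(run_vea(make_dataset(c(k1 = "AAAA"),
                                         data.frame(accession = character(),
                                                    domain_id = character(),
                                                    start = integer(),
                                                    end = integer())))), 0L)
})

test_that("MEA counts distinct modified positions against the Bernoulli rates", {
  # 150 S residues, 30 modified kinome-wide -> p_S = 0.2; unit of 30 S
  # residues -> lambda = 6; 12 observed distinct sites
  ptms <- ptm_rows("k1", c(1:12, seq(40, 125, by = 5)), "S")
  ds <- make_dataset(c(k1 = strrep("S", 150)),
                     data.frame(accession = "k1", domain_id = "d",
                                start = 1L, end = 30L),
                     ptms = ptms)
  res <- run_mea(ds)
  expect_equal(res$observed, 12L)
  expect_equal(res$expected, 6)
  expect_equal(res$raw_p, pois_upper_pmf_sum(12, 6), tolerance = 1e-12)

  # a site with two modification types still counts once
  ptms2 <- rbind(ptm_rows("k1", 1:12, "S"),
                 ptm_rows("k1", 1, "S", mod = "methylation"))
  ds2 <- make_dataset(c(k1 = strrep("S", 150)),
                      data.frame(accession = "k1", domain_id = "d",
                                 start = 1L, end = 30L),
                      ptms = rbind(ptms2, ptm_rows("k1", seq(40, 125, 5), "S")))
  expect_equal(run_mea(ds2)$observed, 12L)

  # nothing passes the confidence filter -> observed 0, p 1
  ds3 <- make_dataset(c(k1 = strrep("S", 150)),
                      data.frame(accession = "k1", domain_id = "d",
                                 start = 1L, end = 30L),
                      ptms = ptm_rows("k1", 1:12, "S", confidence = 1))
  res3 <- run_mea(ds3)
  expect_equal(res3$observed, 0L)
  expect_equal(res3$raw_p, 1)
})

test_that("expected counts are conserved when domains partition the kinome", {
  set.seed(9)
  sim <- simulate_kinome(sim_config(n_kinases = 15, seed = 21))
  ds <- sim$dataset
  # replace domains by a 3-block partition of every sequence
  parts <- do.call(rbind, lapply(seq_len(nrow(ds$kinases)), function(i) {
    L <- nchar(ds$kinases$sequence[i])
    cut <- sort(sample(seq_len(L - 1), 2))
    data.frame(accession = ds$kinases$accession[i],
               domain_id = c("blockA", "blockB", "blockC"),
               start = c(1L, cut[1] + 1L, cut[2] + 1L),
               end = c(cut[1], cut[2], L))
  }))
  ds2 <- validate_dataset(ds$kinases, ds$mutations, ds$ptms, parts)
  vea <- run_vea(ds2)
  expect_equal(sum(vea$expected), nrow(ds2$mutations), tolerance = 1e-9)
  expect_equal(sum(vea$observed), nrow(ds2$mutations))
  mea <- run_mea(ds2)
  n_sites <- nrow(unique(ds2$ptms[, c("accession", "position")]))
  expect_equal(sum(mea$expected), n_sites, tolerance = 1e-9)
  expect_equal(sum(mea$observed), n_sites)
})

test_that("MEA Poisson approximation respects the Le Cam bound", {
  sim <- simulate_kinome(sim_config(n_kinases = 10, seed = 31))
  mea <- run_mea(sim$dataset)
  comp <- attr(mea, "composition")
  sites <- unique(sim$dataset$ptms[, c("accession", "position")])
  E_a <- per_residue_rate(
    table(factor(
      mapply(function(a, p) substr(sim$dataset$kinases$sequence[
        sim$dataset$kinases$accession == a], p, p),
        sites$accession, sites$position), levels = names(comp$N_a))),
    comp, "mea")$E_a
  for (i in seq_len(nrow(mea))) {
    unit <- rownames(comp$N_ad)[i]
    p_i <- E_a[comp$unit_positions$aa[comp$unit_positions$unit == unit]]
    bound <- sum(p_i^2)
    exact <- poisbin_upper(p_i, mea$observed[i])
    expect_lte(abs(mea$raw_p[i] - exact), bound + 1e-12)
  }
})
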