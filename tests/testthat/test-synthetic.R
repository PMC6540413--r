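test_that("default panel mirrors the immune profiling design", {
  cfg <- simulation_config()
  panel <- build_panel(cfg)
  tab <- table(panel$probes$CodeClass)
  expect_equal(unname(tab[["Endogenous"]]), 730)
  expect_equal(unname(tab[["Housekeeping"]]), 40)
  expect_false(anyDuplicated(panel$probes$Name) > 0)

  kinds <- signature_kinds(panel$signatures)
  expect_setequal(names(panel$signatures)[kinds == "cell_type"],
                  nanostring_cell_types())
  expect_setequal(names(panel$signatures)[kinds == "response_category"],
                  response_categories())
  expect_true("Teff" %in% names(panel$signatures))

  # every cell type populated; Treg is the FOXP3 singleton
  sizes <- vapply(panel$signatures, function(s) length(s$genes), integer(1))
  expect_true(all(sizes >= 1L))
  expect_identical(panel$signatures[["Treg"]]$genes, "FOXP3")
  expect_true(all(c("GZMA", "PRF1") %in% panel$probes$Name))

  # response categories overlap partially, so overlap exclusion has work
  cat_genes <- lapply(panel$signatures[kinds == "response_category"],
                      `[[`, "genes")
  shared <- table(unlist(cat_genes))
  expect_true(any(shared >= 2L))
  expect_true(any(shared == 1L))

  # all signature members are endogenous probes
  expect_true(all(unlist(cat_genes) %in% panel$probes$Name))
})

test_that("minimal panel yields singleton cell-type signatures", {
  cfg <- simulation_config(n_endogenous = 24, genes_per_cell_type = 1,
                           n_category_specific = 0)
  panel <- build_panel(cfg)
  kinds <- signature_kinds(panel$signatures)
  sizes <- vapply(panel$signatures[kinds == "cell_type"],
                  function(s) length(s$genes), integer(1))
  expect_true(all(sizes == 1L))
})

test_that("panels too small for the signature layout raise a sizing error", {
  expect_error(build_panel(simulation_config(n_endogenous = 30)),
               "sizing")
})

test_that("identical configuration reproduces the identical cohort", {
  cfg <- simulation_config(n_samples = 20, n_endogenous = 60,
                           genes_per_cell_type = 2, n_category_specific = 0,
                           seed = 11)
  expect_identical(build_panel(cfg), build_panel(cfg))
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$raw$counts, c2$raw$counts)
  expect_identical(c1$annotation, c2$annotation)
  expect_identical(c1$truth, c2$truth)
})

test_that("planted effects land on the targeted signature genes", {
  cfg0 <- simulation_config(n_samples = 12, n_endogenous = 60,
                            genes_per_cell_type = 2, n_category_specific = 0,
                            seed = 3)
  co0 <- simulate_counts(build_panel(cfg0), cfg0)
  expect_true(all(co0$truth$log2fc == 0))

  cfg <- simulation_config(n_samples = 150, effect_map = list("T-cell" = -1),
                           latent_tcell_sd = 0, seed = 5)
  panel <- build_panel(cfg)
  co <- simulate_counts(panel, cfg)
  tc <- panel$signatures[["T-cell"]]$genes
  expect_true(all(co$truth$log2fc[tc] == -1))
  expect_true(all(co$truth$log2fc[setdiff(names(co$truth$log2fc), tc)] == 0))

  rec <- co$annotation$recurrent
  mlog <- rowMeans(log2(co$raw$counts[tc, rec, drop = FALSE] + 1)) -
    rowMeans(log2(co$raw$counts[tc, !rec, drop = FALSE] + 1))
  expect_true(mean(mlog) < -0.5)
})

test_that("vanishing dispersion recovers the planted Poisson means", {
  cfg <- simulation_config(n_samples = 1000, n_endogenous = 30,
                           genes_per_cell_type = 1, n_category_specific = 0,
                           dispersion = 0, library_size_sd = 0,
                           latent_tcell_sd = 0, seed = 9)
  co <- simulate_counts(build_panel(cfg), cfg)
  g <- "GZMA"
  planted <- 2^co$truth$baseline_log2[g]
  obs <- co$raw$counts[g, ]
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - planted), 3 * se)
})

test_that("TIL foci track the latent T-cell level via the link strength", {
  base <- simulation_config(n_samples = 500, n_endogenous = 60,
                            genes_per_cell_type = 2, n_category_specific = 0,
                            seed = 21)

  free <- base
  free$til_link_strength <- 0
  co <- simulate_counts(build_panel(free), free)
  foci <- simulate_foci(co, free)
  max_foci <- vapply(foci, max, integer(1))
  rho0 <- cor(co$truth$latent_tcell, max_foci, method = "spearman")
  expect_lt(abs(rho0), 0.1)

  tight <- base
  tight$til_link_strength <- 2
  foci2 <- simulate_foci(co, tight)
  til <- vapply(foci2, aggregate_til_score, integer(1))
  rho2 <- cor(co$truth$latent_tcell, til, method = "spearman")
  expect_gt(rho2, 0.5)

  expect_identical(simulate_foci(co, tight), foci2)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(recurrence_fraction = 0), "strictly")
  expect_error(simulation_config(recurrence_fraction = 1), "strictly")
  expect_error(simulation_config(n_samples = 0), "positive")
  expect_error(simulation_config(effect_map = list(-1)), "named")
  expect_error(
    simulate_counts(build_panel(simulation_config(n_samples = 10)),
                    simulation_config(n_samples = 10,
                                      effect_map = list(nosuch = 1))),
    "unknown signature")
})
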