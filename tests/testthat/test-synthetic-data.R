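# Synthetic-data generator: network contracts, planted truth, omics.

test_that("the toy network satisfies its construction contract", {
  net <- build_toy_network()
  n <- length(net$rxn_id)
  expect_true(n >= 30 && n <= 60)
  expect_gte(mean(is_bidirectional(net)), 0.25)
  expect_gte(length(unique(net$subsystem)), 3)
  internal <- setdiff(net$rxn_id, fluxtier:::exchange_reactions(net))
  expect_true(all(!vapply(net$gpr[internal], is.null, logical(1))))
  expect_gt(solve_fba(net, "EX_lac", "max")$objective_value, 0)
  # seed does not change topology
  n2 <- build_toy_network(simulation_config(seed = 99))
  expect_identical(net$stoich, n2$stoich)
})

test_that("planted truth fluxes are feasible, distinct across conditions
           and reproducible", {
  cfg <- simulation_config(seed = 1)
  net <- build_toy_network(cfg)
  truth <- plant_condition_fluxes(net, cfg)
  S <- stoichiometric_matrix(net)
  for (cc in truth$conditions) {
    v <- truth$fluxes[[cc]]$t1
    expect_lt(max(abs(S %*% v)), 1e-6)
    expect_true(all(v >= net$lb - 1e-8 & v <= net$ub + 1e-8))
    # every tertile populated
    expect_setequal(unique(truth$classes[, cc]), c(-1L, 0L, 1L))
  }
  # >= 20% of reactions change tertile between some condition pair
  changed <- outer(seq_along(truth$conditions), seq_along(truth$conditions),
                   Vectorize(function(i, j)
                     mean(truth$classes[, i] != truth$classes[, j])))
  expect_gte(max(changed), 0.2)
  truth2 <- plant_condition_fluxes(net, cfg, use_cache = FALSE)
  expect_identical(truth$fluxes, truth2$fluxes)
  expect_identical(truth$labels, truth2$labels)
})

test_that("every internal reaction carries exactly one planted label", {
  cfg <- simulation_config(seed = 1)
  net <- build_toy_network(cfg)
  truth <- plant_condition_fluxes(net, cfg)
  internal <- setdiff(net$rxn_id, fluxtier:::exchange_reactions(net))
  expect_setequal(names(truth$labels), internal)
  expect_true(all(truth$labels %in%
                    c("TR", "TL-up", "TL-down", "PTL-activating",
                      "PTL-inhibiting", "IR")))
  expect_gt(sum(truth$labels == "TR"), 0)
  expect_gt(sum(startsWith(truth$labels, "TL")), 0)
  expect_gt(sum(startsWith(truth$labels, "PTL")), 0)
})

test_that("noise-free omics encode the planted labels exactly", {
  cfg <- simulation_config(seed = 1, noise_sd = 0)
  ds <- simulate_dataset(cfg)
  net <- ds$net; truth <- ds$truth; om <- ds$omics
  es <- discretize_matrix(om$expression)
  ann <- om$samples
  # a TR reaction's transcript-derived state equals its flux class in
  # every sample of every condition
  for (r in names(truth$labels)[truth$labels == "TR"]) {
    gs <- gpr_leaves(net$gpr[[r]])
    for (cc in truth$conditions) {
      smp <- ann$sample[ann$condition == cc]
      for (s in smp) {
        st <- fluxtier:::evaluate_gpr_discrete(
          net$gpr[[r]], stats::setNames(es[gs, s], gs))
        expect_identical(st, truth$classes[r, cc])
      }
    }
  }
  # a PTL site's 6-point mean series has |rho| = 1 against the truth flux
  key <- paste(ann$condition, ann$timepoint)
  for (r in names(truth$labels)[startsWith(truth$labels, "PTL")]) {
    g <- gpr_leaves(net$gpr[[r]])[1]
    site <- om$site_map$site[om$site_map$gene == g][1]
    sm <- tapply(om$phospho[site, ], key, mean)
    fl <- vapply(strsplit(names(sm), " "), function(p)
      truth$fluxes[[p[1]]][[p[2]]][r], numeric(1))
    rho <- stats::cor(sm, fl, method = "spearman")
    expect_equal(abs(rho), 1,
                 info = paste(r, truth$labels[r]))
    expect_equal(sign(rho),
                 if (truth$labels[r] == "PTL-activating") 1 else -1)
  }
})

test_that("omics shapes, coverage and determinism match the config", {
  cfg <- simulation_config(seed = 2)
  ds <- simulate_dataset(cfg)
  om <- ds$omics
  ns <- cfg$n_conditions * cfg$n_timepoints * cfg$n_replicates
  expect_equal(dim(om$expression), c(cfg$n_genes, ns))
  expect_equal(nrow(om$protein),
               round(cfg$protein_coverage * cfg$n_genes))
  expect_equal(nrow(om$phospho), cfg$phospho_sites)
  expect_equal(nrow(om$measured_fluxes), cfg$measured_flux_count)
  expect_identical(colnames(om$expression), colnames(om$protein))
  expect_identical(colnames(om$expression), colnames(om$phospho))
  gpr_genes <- unique(unlist(lapply(ds$net$gpr, gpr_leaves)))
  expect_true(all(om$site_map$gene %in% gpr_genes))
  expect_true(all(rownames(om$measured_fluxes) %in% ds$net$rxn_id))
  om2 <- generate_omics(ds$net, ds$truth, config = cfg)
  expect_identical(om$expression, om2$expression)
  expect_identical(om$phospho, om2$phospho)
  # a different noise seed changes intensities, not structure
  om3 <- generate_omics(ds$net, ds$truth,
                        config = simulation_config(seed = 3))
  expect_false(identical(om$expression, om3$expression))
  expect_identical(rownames(om$expression), rownames(om3$expression))
})

test_that("a PTL label on a GPR-less reaction is rejected", {
  cfg <- simulation_config(seed = 1)
  ds <- simulate_dataset(cfg)
  truth <- ds$truth
  bad <- truth
  bad$labels <- c(truth$labels,
                  stats::setNames("PTL-activating", "EX_glc"))
  expect_error(generate_omics(ds$net, bad, config = cfg),
               "without GPR")
})

test_that("dataset files round-trip through the TSV writer", {
  cfg <- simulation_config(seed = 1)
  ds <- simulate_dataset(cfg)
  dir <- tempfile()
  write_dataset(ds$net, ds$truth, ds$omics, dir)
  om <- read_omics_dir(dir)
  expect_equal(unname(om$expression), unname(ds$omics$expression),
               tolerance = 1e-8)
  expect_equal(om$samples, ds$omics$samples)
  net <- load_model(file.path(dir, "model.json"))
  expect_equal(net$rxn_id, ds$net$rxn_id)
})
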