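# Model structures, I/O, GPR evaluation and FBA.

fixture <- function(f) system.file("extdata", f, package = "fluxtier")

test_that("JSON and SBML loaders agree on the toy fixture", {
  nj <- load_model(fixture("toy_model.json"))
  ns <- load_model(fixture("toy_model.sbml"))
  expect_equal(length(nj$mets), 4)
  expect_equal(length(nj$rxn_id), 5)
  expect_equal(nj$rxn_id, ns$rxn_id)
  expect_equal(unname(nj$lb), unname(ns$lb))
  expect_equal(unname(nj$ub), unname(ns$ub))
  # the worked GPR example: (g1 or g2) and g3
  for (net in list(nj, ns)) {
    tree <- net$gpr$R1
    expect_equal(tree$kind, "and")
    expect_equal(tree$children[[1]]$kind, "or")
    expect_equal(sort(gpr_leaves(tree)), c("g1", "g2", "g3"))
  }
  # JSON round-trip
  tmp <- tempfile(fileext = ".json")
  write_model_json(nj, tmp)
  n2 <- load_model(tmp)
  expect_equal(n2$stoich, nj$stoich)
  expect_equal(n2$lb, nj$lb)
  expect_equal(lapply(n2$gpr, gpr_leaves), lapply(nj$gpr, gpr_leaves))
})

test_that("validation rejects malformed networks", {
  expect_error(
    metabolic_network("A", list(
      reaction("R1", c(A = -1, Zz = 1), 0, 10))),
    "undeclared metabolite")
  expect_error(
    metabolic_network(c("A", "B"), list(
      reaction("R1", c(A = -1), 0, 10),
      reaction("R1", c(B = -1), 0, 10))),
    "duplicate reaction")
  expect_error(
    metabolic_network(c("A", "A"), list(reaction("R1", c(A = -1), 0, 10))),
    "duplicate metabolite")
  expect_error(reaction("R1", c(A = -1), 5, 1), "lower_bound")
})

test_that("infinite bounds are clamped at load", {
  r <- reaction("R1", c(A = -1), -Inf, Inf)
  expect_equal(r$lower_bound, -1000)
  expect_equal(r$upper_bound, 1000)
})

test_that("stoichiometric matrix columns encode reaction stoichiometry", {
  net <- metabolic_network(c("A", "B", "C"), list(
    reaction("R1", c(A = -1, B = 1), 0, 1),
    reaction("R2", c(A = -1, B = -1, C = 2), 0, 1)))
  S <- stoichiometric_matrix(net)
  expect_equal(S[, "R1"], c(A = -1, B = 1, C = 0))
  expect_equal(S[, "R2"], c(A = -1, B = -1, C = 2))
  # round-trip: columns reproduce the stored stoichiometries exactly
  for (r in net$rxn_id) {
    col <- S[, r]
    expect_equal(col[col != 0], net$stoich[[r]][names(col[col != 0])])
  }
  empty <- metabolic_network(character(0), list())
  expect_equal(dim(stoichiometric_matrix(empty)), c(0, 0))
})

test_that("GPR evaluation follows min/max semantics and matches an
           independent evaluator on random trees", {
  tree <- parse_gpr("(g1 or g2) and g3")
  expect_equal(evaluate_gpr(tree, c(g1 = 5, g2 = 2, g3 = 3)), 3)
  expect_equal(evaluate_gpr(parse_gpr("g1"), c(g1 = 7)), 7)
  # missing-gene policy: dropped under OR; AND of all-missing is NA
  expect_equal(evaluate_gpr(tree, c(g2 = 2, g3 = 9)), 2)
  expect_true(is.na(evaluate_gpr(tree, c(g9 = 1))))
  set.seed(42)
  genes <- paste0("g", 1:6)
  for (i in 1:300) {
    tr <- random_gpr(depth = sample(1:5, 1), genes = genes)
    vals <- stats::setNames(stats::rnorm(6), genes)
    if (i %% 3 == 0) vals[sample(6, 2)] <- NA
    expect_identical(evaluate_gpr(tr, vals), oracle_gpr(tr, vals))
  }
})

test_that("GPR evaluation is monotone in gene values", {
  set.seed(11)
  genes <- paste0("g", 1:5)
  for (i in 1:100) {
    tr <- random_gpr(depth = 3, genes = genes)
    vals <- stats::setNames(stats::runif(5), genes)
    v0 <- evaluate_gpr(tr, vals)
    g <- sample(genes, 1)
    vals2 <- vals
    vals2[g] <- vals[g] + stats::runif(1, 0, 2)
    expect_gte(evaluate_gpr(tr, vals2), v0)
  }
})

test_that("GPR parser flags malformed rules", {
  expect_error(parse_gpr("(g1 or g2"), "missing")
  expect_error(parse_gpr("g1 or"), "unexpected")
  expect_error(parse_gpr("g1 g2"), "trailing")
})

test_that("bidirectionality is defined by the bounds", {
  net <- metabolic_network("A", list(
    reaction("R1", c(A = 1), -1000, 1000),
    reaction("R2", c(A = -1), 0, 1000),
    reaction("R3", c(A = -1), -1000, 0)))
  expect_equal(unname(is_bidirectional(net)), c(TRUE, FALSE, FALSE))
})

test_that("FBA solves the chain, degenerate and branched cases", {
  f <- solve_fba(chain_net(10), "EX_B", "max")
  expect_equal(unname(f$flux), c(10, 10, 10), tolerance = 1e-8)
  zero <- metabolic_network("A", list(
    reaction("R1", c(A = 1), 0, 0), reaction("R2", c(A = -1), 0, 0)))
  fz <- solve_fba(zero, "R1", "max")
  expect_equal(unname(fz$flux), c(0, 0))
  expect_error(solve_fba(chain_net(), "nope", "max"), "not in model")
})

test_that("FBA optimum matches an independent LP solver on a branched
           network", {
  skip_if_not_installed("pracma")
  net <- branched_net()
  S <- stoichiometric_matrix(net)
  n <- length(net$rxn_id)
  ours <- solve_fba(net, "EX_C", "max")$objective_value
  # pracma::linprog solves max c'x, Ax <= b, x >= 0; shift x = v - lb and
  # encode S(v) = 0 as two inequalities, bounds as rows
  lb <- net$lb; ub <- net$ub
  A <- rbind(S, -S, diag(n))
  b <- c(as.numeric(-S %*% lb), as.numeric(S %*% lb), ub - lb)
  cc <- as.numeric(net$rxn_id == "EX_C")
  ref <- pracma::linprog(cc, A = A, b = b, maximize = TRUE)
  expect_equal(ours, ref$fval + sum(cc * lb), tolerance = 1e-6)
})

test_that("every FBA flux vector is mass balanced and within bounds", {
  for (seed in 1:5) {
    net <- random_small_net(seed)
    f <- solve_fba(net, "SNK", "max")$flux
    S <- stoichiometric_matrix(net)
    expect_lt(max(abs(S %*% f)), 1e-6)
    expect_true(all(f >= net$lb - 1e-8 & f <= net$ub + 1e-8))
  }
})
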