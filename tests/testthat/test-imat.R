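# iMAT MILP, activity fixing and ACHR sampling.

test_that("iMAT handles empty sets and conservation-forced chains", {
  net <- chain_net(10)
  s0 <- solve_imat(imat_problem(net, character(0), character(0)))
  expect_equal(s0$objective, 0L)
  s2 <- solve_imat(imat_problem(net, c("R1", "EX_B"), character(0)))
  expect_equal(s2$objective, 2L)
  expect_true(all(s2$satisfied))
  expect_true(all(abs(s2$flux[c("R1", "EX_B")]) >= 1 - 1e-8))
  # conflicting high and low on a conservation-locked pair: only one wins
  s1 <- solve_imat(imat_problem(net, "EX_A", "R1"))
  expect_equal(s1$objective, 1L)
})

test_that("problem construction validates its inputs", {
  net <- chain_net()
  expect_error(imat_problem(net, "R1", "R1"), "overlap")
  expect_error(imat_problem(net, "R1", character(0), epsilon = 1e-5,
                            delta = 1e-4), "delta < epsilon")
})

test_that("iMAT objective equals exhaustive enumeration on random small
           networks", {
  set.seed(5)
  for (i in 1:12) {
    net <- random_small_net(seed = 100 + i,
                            n_internal = sample(4:8, 1))
    con <- sample(net$rxn_id, sample(3:6, 1))
    hi <- con[seq_len(min(3, length(con) - 1))]
    lo <- setdiff(con, hi)
    sol <- solve_imat(imat_problem(net, hi, lo))
    expect_equal(sol$objective, oracle_imat(net, hi, lo),
                 info = paste("net", i))
  }
})

test_that("objective is invariant under reaction reordering and sign
           flips, and monotone in epsilon", {
  net <- random_small_net(7, n_internal = 6)
  hi <- c("R1", "R3"); lo <- c("R5")
  obj <- solve_imat(imat_problem(net, hi, lo))$objective
  # reorder reactions
  perm <- sample(seq_along(net$rxn_id))
  net2 <- net
  net2$rxn_id <- net$rxn_id[perm]
  net2$stoich <- net$stoich[perm]
  net2$lb <- net$lb[perm]; net2$ub <- net$ub[perm]
  net2$gpr <- net$gpr[perm]; net2$subsystem <- net$subsystem[perm]
  expect_equal(solve_imat(imat_problem(net2, hi, lo))$objective, obj)
  # flip a reversible reaction's sign convention
  net3 <- net
  r <- "R2"
  net3$stoich[[r]] <- -net3$stoich[[r]]
  old_lb <- net3$lb[r]
  net3$lb[r] <- -net3$ub[r]; net3$ub[r] <- -old_lb
  expect_equal(solve_imat(imat_problem(net3, hi, lo))$objective, obj)
  # larger epsilon can never satisfy more reactions
  obj_big <- solve_imat(imat_problem(net, hi, lo, epsilon = 5))$objective
  expect_lte(obj_big, obj)
})

test_that("fixing activity states tightens bounds as recorded and stays
           feasible", {
  net <- chain_net(10)
  pr <- imat_problem(net, c("R1", "EX_B"), "EX_A")
  sol <- solve_imat(pr)
  cnet <- fix_activity_states(pr, sol)
  for (r in c("R1", "EX_B")) if (isTRUE(sol$satisfied[r])) {
    if (sol$direction[[r]] == "forward") expect_gte(cnet$lb[r], 1)
    else expect_lte(cnet$ub[r], -1)
  }
  if (isTRUE(sol$satisfied["EX_A"])) {
    expect_gte(cnet$lb["EX_A"], -1e-4)
    expect_lte(cnet$ub["EX_A"], 1e-4)
  }
  expect_silent(solve_fba(cnet, "EX_B", "max"))
  # a satisfied reversible high reaction driven backwards
  net2 <- metabolic_network(c("A", "B"), list(
    reaction("EX_A", c(A = 1), -10, 0),      # must secrete A
    reaction("R1", c(A = -1, B = 1), -20, 20),
    reaction("EX_B", c(B = -1), -10, 0)))    # must take up B
  pr2 <- imat_problem(net2, "R1", character(0))
  sol2 <- solve_imat(pr2)
  expect_true(sol2$satisfied[["R1"]])
  expect_equal(sol2$direction[["R1"]], "backward")
  cnet2 <- fix_activity_states(pr2, sol2)
  expect_lte(cnet2$ub["R1"], -1)
})

test_that("ACHR samples are feasible, deterministic and span the
           polytope", {
  net <- chain_net(10)
  fs <- sample_fluxes(net, n_samples = 400, seed = 3, thin = 25)
  S <- stoichiometric_matrix(net)
  expect_lt(max(abs(S %*% fs$samples)), 1e-6)
  expect_true(all(fs$samples >= net$lb - 1e-9 &
                    fs$samples <= net$ub + 1e-9))
  # conservation forces all three fluxes equal in every sample
  expect_lt(max(abs(fs$samples["R1", ] - fs$samples["EX_A", ])), 1e-9)
  # span of the free uptake direction: compare with a uniform oracle
  expect_lt(min(fs$samples["EX_A", ]), 2)
  expect_gt(max(fs$samples["EX_A", ]), 8)
  fs2 <- sample_fluxes(net, n_samples = 400, seed = 3, thin = 25)
  expect_identical(fs$samples, fs2$samples)
  expect_equal(fs$mean_flux, rowMeans(fs$samples))
})

test_that("a point polytope yields constant samples and an empty one
           errors", {
  net <- metabolic_network(c("A", "B"), list(
    reaction("EX_A", c(A = 1), 5, 5),
    reaction("R1", c(A = -1, B = 1), 0, 1000),
    reaction("EX_B", c(B = -1), 0, 1000)))
  fs <- sample_fluxes(net, n_samples = 50, seed = 1, thin = 5)
  expect_true(all(abs(fs$samples - 5) < 1e-6))
  bad <- metabolic_network("A", list(
    reaction("EX_A", c(A = 1), 5, 5),
    reaction("SNK", c(A = -1), 0, 1)))
  expect_error(sample_fluxes(bad, n_samples = 10, seed = 1), "empty")
})

test_that("chain means from two seeds agree within three standard
           errors", {
  net <- chain_net(10)
  f1 <- sample_fluxes(net, n_samples = 1000, seed = 11, thin = 50)
  f2 <- sample_fluxes(net, n_samples = 1000, seed = 99, thin = 50)
  for (r in net$rxn_id) {
    se <- sqrt(batch_se(f1$samples[r, ])^2 + batch_se(f2$samples[r, ])^2)
    expect_lt(abs(f1$mean_flux[r] - f2$mean_flux[r]), 3 * se + 1e-9)
  }
})
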