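# Step 1-2 classifier: flux discretization, TR/TL assignment, Spearman
# screening for PTL.

ann4 <- data.frame(sample = paste0("s", 1:4), condition = "c1")

test_that("flux discretization ignores sign and handles degenerate
           input", {
  mf <- matrix(c(1:8, -9), 9, 1, dimnames = list(paste0("r", 1:9), "c1"))
  fs <- discretize_flux(mf)
  expect_equal(sum(fs == 1), 3)
  expect_equal(sum(fs == -1), 3)
  expect_equal(fs["r9", 1], 1L)   # |-9| is the largest magnitude
  zero <- matrix(0, 5, 1, dimnames = list(paste0("r", 1:5), "c1"))
  expect_true(all(discretize_flux(zero) == 0L))
})

test_that("TR assignment implements the 3-of-4 replicate rule", {
  fs <- matrix(1L, 2, 1, dimnames = list(c("rA", "rB"), "c1"))
  es <- rbind(rA = c(1L, 1L, 1L, 0L), rB = c(1L, 1L, 0L, 0L))
  colnames(es) <- ann4$sample
  tr <- assign_tr(fs, es, ann4)
  expect_true(tr$tr["rA", "c1"])
  expect_false(tr$tr["rB", "c1"])
  expect_equal(tr$subtype["rA", "c1"], "TR-high")
  expect_equal(tr$matches["rB", "c1"], 2L)
})

test_that("TR assignment is invariant to replicate order and matches a
           counting script", {
  set.seed(9)
  n <- 100
  fs <- matrix(sample(c(-1L, 0L, 1L), n, TRUE), n, 1,
               dimnames = list(paste0("r", 1:n), "c1"))
  es <- matrix(sample(c(-1L, 0L, 1L, NA), n * 4, TRUE), n, 4,
               dimnames = list(paste0("r", 1:n), ann4$sample))
  tr <- assign_tr(fs, es, ann4)
  want <- vapply(seq_len(n), function(i)
    sum(es[i, ] == fs[i, 1], na.rm = TRUE) >= 3, logical(1))
  expect_equal(unname(tr$tr[, 1]), want)
  perm <- sample(4)
  es2 <- es[, perm]
  ann_p <- data.frame(sample = colnames(es2), condition = "c1")
  expect_equal(assign_tr(fs, es2, ann_p)$tr, tr$tr)
})

test_that("TL assignment requires protein match, excludes TR, and sets
           the direction from the transcript disparity", {
  fs <- matrix(c(1L, -1L, 1L), 3, 1,
               dimnames = list(c("up", "down", "istr"), "c1"))
  ps <- rbind(up = c(1L, 1L, 1L, 1L), down = c(-1L, -1L, -1L, 0L),
              istr = c(1L, 1L, 1L, 1L))
  es <- rbind(up = c(0L, 0L, 0L, 0L), down = c(1L, 1L, 1L, 1L),
              istr = c(1L, 1L, 1L, 1L))
  colnames(ps) <- colnames(es) <- ann4$sample
  tr <- assign_tr(fs, es, ann4)
  expect_true(tr$tr["istr", 1])     # transcript matches -> TR
  tl <- assign_tl(fs, ps, es, ann4, tr$tr)
  expect_true(tl$tl["up", 1])
  expect_equal(tl$subtype["up", 1], "TL-up")
  expect_true(tl$tl["down", 1])
  expect_equal(tl$subtype["down", 1], "TL-down")
  expect_false(tl$tl["istr", 1])    # already TR, excluded
})

test_that("spearman_test matches examples and full enumeration at n = 6", {
  expect_equal(spearman_test(1:3, 1:3)$rho, 1)
  expect_equal(spearman_test(1:3, 3:1)$rho, -1)
  expect_true(is.na(spearman_test(1:5, rep(2, 5))$rho))
  set.seed(31)
  for (i in 1:60) {
    x <- sample(1:4, 6, replace = TRUE) + stats::rnorm(6, 0, 1e-3)
    y <- if (i %% 3 == 0) x + stats::rnorm(6, 0, 2) else stats::rnorm(6)
    got <- spearman_test(x, y)
    expect_equal(got$rho, stats::cor(x, y, method = "spearman"))
    expect_equal(got$p, oracle_spearman_p(x, y), tolerance = 1e-12)
  }
  # t approximation for larger n stays close to cor.test
  x <- stats::rnorm(30); y <- x + stats::rnorm(30)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(spearman_test(x, y)$p, ref$p.value, tolerance = 0.05)
})

test_that("PTL screening finds proportional sites and flags degenerate
           ones", {
  net <- metabolic_network("A", list(
    reaction("R1", c(A = 1), 0, 10, gpr = "gA"),
    reaction("R2", c(A = -1), 0, 10, gpr = "gB")))
  flux <- rbind(R1 = c(1, 2, 3, 4, 5, 6), R2 = c(2, 2, 2, 2, 2, 2))
  sites <- rbind(sA = c(2, 4, 6, 8, 10, 12), sB = rep(1, 6))
  map <- data.frame(site = c("sA", "sB"), gene = c("gA", "gB"))
  res <- assign_ptl(c("R1", "R2"), flux, sites, map, net)
  expect_true(res$ptl[res$reaction == "R1"])
  expect_equal(res$rho[res$reaction == "R1"], 1)
  expect_equal(res$direction[res$reaction == "R1"], "activating")
  # constant site series: rho undefined, flagged not PTL
  expect_false(res$ptl[res$reaction == "R2"])
  expect_true(is.na(res$rho[res$reaction == "R2"]))
  # inhibiting direction
  res2 <- assign_ptl("R1", flux, rbind(sA = c(12, 10, 8, 6, 4, 2)),
                     map[1, ], net)
  expect_equal(res2$direction, "inhibiting")
})

test_that("no reaction holds two direct labels in the same condition", {
  rep <- get_report(noise = 0.1)
  for (cc in rep$conditions) {
    both <- rep$tr$tr[, cc] & rep$tl$tl[, cc]
    expect_false(any(both))
    ptl_set <- rep$ptl$reaction[rep$ptl$ptl]
    expect_false(any(rep$tr$tr[ptl_set, cc]))
    expect_false(any(rep$tl$tl[ptl_set, cc]))
  }
})
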