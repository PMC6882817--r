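# Shared fixtures and independent brute-force oracles for the test suite.

## ---- tiny fixture networks ------------------------------------------------

# EX_A -> A -> B -> EX_B, uptake capped at 10
chain_net <- function(uptake = 10) {
  metabolic_network(c("A", "B"), list(
    reaction("EX_A", c(A = 1), 0, uptake),
    reaction("R1", c(A = -1, B = 1), 0, 1000, gpr = "g1"),
    reaction("EX_B", c(B = -1), 0, 1000, gpr = "g2")))
}

# two structurally disconnected chains with independent free fluxes
two_chain_net <- function() {
  metabolic_network(c("A", "B", "X", "Y"), list(
    reaction("EX_A", c(A = 1), 0, 10),
    reaction("R1", c(A = -1, B = 1), 0, 10),
    reaction("EX_B", c(B = -1), 0, 10),
    reaction("EX_X", c(X = 1), 0, 10),
    reaction("R2", c(X = -1, Y = 1), 0, 10),
    reaction("EX_Y", c(Y = -1), 0, 10)))
}

# branched network with a nontrivial LP optimum for the second-solver test
branched_net <- function() {
  metabolic_network(c("A", "B", "C"), list(
    reaction("EX_A", c(A = 1), 0, 10),
    reaction("R1", c(A = -1, B = 1), 0, 6),
    reaction("R2", c(A = -1, C = 1), 0, 8),
    reaction("R3", c(B = -1, C = 1), -5, 5),
    reaction("EX_B", c(B = -1), 0, 4),
    reaction("EX_C", c(C = -1), 0, 20)))
}

# random small network for the iMAT enumeration oracle: a source, a sink
# and random internal conversions, always feasible (v = 0 works)
random_small_net <- function(seed, n_mets = 4, n_internal = 6) {
  set.seed(seed)
  mets <- paste0("M", seq_len(n_mets))
  rxns <- list(reaction("SRC", stats::setNames(1, mets[1]), 0, 10),
               reaction("SNK", stats::setNames(-1, mets[n_mets]), 0, 10))
  for (i in seq_len(n_internal)) {
    from <- sample(n_mets - 1, 1)
    to <- sample((from + 1):n_mets, 1)
    st <- stats::setNames(c(-1, sample(1:2, 1)), c(mets[from], mets[to]))
    rev <- stats::runif(1) < 0.4
    rxns[[length(rxns) + 1]] <-
      reaction(paste0("R", i), st, if (rev) -10 else 0, 10)
  }
  metabolic_network(mets, rxns)
}

## ---- independent oracles --------------------------------------------------

# independent recursive GPR evaluator (Reduce-based, unlike the package's
# vapply form)
oracle_gpr <- function(tree, values) {
  if (is.null(tree)) return(NA_real_)
  if (tree$kind == "gene") {
    v <- values[tree$gene]
    return(if (length(v) == 0 || is.na(v)) NA_real_ else unname(v))
  }
  vals <- Filter(Negate(is.na),
                 lapply(tree$children, oracle_gpr, values = values))
  if (length(vals) == 0) return(NA_real_)
  Reduce(if (tree$kind == "and") min else max, unlist(vals))
}

random_gpr <- function(depth, genes) {
  if (depth == 0 || stats::runif(1) < 0.35)
    return(list(kind = "gene", gene = sample(genes, 1)))
  kind <- sample(c("and", "or"), 1)
  list(kind = kind,
       children = lapply(seq_len(sample(2:3, 1)), function(i)
         random_gpr(depth - 1, genes)))
}

# positional rank-and-slice tertile oracle with whole-tie-group demotion
oracle_tertile <- function(v) {
  v <- round(v, 8)
  n <- length(v); k <- ceiling(n / 3)
  ord <- order(v)
  cls <- integer(n)
  cls[ord[1:k]] <- -1L
  cls[ord[(n - k + 1):n]] <- 1L
  for (val in unique(v)) {
    idx <- which(v == val)
    if (length(unique(cls[idx])) > 1) cls[idx] <- 0L
  }
  cls
}

# exact permutation p for |Spearman rho| by full n! enumeration
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

.perm_cache <- new.env(parent = emptyenv())

oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  key <- as.character(n)
  if (is.null(.perm_cache[[key]])) .perm_cache[[key]] <- all_perms(n)
  P <- .perm_cache[[key]]
  zx <- rx - mean(rx); zy <- ry - mean(ry)
  denom <- sqrt(sum(zx^2) * sum(zy^2))
  obs <- abs(sum(zx * zy)) / denom
  rhos <- abs(matrix(zy[P], nrow(P)) %*% zx) / denom
  mean(rhos >= obs - 1e-12)
}

# upper-tail hypergeometric by direct summation of the pmf
oracle_hyper <- function(k, K, n_draw, N) {
  if (k == 0) return(1)
  i <- k:min(n_draw, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n_draw - i) - lchoose(N, n_draw)))
}

# literal per-index FDR filter, re-derived independently
oracle_fdr_literal <- function(p, alpha = 0.05) {
  n <- length(p)
  ord <- order(p)
  keep <- logical(n)
  for (i in seq_len(n)) keep[ord[i]] <- p[ord[i]] <= i / n * alpha
  sort(which(keep))
}

# iMAT optimum by exhaustive enumeration over satisfaction patterns
# (subsets of constrained reactions, with both directions tried for each
# satisfied high reaction), checking LP feasibility of each pattern
oracle_imat <- function(net, high, low, eps = 1, delta = 1e-4) {
  S <- stoichiometric_matrix(net)
  feasible <- function(lb, ub) {
    if (any(lb > ub)) return(FALSE)
    res <- fluxtier:::lp_solve(numeric(length(lb)), "max", A_eq = S,
                               b_eq = numeric(nrow(S)), lb = lb, ub = ub)
    res$status == "optimal"
  }
  con <- c(high, low)
  for (k in rev(seq_len(length(con)))) {
    for (cs in utils::combn(con, k, simplify = FALSE)) {
      hs <- intersect(cs, high); ls <- intersect(cs, low)
      dir_grid <- if (length(hs) > 0)
        expand.grid(rep(list(c(1, -1)), length(hs))) else
        data.frame(x = 1)[, 0, drop = FALSE]
      for (di in seq_len(max(1, nrow(dir_grid)))) {
        lb <- net$lb; ub <- net$ub
        for (j in seq_along(hs)) {
          if (ncol(dir_grid) > 0 && dir_grid[di, j] > 0)
            lb[hs[j]] <- max(lb[hs[j]], eps)
          else
            ub[hs[j]] <- min(ub[hs[j]], -eps)
        }
        for (r in ls) {
          lb[r] <- max(lb[r], -delta); ub[r] <- min(ub[r], delta)
        }
        if (feasible(lb, ub)) return(k)
      }
    }
  }
  0L
}

# batch-means standard error of a (thinned, near-independent) chain mean
batch_se <- function(x, n_batch = 10) {
  bm <- tapply(x, cut(seq_along(x), n_batch, labels = FALSE), mean)
  stats::sd(bm) / sqrt(n_batch)
}

## ---- cached expensive artifacts -------------------------------------------

.test_cache <- new.env(parent = emptyenv())

get_report <- function(noise = 0.1, seed = 7L) {
  key <- paste0("rep_", noise, "_", seed)
  if (is.null(.test_cache[[key]])) {
    cfg <- pipeline_config(sim = simulation_config(seed = 1L,
                                                   noise_sd = noise),
                           seed = seed)
    .test_cache[[key]] <- run_pipeline(cfg)
  }
  .test_cache[[key]]
}
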