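## iMAT: maximise the number of reactions whose flux activity agrees with
## their discretized omics state, fix the chosen activity pattern, and
## sample the resulting flux polytope with artificial-centering
## hit-and-run.

#' Define an iMAT problem
#'
#' @param net metabolic_network.
#' @param high_set reaction ids whose state calls for active flux
#'   (|v| >= epsilon).
#' @param low_set reaction ids whose state calls for inactivity
#'   (|v| <= delta).
#' @param epsilon activation threshold flux (model units); default 1.
#' @param delta inactivity tolerance; default 1e-4.
#' @return list of class "imat_problem".
#' @export
imat_problem <- function(net, high_set, low_set, epsilon = 1, delta = 1e-4) {
  high_set <- intersect(high_set, net$rxn_id)
  low_set <- intersect(low_set, net$rxn_id)
  if (length(intersect(high_set, low_set)) > 0)
    stop("imat_problem: high_set and low_set overlap")
  if (!(0 < delta && delta < epsilon))
    stop("imat_problem: need 0 < delta < epsilon")
  structure(list(net = net, high_set = high_set, low_set = low_set,
                 epsilon = epsilon, delta = delta),
            class = "imat_problem")
}

# Build the MILP matrices for an iMAT problem.  Variable layout:
# v (n fluxes), then per high reaction (y_forward, y_backward), then per
# low reaction z.  Indicator linearization:
#   forward : v_i + y_f (lb_i - eps) >= lb_i   (y_f = 1 -> v_i >= eps)
#   backward: v_i + y_b (ub_i + eps) <= ub_i   (y_b = 1 -> v_i <= -eps)
#   y_f + y_b <= 1
#   low     : v_j <= ub_j - z (ub_j - delta),  v_j >= lb_j - z (lb_j + delta)
imat_milp <- function(problem) {
  net <- problem$net
  n <- length(net$rxn_id)
  hi <- match(problem$high_set, net$rxn_id)
  lo <- match(problem$low_set, net$rxn_id)
  nh <- length(hi); nl <- length(lo)
  ntot <- n + 2 * nh + nl
  eps <- problem$epsilon; del <- problem$delta

  S <- stoichiometric_matrix(net)
  A_eq <- cbind(S, matrix(0, nrow(S), 2 * nh + nl))

  rows <- list(); rhs <- numeric(0)
  add <- function(r, b) { rows[[length(rows) + 1L]] <<- r; rhs[length(rhs) + 1L] <<- b }
  for (k in seq_along(hi)) {
    i <- hi[k]; yf <- n + 2 * k - 1; yb <- n + 2 * k
    r <- numeric(ntot); r[i] <- -1; r[yf] <- -(net$lb[i] - eps); add(r, -net$lb[i])
    r <- numeric(ntot); r[i] <- 1; r[yb] <- net$ub[i] + eps; add(r, net$ub[i])
    r <- numeric(ntot); r[yf] <- 1; r[yb] <- 1; add(r, 1)
  }
  for (k in seq_along(lo)) {
    j <- lo[k]; z <- n + 2 * nh + k
    r <- numeric(ntot); r[j] <- 1; r[z] <- net$ub[j] - del; add(r, net$ub[j])
    r <- numeric(ntot); r[j] <- -1; r[z] <- -(net$lb[j] + del); add(r, -net$lb[j])
  }
  A_ub <- if (length(rows) > 0) do.call(rbind, rows) else NULL

  obj <- c(numeric(n), rep(1, 2 * nh + nl))
  lb <- c(net$lb, rep(0, 2 * nh + nl))
  ub <- c(net$ub, rep(1, 2 * nh + nl))
  list(obj = obj, A_eq = A_eq, b_eq = numeric(nrow(A_eq)),
       A_ub = A_ub, b_ub = rhs, lb = lb, ub = ub,
       binary_idx = if (2 * nh + nl > 0) n + seq_len(2 * nh + nl) else integer(0),
       n = n, hi = hi, lo = lo)
}

#' Solve the iMAT mixed-integer program
#'
#' Maximises the count of high-state reactions carrying flux of at least
#' epsilon in some direction plus low-state reactions with |v| <= delta,
#' subject to mass balance and bounds.  Solved exactly by branch-and-bound
#' on the package's simplex.
#'
#' @param problem an \code{\link{imat_problem}}.
#' @return list of class "imat_solution": \code{objective} (integer),
#'   \code{satisfied} (named logical over constrained reactions),
#'   \code{direction} (named, "forward"/"backward" for satisfied high
#'   reactions), \code{flux} (named vector).
#' @export
solve_imat <- function(problem) {
  net <- problem$net
  mp <- imat_milp(problem)
  if (length(mp$binary_idx) == 0) {
    f <- lp_solve(mp$obj, "max", mp$A_eq, mp$b_eq, NULL, NULL, mp$lb, mp$ub)
    if (f$status != "optimal") stop("iMAT base model infeasible")
    return(structure(list(objective = 0L,
                          satisfied = stats::setNames(logical(0), character(0)),
                          direction = character(0),
                          flux = stats::setNames(f$v[seq_len(mp$n)], net$rxn_id),
                          problem = problem),
                     class = "imat_solution"))
  }
  res <- milp_solve(mp$obj, mp$A_eq, mp$b_eq, mp$A_ub, mp$b_ub,
                    mp$lb, mp$ub, mp$binary_idx)
  if (res$status != "optimal") {
    base <- lp_solve(numeric(length(mp$obj)), "max", mp$A_eq, mp$b_eq,
                     NULL, NULL, mp$lb, mp$ub)
    if (base$status != "optimal") stop("iMAT: base model infeasible")
    stop("iMAT: MILP solver failed (base model is feasible)")
  }
  v <- res$v
  n <- mp$n; nh <- length(mp$hi)
  sat <- logical(0); dir <- character(0)
  for (k in seq_along(mp$hi)) {
    id <- net$rxn_id[mp$hi[k]]
    yf <- v[n + 2 * k - 1] > 0.5; yb <- v[n + 2 * k] > 0.5
    sat[id] <- yf || yb
    if (yf) dir[id] <- "forward" else if (yb) dir[id] <- "backward"
  }
  for (k in seq_along(mp$lo)) {
    id <- net$rxn_id[mp$lo[k]]
    sat[id] <- v[n + 2 * nh + k] > 0.5
  }
  structure(list(objective = as.integer(round(res$obj)),
                 satisfied = sat, direction = dir,
                 flux = stats::setNames(v[seq_len(n)], net$rxn_id),
                 problem = problem),
            class = "imat_solution")
}

#' Fix the activity pattern of an iMAT optimum into network bounds
#'
#' Satisfied high reactions are constrained to carry at least epsilon flux
#' in the direction the optimum chose; satisfied low reactions are pinned
#' to [-delta, delta]; unsatisfied constrained reactions keep their
#' original bounds.  The result is a convex flux polytope suitable for
#' sampling.
#'
#' @param problem the \code{\link{imat_problem}} that was solved.
#' @param solution the corresponding \code{\link{solve_imat}} result.
#' @return a metabolic_network with tightened bounds.
#' @export
fix_activity_states <- function(problem, solution) {
  net <- problem$net
  eps <- problem$epsilon; del <- problem$delta
  for (id in problem$high_set) {
    if (!isTRUE(solution$satisfied[id])) next
    if (identical(solution$direction[[id]], "forward")) {
      net$lb[id] <- max(net$lb[id], eps)
    } else {
      net$ub[id] <- min(net$ub[id], -eps)
    }
  }
  for (id in problem$low_set) {
    if (!isTRUE(solution$satisfied[id])) next
    net$lb[id] <- max(net$lb[id], -del)
    net$ub[id] <- min(net$ub[id], del)
  }
  net
}

#' Sample feasible flux vectors with artificial-centering hit-and-run
#'
#' Warmup points are the FBA maxima and minima of every reaction (2n
#' points); the chain runs in an orthonormal null-space basis of S so
#' every retained sample satisfies mass balance to machine precision.
#'
#' @param net metabolic_network (typically state-fixed).
#' @param n_samples number of retained samples; default 2000.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param thin chain steps between retained samples; default 100.
#' @return list of class "flux_sample_set": \code{samples} (reactions x
#'   n_samples matrix), \code{mean_flux} (named vector), \code{seed},
#'   \code{condition}.
#' @export
sample_fluxes <- function(net, n_samples = 2000, seed, thin = 100,
                          condition = NA_character_) {
  if (missing(seed)) stop("sample_fluxes: seed is required")
  S <- stoichiometric_matrix(net)
  n <- length(net$rxn_id)

  # warmup: max/min each reaction
  warm <- matrix(NA_real_, n, 2 * n)
  for (j in seq_len(n)) {
    for (s in c("max", "min")) {
      res <- lp_solve(as.numeric(seq_len(n) == j), s, A_eq = S,
                      b_eq = numeric(nrow(S)), lb = net$lb, ub = net$ub)
      if (res$status != "optimal")
        stop("sample_fluxes: flux polytope is empty (", res$status, ")")
      warm[, 2 * j - (s == "max")] <- res$v
    }
  }
  v0 <- rowMeans(warm)

  sv <- svd(S, nu = 0, nv = n)
  rank <- sum(sv$d > 1e-9 * max(sv$d, 1))
  N <- if (rank < n) sv$v[, (rank + 1):n, drop = FALSE] else
    matrix(0, n, 0)

  if (ncol(N) == 0 || max(apply(warm, 1, function(r) diff(range(r)))) < 1e-9) {
    samples <- matrix(v0, n, n_samples)
  } else {
    warm_u <- crossprod(N, warm - v0)
    set.seed(seed)
    samples <- achr_sample_cpp(N, v0, net$lb, net$ub, warm_u,
                               as.integer(n_samples), as.integer(thin))
  }
  rownames(samples) <- net$rxn_id
  structure(list(samples = samples,
                 mean_flux = stats::setNames(rowMeans(samples), net$rxn_id),
                 seed = seed, thin = thin, condition = condition),
            class = "flux_sample_set")
}
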