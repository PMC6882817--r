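#' @useDynLib fluxtier, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Solve a bounded linear program
#'
#' Minimises or maximises \code{obj'v} subject to \code{A_eq v = b_eq},
#' \code{A_ub v <= b_ub} and \code{lb <= v <= ub}.  All bounds must be
#' finite (network loading clamps infinite bounds).  The problem is shifted
#' to standard form and handed to the package's dense two-phase simplex.
#'
#' @param obj numeric objective coefficients, length n.
#' @param sense \code{"max"} or \code{"min"}.
#' @param A_eq,b_eq equality constraints (matrix may have 0 rows).
#' @param A_ub,b_ub inequality constraints \code{A_ub v <= b_ub} (optional).
#' @param lb,ub finite variable bounds.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}, \code{"maxiter"}), \code{v}, \code{obj}.
#' @keywords internal
lp_solve <- function(obj, sense = c("max", "min"), A_eq = NULL, b_eq = NULL,
                     A_ub = NULL, b_ub = NULL, lb, ub) {
  sense <- match.arg(sense)
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite bounds")
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible"))

  if (is.null(A_eq)) A_eq <- matrix(0, 0, n)
  if (is.null(A_ub)) A_ub <- matrix(0, 0, n)
  A_eq <- as.matrix(A_eq); A_ub <- as.matrix(A_ub)
  if (is.null(b_eq)) b_eq <- numeric(0)
  if (is.null(b_ub)) b_ub <- numeric(0)

  # shift x = v - lb so x >= 0
  rng <- ub - lb
  b_eq2 <- b_eq - as.numeric(A_eq %*% lb)
  b_ub2 <- b_ub - as.numeric(A_ub %*% lb)

  m_eq <- nrow(A_eq); m_ub <- nrow(A_ub)
  # slack columns: one per inequality row, one per finite upper-bound row
  ub_rows <- which(rng < 1e12) # all, in practice
  n_sl <- m_ub + length(ub_rows)
  ncol_tot <- n + n_sl
  A <- matrix(0, m_eq + m_ub + length(ub_rows), ncol_tot)
  b <- numeric(nrow(A))
  if (m_eq > 0) { A[seq_len(m_eq), seq_len(n)] <- A_eq; b[seq_len(m_eq)] <- b_eq2 }
  if (m_ub > 0) {
    r <- m_eq + seq_len(m_ub)
    A[r, seq_len(n)] <- A_ub
    A[cbind(r, n + seq_len(m_ub))] <- 1
    b[r] <- b_ub2
  }
  if (length(ub_rows) > 0) {
    r <- m_eq + m_ub + seq_along(ub_rows)
    A[cbind(r, ub_rows)] <- 1
    A[cbind(r, n + m_ub + seq_along(ub_rows))] <- 1
    b[r] <- rng[ub_rows]
  }

  cc <- c(if (sense == "max") -obj else obj, numeric(n_sl))
  res <- lp_simplex_cpp(A, b, cc)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "3" = "maxiter")
  if (status != "optimal") return(list(status = status))
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", v = v,
       obj = sum(obj * v))
}

#' Branch-and-bound over binary variables
#'
#' Maximises \code{obj'v} over the mixed-binary polytope.  Depth-first
#' branch-and-bound on the LP relaxation; branching on the most fractional
#' binary.  When \code{integral_objective} is TRUE the bound is floored,
#' which prunes aggressively for cardinality objectives such as iMAT's.
#'
#' @param binary_idx indices of variables constrained to \{0,1\}.
#' @keywords internal
milp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                       lb, ub, binary_idx, integral_objective = TRUE,
                       max_nodes = 100000L) {
  tol <- 1e-6
  best <- list(obj = -Inf, v = NULL)
  # stack of nodes: each is list(lb, ub)
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  while (length(stack) > 0) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > max_nodes) stop("milp_solve: node limit exceeded")
    rel <- lp_solve(obj, "max", A_eq, b_eq, A_ub, b_ub, nd$lb, nd$ub)
    if (rel$status != "optimal") next
    bound <- rel$obj
    if (integral_objective) bound <- floor(bound + 1e-6)
    if (bound <= best$obj + 1e-9) next
    frac <- abs(rel$v[binary_idx] - round(rel$v[binary_idx]))
    if (all(frac < tol)) {
      if (rel$obj > best$obj + 1e-9) best <- list(obj = rel$obj, v = rel$v)
      next
    }
    j <- binary_idx[which.max(frac)]
    lo <- nd; lo$ub[j] <- 0
    hi <- nd; hi$lb[j] <- 1
    # explore the rounded-up branch first (tends to find incumbents early)
    stack[[length(stack) + 1L]] <- lo
    stack[[length(stack) + 1L]] <- hi
  }
  if (!is.finite(best$obj)) return(list(status = "infeasible"))
  list(status = "optimal", v = best$v, obj = best$obj, nodes = nodes)
}
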