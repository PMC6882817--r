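## Step 4: stoichiometric coupling from flux samples.  Coupling between
## two reactions is the absolute Spearman correlation of their fluxes
## across the sampled feasible flux distributions.

#' Pairwise stoichiometric coupling matrix
#'
#' @param fs a \code{\link{sample_fluxes}} result (>= 100 samples).
#' @return list of class "coupling_matrix": \code{matrix} (n x n absolute
#'   Spearman correlations; NA where a reaction's sampled flux is
#'   constant), \code{undefined} (logical per reaction), \code{n_samples},
#'   \code{condition}.
#' @export
pairwise_coupling <- function(fs) {
  samples <- fs$samples
  if (ncol(samples) < 100)
    stop("pairwise_coupling: need at least 100 samples")
  const <- apply(samples, 1, function(x) max(x) - min(x) < 1e-12)
  cm <- matrix(NA_real_, nrow(samples), nrow(samples),
               dimnames = list(rownames(samples), rownames(samples)))
  if (any(!const)) {
    sub <- abs(stats::cor(t(samples[!const, , drop = FALSE]),
                          method = "spearman"))
    cm[!const, !const] <- sub
  }
  diag(cm)[!const] <- 1
  structure(list(matrix = cm, undefined = const,
                 n_samples = ncol(samples), condition = fs$condition),
            class = "coupling_matrix")
}

#' Compare between-group and within-group coupling
#'
#' Tests whether the couplings from group A to group B are stochastically
#' larger than the couplings among group A itself, with a one-sided
#' Wilcoxon rank-sum test (exact below 50 values per side, normal
#' approximation with tie correction otherwise).  Undefined couplings are
#' excluded and counted.
#'
#' @param cm a \code{\link{pairwise_coupling}} result.
#' @param group_a,group_b disjoint reaction sets, each >= 2 reactions.
#' @return list: statistic, p (one-sided, alternative A-to-B greater),
#'   n_ab, n_aa, excluded.
#' @export
compare_coupling <- function(cm, group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("compare_coupling: both groups need at least 2 reactions")
  if (length(intersect(group_a, group_b)) > 0)
    stop("compare_coupling: groups must be disjoint")
  m <- cm$matrix
  ab <- as.vector(m[group_a, group_b])
  aa_m <- m[group_a, group_a]
  aa <- aa_m[upper.tri(aa_m)]
  excluded <- sum(is.na(ab)) + sum(is.na(aa))
  ab <- ab[!is.na(ab)]; aa <- aa[!is.na(aa)]
  if (length(ab) < 1 || length(aa) < 1)
    stop("compare_coupling: no defined couplings to compare")
  exact <- length(ab) < 50 && length(aa) < 50
  wt <- stats::wilcox.test(ab, aa, alternative = "greater", exact = exact)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_ab = length(ab), n_aa = length(aa), excluded = excluded)
}

#' Bidirectional-reaction enrichment of a reaction group
#'
#' Hypergeometric upper-tail test for the count of bidirectional
#' reactions in the group against the model-wide totals.
#'
#' @param group reaction ids (subset of the model, nonempty).
#' @param net metabolic_network.
#' @return list: overlap, group_size, n_bidirectional, n_reactions, p.
#' @export
bidirectional_enrichment <- function(group, net) {
  if (length(group) == 0) stop("bidirectional_enrichment: empty group")
  if (!all(group %in% net$rxn_id))
    stop("bidirectional_enrichment: group contains unknown reactions")
  bid <- is_bidirectional(net)
  k <- sum(bid[group])
  list(overlap = k, group_size = length(group),
       n_bidirectional = sum(bid), n_reactions = length(bid),
       p = hypergeometric_test(k, sum(bid), length(group), length(bid)))
}

#' Planted-coupling structure experiment
#'
#' Tests the step-4 claim on planted ground truth: one member of every
#' pathway chain is left without an activity constraint (the planted
#' indirect reaction) while its chain-mates are constrained to the
#' condition's intended activity profile; flux sampling then measures
#' whether the unconstrained reactions' couplings to the constrained
#' drivers stochastically exceed their couplings among themselves
#' (one-sided rank-sum, pooled across conditions).
#'
#' @param config a \code{\link{simulation_config}}.
#' @param seed RNG seed for the sampler chains.
#' @return list: \code{per_condition} (compare_coupling results),
#'   \code{pooled} (p, median_ab, median_aa, n_ab, n_aa),
#'   \code{indirect}, \code{drivers} (per condition).
#' @export
coupling_structure_experiment <- function(config = simulation_config(),
                                          seed = 1L) {
  net <- build_toy_network(config)
  profiles <- intended_profiles(config$n_conditions)
  chains <- pathway_chains(net)
  reserved <- unlist(lapply(chains, function(g) reserve_member(net, g)))
  has_gpr <- !vapply(net$gpr, is.null, logical(1))
  internal <- setdiff(net$rxn_id, exchange_reactions(net))
  per_condition <- list()
  ab_all <- aa_all <- numeric(0)
  drivers <- list()
  for (ci in seq_len(config$n_conditions)) {
    lv <- profiles[[ci]]
    st <- ifelse(has_gpr, as.integer(lv[net$subsystem]), 0L)
    st[is.na(st)] <- 0L
    names(st) <- net$rxn_id
    st[reserved] <- 0L
    pr <- imat_problem(net, net$rxn_id[st == 1L], net$rxn_id[st == -1L],
                       epsilon = config$epsilon, delta = config$delta)
    sol <- solve_imat(pr)
    cnet <- fix_activity_states(pr, sol)
    fs <- sample_fluxes(cnet, n_samples = config$n_samples,
                        seed = sub_seed(seed, 30L + ci),
                        thin = config$thin,
                        condition = sprintf("c%d", ci))
    cm <- pairwise_coupling(fs)
    drv <- setdiff(internal[has_gpr[internal] & st[internal] != 0L],
                   reserved)
    drivers[[ci]] <- drv
    per_condition[[ci]] <- compare_coupling(cm, reserved, drv)
    m <- cm$matrix
    # "IR to its drivers": each reserved reaction against the direct
    # drivers of its own pathway chain (the reactions that drive it)
    ab <- unlist(lapply(chains, function(g) {
      a <- intersect(g, reserved); b <- intersect(g, drv)
      if (length(a) == 0 || length(b) == 0) return(numeric(0))
      as.vector(m[a, b, drop = FALSE])
    }))
    aam <- m[reserved, reserved]
    aa <- aam[upper.tri(aam)]
    ab_all <- c(ab_all, ab[!is.na(ab)])
    aa_all <- c(aa_all, aa[!is.na(aa)])
  }
  wt <- stats::wilcox.test(ab_all, aa_all, alternative = "greater",
                           exact = FALSE)
  list(per_condition = per_condition,
       pooled = list(p = wt$p.value,
                     median_ab = stats::median(ab_all),
                     median_aa = stats::median(aa_all),
                     n_ab = length(ab_all), n_aa = length(aa_all)),
       indirect = reserved, drivers = drivers)
}
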