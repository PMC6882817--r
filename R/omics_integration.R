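## Discretization of omics layers to three activity levels, merging of
## transcript and protein evidence, and GPR mapping of gene states to
## reaction states.  Discrete states are integer matrices (entities x
## samples) with values -1/0/+1; NA encodes "unconstrained".

#' Tertile discretization of a measurement vector
#'
#' Splits values into low (-1), moderate (0) and high (+1) thirds.  Ranks
#' use average ties and the split points are at positions ceiling(n/3) and
#' n - ceiling(n/3); a tie group straddling either boundary is assigned
#' wholly to the moderate class, so rank order among equal values never
#' decides a call.
#'
#' @param values numeric vector, length >= 3, all finite.
#' @return integer vector in \{-1, 0, 1\}, same length and names.
#' @export
tertile_discretize <- function(values) {
  n <- length(values)
  if (n < 3) stop("tertile_discretize needs at least 3 values")
  if (any(!is.finite(values))) stop("tertile_discretize: non-finite values")
  out <- integer(n)
  # values equal to within 1e-8 count as tied (conservation-locked fluxes
  # are equal only to machine precision)
  v <- round(values, 8)
  s <- sort(v)
  k <- ceiling(n / 3)
  low_cut <- s[k]
  if (s[k + 1] == low_cut) {          # tie straddles the lower boundary
    out[v < low_cut] <- -1L
  } else {
    out[v <= low_cut] <- -1L
  }
  high_cut <- s[n - k + 1]
  if (s[n - k] == high_cut) {         # tie straddles the upper boundary
    out[v > high_cut] <- 1L
  } else {
    out[v >= high_cut] <- 1L
  }
  names(out) <- names(values)
  out
}

#' Discretize an omics matrix per sample
#'
#' Applies \code{\link{tertile_discretize}} down each column (each sample's
#' measurement set), the orientation in which "top third" statements about
#' expression are made.
#'
#' @param mat numeric matrix, entities x samples.
#' @return integer matrix of the same shape with values -1/0/+1.
#' @export
discretize_matrix <- function(mat) {
  out <- apply(mat, 2, tertile_discretize)
  dimnames(out) <- dimnames(mat)
  storage.mode(out) <- "integer"
  out
}

#' Merge transcript- and protein-level discrete states
#'
#' Protein evidence wins where measured, except on hard disagreement
#' (transcript +1 vs protein -1, or the reverse), which leaves the gene
#' unconstrained (NA) so the downstream flux prediction is not forced
#' either way.  Genes without protein coverage keep the transcript state.
#'
#' @param expr_state integer matrix, genes x samples, values -1/0/+1.
#' @param prot_state integer matrix over a subset of the same genes, same
#'   sample columns.
#' @return integer matrix over the expr_state genes with NA for
#'   unconstrained entries.
#' @export
merge_layers <- function(expr_state, prot_state) {
  if (!identical(colnames(expr_state), colnames(prot_state)))
    stop("merge_layers: sample columns differ between layers")
  out <- expr_state
  common <- intersect(rownames(prot_state), rownames(expr_state))
  for (g in common) {
    e <- expr_state[g, ]; p <- prot_state[g, ]
    merged <- p
    clash <- (e == 1L & p == -1L) | (e == -1L & p == 1L)
    merged[clash] <- NA_integer_
    out[g, ] <- merged
  }
  out
}

# Evaluate a GPR over discrete gene states with interval semantics for
# unconstrained (NA) genes: evaluate once with NA pushed to -1 and once
# pushed to +1; if the two results differ the reaction is unconstrained.
# Genes missing from the state vector entirely follow the evaluate_gpr
# unmeasured-gene policy.
evaluate_gpr_discrete <- function(tree, states) {
  if (is.null(tree)) return(NA_integer_)
  g_lo <- states; g_lo[is.na(g_lo)] <- -1
  g_hi <- states; g_hi[is.na(g_hi)] <- 1
  # genes absent from `states` are handled inside evaluate_gpr (dropped)
  r_lo <- evaluate_gpr(tree, g_lo)
  r_hi <- evaluate_gpr(tree, g_hi)
  if (is.na(r_lo) || is.na(r_hi)) return(NA_integer_)
  if (r_lo != r_hi) return(NA_integer_)
  as.integer(r_lo)
}

#' Map gene states to reaction states through GPR rules
#'
#' Per sample, each reaction's state is the min/max evaluation of its GPR
#' over the gene states, with unconstrained genes propagated by interval
#' semantics (see \code{evaluate_gpr_discrete}).  Reactions without a GPR
#' are unconstrained.
#'
#' @param net metabolic_network.
#' @param gene_state integer matrix, genes x samples, values -1/0/+1/NA.
#' @return integer matrix, reactions x samples, values -1/0/+1/NA.
#' @export
map_to_reactions <- function(net, gene_state) {
  samples <- colnames(gene_state)
  out <- matrix(NA_integer_, length(net$rxn_id), ncol(gene_state),
                dimnames = list(net$rxn_id, samples))
  for (j in seq_len(ncol(gene_state))) {
    st <- stats::setNames(gene_state[, j], rownames(gene_state))
    for (r in net$rxn_id) {
      tree <- net$gpr[[r]]
      if (!is.null(tree)) out[r, j] <- evaluate_gpr_discrete(tree, st)
    }
  }
  out
}

#' Write a reaction-state matrix as TSV
#' @param state integer matrix reactions x samples.
#' @param path output path.
#' @export
write_state_tsv <- function(state, path) {
  utils::write.table(data.frame(reaction = rownames(state), state,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
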