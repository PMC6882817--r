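## Shared statistics: hypergeometric enrichment and the FDR filter
## (literal per-index rule by default, standard step-up as an option).

#' Hypergeometric upper-tail test
#'
#' P(X >= k) for X hypergeometric: draw \code{n_draw} from a population
#' of \code{N} containing \code{K} successes.
#'
#' @param k observed overlap.
#' @param K category size in the population.
#' @param n_draw drawn set size.
#' @param N population size.
#' @return upper-tail p-value in (0, 1].
#' @export
hypergeometric_test <- function(k, K, n_draw, N) {
  stopifnot(0 <= k, k <= min(n_draw, K), max(n_draw, K) <= N)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
}

#' False-discovery-rate filter
#'
#' The default \code{"literal"} rule sorts the p-values ascending and
#' keeps each p_i with p_i <= (i/n) * alpha at its own index — a
#' per-index filter.  \code{"step-up"} is the standard Benjamini-Hochberg
#' rule: keep all i up to the largest i with p_i <= (i/n) * alpha.  The
#' literal rule's kept set is always a subset of the step-up set.
#'
#' @param p_values numeric vector in [0, 1].
#' @param alpha FDR level; default 0.05.
#' @param method "literal" (default) or "step-up".
#' @return integer indices (into the original vector) of kept p-values.
#' @export
fdr_filter <- function(p_values, alpha = 0.05,
                       method = c("literal", "step-up")) {
  method <- match.arg(method)
  stopifnot(all(p_values >= 0 & p_values <= 1))
  n <- length(p_values)
  if (n == 0) return(integer(0))
  ord <- order(p_values)
  ps <- p_values[ord]
  thresh <- seq_len(n) / n * alpha
  if (method == "literal") {
    keep <- ps <= thresh
  } else {
    last <- suppressWarnings(max(which(ps <= thresh)))
    keep <- seq_len(n) <= (if (is.finite(last)) last else 0)
  }
  sort(ord[keep])
}

#' Pathway enrichment of a reaction set
#'
#' One hypergeometric test per pathway over the reaction universe, with
#' the FDR filter applied across pathways.
#'
#' @param label_set reaction ids (subset of universe, nonempty).
#' @param subsystems named character vector, reaction -> pathway.
#' @param universe all model reaction ids.
#' @param alpha FDR level; default 0.05.
#' @param method FDR method, see \code{\link{fdr_filter}}.
#' @return data.frame: pathway, overlap k, group size, category size K,
#'   population N, p_value, fdr_pass.
#' @export
pathway_enrichment <- function(label_set, subsystems, universe,
                               alpha = 0.05, method = "literal") {
  if (length(label_set) == 0) stop("pathway_enrichment: empty label set")
  if (!all(label_set %in% universe))
    stop("pathway_enrichment: label_set outside universe")
  pws <- sort(unique(subsystems[universe]))
  res <- do.call(rbind, lapply(pws, function(pw) {
    members <- universe[subsystems[universe] == pw]
    k <- length(intersect(label_set, members))
    data.frame(pathway = pw, k = k, n_draw = length(label_set),
               K = length(members), N = length(universe),
               p_value = hypergeometric_test(k, length(members),
                                             length(label_set),
                                             length(universe)))
  }))
  res$fdr_pass <- FALSE
  res$fdr_pass[fdr_filter(res$p_value, alpha, method)] <- TRUE
  rownames(res) <- NULL
  res
}

#' Generic annotation enrichment of a gene set
#'
#' Hypergeometric test per annotation term over the gene universe, plus
#' an aggregate test (genes carrying at least one term versus genes
#' carrying none) mirroring promoter-binding-style analyses.
#'
#' @param gene_set gene ids (subset of universe).
#' @param annotation data.frame with columns \code{gene}, \code{term}.
#' @param universe all gene ids.
#' @param alpha FDR level applied across terms.
#' @param method FDR method.
#' @return list: \code{per_term} data.frame (term, k, n_draw, K, N,
#'   p_value, fdr_pass), \code{aggregate} (k, K, p_value).
#' @export
annotation_enrichment <- function(gene_set, annotation, universe,
                                  alpha = 0.05, method = "literal") {
  stopifnot(all(c("gene", "term") %in% colnames(annotation)))
  if (!all(gene_set %in% universe))
    stop("annotation_enrichment: gene_set outside universe")
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  terms <- sort(unique(ann$term))
  per_term <- do.call(rbind, lapply(terms, function(tm) {
    members <- unique(ann$gene[ann$term == tm])
    k <- length(intersect(gene_set, members))
    data.frame(term = tm, k = k, n_draw = length(gene_set),
               K = length(members), N = length(universe),
               p_value = hypergeometric_test(k, length(members),
                                             length(gene_set),
                                             length(universe)))
  }))
  if (is.null(per_term)) {
    per_term <- data.frame(term = character(0), k = integer(0),
                           n_draw = integer(0), K = integer(0),
                           N = integer(0), p_value = numeric(0),
                           fdr_pass = logical(0))
  } else {
    per_term$fdr_pass <- FALSE
    per_term$fdr_pass[fdr_filter(per_term$p_value, alpha, method)] <- TRUE
    rownames(per_term) <- NULL
  }
  annotated <- unique(ann$gene)
  k_agg <- length(intersect(gene_set, annotated))
  list(per_term = per_term,
       aggregate = list(k = k_agg, K = length(annotated),
                        p_value = hypergeometric_test(
                          k_agg, length(annotated), length(gene_set),
                          length(universe))))
}
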