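## Step 1-2 of the tiered-regulation analysis: assign TR, TL and PTL
## labels by comparing discretized predicted flux activity to discretized
## omics across replicates, and screen phosphosites by rank correlation.

#' Discretize predicted mean fluxes into activity classes
#'
#' Tertiles of |mean flux| across reactions, per condition: the most
#' active third is +1, the least active third -1 (sign of the flux is
#' ignored so reversible reactions running backwards count as active).
#'
#' @param mean_flux numeric matrix, reactions x conditions.
#' @return integer matrix of the same shape with values -1/0/+1.
#' @export
discretize_flux <- function(mean_flux) {
  out <- apply(abs(mean_flux), 2, tertile_discretize)
  dimnames(out) <- dimnames(mean_flux)
  storage.mode(out) <- "integer"
  out
}

# majority discrete state of a reaction across a condition's samples
# (ties resolve towards moderate)
majority_state <- function(states) {
  states <- states[!is.na(states)]
  if (length(states) == 0) return(NA_integer_)
  tab <- table(factor(states, levels = c(-1, 0, 1)))
  winners <- as.integer(names(tab)[tab == max(tab)])
  if (length(winners) == 1) winners else 0L
}

#' Identify transcriptionally regulated (TR) reactions
#'
#' A reaction is TR in a condition when its flux activity class equals
#' its transcript-derived reaction state in at least
#' \code{ceiling(min_frac * k)} of the condition's k replicate samples
#' (3 of 4 in the default 2 timepoints x 2 replicates design).  The TR
#' subtype is the flux class itself (TR-high / TR-moderate / TR-low).
#'
#' @param flux_state integer matrix, reactions x conditions (from
#'   \code{\link{discretize_flux}}).
#' @param expr_state integer matrix, reactions x samples: transcript-
#'   derived reaction states.
#' @param samples sample annotation with columns \code{sample},
#'   \code{condition}.
#' @param min_frac fraction of replicates that must match; default 0.75.
#' @return list with \code{tr} (logical reactions x conditions),
#'   \code{matches} (integer counts), \code{subtype} (character matrix,
#'   NA where not TR).
#' @export
assign_tr <- function(flux_state, expr_state, samples, min_frac = 0.75) {
  conds <- colnames(flux_state)
  rxns <- rownames(flux_state)
  matches <- matrix(0L, length(rxns), length(conds),
                    dimnames = list(rxns, conds))
  need <- integer(length(conds))
  for (ci in seq_along(conds)) {
    smp <- samples$sample[samples$condition == conds[ci]]
    need[ci] <- ceiling(min_frac * length(smp))
    st <- expr_state[rxns, smp, drop = FALSE]
    matches[, ci] <- rowSums(st == flux_state[, ci], na.rm = TRUE)
  }
  tr <- sweep(matches, 2, need, `>=`)
  subtype <- matrix(NA_character_, length(rxns), length(conds),
                    dimnames = list(rxns, conds))
  subtype[tr] <- c("TR-low", "TR-moderate", "TR-high")[flux_state[tr] + 2L]
  list(tr = tr, matches = matches, subtype = subtype, min_matches = need)
}

#' Identify translationally regulated (TL) reactions
#'
#' Among reactions not already TR in a condition, a reaction is TL when
#' its flux class matches its protein-derived reaction state in at least
#' \code{ceiling(min_frac * k)} of the k replicates.  TL-up means the
#' flux/protein class exceeds the transcript class (the transcript
#' under-states the activity), TL-down the reverse.
#'
#' @param flux_state integer matrix, reactions x conditions.
#' @param prot_state integer matrix, reactions x samples: protein-derived
#'   reaction states (NA where no protein coverage resolves the GPR).
#' @param expr_state transcript-derived reaction states (for the subtype).
#' @param samples sample annotation.
#' @param tr logical matrix from \code{\link{assign_tr}}.
#' @param min_frac fraction of replicates that must match; default 0.75.
#' @return list with \code{tl} (logical), \code{matches},
#'   \code{subtype} ("TL-up"/"TL-down"/NA).
#' @export
assign_tl <- function(flux_state, prot_state, expr_state, samples, tr,
                      min_frac = 0.75) {
  conds <- colnames(flux_state)
  rxns <- rownames(flux_state)
  matches <- matrix(0L, length(rxns), length(conds),
                    dimnames = list(rxns, conds))
  covered <- matrix(FALSE, length(rxns), length(conds),
                    dimnames = list(rxns, conds))
  subtype <- matrix(NA_character_, length(rxns), length(conds),
                    dimnames = list(rxns, conds))
  tl <- covered
  for (ci in seq_along(conds)) {
    smp <- samples$sample[samples$condition == conds[ci]]
    need <- ceiling(min_frac * length(smp))
    st <- prot_state[rxns, smp, drop = FALSE]
    covered[, ci] <- rowSums(!is.na(st)) > 0
    matches[, ci] <- rowSums(st == flux_state[, ci], na.rm = TRUE)
    tl[, ci] <- covered[, ci] & !tr[, ci] & matches[, ci] >= need
    if (any(tl[, ci])) {
      e_cl <- apply(expr_state[rxns, smp, drop = FALSE], 1, majority_state)
      for (r in which(tl[, ci])) {
        d <- flux_state[r, ci] - e_cl[r]
        subtype[r, ci] <- if (is.na(d) || d == 0) NA_character_
                          else if (d > 0) "TL-up" else "TL-down"
      }
      # a TL call with no transcript disparity carries no direction;
      # it stays TL with subtype NA
    }
  }
  list(tl = tl, matches = matches, subtype = subtype, covered = covered)
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' rho uses average ranks for ties.  For n <= 9 the two-sided p-value is
#' exact, by enumeration over all distinct permutations of the y-ranks;
#' for larger n the usual t approximation is used.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{rho}, \code{p}, \code{n}.  A constant series
#'   gives rho = NA, p = NA.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (n <= 9) {
    spearman_perm_p_cpp(rx, ry)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Identify post-translationally regulated (PTL) reactions
#'
#' Among reactions not already TR or TL, a reaction with at least one
#' mapped phosphosite is PTL when some site's phosphorylation series has
#' |rho| > rho_cutoff and p < p_cutoff against the predicted flux series
#' across the condition x timepoint points.  The correlation sign gives
#' the regulation direction (activating / inhibiting).
#'
#' @param candidates reaction ids not assigned TR or TL.
#' @param flux_series numeric matrix, reactions x (condition-timepoint)
#'   points: predicted mean fluxes.
#' @param site_series numeric matrix, sites x the same points: mean site
#'   intensities (replicates averaged).
#' @param site_map data.frame with columns \code{site}, \code{gene}.
#' @param net metabolic_network (for GPR gene -> reaction mapping).
#' @param rho_cutoff,p_cutoff screening thresholds; defaults 0.6 / 0.05.
#' @return data.frame with one row per candidate-with-sites: reaction,
#'   site (best), rho, p, ptl (logical), direction.
#' @export
assign_ptl <- function(candidates, flux_series, site_series, site_map, net,
                       rho_cutoff = 0.6, p_cutoff = 0.05) {
  rows <- list()
  for (r in candidates) {
    genes <- gpr_leaves(net$gpr[[r]])
    sites <- site_map$site[site_map$gene %in% genes]
    if (length(sites) == 0) next
    best <- NULL
    for (s in sites) {
      ct <- spearman_test(flux_series[r, ], site_series[s, ])
      if (is.na(ct$rho)) next
      if (is.null(best) || abs(ct$rho) > abs(best$rho))
        best <- list(site = s, rho = ct$rho, p = ct$p)
    }
    if (is.null(best)) {
      rows[[r]] <- data.frame(reaction = r, site = NA_character_,
                              rho = NA_real_, p = NA_real_, ptl = FALSE,
                              direction = NA_character_)
      next
    }
    hit <- abs(best$rho) > rho_cutoff && best$p < p_cutoff
    rows[[r]] <- data.frame(
      reaction = r, site = best$site, rho = best$rho, p = best$p,
      ptl = hit,
      direction = if (!hit) NA_character_
                  else if (best$rho > 0) "activating" else "inhibiting")
  }
  if (length(rows) == 0)
    return(data.frame(reaction = character(0), site = character(0),
                      rho = numeric(0), p = numeric(0), ptl = logical(0),
                      direction = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
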