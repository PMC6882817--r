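## End-to-end orchestration of the four-step tiered-regulation analysis:
## discretize omics -> merge layers -> map to reactions -> iMAT + ACHR
## per condition -> TR/TL/PTL assignment -> SVM extension -> coupling and
## enrichment, with planted-truth scoring on synthetic runs.

#' Pipeline configuration
#'
#' @param sim a \code{\link{simulation_config}} for synthetic runs, or
#'   NULL when loading data from files.
#' @param model_path,omics_dir inputs for file-based runs (a JSON/SBML
#'   model and a directory of TSVs as written by
#'   \code{\link{write_dataset}}).
#' @param seed pipeline seed (ACHR chains, fold assignment); independent
#'   of the simulation's seeds.
#' @param epsilon,delta,n_samples,thin iMAT/sampling parameters;
#'   defaulted from \code{sim} when given.
#' @param min_frac replicate-match fraction for TR/TL calls (default
#'   0.75, i.e. 3 of 4).
#' @param rho_cutoff,p_cutoff PTL screening thresholds.
#' @param folds,svm_cost,min_positive SVM parameters.
#' @param out_dir optional directory for artifacts.
#' @return list of class "pipeline_config".
#' @export
pipeline_config <- function(sim = simulation_config(), model_path = NULL,
                            omics_dir = NULL, seed = 7L,
                            epsilon = NULL, delta = NULL,
                            n_samples = NULL, thin = NULL,
                            min_frac = 0.75, rho_cutoff = 0.6,
                            p_cutoff = 0.05, folds = 5L, svm_cost = 1,
                            min_positive = 10L, out_dir = NULL) {
  if (is.null(sim) && (is.null(model_path) || is.null(omics_dir)))
    stop("pipeline_config: need either a simulation config or model_path + omics_dir")
  if (!is.null(model_path) && !file.exists(model_path))
    stop("pipeline_config: model file not found: ", model_path)
  if (!is.null(omics_dir) && !dir.exists(omics_dir))
    stop("pipeline_config: omics directory not found: ", omics_dir)
  default <- function(x, f) if (is.null(x)) f else x
  base <- if (is.null(sim)) simulation_config() else sim
  structure(list(sim = sim, model_path = model_path, omics_dir = omics_dir,
                 seed = as.integer(seed),
                 epsilon = default(epsilon, base$epsilon),
                 delta = default(delta, base$delta),
                 n_samples = default(n_samples, base$n_samples),
                 thin = default(thin, base$thin),
                 min_frac = min_frac, rho_cutoff = rho_cutoff,
                 p_cutoff = p_cutoff, folds = as.integer(folds),
                 svm_cost = svm_cost, min_positive = as.integer(min_positive),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read an omics bundle from a directory of TSVs
#'
#' Expects the layout written by \code{\link{write_dataset}}.
#'
#' @param dir directory path.
#' @return an "omics_bundle" list (without a simulation config).
#' @export
read_omics_dir <- function(dir) {
  rd <- function(f) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  structure(list(
    expression = rd("expression.tsv"),
    protein = rd("protein.tsv"),
    phospho = rd("phospho.tsv"),
    measured_fluxes = rd("measured_fluxes.tsv"),
    site_map = utils::read.delim(file.path(dir, "site_map.tsv"),
                                 stringsAsFactors = FALSE),
    samples = utils::read.delim(file.path(dir, "samples.tsv"),
                                stringsAsFactors = FALSE)),
    class = "omics_bundle")
}

# GPR-evaluate a continuous gene-level matrix to the reaction level
reaction_level_matrix <- function(net, gene_mat) {
  out <- matrix(NA_real_, length(net$rxn_id), ncol(gene_mat),
                dimnames = list(net$rxn_id, colnames(gene_mat)))
  for (j in seq_len(ncol(gene_mat))) {
    gv <- stats::setNames(gene_mat[, j], rownames(gene_mat))
    for (r in net$rxn_id) {
      tree <- net$gpr[[r]]
      if (!is.null(tree)) out[r, j] <- evaluate_gpr(tree, gv)
    }
  }
  out
}

#' Spearman validation of predicted against measured fluxes
#'
#' @param mean_flux reactions x conditions matrix of predicted means.
#' @param measured reactions x conditions matrix of measured fluxes
#'   (subset of reactions).
#' @return list: rho, p, n (pooled across conditions), per_condition.
#' @export
validate_against_measured <- function(mean_flux, measured) {
  common <- intersect(rownames(measured), rownames(mean_flux))
  conds <- intersect(colnames(measured), colnames(mean_flux))
  if (length(common) < 3) stop("validate_against_measured: <3 shared reactions")
  pred <- as.vector(mean_flux[common, conds])
  meas <- as.vector(measured[common, conds])
  pooled <- spearman_test(pred, meas)
  per_cond <- sapply(conds, function(cc)
    spearman_test(mean_flux[common, cc], measured[common, cc])$rho)
  list(rho = pooled$rho, p = pooled$p, n = pooled$n,
       per_condition = per_cond)
}

#' Run the full tiered-regulation pipeline
#'
#' Executes: omics discretization and layer merging, GPR mapping, iMAT +
#' ACHR flux prediction per condition, TR/TL assignment (3-of-4
#' replicate match), PTL phosphosite screening, SVM extension of labels,
#' stoichiometric-coupling analysis, pathway enrichment and measured-flux
#' validation.  On synthetic runs the report includes recovery metrics
#' against the planted truth.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class "pipeline_report"; see fields in the vignette.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!is.null(config$sim)) {
    ds <- simulate_dataset(config$sim)
    net <- ds$net; omics <- ds$omics; truth <- ds$truth
  } else {
    net <- load_model(config$model_path)
    omics <- read_omics_dir(config$omics_dir)
    truth <- NULL
  }
  ann <- omics$samples
  conds <- unique(ann$condition)

  ## ---- discretize and map --------------------------------------------
  expr_state_g <- discretize_matrix(omics$expression)
  prot_state_g <- discretize_matrix(omics$protein)
  merged_g <- merge_layers(expr_state_g, prot_state_g)
  state_merged <- map_to_reactions(net, merged_g)
  state_expr <- map_to_reactions(net, expr_state_g)
  state_prot <- map_to_reactions(net, prot_state_g)

  ## ---- iMAT + sampling per condition ---------------------------------
  n <- length(net$rxn_id)
  mean_flux <- matrix(NA_real_, n, length(conds),
                      dimnames = list(net$rxn_id, conds))
  sample_sets <- list()
  imat_meta <- list()
  for (ci in seq_along(conds)) {
    smp <- ann$sample[ann$condition == conds[ci]]
    cond_state <- apply(state_merged[, smp, drop = FALSE], 1, majority_state)
    hi <- net$rxn_id[!is.na(cond_state) & cond_state == 1L]
    lo <- net$rxn_id[!is.na(cond_state) & cond_state == -1L]
    pr <- imat_problem(net, hi, lo, epsilon = config$epsilon,
                       delta = config$delta)
    sol <- solve_imat(pr)
    cnet <- fix_activity_states(pr, sol)
    fs <- sample_fluxes(cnet, n_samples = config$n_samples,
                        seed = sub_seed(config$seed, 500L + ci),
                        thin = config$thin, condition = conds[ci])
    mean_flux[, ci] <- fs$mean_flux
    sample_sets[[conds[ci]]] <- fs
    imat_meta[[conds[ci]]] <- list(n_high = length(hi), n_low = length(lo),
                                   objective = sol$objective,
                                   satisfied = sol$satisfied)
  }

  ## ---- step 1: TR / TL ------------------------------------------------
  flux_state <- discretize_flux(mean_flux)
  tr <- assign_tr(flux_state, state_expr, ann, config$min_frac)
  tl <- assign_tl(flux_state, state_prot, state_expr, ann, tr$tr,
                  config$min_frac)

  ## ---- step 2: PTL -----------------------------------------------------
  ct <- unique(ann[, c("condition", "timepoint")])
  ct_key <- sprintf("%s_%s", ct$condition, ct$timepoint)
  flux_series <- mean_flux[, match(ct$condition, conds), drop = FALSE]
  colnames(flux_series) <- ct_key
  samp_key <- sprintf("%s_%s", ann$condition, ann$timepoint)
  site_series <- t(apply(omics$phospho, 1, function(x)
    tapply(x, samp_key, mean)[ct_key]))
  colnames(site_series) <- ct_key
  never_direct <- rowSums(tr$tr) == 0 & rowSums(tl$tl) == 0
  ptl <- assign_ptl(net$rxn_id[never_direct], flux_series, site_series,
                    omics$site_map, net, config$rho_cutoff, config$p_cutoff)
  ptl_set <- ptl$reaction[ptl$ptl]

  ## ---- per-condition label matrix -------------------------------------
  label <- matrix("unassigned", n, length(conds),
                  dimnames = list(net$rxn_id, conds))
  for (ci in seq_along(conds)) {
    label[tr$tr[, ci], ci] <- tr$subtype[tr$tr[, ci], ci]
    tl_i <- tl$tl[, ci]
    label[tl_i, ci] <- ifelse(is.na(tl$subtype[tl_i, ci]), "TL",
                              tl$subtype[tl_i, ci])
  }
  label[ptl_set, ] <- "PTL"

  ## ---- step 3: SVM extension -----------------------------------------
  expr_rxn <- reaction_level_matrix(net, omics$expression)
  svm_label <- matrix(NA_character_, n, length(conds),
                      dimnames = list(net$rxn_id, conds))
  cv_reports <- list()
  has_gpr <- !vapply(net$gpr, is.null, logical(1))
  for (ci in seq_along(conds)) {
    smp <- ann$sample[ann$condition == conds[ci]]
    feats <- build_features(net, expr_rxn[, smp, drop = FALSE],
                            matrix(mean_flux[, ci], n, 4,
                                   dimnames = list(net$rxn_id, NULL)))
    lab_c <- label[, ci]
    train_idx <- has_gpr & lab_c %in% REGULATION_CLASSES
    pred_idx <- has_gpr & lab_c == "unassigned"
    if (sum(train_idx) >= config$min_positive) {
      clf <- suppressWarnings(train_classifiers(
        feats[train_idx, ], lab_c[train_idx], cost = config$svm_cost,
        min_positive = config$min_positive,
        seed = sub_seed(config$seed, 600L + ci)))
      cv_reports[[conds[ci]]] <- tryCatch(
        suppressWarnings(cross_validate(
          feats[train_idx, ], lab_c[train_idx], k = config$folds,
          seed = sub_seed(config$seed, 700L + ci),
          cost = config$svm_cost, min_positive = config$min_positive)),
        error = function(e) NULL)
      if (any(!vapply(clf$models, is.null, logical(1))) && sum(pred_idx) > 0) {
        pred <- predict_unassigned(clf, feats[pred_idx, , drop = FALSE])
        svm_label[pred_idx, ci] <- pred$labels
      }
    }
  }
  label[!is.na(svm_label) & label == "unassigned"] <-
    paste0("SVM-", svm_label[!is.na(svm_label) & label == "unassigned"])

  ## ---- step 4: coupling ------------------------------------------------
  coupling <- list()
  for (ci in seq_along(conds)) {
    cm <- pairwise_coupling(sample_sets[[conds[ci]]])
    lab_c <- label[, ci]
    indirect <- net$rxn_id[lab_c == "unassigned"]
    direct_tlptl <- net$rxn_id[startsWith(lab_c, "TL") | lab_c == "PTL"]
    cmp <- if (length(indirect) >= 2 && length(direct_tlptl) >= 2)
      compare_coupling(cm, indirect, direct_tlptl) else NULL
    bde <- if (length(indirect) > 0)
      bidirectional_enrichment(indirect, net) else NULL
    coupling[[conds[ci]]] <- list(matrix = cm, indirect_vs_direct = cmp,
                                  bidirectional = bde,
                                  n_indirect = length(indirect))
  }

  ## ---- enrichment and validation --------------------------------------
  enrichment <- lapply(seq_along(conds), function(ci) {
    tr_set <- net$rxn_id[startsWith(label[, ci], "TR")]
    if (length(tr_set) == 0) return(NULL)
    pathway_enrichment(tr_set, net$subsystem, net$rxn_id)
  })
  names(enrichment) <- conds
  validation <- if (!is.null(omics$measured_fluxes))
    validate_against_measured(mean_flux, omics$measured_fluxes) else NULL

  ## ---- counts and truth scoring ---------------------------------------
  counts <- sapply(conds, function(cc) {
    l <- label[, cc]
    c(TR = sum(startsWith(l, "TR")), TL = sum(startsWith(l, "TL")),
      PTL = sum(l == "PTL"), SVM = sum(startsWith(l, "SVM")),
      unassigned = sum(l == "unassigned"))
  })
  # reactions whose activity class is not reproducible under the
  # sampler's Monte-Carlo jitter ("tertile ties"): re-discretize under
  # perturbations of the mean fluxes, moving conservation-locked tie
  # groups as units, and flag any reaction whose class ever changes
  tied <- sapply(conds, function(cc) {
    a <- abs(mean_flux[, cc])
    se <- apply(sample_sets[[cc]]$samples, 1, stats::sd) /
      sqrt(ncol(sample_sets[[cc]]$samples))
    class_tie_zone(a, se, seed = sub_seed(config$seed, 800L))
  })
  rownames(tied) <- net$rxn_id
  recovery <- if (!is.null(truth))
    score_recovery(truth, label, ptl, conds, tied) else NULL

  report <- structure(list(
    conditions = conds, counts = counts, label = label,
    flux_state = flux_state, mean_flux = mean_flux,
    tr = tr, tl = tl, ptl = ptl, svm = list(label = svm_label,
                                            cv = cv_reports),
    tied = tied, coupling = coupling, enrichment = enrichment,
    validation = validation, imat = imat_meta,
    sample_sets = sample_sets, recovery = recovery, truth = truth,
    net = net, omics = omics, config = config),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Which reactions' tertile classes are volatile under Monte-Carlo
# jitter of the sampled means?  Perturb the means with 3-standard-error
# noise (one shared draw per machine-precision tie group, since
# conservation-locked reactions move together), re-discretize, and flag
# reactions whose class changes in any replicate.
class_tie_zone <- function(a, se, n_rep = 25, seed = 1L) {
  base <- tertile_discretize(a)
  grp <- match(round(a, 8), unique(round(a, 8)))
  gse <- tapply(se, grp, mean)
  tied <- rep(FALSE, length(a))
  set.seed(seed)
  for (b in seq_len(n_rep)) {
    shift <- stats::rnorm(length(gse), 0, 3 * gse + 1e-9)
    tied <- tied | tertile_discretize(pmax(a + shift[grp], 0)) != base
  }
  tied
}

# Recovery of planted labels: per (reaction, condition) for TR/TL, per
# reaction for the global PTL screen.  The tie-adjusted sensitivities
# exclude (reaction, condition) pairs whose activity class is a
# boundary tie (see `tied` in run_pipeline); a planted label can only be
# recovered where the flux discretization itself is reproducible.
score_recovery <- function(truth, label, ptl, conds, tied) {
  lab <- truth$labels
  tr_rxn <- names(lab)[lab == "TR"]
  tl_rxn <- names(lab)[startsWith(lab, "TL")]
  ptl_rxn <- names(lab)[startsWith(lab, "PTL")]
  ir_rxn <- names(lab)[lab == "IR"]
  tr_hit <- startsWith(label[tr_rxn, , drop = FALSE], "TR")
  tl_hit <- startsWith(label[tl_rxn, , drop = FALSE], "TL")
  ptl_hit <- ptl$reaction[ptl$ptl]
  confusion <- table(
    planted = sub("-.*", "", lab[rownames(label)[rownames(label) %in% names(lab)]]),
    assigned = sub("-.*", "", label[names(lab), 1]))
  ok_tr <- !tied[tr_rxn, , drop = FALSE]
  ok_tl <- !tied[tl_rxn, , drop = FALSE]
  list(tr_sensitivity = mean(tr_hit),
       tl_sensitivity = mean(tl_hit),
       ptl_sensitivity = mean(ptl_rxn %in% ptl_hit),
       tr_sensitivity_tie_adjusted = mean(tr_hit[ok_tr]),
       tl_sensitivity_tie_adjusted = mean(tl_hit[ok_tl]),
       tr_tied_pairs = sum(!ok_tr), tl_tied_pairs = sum(!ok_tl),
       ir_specificity = mean(label[ir_rxn, ] == "unassigned" |
                               startsWith(label[ir_rxn, , drop = FALSE], "SVM")),
       confusion_c1 = confusion)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("tiered-regulation pipeline report\n")
  cat("conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("label counts per condition:\n")
  print(x$counts)
  if (!is.null(x$validation))
    cat(sprintf("measured-flux validation: rho = %.3f (n = %d, p = %.2g)\n",
                x$validation$rho, x$validation$n, x$validation$p))
  if (!is.null(x$recovery))
    cat(sprintf("planted-label recovery: TR %.2f | TL %.2f | PTL %.2f\n",
                x$recovery$tr_sensitivity, x$recovery$tl_sensitivity,
                x$recovery$ptl_sensitivity))
  invisible(x)
}

# persist the main artifacts as TSV/JSON
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(reaction = rownames(report$label), report$label,
               check.names = FALSE),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(reaction = rownames(report$mean_flux), report$mean_flux,
               check.names = FALSE),
    file.path(dir, "mean_flux.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(report$ptl, file.path(dir, "ptl_evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(counts = as.data.frame(report$counts),
         validation = report$validation[c("rho", "p", "n")],
         recovery = report$recovery[c("tr_sensitivity", "tl_sensitivity",
                                      "ptl_sensitivity")]),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}
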