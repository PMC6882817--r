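## Step 3: extend the direct-regulation labels with SVM classifiers.
## Five one-vs-rest binary classifiers (TR-high, TR-low, TR-moderate,
## TL-up, TL-down) with a quadratic (degree-2 polynomial) kernel; a
## reaction is predicted regulated when exactly one classifier fires.

REGULATION_CLASSES <- c("TR-high", "TR-low", "TR-moderate", "TL-up", "TL-down")

#' Build the 13-feature table for reaction classification
#'
#' Features: reaction-level expression at the condition's 4 samples,
#' predicted fluxes at 4 data points, reversibility flag, an integer
#' pathway index (stable alphabetical enumeration of subsystem labels),
#' and metabolite / substrate / product counts.
#'
#' @param net metabolic_network.
#' @param reaction_expr numeric matrix, reactions x 4 samples
#'   (reaction-level expression, GPR-evaluated).
#' @param fluxes_4pt numeric matrix, reactions x 4 data points.
#' @return data.frame with 13 feature columns, rownames = reaction ids.
#' @export
build_features <- function(net, reaction_expr, fluxes_4pt) {
  stopifnot(ncol(reaction_expr) == 4, ncol(fluxes_4pt) == 4)
  rxns <- net$rxn_id
  pathway_levels <- sort(unique(net$subsystem))
  n_sub <- vapply(net$stoich, function(s) sum(s < 0), integer(1))
  n_pro <- vapply(net$stoich, function(s) sum(s > 0), integer(1))
  df <- data.frame(
    expr_1 = reaction_expr[rxns, 1], expr_2 = reaction_expr[rxns, 2],
    expr_3 = reaction_expr[rxns, 3], expr_4 = reaction_expr[rxns, 4],
    flux_1 = fluxes_4pt[rxns, 1], flux_2 = fluxes_4pt[rxns, 2],
    flux_3 = fluxes_4pt[rxns, 3], flux_4 = fluxes_4pt[rxns, 4],
    reversible = as.integer(is_bidirectional(net)[rxns]),
    pathway_index = match(net$subsystem[rxns], pathway_levels),
    n_metabolites = n_sub + n_pro,
    n_substrates = n_sub,
    n_products = n_pro,
    row.names = rxns)
  df
}

fit_one_svm <- function(x, y, cost = 1) {
  wt <- 1 / table(y)
  wt <- wt / sum(wt) * 2
  e1071::svm(x, y, kernel = "polynomial", degree = 2, coef0 = 1,
             cost = cost, scale = TRUE, class.weights = wt)
}

decision_scores <- function(model, x) {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # orient so positive score means the "pos" class
  if (grepl("^neg", colnames(dv)[1])) dv <- -dv
  drop(dv)
}

#' Train one-vs-rest SVM classifiers for the direct-regulation classes
#'
#' @param features feature data.frame from \code{\link{build_features}}
#'   (rows = labeled reactions).
#' @param labels character vector of step-1 labels aligned with rows;
#'   values among \code{REGULATION_CLASSES} or anything else (negative).
#' @param classes classes to train; default all five.
#' @param cost SVM regularization constant; default 1.
#' @param min_positive minimum positives to train a class; classes below
#'   it are skipped with a warning.
#' @param seed RNG seed (SVM training is deterministic, but kept for
#'   interface stability).
#' @return list of class "regulation_classifiers": per-class svm model or
#'   NULL, plus the skipped classes.
#' @export
train_classifiers <- function(features, labels,
                              classes = REGULATION_CLASSES, cost = 1,
                              min_positive = 10, seed = 1) {
  stopifnot(nrow(features) == length(labels))
  set.seed(seed)
  x <- as.matrix(features)
  models <- stats::setNames(vector("list", length(classes)), classes)
  skipped <- character(0)
  for (cl in classes) {
    pos <- labels == cl
    if (sum(pos) < min_positive) {
      warning("class ", cl, ": only ", sum(pos),
              " positives, classifier skipped")
      skipped <- c(skipped, cl)
      next
    }
    y <- factor(ifelse(pos, "pos", "neg"), levels = c("pos", "neg"))
    models[[cl]] <- fit_one_svm(x, y, cost)
  }
  structure(list(models = models, skipped = skipped, cost = cost),
            class = "regulation_classifiers")
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (grp in unique(y)) {
    idx <- sample(which(y == grp))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validate the regulation classifiers
#'
#' Stratified k-fold; standardization happens inside each training fold
#' (the SVM scales on its training data only), so no information leaks
#' from held-out folds.  AUC, precision and recall are computed on the
#' held-out folds and averaged.
#'
#' @param features,labels as in \code{\link{train_classifiers}}.
#' @param k number of folds; default 5.
#' @param seed fold-assignment seed.
#' @param classes classes to evaluate.
#' @param cost,min_positive passed through.
#' @return data.frame of class "classifier_report": class, n_positive,
#'   auc, precision, recall (NA for skipped classes).
#' @export
cross_validate <- function(features, labels, k = 5, seed = 1,
                           classes = REGULATION_CLASSES, cost = 1,
                           min_positive = 10) {
  stopifnot(nrow(features) == length(labels))
  x <- as.matrix(features)
  out <- data.frame(class = classes, n_positive = NA_integer_,
                    auc = NA_real_, precision = NA_real_, recall = NA_real_)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    pos <- labels == cl
    out$n_positive[i] <- sum(pos)
    if (sum(pos) < min_positive) next
    if (k > sum(pos))
      stop("cross_validate: k = ", k, " exceeds positive count for ", cl)
    y <- factor(ifelse(pos, "pos", "neg"), levels = c("pos", "neg"))
    fold <- stratified_folds(y, k, seed + i)
    aucs <- precs <- recs <- numeric(0)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      if (length(unique(y[tr])) < 2 || sum(y[te] == "pos") == 0) next
      m <- fit_one_svm(x[tr, , drop = FALSE], y[tr], cost)
      sc <- decision_scores(m, x[te, , drop = FALSE])
      roc <- pROC::roc(response = y[te], predictor = sc,
                       levels = c("neg", "pos"), direction = "<",
                       quiet = TRUE)
      aucs <- c(aucs, as.numeric(pROC::auc(roc)))
      pred_pos <- sc > 0
      tp <- sum(pred_pos & y[te] == "pos")
      precs <- c(precs, if (sum(pred_pos) > 0) tp / sum(pred_pos) else NA)
      recs <- c(recs, tp / sum(y[te] == "pos"))
    }
    out$auc[i] <- mean(aucs)
    out$precision[i] <- mean(precs, na.rm = TRUE)
    out$recall[i] <- mean(recs)
  }
  class(out) <- c("classifier_report", class(out))
  out
}

#' Predict direct regulation for unassigned reactions
#'
#' A reaction receives a class label iff exactly one classifier scores it
#' positive; reactions positive in zero or several classifiers stay
#' unassigned (the multi-positive count is reported).
#'
#' @param classifiers a \code{\link{train_classifiers}} result.
#' @param features feature rows for the unassigned reactions.
#' @return list with \code{labels} (named character, NA = unassigned),
#'   \code{n_positive} (named integer), \code{multi_positive} count.
#' @export
predict_unassigned <- function(classifiers, features) {
  x <- as.matrix(features)
  active <- !vapply(classifiers$models, is.null, logical(1))
  scores <- sapply(names(classifiers$models)[active], function(cl)
    decision_scores(classifiers$models[[cl]], x))
  if (nrow(x) == 1) scores <- matrix(scores, nrow = 1,
                                     dimnames = list(rownames(x), names(scores)))
  pos <- scores > 0
  n_pos <- rowSums(pos)
  labels <- rep(NA_character_, nrow(x))
  one <- which(n_pos == 1)
  labels[one] <- colnames(pos)[apply(pos[one, , drop = FALSE], 1, which)]
  names(labels) <- rownames(x)
  list(labels = labels,
       n_positive = stats::setNames(n_pos, rownames(x)),
       multi_positive = sum(n_pos >= 2))
}
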