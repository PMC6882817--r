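## Metabolic-model data structures, I/O, stoichiometric algebra, GPR
## evaluation and FBA.  Networks are plain lists of class
## "metabolic_network" with parallel per-reaction vectors, in the style of
## small constraint-based modelling toolboxes.

# Infinite bounds are clamped to this magnitude at load time; keeps big-M
# constructions in the iMAT MILP finite.
BOUND_CLAMP <- 1000

FEAS_TOL <- 1e-6

#' Construct a reaction
#'
#' @param id reaction identifier.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient
#'   (negative = consumed).
#' @param lower_bound,upper_bound flux bounds in model units
#'   (e.g. mmol/gDW/h); infinite values are clamped to +/-1000.
#' @param gpr a GPR tree (see \code{\link{parse_gpr}}), a GPR string, or
#'   NULL for reactions without gene association.
#' @param subsystem pathway label; defaults to "unassigned".
#' @return a list of class \code{"reaction"}.
#' @export
reaction <- function(id, stoichiometry, lower_bound, upper_bound,
                     gpr = NULL, subsystem = "unassigned") {
  stopifnot(is.character(id), length(id) == 1)
  if (length(stoichiometry) > 0 && is.null(names(stoichiometry)))
    stop("stoichiometry must be a named vector")
  lower_bound <- max(lower_bound, -BOUND_CLAMP)
  upper_bound <- min(upper_bound, BOUND_CLAMP)
  if (lower_bound > upper_bound)
    stop(sprintf("reaction '%s': lower_bound > upper_bound", id))
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  structure(list(id = id, stoichiometry = stoichiometry,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 gpr = gpr, subsystem = subsystem),
            class = "reaction")
}

#' Construct and validate a metabolic network
#'
#' @param metabolites data.frame with columns \code{id} and
#'   \code{compartment}, or a character vector of ids.
#' @param reactions list of \code{\link{reaction}} objects.
#' @param genes optional character vector; defaults to the union of GPR
#'   leaves.
#' @return object of class \code{"metabolic_network"} with fields
#'   \code{mets}, \code{compartment}, \code{rxn_id}, \code{stoich} (list),
#'   \code{lb}, \code{ub}, \code{gpr} (list), \code{subsystem},
#'   \code{genes}.
#' @export
metabolic_network <- function(metabolites, reactions, genes = NULL) {
  if (is.character(metabolites))
    metabolites <- data.frame(id = metabolites,
                              compartment = rep("c", length(metabolites)))
  mets <- as.character(metabolites$id)
  if (anyDuplicated(mets))
    stop("duplicate metabolite ids: ",
         paste(unique(mets[duplicated(mets)]), collapse = ", "))
  rxn_id <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_id))
    stop("duplicate reaction ids: ",
         paste(unique(rxn_id[duplicated(rxn_id)]), collapse = ", "))
  stoich <- lapply(reactions, `[[`, "stoichiometry")
  names(stoich) <- rxn_id
  for (r in rxn_id) {
    bad <- setdiff(names(stoich[[r]]), mets)
    if (length(bad) > 0)
      stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                   r, paste(bad, collapse = ", ")))
  }
  gpr <- lapply(reactions, `[[`, "gpr")
  names(gpr) <- rxn_id
  gpr_genes <- unique(unlist(lapply(gpr, gpr_leaves)))
  if (is.null(genes)) genes <- gpr_genes
  bad <- setdiff(gpr_genes, genes)
  if (length(bad) > 0)
    stop("GPR references undeclared gene(s): ", paste(bad, collapse = ", "))
  net <- structure(list(
    mets = mets,
    compartment = stats::setNames(as.character(metabolites$compartment), mets),
    rxn_id = rxn_id,
    stoich = stoich,
    lb = stats::setNames(vapply(reactions, `[[`, numeric(1), "lower_bound"), rxn_id),
    ub = stats::setNames(vapply(reactions, `[[`, numeric(1), "upper_bound"), rxn_id),
    gpr = gpr,
    subsystem = stats::setNames(
      vapply(reactions, function(r) {
        s <- r$subsystem
        if (is.null(s) || is.na(s) || !nzchar(s)) "unassigned" else s
      }, character(1)), rxn_id),
    genes = genes
  ), class = "metabolic_network")
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network: %d metabolites x %d reactions\n",
              length(x$mets), length(x$rxn_id)))
  cat(sprintf("  reversible: %d | GPR-covered: %d | genes: %d | subsystems: %d\n",
              sum(is_bidirectional(x)),
              sum(!vapply(x$gpr, is.null, logical(1))),
              length(x$genes), length(unique(x$subsystem))))
  invisible(x)
}

## ---- GPR trees -----------------------------------------------------------

gpr_gene <- function(g) list(kind = "gene", gene = g)
gpr_and  <- function(...) list(kind = "and", children = list(...))
gpr_or   <- function(...) list(kind = "or",  children = list(...))

gpr_leaves <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$kind == "gene") return(tree$gene)
  unlist(lapply(tree$children, gpr_leaves))
}

#' Parse a Boolean GPR string into a tree
#'
#' Accepts the usual rule syntax, e.g. \code{"(g1 or g2) and g3"}; operators
#' are case-insensitive, \code{and} binds tighter than \code{or}.
#'
#' @param s rule string; empty or all-whitespace gives NULL.
#' @return GPR tree: nodes are lists with \code{kind} in
#'   \code{"gene"/"and"/"or"}.
#' @export
parse_gpr <- function(s) {
  if (is.null(s) || !nzchar(trimws(s))) return(NULL)
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    left <- parse_and()
    kids <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance(); kids[[length(kids) + 1L]] <- parse_and()
    }
    if (length(kids) == 1) kids[[1]] else list(kind = "or", children = kids)
  }
  parse_and <- function() {
    left <- parse_atom()
    kids <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance(); kids[[length(kids) + 1L]] <- parse_atom()
    }
    if (length(kids) == 1) kids[[1]] else list(kind = "and", children = kids)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule: ", s)
    if (t == "(") {
      advance()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")")
        stop("GPR parse error: missing ')' in rule: ", s)
      advance()
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("GPR parse error: unexpected token '", t, "' in rule: ", s)
    advance()
    gpr_gene(t)
  }
  out <- parse_or()
  if (pos <= length(toks))
    stop("GPR parse error: trailing tokens in rule: ", s)
  out
}

deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (tree$kind == "gene") return(tree$gene)
  op <- if (tree$kind == "and") " and " else " or "
  paste0("(", paste(vapply(tree$children, deparse_gpr, character(1)),
                    collapse = op), ")")
}

#' Evaluate a GPR tree over numeric gene levels
#'
#' OR nodes take the maximum of their children, AND nodes the minimum —
#' the standard conversion of Boolean enzyme rules to activity levels.
#' A gene absent from \code{gene_values} (or NA) is treated as unmeasured:
#' it is dropped under OR, and dropped under AND unless every child is
#' unmeasured; a fully unmeasured (sub)rule evaluates to NA.
#'
#' @param tree GPR tree from \code{\link{parse_gpr}} (NULL gives NA).
#' @param gene_values named numeric vector of gene levels.
#' @return numeric level, or NA if the rule is uninformative.
#' @export
evaluate_gpr <- function(tree, gene_values) {
  if (is.null(tree)) return(NA_real_)
  if (tree$kind == "gene") {
    v <- gene_values[tree$gene]
    if (length(v) == 0 || is.na(v)) return(NA_real_)
    return(unname(v))
  }
  vals <- vapply(tree$children, evaluate_gpr, numeric(1),
                 gene_values = gene_values)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NA_real_)
  if (tree$kind == "or") max(vals) else min(vals)
}

## ---- stoichiometric algebra ---------------------------------------------

#' Stoichiometric matrix of a network
#'
#' @param net metabolic_network.
#' @return dense m x n matrix; rows ordered as \code{net$mets}, columns as
#'   \code{net$rxn_id}; entry (i, j) is the coefficient of metabolite i in
#'   reaction j.
#' @export
stoichiometric_matrix <- function(net) {
  m <- length(net$mets); n <- length(net$rxn_id)
  S <- matrix(0, m, n, dimnames = list(net$mets, net$rxn_id))
  for (j in seq_len(n)) {
    st <- net$stoich[[j]]
    if (length(st) > 0) S[names(st), j] <- st
  }
  S
}

#' Can a reaction carry flux in both directions?
#'
#' @param net metabolic_network.
#' @param rxn optional reaction id(s); default all.
#' @return named logical vector: TRUE iff lower bound < 0 < upper bound.
#' @export
is_bidirectional <- function(net, rxn = NULL) {
  if (is.null(rxn)) rxn <- net$rxn_id
  net$lb[rxn] < 0 & net$ub[rxn] > 0
}

#' Flux balance analysis
#'
#' Solves the LP max/min \code{v[objective]} subject to \code{S v = 0} and
#' the network bounds.
#'
#' @param net metabolic_network.
#' @param objective reaction id to optimise.
#' @param sense "max" (default) or "min".
#' @return list with \code{flux} (named vector over all reactions) and
#'   \code{objective_value}.
#' @export
solve_fba <- function(net, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (!objective %in% net$rxn_id)
    stop("objective reaction not in model: ", objective)
  S <- stoichiometric_matrix(net)
  obj <- as.numeric(net$rxn_id == objective)
  res <- lp_solve(obj, sense, A_eq = S, b_eq = numeric(nrow(S)),
                  lb = net$lb, ub = net$ub)
  if (res$status != "optimal")
    stop("FBA failed: model is ", res$status)
  flux <- stats::setNames(res$v, net$rxn_id)
  stopifnot(max(abs(S %*% flux)) <= FEAS_TOL)
  list(flux = flux, objective_value = res$obj)
}

## ---- I/O -----------------------------------------------------------------

#' Read a metabolic model from JSON or SBML
#'
#' The JSON dialect mirrors the SBML content field-for-field:
#' \code{metabolites} (id, compartment), \code{reactions} (id,
#' stoichiometry map, lower_bound, upper_bound, gpr string, subsystem) and
#' optional \code{genes}.  SBML is read at Level 3 with the fbc package
#' (flux bounds via parameters, GPRs via geneProductAssociation).
#' Infinite or missing bounds are clamped to +/-1000.
#'
#' @param path file path.
#' @param format "json" or "sbml"; guessed from the extension by default.
#' @return a \code{\link{metabolic_network}}.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "json") load_model_json(path) else load_model_sbml(path)
}

load_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("malformed model JSON: missing 'metabolites' or 'reactions'")
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
    compartment = vapply(doc$metabolites, function(m)
      if (is.null(m$compartment)) "c" else as.character(m$compartment),
      character(1)))
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("malformed model JSON: reaction without id")
    st <- unlist(r$stoichiometry)
    if (is.null(st)) st <- stats::setNames(numeric(0), character(0))
    reaction(id = as.character(r$id), stoichiometry = st,
             lower_bound = if (is.null(r$lower_bound)) -BOUND_CLAMP else r$lower_bound,
             upper_bound = if (is.null(r$upper_bound)) BOUND_CLAMP else r$upper_bound,
             gpr = if (is.null(r$gpr)) NULL else as.character(r$gpr),
             subsystem = if (is.null(r$subsystem)) "unassigned" else r$subsystem)
  })
  genes <- if (is.null(doc$genes)) NULL else
    vapply(doc$genes, as.character, character(1))
  metabolic_network(mets, rxns, genes = genes)
}

#' Write a network to the JSON model dialect
#'
#' @param net metabolic_network.
#' @param path output path.
#' @export
write_model_json <- function(net, path) {
  doc <- list(
    metabolites = lapply(net$mets, function(m)
      list(id = m, compartment = unname(net$compartment[m]))),
    reactions = lapply(net$rxn_id, function(r)
      list(id = r,
           stoichiometry = as.list(net$stoich[[r]]),
           lower_bound = unname(net$lb[r]),
           upper_bound = unname(net$ub[r]),
           gpr = deparse_gpr(net$gpr[[r]]),
           subsystem = unname(net$subsystem[r]))),
    genes = as.list(net$genes))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

load_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("malformed SBML: no <model>")

  sp <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    compartment = ifelse(is.na(xml2::xml_attr(sp, "compartment")), "c",
                         xml2::xml_attr(sp, "compartment")))
  # boundary-condition species are environment pseudo-metabolites
  boundary <- xml2::xml_attr(sp, "boundaryCondition")
  drop <- mets$id[!is.na(boundary) & boundary == "true"]
  mets <- mets[!mets$id %in% drop, , drop = FALSE]

  pars <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  read_side <- function(rx, tag, sign) {
    refs <- xml2::xml_find_all(rx, paste0("./", tag, "/speciesReference"))
    if (length(refs) == 0) return(stats::setNames(numeric(0), character(0)))
    s <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    s[is.na(s)] <- 1
    stats::setNames(sign * s, xml2::xml_attr(refs, "species"))
  }
  gpr_from_node <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(gpr_gene(xml2::xml_attr(node, "geneProduct")))
    kids <- lapply(xml2::xml_children(node), gpr_from_node)
    kids <- Filter(Negate(is.null), kids)
    if (length(kids) == 0) return(NULL)
    if (length(kids) == 1) return(kids[[1]])
    list(kind = if (nm == "and") "and" else "or", children = kids)
  }

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  rxns <- lapply(rx_nodes, function(rx) {
    id <- xml2::xml_attr(rx, "id")
    st <- c(read_side(rx, "listOfReactants", -1),
            read_side(rx, "listOfProducts", +1))
    st <- st[!names(st) %in% drop]
    # merge duplicated species references
    if (anyDuplicated(names(st)))
      st <- tapply(st, names(st), sum)
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(parval)) parval[lb_ref] else {
      rev <- xml2::xml_attr(rx, "reversible")
      if (!is.na(rev) && rev == "false") 0 else -BOUND_CLAMP
    }
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(parval)) parval[ub_ref]
          else BOUND_CLAMP
    kids <- xml2::xml_children(rx)
    gpa <- kids[xml2::xml_name(kids) == "geneProductAssociation"]
    gpr <- if (length(gpa) == 0) NULL else {
      inner <- xml2::xml_children(gpa[[1]])
      if (length(inner) == 0) NULL else gpr_from_node(inner[[1]])
    }
    notes <- kids[xml2::xml_name(kids) == "notes"]
    subsystem <- "unassigned"
    if (length(notes) > 0) {
      txt <- xml2::xml_text(notes[[1]])
      if (grepl("SUBSYSTEM:", txt))
        subsystem <- trimws(sub(".*SUBSYSTEM:\\s*([^\n<]*).*", "\\1", txt))
    }
    reaction(id = id, stoichiometry = st,
             lower_bound = if (is.na(lb)) -BOUND_CLAMP else lb,
             upper_bound = if (is.na(ub)) BOUND_CLAMP else ub,
             gpr = gpr, subsystem = subsystem)
  })
  metabolic_network(mets, rxns)
}

#' Summarise a model for validation
#'
#' @param net metabolic_network.
#' @return list with m, n, n_reversible, n_gpr.
#' @export
model_summary <- function(net) {
  list(m = length(net$mets), n = length(net$rxn_id),
       n_reversible = sum(unname(is_bidirectional(net))),
       n_gpr = sum(!vapply(net$gpr, is.null, logical(1))))
}
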