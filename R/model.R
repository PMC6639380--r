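#' Construct a constraint-based metabolic model
#'
#' Builds the in-memory representation used throughout the package: a
#' stoichiometric matrix `S` (metabolites x reactions), per-reaction flux
#' bounds, and a single biomass objective reaction. Reaction classes are
#' inferred unless given: a reaction touching exactly one metabolite is an
#' `exchange`, the objective reaction is `biomass`, everything else is
#' `internal`.
#'
#' @param id model identifier.
#' @param reactions list of reaction records; each a list with elements
#'   `id`, `stoich` (named numeric: metabolite -> coefficient), `lower`,
#'   `upper`, and optionally `class`.
#' @param objective id of the biomass (objective) reaction.
#' @param metabolites optional data.frame with columns `id`, `compartment`;
#'   inferred from stoichiometries (compartment `"c"`) when omitted.
#' @return an object of class `metabolic_model` with elements `id`,
#'   `reactions` (data.frame: id, lower, upper, reversible, class),
#'   `metabolites`, `S` (sparse [Matrix::Matrix]), `objective`.
#' @examples
#' mod <- make_toy_model(toy_spec("chain"))
#' mod
#' @export
metabolic_model <- function(id, reactions, objective, metabolites = NULL) {
  stopifnot(is.list(reactions), length(reactions) >= 1)
  rid <- vapply(reactions, function(r) as.character(r$id), "")
  if (anyDuplicated(rid)) stop("duplicate reaction ids: ",
                               paste(unique(rid[duplicated(rid)]), collapse = ", "))
  mets <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  if (is.null(metabolites)) {
    metabolites <- data.frame(id = mets, compartment = "c",
                              stringsAsFactors = FALSE)
  }
  lower <- vapply(reactions, function(r) as.numeric(r$lower), 0)
  upper <- vapply(reactions, function(r) as.numeric(r$upper), 0)

  trips <- do.call(rbind, lapply(seq_along(reactions), function(j) {
    st <- reactions[[j]]$stoich
    cbind(match(names(st), metabolites$id), j, as.numeric(st))
  }))
  S <- Matrix::sparseMatrix(i = trips[, 1], j = trips[, 2], x = trips[, 3],
                            dims = c(nrow(metabolites), length(reactions)),
                            dimnames = list(metabolites$id, rid))

  cls <- vapply(reactions, function(r)
    if (is.null(r$class)) NA_character_ else as.character(r$class), "")
  n_met <- Matrix::colSums(S != 0)
  cls[is.na(cls)] <- ifelse(rid[is.na(cls)] == objective, "biomass",
                            ifelse(n_met[is.na(cls)] == 1L, "exchange", "internal"))

  model <- structure(list(
    id = id,
    reactions = data.frame(id = rid, lower = lower, upper = upper,
                           reversible = lower < 0 & upper > 0,
                           class = cls, stringsAsFactors = FALSE),
    metabolites = metabolites,
    S = S,
    objective = objective
  ), class = "metabolic_model")
  validate_metabolic_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks that bounds are ordered, the objective exists, exactly one
#' reaction is classed `biomass`, and exchange reactions touch exactly one
#' metabolite. Called by the constructor and the readers.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the offending element.
#' @export
validate_metabolic_model <- function(model) {
  rx <- model$reactions
  bad <- which(rx$lower > rx$upper)
  if (length(bad)) stop("invalid bounds (lower > upper) for reaction ",
                        rx$id[bad[1]])
  if (!model$objective %in% rx$id)
    stop("objective reaction '", model$objective, "' not found in model")
  if (sum(rx$class == "biomass") != 1L)
    stop("model must contain exactly one biomass reaction, found ",
         sum(rx$class == "biomass"))
  n_met <- Matrix::colSums(model$S != 0)
  bad <- which(rx$class == "exchange" & n_met != 1L)
  if (length(bad)) stop("exchange reaction ", rx$id[bad[1]],
                        " touches more than one metabolite")
  orphan <- setdiff(rownames(model$S), model$metabolites$id)
  if (length(orphan)) stop("stoichiometry references undeclared metabolite ",
                           orphan[1])
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions),
      " (", sum(x$reactions$class == "internal"), " internal, ",
      sum(x$reactions$class == "exchange"), " exchange)\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites), "\n", sep = "")
  cat("  objective:   ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Reaction ids carrying genetic constraints
#'
#' The loci of the genetics layer: all internal reactions. Exchange and
#' biomass reactions never carry alleles.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids, in model order.
#' @export
constrained_loci <- function(model) {
  model$reactions$id[model$reactions$class == "internal"]
}

# dense solver inputs with infinite bounds clamped
lp_parts <- function(model) {
  rx <- model$reactions
  list(S = as.matrix(model$S),
       lb = pmax(rx$lower, -FLUX_BIG),
       ub = pmin(rx$upper, FLUX_BIG),
       obj = as.numeric(rx$id == model$objective))
}
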