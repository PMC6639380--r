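#' Read a constraint-based model from disk
#'
#' Supports a COBRA-style JSON dialect (`metabolites` / `reactions` arrays
#' with `lower_bound`, `upper_bound`, `objective_coefficient`) and SBML
#' Level 3 with the FBC package (flux bounds as referenced parameters, the
#' objective as an FBC flux objective). Reaction classes are inferred on
#' load: single-metabolite reactions are exchanges, the objective reaction
#' is biomass.
#'
#' @param path file path.
#' @param dialect `"json"` or `"sbml"`; inferred from the file extension
#'   (`.json` vs `.xml`/`.sbml`) when omitted.
#' @return a validated `metabolic_model`.
#' @export
load_model <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  dialect <- dialect %||% infer_dialect(path)
  switch(match.arg(dialect, c("json", "sbml")),
         json = read_model_json(path),
         sbml = read_model_sbml(path))
}

#' Write a constraint-based model to disk
#'
#' Inverse of [load_model()]; both dialects round-trip losslessly through
#' the reader (up to reaction-class inference).
#'
#' @param model a `metabolic_model`.
#' @inheritParams load_model
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = NULL) {
  if (!nzchar(path %||% "")) stop("empty output path")
  validate_metabolic_model(model)
  dialect <- dialect %||% infer_dialect(path)
  switch(match.arg(dialect, c("json", "sbml")),
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

infer_dialect <- function(path) {
  switch(tolower(tools::file_ext(path)),
         json = "json", xml = "sbml", sbml = "sbml",
         stop("cannot infer model dialect from extension of '", path,
              "'; pass dialect = \"json\" or \"sbml\""))
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("JSON parse failure in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(doc$reactions)) stop("format error: no 'reactions' array in ", path)
  obj <- NULL
  rx <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("format error: reaction without id in ", path)
    oc <- r$objective_coefficient %||% 0
    if (oc != 0) obj <<- r$id
    list(id = r$id, stoich = unlist(r$metabolites),
         lower = r$lower_bound %||% -Inf, upper = r$upper_bound %||% Inf)
  })
  if (is.null(obj)) stop("validation error: no objective reaction declared in ",
                         path)
  mets <- if (length(doc$metabolites)) {
    data.frame(id = vapply(doc$metabolites, function(m) m$id, ""),
               compartment = vapply(doc$metabolites,
                                    function(m) m$compartment %||% "c", ""),
               stringsAsFactors = FALSE)
  } else NULL
  metabolic_model(doc$id %||% tools::file_path_sans_ext(basename(path)),
                  rx, objective = obj, metabolites = mets)
}

write_model_json <- function(model, path) {
  rx <- model$reactions
  st_list <- lapply(seq_len(nrow(rx)), function(j) {
    col <- model$S[, j]
    as.list(col[col != 0])
  })
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(seq_len(nrow(rx)), function(j)
      list(id = rx$id[j],
           metabolites = st_list[[j]],
           lower_bound = rx$lower[j],
           upper_bound = rx$upper[j],
           objective_coefficient = if (rx$id[j] == model$objective) 1 else 0)),
    version = "1")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
}

# --- SBML Level 3 + FBC version 2 -------------------------------------
# Only the subset this package needs: compartments, species, reactions
# with FBC bound parameters, and one maximisation objective. Ids gain the
# conventional M_/R_ prefixes on write and lose them on read.

sbml_num <- function(x) {
  ifelse(x == Inf, "INF", ifelse(x == -Inf, "-INF", format(x, digits = 17)))
}

parse_sbml_num <- function(s) {
  ifelse(s == "INF", Inf, ifelse(s == "-INF", -Inf, suppressWarnings(as.numeric(s))))
}

xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_model_sbml <- function(model, path) {
  rx <- model$reactions
  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
         paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
                'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
                'level="3" version="1" fbc:required="false">'),
         sprintf('  <model id="%s" fbc:strict="true">', xesc(model$id)),
         '    <listOfCompartments>')
  for (cp in unique(model$metabolites$compartment))
    L <- c(L, sprintf('      <compartment id="%s" constant="true"/>', xesc(cp)))
  L <- c(L, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites)))
    L <- c(L, sprintf(paste0('      <species id="M_%s" compartment="%s" ',
                             'hasOnlySubstanceUnits="false" ',
                             'boundaryCondition="false" constant="false"/>'),
                      xesc(model$metabolites$id[i]),
                      xesc(model$metabolites$compartment[i])))
  L <- c(L, '    </listOfSpecies>', '    <listOfParameters>')
  for (j in seq_len(nrow(rx)))
    L <- c(L, sprintf('      <parameter id="bnd_lb_%d" value="%s" constant="true"/>',
                      j, sbml_num(rx$lower[j])),
           sprintf('      <parameter id="bnd_ub_%d" value="%s" constant="true"/>',
                   j, sbml_num(rx$upper[j])))
  L <- c(L, '    </listOfParameters>', '    <listOfReactions>')
  for (j in seq_len(nrow(rx))) {
    col <- model$S[, j]
    col <- col[col != 0]
    L <- c(L, sprintf(paste0('      <reaction id="R_%s" reversible="%s" ',
                             'fast="false" fbc:lowerFluxBound="bnd_lb_%d" ',
                             'fbc:upperFluxBound="bnd_ub_%d">'),
                      xesc(rx$id[j]), tolower(rx$reversible[j]), j, j))
    reac <- col[col < 0]; prod <- col[col > 0]
    if (length(reac)) {
      L <- c(L, '        <listOfReactants>')
      for (k in seq_along(reac))
        L <- c(L, sprintf(paste0('          <speciesReference species="M_%s" ',
                                 'stoichiometry="%s" constant="true"/>'),
                          xesc(names(reac)[k]), format(-reac[k], digits = 17)))
      L <- c(L, '        </listOfReactants>')
    }
    if (length(prod)) {
      L <- c(L, '        <listOfProducts>')
      for (k in seq_along(prod))
        L <- c(L, sprintf(paste0('          <speciesReference species="M_%s" ',
                                 'stoichiometry="%s" constant="true"/>'),
                          xesc(names(prod)[k]), format(prod[k], digits = 17)))
      L <- c(L, '        </listOfProducts>')
    }
    L <- c(L, '      </reaction>')
  }
  L <- c(L, '    </listOfReactions>',
         '    <fbc:listOfObjectives fbc:activeObjective="obj">',
         '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
         '        <fbc:listOfFluxObjectives>',
         sprintf(paste0('          <fbc:fluxObjective fbc:reaction="R_%s" ',
                        'fbc:coefficient="1"/>'), xesc(model$objective)),
         '        </fbc:listOfFluxObjectives>',
         '      </fbc:objective>',
         '    </fbc:listOfObjectives>',
         '  </model>', '</sbml>')
  writeLines(L, path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)

  params <- xml2::xml_find_all(doc, "//*[local-name()='parameter']")
  pval <- setNames(parse_sbml_num(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))

  species <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  mets <- data.frame(id = strip(xml2::xml_attr(species, "id"), "M_"),
                     compartment = xml2::xml_attr(species, "compartment"),
                     stringsAsFactors = FALSE)

  fobj <- xml2::xml_find_first(doc, "//*[local-name()='fluxObjective']")
  if (inherits(fobj, "xml_missing"))
    stop("validation error: no FBC flux objective in ", path)
  objective <- strip(xml2::xml_attr(fobj, "reaction"), "R_")

  rnodes <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  rx <- lapply(rnodes, function(nd) {
    id <- strip(xml2::xml_attr(nd, "id"), "R_")
    lb_ref <- xml2::xml_attr(nd, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(nd, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]] else -Inf
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else Inf
    sto <- c()
    for (sr in xml2::xml_find_all(nd, ".//*[local-name()='listOfReactants']/*"))
      sto[strip(xml2::xml_attr(sr, "species"), "M_")] <-
        -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(nd, ".//*[local-name()='listOfProducts']/*"))
      sto[strip(xml2::xml_attr(sr, "species"), "M_")] <-
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    list(id = id, stoich = sto, lower = lb, upper = ub)
  })
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, "//*[local-name()='model']"), "id")
  metabolic_model(mid %||% tools::file_path_sans_ext(basename(path)),
                  rx, objective = objective, metabolites = mets)
}
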