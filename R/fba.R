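#' Flux balance analysis
#'
#' Maximises the biomass objective `c'v` subject to the steady-state
#' constraint `S v = 0` and the flux bounds, and returns one optimal
#' vertex.
#'
#' @param model a `metabolic_model`.
#' @return a `flux_distribution`: list with `flux` (named, signed),
#'   `objective_value` (biomass flux), `total_flux` (sum of |v|),
#'   `parsimonious` flag.
#' @examples
#' run_fba(make_toy_model(toy_spec("chain")))$objective_value
#' @export
run_fba <- function(model) {
  solve_flux(model, parsimonious = FALSE)
}

#' Parsimonious flux balance analysis (pFBA)
#'
#' Two-stage optimisation: maximise biomass, then minimise total flux
#' `sum_j |v_j|` while holding biomass at its optimum. Internally every
#' reaction is split into non-negative forward and reverse components, the
#' split problem is solved, and the components are re-merged, so the
#' returned fluxes are signed. Minimising total flux suppresses futile
#' cycles and represents efficient enzyme usage.
#'
#' Ties in total flux between alternate parsimonious optima are broken by
#' the solver's pivoting order; downstream code may rely on the objective
#' and the total flux being unique, but not on the flux vector itself.
#'
#' @inheritParams run_fba
#' @return a `flux_distribution` (see [run_fba()]) with
#'   `parsimonious = TRUE`.
#' @export
run_pfba <- function(model) {
  solve_flux(model, parsimonious = TRUE)
}

solve_flux <- function(model, parsimonious) {
  p <- lp_parts(model)
  res <- pfba_cpp(p$S, p$lb, p$ub, p$obj, parsimonious)
  if (res$status == 1L) stop("model '", model$id, "' is infeasible")
  if (res$status == 2L) stop("model '", model$id, "' has an unbounded objective; ",
                             "check bounds on ", model$objective)
  if (res$status != 0L) stop("LP solver failed with status ", res$status)
  # infinite bounds are clamped to FLUX_BIG before solving; an optimum at
  # that scale means the printed bounds do not actually bound the objective
  if (res$objective > 0.9 * FLUX_BIG)
    stop("model '", model$id, "' has an unbounded objective; ",
         "check bounds on ", model$objective)
  flux_distribution(setNames(res$flux, model$reactions$id),
                    res$objective, parsimonious)
}

flux_distribution <- function(flux, objective_value, parsimonious) {
  structure(list(flux = flux,
                 objective_value = objective_value,
                 total_flux = sum(abs(flux)),
                 parsimonious = parsimonious),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> ", if (x$parsimonious) "pFBA" else "FBA",
      "; objective = ", format(x$objective_value),
      ", total flux = ", format(x$total_flux), "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis (FVA)
#'
#' For every reaction, the minimum and maximum flux attainable while the
#' biomass objective stays at or above `fraction` of its optimum. The
#' default fraction of 0.95 is the one used to delimit allele spaces;
#' 0.90 and 0.99 are the tested alternatives.
#'
#' @inheritParams run_fba
#' @param fraction scalar in (0, 1]: required share of the optimal biomass.
#' @return a `flux_envelope`: data.frame with columns `id`, `min_flux`,
#'   `max_flux` plus attributes `fraction` and `optimum`.
#' @export
run_fva <- function(model, fraction = 0.95) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction <= 1)
  p <- lp_parts(model)
  opt <- run_fba(model)$objective_value
  env <- fva_cpp(p$S, p$lb, p$ub, p$obj, fraction, opt)
  out <- data.frame(id = model$reactions$id,
                    min_flux = env[, 1], max_flux = env[, 2],
                    stringsAsFactors = FALSE)
  # clip solver noise so min <= max holds exactly
  swap <- !is.na(out$min_flux) & out$min_flux > out$max_flux
  if (any(swap)) {
    mid <- (out$min_flux[swap] + out$max_flux[swap]) / 2
    out$min_flux[swap] <- mid
    out$max_flux[swap] <- mid
  }
  structure(out, fraction = fraction, optimum = opt,
            class = c("flux_envelope", "data.frame"))
}

#' Reactions coupled to biomass production
#'
#' A reaction is biomass-coupled when it must carry flux to sustain
#' near-optimal biomass production: the minimum of |v_j| over the feasible
#' set restricted to `biomass >= fraction * optimum` exceeds `tolerance`.
#' This is a directional-coupling criterion expressed directly as the FVA
#' sub-problem; see the methods vignette for why this definition was
#' chosen.
#'
#' @inheritParams run_fva
#' @param tolerance flux magnitude below which a reaction counts as
#'   able to be shut off.
#' @return character vector of coupled reaction ids.
#' @export
compute_biomass_coupling <- function(model, fraction = 0.95,
                                     tolerance = TOL_COMPARE) {
  env <- run_fva(model, fraction)
  # min |v| over the envelope: 0 when it straddles zero
  min_abs <- ifelse(env$min_flux > 0, env$min_flux,
                    ifelse(env$max_flux < 0, -env$max_flux, 0))
  env$id[!is.na(min_abs) & min_abs > tolerance]
}
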