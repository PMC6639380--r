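#' Reference flux distribution (RFD)
#'
#' Parsimonious FBA on the unconstrained model. The RFD anchors the whole
#' genetics layer: it fixes each reaction's working direction (which bound
#' a genetic capacity tightens) and its total flux is the normalisation
#' budget that gives every individual the same total metabolic capacity.
#'
#' @param model a `metabolic_model`.
#' @return a `flux_distribution` (see [run_pfba()]).
#' @export
build_reference <- function(model) {
  run_pfba(model)
}

#' Build per-locus allele spaces from an FVA envelope
#'
#' Each constrained locus (internal reaction) receives `levels` evenly
#' spaced candidate capacities spanning the absolute-flux range of its FVA
#' envelope restricted to the direction the reaction works in the RFD.
#' An allele is then a discrete-uniform draw from this set, emulating a
#' standing population purged of strongly sub-optimal variants by past
#' selection. Degenerate envelopes give a monomorphic single-value space
#' (with a warning).
#'
#' @param model a `metabolic_model`.
#' @param envelope a `flux_envelope` from [run_fva()] on `model`.
#' @param rfd the reference [flux_distribution] from [build_reference()].
#' @param levels integer >= 1: number of evenly spaced candidate values.
#' @return named list: locus id -> sorted numeric vector of candidate
#'   capacities (class `allele_space`).
#' @export
build_allele_space <- function(model, envelope, rfd, levels = 101L) {
  stopifnot(levels >= 1L)
  loci <- constrained_loci(model)
  if (!all(loci %in% envelope$id) || !all(loci %in% names(rfd$flux)))
    stop("envelope/rfd do not cover the model's constrained loci")
  env <- envelope[match(loci, envelope$id), ]
  mono <- character(0)
  space <- lapply(seq_along(loci), function(i) {
    v <- rfd$flux[[loci[i]]]
    mn <- env$min_flux[i]; mx <- env$max_flux[i]
    if (v >= TOL_COMPARE) {          # forward in the RFD
      lo <- max(mn, 0); hi <- max(mx, 0)
    } else if (v <= -TOL_COMPARE) {  # backward in the RFD
      lo <- max(-mx, 0); hi <- -mn
    } else {                         # RFD carries no flux: magnitudes
      lo <- if (mn <= 0 && mx >= 0) 0 else min(abs(mn), abs(mx))
      hi <- max(abs(mn), abs(mx))
    }
    if (hi < lo) hi <- lo
    if (hi - lo < TOL_COMPARE) {
      mono <<- c(mono, loci[i])
      return(mean(c(lo, hi)))
    }
    seq(lo, hi, length.out = levels)
  })
  if (length(mono))
    warning("monomorphic locus (degenerate FVA envelope): ",
            paste(mono, collapse = ", "))
  structure(setNames(space, loci), class = "allele_space")
}

new_genotype <- function(values, ploidy) {
  structure(values, ploidy = ploidy, class = "genotype")
}

#' Sample a founder genotype
#'
#' Every constrained locus receives `ploidy` independent uniform draws
#' (with replacement) from its candidate allele list, simulating a fully
#' heterozygous founder.
#'
#' @param allele_space from [build_allele_space()].
#' @param ploidy integer >= 2 (diploid default).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return a `genotype`: numeric matrix (loci x ploidy) with locus
#'   rownames and a `ploidy` attribute.
#' @export
sample_founder_genotype <- function(allele_space, ploidy = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(allele_space)
  vals <- matrix(0, nrow = n, ncol = ploidy,
                 dimnames = list(names(allele_space), NULL))
  for (i in seq_len(n)) {
    cand <- allele_space[[i]]
    vals[i, ] <- cand[sample.int(length(cand), ploidy, replace = TRUE)]
  }
  new_genotype(vals, ploidy)
}

#' Fraction of homozygous loci
#'
#' A locus is homozygous when all `ploidy` allele values at it are exactly
#' equal; alleles live on a finite grid, so value equality is exact.
#' Alleles are compared by value, not parental origin: two lines fixed for
#' the same value count as homozygous in their cross.
#'
#' @param genotype a `genotype`.
#' @return scalar in \[0, 1\].
#' @export
homozygosity_fraction <- function(genotype) {
  if (nrow(genotype) == 0L) return(1)
  mean(matrixStats_rowalleq(genotype))
}

matrixStats_rowalleq <- function(m) {
  if (ncol(m) == 2L) m[, 1L] == m[, 2L]
  else apply(m, 1L, function(r) all(r == r[1L]))
}

#' Derive enzyme capacities from a genotype
#'
#' Per locus, the capacity is the additive mean of its allele values,
#' rescaled by `lambda = min(1, T_RFD / T_raw)` so the summed capacity
#' never exceeds the summed absolute flux of the RFD. All individuals
#' therefore command a similar total metabolic capacity: phenotypic gains
#' must come from allocating it more efficiently, not from having more of
#' it. Capacities are never scaled up.
#'
#' @param genotype a `genotype`.
#' @param rfd the reference flux distribution of the lineage.
#' @return a `constraint_set`: list with `capacity` (named), `lambda`,
#'   and `direction` (sign of the RFD flux per locus, used to pick which
#'   bound the capacity tightens).
#' @export
derive_constraints <- function(genotype, rfd) {
  means <- rowMeans(genotype)
  t_rfd <- sum(abs(rfd$flux))
  t_raw <- sum(means)
  lambda <- if (t_raw > t_rfd && t_raw > 0) t_rfd / t_raw else 1
  dirs <- sign(rfd$flux[rownames(genotype)])
  dirs[abs(rfd$flux[rownames(genotype)]) < TOL_COMPARE] <- 0
  structure(list(capacity = means * lambda, lambda = lambda,
                 direction = dirs), class = "constraint_set")
}

# Closure caching the dense LP blocks of a model; the hot path for
# population evaluation (thousands of pFBA solves per breeding run).
make_evaluator <- function(model) {
  p <- lp_parts(model)
  loci <- constrained_loci(model)
  idx <- match(loci, model$reactions$id)
  rxn_ids <- model$reactions$id
  function(constraints) {
    cap <- unname(constraints$capacity[loci])
    dir <- unname(constraints$direction[loci])
    lb <- p$lb; ub <- p$ub
    fwd <- dir >= 0
    ub[idx[fwd]] <- pmin(ub[idx[fwd]], cap[fwd])
    bwd <- dir <= 0
    lb[idx[bwd]] <- pmax(lb[idx[bwd]], -cap[bwd])
    res <- pfba_cpp(p$S, lb, ub, p$obj, TRUE)
    if (res$status != 0L) {      # non-viable genotype, not an error
      return(structure(list(
        biomass_rate = 0,
        flux = setNames(rep(0, length(rxn_ids)), rxn_ids),
        total_flux = 0,
        efficiency = setNames(rep(NA_real_, length(loci)), loci),
        feasible = FALSE), class = "phenotype"))
    }
    flux <- setNames(res$flux, rxn_ids)
    eff <- abs(flux[loci]) / constraints$capacity[loci]
    eff[constraints$capacity[loci] <= TOL_COMPARE] <- NA_real_
    structure(list(biomass_rate = res$objective,
                   flux = flux,
                   total_flux = res$total_flux,
                   efficiency = eff,
                   feasible = TRUE), class = "phenotype")
  }
}

#' Evaluate an individual's phenotype
#'
#' Tightens the model's bounds with the genotype-derived capacities (on
#' the side of the reaction's RFD direction; both sides for reactions the
#' RFD leaves idle), runs parsimonious FBA, and reports the biomass rate,
#' the computed flux vector, and the per-locus efficiency
#' `|computed flux| / capacity`. An infeasible constrained model is a
#' non-viable genotype: it scores biomass 0 with `feasible = FALSE`
#' rather than raising an error, so selection can discard it.
#'
#' @param model a `metabolic_model`.
#' @param constraints a `constraint_set` from [derive_constraints()].
#' @return a `phenotype`: list with `biomass_rate`, `flux`, `total_flux`,
#'   `efficiency` (NA for near-zero capacities), `feasible`.
#' @export
evaluate_individual <- function(model, constraints) {
  make_evaluator(model)(constraints)
}

#' @export
print.phenotype <- function(x, ...) {
  cat("<phenotype> biomass = ", format(x$biomass_rate),
      if (!x$feasible) " (infeasible genotype)", "\n", sep = "")
  invisible(x)
}
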