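#' Mid-parent heterosis of one F1 individual
#'
#' The F1's biomass production rate divided by the mean of its two
#' parents' rates (the ratio), together with the absolute deviation
#' F1 - mid-parent on the flux scale. Ratio above 1 and deviation above 0
#' are equivalent statements of hybrid vigour.
#'
#' @param f1,parent_a,parent_b evaluated `individual`s.
#' @return a `heterosis_record`: list with `f1_id`, `parent_ids`,
#'   `midparent_ratio`, `absolute_deviation`, `f1_biomass`,
#'   `midparent_biomass`.
#' @export
midparent_heterosis <- function(f1, parent_a, parent_b) {
  mp <- (parent_a$phenotype$biomass_rate + parent_b$phenotype$biomass_rate) / 2
  if (mp <= TOL_COMPARE)
    stop("mid-parent biomass is zero; heterosis ratio undefined")
  b <- f1$phenotype$biomass_rate
  structure(list(f1_id = f1$id,
                 parent_ids = c(parent_a$id, parent_b$id),
                 midparent_ratio = b / mp,
                 absolute_deviation = b - mp,
                 f1_biomass = b, midparent_biomass = mp),
            class = "heterosis_record")
}

#' Heterosis records for a whole F1 population
#'
#' Looks each F1's parents up in the two parental line populations and
#' computes [midparent_heterosis()] per individual.
#'
#' @param f1_pop an F1 `population` from [produce_f1()].
#' @param line_a,line_b the parental `population`s.
#' @return data.frame: `f1_id`, `parent_a`, `parent_b`,
#'   `midparent_ratio`, `absolute_deviation`, `f1_biomass`.
#' @export
heterosis_records <- function(f1_pop, line_a, line_b) {
  lut <- c(setNames(line_a$individuals,
                    vapply(line_a$individuals, function(i) i$id, "")),
           setNames(line_b$individuals,
                    vapply(line_b$individuals, function(i) i$id, "")))
  rows <- lapply(f1_pop$individuals, function(ind) {
    rec <- midparent_heterosis(ind, lut[[ind$parent_ids[1L]]],
                               lut[[ind$parent_ids[2L]]])
    data.frame(f1_id = rec$f1_id, parent_a = rec$parent_ids[1L],
               parent_b = rec$parent_ids[2L],
               midparent_ratio = rec$midparent_ratio,
               absolute_deviation = rec$absolute_deviation,
               f1_biomass = rec$f1_biomass, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Single-locus substitution scan of an F1 individual
#'
#' For every constrained locus in turn, the F1 is made homozygous for the
#' allele inherited from each parent (genotype slot 1 = parent A, slot 2 =
#' parent B, as recorded by [cross()]), its constraints are re-derived --
#' including renormalisation, unless `frozen_lambda` -- and its biomass is
#' recomputed; all other loci are untouched. The locus's direct
#' contribution to heterosis is the F1 biomass minus the mean of the two
#' substituted biomasses. Loci at which both parents transmitted the same
#' value are exact no-ops.
#'
#' @param f1 an evaluated F1 `individual` with parental-origin slots.
#' @param ctx a [sim_context()].
#' @param frozen_lambda keep the F1's normalisation factor instead of
#'   renormalising after each substitution.
#' @return data.frame, one row per locus: `locus`, `delta_parent_a`,
#'   `delta_parent_b` (biomass change when homozygous for that parent's
#'   allele), `direct_contribution`.
#' @export
locus_substitution_scan <- function(f1, ctx, frozen_lambda = FALSE) {
  g <- f1$genotype
  if (is.null(rownames(g)) || attr(g, "ploidy") != 2L)
    stop("substitution scan needs a diploid genotype with locus names")
  b0 <- f1$phenotype$biomass_rate
  lam0 <- derive_constraints(g, ctx$rfd)$lambda
  n <- nrow(g)
  d_a <- d_b <- numeric(n)
  for (i in seq_len(n)) {
    if (g[i, 1L] == g[i, 2L]) next  # homozygous: substitution is a no-op
    for (p in 1:2) {
      g2 <- g
      g2[i, ] <- g[i, p]
      cs <- derive_constraints(g2, ctx$rfd)
      if (frozen_lambda) {
        cs$capacity <- rowMeans(g2) * lam0
        cs$lambda <- lam0
      }
      b <- ctx$evaluate(cs)$biomass_rate
      if (p == 1L) d_a[i] <- b - b0 else d_b[i] <- b - b0
    }
  }
  data.frame(locus = rownames(g), delta_parent_a = d_a, delta_parent_b = d_b,
             direct_contribution = -(d_a + d_b) / 2,
             stringsAsFactors = FALSE)
}

#' Decompose heterosis into single- and multi-locus components
#'
#' The summed direct (single-locus) contributions are subtracted from the
#' overall heterotic deviation; the residual is the multi-locus
#' (epistatic) component. The identity
#' `overall = single_locus_sum + multi_locus` holds exactly because the
#' residual is defined by it. Decomposition is done on the absolute
#' deviation (flux units), where additivity is well defined; the ratio is
#' carried alongside.
#'
#' @param record a `heterosis_record` (or one row of
#'   [heterosis_records()]).
#' @param contributions the scan data.frame from
#'   [locus_substitution_scan()] of the same F1.
#' @return list with `overall`, `single_locus_sum`, `multi_locus`,
#'   `midparent_ratio`.
#' @export
decompose_heterosis <- function(record, contributions) {
  overall <- record$absolute_deviation
  singles <- sum(contributions$direct_contribution)
  list(overall = overall,
       single_locus_sum = singles,
       multi_locus = overall - singles,
       midparent_ratio = record$midparent_ratio)
}

#' Correlation between heterosis and per-reaction flux
#'
#' Pearson correlation, across the individuals of an F1 population,
#' between each individual's mid-parent heterosis ratio and its computed
#' flux through each reaction. Reactions with zero flux variance are
#' undefined and reported as `NA` (not 0).
#'
#' @param f1_pop an F1 `population`.
#' @param records matching [heterosis_records()] data.frame.
#' @return named numeric vector: reaction id -> Pearson r (NA where
#'   undefined).
#' @export
flux_heterosis_correlation <- function(f1_pop, records) {
  if (length(f1_pop$individuals) < 3L)
    stop("need at least 3 individuals to estimate correlations")
  ids <- vapply(f1_pop$individuals, function(i) i$id, "")
  h <- records$midparent_ratio[match(ids, records$f1_id)]
  if (anyNA(h)) stop("records do not cover the F1 population")
  if (var(h) <= 0)
    stop("no variance in heterosis across the population")
  fx <- t(vapply(f1_pop$individuals, function(i) i$phenotype$flux,
                 numeric(length(f1_pop$individuals[[1L]]$phenotype$flux))))
  r <- suppressWarnings(as.vector(cor(h, fx)))
  r[apply(fx, 2L, var) <= 0] <- NA_real_
  setNames(r, colnames(fx))
}

#' Reaction-efficiency profile of a population
#'
#' Pools the per-locus efficiencies (|computed flux| / enzyme capacity)
#' of all individuals and summarises the near-saturated tail. Loci with
#' (near-)zero capacity have undefined efficiency and are excluded.
#'
#' @param population an evaluated `population`.
#' @param tail_threshold efficiency above which a reaction counts as
#'   operating near maximal efficiency.
#' @param breaks histogram break points on \[0, 1\].
#' @return list with `efficiencies` (pooled vector), `tail_fraction`
#'   (share above `tail_threshold`), `histogram` (data.frame of bin
#'   mid-points and counts).
#' @export
efficiency_profile <- function(population, tail_threshold = 0.95,
                               breaks = seq(0, 1, by = 0.05)) {
  eff <- unlist(lapply(population$individuals,
                       function(i) i$phenotype$efficiency), use.names = FALSE)
  eff <- eff[!is.na(eff)]
  eff_clipped <- pmin(eff, 1)  # solver noise just above 1
  h <- graphics::hist(eff_clipped, breaks = breaks, plot = FALSE)
  list(efficiencies = eff,
       tail_fraction = if (length(eff)) mean(eff > tail_threshold) else NA_real_,
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Classify reactions by coupling, correlation and contribution
#'
#' Cross-tabulates three reaction sets -- biomass-coupled, flux-correlated
#' with heterosis, and directly contributing to heterosis -- into a
#' membership table and the seven Venn-region counts.
#'
#' @param coupled,correlated,contributing character vectors of reaction
#'   ids.
#' @return list with `table` (data.frame: id + three logical columns) and
#'   `venn` (named counts: `coupled_only`, `correlated_only`,
#'   `contributing_only`, `coupled_correlated`, `coupled_contributing`,
#'   `correlated_contributing`, `all_three`).
#' @export
classify_reactions <- function(coupled, correlated, contributing) {
  ids <- sort(unique(c(coupled, correlated, contributing)))
  tab <- data.frame(id = ids,
                    coupled = ids %in% coupled,
                    correlated = ids %in% correlated,
                    contributing = ids %in% contributing,
                    stringsAsFactors = FALSE)
  key <- paste0(as.integer(tab$coupled), as.integer(tab$correlated),
                as.integer(tab$contributing))
  venn <- c(coupled_only = sum(key == "100"),
            correlated_only = sum(key == "010"),
            contributing_only = sum(key == "001"),
            coupled_correlated = sum(key == "110"),
            coupled_contributing = sum(key == "101"),
            correlated_contributing = sum(key == "011"),
            all_three = sum(key == "111"))
  list(table = tab, venn = venn)
}

#' Loci with a direct contribution to heterosis across a population
#'
#' A locus counts as contributing when the variance of its direct
#' contribution across the scanned F1 individuals exceeds `threshold`.
#'
#' @param scans list of [locus_substitution_scan()] results (one per F1).
#' @param threshold variance threshold (default 1e-8).
#' @return character vector of locus ids.
#' @export
contributing_loci <- function(scans, threshold = 1e-8) {
  if (!length(scans)) return(character(0))
  loci <- scans[[1L]]$locus
  contrib <- vapply(scans, function(s)
    s$direct_contribution[match(loci, s$locus)], numeric(length(loci)))
  v <- apply(matrix(contrib, nrow = length(loci)), 1L, var)
  loci[!is.na(v) & v > threshold]
}
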