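#' Prepare a simulation context for breeding experiments
#'
#' Computes, once per model, everything the breeding loop needs: the
#' reference flux distribution (pFBA on the unconstrained model), the FVA
#' envelope at `fva_fraction`, the per-locus allele spaces, and a cached
#' phenotype evaluator.
#'
#' @param model a `metabolic_model`.
#' @param fva_fraction minimum share of optimal biomass for FVA (default
#'   0.95, the fraction used for allele generation).
#' @param levels number of discrete allele values per locus.
#' @return a `sim_context` list: `model`, `rfd`, `envelope`,
#'   `allele_space`, `evaluate` (function of a `constraint_set`).
#' @export
sim_context <- function(model, fva_fraction = 0.95, levels = 101L) {
  rfd <- build_reference(model)
  envelope <- run_fva(model, fva_fraction)
  allele_space <- build_allele_space(model, envelope, rfd, levels)
  structure(list(model = model, rfd = rfd, envelope = envelope,
                 allele_space = allele_space,
                 evaluate = make_evaluator(model)),
            class = "sim_context")
}

evaluate_genotype <- function(ctx, genotype) {
  ctx$evaluate(derive_constraints(genotype, ctx$rfd))
}

new_individual <- function(id, genotype, phenotype, parent_ids, line_id,
                           generation) {
  structure(list(id = id, genotype = genotype, phenotype = phenotype,
                 parent_ids = parent_ids, line_id = line_id,
                 generation = generation), class = "individual")
}

new_population <- function(individuals, generation_index, line_id,
                           seed = NA_integer_) {
  structure(list(individuals = individuals,
                 generation_index = generation_index,
                 line_id = line_id, seed = seed), class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("<population> line ", x$line_id, ", generation ", x$generation_index,
      ", ", length(x$individuals), " individuals\n", sep = "")
  b <- pop_biomass(x)
  cat("  biomass: mean ", format(mean(b)), ", max ", format(max(b)),
      "; mean homozygosity ", format(round(mean(pop_homozygosity(x)), 3)),
      "\n", sep = "")
  invisible(x)
}

#' Per-individual biomass rates / homozygosity of a population
#' @param population a `population`.
#' @return numeric vector, one entry per individual.
#' @export
pop_biomass <- function(population) {
  vapply(population$individuals, function(i) i$phenotype$biomass_rate, 0)
}

#' @rdname pop_biomass
#' @export
pop_homozygosity <- function(population) {
  vapply(population$individuals, function(i) homozygosity_fraction(i$genotype), 0)
}

#' One-row summary of a population
#' @param population a `population`.
#' @return data.frame: line, generation, size, mean/max biomass,
#'   mean homozygosity.
#' @export
population_summary <- function(population) {
  b <- pop_biomass(population)
  data.frame(line_id = population$line_id,
             generation = population$generation_index,
             size = length(population$individuals),
             mean_biomass = mean(b), max_biomass = max(b),
             mean_homozygosity = mean(pop_homozygosity(population)),
             stringsAsFactors = FALSE)
}

#' Found a fully heterozygous population
#'
#' Each founder draws `ploidy` independent alleles per locus from the
#' context's allele space, and is evaluated immediately.
#'
#' @param ctx a [sim_context()].
#' @param size number of individuals.
#' @param line_id line label.
#' @param ploidy integer >= 2.
#' @param seed optional integer seed.
#' @return a `population` of generation 0.
#' @export
found_population <- function(ctx, size, line_id = "L1", ploidy = 2L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inds <- lapply(seq_len(size), function(i) {
    g <- sample_founder_genotype(ctx$allele_space, ploidy)
    new_individual(sprintf("%s_g000_i%04d", line_id, i), g,
                   evaluate_genotype(ctx, g),
                   parent_ids = c(NA_character_, NA_character_),
                   line_id = line_id, generation = 0L)
  })
  new_population(inds, 0L, line_id, seed %||% NA_integer_)
}

#' Cross two individuals
#'
#' Mendelian transmission with free recombination: at every locus one
#' allele is chosen uniformly from each parent, independently across loci;
#' no linkage, no mutation. Offspring slot 1 carries the allele inherited
#' from `parent_a`, slot 2 the one from `parent_b` (this records parental
#' origin for the substitution scan).
#'
#' @param parent_a,parent_b `individual`s sharing the same locus set.
#' @param seed optional integer seed.
#' @return the offspring `genotype`.
#' @export
cross <- function(parent_a, parent_b, seed = NULL) {
  ga <- parent_a$genotype; gb <- parent_b$genotype
  if (!identical(rownames(ga), rownames(gb)))
    stop("parents have mismatched locus sets")
  if (attr(ga, "ploidy") != 2L || attr(gb, "ploidy") != 2L)
    stop("cross() is defined for diploid parents")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ga)
  picks <- sample.int(2L, 2L * n, replace = TRUE)
  vals <- cbind(ga[cbind(seq_len(n), picks[seq_len(n)])],
                gb[cbind(seq_len(n), picks[n + seq_len(n)])])
  rownames(vals) <- rownames(ga)
  new_genotype(vals, 2L)
}

#' Truncation selection
#'
#' Keeps the `ceiling(fraction * size)` individuals with the highest
#' biomass production rate; ties are broken by individual id so selection
#' is stable and reproducible.
#'
#' @param population an evaluated `population`.
#' @param fraction scalar in (0, 1].
#' @param require_pairs error if fewer than 2 survivors (needed when the
#'   survivors must be crossed without selfing).
#' @return list of selected `individual`s, best first.
#' @export
truncation_select <- function(population, fraction, require_pairs = FALSE) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(population$individuals)
  k <- ceiling(fraction * n)
  if (require_pairs && k < 2L)
    stop("selection would keep fewer than 2 parents; ",
         "increase the fraction or allow selfing")
  b <- pop_biomass(population)
  ids <- vapply(population$individuals, function(i) i$id, "")
  population$individuals[order(-b, ids)[seq_len(k)]]
}

#' Produce the next generation from a parent pool
#'
#' Each offspring results from a cross between a uniformly drawn pair of
#' distinct parents, or, when `allow_selfing = TRUE`, from selfing one
#' uniformly drawn parent (the mode used in the heterosis-fixation
#' experiment). Offspring are evaluated on creation.
#'
#' @param parents list of `individual`s (>= 2 unless selfing).
#' @param size number of offspring.
#' @param ctx a [sim_context()].
#' @param allow_selfing logical; see above.
#' @param line_id,generation metadata for the new population.
#' @param seed optional integer seed.
#' @return a `population`.
#' @export
make_offspring_generation <- function(parents, size, ctx,
                                      allow_selfing = FALSE,
                                      line_id = parents[[1]]$line_id,
                                      generation = parents[[1]]$generation + 1L,
                                      seed = NULL) {
  if (!allow_selfing && length(parents) < 2L)
    stop("need at least 2 distinct parents when selfing is disallowed")
  if (!is.null(seed)) set.seed(seed)
  np <- length(parents)
  inds <- lapply(seq_len(size), function(i) {
    if (allow_selfing) {
      pa <- pb <- parents[[sample.int(np, 1L)]]
    } else {
      pr <- sample.int(np, 2L, replace = FALSE)
      pa <- parents[[pr[1L]]]; pb <- parents[[pr[2L]]]
    }
    g <- cross(pa, pb)
    new_individual(sprintf("%s_g%03d_i%04d", line_id, generation, i), g,
                   evaluate_genotype(ctx, g),
                   parent_ids = c(pa$id, pb$id),
                   line_id = line_id, generation = generation)
  })
  new_population(inds, generation, line_id, seed %||% NA_integer_)
}

#' Selection/breeding configuration
#'
#' Defaults follow the reference breeding design: 500 individuals per
#' generation, top 5% selected, 50 generations, 30% of a line sampled as
#' F1/F2 parents, selfing prevented.
#'
#' @param population_size individuals per generation.
#' @param selection_fraction share selected as parents.
#' @param generations number of selection generations.
#' @param f1_parent_sample_fraction share of a line sampled when making
#'   F1/F2 populations.
#' @param allow_selfing logical.
#' @param seed optional integer root seed.
#' @return a `selection_config` list.
#' @export
selection_config <- function(population_size = 500L,
                             selection_fraction = 0.05,
                             generations = 50L,
                             f1_parent_sample_fraction = 0.30,
                             allow_selfing = FALSE,
                             seed = NULL) {
  stopifnot(selection_fraction > 0, selection_fraction <= 1,
            population_size >= 1, generations >= 0,
            f1_parent_sample_fraction > 0, f1_parent_sample_fraction <= 1)
  if (!allow_selfing &&
      ceiling(population_size * selection_fraction) < 2L)
    stop("config error: population_size * selection_fraction must keep ",
         ">= 2 parents when selfing is disallowed")
  structure(list(population_size = as.integer(population_size),
                 selection_fraction = selection_fraction,
                 generations = as.integer(generations),
                 f1_parent_sample_fraction = f1_parent_sample_fraction,
                 allow_selfing = allow_selfing,
                 seed = seed), class = "selection_config")
}

#' Multi-generation inbreeding under truncation selection
#'
#' Iterates rank-by-biomass truncation selection and random crossing among
#' the selected parents for `config$generations` generations. With an
#' intense selection fraction the line is driven towards homozygosity
#' while mean biomass rises and then plateaus.
#'
#' @param founders an evaluated founder `population`.
#' @param ctx a [sim_context()].
#' @param config a [selection_config()].
#' @return list of `population`s (founders first, one per generation),
#'   with a `summary` attribute: one row per generation (mean/max biomass,
#'   mean homozygosity).
#' @export
run_inbreeding <- function(founders, ctx, config) {
  lineage <- vector("list", config$generations + 1L)
  lineage[[1L]] <- founders
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- founders
  for (g in seq_len(config$generations)) {
    parents <- truncation_select(pop, config$selection_fraction,
                                 require_pairs = !config$allow_selfing)
    pop <- make_offspring_generation(parents, config$population_size, ctx,
                                     allow_selfing = config$allow_selfing,
                                     line_id = founders$line_id,
                                     generation = g)
    lineage[[g + 1L]] <- pop
  }
  attr(lineage, "summary") <- do.call(rbind, lapply(lineage, population_summary))
  lineage
}

#' Produce an F1 population from two inbred lines
#'
#' Samples `sample_fraction` of each line (without replacement) and draws
#' each F1's two parents from the two samples; parent pairs may repeat.
#' The two lines must be distinct.
#'
#' @param line_a,line_b evaluated `population`s with different `line_id`s.
#' @param ctx a [sim_context()].
#' @param n number of F1 individuals.
#' @param sample_fraction share of each line eligible as parents.
#' @param seed optional integer seed.
#' @return a `population`; each individual's genotype slot 1 derives from
#'   `line_a`, slot 2 from `line_b`.
#' @export
produce_f1 <- function(line_a, line_b, ctx, n = 500L, sample_fraction = 0.30,
                       seed = NULL) {
  if (identical(line_a$line_id, line_b$line_id))
    stop("config error: F1 parents must come from two distinct lines")
  if (!is.null(seed)) set.seed(seed)
  pick <- function(pop) {
    k <- max(1L, ceiling(sample_fraction * length(pop$individuals)))
    pop$individuals[sample.int(length(pop$individuals), k)]
  }
  sa <- pick(line_a); sb <- pick(line_b)
  lid <- paste0(line_a$line_id, "x", line_b$line_id)
  inds <- lapply(seq_len(n), function(i) {
    pa <- sa[[sample.int(length(sa), 1L)]]
    pb <- sb[[sample.int(length(sb), 1L)]]
    g <- cross(pa, pb)
    new_individual(sprintf("%s_F1_i%04d", lid, i), g,
                   evaluate_genotype(ctx, g), c(pa$id, pb$id), lid,
                   generation = 1L)
  })
  pop <- new_population(inds, 1L, lid, seed %||% NA_integer_)
  attr(pop, "parent_samples") <- list(a = vapply(sa, function(x) x$id, ""),
                                      b = vapply(sb, function(x) x$id, ""))
  pop
}

#' Produce an F2 population from an F1 population
#'
#' Samples `sample_fraction` of the F1s and crosses distinct pairs within
#' the sample (no selfing) until `n` F2s exist.
#'
#' @param f1_pop an evaluated F1 `population`.
#' @inheritParams produce_f1
#' @return a `population`.
#' @export
produce_f2 <- function(f1_pop, ctx, n = 500L, sample_fraction = 0.30,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(new_population(list(), 2L, f1_pop$line_id,
                                     seed %||% NA_integer_))
  k <- max(2L, ceiling(sample_fraction * length(f1_pop$individuals)))
  if (length(f1_pop$individuals) < 2L)
    stop("config error: need at least 2 F1 individuals to make F2s")
  subset <- f1_pop$individuals[sample.int(length(f1_pop$individuals),
                                          min(k, length(f1_pop$individuals)))]
  inds <- lapply(seq_len(n), function(i) {
    pr <- sample.int(length(subset), 2L, replace = FALSE)
    pa <- subset[[pr[1L]]]; pb <- subset[[pr[2L]]]
    g <- cross(pa, pb)
    new_individual(sprintf("%s_F2_i%04d", f1_pop$line_id, i), g,
                   evaluate_genotype(ctx, g), c(pa$id, pb$id),
                   f1_pop$line_id, generation = 2L)
  })
  new_population(inds, 2L, f1_pop$line_id, seed %||% NA_integer_)
}

#' All pairwise crosses between inbred lines
#'
#' @param lines list of `population`s (or a character vector of line ids).
#' @return data.frame with columns `line_a`, `line_b`: all unordered
#'   distinct pairs in deterministic order; 40 lines give 780 pairs.
#' @export
pairwise_cross_schedule <- function(lines) {
  ids <- if (is.character(lines)) lines
         else vapply(lines, function(p) p$line_id, "")
  if (length(ids) < 2L) stop("need at least 2 lines")
  if (anyDuplicated(ids)) stop("duplicate line ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  prs <- combn(ids, 2L)
  data.frame(line_a = prs[1L, ], line_b = prs[2L, ], stringsAsFactors = FALSE)
}

#' Recurrent selection to fix heterosis in inbred descendants of an F1
#'
#' Mirrors the hybrid-mimic design: one F1 is selfed into a large F2
#' collection; founder F2s (best-ranked in the `selected` arm, uniformly
#' drawn in the `random` arm) each start a selfing lineage in which every
#' generation `select_fraction` of the population is kept (by biomass or
#' at random, per arm) and selfed to produce the next one, through
#' generation F(2 + generations).
#'
#' @param f1 an evaluated `individual` (typically a heterotic F1).
#' @param ctx a [sim_context()].
#' @param n_f2 size of the initial selfed F2 collection (reference design: 1000).
#' @param n_founders founders per arm (reference design: 10).
#' @param pop_size individuals per lineage generation (reference design: 500).
#' @param select_fraction share selected and selfed each generation
#'   (reference design: 0.02).
#' @param generations generations after the F2 (reference design: 9, i.e. F3..F11).
#' @param seed optional integer seed.
#' @return list with `f2` (the F2 population), arms `selected` and
#'   `random` (lists of lineages; a lineage is a list of `population`s),
#'   `summary` (per arm/lineage/generation statistics) and `allele_freq`
#'   (long data.frame of per-locus parental-allele frequencies; loci where
#'   the F1 inherited the same value from both parents are NA).
#' @export
fixation_experiment <- function(f1, ctx, n_f2 = 1000L, n_founders = 10L,
                                pop_size = 500L, select_fraction = 0.02,
                                generations = 9L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a_allele <- f1$genotype[, 1L]
  b_allele <- f1$genotype[, 2L]
  informative <- a_allele != b_allele

  f2 <- make_offspring_generation(list(f1), n_f2, ctx, allow_selfing = TRUE,
                                  line_id = paste0(f1$line_id, "_fix"),
                                  generation = 2L)
  ranked <- truncation_select(f2, 1.0)
  top <- ranked[seq_len(n_founders)]
  rnd <- f2$individuals[sample.int(length(f2$individuals), n_founders)]

  run_arm <- function(founders_arm, by_rate, arm_name) {
    lapply(seq_along(founders_arm), function(li) {
      pop <- make_offspring_generation(
        list(founders_arm[[li]]), pop_size, ctx, allow_selfing = TRUE,
        line_id = sprintf("%s_%s%02d", f1$line_id, arm_name, li),
        generation = 3L)
      lineage <- list(pop)
      for (g in seq_len(generations - 1L)) {
        k <- max(1L, ceiling(select_fraction * pop_size))
        sel <- if (by_rate) truncation_select(pop, select_fraction)
               else pop$individuals[sample.int(length(pop$individuals), k)]
        pop <- make_offspring_generation(sel, pop_size, ctx,
                                         allow_selfing = TRUE,
                                         line_id = pop$line_id,
                                         generation = pop$generation_index + 1L)
        lineage <- c(lineage, list(pop))
      }
      lineage
    })
  }
  selected <- run_arm(top, TRUE, "sel")
  random <- run_arm(rnd, FALSE, "rnd")

  freq_a <- function(pop) {
    fr <- vapply(pop$individuals, function(ind)
      rowMeans(ind$genotype == a_allele), numeric(length(a_allele)))
    out <- rowMeans(fr)
    out[!informative] <- NA_real_
    out
  }
  collect <- function(arm, arm_name) {
    do.call(rbind, lapply(seq_along(arm), function(li)
      do.call(rbind, lapply(arm[[li]], function(pop) {
        s <- population_summary(pop)
        s$arm <- arm_name; s$lineage <- li
        s$generation_label <- paste0("F", pop$generation_index)
        s
      }))))
  }
  afreq <- do.call(rbind, unlist(lapply(c("selected", "random"), function(an) {
    arm <- if (an == "selected") selected else random
    lapply(seq_along(arm), function(li)
      do.call(rbind, lapply(arm[[li]], function(pop) {
        fa <- freq_a(pop)
        data.frame(arm = an, lineage = li,
                   generation = pop$generation_index,
                   locus = names(fa), freq_parent_a = unname(fa),
                   stringsAsFactors = FALSE)
      })))
  }), recursive = FALSE))

  list(f2 = f2, selected = selected, random = random,
       summary = rbind(collect(selected, "selected"),
                       collect(random, "random")),
       allele_freq = afreq)
}
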