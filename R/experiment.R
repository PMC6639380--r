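#' Build an experiment configuration
#'
#' Accepts a named list (or nothing, for all defaults) and fills in the
#' reference breeding design: FVA fraction 0.95, 500 individuals per
#' generation, top 5% selected over 50 generations, 30% parent sampling,
#' 40 lines. Tests and examples override the sizes downwards.
#'
#' @param config named list; recognised fields: `model` (path to a model
#'   file) or `toy` (list with `topology` and topology parameters),
#'   `fva_fraction`, `allele_levels`, `n_lines`, `f1_size`, `f2_size`,
#'   `scan_sample` (number of F1s per cross given a substitution scan; 0
#'   disables scans), `correlation_threshold`, `selection` (fields of
#'   [selection_config()]), `output_dir`, `seed`.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(config = list()) {
  defaults <- list(model = NULL,
                   toy = list(topology = "parallel_paths",
                              capacities = c(4, 4, 4, 4),
                              path_length = 6L, input = 10),
                   fva_fraction = 0.95,
                   allele_levels = 101L,
                   n_lines = 40L,
                   f1_size = 500L,
                   f2_size = 500L,
                   scan_sample = 0L,
                   correlation_threshold = 0.90,
                   selection = list(),
                   output_dir = NULL,
                   seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("config error: unknown field(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(cfg$model) && !file.exists(cfg$model))
    stop("config error: model file not found: ", cfg$model)
  cfg$selection <- do.call(selection_config, cfg$selection)
  if (cfg$n_lines < 2L) stop("config error: need at least 2 lines")
  structure(cfg, class = "experiment_config")
}

#' Run a complete breeding-and-analysis experiment
#'
#' End-to-end workflow: build or load the model, prepare the simulation
#' context, inbreed `n_lines` independent lines, produce F1 and F2
#' populations for every pairwise cross, quantify heterosis, optionally
#' run substitution scans and the single/multi-locus decomposition,
#' profile efficiencies, and classify reactions. Everything is seeded
#' hierarchically from `config$seed`, so re-running the same config
#' reproduces the archive bit for bit.
#'
#' @param config an [experiment_config()] (or the list it accepts).
#' @return invisibly, a list: `config`, `model`, `ctx`, `lines` (final
#'   populations), `line_summaries`, `schedule`, `crosses` (per pair:
#'   `f1`, `f2`, `records`, `scans`, `decomposition`, `efficiency`),
#'   `correlated`, `coupled`, `contributing`, `classification`,
#'   `manifest`. Written as CSV/JSON under `config$output_dir` when set.
#' @export
run_experiment <- function(config = experiment_config()) {
  if (!inherits(config, "experiment_config"))
    config <- experiment_config(config)
  model <- if (!is.null(config$model)) load_model(config$model)
           else make_toy_model(do.call(toy_spec, config$toy))
  ctx <- sim_context(model, config$fva_fraction, config$allele_levels)

  lines <- vector("list", config$n_lines)
  line_summaries <- vector("list", config$n_lines)
  for (i in seq_len(config$n_lines)) {
    lid <- sprintf("L%02d", i)
    founders <- found_population(ctx, config$selection$population_size, lid,
                                 seed = derive_seed(config$seed, 1L, i))
    sel_cfg <- config$selection
    sel_cfg$seed <- derive_seed(config$seed, 2L, i)
    lineage <- run_inbreeding(founders, ctx, sel_cfg)
    lines[[i]] <- lineage[[length(lineage)]]
    s <- attr(lineage, "summary")
    s$line_id <- lid
    line_summaries[[i]] <- s
  }
  names(lines) <- vapply(lines, function(p) p$line_id, "")
  schedule <- pairwise_cross_schedule(lines)

  crosses <- vector("list", nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    la <- lines[[schedule$line_a[k]]]
    lb <- lines[[schedule$line_b[k]]]
    f1 <- produce_f1(la, lb, ctx, config$f1_size,
                     config$selection$f1_parent_sample_fraction,
                     seed = derive_seed(config$seed, 3L, k))
    f2 <- produce_f2(f1, ctx, config$f2_size,
                     config$selection$f1_parent_sample_fraction,
                     seed = derive_seed(config$seed, 4L, k))
    records <- heterosis_records(f1, la, lb)
    scans <- if (config$scan_sample > 0L) {
      take <- seq_len(min(config$scan_sample, length(f1$individuals)))
      lapply(f1$individuals[take],
             function(ind) locus_substitution_scan(ind, ctx))
    } else list()
    decomposition <- if (length(scans)) {
      do.call(rbind, lapply(seq_along(scans), function(j) {
        d <- decompose_heterosis(records[j, ], scans[[j]])
        data.frame(f1_id = records$f1_id[j], overall = d$overall,
                   single_locus_sum = d$single_locus_sum,
                   multi_locus = d$multi_locus,
                   midparent_ratio = d$midparent_ratio,
                   stringsAsFactors = FALSE)
      }))
    } else NULL
    eff <- list(parent_a = efficiency_profile(la),
                parent_b = efficiency_profile(lb),
                f1 = efficiency_profile(f1),
                f2 = efficiency_profile(f2))
    corr <- tryCatch(flux_heterosis_correlation(f1, records),
                     error = function(e) NULL)
    crosses[[k]] <- list(pair = unlist(schedule[k, ]), f1 = f1, f2 = f2,
                         records = records, scans = scans,
                         decomposition = decomposition,
                         efficiency = eff, correlation = corr)
  }

  thr <- config$correlation_threshold
  correlated <- sort(unique(unlist(lapply(crosses, function(cr)
    if (!is.null(cr$correlation))
      names(cr$correlation)[!is.na(cr$correlation) &
                            abs(cr$correlation) > thr]))))
  coupled <- compute_biomass_coupling(model, config$fva_fraction)
  contributing <- contributing_loci(unlist(lapply(crosses, `[[`, "scans"),
                                           recursive = FALSE))
  classification <- classify_reactions(coupled, correlated, contributing)

  manifest <- list(package_version = as.character(utils::packageVersion("heterosim")),
                   seed = config$seed,
                   model_id = model$id,
                   n_lines = config$n_lines,
                   n_crosses = nrow(schedule),
                   individuals_per_generation =
                     nrow(schedule) * config$f1_size,
                   fva_fraction = config$fva_fraction,
                   selection = unclass(config$selection))

  result <- list(config = config, model = model, ctx = ctx, lines = lines,
                 line_summaries = do.call(rbind, line_summaries),
                 schedule = schedule, crosses = crosses,
                 correlated = correlated, coupled = coupled,
                 contributing = contributing,
                 classification = classification, manifest = manifest)
  if (!is.null(config$output_dir)) write_experiment(result, config$output_dir)
  invisible(result)
}

write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- result$config
  cfg$selection <- unclass(cfg$selection)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(result$line_summaries, file.path(dir, "line_summaries.csv"),
            row.names = FALSE)
  write.csv(result$schedule, file.path(dir, "schedule.csv"), row.names = FALSE)
  recs <- do.call(rbind, lapply(result$crosses, function(cr) {
    r <- cr$records
    r$line_a <- cr$pair[[1]]; r$line_b <- cr$pair[[2]]
    r
  }))
  write.csv(recs, file.path(dir, "heterosis_records.csv"), row.names = FALSE)
  pops <- do.call(rbind, lapply(result$crosses, function(cr)
    rbind(population_summary(cr$f1), population_summary(cr$f2))))
  write.csv(pops, file.path(dir, "cross_populations.csv"), row.names = FALSE)
  decomp <- do.call(rbind, lapply(result$crosses, `[[`, "decomposition"))
  if (!is.null(decomp))
    write.csv(decomp, file.path(dir, "decomposition.csv"), row.names = FALSE)
  jsonlite::write_json(list(venn = as.list(result$classification$venn),
                            coupled = result$coupled,
                            correlated = result$correlated,
                            contributing = result$contributing),
                       file.path(dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(result$classification$table, file.path(dir, "classification.csv"),
            row.names = FALSE)
  invisible(dir)
}
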