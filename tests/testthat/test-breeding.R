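# Crosses, selection, inbreeding, F1/F2 production, fixation.

test_that("crossing transmits one allele per parent, Mendelian ratios", {
  ctx <- sim_context(fix_bottleneck())
  pa <- make_homozygote(ctx, c(R1 = 1, R2 = 1), "pa", "A")
  pb <- make_homozygote(ctx, c(R1 = 2, R2 = 2), "pb", "B")
  for (i in 1:5) {
    g <- cross(pa, pb)
    expect_equal(unname(g[, 1]), c(1, 1))  # slot 1 always from parent A
    expect_equal(unname(g[, 2]), c(2, 2))
  }
  expect_equal(homozygosity_fraction(cross(pa, pb)), 0)

  # heterozygote x heterozygote: the four ordered combinations are 1/4 each
  het <- pa
  het$genotype[, 2] <- c(2, 2)
  set.seed(21)
  off <- replicate(10000, cross(het, het)["R1", ])
  counts <- table(factor(paste(off[1, ], off[2, ]),
                         levels = c("1 1", "1 2", "2 1", "2 2")))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  hom_freq <- mean(off[1, ] == off[2, ])
  expect_lt(abs(hom_freq - 0.5), 0.02)

  expect_identical(cross(pa, pb, seed = 99), cross(pa, pb, seed = 99))

  pc <- make_homozygote(sim_context(fix_chain()),
                        setNames(rep(1, 3), c("R1", "R2", "R3")), "pc", "C")
  expect_error(cross(pa, pc), "mismatched locus sets")
})

test_that("truncation selection keeps the right number, ties broken by id", {
  ctx <- sim_context(fix_breeding())
  pop <- found_population(ctx, 100, seed = 8)
  sel <- truncation_select(pop, 0.05)
  expect_length(sel, 5L)
  b <- vapply(sel, function(i) i$phenotype$biomass_rate, 0)
  expect_true(all(b >= sort(pop_biomass(pop), decreasing = TRUE)[5]))

  whole <- truncation_select(pop, 1.0)
  expect_length(whole, 100L)

  # all-equal fitness: selection must be by id order, reproducibly
  clone_pop <- pop
  clone_pop$individuals <- lapply(pop$individuals, function(i) {
    i$phenotype$biomass_rate <- 1; i
  })
  ids1 <- vapply(truncation_select(clone_pop, 0.1), function(i) i$id, "")
  ids2 <- vapply(truncation_select(clone_pop, 0.1), function(i) i$id, "")
  expect_identical(ids1, ids2)
  expect_identical(ids1, sort(ids1))

  expect_error(truncation_select(pop, 0.005, require_pairs = TRUE),
               "fewer than 2")
})

test_that("offspring generations respect parentage and allele containment", {
  ctx <- sim_context(fix_breeding())
  pop <- found_population(ctx, 20, seed = 12)
  parents <- truncation_select(pop, 0.1)  # 2 parents
  off <- make_offspring_generation(parents, 30, ctx, seed = 1)
  pid <- vapply(parents, function(p) p$id, "")
  for (ind in off$individuals) {
    expect_setequal(ind$parent_ids, pid)
    # each allele traces to some parental allele at the same locus
    for (l in rownames(ind$genotype))
      expect_true(all(ind$genotype[l, ] %in%
                      c(parents[[1]]$genotype[l, ], parents[[2]]$genotype[l, ])))
  }

  selfed <- make_offspring_generation(parents[1], 10, ctx,
                                      allow_selfing = TRUE, seed = 2)
  expect_true(all(vapply(selfed$individuals,
                         function(i) all(i$parent_ids == pid[1]), TRUE)))
  expect_error(make_offspring_generation(parents[1], 10, ctx),
               "at least 2")
})

test_that("inbreeding drives selection response and homozygosity upward", {
  ctx <- sim_context(fix_breeding())
  founders <- found_population(ctx, 60, "L1", seed = 31)
  cfg <- selection_config(population_size = 60, selection_fraction = 0.05,
                          generations = 15, seed = 32)
  lineage <- run_inbreeding(founders, ctx, cfg)
  expect_length(lineage, 16L)
  s <- attr(lineage, "summary")
  expect_equal(nrow(s), 16L)
  expect_gte(s$mean_biomass[16], s$mean_biomass[2])
  expect_gt(s$mean_homozygosity[16], s$mean_homozygosity[1] + 0.3)

  # zero generations: founders returned unchanged
  cfg0 <- selection_config(population_size = 60, selection_fraction = 0.05,
                           generations = 0)
  expect_identical(run_inbreeding(founders, ctx, cfg0)[[1]], founders)
})

test_that("runs are reproducible bit-for-bit from the same seed", {
  ctx <- sim_context(fix_breeding())
  go <- function() {
    founders <- found_population(ctx, 30, "L1", seed = 77)
    cfg <- selection_config(population_size = 30, selection_fraction = 0.1,
                            generations = 3, seed = 78)
    run_inbreeding(founders, ctx, cfg)
  }
  l1 <- go(); l2 <- go()
  expect_identical(lapply(l1, pop_biomass), lapply(l2, pop_biomass))
  expect_identical(l1[[4]]$individuals[[7]]$genotype,
                   l2[[4]]$individuals[[7]]$genotype)
})

test_that("selfing halves heterozygosity each generation at neutral loci", {
  ctx <- sim_context(fix_breeding())
  pop <- found_population(ctx, 200, seed = 41)
  het <- 1 - mean(pop_homozygosity(pop))
  set.seed(42)
  for (g in 1:3) {
    pop <- make_offspring_generation(pop$individuals,
                                     length(pop$individuals), ctx,
                                     allow_selfing = TRUE)
    het_next <- 1 - mean(pop_homozygosity(pop))
    expect_lt(abs(het_next - het / 2), 0.08)
    het <- het_next
  }
})

test_that("random mating without selection conserves allele expectations", {
  ctx <- sim_context(fix_breeding())
  founders <- found_population(ctx, 40, seed = 51)
  base_mean <- mean(vapply(founders$individuals,
                           function(i) mean(i$genotype), 0))
  reps <- vapply(1:50, function(r) {
    off <- make_offspring_generation(founders$individuals, 40, ctx,
                                     seed = 1000 + r)
    mean(vapply(off$individuals, function(i) mean(i$genotype), 0))
  }, 0)
  expect_lt(abs(mean(reps) - base_mean), 0.02)
})

test_that("F1 production samples both lines; F2 needs distinct F1 parents", {
  ctx <- sim_context(fix_bottleneck())
  lines <- bottleneck_lines(ctx)
  f1 <- produce_f1(lines$a, lines$b, ctx, n = 50, seed = 61)
  expect_length(f1$individuals, 50L)
  samp <- attr(f1, "parent_samples")
  expect_length(samp$a, ceiling(0.3 * 30))
  for (ind in f1$individuals) {
    expect_true(ind$parent_ids[1] %in% samp$a)
    expect_true(ind$parent_ids[2] %in% samp$b)
  }
  expect_error(produce_f1(lines$a, lines$a, ctx), "distinct lines")

  f2 <- produce_f2(f1, ctx, n = 40, seed = 62)
  expect_length(f2$individuals, 40L)
  for (ind in f2$individuals)
    expect_true(ind$parent_ids[1] != ind$parent_ids[2])  # no selfing
  expect_length(produce_f2(f1, ctx, n = 0)$individuals, 0L)
})

test_that("pairwise schedules enumerate unordered line pairs", {
  expect_equal(nrow(pairwise_cross_schedule(sprintf("L%02d", 1:40))), 780L)
  expect_equal(nrow(pairwise_cross_schedule(c("A", "B"))), 1L)
  expect_equal(nrow(pairwise_cross_schedule(sprintf("L%d", 1:5))), 10L)
  expect_error(pairwise_cross_schedule(c("A", "A")), "duplicate")
  expect_error(pairwise_cross_schedule("A"), "at least 2")
})

test_that("fixation experiment bookkeeping: arms, generations, frequencies", {
  ctx <- sim_context(fix_bottleneck())
  pa <- make_homozygote(ctx, c(R1 = 4, R2 = 8), "pa", "A")
  pb <- make_homozygote(ctx, c(R1 = 8, R2 = 4), "pb", "B")
  f1 <- heterosim:::new_individual("f1", cross(pa, pb, seed = 70),
                                   NULL, c("pa", "pb"), "AxB", 1L)
  f1$phenotype <- heterosim:::evaluate_genotype(ctx, f1$genotype)
  fx <- fixation_experiment(f1, ctx, n_f2 = 80, n_founders = 2,
                            pop_size = 40, select_fraction = 0.05,
                            generations = 4, seed = 71)
  expect_length(fx$selected, 2L)
  expect_length(fx$random, 2L)
  expect_length(fx$selected[[1]], 4L)  # F3..F6
  expect_equal(fx$selected[[1]][[4]]$generation_index, 6L)

  af <- fx$allele_freq
  expect_true(all(af$freq_parent_a >= 0 & af$freq_parent_a <= 1, na.rm = TRUE))
  expect_false(anyNA(af$freq_parent_a))  # both loci informative here

  # selected arm recovers: final mean biomass at least the F2 mean
  last <- vapply(fx$selected, function(lin)
    mean(pop_biomass(lin[[length(lin)]])), 0)
  expect_gte(max(last), mean(pop_biomass(fx$f2)))
})
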