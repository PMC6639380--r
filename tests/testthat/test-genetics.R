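# Genotype -> constraint -> phenotype mapping.

make_genotype <- function(loci, a, b = a) {
  heterosim:::new_genotype(matrix(c(a, b), ncol = 2,
                                  dimnames = list(loci, NULL)), 2L)
}

test_that("allele spaces span the direction-restricted FVA range", {
  m <- fix_parallel(c(5, 5), input = 10)
  rfd <- build_reference(m)
  env <- run_fva(m, 0.95)
  sp2 <- build_allele_space(m, env, rfd, levels = 2L)
  expect_equal(sp2[["P1R1"]], c(4.5, 5.0), tolerance = 1e-6)
  sp101 <- build_allele_space(m, env, rfd, levels = 101L)
  expect_length(sp101[["P1R1"]], 101L)
  expect_equal(range(sp101[["P2R1"]]), c(4.5, 5.0), tolerance = 1e-6)
  expect_equal(diff(sp101[["P1R1"]]), rep(0.005, 100), tolerance = 1e-6)
})

test_that("degenerate envelopes give monomorphic loci with a warning", {
  m <- fix_chain()
  rfd <- build_reference(m)
  env <- run_fva(m, 1.0)  # unique optimum: every envelope collapses
  expect_warning(sp <- build_allele_space(m, env, rfd), "monomorphic")
  expect_true(all(lengths(sp) == 1L))
  g <- sample_founder_genotype(sp, seed = 1)
  expect_equal(homozygosity_fraction(g), 1.0)
})

test_that("founder sampling is deterministic and uniform over candidates", {
  ctx <- sim_context(fix_breeding())
  g1 <- sample_founder_genotype(ctx$allele_space, seed = 7)
  g2 <- sample_founder_genotype(ctx$allele_space, seed = 7)
  expect_identical(g1, g2)
  expect_equal(dim(g1), c(24L, 2L))
  expect_true(all(g1 >= 0 & g1 <= 4 + 1e-9))

  # chi-squared goodness of fit at one locus over 1e4 draws, 5 levels
  sp5 <- lapply(ctx$allele_space, function(v) v[c(1, 26, 51, 76, 101)])
  class(sp5) <- "allele_space"
  set.seed(11)
  draws <- replicate(5000, sample_founder_genotype(sp5)["P1R1", ])
  counts <- table(factor(round(draws, 6),
                         levels = round(sp5[["P1R1"]], 6)))
  expect_length(counts, 5L)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("constraints average alleles and cap the total at the RFD budget", {
  ctx <- sim_context(fix_bottleneck())
  # T_RFD = 40 (four reactions at flux 10), so lambda stays 1 here
  g <- make_genotype(c("R1", "R2"), c(4, 8), c(6, 4))
  cs <- derive_constraints(g, ctx$rfd)
  expect_equal(unname(cs$capacity), c(5, 6))
  expect_equal(cs$lambda, 1)
  # raw total twice the budget -> every capacity halved
  g2 <- make_genotype(c("R1", "R2"), c(40, 40))
  cs2 <- derive_constraints(g2, ctx$rfd)
  expect_equal(cs2$lambda, 0.5)
  expect_equal(unname(cs2$capacity), c(20, 20))
})

test_that("capacity conservation holds over random founders", {
  ctx <- sim_context(fix_breeding())
  t_rfd <- sum(abs(ctx$rfd$flux))
  set.seed(3)
  for (i in 1:100) {
    g <- sample_founder_genotype(ctx$allele_space)
    cs <- derive_constraints(g, ctx$rfd)
    expect_lte(sum(cs$capacity), t_rfd + 1e-9)
  }
})

test_that("phenotype evaluation honours capacities and the RFD anchor", {
  ctx <- sim_context(fix_breeding())
  opt <- ctx$rfd$objective_value
  loci <- constrained_loci(ctx$model)

  # capacities equal to the RFD fluxes reproduce the RFD optimum
  g_rfd <- make_genotype(loci, abs(ctx$rfd$flux[loci]))
  ph <- heterosim:::evaluate_genotype(ctx, g_rfd)
  expect_equal(ph$biomass_rate, opt, tolerance = 1e-6)
  expect_true(ph$feasible)
  used <- !is.na(ph$efficiency) & abs(ctx$rfd$flux[loci]) > 1e-6
  expect_true(all(ph$efficiency[used] <= 1 + 1e-6))

  # zero capacity at every path's first step severs the network
  caps <- setNames(rep(4, length(loci)), loci)
  caps[c("P1R1", "P2R1", "P3R1", "P4R1")] <- 0
  ph0 <- heterosim:::evaluate_genotype(ctx, make_genotype(loci, caps))
  expect_equal(ph0$biomass_rate, 0, tolerance = 1e-9)

  # no phenotype exceeds the unconstrained optimum; efficiency bounded;
  # evaluation is pure
  set.seed(5)
  for (i in 1:20) {
    g <- sample_founder_genotype(ctx$allele_space)
    p1 <- heterosim:::evaluate_genotype(ctx, g)
    expect_lte(p1$biomass_rate, opt + 1e-6)
    eff <- p1$efficiency[!is.na(p1$efficiency)]
    expect_true(all(eff >= -1e-9 & eff <= 1 + 1e-6))
    p2 <- heterosim:::evaluate_genotype(ctx, g)
    expect_identical(p1, p2)
  }
})

test_that("an infeasible constrained model is a zero-biomass phenotype", {
  rx <- list(
    list(id = "EX_src", stoich = c(A = 1), lower = 0, upper = 10),
    list(id = "R1", stoich = c(A = -1, Z = 1), lower = 1, upper = 10),
    list(id = "BIO", stoich = c(Z = -1), lower = 0, upper = Inf))
  m <- metabolic_model("forced", rx, "BIO")
  cs <- structure(list(capacity = c(R1 = 0.5), lambda = 1,
                       direction = c(R1 = 1)), class = "constraint_set")
  ph <- evaluate_individual(m, cs)
  expect_false(ph$feasible)
  expect_equal(ph$biomass_rate, 0)
})

test_that("complementary bottleneck parents produce a superior F1", {
  ctx <- sim_context(fix_bottleneck())
  pa <- make_homozygote(ctx, c(R1 = 4, R2 = 8), "pa", "A")
  pb <- make_homozygote(ctx, c(R1 = 8, R2 = 4), "pb", "B")
  expect_equal(pa$phenotype$biomass_rate, 4, tolerance = 1e-6)
  expect_equal(pb$phenotype$biomass_rate, 4, tolerance = 1e-6)
  f1g <- cross(pa, pb, seed = 1)
  ph <- heterosim:::evaluate_genotype(ctx, f1g)
  expect_equal(ph$biomass_rate, 6, tolerance = 1e-6)  # mean caps (6,6)
  expect_gt(ph$biomass_rate,
            max(pa$phenotype$biomass_rate, pb$phenotype$biomass_rate))
})

test_that("homozygosity counts exact value matches", {
  g <- make_genotype(paste0("L", 1:10), rep(1, 10), c(rep(1, 9), 2))
  expect_equal(homozygosity_fraction(g), 0.9)
  f1 <- make_genotype(paste0("L", 1:10), 1:10, 10:1 + 100)
  expect_equal(homozygosity_fraction(f1), 0)
})
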