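# Heterosis quantification and decomposition.

test_that("mid-parent heterosis is plain arithmetic with a guarded ratio", {
  fake <- function(id, b) heterosim:::new_individual(
    id, NULL, list(biomass_rate = b, feasible = TRUE), c(NA, NA), "L", 0L)
  rec <- midparent_heterosis(fake("f1", 11), fake("a", 10), fake("b", 10))
  expect_equal(rec$midparent_ratio, 1.1)
  expect_equal(rec$absolute_deviation, 1)
  rec0 <- midparent_heterosis(fake("f1", 7), fake("a", 6), fake("b", 8))
  expect_equal(rec0$midparent_ratio, 1.0)
  expect_equal(rec0$absolute_deviation, 0)
  expect_error(midparent_heterosis(fake("f1", 1), fake("a", 0), fake("b", 0)),
               "undefined")
})

test_that("bottleneck F1s show heterosis; the worked two-locus example", {
  ctx <- sim_context(fix_bottleneck())
  pa <- make_homozygote(ctx, c(R1 = 4, R2 = 8), "pa", "A")
  pb <- make_homozygote(ctx, c(R1 = 8, R2 = 4), "pb", "B")
  f1 <- heterosim:::new_individual("f1", cross(pa, pb, seed = 5), NULL,
                                   c("pa", "pb"), "AxB", 1L)
  f1$phenotype <- heterosim:::evaluate_genotype(ctx, f1$genotype)
  rec <- midparent_heterosis(f1, pa, pb)
  expect_equal(rec$midparent_ratio, 1.5, tolerance = 1e-6)   # 6 / 4
  expect_equal(rec$absolute_deviation, 2, tolerance = 1e-6)

  # substitution scan: capacities behave as biomass = min(cap1, cap2);
  # F1 (6,6) -> 6; locus R1 homozygous for 4 -> 4, for 8 -> min(8,6) = 6;
  # direct contribution = 6 - (4+6)/2 = 1 at each locus
  scan <- locus_substitution_scan(f1, ctx)
  expect_equal(scan$direct_contribution[scan$locus == "R1"], 1,
               tolerance = 1e-6)
  expect_equal(scan$direct_contribution[scan$locus == "R2"], 1,
               tolerance = 1e-6)
  expect_equal(scan$delta_parent_a[scan$locus == "R1"], -2, tolerance = 1e-6)
  expect_equal(scan$delta_parent_b[scan$locus == "R1"], 0, tolerance = 1e-6)

  d <- decompose_heterosis(rec, scan)
  expect_equal(d$overall, 2, tolerance = 1e-6)
  expect_equal(d$single_locus_sum, 2, tolerance = 1e-6)
  expect_equal(d$multi_locus, 0, tolerance = 1e-6)
  # residual identity holds exactly, by construction
  expect_identical(d$overall, d$single_locus_sum + d$multi_locus)
})

test_that("scan is a no-op at homozygous loci; clonal cross is all zeros", {
  ctx <- sim_context(fix_breeding())
  g <- sample_founder_genotype(ctx$allele_space, seed = 14)
  g[, 2] <- g[, 1]  # fully homozygous individual
  ind <- heterosim:::new_individual("c", g, heterosim:::evaluate_genotype(ctx, g),
                                    c("p", "p"), "L", 1L)
  scan <- locus_substitution_scan(ind, ctx)
  expect_true(all(scan$direct_contribution == 0))
  expect_true(all(scan$delta_parent_a == 0 & scan$delta_parent_b == 0))

  fake_parent <- heterosim:::new_individual("p", g, ind$phenotype,
                                            c(NA, NA), "L", 0L)
  rec <- midparent_heterosis(ind, fake_parent, fake_parent)
  expect_equal(rec$midparent_ratio, 1)
  d <- decompose_heterosis(rec, scan)
  expect_equal(d$multi_locus, 0)
})

test_that("decomposition arithmetic covers the epistasis quadrants", {
  rec <- list(absolute_deviation = 0, midparent_ratio = 1)
  contr <- data.frame(locus = c("a", "b"), direct_contribution = c(-1, -1))
  d <- decompose_heterosis(rec, contr)
  expect_equal(d$multi_locus, 2)  # positive epistasis despite negative singles
  contr0 <- data.frame(locus = "a", direct_contribution = 0)
  expect_equal(decompose_heterosis(rec, contr0)$multi_locus, rec$absolute_deviation)
})

test_that("flux-heterosis correlations: perfect coupling and NA degeneracy", {
  ratios <- c(1.0, 1.1, 1.3, 0.9, 1.2)
  fake <- function(i) heterosim:::new_individual(
    paste0("f", i), NULL,
    list(biomass_rate = ratios[i],
         flux = c(BIO = 2 * ratios[i],          # proportional to heterosis
                  CONST = 7,                     # zero variance
                  NOISY = c(3, 1, 2, 5, 4)[i]),
         feasible = TRUE),
    c(NA, NA), "L", 1L)
  pop <- heterosim:::new_population(lapply(1:5, fake), 1L, "L")
  recs <- data.frame(f1_id = paste0("f", 1:5), midparent_ratio = ratios)
  r <- flux_heterosis_correlation(pop, recs)
  expect_equal(r[["BIO"]], 1, tolerance = 1e-12)
  expect_true(is.na(r[["CONST"]]))
  expect_true(abs(r[["NOISY"]]) < 1)

  small <- pop; small$individuals <- pop$individuals[1:2]
  expect_error(flux_heterosis_correlation(small, recs), "at least 3")

  # on a real F1 population, coupled-path fluxes correlate with heterosis
  ctx <- sim_context(fix_bottleneck())
  lines <- bottleneck_lines(ctx)
  f1 <- produce_f1(lines$a, lines$b, ctx, n = 40, seed = 91)
  rr <- heterosis_records(f1, lines$a, lines$b)
  rf <- flux_heterosis_correlation(f1, rr)
  expect_true(all(!is.na(rf[c("R1", "R2", "BIO")])))
})

test_that("efficiency profiles: RFD capacities saturate; tails ordered", {
  ctx <- sim_context(fix_breeding())
  loci <- constrained_loci(ctx$model)
  g <- heterosim:::new_genotype(
    matrix(rep(abs(ctx$rfd$flux[loci]), 2), ncol = 2,
           dimnames = list(loci, NULL)), 2L)
  ind <- heterosim:::new_individual("rfdind", g,
                                    heterosim:::evaluate_genotype(ctx, g),
                                    c(NA, NA), "L", 0L)
  pop <- heterosim:::new_population(list(ind), 0L, "L")
  prof <- efficiency_profile(pop)
  used <- prof$efficiencies[prof$efficiencies > 1e-6]
  expect_true(all(abs(used - 1) < 1e-6))
  expect_equal(sum(prof$histogram$count), length(prof$efficiencies))
})

test_that("reaction classification produces consistent Venn regions", {
  cls <- classify_reactions("r1", "r2", "r3")
  expect_equal(unname(cls$venn),
               c(1L, 1L, 1L, 0L, 0L, 0L, 0L))
  cls2 <- classify_reactions(c("a", "b", "c"), c("b", "c"), character(0))
  expect_equal(cls2$venn[["correlated_only"]], 0L)
  expect_equal(cls2$venn[["coupled_correlated"]], 2L)

  set.seed(101)
  for (i in 1:20) {
    u <- paste0("x", 1:15)
    s1 <- sample(u, sample(0:15, 1)); s2 <- sample(u, sample(0:15, 1))
    s3 <- sample(u, sample(0:15, 1))
    cls <- classify_reactions(s1, s2, s3)
    expect_equal(sum(cls$venn), length(unique(c(s1, s2, s3))))
  }
})

test_that("contributing loci are those with variable scan contributions", {
  scans <- list(
    data.frame(locus = c("a", "b"), direct_contribution = c(0, 1)),
    data.frame(locus = c("a", "b"), direct_contribution = c(0, 3)))
  expect_equal(contributing_loci(scans), "b")
  expect_equal(contributing_loci(list()), character(0))
})
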