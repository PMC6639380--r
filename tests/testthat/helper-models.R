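# Shared fixtures, all built in code.

fix_chain <- function(capacity = Inf, input = 10, length = 3L)
  make_toy_model(toy_spec("chain", length = length, input = input,
                          capacity = capacity))

fix_parallel <- function(capacities = c(5, 5), input = 10, path_length = 1L)
  make_toy_model(toy_spec("parallel_paths", capacities = capacities,
                          input = input, path_length = path_length))

fix_bottleneck <- function(input = 10)
  make_toy_model(toy_spec("bottleneck_pair", input = input))

fix_branched <- function(short = 5, long = 5, input = 5)
  make_toy_model(toy_spec("branched", short_capacity = short,
                          long_capacity = long, input = input))

fix_futile <- function() make_toy_model(toy_spec("futile_cycle"))

# the inbreeding workhorse: 4 parallel 6-step paths (24 constrained loci),
# total path capacity 16 over an input of 10 so FVA envelopes are wide
fix_breeding <- function()
  make_toy_model(toy_spec("parallel_paths", capacities = rep(4, 4),
                          path_length = 6L, input = 10))

# hand-built diploid individual on a model, homozygous at the given
# capacities (named by locus); used for bottleneck heterosis fixtures
make_homozygote <- function(ctx, caps, id, line_id) {
  loci <- constrained_loci(ctx$model)
  stopifnot(setequal(names(caps), loci))
  g <- heterosim:::new_genotype(
    matrix(rep(unname(caps[loci]), 2L), ncol = 2L,
           dimnames = list(loci, NULL)), 2L)
  heterosim:::new_individual(id, g, heterosim:::evaluate_genotype(ctx, g),
                             c(NA_character_, NA_character_), line_id, 0L)
}

# population of homozygous individuals whose capacities are drawn from a
# small per-locus grid (keeps a line almost clonal but not degenerate)
make_homozygous_line <- function(ctx, cap_grid, size, line_id, seed) {
  set.seed(seed)
  loci <- constrained_loci(ctx$model)
  inds <- lapply(seq_len(size), function(i) {
    caps <- vapply(loci, function(l) sample(cap_grid[[l]], 1L), 0)
    make_homozygote(ctx, setNames(caps, loci),
                    sprintf("%s_i%03d", line_id, i), line_id)
  })
  heterosim:::new_population(inds, 0L, line_id, seed)
}

# two complementary bottleneck parent lines on fix_bottleneck():
# line A is slow at R1 and fast at R2, line B the reverse
bottleneck_lines <- function(ctx, size = 30L, seed = 42L) {
  jit <- function(x) lapply(x, function(v) v + c(-0.2, 0, 0.2))
  grid_a <- setNames(jit(c(4, 8)), c("R1", "R2"))
  grid_b <- setNames(jit(c(8, 4)), c("R1", "R2"))
  list(a = make_homozygous_line(ctx, grid_a, size, "BA", seed),
       b = make_homozygous_line(ctx, grid_b, size, "BB", seed + 1L))
}
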