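#' Specify a synthetic toy metabolic model
#'
#' Small constraint-based networks with analytically known optima, used to
#' exercise the whole pipeline without any external model file. Available
#' topologies:
#' \describe{
#'   \item{`chain`}{a single linear pathway: one input exchange, `length`
#'     internal reactions, one biomass sink. Optimum = min(input, capacity).}
#'   \item{`parallel_paths`}{one input feeding `length(capacities)`
#'     parallel pathways of `path_length` reactions each (per-reaction
#'     bound = the path's capacity) that reconverge before biomass.
#'     Optimum = min(input, sum(capacities)).}
#'   \item{`bottleneck_pair`}{a linear pathway with two consecutive
#'     internal steps; complementary low enzyme capacities at these two
#'     loci in two parents reproduce the classic bottleneck-relaxation
#'     route to heterosis in their F1.}
#'   \item{`futile_cycle`}{a chain plus a two-reaction cycle detached from
#'     biomass; parsimonious FBA must leave the cycle at zero flux.}
#'   \item{`branched`}{a short (one-reaction) and a long (`long_length`
#'     reactions) path from the input to the biomass precursor;
#'     parsimonious FBA prefers the short path.}
#' }
#'
#' @param topology one of `"chain"`, `"parallel_paths"`,
#'   `"bottleneck_pair"`, `"futile_cycle"`, `"branched"`.
#' @param ... topology parameters overriding the defaults listed above:
#'   `input` (exchange upper bound), `length`, `capacity`, `capacities`,
#'   `path_length`, `cycle_bound`, `short_capacity`, `long_capacity`,
#'   `long_length`.
#' @return a `toy_spec` list.
#' @examples
#' make_toy_model(toy_spec("parallel_paths", capacities = c(3, 5)))
#' @export
toy_spec <- function(topology = c("chain", "parallel_paths", "bottleneck_pair",
                                  "futile_cycle", "branched"), ...) {
  topology <- match.arg(topology)
  defaults <- switch(topology,
    chain = list(length = 3L, input = 10, capacity = Inf),
    parallel_paths = list(capacities = c(5, 5), path_length = 1L, input = Inf),
    bottleneck_pair = list(input = 10, capacity = Inf),
    futile_cycle = list(length = 2L, input = 10, capacity = Inf,
                        cycle_bound = 10),
    branched = list(short_capacity = 5, long_capacity = 5, long_length = 2L,
                    input = Inf))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) stop("unknown parameter(s) for topology '", topology,
                            "': ", paste(unknown, collapse = ", "))
  spec <- utils::modifyList(defaults, override)
  spec$topology <- topology
  structure(spec, class = "toy_spec")
}

#' Build a toy metabolic model from a specification
#'
#' Deterministic: the same spec always yields the same model. Where the
#' optimum is analytic it is attached as attribute `expected_optimum`.
#'
#' @param spec a [toy_spec()].
#' @return a validated `metabolic_model`.
#' @export
make_toy_model <- function(spec) {
  if (!inherits(spec, "toy_spec")) stop("spec must be a toy_spec")
  check_pos <- function(x, what) {
    if (any(!is.finite(x) & x != Inf) || any(x <= 0))
      stop("toy_spec: ", what, " must be positive")
  }
  check_pos(spec$input %||% 1, "input")
  src <- function(input) list(id = "EX_src", stoich = c(A = 1),
                              lower = 0, upper = input, class = "exchange")
  bio <- function(met) list(id = "BIO", stoich = setNames(-1, met),
                            lower = 0, upper = Inf, class = "biomass")
  step <- function(id, from, to, cap)
    list(id = id, stoich = setNames(c(-1, 1), c(from, to)),
         lower = 0, upper = cap)

  rx <- switch(spec$topology,
    chain = ,
    futile_cycle = {
      L <- as.integer(spec$length)
      if (L < 1L) stop("toy_spec: chain length must be >= 1")
      mets <- c("A", if (L > 1L) paste0("M", seq_len(L - 1L)), "Z")
      rr <- c(list(src(spec$input)),
              lapply(seq_len(L), function(i)
                step(paste0("R", i), mets[i], mets[i + 1L], spec$capacity)),
              list(bio("Z")))
      if (spec$topology == "futile_cycle") {
        rr <- c(rr, list(
          list(id = "CYC_f", stoich = c(X = -1, Y = 1), lower = 0,
               upper = spec$cycle_bound),
          list(id = "CYC_r", stoich = c(Y = -1, X = 1), lower = 0,
               upper = spec$cycle_bound)))
      }
      rr
    },
    parallel_paths = {
      caps <- spec$capacities
      check_pos(caps, "capacities")
      PL <- as.integer(spec$path_length)
      rr <- list(src(spec$input))
      for (p in seq_along(caps)) {
        mets <- c("A", if (PL > 1L) paste0("P", p, "_", seq_len(PL - 1L)), "Z")
        rr <- c(rr, lapply(seq_len(PL), function(i)
          step(paste0("P", p, "R", i), mets[i], mets[i + 1L], caps[p])))
      }
      c(rr, list(bio("Z")))
    },
    bottleneck_pair = list(
      src(spec$input),
      step("R1", "A", "B", spec$capacity),
      step("R2", "B", "Z", spec$capacity),
      bio("Z")),
    branched = list(
      src(spec$input),
      step("SHORT", "A", "Z", spec$short_capacity),
      step("LONG1", "A", "L1", spec$long_capacity),
      if (spec$long_length >= 2L) lapply(2:spec$long_length, function(i)
        step(paste0("LONG", i),
             if (i == 2L) "L1" else paste0("L", i - 1L),
             if (i == spec$long_length) "Z" else paste0("L", i),
             spec$long_capacity)),
      bio("Z")))
  # flatten one level of nesting introduced by the branched long path
  rx <- Filter(Negate(is.null), rx)
  flat <- list()
  for (r in rx) flat <- c(flat, if (!is.null(r$id)) list(r) else r)

  expected <- switch(spec$topology,
    chain = ,
    futile_cycle = min(spec$input, spec$capacity),
    parallel_paths = min(spec$input, sum(spec$capacities)),
    bottleneck_pair = min(spec$input, spec$capacity),
    branched = min(spec$input, spec$short_capacity + spec$long_capacity))

  model <- metabolic_model(paste0("toy_", spec$topology), flat,
                           objective = "BIO")
  attr(model, "expected_optimum") <- unname(expected)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
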