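# Brute-force LP oracle, independent of the package's simplex solver.
#
# Enumerates candidate basic solutions of {S v = rhs, lb <= v <= ub}
# (optionally adding v_j = 0 hyperplanes, needed for total-flux minima)
# by activating every subset of bound constraints that completes the
# equality system to full rank, solving the square system, and keeping
# feasible solutions. Only usable on fixtures with <= ~8 reactions.

oracle_vertices <- function(S, rhs, lb, ub, zero_planes = FALSE, tol = 1e-7) {
  n <- ncol(S)
  lb <- pmax(lb, -1e5); ub <- pmin(ub, 1e5)
  r <- qr(S)$rank
  k <- n - r
  cons <- list()
  for (j in seq_len(n)) {
    cons[[length(cons) + 1L]] <- list(j = j, v = lb[j])
    cons[[length(cons) + 1L]] <- list(j = j, v = ub[j])
    if (zero_planes && lb[j] < 0 && ub[j] > 0)
      cons[[length(cons) + 1L]] <- list(j = j, v = 0)
  }
  verts <- list()
  if (k == 0L) {
    sets <- matrix(integer(0), nrow = 0, ncol = 1)
  } else {
    sets <- utils::combn(length(cons), k)
  }
  for (s in seq_len(ncol(sets))) {
    E <- matrix(0, nrow = k, ncol = n)
    ev <- numeric(k)
    for (q in seq_len(k)) {
      cc <- cons[[sets[q, s]]]
      E[q, cc$j] <- 1
      ev[q] <- cc$v
    }
    A <- rbind(S, E)
    b <- c(rhs, ev)
    qa <- qr(A)
    if (qa$rank < n) next
    v <- tryCatch(as.vector(qr.solve(A, b, tol = 1e-10)),
                  error = function(e) NULL)
    if (is.null(v) || anyNA(v)) next
    if (max(abs(A %*% v - b)) > tol) next
    if (any(v < lb - tol) || any(v > ub + tol)) next
    verts[[length(verts) + 1L]] <- pmin(pmax(v, lb), ub)
  }
  if (!length(verts)) return(matrix(numeric(0), ncol = n))
  m <- do.call(rbind, verts)
  m[!duplicated(round(m, 6)), , drop = FALSE]
}

oracle_fba <- function(model) {
  S <- as.matrix(model$S)
  rx <- model$reactions
  obj <- as.numeric(rx$id == model$objective)
  V <- oracle_vertices(S, rep(0, nrow(S)), rx$lower, rx$upper)
  stopifnot(nrow(V) > 0)
  vals <- V %*% obj
  list(objective = max(vals), vertex = V[which.max(vals), ])
}

oracle_pfba <- function(model) {
  S <- as.matrix(model$S)
  rx <- model$reactions
  obj <- as.numeric(rx$id == model$objective)
  vopt <- oracle_fba(model)$objective
  S2 <- rbind(S, obj)
  V <- oracle_vertices(S2, c(rep(0, nrow(S)), vopt), rx$lower, rx$upper,
                       zero_planes = TRUE)
  stopifnot(nrow(V) > 0)
  tot <- rowSums(abs(V))
  list(objective = vopt, total_flux = min(tot), vertex = V[which.min(tot), ])
}
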