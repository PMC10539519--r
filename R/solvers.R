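#' Exact global minimum energy conformation by exhaustive enumeration
#'
#' Brute-force oracle: enumerates every rotamer assignment and returns
#' the global minimum, with ties broken by lexicographic choice order
#' (position order, then choice index). Refuses search spaces larger
#' than `bound`.
#'
#' @param m [energy_matrices()].
#' @param bound maximum number of assignments (default 1e6).
#' @return list of class `RotamerAssignment`: `assign` (integer choice
#'   per position), `energy` (kcal/mol), `method`.
#' @export
brute_force_gmec <- function(m, bound = 1e6) {
  nc <- n_choices(m)
  total <- prod(nc)
  if (total > bound)
    stop("search space (", total, ") exceeds brute-force bound (", bound, ")")
  k <- length(nc)
  grid <- as.matrix(expand.grid(lapply(rev(nc), seq_len)))[, k:1, drop = FALSE]
  # expand.grid varies its first factor fastest; reversing both gives
  # lexicographic row order, so which.min ties break lexicographically.
  e <- numeric(nrow(grid))
  for (i in seq_len(k)) e <- e + m$singles[[i]][grid[, i]]
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      e <- e + m$pairs[[i]][[j]][grid[, c(i, j), drop = FALSE]]
  best <- which.min(e)
  structure(list(assign = as.integer(grid[best, ]), energy = e[best],
                 method = "brute_force"), class = "RotamerAssignment")
}

#' @export
print.RotamerAssignment <- function(x, ...) {
  cat(sprintf("RotamerAssignment (%s): energy %.4f kcal/mol, choices [%s]\n",
              x$method, x$energy, paste(x$assign, collapse = ", ")))
  invisible(x)
}

#' Goldstein dead-end elimination
#'
#' Eliminates rotamer `r` at position `i` whenever some competitor `t`
#' satisfies `E(i_r) - E(i_t) + sum_j min_s [E(i_r,j_s) - E(i_t,j_s)] > 0`
#' (Goldstein criterion), iterating over positions until a fixpoint. The
#' criterion is provably GMEC-preserving.
#'
#' @param m [energy_matrices()].
#' @return list: `m` (pruned [energy_matrices()]), `kept` (list of
#'   original choice indices retained per position).
#' @export
dee_prune <- function(m) {
  k <- nrow(m$positions)
  kept <- lapply(n_choices(m), seq_len)
  cur <- m
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) {
      nc <- n_choices(cur)
      if (nc[i] < 2) next
      elim <- rep(FALSE, nc[i])
      for (r in seq_len(nc[i])) {
        for (t in seq_len(nc[i])) {
          if (t == r || elim[t]) next
          g <- cur$singles[[i]][r] - cur$singles[[i]][t]
          for (j in seq_len(k)) {
            if (j == i) next
            pr <- if (i < j) cur$pairs[[i]][[j]][r, ]
                  else cur$pairs[[j]][[i]][, r]
            pt <- if (i < j) cur$pairs[[i]][[j]][t, ]
                  else cur$pairs[[j]][[i]][, t]
            g <- g + min(pr - pt)
          }
          if (g > 0) { elim[r] <- TRUE; break }
        }
      }
      if (any(elim)) {
        if (all(elim))
          stop("inconsistent matrices: all choices eliminated at position ", i)
        keep_i <- which(!elim)
        kept[[i]] <- kept[[i]][keep_i]
        cur <- subset_choices(cur, i, keep_i)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(m = cur, kept = kept)
}

subset_choices <- function(m, i, keep) {
  k <- nrow(m$positions)
  m$choices[[i]] <- m$choices[[i]][keep, , drop = FALSE]
  m$singles[[i]] <- m$singles[[i]][keep]
  for (j in seq_len(k)) {
    if (j < i) m$pairs[[j]][[i]] <- m$pairs[[j]][[i]][, keep, drop = FALSE]
    if (j > i) m$pairs[[i]][[j]] <- m$pairs[[i]][[j]][keep, , drop = FALSE]
  }
  m
}

# conditional best choice at position i given the rest of the assignment
conditional_best <- function(m, assign, i) {
  k <- length(assign)
  cost <- m$singles[[i]]
  for (j in seq_len(k)) {
    if (j == i) next
    cost <- cost + if (i < j) m$pairs[[i]][[j]][, assign[j]]
                   else m$pairs[[j]][[i]][assign[j], ]
  }
  which.min(cost)    # first minimum = lexicographic tie-break
}

batch_relax <- function(m, assign, max_cycles = 50) {
  k <- length(assign)
  for (cycle in seq_len(max_cycles)) {
    changed <- FALSE
    for (i in seq_len(k)) {
      b <- conditional_best(m, assign, i)
      if (b != assign[i]) { assign[i] <- b; changed <- TRUE }
    }
    if (!changed) break
  }
  assign
}

#' FASTER rotamer/sequence optimization
#'
#' Iterative relaxation heuristic: initialization at the per-position
#' singles minima, iterative batch relaxation (each position takes its
#' conditional best choice given the rest) to convergence, then
#' single-perturbation/relaxation sweeps (fix each candidate choice in
#' turn, relax the remaining positions, accept on strict improvement).
#' Deterministic for a fixed seed and sweep order; the returned energy
#' never exceeds the initialization energy and never beats the exact
#' [brute_force_gmec()] optimum.
#'
#' @param m [energy_matrices()].
#' @param seq optional amino-acid constraint: 3-letter code per position
#'   restricts choices to that sequence.
#' @param seed integer; kept for interface stability (the algorithm is
#'   deterministic).
#' @param max_sweeps maximum perturbation/relaxation sweeps (default 10).
#' @return `RotamerAssignment` (choice indices refer to `m`, or to the
#'   restricted matrices when `seq` is given; see `$choices`), with
#'   `converged` flag.
#' @export
faster_optimize <- function(m, seq = NULL, seed = 1, max_sweeps = 10) {
  index_map <- NULL
  if (!is.null(seq)) {
    rs <- restrict_to_sequence(m, seq)
    m <- rs$m
    index_map <- rs$index_map
  }
  k <- nrow(m$positions)
  assign <- vapply(seq_len(k), function(i) which.min(m$singles[[i]]),
                   integer(1))
  init_energy <- assignment_energy(m, assign)
  assign <- batch_relax(m, assign)
  best <- assign
  best_e <- assignment_energy(m, best)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(k)) {
      for (r in seq_len(n_choices(m)[i])) {
        if (r == best[i]) next
        trial <- best
        trial[i] <- r
        trial <- batch_relax_fixed(m, trial, i)
        e <- assignment_energy(m, trial)
        if (e < best_e - 1e-12) {
          best <- trial; best_e <- e; improved <- TRUE
        }
      }
    }
    if (!improved) { converged <- TRUE; break }
  }
  stopifnot(best_e <= init_energy + 1e-9)
  out_assign <- if (is.null(index_map)) best
                else vapply(seq_len(k), function(i) index_map[[i]][best[i]],
                            integer(1))
  structure(list(assign = as.integer(out_assign), energy = best_e,
                 method = "faster", converged = converged,
                 choices = lapply(seq_len(k), function(i)
                   m$choices[[i]][best[i], , drop = FALSE])),
            class = "RotamerAssignment")
}

# batch relaxation with position `fixed` held at its current choice
batch_relax_fixed <- function(m, assign, fixed, max_cycles = 50) {
  k <- length(assign)
  for (cycle in seq_len(max_cycles)) {
    changed <- FALSE
    for (i in seq_len(k)) {
      if (i == fixed) next
      b <- conditional_best(m, assign, i)
      if (b != assign[i]) { assign[i] <- b; changed <- TRUE }
    }
    if (!changed) break
  }
  assign
}
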