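# Seed-scoped RNG: evaluate expr under a fixed seed without disturbing
# the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Minimization potentials
#'
#' Builds the potential used to relax perturbed structures. The bundled
#' `"enm"` potential places harmonic restraints on all interatomic
#' distances within `cutoff` of each other in the reference geometry
#' (an elastic-network model): relaxing a slightly perturbed copy pulls
#' it back into a minimum near the reference, which is the mechanism the
#' perturbation/minimization ensemble generator relies on. Potentials
#' are pluggable: any list with `energy(x)` and `gradient(x)` functions
#' over an n x 3 coordinate matrix works.
#'
#' @param name potential identifier; only `"enm"` is bundled.
#' @param reference Structure providing the reference geometry.
#' @param cutoff Angstrom; restrain atom pairs closer than this in the
#'   reference (default 5).
#' @param k force constant, kcal/mol/A^2 (default 10).
#' @return list with `energy`, `gradient`, `name`.
#' @export
make_potential <- function(name = "enm", reference, cutoff = 5, k = 10) {
  if (name != "enm") stop("unknown potential: ", name)
  X0 <- coords(reference)
  n <- nrow(X0)
  d0m <- as.matrix(dist(X0))
  pairs <- which(upper.tri(d0m) & d0m < cutoff, arr.ind = TRUE)
  if (nrow(pairs) == 0) stop("no atom pairs within cutoff; potential empty")
  i <- pairs[, 1]; j <- pairs[, 2]; d0 <- d0m[pairs]
  list(
    name = "enm",
    energy = function(x) {
      dx <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
      d <- sqrt(rowSums(dx^2))
      sum(k * (d - d0)^2)
    },
    gradient = function(x) {
      dx <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
      d <- sqrt(rowSums(dx^2))
      coefv <- 2 * k * (d - d0) / pmax(d, 1e-12)
      g <- matrix(0, n, 3)
      f <- dx * coefv
      for (col in 1:3) {
        g[, col] <- g[, col] +
          as.numeric(tapply(f[, col], factor(i, levels = 1:n), sum,
                            default = 0)) -
          as.numeric(tapply(f[, col], factor(j, levels = 1:n), sum,
                            default = 0))
      }
      g
    }
  )
}

#' Energy minimization (truncated Newton)
#'
#' Deterministic bounded minimization: outer Newton iterations with a
#' conjugate-gradient inner loop on finite-difference Hessian-vector
#' products, backtracking line search, and a steepest-descent fallback
#' whenever the Newton step is not a finite descent direction. The
#' energy sequence is monotone non-increasing and the returned energy is
#' never above the input energy.
#'
#' @param s Structure to relax.
#' @param potential a [make_potential()] object.
#' @param max_iter maximum outer iterations (default 100).
#' @param grad_tol stop when the gradient RMS drops below this
#'   (kcal/mol/A, default 1e-8).
#' @return list with `structure` (relaxed), `final_gradient_rms`,
#'   `energy` (final), `energy_trace` (per accepted iteration, monotone),
#'   `iterations`, `fallback_steps` (count of steepest-descent steps).
#' @export
minimize <- function(s, potential, max_iter = 100, grad_tol = 1e-8) {
  x <- coords(s)
  e <- potential$energy(x)
  if (!is.finite(e)) stop("non-finite energy at starting structure")
  trace <- e
  nfall <- 0
  it <- 0
  while (it < max_iter) {
    g <- potential$gradient(x)
    grms <- sqrt(mean(g^2))
    if (grms < grad_tol) break
    p <- tn_direction(potential, x, g)
    if (!all(is.finite(p)) || sum(p * g) >= 0) {
      p <- -g
      nfall <- nfall + 1
    }
    # backtracking line search (Armijo)
    alpha <- 1
    gTp <- sum(g * p)
    accepted <- FALSE
    for (ls in 1:40) {
      xn <- x + alpha * p
      en <- potential$energy(xn)
      if (is.finite(en) && en <= e + 1e-4 * alpha * gTp) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) break
    x <- xn; e <- en
    trace <- c(trace, e)
    it <- it + 1
  }
  out <- s
  coords(out) <- x
  g <- potential$gradient(x)
  list(structure = out, final_gradient_rms = sqrt(mean(g^2)), energy = e,
       energy_trace = trace, iterations = it, fallback_steps = nfall)
}

# Truncated-Newton search direction: CG on H p = -g with Hessian-vector
# products by forward differences of the gradient; capped inner loop.
tn_direction <- function(potential, x, g, max_cg = 25) {
  gv <- as.numeric(g)
  eps <- 1e-6 * max(1, sqrt(sum(x^2)))
  hv <- function(v) {
    vm <- matrix(v, nrow = nrow(x))
    gp <- potential$gradient(x + eps * vm)
    (as.numeric(gp) - gv) / eps
  }
  p <- numeric(length(gv))
  r <- -gv
  d <- r
  rs <- sum(r * r)
  tol <- min(0.5, sqrt(sqrt(rs))) * sqrt(rs)
  for (i in seq_len(max_cg)) {
    if (sqrt(rs) < tol) break
    Hd <- hv(d)
    dHd <- sum(d * Hd)
    if (!is.finite(dHd) || dHd <= 1e-16) {
      if (i == 1) p <- r     # negative curvature at first step: gradient dir
      break
    }
    a <- rs / dHd
    p <- p + a * d
    rn <- r - a * Hd
    rsn <- sum(rn * rn)
    d <- rn + (rsn / rs) * d
    r <- rn
    rs <- rsn
  }
  matrix(p, nrow = nrow(x))
}

#' Random coordinate perturbation
#'
#' Shifts every heavy-atom coordinate by exactly +/-`magnitude` along
#' each Cartesian axis with independent random signs (Rademacher), so
#' each heavy atom moves by exactly `magnitude * sqrt(3)` in Euclidean
#' norm. Hydrogens are untouched. Set `scheme = "uniform"` for uniform
#' sampling in [-magnitude, magnitude] instead.
#'
#' @param s Structure.
#' @param magnitude Angstrom (> 0; default 0.001).
#' @param rng_seed integer seed; the same seed reproduces the output.
#' @param scheme `"sign"` (default) or `"uniform"`.
#' @return perturbed Structure.
#' @export
perturb_structure <- function(s, magnitude = 0.001, rng_seed = 1,
                              scheme = c("sign", "uniform")) {
  scheme <- match.arg(scheme)
  if (magnitude <= 0) stop("magnitude must be > 0")
  heavy <- which(s$atoms$element != "H")
  n <- length(heavy)
  delta <- with_seed(rng_seed, {
    if (scheme == "sign")
      matrix(magnitude * (2 * (stats::runif(3 * n) < 0.5) - 1), ncol = 3)
    else
      matrix(stats::runif(3 * n, -magnitude, magnitude), ncol = 3)
  })
  out <- s
  out$atoms[heavy, c("x", "y", "z")] <-
    out$atoms[heavy, c("x", "y", "z")] + delta
  out
}

#' Ensemble specification
#'
#' @param n_members ensemble size (default 50, matching the published
#'   protocol).
#' @param perturbation Angstrom (default 0.001).
#' @param minimizer_iterations default 100.
#' @param seed integer; member i uses `seed + i`.
#' @param potential potential identifier (default `"enm"`).
#' @return object of class `EnsembleSpec`.
#' @export
ensemble_spec <- function(n_members = 50, perturbation = 0.001,
                          minimizer_iterations = 100, seed = 1,
                          potential = "enm") {
  if (n_members < 2) stop("n_members must be >= 2")
  if (perturbation <= 0) stop("perturbation must be > 0")
  structure(list(n_members = n_members, perturbation = perturbation,
                 minimizer_iterations = minimizer_iterations, seed = seed,
                 potential = potential), class = "EnsembleSpec")
}

#' Perturbation/minimization ensemble generation
#'
#' Generates a backbone ensemble by repeatedly applying a tiny random
#' heavy-atom perturbation to the seed structure and relaxing each copy
#' with [minimize()], yielding an ensemble of nearby local minima that
#' approximates backbone flexibility.
#'
#' @param s seed Structure.
#' @param spec [ensemble_spec()].
#' @return object of class `ConformationalEnsemble`: list with `members`
#'   (list of Structures sharing topology with `s`), `spec`, `seed_structure`
#'   and a `provenance` record.
#' @export
generate_ensemble <- function(s, spec = ensemble_spec()) {
  pot <- make_potential(spec$potential, reference = s)
  members <- vector("list", spec$n_members)
  for (i in seq_len(spec$n_members)) {
    pert <- perturb_structure(s, spec$perturbation, rng_seed = spec$seed + i)
    res <- tryCatch(minimize(pert, pot, max_iter = spec$minimizer_iterations),
                    error = function(e)
                      stop("minimization failed for member ", i, ": ",
                           conditionMessage(e)))
    members[[i]] <- res$structure
  }
  structure(list(members = members, spec = spec, seed_structure = s,
                 provenance = list(member_seeds = spec$seed +
                                     seq_len(spec$n_members),
                                   potential = spec$potential)),
            class = "ConformationalEnsemble")
}

#' @export
print.ConformationalEnsemble <- function(x, ...) {
  cat(sprintf("ConformationalEnsemble: %d members of '%s' (seed %d)\n",
              length(x$members), x$seed_structure$id, x$spec$seed))
  invisible(x)
}

#' Ensemble diversity metrics
#'
#' Mean and sample standard deviation of (i) backbone RMSD over all
#' member pairs and (ii) backbone RMSD of each member to the seed
#' structure, both after least-squares superposition.
#'
#' @param e [generate_ensemble()] result.
#' @return list with `pairwise` and `to_seed`, each `c(mean, sd)` in
#'   Angstrom.
#' @export
ensemble_diversity <- function(e) {
  n <- length(e$members)
  if (n < 2) stop("need at least 2 members")
  sel <- atom_selection(atom_class = "backbone")
  pw <- combn(n, 2, function(ij)
    rmsd_between(e$members[[ij[1]]], e$members[[ij[2]]], sel))
  ts <- vapply(e$members, function(m)
    rmsd_between(m, e$seed_structure, sel), numeric(1))
  list(pairwise = c(mean = mean(pw), sd = sd(pw)),
       to_seed = c(mean = mean(ts), sd = sd(ts)))
}
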