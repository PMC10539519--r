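test_that("perturbation moves every heavy atom by exactly magnitude*sqrt(3)", {
  s <- make_toy_structure(8)
  p <- perturb_structure(s, 0.001, rng_seed = 42)
  d <- sqrt(rowSums((coords(p) - coords(s))^2))
  expect_equal(d, rep(0.001 * sqrt(3), length(d)), tolerance = 1e-12)
  expect_error(perturb_structure(s, 0), "magnitude")
})

test_that("perturbation is deterministic per seed and balanced in sign", {
  s <- make_toy_structure(8)
  expect_identical(perturb_structure(s, 0.001, rng_seed = 7),
                   perturb_structure(s, 0.001, rng_seed = 7))
  expect_false(identical(perturb_structure(s, 0.001, rng_seed = 7),
                         perturb_structure(s, 0.001, rng_seed = 8)))
  # sign balance over ~10^4 coordinates: binomial 3-sigma band
  big <- make_toy_structure(850)   # 3400 atoms -> 10200 coordinates
  pb <- perturb_structure(big, 0.001, rng_seed = 3)
  signs <- sign(coords(pb) - coords(big))
  n <- length(signs)
  frac_plus <- mean(signs > 0)
  expect_lt(abs(frac_plus - 0.5), 3 * sqrt(0.25 / n))
})

test_that("minimization is monotone and stationary at a minimum", {
  s <- make_toy_structure(8)
  pot <- make_potential("enm", s)
  # already at the minimum: unchanged, no productive iterations
  res0 <- minimize(s, pot)
  expect_equal(res0$iterations, 0)
  expect_equal(coords(res0$structure), coords(s), tolerance = 1e-9,
               ignore_attr = TRUE)
  # perturbed copy relaxes with monotone energy
  p <- perturb_structure(s, 0.01, rng_seed = 5)
  res <- minimize(p, pot, max_iter = 100)
  expect_true(all(diff(res$energy_trace) <= 1e-12))
  expect_lte(res$energy, pot$energy(coords(p)))
  expect_lte(res$iterations, 100)
})

test_that("a displaced atom in a harmonic well returns to its minimum", {
  # two-atom elastic pair: analytic minimum restores the rest distance
  s <- make_toy_structure(2)
  pot <- make_potential("enm", s, cutoff = 10)
  p <- s
  p$atoms$x[1] <- p$atoms$x[1] - 1    # stretch by 1 A
  res <- minimize(p, pot, max_iter = 100)
  d0 <- dist(coords(s)[1:2, ])
  # pairwise rest distances restored
  expect_equal(as.matrix(dist(coords(res$structure))),
               as.matrix(dist(coords(s))), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(res$energy, 1e-10)
})

test_that("ensembles are deterministic, sized, and topology-sharing", {
  s <- make_toy_structure(6)
  spec <- ensemble_spec(n_members = 3, seed = 7)
  e1 <- generate_ensemble(s, spec)
  e2 <- generate_ensemble(s, spec)
  expect_identical(e1$members, e2$members)
  expect_length(e1$members, 3)
  for (m in e1$members) {
    expect_equal(m$atoms$name, s$atoms$name)
    expect_gt(rmsd_between(m, s, atom_selection(atom_class = "backbone")),
              0)
  }
  e3 <- generate_ensemble(s, ensemble_spec(n_members = 3, seed = 8))
  expect_false(identical(e1$members, e3$members))
})

test_that("ensemble diversity matches a direct pairwise computation", {
  s <- make_toy_structure(6)
  ens <- generate_ensemble(s, ensemble_spec(n_members = 4, seed = 2,
                                            perturbation = 0.05,
                                            minimizer_iterations = 3))
  div <- ensemble_diversity(ens)
  sel <- atom_selection(atom_class = "backbone")
  pw <- c()
  for (i in 1:3) for (j in (i + 1):4)
    pw <- c(pw, rmsd_between(ens$members[[i]], ens$members[[j]], sel))
  expect_equal(unname(div$pairwise["mean"]), mean(pw), tolerance = 1e-12)
  expect_equal(unname(div$pairwise["sd"]), sd(pw), tolerance = 1e-12)
  # identical members -> zero diversity
  same <- ens
  same$members <- rep(list(s), 3)
  div0 <- ensemble_diversity(same)
  expect_equal(unname(div0$pairwise["mean"]), 0, tolerance = 1e-12)
})

test_that("ensemble spec validates its fields", {
  expect_error(ensemble_spec(n_members = 1), "n_members")
  expect_error(ensemble_spec(perturbation = -0.1), "perturbation")
})
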