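test_that("sequence enumeration is lexicographic with the right count", {
  en <- enumerate_sequences(1, c("B", "A"))
  expect_equal(en$count, 2)
  expect_equal(en$materialize(), c("A", "B"))
  en2 <- enumerate_sequences(3, c("A", "C", "B"))
  mat <- en2$materialize()
  expect_equal(en2$count, 27)
  expect_equal(length(mat), 27)
  expect_equal(mat[1], "AAA")
  expect_equal(mat[27], "CCC")
  expect_false(is.unsorted(mat))
  expect_equal(vapply(seq_len(27), en2$get, character(1)), mat)
  # the designed landscape: 4 positions x 19 amino acids
  expect_equal(enumerate_sequences(4)$count, 130321)
})

test_that("Boltzmann averaging favors low energies within its bounds", {
  expect_equal(boltzmann_average(c(3, 3, 3)), 3)
  # two-level direct evaluation at 300 K
  e <- c(0, 1)
  RT <- 1.9872e-3 * 300
  w <- exp(-e / RT) / sum(exp(-e / RT))
  expect_equal(boltzmann_average(e, 300), sum(e * w), tolerance = 1e-12)
  # low-temperature limit approaches the minimum
  expect_equal(boltzmann_average(c(2, 5, 9), 1e-3), 2, tolerance = 1e-9)
  set.seed(9)
  for (i in 1:20) {
    e <- rnorm(10, 0, 5)
    b <- boltzmann_average(e)
    expect_gte(b, min(e))
    expect_lte(b, mean(e))
  }
  # log-sum-exp stabilization handles huge energies
  expect_equal(boltzmann_average(c(1e4, 1e4 + 1)), 1e4, tolerance = 1e-3)
})

test_that("state energies come from per-member optimization", {
  s <- make_toy_structure(8)
  ens <- generate_ensemble(s, ensemble_spec(n_members = 3, seed = 1))
  mats <- lapply(ens$members, build_energy_matrices,
                 positions = data.frame(chain = "A", resno = c(3, 6)),
                 alphabet = c("ALA", "SER", "VAL"))
  se <- state_energy("AS", mats)
  direct <- vapply(mats, function(m)
    faster_optimize(m, seq = c("ALA", "SER"))$energy, numeric(1))
  expect_equal(se$member_energies, direct)
  expect_equal(se$energy, boltzmann_average(direct, 300), tolerance = 1e-12)
  expect_false(se$clash_flag)
})

test_that("design records enforce the delta-E identity and antisymmetry", {
  rec <- design_records(c("AA", "AB"), c(-5, -3), c(-2, -4))
  expect_equal(rec$delta_e, rec$E_closed - rec$E_open, tolerance = 1e-12)
  swapped <- design_records(rec$sequence, rec$E_open, rec$E_closed)
  expect_equal(swapped$delta_e, -rec$delta_e, tolerance = 1e-12)
})

test_that("the percentile filter discards high-energy outliers", {
  rec <- design_records(sprintf("S%02d", 1:8),
                        e_closed = c(1, 2, 3, 4, 5, 6, 7, 100),
                        e_open = c(8, 7, 6, 5, 4, 3, 2, 1))
  out <- rank_by_delta_e(rec, percentile = 75)
  qc <- quantile(rec$E_closed, 0.75, names = FALSE)
  qo <- quantile(rec$E_open, 0.75, names = FALSE)
  keep <- rec$E_closed <= qc & rec$E_open <= qo
  expect_setequal(out$sequence, rec$sequence[keep])
  expect_false(is.unsorted(out$delta_e))
  # open objective sorts descending
  out2 <- rank_by_delta_e(rec, objective = "open")
  expect_false(is.unsorted(rev(out2$delta_e)))
  # single record survives
  expect_equal(nrow(rank_by_delta_e(rec[1, , drop = FALSE])), 1)
})

test_that("library design picks the top amino acids per position", {
  rec <- design_records(c("A", "C", "D"), c(-10, -6, -2), c(0, 0, 0))
  lib <- clearss_design(rec, target = 2, tol = 0)
  expect_equal(lib$size, 2)
  expect_equal(lib$sets[[1]], c("A", "C"))   # two lowest delta-E letters
})

test_that("library design equals an exhaustive configuration search", {
  set.seed(42)
  aas <- c("A", "C", "D", "E", "F")
  seqs <- apply(expand.grid(aas, aas), 1, paste, collapse = "")
  rec <- design_records(seqs, rnorm(25, -5, 3), rnorm(25, -2, 3))
  lib <- clearss_design(rec, target = 6, tol = 2)
  expect_true(lib$size >= 4 && lib$size <= 8)
  # independent exhaustive enumerator over all set-size configurations
  probs <- lib$probabilities
  best_score <- -Inf
  for (n1 in 1:5) for (n2 in 1:5) {
    sz <- n1 * n2
    if (sz < 4 || sz > 8) next
    sc <- sum(probs[[1]][1:n1]) + sum(probs[[2]][1:n2])
    if (sc > best_score) best_score <- sc
  }
  expect_equal(lib$score, best_score, tolerance = 1e-12)
  # score is monotone non-decreasing in the tolerance
  lib_wide <- clearss_design(rec, target = 6, tol = 4)
  expect_gte(lib_wide$score, lib$score - 1e-12)
  # expansion enumerates size-many sequences
  expect_length(expand_library(lib), lib$size)
})

test_that("the toy pipeline is deterministic end to end", {
  run_once <- function() {
    open_s <- make_toy_structure(8)
    closed_s <- make_toy_structure(8, phi = -70, psi = -30, id = "toy_closed")
    design_pipeline(
      generate_ensemble(open_s, ensemble_spec(n_members = 2, seed = 5)),
      generate_ensemble(closed_s, ensemble_spec(n_members = 2, seed = 1005)),
      data.frame(chain = "A", resno = c(3, 6)),
      alphabet = c("ALA", "SER", "VAL"), target = 4, tol = 1)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$ranked, r2$ranked)
  expect_identical(r1$library$sets, r2$library$sets)
  # delta-E column honors its identity row-wise
  expect_equal(r1$ranked$delta_e, r1$ranked$E_closed - r1$ranked$E_open,
               tolerance = 1e-9)
  # swapping the ensembles negates delta-E
  swapped <- design_records(r1$records$sequence, r1$records$E_open,
                            r1$records$E_closed)
  expect_equal(swapped$delta_e, -r1$records$delta_e, tolerance = 1e-12)
})
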