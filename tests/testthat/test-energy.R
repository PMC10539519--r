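ff <- load_ff_tables()

test_that("the LJ 12-6 term has its minimum, zero crossing and asymptote", {
  p <- confdesign:::ff_lookup(ff, "CB", "C")
  r0 <- 2 * p$lj_radius * ff$lj_radius_scale   # like-pair combined radius
  eps <- p$lj_eps
  expect_equal(lj_energy("CB", "CB", r0), -eps, tolerance = 1e-12)
  expect_equal(lj_energy("CB", "CB", r0 * 2^(-1 / 6)), 0, tolerance = 1e-10)
  expect_equal(lj_energy("CB", "CB", 50), 0, tolerance = 1e-6)
  expect_lt(lj_energy("CB", "CB", 50), 0)          # approaches 0 from below
  expect_equal(lj_energy("CB", "CB", 0.3), 100)    # clash cap
  expect_error(lj_energy("CB", "CB", 0), "r must be > 0")
})

test_that("the hydrogen-bond term hits -8 kcal/mol at 2.8 A and cuts off", {
  expect_equal(hbond_energy(2.8, 180), -8.0, tolerance = 1e-12)
  expect_equal(hbond_energy(2.8, 80), 0)
  expect_gt(hbond_energy(3.2, 180), -8.0)
  # direct evaluation of the 12-10 form at 3.2 A
  rr <- 2.8 / 3.2
  expect_equal(hbond_energy(3.2, 180), 8 * (5 * rr^12 - 6 * rr^10),
               tolerance = 1e-12)
  # angular factor: cos^4
  expect_equal(hbond_energy(2.8, 120), -8 * cos(120 * pi / 180)^4,
               tolerance = 1e-12)
})

test_that("Coulomb term follows 332.0637 q1 q2 / (10 r^2) and sign rules", {
  expect_equal(coulomb_energy(0, 0.5, 3), 0)
  expect_equal(coulomb_energy(0.5, 0.5, 2.8),
               332.0637 * 0.25 / (10 * 2.8^2), tolerance = 1e-12)
  r <- seq(1, 8, 0.5)
  expect_true(all(coulomb_energy(0.4, -0.3, r) < 0))
  constant_ff <- ff
  constant_ff$dielectric_model <- "constant"
  expect_equal(coulomb_energy(0.5, 0.5, 2.8, constant_ff),
               332.0637 * 0.25 / (10 * 2.8), tolerance = 1e-12)
})

test_that("solvation penalty is zero when isolated and monotone in approach", {
  expect_equal(solvation_penalty(0.01, numeric(0), numeric(0)), 0)
  # one neighbor: coefficient x refvol x kernel, by direct evaluation
  expect_equal(solvation_penalty(0.01, 15, 3.5),
               0.01 * 15 * exp(-1), tolerance = 1e-12)
  r <- seq(6, 0.5, -0.25)
  pen <- vapply(r, function(ri) solvation_penalty(0.01, 15, ri), numeric(1))
  expect_true(all(diff(pen) > 0))
})

test_that("secondary-structure propensity is an additive exact lookup", {
  d_gly <- ss_propensity("GLY", "helix")
  d_ala <- ss_propensity("ALA", "helix")
  expect_equal(d_gly - d_ala, 0.45 - (-0.30), tolerance = 1e-12)
  expect_warning(out <- ss_propensity("XXX", "helix"), "XXX")
  expect_equal(out, 0)
  seqv <- c("ALA", "VAL", "LEU", "GLY")
  total <- sum(ss_propensity(seqv, "strand"))
  indiv <- sum(vapply(seqv, function(a) ss_propensity(a, "strand"),
                      numeric(1)))
  expect_equal(total, indiv, tolerance = 1e-12)
})

test_that("phi/psi classes map to helix, strand and other", {
  expect_equal(ss_class_from_phipsi(-60, -45), "helix")
  expect_equal(ss_class_from_phipsi(-120, 130), "strand")
  expect_equal(ss_class_from_phipsi(60, 40), "other")
  expect_equal(ss_class_from_phipsi(NA, 40), "other")
})

test_that("assignment energy decomposes into singles plus pairs exactly", {
  s <- make_toy_structure(8)
  pos <- data.frame(chain = "A", resno = c(3, 6))
  m <- build_energy_matrices(s, pos, alphabet = c("ALA", "SER", "VAL"))
  nc <- vapply(m$singles, length, integer(1))
  for (a1 in seq_len(nc[1])) for (a2 in seq_len(nc[2])) {
    direct <- m$singles[[1]][a1] + m$singles[[2]][a2] +
      m$pairs[[1]][[2]][a1, a2]
    expect_equal(assignment_energy(m, c(a1, a2)), direct,
                 tolerance = 1e-9)
  }
})

test_that("positions beyond the cutoff have zero pair energies", {
  s <- make_toy_structure(30, phi = -120, psi = 130)  # extended chain
  pos <- data.frame(chain = "A", resno = c(2, 29))
  m <- build_energy_matrices(s, pos, alphabet = c("ALA", "SER"))
  expect_true(all(m$pairs[[1]][[2]] == 0))
})

test_that("matrices are invariant under a global rigid motion", {
  s <- make_toy_structure(8)
  pos <- data.frame(chain = "A", resno = c(3, 6))
  m1 <- build_energy_matrices(s, pos, alphabet = c("SER", "VAL"))
  R <- confdesign:::rotation_about_axis(c(1, 0, 1), 33)
  s2 <- transform_structure(s, R, c(3, -2, 1))
  m2 <- build_energy_matrices(s2, pos, alphabet = c("SER", "VAL"))
  expect_equal(m1$singles, m2$singles, tolerance = 1e-8)
  expect_equal(m1$pairs[[1]][[2]], m2$pairs[[1]][[2]], tolerance = 1e-8)
})

test_that("pair energies equal a direct atom-pair term summation", {
  # brute-force oracle: recompute one pair entry term by term
  s <- make_toy_structure(8)
  pos <- data.frame(chain = "A", resno = c(3, 6))
  lib <- load_rotamer_library()
  m <- build_energy_matrices(s, pos, lib = lib, alphabet = c("SER"))
  bb3 <- confdesign:::backbone_frame(s, "A", 3)
  bb6 <- confdesign:::backbone_frame(s, "A", 6)
  r3 <- get_rotamers(lib, "SER")
  for (pick in c(1, nrow(r3))) {
    sc3 <- build_sidechain("SER", r3$chi1[pick], bb3)
    sc6 <- build_sidechain("SER", r3$chi1[1], bb6)
    manual <- 0
    for (i in seq_len(nrow(sc3))) for (j in seq_len(nrow(sc6))) {
      r <- sqrt(sum((sc3[i, ] - sc6[j, ])^2))
      if (r >= ff$cutoff) next
      pi_ <- confdesign:::ff_lookup(ff, rownames(sc3)[i],
                                    substr(rownames(sc3)[i], 1, 1))
      pj <- confdesign:::ff_lookup(ff, rownames(sc6)[j],
                                   substr(rownames(sc6)[j], 1, 1))
      e <- lj_energy(pi_, pj, r) + coulomb_energy(pi_$charge, pj$charge, r)
      if (((pi_$donor == 1 && pj$acceptor == 1) ||
           (pj$donor == 1 && pi_$acceptor == 1)) && r < 3.5)
        e <- e + hbond_energy(r, 180)
      e <- e + pi_$solv_coeff * pj$solv_refvol * exp(-(r / 3.5)^2) +
        pj$solv_coeff * pi_$solv_refvol * exp(-(r / 3.5)^2)
      manual <- manual + min(e, 100)
    }
    expect_equal(m$pairs[[1]][[2]][pick, 1], min(manual, 100),
                 tolerance = 1e-9)
  }
})
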