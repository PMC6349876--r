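test_that("canonical builds close through the analysis layer", {
  seqp <- wt_sequence()
  # PPII-built chain round-trips its dihedrals
  conf <- ideal_conf(-75, 145)
  tp <- compute_torsions(conf)
  expect_lt(max(abs(tp$phi[-1] + 75)), 0.01)
  expect_lt(max(abs(tp$psi[-27] - 145)), 0.01)
  # helix-built chain is read back as helix
  expect_true(all(assign_ss(helix_conf())[2:26] == "H"))
  # build -> measure closure for the fragment CVs
  expect_gte(ss_rmsd_cv(helix_conf(), "alpha"), 0.95 * 22)
  coil <- random_coil_frames(1, seed = 31)$trajectory$frames[[1]]
  expect_lte(ss_rmsd_cv(coil, "alpha"), 0.05 * 22)
})

test_that("drawn block fractions match their probabilities", {
  seqp <- wt_sequence()
  spec <- ss_spec(27, blocks = list(
    list(state = "H", prob = 0.2, residues = 15:18)), noise_sd = 8)
  ens <- sample_ensemble(seqp, spec, 600, seed = 3)
  p <- mean(ens$labels[, 16] == "H")
  expect_lt(abs(p - 0.2), binom_tol3(0.2, 600))
  # drawn-H frames carry helical dihedrals at the block
  hframes <- which(ens$labels[, 16] == "H")
  expect_lt(max(abs(vapply(hframes, function(f)
    ens$torsions[[f]]$phi[16], numeric(1)) + 57.8)), 40)
})

test_that("noise-free P blocks are ground-truth P by the box rule", {
  seqp <- wt_sequence()
  spec <- ss_spec(27, blocks = list(
    list(state = "P", prob = 1, residues = 10:12)), noise_sd = 0)
  ens <- sample_ensemble(seqp, spec, 3, seed = 5)
  expect_true(all(ens$labels[, 10:12] == "P"))
  expect_true(all(ens$labels[, 1] == "C"))
})

test_that("ensembles are deterministic under a fixed seed", {
  seqp <- wt_sequence()
  spec <- ss_spec(27, blocks = list(
    list(state = "H", prob = 0.3, residues = 5:9)), noise_sd = 8)
  e1 <- sample_ensemble(seqp, spec, 5, seed = 17)
  e2 <- sample_ensemble(seqp, spec, 5, seed = 17)
  expect_identical(e1$labels, e2$labels)
  expect_identical(e1$trajectory$frames[[3]]$xyz,
                   e2$trajectory$frames[[3]]$xyz)
  e3 <- sample_ensemble(seqp, spec, 5, seed = 18)
  expect_false(identical(e1$trajectory$frames[[3]]$xyz,
                         e3$trajectory$frames[[3]]$xyz))
})

test_that("E blocks fold into classifiable hairpins", {
  seqp <- wt_sequence()
  spec <- ss_spec(27, blocks = list(
    list(state = "E", prob = 1, strand1 = 5:8, strand2 = 11:14)),
    noise_sd = 2)
  ens <- sample_ensemble(seqp, spec, 10, seed = 7)
  expect_true(all(ens$labels[, c(5:8, 11:14)] == "E"))
  hits <- vapply(ens$trajectory$frames, function(fr) {
    mean(assign_ss(fr)[c(5:8, 11:14)] == "E")
  }, numeric(1))
  expect_gte(mean(hits), 0.75)
})

test_that("toy energy: well depth arithmetic and gradient check", {
  seqp <- wt_sequence()
  model <- toy_energy_model(
    data.frame(res = 0L, phi0 = -57.8, psi0 = -47, depth = 3, width = 30),
    ev_sigma = 0, ev_eps = 0)
  tor <- bemetad:::torsion_table(27, -57.8, -47)
  tor$phi[1] <- NA; tor$psi[27] <- NA
  # 25 residues contribute (undefined terminal angles drop out)
  expect_equal(toy_energy(tor, model), -3 * 25, tolerance = 1e-9)
  # well-to-well energy difference equals the depth difference
  model2 <- toy_energy_model(
    data.frame(res = 0L, phi0 = c(-57.8, -75), psi0 = c(-47, 145),
               depth = c(3, 5), width = c(30, 30)),
    ev_sigma = 0, ev_eps = 0)
  tor_p <- bemetad:::torsion_table(27, -75, 145)
  tor_p$phi[1] <- NA; tor_p$psi[27] <- NA
  da <- toy_energy(tor, model2)
  dp <- toy_energy(tor_p, model2)
  expect_equal(dp - da, -(5 - 3) * 25, tolerance = 1e-6)
  # analytic gradient vs central differences at random points
  set.seed(8)
  tor_r <- bemetad:::torsion_table(27, runif(27, -180, 180),
                                   runif(27, -180, 180))
  g <- toy_energy_gradient(tor_r, model2)
  for (i in sample(2:26, 5)) {
    h <- 1e-4
    tp <- tor_r; tp$phi[i] <- tp$phi[i] + h
    tm <- tor_r; tm$phi[i] <- tm$phi[i] - h
    num <- (toy_energy(tp, model2) - toy_energy(tm, model2)) / (2 * h)
    expect_equal(unname(g[i, "dphi"]), num,
                 tolerance = 1e-4 * max(1, abs(num)))
  }
})

test_that("excluded volume penalises clashes", {
  seqp <- wt_sequence()
  model <- toy_energy_model(
    data.frame(res = 0L, phi0 = 0, psi0 = 0, depth = 0, width = 30),
    ev_sigma = 0.55, ev_eps = 10)
  hel <- helix_conf()   # compact: CA i,i+3 within 0.5 nm
  ext <- extended_conf()
  th <- compute_torsions(hel); te <- compute_torsions(ext)
  expect_gt(toy_energy(th, model, hel), toy_energy(te, model, ext))
  expect_equal(toy_energy(te, model, ext), 0, tolerance = 1e-6)
})

test_that("analytic potentials carry quadrature references", {
  kT <- bemetad:::KB_KJMOL * 330
  sym <- make_analytic_potential("double_well_1d", kT = kT)
  expect_equal(sym$reference$dF, 0, tolerance = 1e-8)
  asym <- make_analytic_potential("asymmetric_double_well_1d", kT = kT)
  # independent re-quadrature on a fine grid
  xs <- seq(-2.2, 2.2, length.out = 20001)
  u <- asym$U(xs)
  split <- asym$reference$basin_split
  simpson_z <- function(f) {
    w <- rep(c(2, 4), length.out = length(xs)); w[1] <- 1; w[length(xs)] <- 1
    sum(w / 3 * f) * diff(xs)[1]
  }
  za <- simpson_z(ifelse(xs < split, exp(-u / kT), 0))
  zb <- simpson_z(ifelse(xs >= split, exp(-u / kT), 0))
  expect_equal(asym$reference$dF, -kT * log(zb / za), tolerance = 1e-3)
  expect_gt(asym$reference$barrier, 0)
  # temperature dependence is consistent with re-quadrature
  asym2 <- make_analytic_potential("asymmetric_double_well_1d", kT = 2 * kT)
  za2 <- simpson_z(ifelse(xs < split, exp(-u / (2 * kT)), 0))
  zb2 <- simpson_z(ifelse(xs >= split, exp(-u / (2 * kT)), 0))
  expect_equal(asym2$reference$dF, -2 * kT * log(zb2 / za2),
               tolerance = 1e-3)
  expect_error(make_analytic_potential("double_well_1d", kT = -1), "kT")
})

test_that("2D potential marginals normalise to zero minimum", {
  pot <- make_analytic_potential("two_basin_2d", kT = 2.744)
  expect_equal(min(pot$reference$marginal_x$F), 0)
  expect_equal(min(pot$reference$marginal_y$F), 0)
  # x-marginal of the coupled surface has the closed Gaussian-integral
  # form a(x^2-1)^2 - c^2 x^2 / (2 ky) + const
  xs <- pot$reference$marginal_x$x
  p <- pot$params
  ref <- p$a * (xs^2 - 1)^2 - p$c^2 * xs^2 / (2 * p$ky)
  ref <- ref - min(ref)
  expect_lt(max(abs(pot$reference$marginal_x$F - ref)), 1e-3)
})
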