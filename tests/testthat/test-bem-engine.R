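kT330 <- bemetad:::KB_KJMOL * 330

test_that("bias energy and gradient: hill sum arithmetic", {
  b <- bias_state(1L)
  expect_equal(bias_energy(b, 0.5), 0)
  sch <- bem_schedule(total_time = 40)
  deposit(b, 0.3, sch, 4)
  expect_equal(bias_energy(b, 0.3), 0.2)
  expect_equal(bias_energy(b, 0.5), 0.2 * exp(-0.5), tolerance = 1e-12)
  deposit(b, 0.3, sch, 8)
  expect_equal(bias_energy(b, 0.3), 0.4)  # linearity of deposits
  expect_error(deposit(b, 0.3, sch, 5), "not aligned")
  # gradient check against central differences
  g <- bias_gradient(b, 0.45)
  num <- (bias_energy(b, 0.45 + 1e-6) - bias_energy(b, 0.45 - 1e-6)) / 2e-6
  expect_equal(g, num, tolerance = 1e-5)
})

test_that("deposition schedule yields floor(T / interval) hills", {
  pot <- make_analytic_potential("double_well_1d", kT = kT330)
  sch <- bem_schedule(total_time = 40, seed = 2)
  run <- run_bem(list(langevin_sampler(pot)), 1L, sch, pot$domain)
  expect_equal(length(run$bias_histories[[1]]$centers), 10L)
  sch0 <- bem_schedule(total_time = 0, seed = 2)
  run0 <- run_bem(list(langevin_sampler(pot)), 1L, sch0, pot$domain)
  expect_equal(length(run0$bias_histories[[1]]$centers), 0L)
})

test_that("exchange: acceptance rules and long-run frequency", {
  streams <- bemetad:::make_rng_streams(1, 1)
  rng <- streams[[1]]
  mk_rep <- function(bias, cvs) {
    e <- new.env(); e$bias <- bias; e$cvs <- cvs; e$time <- 0; e
  }
  sch <- bem_schedule(total_time = 40)
  # identical bias states -> delta 0 -> always accepted
  b1 <- bias_state(1L); deposit(b1, 0.5, sch, 4)
  b2 <- bias_state(1L); deposit(b2, 0.5, sch, 4)
  acc <- vapply(1:20, function(i) {
    attempt_exchange(mk_rep(b1, 0.5), mk_rep(b2, 0.5), kT330, rng)
  }, logical(1))
  expect_true(all(acc))
  # own-bias energies positive, crossed zero -> delta > 0 -> accepted
  b3 <- bias_state(1L); deposit(b3, 0, sch, 4)
  b4 <- bias_state(2L); deposit(b4, 5, sch, 4)
  expect_true(attempt_exchange(mk_rep(b3, c(0, 99)), mk_rep(b4, c(99, 5)),
                               kT330, rng))
  # frozen pair: empirical acceptance matches the analytic probability
  ra_bias <- bias_state(1L)
  for (t in 1:10) deposit(ra_bias, 0.1, sch, 4 * t)  # 2 kJ/mol at 0.1
  rb_bias <- bias_state(1L)
  # replica a sits far from its own hills, so the swap is uphill
  delta <- (bias_energy(ra_bias, 0.9) - bias_energy(ra_bias, 0.1)) / kT330
  p_acc <- min(1, exp(delta))
  expect_lt(p_acc, 1)
  n <- 2000
  hits <- 0
  for (i in 1:n) {
    # fresh replica wrappers each trial; the bias states themselves are
    # never mutated by a swap, so every trial is identical
    if (attempt_exchange(mk_rep(ra_bias, 0.9), mk_rep(rb_bias, 0.1),
                         kT330, rng)) hits <- hits + 1
  }
  expect_lt(abs(hits / n - p_acc), 3 * sqrt(p_acc * (1 - p_acc) / n) + 1e-9)
  expect_error(attempt_exchange(mk_rep(b1, 0.5),
                                { e <- mk_rep(b2, 0.5); e$time <- 4; e },
                                kT330, rng), "common time")
})

test_that("seven replicas with seven CVs keep distinct bias indices", {
  seqp <- wt_sequence()
  sch <- bem_schedule(total_time = 8, seed = 4, exchange_interval = 4)
  samplers <- lapply(1:7, function(i) torsion_mc_sampler(seqp, move_size = 10))
  run <- run_bem(samplers, 1:7, sch,
                 bemetad:::cv_default_ranges(27, cv_config(seqp)),
                 record_cvs = 1:7)
  idx <- sort(vapply(run$bias_histories, function(b) b$cv_index, integer(1)))
  expect_equal(idx, 1:7)
  expect_true(all(vapply(run$bias_histories,
                         function(b) length(b$centers), integer(1)) == 2L))
})

test_that("seeded BEM runs are bit-reproducible", {
  pot <- make_analytic_potential("asymmetric_double_well_1d", kT = kT330)
  sch <- bem_schedule(total_time = 200, seed = 42)
  r1 <- run_bem(list(langevin_sampler(pot)), 1L, sch, pot$domain)
  r2 <- run_bem(list(langevin_sampler(pot)), 1L, sch, pot$domain)
  expect_identical(r1$cv_series, r2$cv_series)
  expect_identical(r1$bias_histories[[1]]$centers,
                   r2$bias_histories[[1]]$centers)
})

test_that("unbiased Langevin equilibrates to the Boltzmann distribution", {
  # harmonic well: sample variance = kT / k_spring
  k_spring <- 8
  harm <- structure(list(kind = "harmonic", dim = 1L,
                         U = function(x) 0.5 * k_spring * x^2,
                         grad = function(x) k_spring * x,
                         domain = list(c(-4, 4)),
                         reference = list(minima = 0)),
                    class = "AnalyticPotential")
  st <- bemetad:::make_rng_streams(8, 1)[[1]]
  s <- langevin_sampler(harm, friction = 2, dt = 0.02, x0 = 0)
  x <- numeric(8000)
  for (i in seq_along(x)) {   # 1 ps apart: ~independent at gamma/k = 0.25 ps
    s <- sampler_advance(s, 1, NULL, kT330, st)
    x[i] <- s$x
  }
  x <- x[-(1:200)]
  expect_lt(abs(var(x) - kT330 / k_spring) / (kT330 / k_spring), 0.05)
  # symmetric double well: equal occupancies within 3 sigma (correlated
  # samples: use a conservative effective n)
  pot <- make_analytic_potential("double_well_1d", kT = kT330)
  sch <- bem_schedule(total_time = 4000, seed = 8, record_interval = 4)
  run2 <- run_bem(list(langevin_sampler(pot, friction = 1, dt = 0.02)),
                  NA_integer_, sch, pot$domain)
  x2 <- run2$cv_series$cv1[-(1:100)]
  p <- mean(x2 > 0)
  n_eff <- length(x2) / 20
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n_eff))
})

test_that("near-zero temperature Langevin descends to the nearest minimum", {
  pot <- make_analytic_potential("double_well_1d", kT = kT330)
  s <- langevin_sampler(pot, x0 = -0.5, dt = 0.01)
  streams <- bemetad:::make_rng_streams(1, 1)
  s <- sampler_advance(s, 50, NULL, 1e-6, streams[[1]])
  expect_equal(s$x, -1, tolerance = 1e-3)
  # zero-span advance is the identity
  x_before <- s$x
  s <- sampler_advance(s, 0, NULL, kT330, streams[[1]])
  expect_identical(s$x, x_before)
})

test_that("torsion MC: flat energy gives uniform dihedral marginals", {
  seqp <- wt_sequence()
  s <- torsion_mc_sampler(seqp, energy_model = NULL, move_size = 60)
  streams <- bemetad:::make_rng_streams(3, 1)
  phis <- numeric(0)
  for (chunk in 1:60) {
    s <- sampler_advance(s, 5, NULL, kT330, streams[[1]])
    phis <- c(phis, s$torsions$phi[10])
  }
  # all proposals accepted under a flat target -> wrapped uniform walk;
  # quadrant occupancy ~ uniform
  counts <- table(cut(phis, breaks = c(-180, -90, 0, 90, 180)))
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.001)
})

test_that("torsion MC with an alpha well folds the chain helical", {
  seqp <- wt_sequence()
  # funnelled alpha well: a broad basin guiding the chain plus a narrow
  # deep well holding it at helical dihedrals
  model <- toy_energy_model(
    data.frame(res = 0L, phi0 = -57.8, psi0 = -47.0,
               depth = c(8, 25), width = c(120, 18)),
    ev_sigma = 0, ev_eps = 0)
  s <- torsion_mc_sampler(seqp, model, move_size = 25)
  streams <- bemetad:::make_rng_streams(6, 1)
  cv1_start <- ss_rmsd_cv(s$conf, "alpha")
  s <- sampler_advance(s, 80, NULL, kT330, streams[[1]])
  cv1_mid <- ss_rmsd_cv(s$conf, "alpha")
  s <- sampler_advance(s, 120, NULL, kT330, streams[[1]])
  cv1_end <- ss_rmsd_cv(s$conf, "alpha")
  expect_lt(cv1_start, 1)
  expect_gt(cv1_mid, cv1_start)   # helix content rises over burn-in
  expect_gt(cv1_end, cv1_mid)
  expect_gt(cv1_end, 15)
})

test_that("MC acceptance respects detailed balance on a two-state toy", {
  # single tight well on one residue's phi: occupancy ratio between the
  # well half-plane and the rest must match the Boltzmann ratio
  seqp <- wt_sequence()
  model <- toy_energy_model(
    data.frame(res = 10L, phi0 = -60, psi0 = 130, depth = 6, width = 50),
    ev_sigma = 0, ev_eps = 0)
  s <- torsion_mc_sampler(seqp, model, move_size = 90)
  streams <- bemetad:::make_rng_streams(9, 1)
  obs <- numeric(0)
  for (chunk in 1:150) {
    s <- sampler_advance(s, 2, NULL, kT330, streams[[1]])
    obs <- c(obs, c(s$torsions$phi[10], s$torsions$psi[10]))
  }
  phi <- obs[seq(1, length(obs), 2)]
  psi <- obs[seq(2, length(obs), 2)]
  inwell <- abs(bemetad:::angle_diff(phi, -60)) < 90 &
    abs(bemetad:::angle_diff(psi, 130)) < 90
  # Boltzmann reference by direct 2D quadrature of the well energy
  gr <- seq(-179.5, 179.5, by = 1)
  en <- function(p, q) -6 * exp(-(bemetad:::angle_diff(p, -60)^2 +
                                    bemetad:::angle_diff(q, 130)^2) / (2 * 50^2))
  z <- outer(gr, gr, function(p, q) exp(-en(p, q) / kT330))
  inbox <- outer(gr, gr, function(p, q)
    abs(bemetad:::angle_diff(p, -60)) < 90 &
      abs(bemetad:::angle_diff(q, 130)) < 90)
  p_ref <- sum(z[inbox]) / sum(z)
  n_eff <- length(inwell) / 15
  expect_lt(abs(mean(inwell) - p_ref),
            3 * sqrt(p_ref * (1 - p_ref) / n_eff))
})
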