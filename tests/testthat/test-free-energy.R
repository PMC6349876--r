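kT <- bemetad:::KB_KJMOL * 330

fake_series <- function(cv1, cv2 = NULL, replica = 1L) {
  d <- data.frame(time_ps = seq_along(cv1), cv1 = cv1, replica = replica)
  if (!is.null(cv2)) d$cv2 <- cv2
  d
}

test_that("histogramming: placement, edge rule, conservation", {
  spec <- cv_grid_spec(1L, 0, 10, 10L)
  h <- histogram_frames(fake_series(5.05), spec, equil_frac = 0)
  expect_equal(sum(h$counts[[1]]), 1L)
  expect_equal(which(h$counts[[1]] == 1L), 6L)
  # interior edge goes to the upper bin; the top edge to the last bin
  h2 <- histogram_frames(fake_series(c(1.0, 10.0)), spec, equil_frac = 0)
  expect_equal(which(h2$counts[[1]] > 0), c(2L, 10L))
  # conservation including out-of-range frames
  set.seed(1)
  vals <- runif(500, -2, 12)
  h3 <- histogram_frames(fake_series(vals), spec, equil_frac = 0)
  expect_equal(sum(h3$counts[[1]]) + h3$out_of_range[1], 500)
  expect_error(histogram_frames(fake_series(c(-5, 20)), spec, 0),
               "outside the grid")
})

test_that("equilibration cut discards the first fraction per replica", {
  spec <- cv_grid_spec(1L, 0, 10, 10L)
  vals <- c(rep(0.5, 10), rep(9.5, 90))
  h <- histogram_frames(fake_series(vals), spec, equil_frac = 0.1)
  expect_equal(sum(h$counts[[1]]), 90L)
  expect_equal(h$counts[[1]][1], 0L)
})

test_that("WHAM degenerate case equals direct Boltzmann inversion", {
  spec <- cv_grid_spec(1L, 0, 10, 20L)
  set.seed(2)
  vals <- rnorm(4000, 5, 1.2)
  h <- histogram_frames(fake_series(vals), spec, equil_frac = 0)
  fes <- wham_combine(h, list(bias_state(NA_integer_)), kT)
  cnt <- h$counts[[1]]
  direct <- -kT * log(cnt / sum(cnt))
  direct <- direct - min(direct[cnt > 0])
  expect_lt(max(abs(fes$values[cnt > 0] - direct[cnt > 0])), 1e-8)
  expect_equal(min(fes$values[fes$visited]), 0)
})

test_that("WHAM recovers a known profile from two analytically biased
           replicas", {
  # target F(x) on a grid; replica r samples from exp(-(F + V_r)/kT)
  spec <- cv_grid_spec(1L, -1.6, 1.6, 32L)
  xs <- bemetad:::grid_centers(spec)[[1]]
  Ftrue <- 4 * (xs^2 - 1)^2
  sch <- bem_schedule(total_time = 40)
  b1 <- bias_state(1L)
  for (t in 1:25) deposit(b1, -1, sch, 4 * t)   # 5 kJ/mol hill stack at -1
  b2 <- bias_state(1L)
  for (t in 1:25) deposit(b2, 1, sch, 4 * t)
  set.seed(7)
  draw <- function(bias, n) {
    p <- exp(-(Ftrue + bias_energy(bias, xs)) / kT)
    sample(xs, n, replace = TRUE, prob = p / sum(p))
  }
  cs <- rbind(fake_series(draw(b1, 60000), replica = 1L),
              fake_series(draw(b2, 60000), replica = 2L))
  h <- histogram_frames(cs, spec, equil_frac = 0)
  fes <- wham_combine(h, list(b1, b2), kT)
  ref <- Ftrue - min(Ftrue)
  ok <- fes$visited
  err <- fes$values[ok] - ref[ok]
  expect_lt(sqrt(mean(err^2)), 0.2)
  # replica order must not matter
  h_perm <- h; h_perm$counts <- h$counts[c(2, 1)]
  fes2 <- wham_combine(h_perm, list(b2, b1), kT)
  expect_equal(fes2$values, fes$values, tolerance = 1e-8)
  # an empty replica must not change the result
  h_aug <- h; h_aug$counts <- c(h$counts, list(rep(0L, 32)))
  fes3 <- wham_combine(h_aug, list(b1, b2, bias_state(1L)), kT)
  expect_equal(fes3$values, fes$values, tolerance = 1e-6)
})

test_that("WHAM reports disconnected histograms", {
  spec <- cv_grid_spec(1L, 0, 10, 10L)
  cs <- rbind(fake_series(rep(0.5, 50), replica = 1L),
              fake_series(rep(9.5, 50), replica = 2L))
  h <- histogram_frames(cs, spec, equil_frac = 0)
  expect_error(wham_combine(h, list(bias_state(NA), bias_state(NA)), kT),
               "non-overlapping")
})

test_that("frame free energies and window assignment follow the grid", {
  spec <- cv_grid_spec(1L, 0, 10, 10L)
  set.seed(3)
  cs <- fake_series(c(rep(0.5, 400), rep(1.5, 100), rep(2.5, 10),
                      rep(3.5, 2)))
  h <- histogram_frames(cs, spec, equil_frac = 0)
  fes <- wham_combine(h, list(bias_state(NA)), kT)
  expect_equal(frame_free_energy(c(0.5), fes), 0)
  expect_true(is.na(frame_free_energy(c(8.5), fes)))  # unvisited
  # manual lookup oracle on random frames
  for (x in runif(10, 0, 4)) {
    cell <- floor(x) + 1
    expect_equal(frame_free_energy(c(x), fes), fes$values[cell])
  }
  wins <- assign_windows(cs, fes)
  expect_equal(wins$window[1], 1L)
  expect_true(all(!is.na(wins$window)))
  # conservation: window populations sum to in-range frames
  expect_equal(sum(table(wins$window)), nrow(cs))
  # exact boundary goes to the upper window
  fe <- c(0, 5, 10)
  w <- floor(fe / 5) + 1L
  expect_equal(w, c(1L, 2L, 3L))
})

test_that("marginalization: identity, symmetry and separable closed form", {
  spec <- cv_grid_spec(c(1L, 2L), c(-2, -2), c(2, 2), c(20L, 20L))
  xs <- bemetad:::grid_centers(spec)[[1]]
  fx <- (xs^2 - 1)^2
  fy <- 2 * xs^2
  vals <- outer(exp(-fx / kT), exp(-fy / kT))
  grid <- structure(list(spec = spec, values = -kT * log(as.vector(vals)),
                         visited = rep(TRUE, 400), kT = kT,
                         iterations = 0L, residual = 0),
                    class = "FreeEnergyGrid")
  grid <- normalize_grid(grid)
  full <- marginalize(grid, c(1L, 2L))
  expect_equal(full$values, grid$values, tolerance = 1e-12)
  m1 <- marginalize(grid, 1L)
  # separable: the x-marginal equals fx up to a constant
  ref <- fx - min(fx)
  expect_lt(max(abs(m1$values - ref)), 1e-6)
  # symmetric input gives a symmetric marginal
  m2 <- marginalize(grid, 2L)
  expect_equal(m2$values, rev(m2$values), tolerance = 1e-9)
  expect_equal(min(m1$values), 0)
})

test_that("the peptide BEM landscape's global minimum basin is
           disordered (low helix count)", {
  seqp <- wt_sequence()
  # coil-favouring toy energy: broad well at extended dihedrals
  model <- toy_energy_model(
    data.frame(res = 0L, phi0 = -135, psi0 = 135, depth = 4, width = 60),
    ev_sigma = 0, ev_eps = 0)
  cvcfg <- cv_config(seqp)
  sch <- bem_schedule(total_time = 40, deposit_interval = 2,
                      exchange_interval = 20, record_interval = 2,
                      seed = 14)
  samplers <- lapply(1:7, function(k)
    torsion_mc_sampler(seqp, model, move_size = 30, config = cvcfg))
  ranges <- bemetad:::cv_default_ranges(27, cvcfg)
  run <- run_bem(samplers, 1:7, sch, ranges, record_cvs = 1:7)
  spec <- cv_grid_spec(1L, 0, 22, 220L)  # fine bins resolve the coil peak
  h <- histogram_frames(run$cv_series, spec, equil_frac = 0.06)
  fes <- suppressWarnings(
    wham_combine(h, run$bias_histories, bemetad:::KB_KJMOL * 330))
  fe <- frame_free_energy(run$cv_series, fes)
  low <- !is.na(fe) & fe < 2
  expect_gt(sum(low), 0)
  expect_gt(sum(!low & !is.na(fe)), 0)  # some frames above 2 kJ/mol
  expect_lt(mean(run$cv_series$cv1[low]), mean(run$cv_series$cv1))
})
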