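# Pluggable samplers for the BEM engine. A sampler state is an
# environment; the engine only relies on the two generics below, so a
# molecular-dynamics backend could be plugged in behind the same
# contract.

#' Current CV values of a sampler state
#'
#' @param state a sampler state.
#' @param indices CV indices actually needed (a peptide sampler may
#'   skip the expensive ones and return NA there); NULL = all.
#' @return numeric CV vector.
#' @export
sampler_cvs <- function(state, indices = NULL) UseMethod("sampler_cvs")

#' Advance a sampler by a time span under a bias
#'
#' Advancing by a zero span is the identity.
#'
#' @param state a sampler state.
#' @param span_ps time to advance (ps).
#' @param bias a `BiasState` acting on one CV (may be NULL/unbiased).
#' @param kT thermal energy (kJ/mol).
#' @param rng the replica's RNG stream.
#' @return the advanced state.
#' @export
sampler_advance <- function(state, span_ps, bias, kT, rng) {
  UseMethod("sampler_advance")
}

# ---- overdamped Langevin on analytic potentials --------------------------

#' Overdamped Langevin sampler on an analytic potential
#'
#' Euler-Maruyama integration of dx = -grad(U + V_bias)/gamma dt +
#' sqrt(2 kT dt / gamma) dW, targeting the Boltzmann distribution of
#' U + V_bias. The coordinates themselves are the CVs.
#'
#' @param potential an [make_analytic_potential()] object.
#' @param kT thermal energy (kJ/mol); stored for reference only, the
#'   engine's schedule temperature governs a BEM run.
#' @param friction gamma (kJ/mol ps per CV unit^2).
#' @param dt integration step (ps).
#' @param x0 initial coordinates (default: first basin minimum).
#' @return sampler state of class `langevin_sampler`.
#' @export
langevin_sampler <- function(potential, kT = 2.744, friction = 10, dt = 0.02,
                             x0 = NULL) {
  e <- new.env(parent = emptyenv())
  e$potential <- potential
  e$kT <- kT
  e$friction <- friction
  e$dt <- dt
  e$x <- if (!is.null(x0)) x0 else
    if (potential$dim == 1L) potential$reference$minima[1L] else
      c(-1, 0)[seq_len(potential$dim)]
  class(e) <- c("langevin_sampler", "sampler_state")
  e
}

#' @export
sampler_cvs.langevin_sampler <- function(state, indices = NULL) state$x

#' @export
sampler_advance.langevin_sampler <- function(state, span_ps, bias, kT, rng) {
  if (span_ps == 0) return(state)
  nsteps <- round(span_ps / state$dt)
  if (abs(nsteps * state$dt - span_ps) > 1e-9) {
    stop("span must be a multiple of dt")
  }
  d <- state$potential$dim
  gam <- state$friction
  dt <- state$dt
  amp <- sqrt(2 * kT * dt / gam)
  noise <- matrix(rng_rnorm(rng, nsteps * d), nsteps, d)
  x <- state$x
  grad <- state$potential$grad
  k <- if (!is.null(bias) && !is.na(bias$cv_index)) bias$cv_index else 0L
  lo <- vapply(state$potential$domain, `[`, numeric(1), 1L)
  hi <- vapply(state$potential$domain, `[`, numeric(1), 2L)
  for (s in seq_len(nsteps)) {
    g <- grad(x)
    if (k > 0L) g[k] <- g[k] + bias_gradient_fast(bias, x[k])
    x <- x - dt / gam * g + amp * noise[s, ]
    # reflecting walls at the domain edges keep the walker in range
    x <- ifelse(x < lo, 2 * lo - x, x)
    x <- ifelse(x > hi, 2 * hi - x, x)
  }
  if (any(!is.finite(x))) stop("Langevin sampler diverged (reduce dt)")
  state$x <- x
  state
}

# ---- torsion-space Metropolis Monte Carlo on peptides --------------------

#' Torsion-space Monte Carlo sampler for a peptide
#'
#' Metropolis random walk in (phi, psi, chi1, chi2): one sweep proposes
#' a Gaussian perturbation of each residue's torsions in turn, rebuilds
#' the chain and accepts with exp(-(dU + dV_bias)/kT). One sweep is
#' bookkept as 1 ps so the BEM deposit/exchange schedule applies
#' unchanged. Detailed balance holds with respect to
#' exp(-(U + V_bias)/kT), the bias being evaluated through the CV layer.
#'
#' @param sequence a [peptide_sequence()].
#' @param energy_model a [toy_energy_model()] or NULL for a flat energy.
#' @param move_size proposal standard deviation (degrees).
#' @param init_torsions starting torsion table (default: extended chain).
#' @param config a [cv_config()] (default built from the sequence).
#' @return sampler state of class `torsion_mc_sampler`.
#' @export
torsion_mc_sampler <- function(sequence, energy_model = NULL, move_size = 20,
                               init_torsions = NULL, config = NULL) {
  e <- new.env(parent = emptyenv())
  e$sequence <- sequence
  e$model <- energy_model
  e$move_size <- move_size
  e$config <- if (is.null(config)) cv_config(sequence) else config
  l <- length(sequence$residues)
  tor <- if (is.null(init_torsions)) {
    data.frame(phi = rep(-135, l), psi = rep(135, l),
               chi1 = chi_reference(sequence, "chi1"),
               chi2 = chi_reference(sequence, "chi2"))
  } else init_torsions
  tor$phi[1L] <- NA_real_
  tor$psi[l] <- NA_real_
  e$torsions <- tor
  e$conf <- build_backbone_from_torsions(sequence, tor)
  e$energy <- model_energy(e$model, tor, e$conf)
  if (!is.finite(e$energy)) stop("rejected start: overlapping conformation")
  class(e) <- c("torsion_mc_sampler", "sampler_state")
  e
}

model_energy <- function(model, torsions, conf) {
  if (is.null(model)) return(0)
  toy_energy(torsions, model, conformation = conf)
}

# Single-CV evaluation used for the bias in MC acceptance.
compute_single_cv <- function(conf, k, config, torsions = NULL) {
  switch(k,
         ss_rmsd_cv(conf, "alpha", config$rmsd_switch),
         ss_rmsd_cv(conf, "para_beta", config$rmsd_switch),
         ss_rmsd_cv(conf, "anti_beta", config$rmsd_switch),
         contact_cv(conf, config$cv4),
         contact_cv(conf, config$cv5),
         alphabeta_cv(if (is.null(torsions)) compute_torsions(conf) else
           torsions, config$chi1_ref, "chi1"),
         alphabeta_cv(if (is.null(torsions)) compute_torsions(conf) else
           torsions, config$chi2_ref, "chi2"))
}

# chi angles enter alphabeta_cv straight from the torsion table (the
# builder places CG/CD at exactly those angles), so CV6/CV7 can be
# evaluated without rebuilding.
#' @export
sampler_cvs.torsion_mc_sampler <- function(state, indices = NULL) {
  if (is.null(indices)) indices <- 1:7
  out <- rep(NA_real_, 7L)
  for (k in indices) {
    out[k] <- compute_single_cv(state$conf, k, state$config, state$torsions)
  }
  out
}

#' @export
sampler_advance.torsion_mc_sampler <- function(state, span_ps, bias, kT, rng) {
  if (span_ps == 0) return(state)
  nsweeps <- round(span_ps)
  l <- length(state$sequence$residues)
  k <- if (!is.null(bias) && !is.na(bias$cv_index) &&
             length(bias$centers) > 0L) bias$cv_index else 0L
  cur_cv <- if (k > 0L) {
    compute_single_cv(state$conf, k, state$config, state$torsions)
  } else NA_real_
  for (sw in seq_len(nsweeps)) {
    noise <- matrix(rng_rnorm(rng, 4L * l, sd = state$move_size), l, 4L)
    us <- rng_runif(rng, l)
    for (i in seq_len(l)) {
      prop <- state$torsions
      if (i > 1L) prop$phi[i] <- wrap_angle(prop$phi[i] + noise[i, 1L])
      if (i < l) prop$psi[i] <- wrap_angle(prop$psi[i] + noise[i, 2L])
      if (!is.na(prop$chi1[i])) {
        prop$chi1[i] <- wrap_angle(prop$chi1[i] + noise[i, 3L])
      }
      if (!is.na(prop$chi2[i])) {
        prop$chi2[i] <- wrap_angle(prop$chi2[i] + noise[i, 4L])
      }
      new_conf <- build_backbone_from_torsions(state$sequence, prop)
      new_e <- model_energy(state$model, prop, new_conf)
      darg <- (new_e - state$energy) / kT
      new_cv <- NA_real_
      if (k > 0L) {
        new_cv <- compute_single_cv(new_conf, k, state$config, prop)
        darg <- darg + (bias_energy_fast(bias, new_cv) -
                          bias_energy_fast(bias, cur_cv)) / kT
      }
      if (us[i] < exp(-darg)) {
        state$torsions <- prop
        state$conf <- new_conf
        state$energy <- new_e
        if (k > 0L) cur_cv <- new_cv
      }
    }
  }
  state
}
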