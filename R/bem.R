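# Bias-exchange metadynamics engine: per-replica one-dimensional
# Gaussian bias with a fixed deposition schedule, Metropolis swaps of
# the bias potentials, and pluggable samplers. Energies in kJ/mol,
# times in ps (one Monte Carlo sweep is bookkept as 1 ps).

KB_KJMOL <- 0.0083145  # Boltzmann constant, kJ/mol/K

#' Bias-exchange metadynamics schedule
#'
#' Defaults follow the study protocol: hills of height 0.2 kJ/mol
#' deposited every 4 ps, bias swaps attempted every 20 ps, per-CV
#' Gaussian widths (0.2, 0.2, 0.2, 2.0, 0.65, 0.5, 0.2), 330 K.
#'
#' @param total_time total simulated time per replica (ps).
#' @param hill_height Gaussian hill height (kJ/mol).
#' @param deposit_interval time between hill depositions (ps).
#' @param exchange_interval time between swap attempts (ps); must be a
#'   multiple of `deposit_interval`.
#' @param widths per-CV Gaussian widths (CV units).
#' @param temperature bath temperature (K).
#' @param seed master seed for all replica and exchange streams.
#' @param deposit_stop_time stop adding hills after this time while
#'   continuing to sample (Inf = deposit throughout); a frozen-bias tail
#'   yields static-bias samples for WHAM.
#' @param record_interval time between CV records (ps).
#' @return object of class `BEMSchedule`.
#' @export
bem_schedule <- function(total_time, hill_height = 0.2, deposit_interval = 4,
                         exchange_interval = 20,
                         widths = c(0.2, 0.2, 0.2, 2.0, 0.65, 0.5, 0.2),
                         temperature = 330, seed = 1L,
                         deposit_stop_time = Inf,
                         record_interval = deposit_interval) {
  if (exchange_interval %% deposit_interval != 0) {
    stop("exchange_interval must be an integer multiple of deposit_interval")
  }
  if (any(widths <= 0)) stop("all widths must be positive")
  structure(list(total_time = total_time, hill_height = hill_height,
                 deposit_interval = deposit_interval,
                 exchange_interval = exchange_interval, widths = widths,
                 temperature = temperature, seed = as.integer(seed),
                 deposit_stop_time = deposit_stop_time,
                 record_interval = record_interval),
            class = "BEMSchedule")
}

#' Create an empty per-replica bias state
#'
#' @param cv_index index of the single CV this bias acts on (NA for an
#'   unbiased replica).
#' @param grid_range optional c(lo, hi) CV range for the cached bias
#'   grid used by the samplers.
#' @param grid_n grid resolution.
#' @return environment of class `BiasState`.
#' @export
bias_state <- function(cv_index, grid_range = NULL, grid_n = 1201L) {
  e <- new.env(parent = emptyenv())
  e$cv_index <- cv_index
  e$centers <- numeric(0)
  e$widths <- numeric(0)
  e$heights <- numeric(0)
  e$times <- numeric(0)
  if (!is.null(grid_range)) {
    e$grid_x <- seq(grid_range[1L], grid_range[2L], length.out = grid_n)
    e$grid_e <- numeric(grid_n)   # bias energy on grid
    e$grid_g <- numeric(grid_n)   # d(bias)/d(cv) on grid
  }
  class(e) <- "BiasState"
  e
}

#' Metadynamics bias energy at a CV value
#'
#' Sum of the deposited Gaussians,
#' sum_k h_k exp(-(cv - c_k)^2 / (2 w_k^2)); 0 for an empty history.
#'
#' @param bias a `BiasState`.
#' @param cv_value CV value(s); vectorised.
#' @return bias energy (kJ/mol).
#' @export
bias_energy <- function(bias, cv_value) {
  if (is.null(bias) || length(bias$centers) == 0L) {
    return(rep(0, length(cv_value)))
  }
  vapply(cv_value, function(x) {
    sum(bias$heights * exp(-(x - bias$centers)^2 / (2 * bias$widths^2)))
  }, numeric(1))
}

#' Gradient of the bias energy with respect to the CV
#'
#' @inheritParams bias_energy
#' @return d(bias)/d(cv) (kJ/mol per CV unit).
#' @export
bias_gradient <- function(bias, cv_value) {
  if (is.null(bias) || length(bias$centers) == 0L) {
    return(rep(0, length(cv_value)))
  }
  vapply(cv_value, function(x) {
    d <- x - bias$centers
    sum(bias$heights * exp(-d^2 / (2 * bias$widths^2)) * (-d / bias$widths^2))
  }, numeric(1))
}

# Fast bias lookup via the cached grid (linear interpolation, clamped
# to the grid range). Falls back to the exact sum without a grid.
bias_energy_fast <- function(bias, x) {
  if (is.null(bias$grid_x)) return(bias_energy(bias, x))
  interp_grid(bias$grid_x, bias$grid_e, x)
}

bias_gradient_fast <- function(bias, x) {
  if (is.null(bias$grid_x)) return(bias_gradient(bias, x))
  interp_grid(bias$grid_x, bias$grid_g, x)
}

interp_grid <- function(gx, gy, x) {
  n <- length(gx)
  x <- pmin(pmax(x, gx[1L]), gx[n])
  h <- (gx[n] - gx[1L]) / (n - 1L)
  j <- pmin(floor((x - gx[1L]) / h) + 1L, n - 1L)
  w <- (x - gx[j]) / h
  gy[j] * (1 - w) + gy[j + 1L] * w
}

#' Deposit one Gaussian hill
#'
#' Appends a hill centred at the current CV value, with the schedule's
#' height and the width assigned to the bias's CV.
#'
#' @param bias a `BiasState` (modified in place and returned).
#' @param cv_value current value of the biased CV.
#' @param schedule a [bem_schedule()].
#' @param time deposition time (ps); must align with the deposit interval.
#' @return the updated `BiasState`.
#' @export
deposit <- function(bias, cv_value, schedule, time) {
  if (abs(time / schedule$deposit_interval -
            round(time / schedule$deposit_interval)) > 1e-9) {
    stop("deposition time not aligned with the deposit interval")
  }
  w <- schedule$widths[bias$cv_index]
  h <- schedule$hill_height
  k <- length(bias$centers) + 1L
  bias$centers[k] <- cv_value
  bias$widths[k] <- w
  bias$heights[k] <- h
  bias$times[k] <- time
  if (!is.null(bias$grid_x)) {
    d <- bias$grid_x - cv_value
    e <- h * exp(-d^2 / (2 * w^2))
    bias$grid_e <- bias$grid_e + e
    bias$grid_g <- bias$grid_g + e * (-d / w^2)
  }
  bias
}

#' Metropolis bias-swap attempt between two replicas
#'
#' Accepts the swap with probability min(1, exp(Delta)) where
#' Delta = (Va(xa) + Vb(xb) - Va(xb) - Vb(xa)) / kT and V_r is replica
#' r's bias evaluated on a configuration's own CVs. Consumes exactly
#' one uniform draw. On acceptance the bias states are swapped between
#' the replicas.
#'
#' @param replica_a,replica_b replica environments with fields `bias`,
#'   `cvs` (current CV vector) and `time`.
#' @param kT thermal energy (kJ/mol).
#' @param rng an exchange RNG stream.
#' @return TRUE if the swap was accepted.
#' @export
attempt_exchange <- function(replica_a, replica_b, kT, rng) {
  if (!isTRUE(all.equal(replica_a$time, replica_b$time))) {
    stop("replicas are not at a common time point")
  }
  u <- rng_runif(rng, 1L)
  va_a <- bias_on_cvs(replica_a$bias, replica_a$cvs)
  vb_b <- bias_on_cvs(replica_b$bias, replica_b$cvs)
  va_b <- bias_on_cvs(replica_a$bias, replica_b$cvs)
  vb_a <- bias_on_cvs(replica_b$bias, replica_a$cvs)
  delta <- (va_a + vb_b - va_b - vb_a) / kT
  accept <- u < exp(delta)
  if (accept) {
    tmp <- replica_a$bias
    replica_a$bias <- replica_b$bias
    replica_b$bias <- tmp
  }
  accept
}

bias_on_cvs <- function(bias, cvs) {
  if (is.null(bias) || is.na(bias$cv_index)) return(0)
  bias_energy(bias, cvs[bias$cv_index])
}

#' Run bias-exchange metadynamics
#'
#' Advances every replica in lockstep: sampler propagation between
#' deposition times, one hill per biased replica at each deposition
#' time (until `deposit_stop_time`), and a Metropolis bias-swap attempt
#' between one randomly chosen replica pair at each exchange time.
#' Fully deterministic for a fixed schedule seed.
#'
#' @param samplers list of sampler states (see [langevin_sampler()],
#'   [torsion_mc_sampler()]).
#' @param cv_assignments integer vector: the CV index biased by each
#'   replica (NA = unbiased replica).
#' @param schedule a [bem_schedule()].
#' @param cv_ranges list of c(lo, hi) per CV index used for the cached
#'   bias grids.
#' @param record_cvs indices of CVs to record in the CV series
#'   (default: all the sampler reports).
#' @return list with `cv_series` (data frame), `bias_histories`,
#'   `events` (deposits/exchanges log), `samplers` (final states).
#' @export
run_bem <- function(samplers, cv_assignments, schedule, cv_ranges,
                    record_cvs = NULL) {
  n_rep <- length(samplers)
  if (length(cv_assignments) != n_rep) {
    stop("one CV assignment per replica required")
  }
  kT <- KB_KJMOL * schedule$temperature
  streams <- make_rng_streams(schedule$seed, n_rep + 1L)
  ex_stream <- streams[[n_rep + 1L]]

  replicas <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    k <- cv_assignments[r]
    rng_range <- if (is.na(k)) NULL else cv_ranges[[k]]
    e <- new.env(parent = emptyenv())
    e$id <- r
    e$sampler <- samplers[[r]]
    e$bias <- bias_state(k, grid_range = rng_range)
    e$time <- 0
    e$cvs <- sampler_cvs(samplers[[r]])
    e$stream <- streams[[r]]
    replicas[[r]] <- e
  }
  if (is.null(record_cvs)) record_cvs <- seq_along(replicas[[1L]]$cvs)

  n_steps <- if (schedule$total_time <= 0) 0L else
    round(schedule$total_time / schedule$deposit_interval)
  ex_every <- round(schedule$exchange_interval / schedule$deposit_interval)
  rec_every <- max(1L, round(schedule$record_interval /
                               schedule$deposit_interval))

  recs <- list()
  events <- list()
  record_row <- function(rep) {
    cvs <- rep$cvs[record_cvs]
    c(time_ps = rep$time, stats::setNames(cvs, paste0("cv", record_cvs)),
      replica = rep$id)
  }
  for (rep in replicas) recs[[length(recs) + 1L]] <- record_row(rep)

  for (step in seq_len(n_steps)) {
    t_new <- step * schedule$deposit_interval
    for (rep in replicas) {
      rep$sampler <- sampler_advance(rep$sampler, schedule$deposit_interval,
                                     rep$bias, kT, rep$stream)
      rep$time <- t_new
      rep$cvs <- sampler_cvs(rep$sampler)
      if (any(!is.finite(rep$cvs))) {
        stop(sprintf("replica %d diverged at t = %g ps", rep$id, t_new))
      }
      if (!is.na(rep$bias$cv_index) && t_new <= schedule$deposit_stop_time) {
        cvv <- rep$cvs[rep$bias$cv_index]
        deposit(rep$bias, cvv, schedule, t_new)
        events[[length(events) + 1L]] <-
          data.frame(time_ps = t_new, type = "deposit", replica = rep$id,
                     cv_index = rep$bias$cv_index, value = cvv)
      }
    }
    if (n_rep >= 2L && step %% ex_every == 0L) {
      pair <- rng_sample(ex_stream, n_rep, 2L)
      a <- replicas[[pair[1L]]]; b <- replicas[[pair[2L]]]
      acc <- attempt_exchange(a, b, kT, ex_stream)
      events[[length(events) + 1L]] <-
        data.frame(time_ps = t_new, type = "exchange", replica = pair[1L],
                   cv_index = pair[2L], value = as.numeric(acc))
    }
    if (step %% rec_every == 0L) {
      for (rep in replicas) recs[[length(recs) + 1L]] <- record_row(rep)
    }
  }

  cv_series <- as.data.frame(do.call(rbind, recs))
  list(cv_series = cv_series,
       bias_histories = lapply(replicas, function(r) r$bias),
       events = if (length(events)) do.call(rbind, events) else
         data.frame(time_ps = numeric(0), type = character(0),
                    replica = integer(0), cv_index = integer(0),
                    value = numeric(0)),
       samplers = lapply(replicas, function(r) r$sampler))
}

#' Free-energy profile estimate from a metadynamics bias history
#'
#' With constant hill height the negated bias oscillates around the
#' negative free energy; averaging the bias over the deposition history
#' after a burn-in damps the oscillation. Returns -<V(x)> pinned to a
#' zero minimum, together with the final-bias estimate.
#'
#' @param bias a `BiasState`.
#' @param xs CV grid on which to evaluate the profile.
#' @param average_from fraction of the hill history used as burn-in
#'   before averaging (default 0.3: the fill transient is over well
#'   before that, and a longer average damps the hill oscillation).
#' @return list with `x`, `F` (time-averaged estimate, kJ/mol) and
#'   `F_final` (negated final bias).
#' @export
metad_profile <- function(bias, xs, average_from = 0.3) {
  k <- length(bias$centers)
  if (k == 0L) stop("empty bias history")
  j0 <- max(1L, floor(k * average_from) + 1L)
  nsnap <- k - j0 + 1L
  w <- (k - pmax(seq_len(k), j0) + 1L) / nsnap
  vavg <- numeric(length(xs))
  vfin <- numeric(length(xs))
  for (j in seq_len(k)) {
    g <- bias$heights[j] *
      exp(-(xs - bias$centers[j])^2 / (2 * bias$widths[j]^2))
    vavg <- vavg + w[j] * g
    vfin <- vfin + g
  }
  f <- -vavg; f <- f - min(f)
  ff <- -vfin; ff <- ff - min(ff)
  list(x = xs, F = f, F_final = ff)
}

#' Write the hill log of a bias state as TSV
#'
#' @param bias a `BiasState`.
#' @param path output path.
#' @export
write_hill_log <- function(bias, path) {
  utils::write.table(
    data.frame(time_ps = bias$times,
               cv_index = rep(bias$cv_index, length(bias$centers)),
               center = bias$centers, width = bias$widths,
               height = bias$heights),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
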