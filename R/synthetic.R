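# Synthetic conformational ensembles with known ground truth, plus the
# toy torsion-well energy model driving the Monte Carlo sampler.

# Frozen hairpin turn (type II' beta turn): dihedrals of the two turn
# residues connecting antiparallel strand blocks so that the built
# hairpin carries real backbone H-bonds and is recognised as E.
HAIRPIN_TURN <- list(phi1 = 60, psi1 = -120, phi2 = -80, psi2 = 0)

#' Per-residue secondary-structure specification for the generator
#'
#' Structure content is specified as blocks: a set of consecutive
#' residues drawn jointly into one state with a given probability, so
#' minimum run lengths are realisable by construction. Blocks sharing
#' residues are mutually exclusive alternatives drawn from one
#' categorical. E blocks must name two strand ranges; the generator
#' folds them into a hairpin with the frozen turn geometry.
#'
#' @param length sequence length.
#' @param blocks list of lists with fields `state` ("H", "P" or "E"),
#'   `prob`, and `residues` (for H/P) or `strand1`/`strand2`
#'   (consecutive ranges separated by exactly two turn residues, for E).
#' @param noise_sd Gaussian dihedral noise SD (degrees).
#' @param chi_noise_sd noise SD on chi angles around the reference
#'   rotamers (degrees).
#' @return object of class `SSSpec`.
#' @export
ss_spec <- function(length, blocks = list(), noise_sd = 8,
                    chi_noise_sd = 30) {
  for (b in blocks) {
    if (!b$state %in% c("H", "E", "P")) stop("block state must be H, E or P")
    if (is.null(b$prob) || b$prob < 0 || b$prob > 1) stop("invalid block prob")
    if (b$state == "E") {
      if (is.null(b$strand1) || is.null(b$strand2)) {
        stop("E blocks need strand1 and strand2")
      }
      if (min(b$strand2) - max(b$strand1) != 3L) {
        stop("strands must be separated by exactly two turn residues")
      }
    } else if (is.null(b$residues) || length(b$residues) < 2L) {
      stop("H/P blocks need at least two residues")
    }
  }
  structure(list(length = as.integer(length), blocks = blocks,
                 noise_sd = noise_sd, chi_noise_sd = chi_noise_sd),
            class = "SSSpec")
}

block_residues <- function(b) {
  if (b$state == "E") c(b$strand1, b$strand2) else b$residues
}

# Group blocks into mutually exclusive alternatives (connected
# components of residue overlap).
block_groups <- function(blocks) {
  n <- length(blocks)
  if (n == 0L) return(list())
  comp <- seq_len(n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a >= b) next
      if (length(intersect(block_residues(blocks[[a]]),
                           block_residues(blocks[[b]]))) > 0L) {
        comp[comp == comp[b]] <- comp[a]
      }
    }
  }
  unname(split(seq_len(n), comp))
}

# Coil dihedral library: a two-basin mixture (extended/beta region and
# left-handed alpha region) that deliberately avoids the PPII box and
# the right-handed helical region, keeping generated ground-truth
# labels crisp.
draw_coil_dihedrals <- function(n) {
  phi <- numeric(n); psi <- numeric(n)
  which_basin <- stats::runif(n) < 0.75
  # left-handed-alpha draws are kept isolated: consecutive ones form
  # genuine structure (left-handed helix turns, beta-turn motifs that
  # nucleate chance hairpins), which coil should not contain
  for (i in seq_len(n)) {
    if (i > 1L && !which_basin[i] && !which_basin[i - 1L]) {
      which_basin[i] <- TRUE
    }
  }
  for (i in seq_len(n)) {
    if (which_basin[i]) {
      repeat {
        p <- stats::runif(1, -170, -95)
        s <- stats::runif(1, 80, 180)
        if (!in_ppii_box(p, s)) break
      }
      phi[i] <- p; psi[i] <- s
    } else {
      phi[i] <- stats::runif(1, 45, 100)
      psi[i] <- stats::runif(1, -10, 60)
    }
  }
  list(phi = phi, psi = psi)
}

#' Sample a synthetic conformational ensemble with known ground truth
#'
#' Per frame, block states are drawn per the [ss_spec()]; residues get
#' their state's canonical dihedrals (H: -57.8/-47; E: -119/113;
#' P: -75/145) plus wrapped Gaussian noise, coil residues draw from the
#' coil library, and chi angles scatter around the reference rotamers.
#' For drawn H blocks the flanking psi/phi are blended to helical
#' values so the block's H-bond pattern is complete (the flanks stay
#' coil in the ground truth). E blocks are folded into a hairpin via
#' the frozen turn. Ground-truth P labels are assigned post hoc from
#' the realised dihedrals (PPII box, runs of >= 2, non-H/E), exactly
#' the classifier's dihedral criterion applied to the known angles.
#'
#' @param sequence a [peptide_sequence()].
#' @param spec an [ss_spec()].
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return list with `trajectory`, `labels` (frames x residues matrix
#'   of ground-truth states) and `torsions` (list of per-frame tables).
#' @export
sample_ensemble <- function(sequence, spec, n_frames, seed = 1L) {
  stopifnot(n_frames >= 1L)
  l <- length(sequence$residues)
  if (spec$length != l) stop("spec length != sequence length")
  groups <- block_groups(spec$blocks)
  stream <- make_rng_streams(seed, 1L)[[1L]]
  chi1_ref <- chi_reference(sequence, "chi1")
  chi2_ref <- chi_reference(sequence, "chi2")
  frames <- vector("list", n_frames)
  torsions <- vector("list", n_frames)
  labels <- matrix("C", n_frames, l)
  with_stream(stream, {
    for (f in seq_len(n_frames)) {
      state <- rep("C", l)
      chosen <- list()
      for (g in groups) {
        probs <- vapply(spec$blocks[g], function(b) b$prob, numeric(1))
        if (sum(probs) > 1) stop("block probabilities in a group exceed 1")
        u <- stats::runif(1)
        pick <- which(u < cumsum(probs))[1L]
        if (!is.na(pick)) {
          b <- spec$blocks[[g[pick]]]
          state[block_residues(b)] <- b$state
          chosen[[length(chosen) + 1L]] <- b
        }
      }
      cd <- draw_coil_dihedrals(l)
      phi <- cd$phi; psi <- cd$psi
      for (st in c("H", "E", "P")) {
        sel <- state == st
        canon <- CANON_DIHEDRALS[[st]]
        phi[sel] <- canon["phi"]
        psi[sel] <- canon["psi"]
      }
      for (b in chosen) {
        if (b$state == "H") {
          # helix caps: the flanking residues get canonical N-cap /
          # C-cap dihedrals so the block's terminal H-bonds can form
          # without themselves reading as helical
          first <- min(b$residues); last <- max(b$residues)
          if (first > 1L && state[first - 1L] == "C") {
            phi[first - 1L] <- -135
            psi[first - 1L] <- CANON_DIHEDRALS$H["psi"]
          }
          if (last < l && state[last + 1L] == "C") {
            phi[last + 1L] <- CANON_DIHEDRALS$H["phi"]
            psi[last + 1L] <- 120
          }
        } else if (b$state == "E") {
          t1 <- max(b$strand1) + 1L; t2 <- t1 + 1L
          phi[t1] <- HAIRPIN_TURN$phi1; psi[t1] <- HAIRPIN_TURN$psi1
          phi[t2] <- HAIRPIN_TURN$phi2; psi[t2] <- HAIRPIN_TURN$psi2
        }
      }
      phi <- wrap_angle(phi + stats::rnorm(l, 0, spec$noise_sd))
      psi <- wrap_angle(psi + stats::rnorm(l, 0, spec$noise_sd))
      chi1 <- wrap_angle(chi1_ref + stats::rnorm(l, 0, spec$chi_noise_sd))
      chi2 <- wrap_angle(chi2_ref + stats::rnorm(l, 0, spec$chi_noise_sd))
      tor <- data.frame(phi = phi, psi = psi, chi1 = chi1, chi2 = chi2)
      tor$phi[1L] <- NA_real_; tor$psi[l] <- NA_real_
      frames[[f]] <- build_backbone_from_torsions(sequence, tor)
      torsions[[f]] <- tor
      # ground truth: drawn H/E plus post-hoc PPII from realised angles
      truth <- state
      truth[truth == "P"] <- "C"
      eligible <- truth == "C" & in_ppii_box(tor$phi, tor$psi)
      r <- rle(as.vector(eligible))
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in seq_along(r$values)) {
        if (r$values[k] && r$lengths[k] >= 2L) {
          truth[starts[k]:ends[k]] <- "P"
        }
      }
      labels[f, ] <- truth
    }
  })
  list(trajectory = trajectory(sequence, frames),
       labels = labels, torsions = torsions)
}

# ---- toy energy model ----------------------------------------------------

#' Toy torsion-well energy model
#'
#' Periodic Gaussian wells in (phi, psi) per residue (negative depths)
#' plus a soft-sphere excluded-volume repulsion over CA pairs at least
#' 3 residues apart. Smooth in all angles; the torsion part has an
#' analytic gradient.
#'
#' @param wells data frame with columns `res` (residue index, 0 = all
#'   residues), `phi0`, `psi0` (degrees), `depth` (kJ/mol, >= 0),
#'   `width` (degrees).
#' @param ev_sigma soft-sphere contact distance (nm); 0 disables.
#' @param ev_eps repulsion strength (kJ/mol).
#' @return object of class `ToyEnergyModel`.
#' @export
toy_energy_model <- function(wells, ev_sigma = 0.38, ev_eps = 20) {
  stopifnot(all(wells$depth >= 0), all(wells$width > 0))
  structure(list(wells = wells, ev_sigma = ev_sigma, ev_eps = ev_eps),
            class = "ToyEnergyModel")
}

#' Toy model energy of a torsion profile / conformation
#'
#' @param torsions a torsion table with `phi`, `psi` columns.
#' @param model a [toy_energy_model()].
#' @param conformation a `Conformation` matching the torsions; required
#'   when the model has an excluded-volume term.
#' @return energy (kJ/mol).
#' @export
toy_energy <- function(torsions, model, conformation = NULL) {
  e <- 0
  for (w in seq_len(nrow(model$wells))) {
    spec <- model$wells[w, ]
    res <- if (spec$res == 0L) seq_len(nrow(torsions)) else spec$res
    dphi <- angle_diff(torsions$phi[res], spec$phi0)
    dpsi <- angle_diff(torsions$psi[res], spec$psi0)
    ok <- !is.na(dphi) & !is.na(dpsi)
    e <- e - spec$depth *
      sum(exp(-(dphi[ok]^2 + dpsi[ok]^2) / (2 * spec$width^2)))
  }
  if (model$ev_sigma > 0 && model$ev_eps > 0) {
    if (is.null(conformation)) {
      stop("excluded-volume term needs a conformation")
    }
    ca <- conf_atom_matrix(conformation, "CA")
    n <- nrow(ca)
    for (i in seq_len(n - 3L)) {
      d <- sqrt(rowSums((ca[(i + 3L):n, , drop = FALSE] -
                           matrix(ca[i, ], n - i - 2L, 3L, byrow = TRUE))^2))
      close <- d < model$ev_sigma
      if (any(close)) {
        e <- e + model$ev_eps * sum((1 - d[close] / model$ev_sigma)^2)
      }
    }
  }
  e
}

#' Analytic gradient of the toy torsion-well energy
#'
#' Gradient with respect to the phi/psi angles (kJ/mol per degree);
#' the excluded-volume term is not included (the Monte Carlo sampler
#' needs no forces).
#'
#' @inheritParams toy_energy
#' @return matrix with columns `dphi`, `dpsi`.
#' @export
toy_energy_gradient <- function(torsions, model) {
  n <- nrow(torsions)
  g <- matrix(0, n, 2L, dimnames = list(NULL, c("dphi", "dpsi")))
  for (w in seq_len(nrow(model$wells))) {
    spec <- model$wells[w, ]
    res <- if (spec$res == 0L) seq_len(n) else spec$res
    dphi <- angle_diff(torsions$phi[res], spec$phi0)
    dpsi <- angle_diff(torsions$psi[res], spec$psi0)
    ok <- !is.na(dphi) & !is.na(dpsi)
    ex <- exp(-(dphi^2 + dpsi^2) / (2 * spec$width^2))
    gphi <- spec$depth * ex * dphi / spec$width^2
    gpsi <- spec$depth * ex * dpsi / spec$width^2
    g[res[ok], 1L] <- g[res[ok], 1L] + gphi[ok]
    g[res[ok], 2L] <- g[res[ok], 2L] + gpsi[ok]
  }
  g
}
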