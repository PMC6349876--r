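# Per-frame structural annotation and per-window aggregation:
# simplified DSSP secondary structure (H/E/C) with a polyproline-II
# overlay, Shrake-Rupley solvent-accessible surface area and radius of
# gyration, aggregated over free-energy windows.

DSSP_ENERGY_CUTOFF <- -0.5  # kcal/mol
DSSP_COUPLING <- 27.888     # kcal/mol * Angstrom (0.42 * 0.20 * 332)

# Backbone H-bond energy map: hb[i, j] TRUE when the carbonyl of
# residue i accepts the amide hydrogen of residue j (|i - j| >= 3).
hbond_matrix <- function(conf) {
  l <- length(conf$sequence$residues)
  o <- conf_atom_matrix(conf, "O") * 10   # nm -> Angstrom
  c_ <- conf_atom_matrix(conf, "C") * 10
  n <- conf_atom_matrix(conf, "N") * 10
  h <- conf_atom_matrix(conf, "H") * 10
  hb <- matrix(FALSE, l, l)
  for (j in seq_len(l)) {
    if (any(is.na(h[j, ]))) next  # no amide H (Pro / N terminus / missing)
    for (i in seq_len(l)) {
      if (abs(i - j) < 3L || any(is.na(o[i, ]))) next
      r_on <- sqrt(sum((o[i, ] - n[j, ])^2))
      r_ch <- sqrt(sum((c_[i, ] - h[j, ])^2))
      r_oh <- sqrt(sum((o[i, ] - h[j, ])^2))
      r_cn <- sqrt(sum((c_[i, ] - n[j, ])^2))
      if (min(r_on, r_ch, r_oh, r_cn) < 0.5) { hb[i, j] <- TRUE; next }
      e <- DSSP_COUPLING * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      hb[i, j] <- e < DSSP_ENERGY_CUTOFF
    }
  }
  hb
}

#' Assign secondary structure (simplified DSSP)
#'
#' Backbone H-bonds are scored with the DSSP electrostatic energy
#' (coupling 27.888 kcal/mol A, cutoff -0.5 kcal/mol); helix (H)
#' requires two consecutive i -> i+4 H-bonded turns, strand (E)
#' requires a bridge extending into a ladder of at least two
#' consecutive bridges (parallel or antiparallel patterns); everything
#' else is coil (C). Missing amide hydrogens are reconstructed
#' geometrically first.
#'
#' @param conformation a `Conformation`.
#' @return character vector of per-residue labels in {H, E, C}.
#' @export
assign_ss <- function(conformation) {
  conf <- reconstruct_amide_h(conformation)
  l <- length(conf$sequence$residues)
  hb <- hbond_matrix(conf)
  lab <- rep("C", l)

  # helix: turns t(i) = Hbond(i, i+4); two consecutive turns label i+1..i+4
  turns <- rep(FALSE, l)
  for (i in seq_len(max(l - 4L, 0L))) turns[i] <- hb[i, i + 4L]
  for (i in seq_len(max(l - 5L, 0L))) {
    if (turns[i] && turns[i + 1L]) lab[(i + 1L):(i + 4L)] <- "H"
  }

  # bridges (unordered i < j, separation >= 3); a residue is E when its
  # bridge extends into a ladder of >= min_ladder consecutive bridges
  anti <- matrix(FALSE, l, l)
  para <- matrix(FALSE, l, l)
  for (i in seq_len(l)) {
    for (j in seq_len(l)) {
      if (j - i < 3L) next
      anti[i, j] <- (hb[i, j] && hb[j, i]) ||
        (i > 1L && j < l && hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      para[i, j] <- (i > 1L && i < l && hb[i - 1L, j] && hb[j, i + 1L]) ||
        (j > 1L && j < l && hb[j - 1L, i] && hb[i, j + 1L])
    }
  }
  min_ladder <- 3L
  mark_ladders <- function(br, step_j) {
    for (i in seq_len(l)) {
      for (j in seq_len(l)) {
        if (!br[i, j]) next
        # only start a walk at a ladder's first rung
        ip <- i - 1L; jp <- j - step_j
        if (ip >= 1L && jp >= 1L && jp <= l && br[ip, jp]) next
        len <- 1L
        while (TRUE) {
          ii <- i + len; jj <- j + step_j * len
          if (ii > l || jj < 1L || jj > l || !br[ii, jj]) break
          len <- len + 1L
        }
        if (len >= min_ladder) {
          for (k in seq_len(len) - 1L) {
            ri <- i + k; rj <- j + step_j * k
            if (lab[ri] != "H") lab[ri] <<- "E"
            if (lab[rj] != "H") lab[rj] <<- "E"
          }
        }
      }
    }
  }
  mark_ladders(anti, -1L)
  mark_ladders(para, +1L)
  lab
}

# PPII dihedral box: (phi, psi) within +/- 29 degrees of (-75, 145).
PPII_CANON <- c(phi = -75, psi = 145)
PPII_EPS <- 29

in_ppii_box <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) &
    abs(angle_diff(phi, PPII_CANON["phi"])) <= PPII_EPS &
    abs(angle_diff(psi, PPII_CANON["psi"])) <= PPII_EPS
}

#' Overlay polyproline-II labels on a secondary-structure assignment
#'
#' A residue becomes P iff it is currently coil, its (phi, psi) lie in
#' the PPII box (-75 +/- 29, 145 +/- 29 degrees) and it belongs to a
#' run of at least two consecutive such residues. Residues with
#' undefined dihedrals (termini) are never P.
#'
#' @param torsions a `TorsionProfile`.
#' @param ss_label labels from [assign_ss()].
#' @param min_run minimum run length (default 2).
#' @return updated label vector in {H, E, P, C}.
#' @export
assign_ppii <- function(torsions, ss_label, min_run = 2L) {
  eligible <- ss_label == "C" & in_ppii_box(torsions$phi, torsions$psi)
  lab <- ss_label
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= min_run) {
      lab[starts[k]:ends[k]] <- "P"
    }
  }
  lab
}

# Deterministic golden-spiral points on the unit sphere.
golden_spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe over the heavy atoms (hydrogens excluded; pseudo
#' side-chain sites count as carbon) using a deterministic golden-
#' spiral point set, so results are bit-stable.
#'
#' @param conformation a `Conformation`.
#' @param probe_radius probe radius (nm), default 0.14.
#' @param n_sphere_points test points per atom, default 960.
#' @return list of class `SASAProfile`: `residue` (per-residue SASA,
#'   nm^2) and `total`.
#' @export
sasa <- function(conformation, probe_radius = 0.14, n_sphere_points = 960L) {
  conf <- conformation
  heavy <- which(conf$atoms$element != "H")
  if (length(heavy) == 0L) stop("no heavy atoms")
  xyz <- conf$xyz[heavy, , drop = FALSE]
  radii <- ELEMENT_RADIUS[conf$atoms$element[heavy]] + probe_radius
  res <- conf$atoms$res[heavy]
  pts <- golden_spiral_points(n_sphere_points)
  n <- length(heavy)
  area <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (a in seq_len(n)) {
    cand <- which(d2[a, ] < (radii[a] + radii)^2 & seq_len(n) != a)
    sp <- pts * radii[a]
    sp <- sweep(sp, 2L, xyz[a, ], "+")
    if (length(cand) > 0L) {
      free <- rep(TRUE, n_sphere_points)
      for (b in cand) {
        db <- (sp[, 1L] - xyz[b, 1L])^2 + (sp[, 2L] - xyz[b, 2L])^2 +
          (sp[, 3L] - xyz[b, 3L])^2
        free <- free & db > radii[b]^2
      }
      frac <- sum(free) / n_sphere_points
    } else {
      frac <- 1
    }
    area[a] <- frac * 4 * pi * radii[a]^2
  }
  per_res <- vapply(seq_len(length(conf$sequence$residues)),
                    function(i) sum(area[res == i]), numeric(1))
  structure(list(residue = per_res, total = sum(per_res)),
            class = "SASAProfile")
}

#' Radius of gyration
#'
#' Mass-weighted RMS distance of the heavy atoms from their center of
#' mass.
#'
#' @param conformation a `Conformation`.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(conformation) {
  conf <- conformation
  heavy <- which(conf$atoms$element != "H")
  if (length(heavy) == 0L) stop("no atoms")
  xyz <- conf$xyz[heavy, , drop = FALSE]
  m <- ELEMENT_MASS[conf$atoms$element[heavy]]
  cm <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2L, cm)^2)) / sum(m))
}

#' Per-window structural report
#'
#' Aggregates per-frame labels (and optionally SASA and Rg) over
#' free-energy windows: per-residue H/E/P fractions per window, window
#' mean total SASA and Rg, and per-residue delta-SASA relative to the
#' global-minimum window.
#'
#' @param labels frames x residues character matrix of SS labels.
#' @param window_assignment an [assign_windows()] result aligned on
#'   frames.
#' @param sasa_profiles optional frames x residues matrix of
#'   per-residue SASA (nm^2).
#' @param rg_values optional per-frame Rg vector (nm).
#' @param mode `"total"`: fractions relative to the total retained
#'   population (the landscape-figure convention); `"within"`:
#'   fractions within each window.
#' @return list of class `WindowReport`: `fractions` (long data frame),
#'   `windows` (per-window summary), `delta_sasa` (residues x windows),
#'   `mode`.
#' @export
window_report <- function(labels, window_assignment, sasa_profiles = NULL,
                          rg_values = NULL, mode = c("total", "within")) {
  mode <- match.arg(mode)
  win <- window_assignment$window
  if (nrow(labels) != length(win)) stop("labels/windows not aligned")
  nres <- ncol(labels)
  present <- sort(unique(win[!is.na(win)]))
  empty <- setdiff(seq_len(max(c(present, 0L))), present)
  if (length(empty) > 0L) {
    message("windows without frames excluded from report: ",
            paste(empty, collapse = ", "))
  }
  n_total <- sum(!is.na(win))
  frac_rows <- list()
  win_rows <- list()
  dsasa <- NULL
  if (!is.null(sasa_profiles)) {
    dsasa <- matrix(NA_real_, nres, length(present),
                    dimnames = list(NULL, paste0("window", present)))
  }
  ref_sasa <- if (!is.null(sasa_profiles) && 1L %in% present) {
    colMeans(sasa_profiles[which(win == 1L), , drop = FALSE])
  } else NULL
  for (wi in seq_along(present)) {
    w <- present[wi]
    sel <- which(!is.na(win) & win == w)
    denom <- if (mode == "total") n_total else length(sel)
    for (state in c("H", "E", "P")) {
      cnt <- colSums(labels[sel, , drop = FALSE] == state)
      frac_rows[[length(frac_rows) + 1L]] <-
        data.frame(residue = seq_len(nres), window = w, state = state,
                   fraction = cnt / denom, n_state = cnt,
                   n_window = length(sel))
    }
    mean_sasa <- if (!is.null(sasa_profiles)) {
      ms <- colMeans(sasa_profiles[sel, , drop = FALSE])
      if (!is.null(ref_sasa)) dsasa[, wi] <- ms - ref_sasa
      sum(ms)
    } else NA_real_
    mean_rg <- if (!is.null(rg_values)) mean(rg_values[sel]) else NA_real_
    win_rows[[length(win_rows) + 1L]] <-
      data.frame(window = w, n_frames = length(sel),
                 mean_total_sasa = mean_sasa, mean_rg = mean_rg)
  }
  structure(list(fractions = do.call(rbind, frac_rows),
                 windows = do.call(rbind, win_rows),
                 delta_sasa = dsasa, mode = mode),
            class = "WindowReport")
}

#' Write a window report as long-format TSV
#'
#' @param report a `WindowReport`.
#' @param path output path.
#' @export
write_window_report <- function(report, path) {
  utils::write.table(report$fractions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
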