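# Conformation container and peptide construction from internal
# coordinates. One Conformation holds one frame: backbone N, CA, C, O,
# amide H (absent for prolines and the N terminus), CB (a constructed
# pseudo-CB for glycine) plus simplified side-chain sites CG/CD used for
# contact CVs and chi angles. All coordinates in nm.

# Ideal covalent geometry (nm / degrees).
GEOM <- list(
  n_ca = 0.1458, ca_c = 0.1525, c_n = 0.1329, c_o = 0.1229,
  ca_cb = 0.1530, n_h = 0.1010, cb_cg = 0.1520, cg_cd = 0.1520,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.5, ang_n_ca_cb = 110.5, ang_ca_cb_cg = 114.0,
  ang_cb_cg_cd = 111.0, omega = 180,
  # rotation about the N-CA axis from C to CB; sign fixed so that
  # residues come out in the L configuration (CORN rule).
  cb_branch_torsion = -122.6
)

# Canonical backbone dihedrals per secondary-structure state.
CANON_DIHEDRALS <- list(
  H = c(phi = -57.8, psi = -47.0),
  E = c(phi = -119.0, psi = 113.0),
  P = c(phi = -75.0, psi = 145.0)
)

new_conformation <- function(sequence, atoms, xyz, index = NULL) {
  stopifnot(nrow(atoms) == nrow(xyz))
  if (any(!is.finite(xyz))) stop("non-finite coordinates in conformation")
  l <- length(sequence$residues)
  if (is.null(index)) {
    index <- list()
    for (nm in unique(atoms$name)) {
      v <- rep(NA_integer_, l)
      sel <- which(atoms$name == nm)
      v[atoms$res[sel]] <- sel
      index[[nm]] <- v
    }
  }
  structure(list(sequence = sequence, atoms = atoms, xyz = xyz,
                 index = index),
            class = "Conformation")
}

# Atom layout (atom table + per-name index) depends only on the
# sequence; cached so repeated builds only fill coordinates.
.layout_cache <- new.env(parent = emptyenv())

conformation_layout <- function(sequence) {
  key <- paste0(paste(sequence$residues, collapse = ""),
                "@", sequence$numbering_offset)
  hit <- .layout_cache[[key]]
  if (!is.null(hit)) return(hit)
  res_codes <- sequence$residues
  l <- length(res_codes)
  res <- integer(0); name <- character(0); element <- character(0)
  pseudo <- logical(0)
  for (i in seq_len(l)) {
    code <- res_codes[i]
    nm <- c("N", "CA", "C", "O")
    el <- c("N", "C", "C", "O")
    ps <- c(FALSE, FALSE, FALSE, FALSE)
    if (i > 1L && code != "P") {
      nm <- c(nm, "H"); el <- c(el, "H"); ps <- c(ps, FALSE)
    }
    nm <- c(nm, "CB"); el <- c(el, "C"); ps <- c(ps, code == "G")
    if (code %in% HAS_CHI1) {
      nm <- c(nm, "CG"); el <- c(el, "C"); ps <- c(ps, FALSE)
      if (code %in% HAS_CHI2) {
        nm <- c(nm, "CD"); el <- c(el, "C"); ps <- c(ps, FALSE)
      }
    }
    res <- c(res, rep(i, length(nm)))
    name <- c(name, nm); element <- c(element, el); pseudo <- c(pseudo, ps)
  }
  atoms <- data.frame(res = res, name = name, element = element,
                      pseudo = pseudo, stringsAsFactors = FALSE)
  index <- list()
  for (nm in unique(atoms$name)) {
    v <- rep(NA_integer_, l)
    sel <- which(atoms$name == nm)
    v[atoms$res[sel]] <- sel
    index[[nm]] <- v
  }
  out <- list(atoms = atoms, index = index, natoms = nrow(atoms))
  .layout_cache[[key]] <- out
  out
}

#' @export
print.Conformation <- function(x, ...) {
  cat(sprintf("Conformation: %d residues, %d atoms\n",
              length(x$sequence$residues), nrow(x$xyz)))
  invisible(x)
}

# Coordinates of atom `name` of residue i (1-based), or NULL if absent.
conf_atom <- function(conf, i, name) {
  v <- conf$index[[name]]
  if (is.null(v)) return(NULL)
  j <- v[i]
  if (is.na(j)) return(NULL)
  conf$xyz[j, ]
}

has_atom <- function(conf, i, name) {
  v <- conf$index[[name]]
  !is.null(v) && !is.na(v[i])
}

# n_res x 3 matrix of one atom type across residues (NA rows if absent).
conf_atom_matrix <- function(conf, name) {
  l <- length(conf$sequence$residues)
  v <- conf$index[[name]]
  out <- matrix(NA_real_, l, 3L)
  if (!is.null(v)) {
    ok <- !is.na(v)
    out[ok, ] <- conf$xyz[v[ok], , drop = FALSE]
  }
  out
}

# Validate chain connectivity: consecutive CA-CA distances in [0.2, 0.45] nm.
check_chain_connectivity <- function(conf) {
  ca <- conf_atom_matrix(conf, "CA")
  d <- sqrt(rowSums((ca[-1L, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
  all(is.finite(d)) && all(d >= 0.2 & d <= 0.45)
}

#' Build a peptide conformation from backbone and side-chain torsions
#'
#' Sequentially places N, CA, C by the NeRF internal-coordinate
#' construction with ideal bond lengths and angles (N-CA 0.1458 nm,
#' CA-C 0.1525 nm, C-N 0.1329 nm, omega fixed at 180 degrees), then adds
#' carbonyl O, amide H (skipped for prolines and the first residue),
#' CB (a pseudo-CB for glycine) and simplified side-chain sites CG/CD at
#' the requested chi1/chi2 torsions for residue types that have them.
#'
#' @param sequence a [peptide_sequence()].
#' @param torsions data frame with columns `phi`, `psi` and optionally
#'   `chi1`, `chi2` (degrees); `phi[1]` and `psi[L]` may be NA.
#' @return a `Conformation`.
#' @export
build_backbone_from_torsions <- function(sequence, torsions) {
  l <- length(sequence$residues)
  if (nrow(torsions) != l) stop("torsion table length != sequence length")
  phi <- torsions$phi
  psi <- torsions$psi
  chi1 <- if ("chi1" %in% names(torsions)) torsions$chi1 else rep(NA_real_, l)
  chi2 <- if ("chi2" %in% names(torsions)) torsions$chi2 else rep(NA_real_, l)
  if (any(is.na(phi[-1L]))) stop("interior phi angles must be defined")
  if (any(is.na(psi[-l]))) stop("interior psi angles must be defined")

  g <- GEOM
  n_xyz <- matrix(NA_real_, l, 3L)
  ca_xyz <- matrix(NA_real_, l, 3L)
  c_xyz <- matrix(NA_real_, l, 3L)

  n_xyz[1L, ] <- c(0, 0, 0)
  ca_xyz[1L, ] <- c(g$n_ca, 0, 0)
  th <- (180 - g$ang_n_ca_c) * DEG2RAD
  c_xyz[1L, ] <- ca_xyz[1L, ] + g$ca_c * c(cos(th), sin(th), 0)

  for (i in seq_len(l)) {
    if (i > 1L) {
      # N(i) from psi(i-1), CA(i) from omega, C(i) from phi(i)
      n_xyz[i, ] <- place_atom(n_xyz[i - 1L, ], ca_xyz[i - 1L, ],
                               c_xyz[i - 1L, ],
                               g$c_n, g$ang_ca_c_n, psi[i - 1L])
      ca_xyz[i, ] <- place_atom(ca_xyz[i - 1L, ], c_xyz[i - 1L, ],
                                n_xyz[i, ],
                                g$n_ca, g$ang_c_n_ca, g$omega)
      c_xyz[i, ] <- place_atom(c_xyz[i - 1L, ], n_xyz[i, ], ca_xyz[i, ],
                               g$ca_c, g$ang_n_ca_c, phi[i])
    }
  }

  res_codes <- sequence$residues
  layout <- conformation_layout(sequence)
  idx <- layout$index
  xyz <- matrix(NA_real_, layout$natoms, 3L)

  for (i in seq_len(l)) {
    code <- res_codes[i]
    xyz[idx$N[i], ] <- n_xyz[i, ]
    xyz[idx$CA[i], ] <- ca_xyz[i, ]
    xyz[idx$C[i], ] <- c_xyz[i, ]
    # carbonyl O anti to the next amide N
    psi_eff <- if (is.na(psi[i])) 180 else psi[i]
    xyz[idx$O[i], ] <- place_atom(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                                  g$c_o, g$ang_ca_c_o,
                                  wrap_angle(psi_eff + 180))
    # amide H: bisector-opposed direction at N; none for Pro / N terminus
    if (i > 1L && code != "P") {
      dir <- -(unit(ca_xyz[i, ] - n_xyz[i, ]) +
                 unit(c_xyz[i - 1L, ] - n_xyz[i, ]))
      xyz[idx$H[i], ] <- n_xyz[i, ] + g$n_h * unit(dir)
    }
    # CB for every residue; pseudo for glycine
    cb <- place_atom(c_xyz[i, ], n_xyz[i, ], ca_xyz[i, ],
                     g$ca_cb, g$ang_n_ca_cb, g$cb_branch_torsion)
    xyz[idx$CB[i], ] <- cb
    # simplified side chain: CG at chi1, CD at chi2
    if (code %in% HAS_CHI1) {
      x1 <- if (is.na(chi1[i])) CHI_REFERENCE_DEFAULT$chi1[[code]] else chi1[i]
      if (is.null(x1) || is.na(x1)) x1 <- -65
      cg <- place_atom(n_xyz[i, ], ca_xyz[i, ], cb,
                       g$cb_cg, g$ang_ca_cb_cg, x1)
      xyz[idx$CG[i], ] <- cg
      if (code %in% HAS_CHI2) {
        x2 <- if (is.na(chi2[i])) CHI_REFERENCE_DEFAULT$chi2[[code]] else chi2[i]
        if (is.null(x2) || is.na(x2)) x2 <- 180
        xyz[idx$CD[i], ] <- place_atom(ca_xyz[i, ], cb, cg,
                                       g$cg_cd, g$ang_cb_cg_cd, x2)
      }
    }
  }
  new_conformation(sequence, layout$atoms, xyz, index = idx)
}

#' Reconstruct missing amide hydrogens
#'
#' Places H on the bisector-opposed N direction at N-H = 0.101 nm for
#' every residue that should carry an amide hydrogen (all but prolines
#' and the N-terminal residue) and lacks one.
#'
#' @param conf a `Conformation`.
#' @return the conformation with hydrogens added.
#' @export
reconstruct_amide_h <- function(conf) {
  l <- length(conf$sequence$residues)
  codes <- conf$sequence$residues
  add_rows <- list()
  add_xyz <- list()
  for (i in seq_len(l)) {
    if (i == 1L || codes[i] == "P" || has_atom(conf, i, "H")) next
    n <- conf_atom(conf, i, "N")
    ca <- conf_atom(conf, i, "CA")
    cprev <- conf_atom(conf, i - 1L, "C")
    if (is.null(n) || is.null(ca) || is.null(cprev)) next
    dir <- -(unit(ca - n) + unit(cprev - n))
    add_rows[[length(add_rows) + 1L]] <-
      data.frame(res = i, name = "H", element = "H", pseudo = FALSE,
                 stringsAsFactors = FALSE)
    add_xyz[[length(add_xyz) + 1L]] <- n + GEOM$n_h * unit(dir)
  }
  if (length(add_rows) == 0L) return(conf)
  atoms <- rbind(conf$atoms, do.call(rbind, add_rows))
  xyz <- rbind(conf$xyz, do.call(rbind, add_xyz))
  new_conformation(conf$sequence, atoms, xyz)
}

#' Backbone and side-chain torsion angles of a conformation
#'
#' Computes phi, psi (IUPAC convention, degrees) and the simplified
#' side-chain chi1/chi2 angles. Angles undefined at the termini or due
#' to missing atoms are NA, never silently zero.
#'
#' @param conformation a `Conformation`.
#' @return data frame of class `TorsionProfile` with columns
#'   `res`, `phi`, `psi`, `chi1`, `chi2`.
#' @export
compute_torsions <- function(conformation) {
  conf <- conformation
  l <- length(conf$sequence$residues)
  codes <- conf$sequence$residues
  phi <- psi <- chi1 <- chi2 <- rep(NA_real_, l)
  for (i in seq_len(l)) {
    n <- conf_atom(conf, i, "N")
    ca <- conf_atom(conf, i, "CA")
    cc <- conf_atom(conf, i, "C")
    if (i > 1L) {
      cp <- conf_atom(conf, i - 1L, "C")
      if (!is.null(cp) && !is.null(n) && !is.null(ca) && !is.null(cc)) {
        phi[i] <- dihedral_angle(cp, n, ca, cc)
      }
    }
    if (i < l) {
      nn <- conf_atom(conf, i + 1L, "N")
      if (!is.null(n) && !is.null(ca) && !is.null(cc) && !is.null(nn)) {
        psi[i] <- dihedral_angle(n, ca, cc, nn)
      }
    }
    cb <- conf_atom(conf, i, "CB")
    cg <- conf_atom(conf, i, "CG")
    if (codes[i] %in% HAS_CHI1 && !is.null(n) && !is.null(ca) &&
        !is.null(cb) && !is.null(cg)) {
      chi1[i] <- dihedral_angle(n, ca, cb, cg)
      cd <- conf_atom(conf, i, "CD")
      if (codes[i] %in% HAS_CHI2 && !is.null(cd)) {
        chi2[i] <- dihedral_angle(ca, cb, cg, cd)
      }
    }
  }
  structure(data.frame(res = seq_len(l), phi = phi, psi = psi,
                       chi1 = chi1, chi2 = chi2),
            class = c("TorsionProfile", "data.frame"))
}

# Uniform dihedral table helper used by generators.
torsion_table <- function(l, phi, psi, chi1 = NA_real_, chi2 = NA_real_) {
  data.frame(phi = rep_len(phi, l), psi = rep_len(psi, l),
             chi1 = rep_len(chi1, l), chi2 = rep_len(chi2, l))
}
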