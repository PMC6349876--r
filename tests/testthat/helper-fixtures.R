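# Shared fixtures and independent brute-force oracles. Oracles are
# deliberately naive (plain loops, textbook formulas) and share no code
# path with the implementation they check.

wt_sequence <- function() {
  peptide_sequence(bemetad:::UVR8_C27_WT, 397L)
}

ideal_conf <- function(phi, psi, seqp = wt_sequence()) {
  l <- length(seqp$residues)
  build_backbone_from_torsions(seqp, bemetad:::torsion_table(l, phi, psi))
}

helix_conf <- function() ideal_conf(-57.8, -47.0)
extended_conf <- function() ideal_conf(-135, 135)

random_coil_frames <- function(n, seed = 5, seqp = wt_sequence()) {
  spec <- ss_spec(length(seqp$residues), blocks = list(), noise_sd = 8)
  sample_ensemble(seqp, spec, n, seed = seed)
}

# Horn's quaternion method for minimal RMSD: an algebraically
# independent check on the SVD-based Kabsch implementation.
quaternion_rmsd <- function(a, b) {
  n <- nrow(a)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  m <- crossprod(ac, bc)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz), 4, 4)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(sum(ac^2) + sum(bc^2) - 2 * lam, 0) / n)
}

# Direct rational switch, no guard tricks.
naive_switch <- function(v, r0, n, m) {
  x <- v / r0
  ifelse(x == 1, n / m, (1 - x^n) / (1 - x^m))
}

# Brute-force fragment-count CV using quaternion RMSD and plain loops.
oracle_ss_rmsd <- function(conf, kind) {
  tmpl <- bemetad:::fragment_template(kind)
  l <- length(conf$sequence$residues)
  get_atoms <- function(residues) {
    out <- NULL
    for (i in residues) {
      for (nm in c("N", "CA", "C", "O", "CB")) {
        out <- rbind(out, bemetad:::conf_atom(conf, i, nm))
      }
    }
    out
  }
  total <- 0
  if (kind == "alpha") {
    for (a in 1:(l - 5)) {
      r <- quaternion_rmsd(get_atoms(a:(a + 5)), tmpl)
      total <- total + naive_switch(r, 0.08, 8, 12)
    }
  } else {
    for (i in 1:(l - 6)) {
      for (j in (i + 4):(l - 2)) {
        r <- quaternion_rmsd(rbind(get_atoms(i:(i + 2)),
                                   get_atoms(j:(j + 2))), tmpl)
        total <- total + naive_switch(r, 0.08, 8, 12)
      }
    }
  }
  total
}

oracle_contact <- function(conf, cs) {
  total <- 0
  for (p in seq_len(nrow(cs$pairs))) {
    si <- bemetad:::contact_site(conf, cs$pairs[p, 1])
    sj <- bemetad:::contact_site(conf, cs$pairs[p, 2])
    d <- sqrt(sum((si - sj)^2))
    total <- total + naive_switch(d, cs$spec$r0, cs$spec$n_exp, cs$spec$m_exp)
  }
  total
}

oracle_alphabeta <- function(torsions, refs, col) {
  total <- 0
  for (i in seq_len(nrow(torsions))) {
    chi <- torsions[[col]][i]
    if (!is.na(chi) && !is.na(refs[i])) {
      total <- total + 0.5 * (1 + cos((chi - refs[i]) * pi / 180))
    }
  }
  total
}

# Brute-force SASA oracle with a latitude-longitude point grid (a
# different point set and bookkeeping than the golden-spiral
# implementation).
oracle_sasa_total <- function(conf, probe = 0.14, nlat = 24) {
  heavy <- which(conf$atoms$element != "H")
  xyz <- conf$xyz[heavy, , drop = FALSE]
  radii <- bemetad:::ELEMENT_RADIUS[conf$atoms$element[heavy]] + probe
  lat <- (seq_len(nlat) - 0.5) / nlat * pi
  pts <- NULL
  for (th in lat) {
    nlon <- max(1, round(2 * nlat * sin(th)))
    ph <- (seq_len(nlon) - 0.5) / nlon * 2 * pi
    pts <- rbind(pts, cbind(sin(th) * cos(ph), sin(th) * sin(ph),
                            rep(cos(th), nlon)))
  }
  wt <- rep(1 / nrow(pts), nrow(pts))
  total <- 0
  for (a in seq_along(heavy)) {
    acc <- 0
    for (p in seq_len(nrow(pts))) {
      q <- xyz[a, ] + radii[a] * pts[p, ]
      blocked <- FALSE
      for (b in seq_along(heavy)) {
        if (b == a) next
        if (sum((q - xyz[b, ])^2) < radii[b]^2) { blocked <- TRUE; break }
      }
      if (!blocked) acc <- acc + wt[p]
    }
    total <- total + acc * 4 * pi * radii[a]^2
  }
  total
}

# 3-sigma binomial tolerance with an Agresti-Coull variance floor so
# zero-count cells have a finite band.
binom_tol3 <- function(p_true, n) {
  q <- (p_true * n + 2) / (n + 4)
  3 * sqrt(q * (1 - q) / n)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(conf, rot, shift = c(0.3, -0.2, 0.5)) {
  conf$xyz <- conf$xyz %*% t(rot) + matrix(shift, nrow(conf$xyz), 3,
                                           byrow = TRUE)
  conf
}
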