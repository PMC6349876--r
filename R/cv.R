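# The seven collective variables:
#   CV1 AlphaRMSD, CV2 ParaBetaRMSD, CV3 AntiBetaRMSD : switched-RMSD
#     counts of 6-residue fragments close to an ideal helix/sheet
#   CV4 hydrophobic contacts, CV5 salt-bridge contacts : switched
#     pairwise contact numbers over side-chain interaction sites
#   CV6, CV7 : chi1/chi2 AlphaBeta similarity to reference rotamers

#' Switching-function specification
#'
#' The rational switch (1-(x/r0)^n)/(1-(x/r0)^m) used both for the
#' fragment RMSD count (r0 = 0.08 nm, n = 8, m = 12) and the contact
#' numbers.
#'
#' @param r0 reference distance or RMSD (nm), > 0.
#' @param n_exp,m_exp numerator/denominator exponents, 0 < n < m.
#' @return an object of class `SwitchingSpec`.
#' @export
switching_spec <- function(r0, n_exp = 8, m_exp = 12) {
  if (r0 <= 0) stop("r0 must be positive")
  if (!(n_exp > 0 && n_exp < m_exp)) stop("need 0 < n_exp < m_exp")
  structure(list(r0 = r0, n_exp = n_exp, m_exp = m_exp),
            class = "SwitchingSpec")
}

RMSD_SWITCH <- NULL  # initialised in .onLoad-free style below

#' Evaluate the rational switching function
#'
#' Smoothly decreasing from 1 at `value = 0`; the removable singularity
#' at `value = r0` evaluates to the analytic limit n/m.
#'
#' @param value nonnegative distance or RMSD (nm); vectorised.
#' @param spec a [switching_spec()].
#' @return switch value(s).
#' @export
switching <- function(value, spec) {
  x <- value / spec$r0
  if (any(x < 0)) stop("switching input must be nonnegative")
  out <- numeric(length(x))
  at1 <- abs(x - 1) < 1e-14
  out[at1] <- spec$n_exp / spec$m_exp
  ok <- !at1 & x > 0
  lx <- log1p(x[ok] - 1)
  out[ok] <- expm1(spec$n_exp * lx) / expm1(spec$m_exp * lx)
  out[x == 0] <- 1
  out
}

# ---- ideal fragment templates -------------------------------------------

TEMPLATE_ATOMS <- c("N", "CA", "C", "O", "CB")

# Build the three frozen 6-residue fragment templates from canonical
# dihedrals and ideal geometry. Used once to generate the package
# fixtures; ss_rmsd_cv() reads the fixtures.
make_fragment_template <- function(kind = c("alpha", "para_beta", "anti_beta")) {
  kind <- match.arg(kind)
  hexa <- peptide_sequence(rep("A", 7L))  # 7-mer; residues 1..6 used
  if (kind == "alpha") {
    conf <- build_backbone_from_torsions(
      hexa, torsion_table(7L, CANON_DIHEDRALS$H["phi"], CANON_DIHEDRALS$H["psi"]))
    return(template_coords(conf, 1:6))
  }
  strand <- build_backbone_from_torsions(
    hexa, torsion_table(7L, CANON_DIHEDRALS$E["phi"], CANON_DIHEDRALS$E["psi"]))
  s1 <- template_coords(strand, 1:3)
  # put strand 1 in a canonical frame: CA1->CA3 along +x, centered
  ca <- s1[seq(2, 15, by = 5), ]
  ctr <- colMeans(s1)
  s1 <- sweep(s1, 2, ctr)
  ex <- unit(ca[3L, ] - ca[1L, ])
  up <- conf_atom(strand, 2L, "O") - conf_atom(strand, 2L, "C")
  ez <- unit(vcross(ex, up))
  ey <- vcross(ez, ex)
  rot <- rbind(ex, ey, ez)
  s1 <- s1 %*% t(rot)
  sep <- 0.48  # inter-strand CA-CA spacing, nm
  if (kind == "anti_beta") {
    # second strand runs -x: rotate pi about z, offset in y
    flip <- diag(c(-1, -1, 1))
    s2 <- s1 %*% t(flip)
    s2[, 2L] <- s2[, 2L] + sep
  } else {
    s2 <- s1
    s2[, 1L] <- s2[, 1L] + 0.12  # half-residue stagger of a parallel sheet
    s2[, 2L] <- s2[, 2L] + sep
  }
  rbind(s1, s2)
}

template_coords <- function(conf, residues) {
  out <- matrix(NA_real_, length(residues) * length(TEMPLATE_ATOMS), 3L)
  k <- 0L
  for (i in residues) {
    for (nm in TEMPLATE_ATOMS) {
      k <- k + 1L
      a <- conf_atom(conf, i, nm)
      if (is.null(a)) stop("template residue missing atom ", nm)
      out[k, ] <- a
    }
  }
  out
}

.template_cache <- new.env(parent = emptyenv())

# Load a frozen template fixture (30 x 3 matrix, nm).
fragment_template <- function(kind) {
  if (!is.null(.template_cache[[kind]])) return(.template_cache[[kind]])
  path <- system.file("extdata", paste0("template_", kind, ".tsv"),
                      package = "bemetad")
  tmpl <- if (nzchar(path) && file.exists(path)) {
    as.matrix(utils::read.table(path, header = TRUE))
  } else {
    make_fragment_template(kind)  # fallback: identical deterministic build
  }
  dimnames(tmpl) <- NULL
  .template_cache[[kind]] <- tmpl
  tmpl
}

# Gather the 5 template atoms for a run of residues; errors name the window.
window_coords <- function(conf, residues, label) {
  out <- matrix(NA_real_, length(residues) * 5L, 3L)
  k <- 0L
  for (i in residues) {
    for (nm in TEMPLATE_ATOMS) {
      k <- k + 1L
      a <- conf_atom(conf, i, nm)
      if (is.null(a)) {
        stop(sprintf("window %s: residue %d missing atom %s", label, i, nm))
      }
      out[k, ] <- a
    }
  }
  out
}

#' Secondary-structure fragment-count CV (CV1-CV3)
#'
#' Counts 6-residue fragments resembling an ideal helix or sheet:
#' the switched RMSD (r0 = 0.08 nm, n = 8, m = 12) of each fragment's
#' N/CA/C/O/CB atoms against the frozen ideal template, summed over all
#' admissible fragments. For `alpha` the fragments are the L-5
#' contiguous windows; for the sheet kinds each fragment is a pair of
#' 3-residue segments (starts i and j with j >= i+4) superposed on the
#' two-strand template.
#'
#' @param conformation a `Conformation`.
#' @param kind `"alpha"`, `"para_beta"` or `"anti_beta"`.
#' @param spec switching spec; default the 0.08 nm RMSD switch.
#' @return CV value.
#' @export
ss_rmsd_cv <- function(conformation, kind = c("alpha", "para_beta", "anti_beta"),
                       spec = switching_spec(0.08, 8, 12)) {
  kind <- match.arg(kind)
  conf <- conformation
  l <- length(conf$sequence$residues)
  if (l < 6L) stop("need at least 6 residues")
  tmpl <- fragment_template(kind)
  nat <- nrow(tmpl)
  m_t <- colSums(tmpl)
  q_t <- sum(tmpl * tmpl)
  eb <- q_t - sum(m_t^2) / nat

  # minimal superposed rmsd from the uncentered cross-sum C = sum(a t'),
  # coordinate sums and squared norms (Kabsch via SVD of the centered
  # cross-covariance)
  pair_rmsd <- function(cmat, m_a, q_a) {
    h <- cmat - tcrossprod(m_a, m_t) / nat
    s <- svd(h)
    d <- sign(det(s$v %*% t(s$u)))
    ea <- q_a - sum(m_a^2) / nat
    sig <- s$d[1L] + s$d[2L] + d * s$d[3L]
    sqrt(max(ea + eb - 2 * sig, 0) / nat)
  }

  total <- 0
  if (kind == "alpha") {
    for (a in seq_len(l - 5L)) {
      w <- window_coords(conf, a:(a + 5L), sprintf("alpha[%d-%d]", a, a + 5L))
      cmat <- crossprod(w, tmpl)
      total <- total + switching(pair_rmsd(cmat, colSums(w), sum(w * w)), spec)
    }
  } else {
    nseg <- l - 2L
    t1 <- tmpl[1:15, , drop = FALSE]
    t2 <- tmpl[16:30, , drop = FALSE]
    c1 <- vector("list", nseg); c2 <- vector("list", nseg)
    ms <- matrix(0, nseg, 3L); qs <- numeric(nseg)
    for (s in seq_len(nseg)) {
      w <- window_coords(conf, s:(s + 2L), sprintf("%s[%d-%d]", kind, s, s + 2L))
      c1[[s]] <- crossprod(w, t1)
      c2[[s]] <- crossprod(w, t2)
      ms[s, ] <- colSums(w)
      qs[s] <- sum(w * w)
    }
    for (i in seq_len(l - 6L)) {
      for (j in seq(i + 4L, nseg)) {
        cmat <- c1[[i]] + c2[[j]]
        r <- pair_rmsd(cmat, ms[i, ] + ms[j, ], qs[i] + qs[j])
        total <- total + switching(r, spec)
      }
    }
  }
  total
}

# ---- contact CVs ---------------------------------------------------------

# Hydrophobic-core residues of the UVR8 C-terminal peptide used for the
# hydrophobic contact CV (author numbering).
UVR8_CV4_RESIDUES <- c(401L, 403L, 404L, 408L, 409L, 410L, 411L)
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "P", "F", "M", "W")

#' Contact set for a contact-number CV
#'
#' @param sequence a [peptide_sequence()].
#' @param pairs two-column integer matrix of residue index pairs (1-based).
#' @param spec a [switching_spec()].
#' @return object of class `ContactSet`.
#' @export
contact_set <- function(sequence, pairs, spec) {
  if (length(pairs) == 0L) {
    pairs <- matrix(integer(0), 0L, 2L)
  } else {
    pairs <- t(apply(pairs, 1L, sort))
    if (any(pairs[, 1L] == pairs[, 2L])) stop("self-pairs not allowed")
    pairs <- unique(pairs)
  }
  structure(list(sequence = sequence, pairs = pairs, spec = spec),
            class = "ContactSet")
}

#' Hydrophobic contact set (CV4)
#'
#' All unordered pairs among the listed hydrophobic residues, excluding
#' sequence-adjacent pairs (|i-j| < `min_seq_sep`). For the 27-residue
#' UVR8 C-terminal peptide the default residue list is V401, P403,
#' A404, A408, V409, V410 and P411; for other sequences all residues of
#' hydrophobic type are used.
#'
#' @param sequence a [peptide_sequence()].
#' @param residues author residue numbers; NULL for the default.
#' @param r0 contact reference distance (nm), default 0.40.
#' @param min_seq_sep minimum index separation of a counted pair.
#' @return a `ContactSet`.
#' @export
hydrophobic_contact_set <- function(sequence, residues = NULL, r0 = 0.40,
                                    min_seq_sep = 2L) {
  if (is.null(residues)) {
    nums <- residue_numbers(sequence)
    if (all(UVR8_CV4_RESIDUES %in% nums)) {
      residues <- UVR8_CV4_RESIDUES
    } else {
      residues <- nums[sequence$residues %in% HYDROPHOBIC_AA]
    }
  }
  idx <- residue_index(sequence, residues)
  pr <- t(utils::combn(sort(idx), 2L))
  pr <- pr[pr[, 2L] - pr[, 1L] >= min_seq_sep, , drop = FALSE]
  contact_set(sequence, pr, switching_spec(r0, 6, 12))
}

#' Salt-bridge contact set (CV5)
#'
#' All (acidic, basic) residue pairs: Asp/Glu against Arg/Lys.
#'
#' @inheritParams hydrophobic_contact_set
#' @param r0 contact reference distance (nm), default 0.35.
#' @return a `ContactSet`.
#' @export
saltbridge_contact_set <- function(sequence, r0 = 0.35, min_seq_sep = 2L) {
  acidic <- which(sequence$residues %in% ACIDIC_AA)
  basic <- which(sequence$residues %in% BASIC_AA)
  pr <- as.matrix(expand.grid(acidic, basic))
  colnames(pr) <- NULL
  pr <- pr[abs(pr[, 2L] - pr[, 1L]) >= min_seq_sep, , drop = FALSE]
  contact_set(sequence, pr, switching_spec(r0, 6, 12))
}

# Side-chain interaction site of residue i: the stored side-chain
# centroid if the input carried full side chains, else the centroid of
# the simplified side-chain atoms (CB/CG/CD), else CB.
contact_site <- function(conf, i) {
  sc <- conf_atom(conf, i, "SC")
  if (!is.null(sc)) return(sc)
  pts <- NULL
  for (nm in c("CB", "CG", "CD")) {
    a <- conf_atom(conf, i, nm)
    if (!is.null(a)) pts <- rbind(pts, a)
  }
  if (is.null(pts)) stop("residue ", i, " has no side-chain site")
  colMeans(pts)
}

#' Contact-number CV (CV4/CV5)
#'
#' Sum of the switched inter-site distances over the pairs of a
#' [contact_set()].
#'
#' @param conformation a `Conformation`.
#' @param cs a `ContactSet`.
#' @return CV value.
#' @export
contact_cv <- function(conformation, cs) {
  if (nrow(cs$pairs) == 0L) {
    warning("empty contact pair set; CV is 0")
    return(0)
  }
  sites <- t(vapply(seq_len(length(conformation$sequence$residues)),
                    function(i) contact_site(conformation, i), numeric(3)))
  d <- sqrt(rowSums((sites[cs$pairs[, 1L], , drop = FALSE] -
                       sites[cs$pairs[, 2L], , drop = FALSE])^2))
  sum(switching(d, cs$spec))
}

#' Chi-angle similarity CV (CV6/CV7)
#'
#' Sum over residues possessing the angle of (1 + cos(chi - chi_ref))/2.
#' Residues lacking the angle (or with it undefined) contribute 0.
#'
#' @param torsions a `TorsionProfile` from [compute_torsions()].
#' @param chi_ref per-residue reference angles (degrees, NA = absent),
#'   e.g. from [chi_reference()].
#' @param angle_kind `"chi1"` or `"chi2"`.
#' @return CV value.
#' @export
alphabeta_cv <- function(torsions, chi_ref, angle_kind = c("chi1", "chi2")) {
  angle_kind <- match.arg(angle_kind)
  chi <- torsions[[angle_kind]]
  ok <- !is.na(chi) & !is.na(chi_ref)
  sum(0.5 * (1 + cos((chi[ok] - chi_ref[ok]) * DEG2RAD)))
}

#' Default CV configuration for a sequence
#'
#' Bundles the switching specs, contact sets and chi references used by
#' [compute_all_cvs()].
#'
#' @param sequence a [peptide_sequence()].
#' @param cv4_r0 hydrophobic contact reference (nm); the 0.40 nm default
#'   and the 0.45 nm alternative are both meaningful presets.
#' @return list of CV parameters.
#' @export
cv_config <- function(sequence, cv4_r0 = 0.40) {
  list(sequence = sequence,
       rmsd_switch = switching_spec(0.08, 8, 12),
       cv4 = hydrophobic_contact_set(sequence, r0 = cv4_r0),
       cv5 = saltbridge_contact_set(sequence),
       chi1_ref = chi_reference(sequence, "chi1"),
       chi2_ref = chi_reference(sequence, "chi2"))
}

#' Compute all seven CVs for every frame of a trajectory
#'
#' @param trj a [trajectory()].
#' @param config a [cv_config()]; defaults to the trajectory's sequence.
#' @return data frame with columns `time_ps`, `cv1`..`cv7`, `replica`.
#' @export
compute_all_cvs <- function(trj, config = NULL) {
  if (is.null(config)) config <- cv_config(trj$sequence)
  n <- length(trj$frames)
  out <- data.frame(time_ps = numeric(n),
                    cv1 = numeric(n), cv2 = numeric(n), cv3 = numeric(n),
                    cv4 = numeric(n), cv5 = numeric(n), cv6 = numeric(n),
                    cv7 = numeric(n),
                    replica = rep(trj$replica, n))
  if (n == 0L) return(out[0L, ])
  for (k in seq_len(n)) {
    fr <- trj$frames[[k]]
    vals <- tryCatch(frame_cvs(fr, config),
                     error = function(e) stop(sprintf("frame %d: %s", k,
                                                      conditionMessage(e))))
    out$time_ps[k] <- trj$time_ps[k]
    out[k, paste0("cv", 1:7)] <- vals
  }
  out
}

# CV 7-vector of one frame.
frame_cvs <- function(conf, config) {
  tor <- compute_torsions(conf)
  c(ss_rmsd_cv(conf, "alpha", config$rmsd_switch),
    ss_rmsd_cv(conf, "para_beta", config$rmsd_switch),
    ss_rmsd_cv(conf, "anti_beta", config$rmsd_switch),
    contact_cv(conf, config$cv4),
    contact_cv(conf, config$cv5),
    alphabeta_cv(tor, config$chi1_ref, "chi1"),
    alphabeta_cv(tor, config$chi2_ref, "chi2"))
}

#' Write a CV series as TSV
#'
#' @param cv_series data frame from [compute_all_cvs()].
#' @param path output TSV path.
#' @export
write_cv_series <- function(cv_series, path) {
  utils::write.table(cv_series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
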