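# Multi-model PDB reading/writing (via bio3d) and the Trajectory
# container. Internal coordinates are nm; PDB files are Angstrom.

# Atom vocabulary the pipeline understands. Glycine's constructed
# pseudo-CB is written with the distinct name "QB" so a re-read never
# mistakes it for a real CB; a side-chain centroid site computed from a
# full-atom input is stored under "SC".
PDB_NAME_OUT <- c(N = "N", CA = "CA", C = "C", O = "O", H = "H",
                  CB = "CB", CG = "CG", CD = "CD", SC = "SC")
BACKBONE_NAMES <- c("N", "CA", "C", "O", "H", "OXT", "H1", "H2", "H3", "HN")

#' Construct a trajectory
#'
#' @param sequence a [peptide_sequence()] shared by all frames.
#' @param frames list of `Conformation` objects.
#' @param time_ps per-frame time stamps (ps), strictly increasing.
#' @param replica replica identifier (integer or NA).
#' @return an object of class `Trajectory`.
#' @export
trajectory <- function(sequence, frames, time_ps = seq_along(frames) - 1,
                       replica = NA_integer_) {
  if (length(frames) != length(time_ps)) stop("frames/time length mismatch")
  if (length(time_ps) > 1L && any(diff(time_ps) <= 0)) {
    stop("time stamps must be strictly increasing")
  }
  structure(list(sequence = sequence, frames = frames,
                 time_ps = as.numeric(time_ps),
                 replica = replica),
            class = "Trajectory")
}

#' @export
length.Trajectory <- function(x) length(x$frames)

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d residues, replica %s\n",
              length(x$frames), length(x$sequence$residues),
              as.character(x$replica)))
  invisible(x)
}

# Quick structural sanity scan of ATOM/HETATM records; errors name the
# offending line number.
check_pdb_records <- function(lines) {
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop(sprintf("malformed ATOM record at line %d", i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (any(is.na(xyz)) || is.na(resno)) {
      stop(sprintf("malformed ATOM record at line %d", i))
    }
  }
  invisible(TRUE)
}

#' Read a (multi-model) peptide PDB file
#'
#' Parses a PDB file with one or more MODEL blocks into a
#' [trajectory()]. Backbone atoms and the simplified side-chain sites
#' written by [write_pdb()] are mapped directly; for full-atom inputs
#' the remaining side-chain heavy atoms of each residue are collapsed
#' into a pseudo "SC" centroid site used by the contact CVs. Author
#' residue numbering is preserved as the sequence numbering offset.
#'
#' @param path PDB file path.
#' @return list with elements `sequence` and `trajectory`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  check_pdb_records(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  chains <- unique(atom$chain[!is.na(atom$chain)])
  if (length(chains) > 1L) stop("unsupported input: multiple chains")
  resnos <- unique(atom$resno)
  resnos <- sort(resnos)
  if (!all(diff(resnos) == 1L)) stop("unsupported input: gapped residue numbering")
  codes <- vapply(resnos, function(r) {
    r3 <- atom$resid[atom$resno == r][1L]
    code <- AA1_FROM_3[r3]
    if (is.na(code)) stop("non-standard residue: ", r3)
    unname(code)
  }, character(1))
  seqp <- peptide_sequence(codes, numbering_offset = resnos[1L])
  l <- length(codes)

  nmodels <- nrow(pdb$xyz)
  frames <- vector("list", nmodels)
  for (m in seq_len(nmodels)) {
    xyz_all <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE) / 10  # A -> nm
    rows <- list(); coords <- list(); k <- 0L
    for (i in seq_len(l)) {
      sel <- which(atom$resno == resnos[i])
      names_i <- atom$elety[sel]
      elem_i <- atom$elesy[sel]
      sc_acc <- NULL
      for (jj in seq_along(sel)) {
        nm <- names_i[jj]
        xyz <- xyz_all[sel[jj], ]
        if (nm == "QB") {
          k <- k + 1L
          rows[[k]] <- data.frame(res = i, name = "CB", element = "C",
                                  pseudo = TRUE)
          coords[[k]] <- xyz
        } else if (nm %in% c("N", "CA", "C", "O", "CB", "CG", "CD", "SC")) {
          k <- k + 1L
          rows[[k]] <- data.frame(res = i, name = nm,
                                  element = if (nm == "SC") "C"
                                            else substr(nm, 1L, 1L),
                                  pseudo = nm == "SC")
          coords[[k]] <- xyz
        } else if (nm %in% c("H", "HN")) {
          k <- k + 1L
          rows[[k]] <- data.frame(res = i, name = "H", element = "H",
                                  pseudo = FALSE)
          coords[[k]] <- xyz
        } else if (!nm %in% BACKBONE_NAMES &&
                   !identical(elem_i[jj], "H") &&
                   !grepl("^[0-9]*H", nm)) {
          # unrecognised side-chain heavy atom: goes into the centroid
          sc_acc <- rbind(sc_acc, xyz)
        }
      }
      if (!is.null(sc_acc)) {
        k <- k + 1L
        rows[[k]] <- data.frame(res = i, name = "SC", element = "C",
                                pseudo = TRUE)
        coords[[k]] <- colMeans(sc_acc)
      }
    }
    atoms <- do.call(rbind, rows)
    xyzm <- do.call(rbind, coords)
    dimnames(xyzm) <- NULL
    frames[[m]] <- new_conformation(seqp, atoms, xyzm)
  }
  list(sequence = seqp,
       trajectory = trajectory(seqp, frames))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Fixed-width PDB records, coordinates converted from nm to Angstrom.
#' Glycine pseudo-CB atoms are emitted under the atom name "QB" and
#' side-chain centroid sites under "SC" so a round trip preserves their
#' pseudo status.
#'
#' @param trj a [trajectory()] (or single `Conformation`).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(trj, path) {
  if (inherits(trj, "Conformation")) {
    trj <- trajectory(trj$sequence, list(trj))
  }
  seqp <- trj$sequence
  ref <- trj$frames[[1L]]
  natoms <- nrow(ref$atoms)
  resno <- residue_numbers(seqp)[ref$atoms$res]
  resid <- unname(AA3[seqp$residues[ref$atoms$res]])
  elety <- ref$atoms$name
  elety[elety == "CB" & ref$atoms$pseudo] <- "QB"
  elesy <- ref$atoms$element
  xyz <- matrix(NA_real_, length(trj$frames), 3L * natoms)
  for (m in seq_along(trj$frames)) {
    fr <- trj$frames[[m]]
    if (nrow(fr$atoms) != natoms || !all(fr$atoms$name == ref$atoms$name)) {
      stop("all frames must share one atom layout")
    }
    xyz[m, ] <- as.vector(t(fr$xyz)) * 10  # nm -> A
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   eleno = seq_len(natoms), elety = elety, elesy = elesy,
                   chain = rep("A", natoms))
  invisible(path)
}
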