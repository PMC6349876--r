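# Free-energy reconstruction: grid clustering of CV space, WHAM
# combination of the biased replicas, zero-pinning at the global
# minimum, 5 kJ/mol window partitioning and marginalization.

#' Grid specification over a subset of CVs
#'
#' Bins are half-open [lo, hi) with the final bin closed at hi.
#'
#' @param cv integer CV indices included in the grid.
#' @param lo,hi per-CV bounds.
#' @param nbins per-CV bin counts (>= 2).
#' @return object of class `CVGridSpec`.
#' @export
cv_grid_spec <- function(cv, lo, hi, nbins) {
  spec <- data.frame(cv = as.integer(cv), lo = lo, hi = hi,
                     nbins = as.integer(nbins))
  if (any(!is.finite(spec$lo)) || any(!is.finite(spec$hi)) ||
      any(spec$lo >= spec$hi) || any(spec$nbins < 2L)) {
    stop("invalid grid spec: need finite lo < hi and nbins >= 2")
  }
  class(spec) <- c("CVGridSpec", "data.frame")
  spec
}

grid_dim <- function(spec) spec$nbins

grid_centers <- function(spec) {
  lapply(seq_len(nrow(spec)), function(d) {
    w <- (spec$hi[d] - spec$lo[d]) / spec$nbins[d]
    spec$lo[d] + (seq_len(spec$nbins[d]) - 0.5) * w
  })
}

# Per-dimension bin index; NA when out of range. Half-open bins, final
# bin closed.
bin_index <- function(x, lo, hi, nbins) {
  w <- (hi - lo) / nbins
  i <- floor((x - lo) / w) + 1
  i[x == hi] <- nbins
  i[x < lo | x > hi] <- NA
  as.integer(i)
}

# Multi-dim cell index (linear) for a matrix of CV values (rows=frames).
cell_index <- function(vals, spec) {
  n <- nrow(vals)
  idx <- matrix(NA_integer_, n, nrow(spec))
  for (d in seq_len(nrow(spec))) {
    idx[, d] <- bin_index(vals[, d], spec$lo[d], spec$hi[d], spec$nbins[d])
  }
  ok <- rowSums(is.na(idx)) == 0L
  lin <- rep(NA_integer_, n)
  if (any(ok)) {
    mult <- cumprod(c(1L, spec$nbins[-nrow(spec)]))
    lin[ok] <- as.integer(1L + (idx[ok, , drop = FALSE] - 1L) %*% mult)
  }
  lin
}

#' Histogram trajectory frames on a CV grid
#'
#' Frames before the equilibration cut (a fraction of each replica's
#' run, default 6%) are discarded; the remainder are counted per grid
#' cell, per replica.
#'
#' @param cv_series data frame with `cv<k>` columns and a `replica`
#'   column (as produced by [run_bem()] or [compute_all_cvs()]).
#' @param grid_spec a [cv_grid_spec()].
#' @param equil_frac fraction of each replica's frames to discard.
#' @return list with `counts` (list per replica of count vectors over
#'   cells), `out_of_range` counts, `replicas` ids.
#' @export
histogram_frames <- function(cv_series, grid_spec, equil_frac = 0.06) {
  if (nrow(cv_series) == 0L) stop("empty CV series")
  reps <- unique(cv_series$replica)
  ncell <- prod(grid_spec$nbins)
  counts <- list()
  oor <- numeric(length(reps))
  for (ri in seq_along(reps)) {
    sub <- cv_series[cv_series$replica == reps[ri], , drop = FALSE]
    drop <- floor(nrow(sub) * equil_frac)
    if (drop > 0L) sub <- sub[-seq_len(drop), , drop = FALSE]
    vals <- as.matrix(sub[, paste0("cv", grid_spec$cv), drop = FALSE])
    lin <- cell_index(vals, grid_spec)
    cnt <- tabulate(lin[!is.na(lin)], nbins = ncell)
    counts[[ri]] <- cnt
    oor[ri] <- sum(is.na(lin))
  }
  if (all(vapply(counts, sum, numeric(1)) == 0)) {
    stop("all frames fall outside the grid")
  }
  list(counts = counts, out_of_range = oor, replicas = reps,
       grid_spec = grid_spec)
}

# Bias of one replica evaluated at all cell centers (kJ/mol). The bias
# acts on a single CV; if that CV is not a grid dimension the replica
# is treated as unbiased on this grid (documented approximation).
replica_bias_on_grid <- function(bias, spec) {
  ncell <- prod(spec$nbins)
  if (is.null(bias) || is.na(bias$cv_index)) return(numeric(ncell))
  d <- match(bias$cv_index, spec$cv)
  if (is.na(d)) {
    warning("bias on cv", bias$cv_index,
            " not representable on this grid; treated as unbiased")
    return(numeric(ncell))
  }
  centers <- grid_centers(spec)[[d]]
  v1 <- bias_energy(bias, centers)
  # expand along the other dimensions
  reps_before <- prod(c(1L, spec$nbins)[seq_len(d)])
  reps_after <- ncell / (reps_before * spec$nbins[d])
  rep(rep(v1, each = reps_before), times = reps_after)
}

#' Combine biased histograms into a free-energy grid by WHAM
#'
#' Standard multi-histogram self-consistency with each replica's bias
#' treated as static (its final deposited bias), iterated until the
#' maximum free-energy change drops below `tol`. The returned grid is
#' pinned so the minimum over visited cells is exactly zero.
#'
#' @param histograms result of [histogram_frames()].
#' @param bias_histories list of `BiasState` (one per replica, same
#'   order as the histogram replicas); NULL entries mean unbiased.
#' @param kT thermal energy (kJ/mol).
#' @param tol convergence tolerance on max |dF| (kJ/mol).
#' @param max_iter iteration cap.
#' @return object of class `FreeEnergyGrid` with `values` (kJ/mol, Inf
#'   where unvisited), `visited`, `spec`, `kT`, `iterations`, `residual`.
#' @export
wham_combine <- function(histograms, bias_histories, kT, tol = 1e-6,
                         max_iter = 5000L) {
  spec <- histograms$grid_spec
  counts <- histograms$counts
  nrep <- length(counts)
  if (length(bias_histories) != nrep) {
    stop("one bias history per replica required")
  }
  ncell <- prod(spec$nbins)
  nmat <- do.call(cbind, counts)            # ncell x nrep
  ntot <- rowSums(nmat)
  nr <- colSums(nmat)
  active <- nr > 0
  check_histogram_overlap(nmat, active)
  vmat <- vapply(bias_histories, replica_bias_on_grid, numeric(ncell),
                 spec = spec)
  wfac <- exp(-vmat / kT)                   # ncell x nrep
  f <- numeric(nrep)                        # exp(f_r/kT) handled in log space
  visited <- ntot > 0
  p <- ntot / sum(ntot)
  fe_old <- rep(Inf, ncell)
  iter <- 0L
  resid <- Inf
  repeat {
    iter <- iter + 1L
    denom <- wfac %*% (nr * exp(f / kT))    # ncell
    p <- ifelse(denom > 0, ntot / denom, 0)
    p <- p / sum(p)
    for (r in which(active)) {
      zr <- sum(p * wfac[, r])
      f[r] <- -kT * log(zr)
    }
    fe <- ifelse(visited & p > 0, -kT * log(p), Inf)
    fin <- is.finite(fe)
    fe[fin] <- fe[fin] - min(fe[fin])
    resid <- max(abs(fe[fin] - fe_old[fin]), 0)
    if (is.na(resid)) resid <- Inf
    if ((iter > 1L && resid < tol) || iter >= max_iter) break
    fe_old <- fe
  }
  structure(list(spec = spec, values = fe, visited = visited, kT = kT,
                 iterations = iter, residual = resid,
                 replica_f = f),
            class = "FreeEnergyGrid")
}

# Replicas must overlap through shared visited cells, otherwise their
# free-energy offsets are undetermined.
check_histogram_overlap <- function(nmat, active) {
  idx <- which(active)
  if (length(idx) <= 1L) return(invisible(TRUE))
  comp <- seq_along(idx)
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (a >= b) next
      if (any(nmat[, idx[a]] > 0 & nmat[, idx[b]] > 0)) {
        comp[comp == comp[b]] <- comp[a]
      }
    }
  }
  if (length(unique(comp)) > 1L) {
    groups <- split(idx, comp)
    stop("non-overlapping replica histograms; disconnected components: ",
         paste(vapply(groups, function(g) paste(g, collapse = ","),
                      character(1)), collapse = " | "))
  }
  invisible(TRUE)
}

#' Re-pin a free-energy grid so its visited minimum is zero
#'
#' @param grid a `FreeEnergyGrid`.
#' @export
normalize_grid <- function(grid) {
  fin <- is.finite(grid$values)
  grid$values[fin] <- grid$values[fin] - min(grid$values[fin])
  grid
}

#' Free energy of the cell containing a frame's CV values
#'
#' @param cv_record numeric CV vector, or a one-row data frame with
#'   `cv<k>` columns.
#' @param grid a `FreeEnergyGrid`.
#' @return free energy (kJ/mol); NA if out of grid or unvisited.
#' @export
frame_free_energy <- function(cv_record, grid) {
  spec <- grid$spec
  if (is.data.frame(cv_record)) {
    vals <- as.matrix(cv_record[, paste0("cv", spec$cv), drop = FALSE])
  } else {
    vals <- matrix(cv_record[spec$cv], 1L)
  }
  lin <- cell_index(vals, spec)
  out <- rep(NA_real_, nrow(vals))
  ok <- !is.na(lin)
  out[ok] <- grid$values[lin[ok]]
  out[!is.finite(out)] <- NA_real_
  out
}

#' Partition frames into free-energy windows
#'
#' Windows are the half-open 5 kJ/mol slices [0,5), [5,10), ... [20,25)
#' above the global minimum; frames above the last boundary (or in
#' unvisited cells) are flagged out of range (window NA).
#'
#' @param cv_series data frame of frames with `cv<k>` columns.
#' @param grid a normalized `FreeEnergyGrid`.
#' @param window_width window width (kJ/mol).
#' @param max_energy upper edge of the last window (kJ/mol).
#' @return data frame of class `WindowAssignment` with columns
#'   `free_energy` and `window` (1-based index, NA out of range).
#' @export
assign_windows <- function(cv_series, grid, window_width = 5,
                           max_energy = 25) {
  fe <- frame_free_energy(cv_series, grid)
  win <- floor(fe / window_width) + 1L
  win[!is.na(fe) & fe >= max_energy] <- NA_integer_
  out <- data.frame(free_energy = fe, window = win)
  class(out) <- c("WindowAssignment", "data.frame")
  out
}

#' Marginalize a free-energy grid onto a subset of its CVs
#'
#' F_marg = -kT log sum exp(-F/kT) over the integrated-out dimensions,
#' re-pinned to zero at its minimum; unvisited cells are excluded from
#' the sums.
#'
#' @param grid a `FreeEnergyGrid`.
#' @param keep_cvs CV indices to keep (must be grid dimensions).
#' @return a `FreeEnergyGrid` over the kept CVs.
#' @export
marginalize <- function(grid, keep_cvs) {
  spec <- grid$spec
  keep <- match(keep_cvs, spec$cv)
  if (any(is.na(keep))) stop("keep_cvs must be grid dimensions")
  if (length(keep) == nrow(spec)) {
    perm <- keep
    if (all(perm == seq_len(nrow(spec)))) return(normalize_grid(grid))
  }
  arr <- array(exp(-grid$values / grid$kT), dim = spec$nbins)
  marg <- apply(arr, keep, sum)
  vals <- as.vector(marg)
  fe <- ifelse(vals > 0, -grid$kT * log(vals), Inf)
  fin <- is.finite(fe)
  fe[fin] <- fe[fin] - min(fe[fin])
  newspec <- cv_grid_spec(spec$cv[keep], spec$lo[keep], spec$hi[keep],
                          spec$nbins[keep])
  structure(list(spec = newspec, values = fe, visited = fin, kT = grid$kT,
                 iterations = grid$iterations, residual = grid$residual),
            class = "FreeEnergyGrid")
}

#' Serialize a free-energy grid as TSV (+ JSON metadata)
#'
#' @param grid a `FreeEnergyGrid`.
#' @param path output TSV path; metadata goes to `<path>.json`.
#' @export
write_fes <- function(grid, path) {
  spec <- grid$spec
  centers <- grid_centers(spec)
  tab <- do.call(expand.grid, centers)
  names(tab) <- paste0("cv", spec$cv)
  tab$free_energy <- ifelse(is.finite(grid$values), grid$values, NA)
  tab$visited <- grid$visited
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(grid = as.data.frame(unclass(spec)), kT = grid$kT,
               iterations = grid$iterations, residual = grid$residual)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
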