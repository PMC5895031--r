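# Trajectory analytics: rigid-body superposition, RMSD/RMSF/Rg,
# equilibrium-window statistics, group comparison, model quality score.

STANDARD_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974)

element_mass <- function(elesy) {
  m <- STANDARD_MASSES[toupper(elesy)]
  if (any(is.na(m)))
    stop_input("no standard mass for element(s): %s",
               paste(unique(elesy[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Construct a trajectory object
#'
#' A trajectory is an ordered set of frames sharing one atom table. Frames
#' are stored as a `nframes x 3N` coordinate matrix (x1,y1,z1,x2,...), the
#' layout used by bio3d.
#'
#' @param atoms Data frame with columns `elety` (atom name), `resno`
#'   (1-based residue index), `elesy` (element symbol) and optionally
#'   `resid`, `mass`. Missing masses are filled from standard atomic
#'   masses by element.
#' @param xyz Numeric matrix, one row per frame, `3 * nrow(atoms)` columns
#'   (Angstrom).
#' @param dt_ps Frame spacing in picoseconds (default 25).
#' @param times_ps Optional explicit frame times; must be strictly
#'   increasing.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(atoms, xyz, dt_ps = 25, times_ps = NULL) {
  xyz <- matrix(as.numeric(xyz), nrow = NROW(xyz))
  if (ncol(xyz) != 3 * nrow(atoms))
    stop_input("xyz has %d columns; expected 3 * %d atoms", ncol(xyz),
               nrow(atoms))
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$elesy)
  if (any(atoms$mass <= 0)) stop_input("atom masses must be positive")
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  if (is.null(times_ps)) times_ps <- (seq_len(nrow(xyz)) - 1) * dt_ps
  if (any(diff(times_ps) <= 0))
    stop_input("frame times must be strictly increasing")
  structure(list(atoms = atoms, xyz = xyz, times_ps = times_ps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d atoms, %d residues, dt ~ %g ps\n",
              nrow(x$xyz), nrow(x$atoms), length(unique(x$atoms$resno)),
              if (nrow(x$xyz) > 1) stats::median(diff(x$times_ps)) else NA))
  invisible(x)
}

# frame as N x 3 matrix
frame_coords <- function(traj, i, sel = NULL) {
  m <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

#' Select atoms from a trajectory
#'
#' @param traj A [trajectory()].
#' @param selection `"backbone"` (atom names N, CA, C, O), `"calpha"`,
#'   `"all"`, or a predicate `function(elety, resno)` returning a logical
#'   vector.
#' @return Integer indices into the atom table.
#' @export
select_atoms <- function(traj, selection = "all") {
  a <- traj$atoms
  idx <- if (is.function(selection)) {
    which(selection(a$elety, a$resno))
  } else {
    switch(selection,
           all = seq_len(nrow(a)),
           backbone = which(toupper(a$elety) %in% c("N", "CA", "C", "O")),
           calpha = which(toupper(a$elety) == "CA"),
           stop_input("unknown selection '%s'", selection))
  }
  if (length(idx) == 0) stop_input("empty atom selection")
  idx
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses MODEL/ENDMDL-framed ATOM records (fixed-column PDB dialect) via
#' bio3d after validating that every model carries the same atom set; an
#' inconsistent model triggers an integrity error naming the first
#' offending atom.
#'
#' @param path PDB file path.
#' @param dt_ps Frame spacing in picoseconds (default 25).
#' @return A [trajectory()].
#' @export
read_multimodel_pdb <- function(path, dt_ps = 25) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path)
  atom_lines <- grepl("^ATOM  |^HETATM", lines)
  if (!any(atom_lines)) stop_input("no ATOM records in %s", path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop_input("unbalanced MODEL/ENDMDL records in %s", path)
    key <- function(i) {
      blk <- lines[model_starts[i]:model_ends[i]]
      blk <- blk[grepl("^ATOM  |^HETATM", blk)]
      paste(trimws(substr(blk, 13, 16)), trimws(substr(blk, 23, 26)))
    }
    ref_key <- key(1)
    for (i in seq_along(model_starts)[-1]) {
      k <- key(i)
      if (length(k) != length(ref_key) || any(k != ref_key)) {
        bad <- if (length(k) < length(ref_key))
          setdiff(ref_key, k)[1] else
            c(setdiff(k, ref_key), k[k != ref_key[seq_along(k)]])[1]
        stop_input(
          "inconsistent atom set in model %d (atom '%s'): all models must share one atom table",
          i, bad)
      }
    }
  }
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(elety = p$atom$elety,
                      resid = p$atom$resid,
                      resno = p$atom$resno,
                      elesy = ifelse(is.na(p$atom$elesy) | p$atom$elesy == "",
                                     substr(trimws(p$atom$elety), 1, 1),
                                     p$atom$elesy),
                      stringsAsFactors = FALSE)
  xyz <- matrix(as.numeric(p$xyz), nrow = nrow(p$xyz))
  trajectory(atoms, xyz, dt_ps = dt_ps)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  a <- traj$atoms
  bio3d::write.pdb(file = path, xyz = traj$xyz,
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = "A", elesy = a$elesy,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Optimal rigid-body (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD
#' between two matched coordinate sets (reflections excluded), via SVD of
#' the weighted covariance matrix.
#'
#' @param mobile,reference `N x 3` coordinate matrices (Angstrom), `N >= 3`
#'   non-collinear points.
#' @param weights Per-atom weights (e.g. masses); default uniform.
#' @return List with `rotation` (3x3, det +1), `translation` (length-3;
#'   the superposed mobile is `mobile %*% t(rotation) + translation`) and
#'   `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop_input("mobile and reference must be matching N x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop_input("need at least 3 atoms for superposition")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w <= 0)) stop_input("bad weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  if (svd(P * sqrt(w))$d[2] < 1e-8)
    stop_input("degenerate (collinear) geometry: rotation is not unique")
  A <- t(P) %*% (Q * w)                      # sum_i w_i p_i q_i^T
  s <- svd(A)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

#' Per-frame RMSD time series after superposition
#'
#' Each frame's selected atoms are optimally superposed onto the reference
#' frame before the deviation is measured, so rigid-body motion never
#' contributes.
#'
#' @param traj A [trajectory()].
#' @param selection See [select_atoms()]; default `"backbone"`.
#' @param reference Reference frame index (default 1, the common
#'   convention).
#' @param mass_weighted Weight atoms by mass (default `FALSE`).
#' @return Data frame with `time_ps` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, selection = "backbone", reference = 1,
                        mass_weighted = FALSE) {
  sel <- select_atoms(traj, selection)
  w <- if (mass_weighted) traj$atoms$mass[sel] else NULL
  ref <- frame_coords(traj, reference, sel)
  vals <- vapply(seq_len(nrow(traj$xyz)), function(i)
    kabsch_superpose(frame_coords(traj, i, sel), ref, w)$rmsd, 0)
  data.frame(time_ps = traj$times_ps, rmsd = vals)
}

#' Per-residue RMSF profile
#'
#' Frames at or after `equil_start_ns` are superposed onto a reference
#' structure — by default the time-averaged structure, iterated to
#' self-consistency — and the root-mean-square fluctuation of each
#' selected atom about its mean position is reported.
#'
#' @param traj A [trajectory()].
#' @param selection Default `"calpha"`.
#' @param equil_start_ns Start of the analysis window in nanoseconds
#'   (default 0).
#' @param reference `"mean"` (iterated mean structure, default) or
#'   `"first"` frame of the window.
#' @param tol Convergence tolerance on the mean structure (Angstrom,
#'   default 1e-6).
#' @param max_iter Maximum mean-structure iterations (default 20).
#' @return Data frame with `resno`, `elety` and `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, selection = "calpha", equil_start_ns = 0,
                         reference = c("mean", "first"), tol = 1e-6,
                         max_iter = 20) {
  reference <- match.arg(reference)
  sel <- select_atoms(traj, selection)
  frames <- which(traj$times_ps >= equil_start_ns * 1000)
  if (length(frames) < 2)
    stop_input("need >= 2 frames at/after %g ns", equil_start_ns)
  coords <- lapply(frames, function(i) frame_coords(traj, i, sel))
  superpose_all <- function(ref) lapply(coords, function(x) {
    k <- kabsch_superpose(x, ref)
    x %*% t(k$rotation) + matrix(k$translation, nrow(x), 3, byrow = TRUE)
  })
  ref <- if (reference == "first") coords[[1]] else
    Reduce(`+`, coords) / length(coords)
  fitted <- superpose_all(ref)
  if (reference == "mean") {
    for (iter in seq_len(max_iter)) {
      new_ref <- Reduce(`+`, fitted) / length(fitted)
      if (max(abs(new_ref - ref)) < tol) break
      ref <- new_ref
      fitted <- superpose_all(ref)
    }
  }
  mean_pos <- Reduce(`+`, fitted) / length(fitted)
  sq <- Reduce(`+`, lapply(fitted, function(x) rowSums((x - mean_pos)^2)))
  data.frame(resno = traj$atoms$resno[sel], elety = traj$atoms$elety[sel],
             rmsf = sqrt(sq / length(fitted)))
}

#' Mass-weighted radius of gyration
#'
#' `Rg = sqrt( sum_i m_i |r_i - r_com|^2 / sum_i m_i )`, the mass-weighted
#' root-mean-square distance of atoms from their centre of mass.
#'
#' @param coords `N x 3` coordinate matrix (Angstrom).
#' @param masses Per-atom masses (> 0 total).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop_input("need at least one atom")
  m <- if (is.null(masses)) rep(1, nrow(coords)) else as.numeric(masses)
  if (sum(m) <= 0) stop_input("total mass must be positive")
  com <- colSums(coords * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(coords, 2, com)^2)) / sum(m))
}

#' Per-frame radius-of-gyration series
#'
#' @param traj A [trajectory()].
#' @param selection See [select_atoms()]; default `"all"`.
#' @return Data frame with `time_ps` and `rg` (Angstrom).
#' @export
rg_series <- function(traj, selection = "all") {
  sel <- select_atoms(traj, selection)
  m <- traj$atoms$mass[sel]
  data.frame(time_ps = traj$times_ps,
             rg = vapply(seq_len(nrow(traj$xyz)), function(i)
               radius_of_gyration(frame_coords(traj, i, sel), m), 0))
}

#' Mean and SD over the post-equilibration window
#'
#' @param values Per-frame values.
#' @param times_ps Frame times in picoseconds.
#' @param equil_start_ns Window start in nanoseconds (default 12).
#' @return List with `mean`, `sd`, `n`, `window_start_ns`.
#' @export
equilibrium_stats <- function(values, times_ps, equil_start_ns = 12) {
  keep <- times_ps >= equil_start_ns * 1000
  if (sum(keep) < 2)
    stop_input("fewer than 2 frames at/after %g ns", equil_start_ns)
  list(mean = mean(values[keep]), sd = stats::sd(values[keep]),
       n = sum(keep), window_start_ns = equil_start_ns)
}

#' Compare two samples of structural statistics
#'
#' Both samples are screened for normality (Shapiro-Wilk at 0.05); when
#' both pass, Welch's t-test is used, otherwise the unpaired Wilcoxon
#' rank-sum test. Significance is declared at `p < alpha`.
#'
#' @param a,b Numeric samples, each of size >= 3.
#' @param alpha Significance level (default 0.05).
#' @return List with `test`, `statistic`, `p_value`, `significant`.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3)
    stop_input("each sample needs >= 3 values")
  normal <- function(x) {
    if (length(unique(x)) == 1) return(TRUE)  # degenerate: no evidence against
    stats::shapiro.test(if (length(x) > 5000) sample(x, 5000) else x)$p.value > 0.05
  }
  if (identical(a, b) || (stats::var(a) == 0 && stats::var(b) == 0 &&
                          mean(a) == mean(b)))
    return(list(test = "none (identical samples)", statistic = NA_real_,
                p_value = 1, significant = FALSE))
  if (normal(a) && normal(b)) {
    t <- stats::t.test(a, b)
    list(test = "t-test", statistic = unname(t$statistic),
         p_value = t$p.value, significant = t$p.value < alpha)
  } else {
    w <- stats::wilcox.test(a, b, exact = FALSE)
    list(test = "wilcoxon", statistic = unname(w$statistic),
         p_value = w$p.value, significant = w$p.value < alpha)
  }
}

#' Combined homology-model quality Z-score
#'
#' Weighted average of the dihedral, 1D-packing and 3D-packing Z-scores:
#' `0.1456 * dihedrals + 0.3906 * packing1d + 0.4656 * packing3d`.
#'
#' @param dihedrals,packing1d,packing3d Component Z-scores.
#' @return Combined Z-score.
#' @export
model_zscore <- function(dihedrals, packing1d, packing3d) {
  stopifnot(is.finite(dihedrals), is.finite(packing1d), is.finite(packing3d))
  0.1456 * dihedrals + 0.3906 * packing1d + 0.4656 * packing3d
}
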