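# Trajectory container, Kabsch superposition and per-residue RMSF.
#
# RMSF here is the root mean square deviation of coordinates from the first
# frame (the reference), averaged over time, after every frame has been
# rigidly aligned onto the first frame.

#' Construct a trajectory
#'
#' @param coords Numeric array of dimension frames x atoms x 3 (angstrom).
#' @param atoms Data frame with one row per atom: columns `resno`,
#'   `resname`, `name` (and optionally `element`; derived from `name` when
#'   absent).
#' @param timestep Optional frame spacing metadata (any units).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(coords, atoms, timestep = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L,
            dim(coords)[2L] == nrow(atoms))
  if (dim(coords)[1L] < 2L) stop("a trajectory needs at least 2 frames")
  if (is.null(atoms$element)) atoms$element <- substr(atoms$name, 1L, 1L)
  structure(list(coords = coords, atoms = atoms, timestep = timestep),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<trajectory> %d frames x %d atoms (%d residues)\n",
              d[1L], d[2L], length(unique(x$atoms$resno))))
  invisible(x)
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation (det = +1) and translation minimizing the
#' (optionally weighted) RMSD between `mobile` and `reference` point sets.
#' Mirror images are never matched by an improper rotation; the best proper
#' rotation is returned with its (positive) residual RMSD.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, not collinear.
#' @param weights Optional non-negative per-point weights.
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (angstrom), and `transform(x)`, a function applying the fit to any
#'   m x 3 matrix.  The fit maps mobile onto reference as
#'   `mobile %*% rotation + translation` (row-vector convention).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- matrix(as.numeric(mobile), ncol = 3L)
  reference <- matrix(as.numeric(reference), ncol = 3L)
  n <- nrow(mobile)
  stopifnot(nrow(reference) == n)
  if (n < 3L) stop("need at least 3 points for a superposition")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  # degenerate (collinear) sets leave the rotation about the axis undefined
  if (svd(P)$d[2L] < 1e-8 * max(1, svd(P)$d[1L])) {
    stop("degenerate (collinear) point set: superposition not unique")
  }
  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  translation <- cr - as.numeric(cm %*% R)
  moved <- P %*% R - Q
  rmsd <- sqrt(sum(w * rowSums(moved^2)))
  transform <- function(x) {
    x <- matrix(as.numeric(x), ncol = 3L)
    sweep(x %*% R, 2L, translation, "+")
  }
  list(rotation = R, translation = translation, rmsd = rmsd,
       transform = transform)
}

.atom_selection <- function(atoms, selection) {
  bb <- c("N", "CA", "C", "O")
  switch(selection,
         all = which(atoms$element != "H"),
         calpha = which(atoms$name == "CA"),
         sidechain = which(!(atoms$name %in% bb) & atoms$element != "H"),
         stop(sprintf("unknown selection '%s'", selection)))
}

#' Per-residue RMSF
#'
#' Aligns every frame onto the first frame (Kabsch fit on
#' `align_selection`, default C-alpha atoms), then computes for every
#' selected atom the root mean square deviation from its first-frame
#' position over all frames, and aggregates per residue as the RMS over the
#' residue's selected atoms.
#'
#' @param traj A [trajectory()].
#' @param selection Atoms entering the profile: `"all"` heavy atoms
#'   (default; subsite tryptophan side chains must be included),
#'   `"calpha"`, or `"sidechain"`.
#' @param align_selection Atoms used for the rigid alignment (default
#'   `"calpha"`).
#' @param per_residue Aggregate per residue (default) or return per-atom
#'   values.
#' @return Data frame with `resno`, `resname`, `rmsf` (angstrom) and
#'   `n_atoms` (per-residue mode) or per-atom rows with `name`; the
#'   selection is recorded in attribute `selection`.
#' @export
compute_rmsf <- function(traj, selection = c("all", "calpha", "sidechain"),
                         align_selection = "calpha", per_residue = TRUE) {
  selection <- match.arg(selection)
  stopifnot(inherits(traj, "trajectory"))
  sel <- .atom_selection(traj$atoms, selection)
  if (length(sel) == 0L) stop("empty atom selection")
  asel <- .atom_selection(traj$atoms, align_selection)
  if (length(asel) < 3L) stop("alignment selection needs at least 3 atoms")
  co <- traj$coords
  n_frames <- dim(co)[1L]
  ref_align <- co[1L, asel, , drop = TRUE]
  ref_sel <- co[1L, sel, , drop = TRUE]
  ssq <- numeric(length(sel))
  for (f in seq.int(2L, n_frames)) {
    fit <- kabsch_superpose(co[f, asel, , drop = TRUE], ref_align)
    moved <- fit$transform(co[f, sel, , drop = TRUE])
    ssq <- ssq + rowSums((moved - ref_sel)^2)
  }
  rmsf_atom <- sqrt(ssq / n_frames)  # frame 1 contributes 0 by construction
  at <- traj$atoms[sel, , drop = FALSE]
  if (!per_residue) {
    out <- data.frame(resno = at$resno, resname = at$resname,
                      name = at$name, rmsf = rmsf_atom,
                      stringsAsFactors = FALSE)
  } else {
    msq <- tapply(rmsf_atom^2, at$resno, mean)
    resno <- as.integer(names(msq))
    out <- data.frame(
      resno = resno,
      resname = at$resname[match(resno, at$resno)],
      rmsf = sqrt(as.numeric(msq)),
      n_atoms = as.integer(table(at$resno)[as.character(resno)]),
      stringsAsFactors = FALSE)
    out <- out[order(out$resno), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "selection") <- selection
  out
}
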