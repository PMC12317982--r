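# Trajectory analysis for helical TMDs: logistic residue-residue contact
# numbers and principal-axis tilt angles relative to the membrane normal.
# Distances are in Angstrom throughout; nm inputs are converted at the
# reader boundary.

#' Logistic contact contribution of one heavy-atom pair
#'
#' \code{1 / (1 + exp(s * (d - d0)))} with midpoint \code{d0 = 4} A and
#' steepness \code{s = 5} per A: exactly 0.5 at 4 A, between 0.5 and 1
#' below, approaching 0 beyond.
#'
#' @param d Distance(s) in Angstrom, \code{>= 0}.
#' @param d0 Sigmoid midpoint in Angstrom.
#' @param steepness Sigmoid steepness in 1/Angstrom.
#' @return Contribution(s) in (0, 1); strictly decreasing in \code{d}.
#' @examples
#' pair_contact(4)    # 0.5
#' pair_contact(100)  # ~0
#' @export
pair_contact <- function(d, d0 = 4, steepness = 5) {
  stopifnot(all(d >= 0), d0 > 0, steepness > 0)
  1 / (1 + exp(steepness * (d - d0)))
}

#' Build a helix trajectory container
#'
#' @param frames List of frames; each frame is a named list mapping residue
#'   ids to numeric matrices (n_atoms x 3) of heavy-atom coordinates in
#'   Angstrom. Every frame must share the same residue/atom grouping.
#' @param box Optional per-trajectory orthorhombic box lengths (length-3
#'   numeric, Angstrom) for minimum-image distances.
#' @param membrane_normal Unit vector (default +z).
#' @return An object of class \code{"helix_trajectory"}.
#' @export
helix_trajectory <- function(frames, box = NULL, membrane_normal = c(0, 0, 1)) {
  stopifnot(length(frames) >= 1L)
  grouping <- lapply(frames[[1L]], nrow)
  for (f in frames) {
    stopifnot(identical(names(f), names(frames[[1L]])),
              identical(lapply(f, nrow), grouping),
              all(vapply(f, function(m) all(is.finite(m)), logical(1L))))
  }
  nrm <- membrane_normal / sqrt(sum(membrane_normal^2))
  structure(list(frames = frames, box = box, membrane_normal = nrm),
            class = "helix_trajectory")
}

#' @export
print.helix_trajectory <- function(x, ...) {
  cat(sprintf("Helix trajectory: %d frames, %d residues, %d heavy atoms%s\n",
              length(x$frames), length(x$frames[[1L]]),
              sum(vapply(x$frames[[1L]], nrow, integer(1L))),
              if (is.null(x$box)) "" else " (periodic box)"))
  invisible(x)
}

# Pairwise distances between two coordinate matrices, with minimum-image
# convention when an orthorhombic box is given.
pair_distances <- function(A, B, box = NULL) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    diff <- outer(A[, k], B[, k], `-`)
    if (!is.null(box)) diff <- diff - box[k] * round(diff / box[k])
    d2 <- d2 + diff^2
  }
  sqrt(d2)
}

#' Time-averaged contact number between two residues
#'
#' Per frame, sums \code{\link{pair_contact}} over all heavy-atom pairs of
#' the two residues (minimum-image distances when the trajectory carries a
#' periodic box), then averages over frames.
#'
#' @param traj A \code{helix_trajectory}.
#' @param residue_i,residue_j Residue ids (names in the frame grouping).
#' @param d0,steepness Contact-function parameters.
#' @return A single non-negative number; symmetric in i and j.
#' @export
contact_number <- function(traj, residue_i, residue_j, d0 = 4,
                           steepness = 5) {
  stopifnot(inherits(traj, "helix_trajectory"))
  per_frame <- vapply(seq_along(traj$frames), function(fi) {
    f <- traj$frames[[fi]]
    for (r in c(residue_i, residue_j))
      if (is.null(f[[r]]) || nrow(f[[r]]) == 0L)
        stop("residue '", r, "' absent from frame ", fi)
    D <- pair_distances(f[[residue_i]], f[[residue_j]], traj$box)
    sum(pair_contact(D, d0, steepness))
  }, numeric(1L))
  mean(per_frame)
}

#' Helix tilt angle from principal-axis decomposition
#'
#' The helix axis is taken as the eigenvector with the largest eigenvalue of
#' the covariance of the heavy-atom coordinates about their centroid
#' (assuming a stiff, essentially straight helix); the tilt is the angle
#' between that axis and the membrane normal, folded to [0, 90] degrees so
#' the axis sign is irrelevant.
#'
#' @param coords Numeric matrix (n x 3) of heavy-atom coordinates of the
#'   helical region, n >= 3 and not collinear.
#' @param membrane_normal Membrane normal vector (default +z); normalized
#'   internally.
#' @return Tilt angle in degrees, in [0, 90]. If the top two eigenvalues are
#'   nearly equal the axis is ill-defined and a warning is issued.
#' @export
tilt_angle <- function(coords, membrane_normal = c(0, 0, 1)) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L, nrow(coords) >= 3L)
  ctr <- sweep(coords, 2L, colMeans(coords))
  ev <- eigen(crossprod(ctr) / nrow(coords), symmetric = TRUE)
  if (ev$values[1L] <= ev$values[2L] * (1 + 1e-8) &&
      ev$values[2L] > 0)
    warning("top two principal components nearly degenerate; ",
            "helix axis ill-defined")
  axis <- ev$vectors[, 1L]
  nrm <- membrane_normal / sqrt(sum(membrane_normal^2))
  acos(pmin(1, abs(sum(axis * nrm)))) * 180 / pi
}

#' Per-frame tilt angles over a trajectory
#'
#' @param traj A \code{helix_trajectory}.
#' @param residues Residue ids defining the helical region (default: all).
#' @param stride Sample every \code{stride}-th frame (default 1).
#' @param breaks Histogram bin edges in degrees (default 2-degree bins over
#'   [0, 90]).
#' @return List with \code{angles} (one per sampled frame) and
#'   \code{histogram} (data.frame: bin midpoints and counts).
#' @export
tilt_distribution <- function(traj, residues = NULL, stride = 1L,
                              breaks = seq(0, 90, by = 2)) {
  stopifnot(inherits(traj, "helix_trajectory"), stride >= 1L)
  if (length(traj$frames) == 0L) stop("empty trajectory")
  if (is.null(residues)) residues <- names(traj$frames[[1L]])
  idx <- seq(from = stride, to = length(traj$frames), by = stride)
  angles <- vapply(idx, function(fi) {
    coords <- do.call(rbind, traj$frames[[fi]][residues])
    tilt_angle(coords, traj$membrane_normal)
  }, numeric(1L))
  h <- graphics::hist(angles, breaks = breaks, plot = FALSE)
  list(angles = angles,
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Generate an ideal alpha-helix point set
#'
#' C-alpha trace of an ideal alpha-helix (radius 2.3 A, rise 1.5 A per
#' residue, 100 degrees per residue) along an arbitrary axis. Used to build
#' synthetic trajectories with known tilt.
#'
#' @param n_res Number of residues.
#' @param axis Helix axis direction (default +z).
#' @param origin Start point.
#' @return Numeric matrix (n_res x 3), Angstrom.
#' @export
ideal_helix <- function(n_res = 20L, axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  t <- (seq_len(n_res) - 1L)
  local <- cbind(2.3 * cos(t * 100 * pi / 180),
                 2.3 * sin(t * 100 * pi / 180),
                 1.5 * t)
  # rotate +z onto the requested axis
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  s <- sqrt(sum(v^2)); cth <- sum(z * axis)
  R <- if (s < 1e-12) diag(3) * sign(cth) else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  sweep(local %*% t(R), 2L, origin, `+`)
}

#' Rotation matrix about a coordinate axis
#' @param theta Angle in degrees.
#' @param about \code{"x"}, \code{"y"} or \code{"z"}.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(theta, about = c("x", "y", "z")) {
  about <- match.arg(about)
  th <- theta * pi / 180
  c2 <- cos(th); s2 <- sin(th)
  switch(about,
         x = matrix(c(1, 0, 0, 0, c2, s2, 0, -s2, c2), 3, 3),
         y = matrix(c(c2, 0, -s2, 0, 1, 0, s2, 0, c2), 3, 3),
         z = matrix(c(c2, s2, 0, -s2, c2, 0, 0, 0, 1), 3, 3))
}

#' Read a plain XYZ-per-frame trajectory with a grouping sidecar
#'
#' The trajectory file holds one line per atom per frame
#' (\code{frame x y z}, whitespace-separated, frames numbered from 1); the
#' sidecar TSV maps atom order within a frame to \code{residue} and
#' \code{element} columns. Hydrogens (element H) are dropped. Coordinates
#' may be given in nm (\code{unit = "nm"}) and are converted to Angstrom.
#'
#' @param coord_file Whitespace-separated trajectory file.
#' @param groups_file Sidecar TSV with columns \code{residue},
#'   \code{element}.
#' @param box Optional orthorhombic box (length 3, same unit as input).
#' @param unit \code{"angstrom"} (default) or \code{"nm"}.
#' @return A \code{helix_trajectory}.
#' @export
read_xyz_frames <- function(coord_file, groups_file, box = NULL,
                            unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  fac <- if (unit == "nm") 10 else 1
  xyz <- utils::read.table(coord_file,
                           col.names = c("frame", "x", "y", "z"))
  grp <- utils::read.table(groups_file, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "element") %in% names(grp)))
  n_atoms <- nrow(grp)
  if (nrow(xyz) %% n_atoms != 0L)
    stop("coordinate rows (", nrow(xyz), ") not a multiple of the ",
         n_atoms, "-atom grouping")
  heavy <- toupper(grp$element) != "H"
  frames <- lapply(split(xyz, factor(xyz$frame,
                                     levels = sort(unique(xyz$frame)))),
                   function(fr) {
    if (nrow(fr) != n_atoms)
      stop("frame ", fr$frame[1L], " has ", nrow(fr), " atoms; expected ",
           n_atoms)
    m <- as.matrix(fr[, c("x", "y", "z")]) * fac
    lapply(split(as.data.frame(m[heavy, , drop = FALSE]),
                 grp$residue[heavy]), as.matrix)
  })
  helix_trajectory(unname(frames), box = if (is.null(box)) NULL else box * fac)
}

#' Read a multi-model PDB file as a helix trajectory
#'
#' Each MODEL becomes a frame; atoms are grouped by residue number and
#' hydrogens are dropped. Requires the bio3d package.
#'
#' @param file PDB path.
#' @param chain Optional chain filter.
#' @param box Optional orthorhombic box in Angstrom.
#' @return A \code{helix_trajectory}.
#' @export
read_pdb_trajectory <- function(file, chain = NULL, box = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB trajectories requires the bio3d package")
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  at <- pdb$atom
  keep <- !grepl("^H", trimws(at$elesy))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  resid <- paste0(at$resid[keep], at$resno[keep])
  n_frames <- dim(pdb$xyz)[1L]
  frames <- lapply(seq_len(n_frames), function(fi) {
    co <- matrix(pdb$xyz[fi, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    lapply(split(as.data.frame(co), resid), as.matrix)
  })
  helix_trajectory(frames, box = box)
}
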