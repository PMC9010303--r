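# Ensemble alignment and inter-nucleosome step parameters.
#
# Step-parameter convention. The relative geometry of two nucleosome frames
# is decomposed about their mid-frame: the rotation midpoint (quaternion
# interpolation at t = 1/2) of the two axis sets, with the origin midpoint.
# Rise is the origin displacement along the mid-frame z; shift_x/shift_y are
# the in-plane components; tilt is the total angle between the two z axes
# (degrees, in [0, 180]); twist is the signed angle (right-hand rule about
# mid-frame z, degrees in (-180, 180]) between the projections of the two
# dyad (y) axes. This mirrors the mid-frame convention of DNA base-step
# parameters; outputs should be labelled with this definition.

#' Rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` over proper
#' rotations only (reflections are excluded), via singular value
#' decomposition.
#'
#' @param reference n-by-3 matrix of reference points (n >= 3,
#'   non-collinear).
#' @param mobile n-by-3 matrix of points to superpose, paired row-wise with
#'   `reference`.
#' @return A `RigidTransform`: list with `rotation` (3x3, det = +1),
#'   `translation` (length 3) and `rmsd` (Angstrom) after superposition. The
#'   transform maps mobile points as `p %*% t(rotation) + translation`.
#' @export
superpose <- function(reference, mobile) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (nrow(reference) != nrow(mobile))
    stop("pairing error: point sets differ in size (",
         nrow(reference), " vs ", nrow(mobile), ")", call. = FALSE)
  if (nrow(reference) < 3)
    stop("need at least 3 points to superpose", call. = FALSE)
  cr <- colMeans(reference); cm <- colMeans(mobile)
  A <- sweep(reference, 2, cr); B <- sweep(mobile, 2, cm)
  sv <- svd(crossprod(B, A))           # 3x3: sum over points of b a^T
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("geometry error: degenerate (collinear) point set", call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cr - as.numeric(R %*% cm)
  moved <- mobile %*% t(R) + matrix(tr, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n-by-3 coordinate matrix.
#' @param transform a `RigidTransform`.
#' @return Transformed n-by-3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  stopifnot(inherits(transform, "RigidTransform"))
  xyz %*% t(transform$rotation) +
    matrix(transform$translation, nrow(xyz), 3, byrow = TRUE)
}

.ref_c1_rows <- function(complex, nucleosome_id) {
  nuc <- .get_nucleosome(complex, nucleosome_id)
  atom <- complex$structure$atom
  rows <- which(atom$chain_id %in% nuc$dna_chains & atom$atom_name == "C1'")
  if (length(rows) == 0)
    stop("gap error: no C1' atoms for nucleosome ", nucleosome_id,
         call. = FALSE)
  rows
}

#' Align a trajectory ensemble on one nucleosome
#'
#' Rigidly transforms every frame so that the C1' atoms of the reference
#' nucleosome superpose, at minimum RMSD, onto those of the reference frame.
#' Atom identity is preserved; only coordinates change.
#'
#' @param ensemble an annotated `TrajectoryEnsemble`.
#' @param reference_nucleosome_id nucleosome whose C1' atoms define the
#'   alignment.
#' @param reference_frame_index frame used as the alignment reference
#'   (default 1).
#' @return The ensemble with aligned frames and `aligned = TRUE`; per-frame
#'   alignment RMSDs are attached as attribute `"alignment_rmsd"`.
#' @export
align_ensemble <- function(ensemble, reference_nucleosome_id,
                           reference_frame_index = 1) {
  stopifnot(inherits(ensemble, "TrajectoryEnsemble"))
  if (is.null(ensemble$topology))
    stop("ensemble has no annotated topology", call. = FALSE)
  rows <- .ref_c1_rows(ensemble$topology, reference_nucleosome_id)
  if (reference_frame_index < 1 || reference_frame_index > ensemble$frame_count)
    stop("reference frame index out of range", call. = FALSE)
  ref_pts <- ensemble$frames[[reference_frame_index]][rows, , drop = FALSE]
  if (any(!is.finite(ref_pts)))
    stop("gap error: non-finite C1' coordinates in frame ",
         reference_frame_index, call. = FALSE)
  rmsds <- numeric(ensemble$frame_count)
  for (f in seq_len(ensemble$frame_count)) {
    pts <- ensemble$frames[[f]][rows, , drop = FALSE]
    if (any(!is.finite(pts)))
      stop("gap error: non-finite C1' coordinates in frame ", f,
           call. = FALSE)
    tr <- superpose(ref_pts, pts)
    ensemble$frames[[f]] <- apply_transform(ensemble$frames[[f]], tr)
    rmsds[f] <- tr$rmsd
  }
  ensemble$structure$frames <- ensemble$frames
  ensemble$aligned <- TRUE
  attr(ensemble, "alignment_rmsd") <- rmsds
  attr(ensemble, "alignment_reference") <-
    list(nucleosome_id = reference_nucleosome_id,
         frame_index = reference_frame_index)
  ensemble
}

#' Dyad / anti-dyad sampling cloud of the mobile nucleosome
#'
#' Records, for every frame of an aligned ensemble, the dyad and anti-dyad
#' points of the mobile nucleosome, and summarizes each cloud by its RMS
#' dispersion (root-mean-square distance of the points to their centroid)
#' and principal axes.
#'
#' @param aligned an aligned `TrajectoryEnsemble` (see [align_ensemble()]).
#' @param mobile_nucleosome_id nucleosome whose points are collected.
#' @param anti_dyad_indices passed to [dyad_points()].
#' @return A `PointCloudSummary`: list with `points` (data.frame of per-frame
#'   coordinates for both point types), `dispersion` (named RMS dispersions,
#'   Angstrom) and `principal` (per point type: eigenvectors and RMS extents
#'   along them).
#' @export
sampling_cloud <- function(aligned, mobile_nucleosome_id,
                           anti_dyad_indices = c(-37, -36, 36, 37)) {
  stopifnot(inherits(aligned, "TrajectoryEnsemble"))
  if (!isTRUE(aligned$aligned))
    stop("state error: ensemble must be aligned before cloud analysis",
         call. = FALSE)
  topo <- aligned$topology
  n <- aligned$frame_count
  dyad <- matrix(NA_real_, n, 3)
  anti <- matrix(NA_real_, n, 3)
  for (f in seq_len(n)) {
    series <- pair_base_steps(topo, mobile_nucleosome_id,
                              xyz = aligned$frames[[f]])
    pts <- dyad_points(series, anti_dyad_indices = anti_dyad_indices)
    dyad[f, ] <- pts$dyad_point
    anti[f, ] <- pts$anti_dyad_point
  }
  summarize <- function(P) {
    ctr <- colMeans(P)
    Pc <- sweep(P, 2, ctr)
    disp <- sqrt(mean(rowSums(Pc^2)))
    ev <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)
    list(centroid = ctr, rms_dispersion = disp,
         axes = ev$vectors, rms_extent = sqrt(pmax(ev$values, 0)))
  }
  sd_ <- summarize(dyad); sa <- summarize(anti)
  pts <- data.frame(
    frame = rep(seq_len(n), 2),
    point = rep(c("dyad", "anti_dyad"), each = n),
    x = c(dyad[, 1], anti[, 1]),
    y = c(dyad[, 2], anti[, 2]),
    z = c(dyad[, 3], anti[, 3]))
  structure(list(points = pts,
                 dispersion = c(dyad = sd_$rms_dispersion,
                                anti_dyad = sa$rms_dispersion),
                 principal = list(dyad = sd_, anti_dyad = sa)),
            class = "PointCloudSummary")
}

#' @export
print.PointCloudSummary <- function(x, ...) {
  cat(sprintf("PointCloudSummary: %d frames; RMS dispersion dyad %.2f A, anti-dyad %.2f A\n",
              nrow(x$points) / 2, x$dispersion["dyad"],
              x$dispersion["anti_dyad"]))
  invisible(x)
}

#' Inter-nucleosome step parameters
#'
#' Decomposes the relative rigid-body geometry of two nucleosome frames about
#' their quaternion-midpoint mid-frame (see the file-level convention note).
#'
#' @param frame1,frame2 `NucleosomeFrame` objects.
#' @return A `StackStep`: one-row data.frame with `rise`, `shift_x`,
#'   `shift_y` (Angstrom), `tilt` (degrees, \[0, 180\]), `twist` (degrees,
#'   (-180, 180\]) and `center_distance` (Angstrom), satisfying
#'   center_distance^2 = rise^2 + shift_x^2 + shift_y^2.
#' @export
step_parameters <- function(frame1, frame2) {
  .validate_frame(frame1); .validate_frame(frame2)
  R1 <- .frame_rotation(frame1); R2 <- .frame_rotation(frame2)
  H <- .rot_sqrt(t(R1) %*% R2)
  M <- R1 %*% H
  zm <- M[, 3]
  d <- frame2$origin - frame1$origin
  rise <- sum(d * zm)
  shift_x <- sum(d * M[, 1])
  shift_y <- sum(d * M[, 2])
  tilt <- acos(.clamp1(sum(frame1$z * frame2$z))) * 180 / pi
  twist <- .twist_of_pair(R1, R2) * 180 / pi
  out <- data.frame(rise = rise, shift_x = shift_x, shift_y = shift_y,
                    tilt = tilt, twist = twist,
                    center_distance = sqrt(sum(d^2)))
  class(out) <- c("StackStep", "data.frame")
  out
}

#' Construct the partner frame of a step
#'
#' Exact inverse of [step_parameters()]: given `frame1` and a target
#' `StackStep`, returns `frame2` such that
#' `step_parameters(frame1, frame2)` reproduces the step (to numerical
#' precision). The bend direction, which the step parameters do not
#' constrain, is set by `azimuth` (degrees about the mid-frame z; 0 bends
#' about mid-frame x).
#'
#' @param frame1 a `NucleosomeFrame`.
#' @param step a `StackStep` or list with `rise`, `shift_x`, `shift_y`,
#'   `tilt`, `twist`.
#' @param azimuth bend azimuth in degrees.
#' @return `frame2`, a `NucleosomeFrame`.
#' @export
frame_from_step <- function(frame1, step, azimuth = 0) {
  .validate_frame(frame1)
  R1 <- .frame_rotation(frame1)
  S <- .half_step(step$tilt * pi / 180, step$twist * pi / 180,
                  azimuth * pi / 180)
  # frame1 = M S^-1 in mid-frame coordinates, so M = R1 S and R2 = M S
  M <- R1 %*% S
  R2 <- M %*% S
  O2 <- frame1$origin +
    as.numeric(M %*% c(step$shift_x, step$shift_y, step$rise))
  .frame_from_rotation(R2, O2)
}

#' Per-frame step parameters over an ensemble
#'
#' @param ensemble an annotated `TrajectoryEnsemble` (alignment is not
#'   required: step parameters are invariant under global rigid motion).
#' @param id1,id2 nucleosome ids; the step is measured from `id1` to `id2`.
#' @return List with `series` (data.frame, one `StackStep` row per frame) and
#'   `summary` (data.frame with mean, sd, min, max per parameter).
#' @export
ensemble_step_stats <- function(ensemble, id1, id2) {
  stopifnot(inherits(ensemble, "TrajectoryEnsemble"))
  if (is.null(ensemble$topology))
    stop("ensemble has no annotated topology", call. = FALSE)
  topo <- ensemble$topology
  rows <- vector("list", ensemble$frame_count)
  for (f in seq_len(ensemble$frame_count)) {
    xyz <- ensemble$frames[[f]]
    step <- tryCatch(
      step_parameters(nucleosome_frame(topo, id1, xyz = xyz),
                      nucleosome_frame(topo, id2, xyz = xyz)),
      error = function(e)
        stop("frame ", f, ": ", conditionMessage(e), call. = FALSE))
    rows[[f]] <- cbind(frame = f, step)
  }
  series <- do.call(rbind, rows)
  class(series) <- "data.frame"
  pars <- c("rise", "shift_x", "shift_y", "tilt", "twist",
            "center_distance")
  summary <- data.frame(
    parameter = pars,
    mean = vapply(pars, function(p) mean(series[[p]]), 0),
    sd = vapply(pars, function(p) stats::sd(series[[p]]), 0),
    min = vapply(pars, function(p) min(series[[p]]), 0),
    max = vapply(pars, function(p) max(series[[p]]), 0),
    row.names = NULL)
  list(series = series, summary = summary)
}
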