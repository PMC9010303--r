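# Per-nucleosome geometry: base-pair series from C1' atoms, the orthonormal
# nucleosome reference frame, superhelical-location (SHL) coordinates, and the
# dyad / anti-dyad sampling points.
#
# Conventions. The base-pair index is 0 at the dyad and negative toward one
# terminus; a canonical 147-bp nucleosome spans -73..+73. One superhelical
# location is one duplex turn, taken as 10.4 bp, so SHL = bp_index / 10.4
# (continuous, dyad = 0). The frame's z axis is the superhelical axis, signed
# so that the base-pair path from -73 to +73 advances clockwise when viewed
# from +z (left-handed wrap); y points from the frame origin toward the dyad;
# x = y cross z, giving a right-handed frame.

BP_PER_SHL <- 10.4

#' Pair DNA strands into a base-pair series
#'
#' Pairs the C1' atoms of the two DNA strands of a nucleosome by 5'-to-3'
#' order: residue j of strand 1 (0-based, in residue-number order) pairs with
#' residue N-1-j of strand 2. The dyad (index 0) is the central pair for odd
#' N; for even N it is the pair containing the 5' member of the central
#' dinucleotide on strand 1.
#'
#' @param complex an `AnnotatedComplex`.
#' @param nucleosome_id id of the nucleosome to pair.
#' @param xyz optional n-by-3 coordinate matrix overriding the complex's
#'   model-1 coordinates (used when iterating over trajectory frames).
#' @return A `BasePairSeries`: data.frame with per-pair index, C1' positions
#'   of both strands, base-pair centers (midpoints of the two C1'), SHL, and
#'   a `stably_bound` flag (FALSE for the `flexible_bp_per_end` terminal base
#'   pairs recorded in the annotation).
#' @export
pair_base_steps <- function(complex, nucleosome_id, xyz = NULL) {
  nuc <- .get_nucleosome(complex, nucleosome_id)
  atom <- complex$structure$atom
  if (is.null(xyz)) xyz <- model_coords(complex$structure)
  rows <- lapply(nuc$dna_chains, function(ch) {
    i <- which(atom$chain_id == ch & atom$atom_name == "C1'")
    i[order(atom$residue_index[i])]
  })
  n1 <- length(rows[[1]]); n2 <- length(rows[[2]])
  if (n1 == 0 || n2 == 0)
    stop("missing C1' atoms on DNA chain(s) of nucleosome ", nuc$id,
         call. = FALSE)
  if (n1 != n2)
    stop(sprintf("pairing error: strands of nucleosome %s have %d and %d C1' atoms",
                 nuc$id, n1, n2), call. = FALSE)
  # contiguity check: a residue gap means a missing C1'
  for (k in 1:2) {
    res <- atom$residue_index[rows[[k]]]
    gaps <- which(diff(res) != 1L)
    if (length(gaps) > 0)
      stop("gap error: chain ", nuc$dna_chains[k],
           " is missing C1' atoms after residue ",
           paste(res[gaps], collapse = ", "), call. = FALSE)
  }
  N <- n1
  j <- seq_len(N)                       # strand1, 5'->3'
  i2 <- rows[[2]][N + 1L - j]           # strand2 partner N-1-j (0-based)
  i1 <- rows[[1]][j]
  dyad_pos <- if (N %% 2 == 1) (N + 1L) %/% 2L else N %/% 2L
  idx <- j - dyad_pos
  p1 <- xyz[i1, , drop = FALSE]
  p2 <- xyz[i2, , drop = FALSE]
  ctr <- (p1 + p2) / 2
  flex <- nuc$flexible_bp_per_end
  stably <- rep(TRUE, N)
  if (flex > 0) {
    if (2 * flex >= N)
      stop("flexible_bp_per_end too large for ", N, " bp", call. = FALSE)
    stably[c(seq_len(flex), N - seq_len(flex) + 1L)] <- FALSE
  }
  out <- data.frame(
    index = idx,
    x1 = p1[, 1], y1 = p1[, 2], z1 = p1[, 3],
    x2 = p2[, 1], y2 = p2[, 2], z2 = p2[, 3],
    cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
    shl = idx / BP_PER_SHL,
    stably_bound = stably,
    chain1 = atom$chain_id[i1], resno1 = atom$residue_index[i1],
    chain2 = atom$chain_id[i2], resno2 = atom$residue_index[i2],
    stringsAsFactors = FALSE)
  class(out) <- c("BasePairSeries", "data.frame")
  attr(out, "nucleosome_id") <- nuc$id
  out
}

.bp_centers <- function(series) {
  as.matrix(series[, c("cx", "cy", "cz")])
}

#' Nucleosome reference frame from a base-pair series
#'
#' The origin is the centroid of the stably bound base-pair centers; z is the
#' unit normal of their best-fit plane (smallest principal direction), signed
#' so the base-pair path advances clockwise viewed from +z (left-handed
#' wrap); y is the in-plane unit vector toward the dyad base pair; x = y
#' cross z. Flexible (unwrapped) base pairs are excluded from the fit.
#'
#' @param series a `BasePairSeries`.
#' @param min_bp minimum number of bound base pairs required.
#' @return A `NucleosomeFrame`: list with `origin` and unit axes `x`, `y`,
#'   `z` satisfying det\[x y z\] = +1.
#' @export
compute_frame <- function(series, min_bp = 20) {
  stopifnot(inherits(series, "BasePairSeries"))
  bound <- series[series$stably_bound, , drop = FALSE]
  if (nrow(bound) < min_bp)
    stop("need at least ", min_bp, " stably bound base pairs", call. = FALSE)
  if (min(bound$index) >= 0 || max(bound$index) <= 0)
    stop("bound base pairs must span the dyad", call. = FALSE)
  P <- unname(.bp_centers(bound))
  O <- colMeans(P)
  Pc <- sweep(P, 2, O)
  ev <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)
  if (ev$values[2] < 1e-9 * max(ev$values[1], 1))
    stop("geometry error: base-pair centers are (near-)collinear",
         call. = FALSE)
  z <- ev$vectors[, 3]
  # handedness: sum of consecutive cross products points against +z for a
  # clockwise (left-handed) wrap
  S <- c(0, 0, 0)
  for (k in seq_len(nrow(Pc) - 1))
    S <- S + .cross3(Pc[k, ], Pc[k + 1, ])
  if (sum(S * z) > 0) z <- -z
  d0 <- series[series$index == 0, , drop = FALSE]
  if (nrow(d0) == 0)
    stop("series lacks the dyad base pair (index 0)", call. = FALSE)
  v <- unname(as.numeric(d0[1, c("cx", "cy", "cz")])) - O
  v <- v - sum(v * z) * z
  y <- .unit(v)
  x <- .cross3(y, z)
  structure(list(origin = O, x = x, y = y, z = z),
            class = "NucleosomeFrame")
}

#' @export
print.NucleosomeFrame <- function(x, ...) {
  cat(sprintf("NucleosomeFrame: O = (%.2f, %.2f, %.2f)\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

.frame_rotation <- function(frame) cbind(frame$x, frame$y, frame$z)

.frame_from_rotation <- function(R, origin) {
  structure(list(origin = as.numeric(origin),
                 x = R[, 1], y = R[, 2], z = R[, 3]),
            class = "NucleosomeFrame")
}

.validate_frame <- function(frame) {
  if (!inherits(frame, "NucleosomeFrame"))
    stop("not a NucleosomeFrame", call. = FALSE)
  R <- .frame_rotation(frame)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("validation error: frame axes are not a proper orthonormal set",
         call. = FALSE)
  invisible(frame)
}

#' Reference frame of a nucleosome in a complex
#'
#' Convenience wrapper: [pair_base_steps()] followed by [compute_frame()].
#'
#' @inheritParams pair_base_steps
#' @param ... passed to [compute_frame()].
#' @return A `NucleosomeFrame`.
#' @export
nucleosome_frame <- function(complex,
                             nucleosome_id = names(complex$nucleosomes)[1],
                             xyz = NULL, ...) {
  compute_frame(pair_base_steps(complex, nucleosome_id, xyz = xyz), ...)
}

#' Superhelical location of a base-pair index
#'
#' SHL = bp_index / 10.4, continuous, dyad = 0, antisymmetric.
#'
#' @param bp_index integer base-pair index (|index| <= 73).
#' @return Numeric SHL value(s).
#' @export
shl_of <- function(bp_index) {
  if (any(abs(bp_index) > 73))
    stop("bp index out of range: |index| must be <= 73", call. = FALSE)
  bp_index / BP_PER_SHL
}

#' Half-open SHL bin label
#'
#' Bins a continuous |SHL| value into \[k, k+1).
#'
#' @param shl numeric SHL value(s); the absolute value is binned.
#' @return Integer lower bin edge(s) k such that |shl| is in \[k, k+1).
#' @export
shl_bin <- function(shl) as.integer(floor(abs(shl)))

#' Dyad and anti-dyad sampling points
#'
#' The dyad point is the geometric center of the C1' atoms of base pairs
#' -1..+1 (three pairs, six atoms, damping single-residue noise). The
#' anti-dyad point is the geometric center of the C1' atoms of the base pairs
#' at `anti_dyad_indices` - by default the disc position diametrically
#' opposite the dyad (indices -37, -36, +36, +37, about SHL 3.5). The index
#' set is exposed so that other readings (e.g. the DNA termini, SHL 7) can be
#' reproduced.
#'
#' @param series a `BasePairSeries`.
#' @param dyad_indices base-pair indices averaged for the dyad point.
#' @param anti_dyad_indices base-pair indices averaged for the anti-dyad
#'   point.
#' @return List with numeric `dyad_point` and `anti_dyad_point` (Angstrom).
#' @export
dyad_points <- function(series, dyad_indices = -1:1,
                        anti_dyad_indices = c(-37, -36, 36, 37)) {
  stopifnot(inherits(series, "BasePairSeries"))
  get_center <- function(idx, what) {
    rows <- series[series$index %in% idx, , drop = FALSE]
    if (nrow(rows) != length(idx))
      stop("gap error: ", what, " requires base pairs ",
           paste(idx, collapse = ", "), "; missing ",
           paste(setdiff(idx, rows$index), collapse = ", "), call. = FALSE)
    pts <- rbind(unname(as.matrix(rows[, c("x1", "y1", "z1")])),
                 unname(as.matrix(rows[, c("x2", "y2", "z2")])))
    unname(colMeans(pts))
  }
  list(dyad_point = get_center(dyad_indices, "dyad point"),
       anti_dyad_point = get_center(anti_dyad_indices, "anti-dyad point"))
}

#' Export a per-base-pair table
#'
#' @param series a `BasePairSeries`.
#' @param path output CSV path.
#' @export
write_bp_table <- function(series, path) {
  stopifnot(inherits(series, "BasePairSeries"))
  write_records(series[, c("index", "shl", "cx", "cy", "cz",
                           "stably_bound")], path, format = "csv")
}
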