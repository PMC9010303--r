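# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed per call site.

# Random proper rotation (Haar-ish via QR, reflection corrected).
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Random ground-truth step in a realistic stacked-nucleosome range.
random_step <- function() {
  stack_spec(rise = runif(1, 40, 80),
             shift_x = runif(1, -10, 10),
             shift_y = runif(1, -10, 10),
             tilt = runif(1, 0, 40),
             twist = runif(1, -150, 150),
             n_factors = 0)
}

# Apply a global rigid motion to an annotated complex.
rigid_move_complex <- function(complex, R, tv) {
  xyz <- model_coords(complex$structure)
  set_coords(complex, xyz %*% t(R) + matrix(tv, nrow(xyz), 3, byrow = TRUE))
}

rigid_move_frame <- function(frame, R, tv) {
  nucstack:::.frame_from_rotation(
    R %*% nucstack:::.frame_rotation(frame),
    as.numeric(R %*% frame$origin) + tv)
}

# Random annotated complex for contact testing: one "nucleosome" of two DNA
# chains plus a histone chain, one factor chain, atoms scattered in a box so
# that some pairs fall under typical cutoffs.
random_contact_complex <- function(n_nuc_atoms, n_factor_atoms,
                                   box = 30) {
  per <- ceiling(n_nuc_atoms / 3)
  n_nuc_atoms <- 3 * per
  atom <- data.frame(
    atom_name = c(rep("P", 2 * per), rep("CA", per),
                  rep("CB", n_factor_atoms)),
    element = c(rep("P", 2 * per), rep("C", per),
                rep("C", n_factor_atoms)),
    residue_name = c(rep("DA", 2 * per), rep("GLY", per),
                     rep("LYS", n_factor_atoms)),
    residue_index = c(seq_len(per), seq_len(per), seq_len(per),
                      seq_len(n_factor_atoms)),
    chain_id = c(rep("I", per), rep("J", per), rep("A", per),
                 rep("X", n_factor_atoms)),
    stringsAsFactors = FALSE)
  xyz <- matrix(runif((n_nuc_atoms + n_factor_atoms) * 3, 0, box),
                ncol = 3)
  model <- structure_model(atom, list(xyz))
  assign_roles(model, list(
    nucleosomes = list(nuc1 = list(dna = list("I", "J"),
                                   histones = list(A = "H3"))),
    factors = list(f1 = list(chain = "X", label = "CENP-N"))))
}

# Ideal circular base-pair series (one full turn, uniformly spaced) in the
# global xy-plane: dyad at +y, path clockwise viewed from +z, so
# compute_frame must return the global axes and the circle center.
circle_series <- function(n = 147, radius = 41.9) {
  half <- (n - 1) / 2
  idx <- (-half):half
  delta <- 2 * pi / n
  theta <- pi / 2 - idx * delta
  ctr <- cbind(radius * cos(theta), radius * sin(theta), 0)
  out <- data.frame(
    index = idx,
    x1 = ctr[, 1], y1 = ctr[, 2], z1 = ctr[, 3] + 1,
    x2 = ctr[, 1], y2 = ctr[, 2], z2 = ctr[, 3] - 1,
    cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
    shl = idx / 10.4, stably_bound = TRUE,
    chain1 = "I", resno1 = seq_len(n),
    chain2 = "J", resno2 = rev(seq_len(n)),
    stringsAsFactors = FALSE)
  class(out) <- c("BasePairSeries", "data.frame")
  attr(out, "nucleosome_id") <- "nuc1"
  out
}
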