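# Synthetic pseudo-atomic structure generator.
#
# Nucleosomes are idealized: the C1' atoms of both DNA strands are traced
# along a left-handed superhelix (radius 41.9 A, pitch 25.9 A, 1.65 turns
# over 147 bp - canonical literature values, overridable), and histones are
# placeholder pseudo-atom chains placed inside the DNA gyres with correct
# role labels. Bridging factors are placeholder chains whose residues are
# numbered and named after the basic face of the CENP-N alpha6 helix
# (K102, K105, K109, K110, R114, K117), anchored 3 A from their target atoms
# so that interface reports on synthetic data read like those on real
# structures. Every generator records its ground-truth parameters in the
# "ground_truth" attribute of the returned complex, and every analysis
# operation recovers them on noiseless output (generator/analyzer closure).

ALPHA6_RESIDUES <- c(102L, 105L, 109L, 110L, 114L, 117L)
ALPHA6_RESNAMES <- c("LYS", "LYS", "LYS", "LYS", "ARG", "LYS")

#' Specify an idealized nucleosome
#'
#' @param n_bp number of base pairs (default 147).
#' @param radius superhelix radius in Angstrom.
#' @param pitch superhelix pitch (rise per superhelical turn) in Angstrom.
#' @param c1_separation across-pair C1'-C1' distance in Angstrom.
#' @param wrap_turns total superhelical turns traced by the DNA.
#' @param flexible_bp_per_end terminal base pairs per end that are not
#'   stably bound (displaced off the superhelix and flagged
#'   `stably_bound = FALSE`).
#' @param histone_atoms placeholder atoms per histone chain.
#' @param variant histone variant of the H3-position chain: `"H3"` or
#'   `"CENP-A"`.
#' @return A `NucleosomeSpec` list.
#' @export
nucleosome_spec <- function(n_bp = 147, radius = 41.9, pitch = 25.9,
                            c1_separation = 10.5, wrap_turns = 1.65,
                            flexible_bp_per_end = 0, histone_atoms = 8,
                            variant = c("H3", "CENP-A")) {
  variant <- match.arg(variant)
  if (radius <= 0 || pitch <= 0)
    stop("spec error: superhelix radius and pitch must be positive",
         call. = FALSE)
  if (2 * flexible_bp_per_end >= n_bp)
    stop("spec error: flexible_bp_per_end too large for n_bp",
         call. = FALSE)
  structure(list(n_bp = as.integer(n_bp), radius = radius, pitch = pitch,
                 c1_separation = c1_separation, wrap_turns = wrap_turns,
                 flexible_bp_per_end = as.integer(flexible_bp_per_end),
                 histone_atoms = as.integer(histone_atoms),
                 variant = variant),
            class = "NucleosomeSpec")
}

#' CENP-A nucleosome preset
#'
#' A CENP-A nucleosome stably binds only 121 of its 147 bp: 13 terminal
#' base pairs per end are flexible.
#'
#' @param ... overrides passed to [nucleosome_spec()].
#' @return A `NucleosomeSpec`.
#' @export
cenpa_nucleosome_spec <- function(...) {
  args <- list(...)
  defaults <- list(flexible_bp_per_end = 13, variant = "CENP-A")
  do.call(nucleosome_spec, utils::modifyList(defaults, args))
}

# Atom table + coordinates of one canonical nucleosome in its own
# coordinates (dyad toward +y, superhelical axis ~ +z, left-handed wrap).
.nucleosome_atoms <- function(spec, dna_chains = c("I", "J"),
                              histone_chains = c("A", "B")) {
  N <- spec$n_bp
  dyad_pos <- if (N %% 2 == 1) (N + 1L) %/% 2L else N %/% 2L
  idx <- seq_len(N) - dyad_pos
  delta <- 2 * pi * spec$wrap_turns / (N - 1)
  theta <- pi / 2 - idx * delta          # clockwise from +z as index grows
  ctr <- cbind(spec$radius * cos(theta),
               spec$radius * sin(theta),
               spec$pitch * idx * delta / (2 * pi))
  flex <- spec$flexible_bp_per_end
  if (flex > 0) {
    # unwrapped terminal bp leave the superhelix along the local tangent
    lo <- flex + 1L; hi <- N - flex
    step_lo <- ctr[lo, ] - ctr[lo + 1L, ]
    step_hi <- ctr[hi, ] - ctr[hi - 1L, ]
    for (k in seq_len(flex)) {
      ctr[lo - k, ] <- ctr[lo, ] + k * step_lo
      ctr[hi + k, ] <- ctr[hi, ] + k * step_hi
    }
  }
  half <- spec$c1_separation / 2
  off <- matrix(rep(c(0, 0, half), N), ncol = 3, byrow = TRUE)
  s1 <- ctr + off                        # strand 1, residue j at bp j
  s2 <- ctr - off                        # strand 2, antiparallel numbering
  s2 <- s2[rev(seq_len(N)), , drop = FALSE]
  nh <- spec$histone_atoms
  ang <- 2 * pi * (seq_len(nh) - 1) / nh
  hist1 <- cbind(18 * cos(ang), 18 * sin(ang), rep(4, nh))
  hist2 <- cbind(18 * cos(ang + pi / nh), 18 * sin(ang + pi / nh),
                 rep(-4, nh))
  atom <- data.frame(
    atom_name = c(rep("C1'", 2 * N), rep("CA", 2 * nh)),
    element = c(rep("C", 2 * N), rep("C", 2 * nh)),
    residue_name = c(rep("DA", 2 * N), rep("GLY", 2 * nh)),
    residue_index = c(seq_len(N), seq_len(N), seq_len(nh), seq_len(nh)),
    chain_id = c(rep(dna_chains[1], N), rep(dna_chains[2], N),
                 rep(histone_chains[1], nh), rep(histone_chains[2], nh)),
    stringsAsFactors = FALSE)
  xyz <- rbind(s1, s2, hist1, hist2)
  list(atom = atom, xyz = xyz, dyad_pos = dyad_pos)
}

.nucleosome_role_entry <- function(spec, dna_chains, histone_chains,
                                   flexible = FALSE) {
  hist <- stats::setNames(list(spec$variant, "H4"),
                          histone_chains)
  list(dna = as.list(dna_chains), histones = hist,
       flexible = flexible,
       flexible_bp_per_end = spec$flexible_bp_per_end)
}

#' Build an idealized nucleosome
#'
#' @param spec a [nucleosome_spec()].
#' @return An `AnnotatedComplex` with one nucleosome (`nuc1`): DNA chains
#'   I/J, histone placeholder chains A (variant) and B (H4).
#' @export
build_nucleosome <- function(spec = nucleosome_spec()) {
  parts <- .nucleosome_atoms(spec)
  model <- structure_model(parts$atom, list(parts$xyz))
  role_map <- list(nucleosomes = list(
    nuc1 = .nucleosome_role_entry(spec, c("I", "J"), c("A", "B"))))
  cx <- assign_roles(model, role_map)
  attr(cx, "ground_truth") <- list(spec = spec)
  cx
}

#' Specify a bridged two-nucleosome stack
#'
#' @param rise,shift_x,shift_y,tilt,twist ground-truth step parameters of
#'   nucleosome 2's frame relative to nucleosome 1's (Angstrom / degrees).
#' @param n_factors number of bridging factor copies (0, 1 or 2).
#' @param anchor_bp base-pair index (dyad = 0) on the neighbor nucleosome
#'   where the factor's alpha6 face docks; 47 puts the contacts at SHL
#'   4.3-4.8.
#' @param azimuth bend azimuth of the step construction (degrees).
#' @return A `StackSpec` list; the ground-truth `StackStep` is in `$step`.
#' @export
stack_spec <- function(rise = 60, shift_x = 2, shift_y = -3, tilt = 4,
                       twist = 20, n_factors = 2, anchor_bp = 47,
                       azimuth = 0) {
  if (!n_factors %in% 0:2)
    stop("spec error: n_factors must be 0, 1 or 2", call. = FALSE)
  step <- data.frame(rise = rise, shift_x = shift_x, shift_y = shift_y,
                     tilt = tilt, twist = twist,
                     center_distance = sqrt(rise^2 + shift_x^2 + shift_y^2))
  class(step) <- c("StackStep", "data.frame")
  structure(list(step = step, n_factors = as.integer(n_factors),
                 anchor_bp = as.integer(anchor_bp), azimuth = azimuth),
            class = "StackSpec")
}

# Rigid transform mapping frame `from` onto frame `to`.
.transform_between_frames <- function(from, to) {
  R <- .frame_rotation(to) %*% t(.frame_rotation(from))
  structure(list(rotation = R,
                 translation = to$origin - as.numeric(R %*% from$origin),
                 rmsd = 0),
            class = "RigidTransform")
}

# Placeholder factor chain bridging a specific nucleosome (histone + DNA
# contacts) and a neighbor nucleosome (DNA-only contacts at anchor_bp).
# Returns atom table + coordinates. Atoms sit 3 A outside their target
# atoms, radially from the owning nucleosome's frame origin.
.factor_atoms <- function(chain_id, atom, xyz,
                          specific, neighbor, anchor_bp,
                          spec_frame, neigh_frame, dyad_pos) {
  outward <- function(p, origin) p + 3 * .unit(p - origin)
  pos <- list(); resno <- integer(0); resname <- character(0)
  # body: one atom at a histone placeholder, one at specific-side DNA
  hrow <- which(atom$chain_id == specific$histone[1])[1]
  pos[[1]] <- outward(xyz[hrow, ], spec_frame$origin)
  drow <- which(atom$chain_id == specific$dna[1] &
                  atom$residue_index == dyad_pos - 3L &
                  atom$atom_name == "C1'")
  pos[[2]] <- outward(xyz[drow, ], spec_frame$origin)
  resno <- c(1L, 2L); resname <- c("ALA", "ALA")
  # alpha6 face: six atoms along the neighbor's DNA at the anchor
  target_bp <- anchor_bp + (-2):3
  for (i in seq_along(ALPHA6_RESIDUES)) {
    trow <- which(atom$chain_id == neighbor$dna[1] &
                    atom$residue_index == dyad_pos + target_bp[i] &
                    atom$atom_name == "C1'")
    if (length(trow) != 1)
      stop("spec error: factor anchor bp ", target_bp[i],
           " outside wrapped DNA", call. = FALSE)
    pos[[2 + i]] <- outward(xyz[trow, ], neigh_frame$origin)
    resno <- c(resno, ALPHA6_RESIDUES[i])
    resname <- c(resname, ALPHA6_RESNAMES[i])
  }
  n <- length(pos)
  list(atom = data.frame(atom_name = rep("CA", n),
                         element = rep("C", n),
                         residue_name = resname,
                         residue_index = resno,
                         chain_id = rep(chain_id, n),
                         stringsAsFactors = FALSE),
       xyz = do.call(rbind, pos))
}

#' Build a bridged two-nucleosome stack
#'
#' Nucleosome 2's frame is related to nucleosome 1's by exactly the
#' ground-truth `StackStep` of the spec ([step_parameters()] on the built
#' stack returns it to numerical precision). Factor placeholder chains are
#' placed with atoms within 4 A of histone and DNA atoms of their specific
#' nucleosome and of DNA-only atoms of the neighbor at the anchored SHL.
#'
#' @param spec a [stack_spec()].
#' @param nuc_spec a [nucleosome_spec()] shared by both nucleosomes.
#' @return An `AnnotatedComplex` with nucleosomes `nuc1` (chains I/J/A/B),
#'   `nuc2` (chains K/L/C/D) and factors `f1` (chain X, specific to nuc1)
#'   and, if requested, `f2` (chain Y, specific to nuc2).
#' @export
build_stack <- function(spec = stack_spec(),
                        nuc_spec = nucleosome_spec()) {
  if (abs(spec$anchor_bp) + 3L >
      (nuc_spec$n_bp - 1L) %/% 2L - nuc_spec$flexible_bp_per_end)
    stop("spec error: factor anchor outside wrapped DNA", call. = FALSE)
  p1 <- .nucleosome_atoms(nuc_spec, c("I", "J"), c("A", "B"))
  p2 <- .nucleosome_atoms(nuc_spec, c("K", "L"), c("C", "D"))
  # frame of the canonical nucleosome, then place nucleosome 2 by the step
  tmp <- build_nucleosome(nuc_spec)
  F1 <- nucleosome_frame(tmp)
  F2 <- frame_from_step(F1, spec$step, azimuth = spec$azimuth)
  tr <- .transform_between_frames(F1, F2)
  p2$xyz <- apply_transform(p2$xyz, tr)
  atom <- rbind(p1$atom, p2$atom)
  xyz <- rbind(p1$xyz, p2$xyz)
  nucs <- list(
    nuc1 = .nucleosome_role_entry(nuc_spec, c("I", "J"), c("A", "B")),
    nuc2 = .nucleosome_role_entry(nuc_spec, c("K", "L"), c("C", "D")))
  factors <- list()
  if (spec$n_factors >= 1) {
    f <- .factor_atoms("X", atom, xyz,
                       specific = list(histone = "A", dna = "I"),
                       neighbor = list(dna = "K"),
                       anchor_bp = spec$anchor_bp,
                       spec_frame = F1, neigh_frame = F2,
                       dyad_pos = p1$dyad_pos)
    atom <- rbind(atom, f$atom); xyz <- rbind(xyz, f$xyz)
    factors$f1 <- list(chain = "X", label = "CENP-N")
  }
  if (spec$n_factors == 2) {
    f <- .factor_atoms("Y", atom, xyz,
                       specific = list(histone = "C", dna = "K"),
                       neighbor = list(dna = "I"),
                       anchor_bp = -spec$anchor_bp,
                       spec_frame = F2, neigh_frame = F1,
                       dyad_pos = p1$dyad_pos)
    atom <- rbind(atom, f$atom); xyz <- rbind(xyz, f$xyz)
    factors$f2 <- list(chain = "Y", label = "CENP-N")
  }
  model <- structure_model(atom, list(xyz))
  cx <- assign_roles(model, list(nucleosomes = nucs, factors = factors))
  attr(cx, "ground_truth") <- list(step = spec$step,
                                   anchor_bp = spec$anchor_bp,
                                   n_factors = spec$n_factors,
                                   nuc_spec = nuc_spec)
  cx
}

#' Specify a nucleosomal-array fiber
#'
#' Presets: `"cenpn_like"` - a two-start twisted fiber with large
#' nucleosome tilt-out, large (n, n+2) separation and steep twist, factors
#' anchored at SHL 6-7 of the n+2 nucleosome; `"h1_like"` - a more compact
#' two-start fiber (smaller stacked-pair distance and angle, shallower
#' twist, no bridging factors); `"ladder"` - parallel stacks with zero
#' (n, n+2) twist.
#'
#' @param n_nucleosomes number of array members (>= 2).
#' @param rise axial increment per consecutive nucleosome (Angstrom).
#' @param twist azimuthal increment per consecutive nucleosome (degrees).
#' @param tilt_out tilt of each nucleosome's z axis away from the fiber
#'   axis (degrees).
#' @param radius fiber radius: distance of nucleosome origins from the
#'   fiber axis (Angstrom).
#' @param terminal_flexible_count flexible nucleosomes per end (excluded
#'   from geometry fits).
#' @param factor_copies bridging-factor copies per (n, n+2) pair (0-2).
#' @param anchor_bp neighbor-side base-pair anchor of the factor's alpha6
#'   face; 65 puts the contacts at SHL 6.1-6.5.
#' @param preset optional preset name overriding the geometry arguments.
#' @return A `FiberSpec` list.
#' @export
fiber_spec <- function(n_nucleosomes = 12, rise = 30, twist = 170,
                       tilt_out = 12, radius = 50,
                       terminal_flexible_count = 2, factor_copies = 2,
                       anchor_bp = 66, preset = NULL) {
  if (!is.null(preset)) {
    presets <- list(
      cenpn_like = list(rise = 30, twist = 170, tilt_out = 18,
                        radius = 50, factor_copies = 2, anchor_bp = 66),
      h1_like = list(rise = 12, twist = 155, tilt_out = 5,
                     radius = 50, factor_copies = 0, anchor_bp = 66),
      ladder = list(rise = 30, twist = 0, tilt_out = 0, radius = 50,
                    factor_copies = 0, anchor_bp = 66))
    if (!preset %in% names(presets))
      stop("spec error: unknown fiber preset '", preset, "'",
           call. = FALSE)
    p <- presets[[preset]]
    rise <- p$rise; twist <- p$twist; tilt_out <- p$tilt_out
    radius <- p$radius; factor_copies <- p$factor_copies
    anchor_bp <- p$anchor_bp
  }
  if (n_nucleosomes < 2)
    stop("spec error: need >= 2 nucleosomes", call. = FALSE)
  structure(list(n_nucleosomes = as.integer(n_nucleosomes), rise = rise,
                 twist = twist, tilt_out = tilt_out, radius = radius,
                 terminal_flexible_count =
                   as.integer(terminal_flexible_count),
                 factor_copies = as.integer(factor_copies),
                 anchor_bp = as.integer(anchor_bp),
                 preset = preset %||% "custom"),
            class = "FiberSpec")
}

#' Build a nucleosomal-array fiber
#'
#' Ordered nucleosome frames follow the helical rule: nucleosome k sits at
#' radius `radius` from the fiber (z) axis at azimuth k * twist and height
#' k * rise, its own z axis tilted `tilt_out` degrees away from the fiber
#' axis (for the `"ladder"` preset: two parallel columns with identical
#' orientations). Terminal flexible nucleosomes are displaced off the
#' helical rule and flagged flexible in the annotation.
#'
#' @param spec a [fiber_spec()].
#' @param nuc_spec a [nucleosome_spec()] shared by all members.
#' @return An `AnnotatedComplex` with nucleosomes `nuc1`..`nucN` (chains
#'   I*k*/J*k*/A*k*/B*k*) and factors bridging n to n+2 among the ordered
#'   members.
#' @export
build_fiber <- function(spec = fiber_spec(),
                        nuc_spec = nucleosome_spec()) {
  n <- spec$n_nucleosomes
  tmp <- build_nucleosome(nuc_spec)
  Fc <- nucleosome_frame(tmp)
  ladder <- identical(spec$preset, "ladder")
  omega <- spec$twist * pi / 180
  tau <- spec$tilt_out * pi / 180
  target <- vector("list", n)
  for (k in seq_len(n)) {
    if (ladder) {
      R <- diag(3)
      O <- c(((k - 1) %% 2) * 70, 0, ((k - 1) %/% 2) * 2 * spec$rise)
    } else {
      th <- (k - 1) * omega
      R <- .rot_z(th) %*% .rot_y(tau)
      O <- c(spec$radius * cos(th), spec$radius * sin(th),
             (k - 1) * spec$rise)
    }
    target[[k]] <- .frame_from_rotation(R, O)
  }
  tflex <- spec$terminal_flexible_count
  flex_ids <- c(seq_len(min(tflex, n)), n + 1 - seq_len(min(tflex, n)))
  flex_ids <- unique(flex_ids[flex_ids >= 1 & flex_ids <= n])
  atom <- NULL; xyz <- NULL; nucs <- list()
  dyad_pos <- NULL
  for (k in seq_len(n)) {
    ch <- c(paste0("I", k), paste0("J", k), paste0("A", k),
            paste0("B", k))
    part <- .nucleosome_atoms(nuc_spec, ch[1:2], ch[3:4])
    dyad_pos <- part$dyad_pos
    Ft <- target[[k]]
    if (k %in% flex_ids) {
      # disordered terminal member: kick it off the helical rule
      R <- .frame_rotation(Ft) %*% .rot_y(30 * pi / 180) %*%
        .rot_z(40 * pi / 180)
      radial <- Ft$origin - c(0, 0, Ft$origin[3])
      if (sqrt(sum(radial^2)) < 1e-9) radial <- c(1, 0, 0)
      O <- Ft$origin + c(0, 0, 15) + 20 * .unit(radial)
      Ft <- .frame_from_rotation(R, O)
    }
    part$xyz <- apply_transform(part$xyz,
                                .transform_between_frames(Fc, Ft))
    atom <- rbind(atom, part$atom); xyz <- rbind(xyz, part$xyz)
    nucs[[paste0("nuc", k)]] <-
      .nucleosome_role_entry(nuc_spec, ch[1:2], ch[3:4],
                             flexible = k %in% flex_ids)
  }
  factors <- list()
  if (spec$factor_copies > 0) {
    ordered_ids <- setdiff(seq_len(n), flex_ids)
    for (k in ordered_ids) {
      if (!(k + 2) %in% ordered_ids) next
      f <- .factor_atoms(paste0("X", k), atom, xyz,
                         specific = list(histone = paste0("A", k),
                                         dna = paste0("I", k)),
                         neighbor = list(dna = paste0("I", k + 2)),
                         anchor_bp = spec$anchor_bp,
                         spec_frame = target[[k]],
                         neigh_frame = target[[k + 2]],
                         dyad_pos = dyad_pos)
      atom <- rbind(atom, f$atom); xyz <- rbind(xyz, f$xyz)
      factors[[paste0("f", k)]] <-
        list(chain = paste0("X", k), label = "CENP-N")
      if (spec$factor_copies >= 2) {
        f2 <- .factor_atoms(paste0("Y", k), atom, xyz,
                            specific = list(histone = paste0("A", k + 2),
                                            dna = paste0("I", k + 2)),
                            neighbor = list(dna = paste0("I", k)),
                            anchor_bp = -spec$anchor_bp,
                            spec_frame = target[[k + 2]],
                            neigh_frame = target[[k]],
                            dyad_pos = dyad_pos)
        atom <- rbind(atom, f2$atom); xyz <- rbind(xyz, f2$xyz)
        factors[[paste0("g", k)]] <-
          list(chain = paste0("Y", k), label = "CENP-N")
      }
    }
  }
  model <- structure_model(atom, list(xyz))
  cx <- assign_roles(model, list(nucleosomes = nucs, factors = factors))
  attr(cx, "ground_truth") <- list(spec = spec, nuc_spec = nuc_spec,
                                   frames = target)
  cx
}

#' Specify ensemble dispersion
#'
#' @param n_frames number of frames to draw (>= 1).
#' @param seed RNG seed (mandatory; identical seed gives an identical
#'   ensemble).
#' @param sd_rise,sd_shift standard deviations of the rise and in-plane
#'   shift perturbations (Angstrom).
#' @param sd_tilt,sd_twist standard deviations of the tilt and twist
#'   perturbations (degrees).
#' @param coord_jitter isotropic per-atom Gaussian jitter (Angstrom per
#'   coordinate) applied to all atoms after the frame perturbation.
#' @return A `DispersionSpec` list.
#' @export
dispersion_spec <- function(n_frames, seed, sd_rise = 0, sd_shift = 0,
                            sd_tilt = 0, sd_twist = 0, coord_jitter = 0) {
  if (missing(seed)) stop("spec error: seed is mandatory", call. = FALSE)
  if (n_frames < 1)
    stop("spec error: n_frames must be >= 1", call. = FALSE)
  if (any(c(sd_rise, sd_shift, sd_tilt, sd_twist, coord_jitter) < 0))
    stop("spec error: dispersions must be >= 0", call. = FALSE)
  structure(list(n_frames = as.integer(n_frames), seed = seed,
                 sd_rise = sd_rise, sd_shift = sd_shift,
                 sd_tilt = sd_tilt, sd_twist = sd_twist,
                 coord_jitter = coord_jitter),
            class = "DispersionSpec")
}

#' Dispersion presets for stacked-nucleosome sampling
#'
#' `"bridged"` (and its aliases `"one_factor"`/`"two_factor"`): the narrow
#' sampling of a factor-stabilized stack. `"unbridged"`: the wide range of
#' relative orientations explored by a bare nucleosome stack.
#'
#' @param preset preset name.
#' @param n_frames,seed passed to [dispersion_spec()].
#' @return A `DispersionSpec`.
#' @export
dispersion_preset <- function(preset = c("bridged", "one_factor",
                                         "two_factor", "unbridged"),
                              n_frames, seed) {
  preset <- match.arg(preset)
  if (preset == "unbridged") {
    dispersion_spec(n_frames, seed, sd_rise = 3, sd_shift = 3,
                    sd_tilt = 10, sd_twist = 12, coord_jitter = 0.3)
  } else {
    dispersion_spec(n_frames, seed, sd_rise = 0.5, sd_shift = 0.5,
                    sd_tilt = 2, sd_twist = 2, coord_jitter = 0.3)
  }
}

#' Sample a jittered ensemble around a stacked complex
#'
#' Frames are drawn by perturbing the mobile nucleosome's frame with
#' independent Gaussian noise per step parameter (rise, shift_x, shift_y,
#' tilt, twist), holding the reference nucleosome fixed, then adding
#' optional isotropic per-atom jitter to all atoms. Tilt perturbations are
#' reflected at zero. The draw is fully determined by the spec's seed.
#'
#' @param base an `AnnotatedComplex` with >= 2 nucleosomes.
#' @param dispersion a [dispersion_spec()].
#' @param mobile_id nucleosome perturbed per frame (default: the second).
#' @param reference_id nucleosome held fixed (default: the first).
#' @return An (unaligned) `TrajectoryEnsemble` with `topology = base`.
#' @export
sample_ensemble <- function(base, dispersion,
                            mobile_id = names(base$nucleosomes)[2],
                            reference_id = names(base$nucleosomes)[1]) {
  stopifnot(inherits(base, "AnnotatedComplex"),
            inherits(dispersion, "DispersionSpec"))
  if (length(base$nucleosomes) < 2)
    stop("need >= 2 nucleosomes for step dispersion", call. = FALSE)
  F1 <- nucleosome_frame(base, reference_id)
  F2 <- nucleosome_frame(base, mobile_id)
  s0 <- step_parameters(F1, F2)
  mob <- .get_nucleosome(base, mobile_id)
  mob_chains <- c(mob$dna_chains, names(mob$histone_chains))
  atom <- base$structure$atom
  mob_rows <- which(atom$chain_id %in% mob_chains)
  xyz0 <- model_coords(base$structure)
  n <- dispersion$n_frames
  frames <- .with_seed(dispersion$seed, {
    lapply(seq_len(n), function(f) {
      sf <- list(
        rise = s0$rise + stats::rnorm(1, 0, dispersion$sd_rise),
        shift_x = s0$shift_x + stats::rnorm(1, 0, dispersion$sd_shift),
        shift_y = s0$shift_y + stats::rnorm(1, 0, dispersion$sd_shift),
        tilt = abs(s0$tilt + stats::rnorm(1, 0, dispersion$sd_tilt)),
        twist = s0$twist + stats::rnorm(1, 0, dispersion$sd_twist))
      F2f <- frame_from_step(F1, sf)
      tr <- .transform_between_frames(F2, F2f)
      xyz <- xyz0
      xyz[mob_rows, ] <- apply_transform(xyz0[mob_rows, , drop = FALSE],
                                         tr)
      if (dispersion$coord_jitter > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0,
                                         dispersion$coord_jitter),
                            nrow(xyz), 3)
      xyz
    })
  })
  model <- structure_model(atom, frames)
  trajectory_ensemble(model, topology = base)
}

#' Write a synthetic complex or ensemble plus its role sidecar
#'
#' Writes the coordinates in a standard format (PDB, or mmCIF when chain
#' ids exceed the PDB single-character namespace; multi-model PDB for
#' ensembles) and the chain-role map as a YAML sidecar, so that
#' [read_structure()]/[read_trajectory()] plus [read_role_map()] reproduce
#' the annotated object without loss.
#'
#' @param x an `AnnotatedComplex` or `TrajectoryEnsemble`.
#' @param path output structure path.
#' @param roles_path sidecar path (default: `path` + `.roles.yaml`).
#' @return Invisibly, a list with the two paths written.
#' @export
write_fixture <- function(x, path,
                          roles_path = paste0(path, ".roles.yaml")) {
  if (inherits(x, "AnnotatedComplex")) {
    struct <- x$structure; role_map <- x$role_map
  } else if (inherits(x, "TrajectoryEnsemble")) {
    if (is.null(x$topology))
      stop("ensemble has no annotated topology", call. = FALSE)
    struct <- x$structure; role_map <- x$topology$role_map
  } else stop("x must be an AnnotatedComplex or TrajectoryEnsemble",
              call. = FALSE)
  fmt <- .guess_format(path, "auto")
  if (fmt == "pdb" && !.pdb_chain_ok(struct$atom$chain_id))
    stop("chain ids exceed the PDB namespace; use a .cif path",
         call. = FALSE)
  write_structure(struct, path, format = fmt)
  write_role_map(role_map, roles_path)
  invisible(list(structure = path, roles = roles_path))
}
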