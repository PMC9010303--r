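# Contact detection, occupancy, bridge classification, SHL mapping.

two_atom_complex <- function(d) {
  atom <- data.frame(
    atom_name = c("P", "P", "CA", "CB"),
    element = c("P", "P", "C", "C"),
    residue_name = c("DA", "DA", "GLY", "LYS"),
    residue_index = c(1L, 1L, 1L, 1L),
    chain_id = c("I", "J", "A", "X"))
  xyz <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0), c(d, 0, 0))
  assign_roles(structure_model(atom, list(xyz)), list(
    nucleosomes = list(nuc1 = list(dna = list("I", "J"),
                                   histones = list(A = "H3"))),
    factors = list(f1 = list(chain = "X", label = "CENP-N"))))
}

test_that("a single pair at 3.0 A under cutoff 4.5 yields one exact record", {
  con <- find_contacts(two_atom_complex(3), cutoff = 4.5)
  expect_identical(nrow(con), 1L)
  expect_equal(con$distance, 3, tolerance = 1e-12)
  expect_identical(con$target_kind, "DNA")
  expect_identical(nrow(find_contacts(two_atom_complex(5), cutoff = 4.5)),
                   0L)
  expect_error(find_contacts(two_atom_complex(3), cutoff = 0),
               "positive")
})

test_that("cell-list contacts equal the brute-force oracle and are monotone in cutoff", {
  set.seed(51)
  for (i in 1:10) {
    cx <- random_contact_complex(n_nuc_atoms = sample(150:450, 1),
                                 n_factor_atoms = sample(30:80, 1))
    prev <- NULL
    for (cutoff in c(3.5, 4.0, 4.5, 5.0)) {
      fast <- find_contacts(cx, cutoff, method = "cells")
      slow <- find_contacts(cx, cutoff, method = "brute")
      expect_equal(fast, slow, ignore_attr = TRUE)
      if (!is.null(prev)) {
        k_prev <- with(prev, paste(factor_resno, target_chain,
                                   target_resno, target_atom))
        k_now <- with(fast, paste(factor_resno, target_chain,
                                  target_resno, target_atom))
        expect_true(all(k_prev %in% k_now))
      }
      prev <- fast
    }
  }
})

test_that("hydrogens are excluded from contact detection", {
  cx <- two_atom_complex(3)
  atom <- cx$structure$atom
  xyz <- model_coords(cx$structure)
  atom <- rbind(atom, data.frame(atom_name = "H1", element = "H",
                                 residue_name = "LYS", residue_index = 1L,
                                 chain_id = "X"))
  xyz <- rbind(xyz, c(1, 0, 0))
  cx2 <- assign_roles(structure_model(atom, list(xyz)), cx$role_map)
  con <- find_contacts(cx2, cutoff = 4.5)
  expect_false(any(con$factor_atom == "H1"))
})

test_that("occupancy counts frames in contact and is monotone in cutoff and jitter", {
  # constructed 20-frame ensemble: contact present in exactly 7 frames
  cx <- two_atom_complex(3)
  xyz0 <- model_coords(cx$structure)
  frames <- lapply(1:20, function(f) {
    xyz <- xyz0
    if (f > 7) xyz[4, 1] <- 50   # move the factor atom out of range
    xyz
  })
  ens <- trajectory_ensemble(structure_model(cx$structure$atom, frames),
                             topology = cx)
  occ <- contact_occupancy(ens, cutoff = 4.5)
  expect_identical(nrow(occ), 1L)
  expect_equal(occ$occupancy, 0.35)
  expect_false(occ$strong)
  occ2 <- contact_occupancy(ens, cutoff = 4.5, strong_threshold = 0.3)
  expect_true(occ2$strong)
  expect_error(contact_occupancy(ens, factor_id = "nope"),
               "selection error")

  # occupancy of the bridging interface decays as coordinate jitter grows
  st <- build_stack(stack_spec(n_factors = 1))
  mean_occ <- vapply(c(0.2, 0.8, 1.6), function(sj) {
    e <- sample_ensemble(st, dispersion_spec(n_frames = 25, seed = 13,
                                             coord_jitter = sj))
    o <- contact_occupancy(e, cutoff = 4.5, factor_id = "f1",
                           target_kind = "DNA")
    mean(o$occupancy)
  }, 0)
  expect_true(all(diff(mean_occ) < 0))
  expect_true(all(mean_occ >= 0 & mean_occ <= 1))
})

test_that("bridge classification separates specific and neighbor partners", {
  st <- build_stack(stack_spec(n_factors = 2))
  con <- find_contacts(st)
  b1 <- classify_bridge(con, "f1")
  expect_true(b1$is_bridge)
  expect_identical(b1$specific_nucleosome_id, "nuc1")
  expect_identical(b1$neighbor_nucleosome_id, "nuc2")
  expect_false(b1$ambiguous)
  # neighbor side receives DNA-only contacts
  expect_false(any(con$factor_id == "f1" & con$nucleosome_id == "nuc2" &
                     con$target_kind == "histone"))
  b2 <- classify_bridge(con, "f2")
  expect_identical(b2$specific_nucleosome_id, "nuc2")
  expect_identical(b2$neighbor_nucleosome_id, "nuc1")
  expect_identical(sum(vapply(c("f1", "f2"), function(f)
    classify_bridge(con, f)$is_bridge, TRUE)), 2L)

  # factor touching one nucleosome only: not a bridge
  mono_con <- con[con$nucleosome_id == "nuc1" & con$factor_id == "f1", ]
  b <- classify_bridge(mono_con, "f1")
  expect_false(b$is_bridge)
  expect_identical(b$neighbor_nucleosome_id, NA_character_)
  # zero contacts: empty interface, not an error
  empty <- classify_bridge(con[0, ], "f1")
  expect_false(empty$is_bridge)
  # histone contacts on both nucleosomes: flagged ambiguous, both listed
  amb <- con
  amb$target_kind[amb$factor_id == "f1" &
                    amb$nucleosome_id == "nuc2"][1] <- "histone"
  ba <- classify_bridge(amb, "f1")
  expect_true(ba$ambiguous)
  expect_setequal(ba$specific_nucleosome_id, c("nuc1", "nuc2"))
})

test_that("alpha6-labelled factor residues contact the neighbor DNA only", {
  st <- build_stack(stack_spec(n_factors = 1))
  con <- find_contacts(st, cutoff = 4.5)
  neigh <- con[con$nucleosome_id == "nuc2", ]
  expect_true(all(neigh$target_kind == "DNA"))
  expect_true(all(neigh$factor_resno %in% c(102, 105, 109, 110, 114, 117)))
  expect_setequal(unique(neigh$factor_resname), c("LYS", "ARG"))
})

test_that("SHL mapping reproduces the stated spans and bins", {
  nuc <- build_nucleosome()
  series <- pair_base_steps(nuc, "nuc1")
  dyad_pos <- 74L
  fake <- data.frame(
    factor_id = "f1", factor_chain = "X",
    factor_resno = c(102L, 105L), factor_resname = "LYS",
    factor_atom = "CA", nucleosome_id = "nuc1", target_kind = "DNA",
    target_chain = "I", target_resno = dyad_pos + c(44L, 50L),
    target_atom = "C1'", distance = 3)
  m <- map_contacts_to_shl(fake, series)
  expect_identical(m$status, "ok")
  expect_equal(m$span, c(44, 50) / 10.4, tolerance = 1e-9)
  expect_identical(m$bin_counts$bin, 4L)
  expect_identical(m$bin_counts$label, "[4,5)")
  expect_identical(m$bin_counts$count, 2L)
  # empty DNA-contact list -> explicit status
  none <- map_contacts_to_shl(fake[0, ], series)
  expect_identical(none$status, "no neighbor contacts")
  # residue outside the series -> gap error
  bad <- fake; bad$target_resno[1] <- 999L
  expect_error(map_contacts_to_shl(bad, series), "gap error")
  # strand-2 residues map through the same pairing
  fake2 <- fake
  fake2$target_chain <- "J"
  fake2$target_resno <- 148L - (dyad_pos + c(44L, 50L))
  m2 <- map_contacts_to_shl(fake2, series)
  expect_equal(m2$span, c(44, 50) / 10.4, tolerance = 1e-9)
})

test_that("preset stacks and fibers map their bridging contacts to the constructed SHL bins", {
  st <- build_stack(stack_spec(n_factors = 1, anchor_bp = 47))
  con <- find_contacts(st)
  m <- map_contacts_to_shl(con[con$factor_id == "f1", ],
                           pair_base_steps(st, "nuc2"))
  expect_identical(unique(m$per_contact$shl_bin), 4L)
  expect_true(m$span[1] >= 4 && m$span[2] < 5)

  fib <- build_fiber(fiber_spec(preset = "cenpn_like"))
  fcon <- find_contacts(fib)
  fid <- fib$factors$factor_id[1]
  k <- as.integer(sub("f", "", fid))
  fm <- map_contacts_to_shl(fcon[fcon$factor_id == fid, ],
                            pair_base_steps(fib, paste0("nuc", k + 2)))
  expect_identical(unique(fm$per_contact$shl_bin), 6L)
  expect_true(fm$span[1] >= 6 && fm$span[2] < 7)
})
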