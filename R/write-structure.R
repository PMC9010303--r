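# Structure writers. PDB output goes through bio3d (which handles the fixed
# columns and multi-model records); mmCIF output is a minimal atom_site loop,
# used for complexes whose chain count exceeds the single-character PDB chain
# namespace (e.g. annotated 12-mer fibers).

.pdb_chain_ok <- function(chains) all(nchar(chains) == 1)

#' Write a structure model to PDB or mmCIF
#'
#' @param structure a `StructureModel` (all models are written).
#' @param path output path; extension `.cif` selects mmCIF under
#'   `format = "auto"`.
#' @param format `"auto"`, `"pdb"` or `"mmcif"`. PDB requires single-character
#'   chain identifiers; complexes with longer chain ids must use mmCIF.
#' @export
write_structure <- function(structure, path,
                            format = c("auto", "pdb", "mmcif")) {
  stopifnot(inherits(structure, "StructureModel"))
  fmt <- .guess_format(path, match.arg(format))
  atom <- structure$atom
  if (fmt == "pdb") {
    if (!.pdb_chain_ok(atom$chain_id))
      stop("PDB output requires single-character chain ids; use mmCIF",
           call. = FALSE)
    xyz <- do.call(rbind, lapply(structure$frames, function(m)
      as.numeric(t(m))))
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = atom$residue_index,
                     resid = atom$residue_name,
                     chain = atom$chain_id,
                     eleno = seq_len(nrow(atom)),
                     elety = atom$atom_name,
                     elesy = atom$element)
  } else {
    .write_mmcif(structure, path)
  }
  invisible(path)
}

# Canonical wwPDB atom_site column order (21 fields), which is also the
# fixed layout the bio3d mmCIF reader expects.
.write_mmcif <- function(structure, path) {
  atom <- structure$atom
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_nucstack", "#", "loop_",
               "_atom_site.group_PDB",
               "_atom_site.id",
               "_atom_site.type_symbol",
               "_atom_site.label_atom_id",
               "_atom_site.label_alt_id",
               "_atom_site.label_comp_id",
               "_atom_site.label_asym_id",
               "_atom_site.label_entity_id",
               "_atom_site.label_seq_id",
               "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x",
               "_atom_site.Cartn_y",
               "_atom_site.Cartn_z",
               "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv",
               "_atom_site.pdbx_formal_charge",
               "_atom_site.auth_seq_id",
               "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id",
               "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  n <- nrow(atom)
  id <- 0L
  q <- function(x) {
    # quote atom names containing a prime so the reader keeps them intact
    ifelse(grepl("'", x, fixed = TRUE), paste0('"', x, '"'), x)
  }
  for (m in seq_along(structure$frames)) {
    xyz <- structure$frames[[m]]
    lines <- sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s %d",
      id + seq_len(n), atom$element, q(atom$atom_name), atom$residue_name,
      atom$chain_id, atom$residue_index,
      xyz[, 1], xyz[, 2], xyz[, 3],
      atom$residue_index, atom$residue_name, atom$chain_id,
      q(atom$atom_name), m)
    writeLines(lines, con)
    id <- id + n
  }
  writeLines("#", con)
}
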