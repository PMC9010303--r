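# Structure input/output and chain-role annotation.
#
# A StructureModel is the in-memory carrier for all atomic coordinates: an
# atom table (one row per atom of the shared topology) plus one coordinate
# matrix per model. An AnnotatedComplex groups the chains of a StructureModel
# into nucleosomes (two DNA strands plus histone chains) and free factors
# (e.g. CENP-N); every analysis in the package runs on an AnnotatedComplex.

HISTONE_IDENTITIES <- c("H3", "CENP-A", "H4", "H2A", "H2B")

#' Construct a structure model
#'
#' @param atom data.frame with columns `atom_name`, `element`, `residue_name`,
#'   `residue_index` (integer), `chain_id`.
#' @param frames list of n-by-3 numeric coordinate matrices (Angstrom), one
#'   per model, all conforming to `atom`.
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(atom, frames) {
  stopifnot(is.data.frame(atom), is.list(frames), length(frames) >= 1)
  need <- c("atom_name", "element", "residue_name", "residue_index", "chain_id")
  miss <- setdiff(need, names(atom))
  if (length(miss) > 0)
    stop("atom table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(atom) == 0)
    stop("empty structure: atom table has zero rows", call. = FALSE)
  for (i in seq_along(frames)) {
    xyz <- frames[[i]]
    if (!is.matrix(xyz) || ncol(xyz) != 3 || nrow(xyz) != nrow(atom))
      stop("frame ", i, " does not conform to the atom table", call. = FALSE)
    if (!all(is.finite(xyz)))
      stop("frame ", i, " contains non-finite coordinates", call. = FALSE)
  }
  key <- paste(atom$chain_id, atom$residue_index, atom$atom_name)
  if (anyDuplicated(key)) {
    warning("duplicate (chain, residue, atom) records; keeping first of each")
    keep <- !duplicated(key)
    atom <- atom[keep, , drop = FALSE]
    frames <- lapply(frames, function(m) m[keep, , drop = FALSE])
  }
  rownames(atom) <- NULL
  structure(list(atom = atom, frames = frames,
                 model_count = length(frames)),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel: %d atoms, %d chain(s), %d model(s)\n",
              nrow(x$atom), length(unique(x$atom$chain_id)), x$model_count))
  invisible(x)
}

#' Coordinates of one model
#'
#' @param structure a `StructureModel`.
#' @param model model number (1-based).
#' @return n-by-3 coordinate matrix.
#' @export
model_coords <- function(structure, model = 1) {
  stopifnot(inherits(structure, "StructureModel"))
  if (model < 1 || model > structure$model_count)
    stop("model index out of range", call. = FALSE)
  structure$frames[[model]]
}

.guess_format <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
}

.bio3d_to_model <- function(pdb) {
  # strip mmCIF quoting of primed atom names ("C1'" -> C1')
  elety <- gsub('^"|"$', "", trimws(pdb$atom$elety))
  atom <- data.frame(
    atom_name = elety,
    element = trimws(ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                            substr(elety, 1, 1),
                            pdb$atom$elesy)),
    residue_name = trimws(pdb$atom$resid),
    residue_index = as.integer(pdb$atom$resno),
    chain_id = as.character(pdb$atom$chain),
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  structure_model(atom, frames)
}

#' Read an atomic model
#'
#' Reads PDB or mmCIF files (via bio3d) into a [structure_model()]. Multi-model
#' PDB files yield `model_count > 1`.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"pdb"`, `"mmcif"`; `"auto"` decides by
#'   extension.
#' @return A `StructureModel`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  if (!file.exists(path))
    stop("cannot read structure file: ", path, call. = FALSE)
  fmt <- .guess_format(path, format)
  pdb <- tryCatch(
    if (fmt == "mmcif") suppressWarnings(bio3d::read.cif(path,
                                                         verbose = FALSE))
    else bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("empty structure (zero atoms) in ", path, call. = FALSE)
  .bio3d_to_model(pdb)
}

# Count ATOM/HETATM records per MODEL block of a PDB file. Used to report
# topology mismatches with the first offending model.
.scan_model_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) == 0) return(sum(is_atom))
  bounds <- c(model_starts, length(lines) + 1L)
  vapply(seq_along(model_starts), function(i)
    sum(is_atom[bounds[i]:(bounds[i + 1] - 1L)]), integer(1))
}

#' Read a trajectory ensemble from a multi-model PDB file
#'
#' All models must share one topology (same atoms in the same order); the
#' frames are returned in file order.
#'
#' @param path multi-model PDB file.
#' @param role_map optional role map (see [read_role_map()]) used to annotate
#'   the topology.
#' @return A `TrajectoryEnsemble`.
#' @export
read_trajectory <- function(path, role_map = NULL) {
  if (!file.exists(path))
    stop("cannot read trajectory file: ", path, call. = FALSE)
  sizes <- .scan_model_sizes(path)
  if (length(sizes) > 1 && length(unique(sizes)) > 1) {
    bad <- which(sizes != sizes[1])[1]
    stop(sprintf(
      "topology mismatch: model %d has %d atoms, model 1 has %d",
      bad, sizes[bad], sizes[1]), call. = FALSE)
  }
  model <- read_structure(path, format = "pdb")
  topo <- if (!is.null(role_map)) assign_roles(model, role_map) else NULL
  trajectory_ensemble(model, topology = topo)
}

#' Construct a trajectory ensemble
#'
#' @param structure a `StructureModel` (its models are the frames).
#' @param topology optional `AnnotatedComplex` over the same atoms.
#' @param aligned logical: has the ensemble been aligned on a reference
#'   nucleosome (see [align_ensemble()])?
#' @return A `TrajectoryEnsemble`.
#' @export
trajectory_ensemble <- function(structure, topology = NULL, aligned = FALSE) {
  stopifnot(inherits(structure, "StructureModel"))
  if (!is.null(topology)) {
    stopifnot(inherits(topology, "AnnotatedComplex"))
    if (!identical(dim(topology$structure$frames[[1]]),
                   dim(structure$frames[[1]])))
      stop("topology does not conform to the ensemble atoms", call. = FALSE)
  }
  structure(list(structure = structure, topology = topology,
                 frames = structure$frames,
                 frame_count = structure$model_count,
                 aligned = isTRUE(aligned)),
            class = "TrajectoryEnsemble")
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  cat(sprintf("TrajectoryEnsemble: %d frames, %d atoms, %saligned\n",
              x$frame_count, nrow(x$structure$atom),
              if (x$aligned) "" else "not "))
  invisible(x)
}

#' Read a chain-role map
#'
#' The role map is a YAML file assigning each analyzed chain a biological
#' role. Schema:
#' ```yaml
#' nucleosomes:
#'   nuc1:
#'     dna: [I, J]
#'     histones: {A: CENP-A, B: H4}
#'     flexible: false            # optional, for array members
#'     flexible_bp_per_end: 0     # optional, unwrapped terminal bp
#' factors:
#'   f1: {chain: X, label: CENP-N}
#' ```
#'
#' @param path YAML file path.
#' @return A role-map list suitable for [assign_roles()].
#' @export
read_role_map <- function(path) {
  if (!file.exists(path)) stop("role map not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Write a chain-role map
#'
#' @param role_map role-map list (see [read_role_map()]).
#' @param path output YAML path.
#' @export
write_role_map <- function(role_map, path) {
  yaml::write_yaml(role_map, path)
  invisible(path)
}

#' Annotate chains with biological roles
#'
#' Groups chains into nucleosomes (exactly two DNA strands each, plus histone
#' chains) and factors. Chain-role assignment is explicit: nothing is inferred
#' from sequence. Chains absent from the map are retained in the structure but
#' ignored by all analyses.
#'
#' @param structure a `StructureModel` (or, for the `TrajectoryEnsemble`
#'   method, an ensemble whose topology gets annotated).
#' @param role_map role-map list (see [read_role_map()]).
#' @return An `AnnotatedComplex` (or the annotated ensemble).
#' @export
assign_roles <- function(structure, role_map) UseMethod("assign_roles")

#' @export
assign_roles.StructureModel <- function(structure, role_map) {
  stopifnot(is.list(role_map))
  chains <- unique(structure$atom$chain_id)
  nucs <- role_map$nucleosomes
  if (is.null(nucs) || length(nucs) == 0)
    stop("role map defines no nucleosomes", call. = FALSE)
  ids <- names(nucs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("nucleosome ids must be unique and named", call. = FALSE)
  nucleosomes <- lapply(ids, function(id) {
    spec <- nucs[[id]]
    dna <- as.character(unlist(spec$dna))
    if (length(dna) != 2)
      stop("nucleosome '", id, "' must have exactly 2 DNA chains, got ",
           length(dna), call. = FALSE)
    hist <- unlist(spec$histones)
    if (length(hist) > 0) {
      bad <- setdiff(unname(hist), HISTONE_IDENTITIES)
      if (length(bad) > 0)
        stop("unknown histone identity: ", paste(bad, collapse = ", "),
             call. = FALSE)
    }
    for (ch in c(dna, names(hist))) {
      if (!ch %in% chains)
        stop("annotated chain '", ch, "' absent from structure",
             call. = FALSE)
    }
    list(id = id, dna_chains = dna,
         histone_chains = if (length(hist)) hist else character(0),
         flexible = isTRUE(spec$flexible),
         flexible_bp_per_end =
           as.integer(spec$flexible_bp_per_end %||% 0L))
  })
  names(nucleosomes) <- ids
  facs <- role_map$factors
  factors <- if (is.null(facs) || length(facs) == 0) {
    data.frame(factor_id = character(0), chain_id = character(0),
               label = character(0), stringsAsFactors = FALSE)
  } else {
    fid <- names(facs)
    if (is.null(fid) || anyDuplicated(fid))
      stop("factor ids must be unique and named", call. = FALSE)
    df <- data.frame(
      factor_id = fid,
      chain_id = vapply(facs, function(f) as.character(f$chain), ""),
      label = vapply(facs, function(f)
        as.character(f$label %||% "factor"), ""),
      stringsAsFactors = FALSE)
    for (ch in df$chain_id)
      if (!ch %in% chains)
        stop("annotated chain '", ch, "' absent from structure",
             call. = FALSE)
    rownames(df) <- NULL
    df
  }
  structure(list(structure = structure, nucleosomes = nucleosomes,
                 factors = factors, role_map = role_map),
            class = "AnnotatedComplex")
}

#' @export
assign_roles.TrajectoryEnsemble <- function(structure, role_map) {
  ens <- structure
  ens$topology <- assign_roles(ens$structure, role_map)
  ens
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.AnnotatedComplex <- function(x, ...) {
  cat(sprintf("AnnotatedComplex: %d nucleosome(s), %d factor(s), %d atoms\n",
              length(x$nucleosomes), nrow(x$factors),
              nrow(x$structure$atom)))
  invisible(x)
}

.get_nucleosome <- function(complex, nucleosome_id) {
  stopifnot(inherits(complex, "AnnotatedComplex"))
  nuc <- complex$nucleosomes[[as.character(nucleosome_id)]]
  if (is.null(nuc))
    stop("unknown nucleosome id: ", nucleosome_id, call. = FALSE)
  nuc
}

# Role ("DNA", "histone", "factor" or NA) of every atom, as a character
# vector aligned with the atom table, plus the owning nucleosome/factor id.
.atom_roles <- function(complex) {
  atom <- complex$structure$atom
  role <- rep(NA_character_, nrow(atom))
  owner <- rep(NA_character_, nrow(atom))
  for (nuc in complex$nucleosomes) {
    i <- atom$chain_id %in% nuc$dna_chains
    role[i] <- "DNA"; owner[i] <- nuc$id
    j <- atom$chain_id %in% names(nuc$histone_chains)
    role[j] <- "histone"; owner[j] <- nuc$id
  }
  if (nrow(complex$factors) > 0) {
    for (k in seq_len(nrow(complex$factors))) {
      i <- atom$chain_id == complex$factors$chain_id[k]
      role[i] <- "factor"; owner[i] <- complex$factors$factor_id[k]
    }
  }
  data.frame(role = role, owner = owner, stringsAsFactors = FALSE)
}

#' Replace the coordinates of an annotated complex
#'
#' @param complex an `AnnotatedComplex`.
#' @param xyz n-by-3 coordinate matrix conforming to the complex's atoms.
#' @return The complex with model-1 coordinates replaced.
#' @export
set_coords <- function(complex, xyz) {
  stopifnot(inherits(complex, "AnnotatedComplex"),
            is.matrix(xyz), ncol(xyz) == 3,
            nrow(xyz) == nrow(complex$structure$atom))
  complex$structure$frames <- list(xyz)
  complex$structure$model_count <- 1L
  complex
}

#' Extract one frame of an ensemble as an annotated complex
#'
#' @param ensemble an annotated `TrajectoryEnsemble`.
#' @param frame frame number (1-based).
#' @return An `AnnotatedComplex` carrying that frame's coordinates.
#' @export
frame_complex <- function(ensemble, frame) {
  stopifnot(inherits(ensemble, "TrajectoryEnsemble"))
  if (is.null(ensemble$topology))
    stop("ensemble has no annotated topology; call assign_roles() first",
         call. = FALSE)
  if (frame < 1 || frame > ensemble$frame_count)
    stop("frame index out of range", call. = FALSE)
  set_coords(ensemble$topology, ensemble$frames[[frame]])
}

#' Write tabular analysis records
#'
#' Output is bit-stable for identical input: column order is taken from the
#' data frame and floating-point columns are written at fixed precision.
#'
#' @param records non-empty data.frame of homogeneous records.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param digits decimal places for numeric columns.
#' @export
write_records <- function(records, path, format = c("csv", "json"),
                          digits = 6) {
  format <- match.arg(format)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data frame", call. = FALSE)
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], format = "f", digits = digits)
  }
  ok <- tryCatch({
    if (format == "csv") {
      utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    } else {
      jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE)
    }
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path))
    stop("could not write records to ", path, call. = FALSE)
  invisible(path)
}
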