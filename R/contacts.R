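# Protein-DNA / protein-histone contact detection, trajectory occupancy, and
# bridging-interface classification with SHL mapping.
#
# A contact is a heavy-atom pair (factor atom, nucleosome atom) at distance
# <= cutoff. The default cutoff is 4.5 A; outputs record the cutoff used.
# "Strong" contacts over an ensemble are defined by occupancy (fraction of
# frames in contact), threshold 0.5 by default.

DEFAULT_CONTACT_CUTOFF <- 4.5

.heavy <- function(atom) !(toupper(atom$element) %in% c("H", "D"))

.contact_pairs_df <- function(atom, roles, fi, ti, dist) {
  data.frame(
    factor_id = roles$owner[fi],
    factor_chain = atom$chain_id[fi],
    factor_resno = atom$residue_index[fi],
    factor_resname = atom$residue_name[fi],
    factor_atom = atom$atom_name[fi],
    nucleosome_id = roles$owner[ti],
    target_kind = roles$role[ti],
    target_chain = atom$chain_id[ti],
    target_resno = atom$residue_index[ti],
    target_atom = atom$atom_name[ti],
    distance = dist,
    stringsAsFactors = FALSE)
}

.order_contacts <- function(df) {
  df <- df[order(df$factor_chain, df$factor_resno, df$factor_atom,
                 df$target_chain, df$target_resno, df$target_atom), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

# Brute-force all-pairs reference used as the exhaustive oracle in tests.
.contacts_brute <- function(xyz, atom, roles, fidx, tidx, cutoff) {
  F <- xyz[fidx, , drop = FALSE]
  T <- xyz[tidx, , drop = FALSE]
  d2 <- outer(rowSums(F^2), rowSums(T^2), "+") - 2 * F %*% t(T)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(.contact_pairs_df(atom, roles, integer(0), integer(0), numeric(0)))
  .contact_pairs_df(atom, roles, fidx[hit[, 1]], tidx[hit[, 2]],
                    sqrt(pmax(d2[hit], 0)))
}

# Cell-list culling: nucleosome atoms are hashed on a grid with edge =
# cutoff; each factor atom only visits its 27 neighboring cells. Contract:
# identical result to the brute-force reference.
.contacts_cells <- function(xyz, atom, roles, fidx, tidx, cutoff) {
  T <- xyz[tidx, , drop = FALSE]
  key3 <- function(P) floor(P / cutoff)
  tk <- key3(T)
  tkey <- paste(tk[, 1], tk[, 2], tk[, 3])
  cells <- split(seq_along(tidx), tkey)
  out_f <- integer(0); out_t <- integer(0); out_d <- numeric(0)
  F <- xyz[fidx, , drop = FALSE]
  fk <- key3(F)
  fkey <- paste(fk[, 1], fk[, 2], fk[, 3])
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (fk_cell in unique(fkey)) {
    fi_local <- which(fkey == fk_cell)
    base <- fk[fi_local[1], ]
    neigh_keys <- paste(base[1] + off[, 1], base[2] + off[, 2],
                        base[3] + off[, 3])
    cand <- unlist(cells[neigh_keys], use.names = FALSE)
    if (length(cand) == 0) next
    Fc <- F[fi_local, , drop = FALSE]
    Tc <- T[cand, , drop = FALSE]
    d2 <- outer(rowSums(Fc^2), rowSums(Tc^2), "+") - 2 * Fc %*% t(Tc)
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    out_f <- c(out_f, fidx[fi_local[hit[, 1]]])
    out_t <- c(out_t, tidx[cand[hit[, 2]]])
    out_d <- c(out_d, sqrt(pmax(d2[hit], 0)))
  }
  .contact_pairs_df(atom, roles, out_f, out_t, out_d)
}

#' Find factor-nucleosome atomic contacts
#'
#' Reports every heavy-atom pair (factor atom, nucleosome DNA or histone
#' atom) within `cutoff`, exactly once. Hydrogens are excluded. The default
#' implementation culls candidate pairs with a cell list (cell edge =
#' cutoff); `method = "brute"` is the O(n^2) reference used for testing -
#' both produce identical contact sets.
#'
#' @param complex an `AnnotatedComplex` with at least one annotated factor.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @param method `"cells"` (default) or `"brute"`.
#' @param xyz optional coordinate override (n-by-3), e.g. one trajectory
#'   frame.
#' @return Data.frame of `ContactRecord` rows: factor side (id, chain,
#'   residue, atom), target side (nucleosome id, kind DNA/histone, chain,
#'   residue, atom) and distance; attribute `"cutoff"` records the cutoff.
#' @export
find_contacts <- function(complex, cutoff = DEFAULT_CONTACT_CUTOFF,
                          method = c("cells", "brute"), xyz = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(complex, "AnnotatedComplex"))
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("cutoff must be positive", call. = FALSE)
  if (nrow(complex$factors) == 0)
    stop("annotation error: no factor chains annotated", call. = FALSE)
  atom <- complex$structure$atom
  roles <- .atom_roles(complex)
  if (is.null(xyz)) xyz <- model_coords(complex$structure)
  heavy <- .heavy(atom)
  fidx <- which(roles$role == "factor" & heavy)
  tidx <- which(roles$role %in% c("DNA", "histone") & heavy)
  df <- if (length(fidx) == 0 || length(tidx) == 0) {
    .contact_pairs_df(atom, roles, integer(0), integer(0), numeric(0))
  } else if (method == "brute") {
    .contacts_brute(xyz, atom, roles, fidx, tidx, cutoff)
  } else {
    .contacts_cells(xyz, atom, roles, fidx, tidx, cutoff)
  }
  df <- .order_contacts(df)
  attr(df, "cutoff") <- cutoff
  df
}

#' Residue-pair contact occupancy over an ensemble
#'
#' Occupancy of a residue pair is the fraction of frames in which the pair
#' has at least one heavy-atom contact within `cutoff`. Pairs with occupancy
#' at or above `strong_threshold` are labelled strong.
#'
#' @param ensemble an annotated `TrajectoryEnsemble`.
#' @param cutoff distance cutoff in Angstrom.
#' @param factor_id restrict to one factor (default: all factors).
#' @param target_kind restrict the target side to `"DNA"`, `"histone"` or
#'   both (default).
#' @param strong_threshold occupancy at or above which a pair is "strong".
#' @return Data.frame with one row per residue pair ever in contact:
#'   factor/target residue identifiers, minimum distance observed, occupancy
#'   in \[0, 1\] and logical `strong`.
#' @export
contact_occupancy <- function(ensemble, cutoff = DEFAULT_CONTACT_CUTOFF,
                              factor_id = NULL,
                              target_kind = c("DNA", "histone"),
                              strong_threshold = 0.5) {
  stopifnot(inherits(ensemble, "TrajectoryEnsemble"))
  if (is.null(ensemble$topology))
    stop("ensemble has no annotated topology", call. = FALSE)
  target_kind <- match.arg(target_kind, several.ok = TRUE)
  topo <- ensemble$topology
  if (!is.null(factor_id) &&
      !factor_id %in% topo$factors$factor_id)
    stop("selection error: unknown factor id ", factor_id, call. = FALSE)
  n <- ensemble$frame_count
  tallies <- new.env(parent = emptyenv())
  for (f in seq_len(n)) {
    con <- find_contacts(topo, cutoff = cutoff,
                         xyz = ensemble$frames[[f]])
    con <- con[con$target_kind %in% target_kind, , drop = FALSE]
    if (!is.null(factor_id))
      con <- con[con$factor_id == factor_id, , drop = FALSE]
    if (nrow(con) == 0) next
    key <- paste(con$factor_chain, con$factor_resno, con$target_chain,
                 con$target_resno, sep = "|")
    mind <- tapply(con$distance, key, min)
    first <- con[!duplicated(key), , drop = FALSE]
    ukey <- unique(key)
    for (i in seq_along(ukey)) {
      k <- ukey[i]
      rec <- tallies[[k]]
      if (is.null(rec)) {
        r <- first[i, ]
        tallies[[k]] <- list(row = r, count = 1L,
                             min_distance = mind[[k]])
      } else {
        rec$count <- rec$count + 1L
        rec$min_distance <- min(rec$min_distance, mind[[k]])
        tallies[[k]] <- rec
      }
    }
  }
  keys <- ls(tallies)
  if (length(keys) == 0)
    stop("selection error: no residue pairs in contact under the selection",
         call. = FALSE)
  rows <- lapply(keys, function(k) {
    rec <- tallies[[k]]
    data.frame(
      factor_id = rec$row$factor_id,
      factor_chain = rec$row$factor_chain,
      factor_resno = rec$row$factor_resno,
      factor_resname = rec$row$factor_resname,
      nucleosome_id = rec$row$nucleosome_id,
      target_kind = rec$row$target_kind,
      target_chain = rec$row$target_chain,
      target_resno = rec$row$target_resno,
      min_distance = rec$min_distance,
      occupancy = rec$count / n,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$strong <- out$occupancy >= strong_threshold
  out <- out[order(out$factor_chain, out$factor_resno, out$target_chain,
                   out$target_resno), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "strong_threshold") <- strong_threshold
  out
}

#' Classify a factor's bridging interface
#'
#' The specific partner is the nucleosome receiving any histone contacts
#' from the factor; a neighbor partner receives DNA-only contacts. A factor
#' is a bridge when its contacts reach at least two distinct nucleosomes.
#' Histone contacts to more than one nucleosome are flagged ambiguous (both
#' are listed) rather than silently resolved.
#'
#' @param contacts contact records from [find_contacts()].
#' @param factor_id the factor to classify.
#' @return A `BridgeInterface`: list with `factor_id`,
#'   `specific_nucleosome_id`, `neighbor_nucleosome_id` (NA if none),
#'   `is_bridge`, `ambiguous`, and `per_residue` contact counts.
#' @export
classify_bridge <- function(contacts, factor_id) {
  con <- contacts[contacts$factor_id == factor_id, , drop = FALSE]
  if (nrow(con) == 0) {
    return(structure(list(factor_id = factor_id,
                          specific_nucleosome_id = NA_character_,
                          neighbor_nucleosome_id = NA_character_,
                          is_bridge = FALSE, ambiguous = FALSE,
                          per_residue = NULL),
                     class = "BridgeInterface"))
  }
  nucs <- unique(con$nucleosome_id)
  hist_nucs <- unique(con$nucleosome_id[con$target_kind == "histone"])
  dna_only <- setdiff(nucs, hist_nucs)
  ambiguous <- length(hist_nucs) > 1
  specific <- if (length(hist_nucs) >= 1) hist_nucs else NA_character_
  neighbor <- if (length(dna_only) >= 1) dna_only else NA_character_
  per_res <- stats::aggregate(
    list(n_contacts = con$distance),
    by = list(factor_resno = con$factor_resno,
              factor_resname = con$factor_resname,
              nucleosome_id = con$nucleosome_id,
              target_kind = con$target_kind),
    FUN = length)
  structure(list(factor_id = factor_id,
                 specific_nucleosome_id = specific,
                 neighbor_nucleosome_id = neighbor,
                 is_bridge = length(nucs) >= 2,
                 ambiguous = ambiguous,
                 per_residue = per_res),
            class = "BridgeInterface")
}

#' @export
print.BridgeInterface <- function(x, ...) {
  cat(sprintf("BridgeInterface %s: specific = %s, neighbor = %s%s%s\n",
              x$factor_id, paste(x$specific_nucleosome_id, collapse = "+"),
              paste(x$neighbor_nucleosome_id, collapse = "+"),
              if (x$is_bridge) " [bridge]" else "",
              if (x$ambiguous) " [ambiguous specificity]" else ""))
  invisible(x)
}

#' Map neighbor-DNA contacts to superhelical locations
#'
#' Each DNA contact is mapped through the neighbor nucleosome's base-pair
#' series to its base-pair index, then to continuous SHL (index / 10.4). The
#' span is the \[min, max\] of |SHL| values; counts are reported in half-open
#' |SHL| bins \[k, k+1).
#'
#' @param contacts contact records from [find_contacts()].
#' @param neighbor_series `BasePairSeries` of the neighbor nucleosome.
#' @return List with `status` (`"ok"` or `"no neighbor contacts"`), `span`
#'   (numeric length 2 or NULL), `per_contact` (data.frame with SHL per
#'   contact) and `bin_counts` (data.frame of counts per |SHL| bin).
#' @export
map_contacts_to_shl <- function(contacts, neighbor_series) {
  stopifnot(inherits(neighbor_series, "BasePairSeries"))
  nuc_id <- attr(neighbor_series, "nucleosome_id")
  con <- contacts[contacts$target_kind == "DNA" &
                    contacts$nucleosome_id == nuc_id, , drop = FALSE]
  if (nrow(con) == 0) {
    return(list(status = "no neighbor contacts", span = NULL,
                per_contact = NULL, bin_counts = NULL))
  }
  lut <- rbind(
    data.frame(chain = neighbor_series$chain1,
               resno = neighbor_series$resno1,
               index = neighbor_series$index),
    data.frame(chain = neighbor_series$chain2,
               resno = neighbor_series$resno2,
               index = neighbor_series$index))
  key <- paste(con$target_chain, con$target_resno)
  m <- match(key, paste(lut$chain, lut$resno))
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    stop("gap error: contact residue(s) absent from base-pair series: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  bp <- lut$index[m]
  shl <- bp / BP_PER_SHL
  per <- cbind(con, bp_index = bp, shl = shl, shl_bin = shl_bin(shl))
  bins <- as.data.frame(table(bin = shl_bin(shl)),
                        stringsAsFactors = FALSE)
  names(bins) <- c("bin", "count")
  bins$bin <- as.integer(bins$bin)
  bins$label <- sprintf("[%d,%d)", bins$bin, bins$bin + 1L)
  list(status = "ok",
       span = range(abs(shl)),
       per_contact = per,
       bin_counts = bins)
}
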