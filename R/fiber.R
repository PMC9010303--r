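# Nucleosomal-array geometry: per-step n/n+1 and n/n+2 stacking, start-number
# classification, helical fiber parameters (in analogy to the base-step
# description of a DNA double helix), and repeat/linker accounting.
#
# "Stacked-pair distance" and "stacked-pair angle" reported here are,
# respectively, the mean center-to-center distance and the mean inter-z-axis
# angle over (n, n+2) nucleosome pairs; outputs are labelled with this
# definition since different fiber descriptions use different conventions.

#' Order array nucleosomes and compute their frames
#'
#' Order comes from the annotation (repeat order of the nucleosome list in
#' the role map), not from DNA connectivity tracing. Nucleosomes flagged
#' flexible in the annotation get `ordered_flag = FALSE` and are excluded
#' from geometry fits.
#'
#' @param complex an `AnnotatedComplex` with >= 2 nucleosomes.
#' @return Data.frame with `nucleosome_id`, `ordered_flag` and a `frame`
#'   list-column of `NucleosomeFrame`s (NULL for flexible members).
#' @export
order_nucleosomes <- function(complex) {
  stopifnot(inherits(complex, "AnnotatedComplex"))
  if (length(complex$nucleosomes) < 2)
    stop("insufficient data: need >= 2 nucleosomes", call. = FALSE)
  ids <- names(complex$nucleosomes)
  ordered_flag <- !vapply(complex$nucleosomes, function(n) n$flexible,
                          TRUE)
  if (sum(ordered_flag) < 2)
    stop("insufficient data: fewer than 2 ordered nucleosomes",
         call. = FALSE)
  frames <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    if (!ordered_flag[k]) next
    frames[[k]] <- tryCatch(
      nucleosome_frame(complex, ids[k]),
      error = function(e) stop("nucleosome ", ids[k], ": ",
                               conditionMessage(e), call. = FALSE))
  }
  out <- data.frame(nucleosome_id = ids, ordered_flag = ordered_flag,
                    stringsAsFactors = FALSE)
  out$frame <- frames
  rownames(out) <- NULL
  out
}

#' Stack steps along an array for offsets 1 and 2
#'
#' @param ordered output of [order_nucleosomes()] (flexible members are
#'   dropped).
#' @return Data.frame of `StackStep` rows with `offset` (1 or 2), `from` and
#'   `to` nucleosome ids; N ordered nucleosomes give N-1 offset-1 and N-2
#'   offset-2 steps.
#' @export
fiber_steps <- function(ordered) {
  keep <- ordered[ordered$ordered_flag, , drop = FALSE]
  n <- nrow(keep)
  if (n < 3)
    stop("insufficient data: need >= 3 ordered nucleosomes", call. = FALSE)
  rows <- list()
  for (off in 1:2) {
    for (k in seq_len(n - off)) {
      st <- step_parameters(keep$frame[[k]], keep$frame[[k + off]])
      rows[[length(rows) + 1L]] <-
        cbind(offset = off, from = keep$nucleosome_id[k],
              to = keep$nucleosome_id[k + off], st)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

#' Classify the start number of a fiber
#'
#' A fiber is two-start when nucleosome n stacks on n+2, i.e. when the
#' median (n, n+2) center distance is smaller than the median (n, n+1)
#' distance; otherwise one-start. A tie within `tol` (relative) is reported
#' as ambiguous rather than silently resolved.
#'
#' @param steps output of [fiber_steps()].
#' @param tol relative tolerance for calling a tie.
#' @return List with `start_number` (1, 2 or NA), `partner_offset`,
#'   `status` (`"ok"` or `"ambiguous"`), and the two median distances.
#' @export
classify_start_number <- function(steps, tol = 0.01) {
  d1 <- stats::median(steps$center_distance[steps$offset == 1])
  d2 <- stats::median(steps$center_distance[steps$offset == 2])
  if (!is.finite(d1) || !is.finite(d2))
    stop("step series must contain offsets 1 and 2", call. = FALSE)
  if (abs(d1 - d2) <= tol * max(d1, d2)) {
    return(list(start_number = NA_integer_, partner_offset = NA_integer_,
                status = "ambiguous", median_d1 = d1, median_d2 = d2))
  }
  two_start <- d2 < d1
  list(start_number = if (two_start) 2L else 1L,
       partner_offset = if (two_start) 2L else 1L,
       status = "ok", median_d1 = d1, median_d2 = d2)
}

# Unwrap an angle series to the nearest branch (avoids +/-360 jumps).
.unwrap <- function(theta) {
  out <- theta
  for (k in seq_along(theta)[-1]) {
    d <- theta[k] - out[k - 1]
    out[k] <- out[k - 1] + atan2(sin(d), cos(d))
  }
  out
}

#' Helical fit of an ordered fiber
#'
#' The fiber axis direction is taken from the screw decomposition of the
#' relative rotations between consecutive ordered nucleosome frames (their
#' common rotation axis), seeded and sign-oriented by the principal direction
#' of the origins; for twist-free (ladder-like) fibers it falls back to the
#' mean origin increment. Per-nucleosome azimuths about the axis are
#' unwrapped to the nearest branch; rise and twist per nucleosome are the
#' mean consecutive axial and azimuthal increments.
#'
#' @param ordered output of [order_nucleosomes()] (>= 4 ordered members).
#' @return A `FiberGeometry`: list with `axis` (unit vector), `axis_point`
#'   (centroid of origins), `rise_per_nucleosome` (Angstrom),
#'   `twist_per_nucleosome` (degrees, signed about the axis),
#'   `start_number`, `stacked_pair_distance` and `stacked_pair_angle`
#'   (mean over (n, n+2) pairs), `radius` and `n_ordered`.
#' @export
fiber_helix_fit <- function(ordered) {
  keep <- ordered[ordered$ordered_flag, , drop = FALSE]
  n <- nrow(keep)
  if (n < 4)
    stop("insufficient data: need >= 4 ordered nucleosomes", call. = FALSE)
  O <- t(vapply(keep$frame, function(f) f$origin, numeric(3)))
  ctr <- colMeans(O)
  Oc <- sweep(O, 2, ctr)
  ev <- eigen(crossprod(Oc) / n, symmetric = TRUE)
  pca_axis <- ev$vectors[, 1]
  if (sum(pca_axis * (O[n, ] - O[1, ])) < 0) pca_axis <- -pca_axis
  # screw axes of consecutive relative rotations
  axes <- NULL; angles <- numeric(0)
  for (k in seq_len(n - 1)) {
    G <- .frame_rotation(keep$frame[[k + 1]]) %*%
      t(.frame_rotation(keep$frame[[k]]))
    aa <- .axis_angle(G)
    # below ~2e-4 deg the "rotation" is numerical noise from the frame
    # fits; treat the step as twist-free
    if (aa$angle > 1e-5) {
      ax <- aa$axis
      if (sum(ax * pca_axis) < 0) { ax <- -ax; aa$angle <- -aa$angle }
      axes <- rbind(axes, ax)
      angles <- c(angles, aa$angle)
    }
  }
  axis <- if (is.null(axes)) {
    # twist-free (ladder-like): axis from the mean origin increment
    d <- colMeans(O[-1, , drop = FALSE] - O[-n, , drop = FALSE])
    if (sqrt(sum(d^2)) < 1e-9)
      stop("geometry error: degenerate fiber (no net advance, no twist)",
           call. = FALSE)
    .unit(d)
  } else .unit(colMeans(axes))
  axial <- as.numeric(Oc %*% axis)
  if (max(axial) - min(axial) < 1e-9)
    stop("geometry error: degenerate coplanar ring of origins",
         call. = FALSE)
  # in-plane coordinates about the axis: locate the axis in the transverse
  # plane by an algebraic circle fit (exact for noiseless helices), then
  # measure azimuths about that center. The in-plane reference direction is
  # taken from the origin with the largest transverse component; origins
  # collinear with the axis have no azimuthal structure (twist 0).
  trans <- Oc - outer(axial, axis)
  tnorm <- sqrt(rowSums(trans^2))
  rise <- mean(diff(axial))
  if (max(tnorm) < 1e-9) {
    azimuth <- rep(0, n); twist <- 0; radius <- 0
  } else {
    ref <- .unit(trans[which.max(tnorm), ])
    ref2 <- .cross3(axis, ref)
    u <- as.numeric(Oc %*% ref)
    v <- as.numeric(Oc %*% ref2)
    center <- c(0, 0)
    if (!is.null(axes)) {
      A <- cbind(2 * u, 2 * v, 1)
      fit <- tryCatch(qr.solve(A, u^2 + v^2), error = function(e) NULL)
      if (!is.null(fit)) center <- fit[1:2]
    }
    du <- u - center[1]; dv <- v - center[2]
    azimuth <- .unwrap(atan2(dv, du))
    twist <- if (is.null(axes)) 0 else mean(diff(azimuth)) * 180 / pi
    radius <- mean(sqrt(du^2 + dv^2))
  }
  # (n, n+2) stacked-pair metrics
  d2 <- numeric(0); a2 <- numeric(0)
  for (k in seq_len(n - 2)) {
    d2 <- c(d2, sqrt(sum((O[k + 2, ] - O[k, ])^2)))
    a2 <- c(a2, acos(.clamp1(sum(keep$frame[[k]]$z *
                                   keep$frame[[k + 2]]$z))) * 180 / pi)
  }
  start <- if (n >= 3) {
    st <- classify_start_number(fiber_steps(ordered))
    st$start_number
  } else NA_integer_
  structure(list(axis = axis, axis_point = ctr,
                 rise_per_nucleosome = rise,
                 twist_per_nucleosome = twist,
                 start_number = start,
                 stacked_pair_distance = mean(d2),
                 stacked_pair_angle = mean(a2),
                 radius = radius, n_ordered = n,
                 azimuth = azimuth * 180 / pi, axial = axial),
            class = "FiberGeometry")
}

#' @export
print.FiberGeometry <- function(x, ...) {
  cat(sprintf(
    "FiberGeometry: %d ordered nucleosomes, rise %.2f A, twist %.2f deg, %s-start\n",
    x$n_ordered, x$rise_per_nucleosome, x$twist_per_nucleosome,
    ifelse(is.na(x$start_number), "?", x$start_number)))
  cat(sprintf("  (n, n+2): distance %.2f A, angle %.2f deg\n",
              x$stacked_pair_distance, x$stacked_pair_angle))
  invisible(x)
}

#' Define a nucleosomal array
#'
#' @param n_repeats number of tandem repeats (>= 1).
#' @param repeat_length repeat length in bp.
#' @param wrapped_length wrapped length in bp (<= repeat_length; default
#'   147).
#' @param terminal_flexible_count flexible nucleosomes per end.
#' @return An `ArrayDefinition` list.
#' @export
array_definition <- function(n_repeats, repeat_length,
                             wrapped_length = 147,
                             terminal_flexible_count = 0) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  if (repeat_length < wrapped_length)
    stop("repeat_length must be >= wrapped_length", call. = FALSE)
  structure(list(n_repeats = as.integer(n_repeats),
                 repeat_length = as.integer(repeat_length),
                 wrapped_length = as.integer(wrapped_length),
                 terminal_flexible_count =
                   as.integer(terminal_flexible_count)),
            class = "ArrayDefinition")
}

#' Linker length of an array
#'
#' linker = repeat length - wrapped length (bp); e.g. a 167-bp repeat with
#' 147 bp wrapped leaves a 20-bp linker.
#'
#' @param array an `ArrayDefinition`.
#' @return Integer linker length in bp.
#' @export
linker_accounting <- function(array) {
  stopifnot(inherits(array, "ArrayDefinition"))
  array$repeat_length - array$wrapped_length
}
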