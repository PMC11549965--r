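# Inscribed-sphere pore profiling.
#
# The channel profile of a barrel structure is measured in the spirit of
# PoreWalker/MOLE: at each slice along the channel axis, find the
# largest sphere centered in that slice that touches no atom's van der
# Waals surface.  The slice radius is
#   r(x, y) = min_i ( ||p - a_i|| - vdw_i )
# maximized over the in-slice center (x, y) with full 3D distances to
# the atoms, so the result is a true inscribed sphere.

# Bondi van der Waals radii for heavy atoms (Angstrom)
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90)

vdw_radius <- function(elements) {
  r <- .vdw_radii[toupper(elements)]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Principal channel axis of a structure
#'
#' The axis is the first principal component of the transmembrane
#' Calpha coordinates, anchored at their centroid and oriented toward
#' +z.
#'
#' @param x a `tmb_backbone` or a numeric matrix of Calpha coordinates
#'   (columns x, y, z).
#' @return list with `point` (centroid) and `dir` (unit axis vector).
#' @export
find_axis <- function(x) {
  P <- if (inherits(x, "tmb_backbone")) ca_coords(x, tm_only = TRUE) else
    as.matrix(x)
  if (nrow(P) < 9) stop("too few coordinates to define a channel axis")
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  sv <- svd(Q)
  if (sv$d[3] < 1e-6 * sv$d[1])
    stop("degenerate (planar) coordinates: channel axis undefined")
  dir <- sv$v[, 1]
  if (dir[3] < 0) dir <- -dir
  list(point = ctr, dir = dir)
}

#' Profile the water-accessible pore of a structure
#'
#' Slices the structure along its channel axis and finds, per slice, the
#' largest inscribed sphere centered in the slice plane.  The in-slice
#' maximization uses a Nelder-Mead simplex seeded at the previous slice
#' center, with an exhaustive grid fallback whenever the optimized
#' center jumps more than 2 Angstrom between slices (robustness on
#' noncylindrical pores).  Fully occluded slices record radius 0.
#'
#' @param x a `tmb_backbone`, an atom data frame from
#'   [read_structure()], or a list with `xyz` (n x 3 matrix) and
#'   `elements` (character).
#' @param step slice spacing along the axis, Angstrom (default 1).
#' @param z_range axial range to profile, relative to the atom centroid
#'   along the axis; defaults to the transmembrane z-range for backbone
#'   models and the central half of the atom extent otherwise.
#' @param axis optional axis as returned by [find_axis()].
#' @return a `pore_profile` data frame with columns `z`, `x`, `y`,
#'   `radius` (Angstrom).
#' @examples
#' ## ring of atoms of radius 10 around the z axis
#' th <- seq(0, 2 * pi, length.out = 37)[-37]
#' at <- list(xyz = cbind(10 * cos(th), 10 * sin(th), 0), elements = "C")
#' ## per-slice radius 10 - 1.7 = 8.3
#' @export
profile_pore <- function(x, step = 1.0, z_range = NULL, axis = NULL) {
  at <- as_atom_set(x)
  if (is.null(axis))
    axis <- if (inherits(x, "tmb_backbone")) x$axis else find_axis(at$xyz)
  # rotate into the axis frame (axis = +z through the centroid)
  R <- rotation_to_z(axis$dir)
  P <- sweep(at$xyz, 2, axis$point) %*% t(R)
  vdw <- rep_len(vdw_radius(at$elements), nrow(P))
  if (is.null(z_range)) {
    z_range <- if (inherits(x, "tmb_backbone")) x$tm_z else {
      zr <- range(P[, 3]); mid <- mean(zr)
      mid + c(-0.25, 0.25) * diff(zr)
    }
  }
  zs <- seq(z_range[1], z_range[2], by = step)
  rmax_box <- max(sqrt(P[, 1]^2 + P[, 2]^2))
  ctr <- c(0, 0)
  out <- data.frame(z = zs, x = NA_real_, y = NA_real_, radius = NA_real_)
  for (si in seq_along(zs)) {
    z <- zs[si]
    keep <- abs(P[, 3] - z) < rmax_box + max(vdw)
    A <- P[keep, , drop = FALSE]; vr <- vdw[keep]
    fobj <- function(xy) {
      if (sqrt(sum(xy^2)) > rmax_box) return(1e6)
      d <- sqrt((A[, 1] - xy[1])^2 + (A[, 2] - xy[2])^2 + (A[, 3] - z)^2)
      -min(d - vr)
    }
    o <- stats::optim(ctr, fobj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
    # pore slices can be multi-modal (noncylindrical shapes, side
    # pockets): refine from a coarse-grid seed as well and keep the
    # better optimum, with a finer grid when the center jumps
    g <- slice_grid_search(A, vr, z, rmax_box, 0.5)
    o2 <- stats::optim(g$center, fobj, method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-10))
    if (o2$value < o$value) o <- o2
    if (sqrt(sum((o$par - ctr)^2)) > 2) {
      g <- slice_grid_search(A, vr, z, rmax_box, 0.25)
      o3 <- stats::optim(g$center, fobj, method = "Nelder-Mead",
                         control = list(maxit = 400, reltol = 1e-10))
      if (o3$value < o$value) o <- o3
    }
    r <- max(-o$value, 0)
    out$x[si] <- o$par[1]; out$y[si] <- o$par[2]; out$radius[si] <- r
    if (r > 0) ctr <- o$par
  }
  attr(out, "axis") <- axis
  attr(out, "z_range") <- z_range
  class(out) <- c("pore_profile", "data.frame")
  out
}

# Exhaustive in-slice grid search (also the brute-force oracle used in
# the tests, at a finer grid).  Vectorized over grid chunks.
slice_grid_search <- function(A, vdw, z, rmax, h) {
  gx <- seq(-rmax, rmax, by = h)
  G <- as.matrix(expand.grid(x = gx, y = gx))
  G <- G[G[, 1]^2 + G[, 2]^2 <= rmax^2, , drop = FALSE]
  dz2 <- (A[, 3] - z)^2
  best <- -Inf; bc <- c(0, 0)
  for (start in seq(1, nrow(G), by = 20000L)) {
    ch <- G[start:min(start + 19999L, nrow(G)), , drop = FALSE]
    d2 <- outer(ch[, 1], A[, 1], "-")^2 + outer(ch[, 2], A[, 2], "-")^2
    d2 <- sweep(d2, 2, dz2, "+")
    v <- apply(sweep(sqrt(d2), 2, vdw, "-"), 1, min)
    i <- which.max(v)
    if (v[i] > best) { best <- v[i]; bc <- ch[i, ] }
  }
  list(center = unname(bc), radius = max(best, 0))
}

as_atom_set <- function(x) {
  if (inherits(x, "tmb_backbone")) {
    if (is.null(x$xyz$cb)) stop("profile needs a full backbone model")
    xyz <- rbind(x$xyz$n, x$xyz$ca, x$xyz$c, x$xyz$o, x$xyz$cb)
    el <- rep(c("N", "C", "C", "O", "C"), each = nrow(x$xyz$ca))
    list(xyz = xyz, elements = el)
  } else if (is.data.frame(x)) {
    list(xyz = as.matrix(x[, c("x", "y", "z")]), elements = x$element)
  } else if (is.list(x) && !is.null(x$xyz)) {
    list(xyz = as.matrix(x$xyz), elements = x$elements)
  } else stop("cannot interpret input as an atom set")
}

# rotation taking unit vector v to +z
rotation_to_z <- function(v) {
  v <- vunit(v)
  if (abs(v[3] - 1) < 1e-12) return(diag(3))
  if (abs(v[3] + 1) < 1e-12) return(diag(c(1, -1, -1)))
  ax <- vunit(vcross(v, c(0, 0, 1)))
  rotation_matrix(ax, acos(v[3]))
}

#' Summarize a pore profile
#'
#' @param object a `pore_profile`.
#' @param ... unused.
#' @return list with `average_diameter`, `min_diameter`, `sd_diameter`
#'   (per-slice standard deviation) and `n_slices`, all in Angstrom.
#' @export
summary.pore_profile <- function(object, ...) {
  if (nrow(object) == 0) stop("empty pore profile")
  d <- 2 * object$radius
  out <- list(average_diameter = mean(d), min_diameter = min(d),
              sd_diameter = stats::sd(d), n_slices = length(d))
  class(out) <- "summary.pore_profile"
  out
}

#' @export
print.summary.pore_profile <- function(x, ...) {
  cat(sprintf("Pore profile: average diameter %.2f +/- %.2f A, min %.2f A (%d slices)\n",
              x$average_diameter,
              ifelse(is.na(x$sd_diameter), 0, x$sd_diameter),
              x$min_diameter, x$n_slices))
  invisible(x)
}

#' @export
print.pore_profile <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Pore profile over z = %.1f..%.1f A (%d slices)\n",
              min(x$z), max(x$z), nrow(x)))
  print(s)
  invisible(x)
}

#' @export
plot.pore_profile <- function(x, ...) {
  graphics::plot(x$z, 2 * x$radius, type = "b", xlab = "z (A)",
                 ylab = "pore diameter (A)", ...)
  invisible(x)
}

#' Write a pore profile as TSV
#' @param profile a `pore_profile`.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[, c("z", "x", "y", "radius")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
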