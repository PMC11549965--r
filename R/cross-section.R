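# Cross-section curves.
#
# A sculpted barrel cross-section is represented as a closed planar curve
# of total arc length equal to the barrel circumference C, parameterized
# by arc position t in [0, C).  The cylinder is a circle; kink-sculpted
# shapes are convex polygons with rounded corners (and the oval is a
# stadium, i.e. a rounded 2-gon).  Atoms are placed by mapping the
# unrolled circumferential lattice coordinate u to arc position t, which
# preserves the circumference exactly and keeps faces flat between
# corners.

# Arc positions (offsets from the phase origin) of the corner centers for
# each shape, as fractions of the circumference, plus per-corner exterior
# turn angles and default rounding radii.
shape_corner_layout <- function(shape, C) {
  switch(shape,
    square = list(frac = c(0, 1, 2, 3) / 4,
                  ext = rep(pi / 2, 4), rho = 1.8, stacked = FALSE),
    rectangle = list(frac = cumsum(c(0, 2, 1, 2)) / 6,
                     ext = rep(pi / 2, 4), rho = 1.8, stacked = FALSE),
    triangle = list(frac = c(0, 1, 2) / 3,
                    ext = rep(2 * pi / 3, 3), rho = 2.0, stacked = TRUE),
    oval = list(frac = c(0, 1) / 2,
                ext = rep(pi, 2), rho = C / (4 + 2 * pi), stacked = TRUE),
    stop("unknown cross-section shape: ", shape)
  )
}

cs_circle <- function(C) {
  structure(list(type = "circle", perim = C, R = C / (2 * pi)),
            class = "cs_curve")
}

# Rounded polygon with corner centers at arc positions corner_t (sorted,
# within [0, C)), exterior turn angles ext (must sum to 2*pi) and corner
# rounding radius rho.  The curve is built by walking arc/line segments
# and recentered so its centroid sits at the origin.
cs_rounded_polygon <- function(C, corner_t, ext, rho) {
  nc <- length(corner_t)
  stopifnot(length(ext) == nc, abs(sum(ext) - 2 * pi) < 1e-9)
  ord <- order(corner_t)
  corner_t <- corner_t[ord]; ext <- ext[ord]
  arc_len <- rho * ext
  gap <- diff(c(corner_t, corner_t[1] + C))          # corner-to-corner spacing
  straight <- gap - (arc_len + c(arc_len[-1], arc_len[1])) / 2
  if (any(straight < 0))
    stop("corner rounding radius too large for this cross-section")

  # walk starts at the beginning of corner 1's arc
  t_start <- corner_t[1] - arc_len[1] / 2
  segs <- list(); p <- c(0, 0); h <- 0
  for (i in seq_len(nc)) {
    # corner arc (counter-clockwise turn by ext[i])
    segs[[length(segs) + 1]] <- list(kind = "arc", len = arc_len[i],
                                     p0 = p, h0 = h, turn = ext[i], rho = rho)
    ctr <- p + rho * c(-sin(h), cos(h))
    h <- h + ext[i]
    p <- ctr - rho * c(-sin(h), cos(h))
    # straight face
    segs[[length(segs) + 1]] <- list(kind = "line", len = straight[i],
                                     p0 = p, h0 = h)
    p <- p + straight[i] * c(cos(h), sin(h))
  }
  if (vnorm(p) > 1e-6)
    stop("cross-section polygon failed to close (asymmetric corner layout)")
  cum <- cumsum(vapply(segs, `[[`, numeric(1), "len"))
  crv <- structure(list(type = "poly", perim = C, segs = segs,
                        cum = cum, t_start = t_start,
                        corner_t = corner_t, center = c(0, 0)),
                   class = "cs_curve")
  # recenter on the centroid of the sampled outline
  ts <- seq(0, C, length.out = 512L)[-1]
  pts <- t(vapply(ts, function(t) cs_point(crv, t)$p, numeric(2)))
  crv$center <- colMeans(pts)
  crv
}

# Point and outward normal at arc position t (2D, in the cross-section
# plane).  Returns list(p = c(x, y), nrm = c(nx, ny)).
cs_point <- function(curve, t) {
  C <- curve$perim
  t <- t %% C
  if (curve$type == "circle") {
    th <- t / curve$R
    nrm <- c(cos(th), sin(th))
    return(list(p = curve$R * nrm, nrm = nrm))
  }
  tt <- (t - curve$t_start) %% C
  i <- findInterval(tt, curve$cum, left.open = TRUE) + 1L
  s <- curve$segs[[i]]
  l <- tt - if (i > 1L) curve$cum[i - 1L] else 0
  if (s$kind == "line") {
    p <- s$p0 + l * c(cos(s$h0), sin(s$h0))
    nrm <- c(sin(s$h0), -cos(s$h0))
  } else {
    ctr <- s$p0 + s$rho * c(-sin(s$h0), cos(s$h0))
    phi0 <- s$h0 - pi / 2
    phi <- phi0 + l / s$rho
    nrm <- c(cos(phi), sin(phi))
    p <- ctr + s$rho * nrm
  }
  list(p = p - curve$center, nrm = nrm)
}

#' Place glycine kinks for a sculpted cross-section
#'
#' Glycine kinks are the corner-forming elements of a sculpted barrel:
#' a glycine in the extended positive-phi conformation bends a
#' beta-strand locally.  Corners of the target cross-section are realized
#' as kink columns running parallel to the barrel axis, one kink position
#' per strand crossing.  Corners with an interior angle of at least 90
#' degrees (square, rectangle, oval flanks) use a single kink per
#' crossing; the tighter corners of the triangle and the high-curvature
#' ends of the oval use two stacked/adjacent kinks per crossing.
#'
#' @param spec a [barrel_spec()].
#' @param shape target cross-section; defaults to the spec's
#'   `cross_section`.  `"cylinder"` yields an empty kink map.
#' @return a data frame with columns `strand` (0-based strand index),
#'   `k` (lattice register index along the strand), `corner` (corner id)
#'   and `u` (circumferential lattice coordinate, Angstrom), with the
#'   shape stored in `attr(, "shape")`.
#' @examples
#' km <- place_glycine_kinks(barrel_spec(12), "square")
#' nrow(km)  # 12 strands x 4 corners x 1 kink
#' @export
place_glycine_kinks <- function(spec, shape = spec$cross_section) {
  stopifnot(inherits(spec, "barrel_spec"))
  empty <- data.frame(strand = integer(), k = integer(),
                      corner = integer(), u = numeric())
  if (shape == "cylinder") {
    attr(empty, "shape") <- "cylinder"
    return(empty)
  }
  lay <- shape_corner_layout(shape, barrel_circumference(spec))
  nc <- length(lay$frac)
  if (nc > spec$n_strands / 2)
    stop("cross-section has more corners than n_strands/2 supports")
  C <- barrel_circumference(spec)
  corner_u <- lay$frac * C
  lat <- lattice_uz(spec)
  tm <- lat[lat$label == "strand", ]
  out <- NULL
  per <- if (lay$stacked) 2L else 1L
  # circumferential spacing between consecutive residues along a strand;
  # a strand crosses a corner edge iff its nearest residue is within
  # roughly half this step of the corner
  ustep <- spec$rise_per_residue^2 * spec$shear / C
  for (ci in seq_len(nc)) {
    for (j in unique(tm$strand)) {
      sj <- tm[tm$strand == j, ]
      # circular distance of each residue's u to the corner
      d <- abs(((sj$u - corner_u[ci] + C / 2) %% C) - C / 2)
      if (per == 1L) {
        # single kinks sit on outward-pleating (even-register) residues,
        # where the corner bend and the beta-pleat cooperate
        ok <- sj$k %% 2 == 0
        if (min(d[ok]) > 1.1 * ustep) next  # strand does not cross here
        pick <- which(ok)[order(d[ok])][1L]
      } else {
        if (min(d) > 0.55 * ustep) next
        pick <- order(d)[seq_len(per)]
      }
      out <- rbind(out, data.frame(strand = j, k = sj$k[pick],
                                   corner = ci, u = sj$u[pick]))
    }
  }
  if (is.null(out))
    stop("no strand crossings found for any corner; strands too short?")
  out <- out[order(out$corner, out$strand, out$k), ]
  rownames(out) <- NULL
  attr(out, "shape") <- shape
  out
}

# Build the sculpting curve implied by a kink map: corner phases are read
# off the kink columns, the corner spacing pattern and turn angles come
# from the shape layout.
curve_from_kink_map <- function(kink_map, C) {
  shape <- attr(kink_map, "shape")
  if (is.null(shape)) {
    ncorner <- length(unique(kink_map$corner))
    shape <- switch(as.character(ncorner), "2" = "oval", "3" = "triangle",
                    "4" = "square", stop("cannot infer shape from kink map"))
  }
  lay <- shape_corner_layout(shape, C)
  # circular mean phase of the corner columns relative to the canonical layout
  ph <- numeric(0)
  for (ci in sort(unique(kink_map$corner))) {
    uu <- kink_map$u[kink_map$corner == ci]
    off <- (uu - lay$frac[ci] * C) * 2 * pi / C
    ph <- c(ph, off)
  }
  phase <- atan2(mean(sin(ph)), mean(cos(ph))) * C / (2 * pi)
  cs_rounded_polygon(C, (lay$frac * C + phase) %% C, lay$ext, lay$rho)
}
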