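# Idealized Calpha lattice of a closed beta-barrel.
#
# The barrel wall is the unrolled beta-sheet lattice wrapped on the
# cross-section curve.  With rise a along the strand, interstrand
# spacing b, strand count n and shear S, the wall closes on a cylinder of
# circumference C = sqrt((S a)^2 + (n b)^2); the strands are tilted by
# alpha = atan2(S a, n b) with cos(alpha) = n b / C and
# sin(alpha) = S a / C.  Residue (j, k) of the lattice (strand j,
# register index k) sits at circumferential coordinate
#   u = j b cos(alpha) - k a sin(alpha)
# and height
#   z = j b sin(alpha) + k a cos(alpha),
# which makes the barrel exactly periodic: (j + n, k) coincides with
# (j, k + S) after one wrap of the circumference.  Each strand spans
# register indices k0_j + 0:(L-1) with k0_j = -round(j S / n) so that all
# strands cover the same membrane z-range and the shear is distributed
# in steps of 1-2 registers per strand pair.  The beta-pleat is modeled
# as an alternating displacement of (-1)^k along the local wall normal
# with amplitude sqrt(3.8^2 - a^2)/2, giving the canonical 3.8 Angstrom
# consecutive Calpha distance.

barrel_circumference <- function(spec) {
  sqrt((spec$shear * spec$rise_per_residue)^2 +
       (spec$n_strands * spec$interstrand_distance)^2)
}

pleat_amplitude <- function(a) sqrt(3.8^2 - a^2) / 2

# Per-residue lattice bookkeeping in chain order (TM strands only,
# antiparallel traversal: even strands ascend in k, odd strands descend).
lattice_uz <- function(spec) {
  n <- spec$n_strands; S <- spec$shear
  a <- spec$rise_per_residue; b <- spec$interstrand_distance
  L <- spec$strand_length
  C <- barrel_circumference(spec)
  ca <- n * b / C; sa <- S * a / C
  res <- NULL
  for (j in 0:(n - 1)) {
    k0 <- -round(j * S / n)
    ks <- k0 + 0:(L - 1)
    if (j %% 2 == 1) ks <- rev(ks)
    res <- rbind(res, data.frame(strand = j, k = ks,
                                 u = j * b * ca - ks * a * sa,
                                 z = j * b * sa + ks * a * ca))
  }
  res$z <- res$z - mean(res$z)          # membrane midplane at z = 0
  res$label <- "strand"
  res
}

# Regenerate Cartesian Calpha coordinates of TM residues from their
# lattice coordinates and the model's cross-section curve, and refresh
# the stored wall normals.
reproject_ca <- function(model) {
  rs <- model$residues
  tm <- which(rs$label == "strand")
  amp <- pleat_amplitude(model$spec$rise_per_residue)
  for (i in tm) {
    cp <- cs_point(model$curve, rs$u[i])
    off <- amp * (-1)^rs$k[i]
    model$xyz$ca[i, ] <- c(cp$p + off * cp$nrm, rs$z[i])
    model$residues$nx[i] <- cp$nrm[1]
    model$residues$ny[i] <- cp$nrm[2]
  }
  model
}

#' Build the Calpha lattice of an idealized barrel
#'
#' Wraps the ideal beta-sheet lattice implied by a [barrel_spec()] on a
#' cylinder of radius [barrel_radius()], with antiparallel strand
#' traversal, distributed shear register offsets and an alternating
#' beta-pleat.  The result is a Calpha-only backbone model; sculpt it
#' with [sculpt_cross_section()], close it with [close_hairpins()] and
#' complete it with [build_full_backbone()], or use [design_backbone()]
#' to run the whole pipeline.
#'
#' @param spec a [barrel_spec()].
#' @return an object of class `tmb_backbone` at stage `"calpha"`.
#' @examples
#' m <- build_calpha_lattice(barrel_spec(10))
#' mean(sqrt(rowSums(ca_coords(m)[, 1:2]^2)))  # matches barrel_radius()
#' @export
build_calpha_lattice <- function(spec) {
  stopifnot(inherits(spec, "barrel_spec"))
  rs <- lattice_uz(spec)
  rs$index <- seq_len(nrow(rs))
  rs$kink <- FALSE
  rs$nx <- NA_real_; rs$ny <- NA_real_
  C <- barrel_circumference(spec)
  model <- structure(list(
    residues = rs,
    xyz = list(ca = matrix(NA_real_, nrow(rs), 3,
                           dimnames = list(NULL, c("x", "y", "z"))),
               n = NULL, c = NULL, o = NULL, cb = NULL),
    spec = spec,
    curve = cs_circle(C),
    axis = list(point = c(0, 0, 0), dir = c(0, 0, 1)),
    stage = "calpha"
  ), class = "tmb_backbone")
  model <- reproject_ca(model)
  model$tm_z <- range(rs$z)
  model
}

#' Calpha coordinates of a backbone model
#'
#' @param model a `tmb_backbone`.
#' @param tm_only drop loop residues?
#' @return numeric matrix with one row per residue, columns x, y, z.
#' @export
ca_coords <- function(model, tm_only = FALSE) {
  stopifnot(inherits(model, "tmb_backbone"))
  xyz <- model$xyz$ca
  if (tm_only) xyz <- xyz[model$residues$label == "strand", , drop = FALSE]
  xyz
}

#' Sculpt the barrel cross-section at the glycine kinks
#'
#' Remaps the barrel wall from the cylinder onto the rounded-polygon
#' cross-section implied by a kink map (see [place_glycine_kinks()]).
#' The mapping is an arc-length isometry of the wall: the circumference
#' is preserved exactly, faces between kink columns are flat, and all
#' bending is localized in the rounded corners at the kink columns.
#' Residues listed in the kink map are flagged as glycine kinks; the
#' register (and hence the shear number) is untouched.
#'
#' @param model a `tmb_backbone` from [build_calpha_lattice()] (sculpt
#'   before closing hairpins).
#' @param kink_map data frame from [place_glycine_kinks()]; an empty map
#'   returns the model unchanged.
#' @return the sculpted `tmb_backbone`.
#' @export
sculpt_cross_section <- function(model, kink_map) {
  stopifnot(inherits(model, "tmb_backbone"))
  if (nrow(kink_map) == 0) return(model)
  if (any(model$residues$label == "loop"))
    stop("sculpt the cross-section before closing hairpins")
  C <- barrel_circumference(model$spec)
  model$curve <- curve_from_kink_map(kink_map, C)
  key <- paste(model$residues$strand, model$residues$k)
  model$residues$kink <- key %in% paste(kink_map$strand, kink_map$k)
  model <- reproject_ca(model)
  model$stage <- "sculpted"
  model
}

#' Close the barrel with short beta-hairpin loops
#'
#' Connects consecutive strands with 2- or 3-residue beta-hairpin turns,
#' alternating between the two barrel ends.  Loop Calpha positions are
#' placed analytically on a circular arc bulging axially outward from
#' the two strand termini, with equal segment lengths close to the
#' canonical 3.8 Angstrom virtual bond (always <= 4.1 Angstrom).
#' Transmembrane residues are untouched.
#'
#' @param model a `tmb_backbone` (Calpha stage, sculpted or not).
#' @param loop_lengths per-connection loop lengths (2 or 3), recycled;
#'   defaults to the spec's `loop_lengths`.
#' @return a `tmb_backbone` at stage `"closed"` with
#'   `n_strands * strand_length + sum(loop_lengths)` residues.
#' @export
close_hairpins <- function(model, loop_lengths = model$spec$loop_lengths) {
  stopifnot(inherits(model, "tmb_backbone"))
  if (any(model$residues$label == "loop"))
    stop("hairpins already closed")
  spec <- model$spec
  n <- spec$n_strands
  loop_lengths <- as.integer(rep_len(loop_lengths, n - 1L))
  if (!all(loop_lengths %in% c(2L, 3L)))
    stop("loop_lengths must be 2 or 3 residues")
  rs <- model$residues
  ca <- model$xyz$ca
  new_rows <- list(); new_ca <- list()
  for (j in 0:(n - 1)) {
    idx <- which(rs$strand == j)
    new_rows[[length(new_rows) + 1]] <- rs[idx, ]
    new_ca[[length(new_ca) + 1]] <- ca[idx, , drop = FALSE]
    if (j == n - 1) break
    m <- loop_lengths[j + 1]
    E <- ca[idx[length(idx)], ]
    idx2 <- which(rs$strand == j + 1)
    S <- ca[idx2[1], ]
    pts <- hairpin_arc(E, S, m)
    lr <- rs[rep(idx[1], m), ]
    lr$label <- "loop"; lr$strand <- NA_integer_; lr$k <- NA_integer_
    lr$u <- NA_real_; lr$kink <- FALSE
    lr$nx <- NA_real_; lr$ny <- NA_real_
    lr$z <- pts[, 3]
    new_rows[[length(new_rows) + 1]] <- lr
    new_ca[[length(new_ca) + 1]] <- pts
  }
  rs2 <- do.call(rbind, new_rows)
  rs2$index <- seq_len(nrow(rs2))
  rownames(rs2) <- NULL
  model$residues <- rs2
  model$xyz$ca <- do.call(rbind, new_ca)
  model$stage <- "closed"
  model
}

# Analytic beta-turn placement: m loop Calpha positions on a circular
# arc through the two strand termini, bulging axially outward, with
# m + 1 equal chord segments targeting 3.6 Angstrom (never above the
# 4.1 Angstrom chain-connectivity bound).  Close termini use the major
# arc (a proper hairpin turn); distant termini fall back to the minor
# arc or, at the limit, to linear interpolation.
hairpin_arc <- function(E, S, m, target = 3.6) {
  g <- vnorm(S - E)
  if (g > (m + 1) * 4.1)
    stop("strand termini too far apart for a ", m, "-residue hairpin")
  if (g / (m + 1) >= target) {     # nearly taut: straight placement
    return(t(vapply(seq_len(m), function(i) E + i * (S - E) / (m + 1),
                    numeric(3))))
  }
  zdir <- if (mean(c(E[3], S[3])) >= 0) c(0, 0, 1) else c(0, 0, -1)
  e1 <- vunit(S - E)
  bdir <- zdir - sum(zdir * e1) * e1
  if (vnorm(bdir) < 1e-6) bdir <- c(E[1] + S[1], E[2] + S[2], 0)  # radial fallback
  bdir <- vunit(bdir)
  nseg <- m + 1
  chord_major <- function(rho)
    2 * rho * sin((2 * pi - 2 * asin(pmin(1, g / (2 * rho)))) / (2 * nseg))
  chord_minor <- function(rho)
    2 * rho * sin(2 * asin(pmin(1, g / (2 * rho))) / (2 * nseg))
  lo <- g / 2 * (1 + 1e-9)
  if (chord_major(lo) <= target) {
    hi <- 12
    while (chord_major(hi) < target) hi <- hi * 2
    rho <- stats::uniroot(function(r) chord_major(r) - target, c(lo, hi),
                          tol = 1e-10)$root
    theta <- 2 * pi - 2 * asin(pmin(1, g / (2 * rho)))
    side <- 1
  } else {
    rho <- stats::uniroot(function(r) chord_minor(r) - target,
                          c(lo, 1e4), tol = 1e-10)$root
    theta <- 2 * asin(pmin(1, g / (2 * rho)))
    side <- -1
  }
  h <- sqrt(max(rho^2 - (g / 2)^2, 0))
  ctr <- (E + S) / 2 + side * h * bdir
  aE <- atan2(sum((E - ctr) * bdir), sum((E - ctr) * e1))
  step <- theta / nseg
  t(vapply(seq_len(m), function(i) {
    ang <- aE - i * step
    ctr + rho * (cos(ang) * e1 + sin(ang) * bdir)
  }, numeric(3)))
}

#' Shear number by register traversal
#'
#' Identifies the register partner of a mid-strand reference residue on
#' each neighboring strand by nearest-Calpha pairing and accumulates the
#' register offsets (in residue ranks ordered along the membrane normal)
#' over one full circuit of the barrel, including the closure seam.  The
#' absolute value of the accumulated offset is the shear number.
#'
#' Pairing is performed on pleat-smoothed Calpha coordinates (each
#' position averaged with its two strand neighbors) so that the
#' alternating beta-pleat cannot flip a nearest-neighbor decision to a
#' diagonal partner.
#'
#' @param model a `tmb_backbone` at any stage.
#' @return integer shear number.
#' @examples
#' compute_shear(build_calpha_lattice(barrel_spec(12)))  # 14
#' @export
compute_shear <- function(model) {
  stopifnot(inherits(model, "tmb_backbone"))
  rs <- model$residues
  ca <- model$xyz$ca
  strands <- sort(unique(rs$strand[rs$label == "strand"]))
  n <- length(strands)
  if (n < 3) stop("not a closed barrel: fewer than 3 strands")
  sm <- ca
  for (j in strands) {
    idx <- which(rs$strand %in% j)
    for (ii in seq_along(idx)) {
      lo <- idx[max(ii - 1, 1)]; hi <- idx[min(ii + 1, length(idx))]
      sm[idx[ii], ] <- (ca[lo, ] + 2 * ca[idx[ii], ] + ca[hi, ]) / 4
    }
  }
  b <- model$spec$interstrand_distance
  total <- 0
  for (jj in seq_len(n)) {
    j <- strands[jj]; jn <- strands[(jj %% n) + 1]
    i1 <- which(rs$strand %in% j); i2 <- which(rs$strand %in% jn)
    o1 <- i1[order(ca[i1, 3])]; o2 <- i2[order(ca[i2, 3])]
    # register offset from every reference in the middle of strand j;
    # the median is robust to corner-local pairing ambiguity
    L1 <- length(o1)
    refs <- o1[seq(ceiling(L1 * 0.25), floor(L1 * 0.75))]
    offs <- vapply(refs, function(ref) {
      dd <- sqrt(colSums((t(sm[i2, , drop = FALSE]) - sm[ref, ])^2))
      if (min(dd) > b + 1.5) return(NA_real_)
      match(i2[which.min(dd)], o2) - match(ref, o1)
    }, numeric(1))
    if (all(is.na(offs)))
      stop("open barrel: strand ", j, " has no register partner on strand ", jn)
    total <- total + stats::median(offs, na.rm = TRUE)
  }
  as.integer(abs(total))
}
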