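#' Blueprint specification for an idealized transmembrane beta-barrel
#'
#' A `barrel_spec` collects the parameters that fully determine an
#' idealized TMB backbone: the number of beta-strands `n`, the shear
#' number `S` (register offset accumulated over one full circuit of
#' strand-to-strand hydrogen bonding), the canonical beta-sheet spacings,
#' the number of transmembrane residues per strand, the cross-section
#' shape sculpted by glycine kinks, and the beta-hairpin loop lengths.
#'
#' Designed barrels in this family follow the shear rule `S = n + 2`,
#' which is the default when `shear` is not given.  Together `n` and `S`
#' fix the barrel radius (see [barrel_radius()]) and the strand tilt
#' angle `alpha = atan2(S*a, n*b)` relative to the barrel axis.
#'
#' @param n_strands even integer number of beta-strands (8--14 are the
#'   design-family values; other even counts >= 6 are accepted with a
#'   warning).
#' @param shear nonnegative integer shear number; default `n_strands + 2`.
#' @param rise_per_residue Calpha--Calpha spacing along a strand, Angstrom
#'   (symbol `a`); must lie in \[3.2, 3.5\].
#' @param interstrand_distance spacing between hydrogen-bonded strands,
#'   Angstrom (symbol `b`); must lie in \[4.4, 4.9\].
#' @param strand_length number of transmembrane residues per strand.
#' @param cross_section one of `"cylinder"`, `"square"`, `"triangle"`,
#'   `"rectangle"`, `"oval"`.
#' @param loop_lengths beta-hairpin lengths (2 or 3 residues), recycled to
#'   the `n_strands - 1` strand connections.
#' @param kink_phi,kink_psi target backbone dihedrals (degrees) for
#'   glycine-kink residues; the defaults are the extended positive-phi
#'   conformation.
#' @return an object of class `barrel_spec`.
#' @examples
#' spec <- barrel_spec(10)          # 10 strands, shear 12
#' spec12 <- barrel_spec(12, cross_section = "square")
#' @seealso [barrel_radius()], [build_calpha_lattice()], [design_backbone()]
#' @export
barrel_spec <- function(n_strands,
                        shear = n_strands + 2,
                        rise_per_residue = 3.32,
                        interstrand_distance = 4.6,
                        strand_length = 10,
                        cross_section = c("cylinder", "square", "triangle",
                                          "rectangle", "oval"),
                        loop_lengths = 2,
                        kink_phi = 75,
                        kink_psi = -150) {
  cross_section <- match.arg(cross_section)
  n_strands <- as.integer(n_strands)
  shear <- as.integer(shear)
  if (length(n_strands) != 1L || is.na(n_strands) || n_strands < 6L ||
      n_strands %% 2L != 0L)
    stop("n_strands must be a single even integer >= 6")
  if (!n_strands %in% c(8L, 10L, 12L, 14L))
    warning("n_strands outside the design-family range {8, 10, 12, 14}")
  if (shear < 0L) stop("shear must be a nonnegative integer")
  if (rise_per_residue < 3.2 || rise_per_residue > 3.5)
    stop("rise_per_residue must lie in [3.2, 3.5] Angstrom")
  if (interstrand_distance < 4.4 || interstrand_distance > 4.9)
    stop("interstrand_distance must lie in [4.4, 4.9] Angstrom")
  if (strand_length < 6L) stop("strand_length must be at least 6 residues")
  loop_lengths <- as.integer(rep_len(loop_lengths, n_strands - 1L))
  if (!all(loop_lengths %in% c(2L, 3L)))
    stop("loop_lengths must be 2 or 3 residues")
  structure(list(
    n_strands = n_strands,
    shear = shear,
    rise_per_residue = rise_per_residue,
    interstrand_distance = interstrand_distance,
    strand_length = as.integer(strand_length),
    cross_section = cross_section,
    loop_lengths = loop_lengths,
    kink_phi = kink_phi,
    kink_psi = kink_psi
  ), class = "barrel_spec")
}

#' @export
print.barrel_spec <- function(x, ...) {
  cat(sprintf("TMB blueprint: %d strands, shear %d, %s cross-section\n",
              x$n_strands, x$shear, x$cross_section))
  cat(sprintf("  spacings a = %.2f A (rise), b = %.2f A (interstrand)\n",
              x$rise_per_residue, x$interstrand_distance))
  cat(sprintf("  strand length %d TM residues; mean barrel diameter %.1f A\n",
              x$strand_length,
              2 * barrel_radius(x$n_strands, x$shear,
                                x$rise_per_residue, x$interstrand_distance)))
  invisible(x)
}

#' Mean radius of an idealized beta-barrel
#'
#' Classical beta-barrel geometry: a barrel of `n` strands and shear
#' number `S` built from a beta-sheet with rise `a` per residue along the
#' strand and interstrand spacing `b` closes on a cylinder of
#' circumference `sqrt((S*a)^2 + (n*b)^2)`, i.e.
#' \deqn{R = \sqrt{(S a)^2 + (n b)^2} / (2\pi).}
#'
#' With the canonical spacings (`a = 3.32`, `b = 4.6` Angstrom) and the
#' family shear rule `S = n + 2` this gives mean diameters of 19.4, 22.8
#' and 26.6 Angstrom for 10-, 12- and 14-stranded barrels.
#'
#' @param n even integer number of strands (>= 8 for a closed barrel).
#' @param S nonnegative integer shear number.
#' @param a rise per residue along a strand, Angstrom.
#' @param b interstrand (hydrogen-bonding) spacing, Angstrom.
#' @return mean barrel radius in Angstrom.
#' @examples
#' 2 * barrel_radius(10, 12, 3.32, 4.6)   # ~19.4 A
#' 2 * barrel_radius(12, 14, 3.32, 4.6)   # ~23 A
#' @export
barrel_radius <- function(n, S, a = 3.32, b = 4.6) {
  if (a <= 0 || b <= 0) stop("spacings a and b must be positive")
  if (n < 8 || n %% 2 != 0) stop("n must be an even integer >= 8")
  if (S < 0) stop("shear S must be nonnegative")
  sqrt((S * a)^2 + (n * b)^2) / (2 * pi)
}

# Strand tilt angle (radians) relative to the barrel axis.
strand_tilt <- function(n, S, a, b) atan2(S * a, n * b)
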