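# Full-backbone completion from a Calpha trace.
#
# Backbone N and C atoms are placed as rigid planar trans-peptide units
# spanning consecutive Calpha positions.  Each unit is solved once for
# the observed Calpha-Calpha distance from ideal bond lengths and angles
# (Calpha-C 1.525, C-N 1.329, N-Calpha 1.458 Angstrom; Calpha-C-N
# 116.2 deg), which makes omega exactly 180 degrees by construction.
# The free parameter is the orientation of each peptide plane about its
# Calpha-Calpha axis: beta-strand residues alternate the carbonyl
# direction along the intra-wall hydrogen-bond axis (+/-90 deg from the
# wall normal, following the register parity), which lands phi/psi in
# the beta region.  A glycine kink flips the orientation of the unit
# preceding it, which mirrors the local dipeptide into the extended
# positive-phi conformation.

# Planar peptide-unit geometry for Calpha-Calpha distance d: in-plane
# offsets of C (from the first Calpha) and N (from the second), with the
# x axis along the Calpha-Calpha vector and y along the plane
# orientation vector.  Newton solve, memoized on d.
peptide_unit_2d <- local({
  cache <- new.env(parent = emptyenv())
  function(d) {
    key <- sprintf("%.6f", d)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- function(th) {
      C <- c(1.525 * cos(th[1]), 1.525 * sin(th[1]))
      N <- c(d - 1.458 * cos(th[2]), -1.458 * sin(th[2]))
      ang <- acos(sum(vunit(-C) * vunit(N - C))) * 180 / pi
      c(vnorm(C - N) - 1.329, ang - 116.2)
    }
    th <- c(0.35, 0.35)
    for (it in 1:60) {
      F <- f(th)
      if (max(abs(F)) < 1e-12) break
      J <- matrix(0, 2, 2)
      for (k in 1:2) {
        e <- c(0, 0); e[k] <- 1e-7
        J[, k] <- (f(th + e) - F) / 1e-7
      }
      th <- th - solve(J, F)
    }
    out <- list(C = c(1.525 * cos(th[1]), 1.525 * sin(th[1])),
                N = c(d - 1.458 * cos(th[2]), -1.458 * sin(th[2])))
    cache[[key]] <- out
    out
  }
})

#' Complete a Calpha model to a full backbone
#'
#' Places N, C, O and Cbeta atoms with ideal peptide geometry on the
#' Calpha trace and computes phi/psi/omega dihedrals from the resulting
#' coordinates.  All peptide bonds are planar trans units (omega = 180
#' degrees); strand residues obtain beta-region dihedrals and glycine
#' kink residues the extended positive-phi conformation.  Cbeta atoms
#' are placed for every residue (virtual for glycine kinks) with ideal
#' L-amino-acid tetrahedral geometry, which makes the side chains
#' alternate between the lumen and the lipid face.
#'
#' @param model a `tmb_backbone` with Calpha coordinates (any stage).
#' @return the model at stage `"full"`, with `$xyz$n`, `$xyz$c`,
#'   `$xyz$o`, `$xyz$cb` filled and `$phi`, `$psi`, `$omega` (degrees)
#'   attached.
#' @export
build_full_backbone <- function(model) {
  stopifnot(inherits(model, "tmb_backbone"))
  ca <- model$xyz$ca
  N <- nrow(ca)
  dca <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-N, , drop = FALSE])^2))
  if (any(dca < 2.5 | dca > 4.3))
    stop("impossible consecutive Calpha distances in trace: range ",
         paste(sprintf("%.2f", range(dca)), collapse = " - "))
  rs <- model$residues

  # chain-order pleat parity: register parity on strands, continued
  # alternation through loops
  par <- integer(N)
  for (i in seq_len(N)) {
    par[i] <- if (rs$label[i] == "strand") rs$k[i] %% 2L
              else (par[i - 1] + 1L) %% 2L
  }

  # peptide-unit frames; extended unit e = 1..N+1 spans residues
  # (e-1, e), with virtual Calpha extrapolation at the chain termini
  cav <- rbind(2 * ca[1, ] - ca[2, ], ca, 2 * ca[N, ] - ca[N - 1, ])
  frames <- vector("list", N + 1)
  for (e_i in seq_len(N + 1)) {
    A <- cav[e_i, ]; B <- cav[e_i + 1, ]
    ev <- vunit(B - A)
    ref <- wall_normal(model, e_i - 1L, (A + B) / 2)
    rp <- ref - sum(ref * ev) * ev
    if (vnorm(rp) < 0.05) rp <- vcross(ev, c(0, 0, 1))
    rp <- vunit(rp)
    frames[[e_i]] <- list(A = A, e = ev, rp = rp, cc = vcross(ev, rp),
                          p2 = peptide_unit_2d(vnorm(B - A)))
  }
  unit_atoms <- function(e_i, tau) {
    f <- frames[[e_i]]
    w <- cos(tau) * f$rp + sin(tau) * f$cc
    list(C = f$A + f$p2$C[1] * f$e + f$p2$C[2] * w,
         N = f$A + f$p2$N[1] * f$e + f$p2$N[2] * w)
  }

  # base orientation: carbonyls along the hydrogen-bond direction,
  # alternating with the register parity of the unit's first residue
  par_ext <- c(par[1], par[-N], par[N - 1])   # parity for units 1..N+1
  tau <- ifelse(par_ext == 0L, 1, -1) * pi / 2
  units <- lapply(seq_len(N + 1), function(e_i) unit_atoms(e_i, tau[e_i]))

  # glycine kinks: refine the orientations of the units flanking each
  # kink run so that the kink dihedrals land on the extended
  # positive-phi target while the neighboring residues stay beta
  tau <- refine_kink_units(model, frames, unit_atoms, units, tau, ca)
  units <- lapply(seq_len(N + 1), function(e_i) unit_atoms(e_i, tau[e_i]))

  unitC <- t(vapply(units, `[[`, numeric(3), "C"))
  unitN <- t(vapply(units, `[[`, numeric(3), "N"))

  xyz <- model$xyz
  xyz$n <- unitN[seq_len(N), , drop = FALSE]
  xyz$c <- unitC[seq_len(N) + 1L, , drop = FALSE]
  # carbonyl O bisects away from the chain
  xyz$o <- t(vapply(seq_len(N), function(i) {
    C <- xyz$c[i, ]
    dO <- -vunit(vunit(ca[i, ] - C) + vunit(unitN[i + 1, ] - C))
    C + 1.231 * dO
  }, numeric(3)))
  # ideal L Cbeta (virtual for glycine)
  xyz$cb <- t(vapply(seq_len(N), function(i) {
    u1 <- vunit(xyz$n[i, ] - ca[i, ])
    u2 <- vunit(xyz$c[i, ] - ca[i, ])
    m <- vunit(u1 + u2); nn <- vunit(vcross(u1, u2))
    ca[i, ] + 1.521 * (-0.618 * m + 0.786 * nn) / vnorm(-0.618 * m + 0.786 * nn)
  }, numeric(3)))
  model$xyz <- xyz

  model$phi <- c(NA_real_, vapply(2:N, function(i)
    dihedral_angle(xyz$c[i - 1, ], xyz$n[i, ], ca[i, ], xyz$c[i, ]),
    numeric(1)))
  model$phi[1] <- dihedral_angle(unitC[1, ], xyz$n[1, ], ca[1, ], xyz$c[1, ])
  model$psi <- vapply(seq_len(N), function(i)
    dihedral_angle(xyz$n[i, ], ca[i, ], xyz$c[i, ], unitN[i + 1, ]),
    numeric(1))
  model$omega <- c(vapply(seq_len(N - 1), function(i)
    dihedral_angle(ca[i, ], xyz$c[i, ], xyz$n[i + 1, ], ca[i + 1, ]),
    numeric(1)), NA_real_)
  model$stage <- "full"
  model
}

# Deterministic local refinement of peptide-plane orientations around
# glycine kinks.  For each contiguous kink run the orientation angles of
# the flanking units are optimized (multi-start Nelder-Mead over a small
# number of axis-aligned starting patterns) so that the kink residues
# reach the extended positive-phi target dihedrals while the bordering
# non-kink residues stay at their beta-sheet values.
refine_kink_units <- function(model, frames, unit_atoms, units, tau, ca) {
  rs <- model$residues
  N <- nrow(ca)
  kinks <- which(rs$kink)
  if (length(kinks) == 0) return(tau)
  phi_t <- model$spec$kink_phi
  psi_t <- model$spec$kink_psi

  get_phi <- function(u, r) dihedral_angle(u[[r]]$C, u[[r]]$N, ca[r, ],
                                           u[[r + 1]]$C)
  get_psi <- function(u, r) dihedral_angle(u[[r]]$N, ca[r, ],
                                           u[[r + 1]]$C, u[[r + 1]]$N)
  base_phi <- vapply(seq_len(N), function(r) get_phi(units, r), numeric(1))
  base_psi <- vapply(seq_len(N), function(r) get_psi(units, r), numeric(1))

  runs <- split(kinks, cumsum(c(1, diff(kinks) != 1)))
  for (run in runs) {
    r0 <- run[1]; r1 <- run[length(run)]
    ue <- max(1, r0):min(N + 1, r1 + 1)      # free unit indices (e-space)
    nb <- setdiff(intersect(c(r0 - 1, r1 + 1), seq_len(N)), kinks)
    obj <- function(tv) {
      u <- units
      for (ii in seq_along(ue)) u[[ue[ii]]] <- unit_atoms(ue[ii], tv[ii])
      err <- 0
      for (r in run)
        err <- err + ang_diff(get_phi(u, r), phi_t)^2 +
                     ang_diff(get_psi(u, r), psi_t)^2
      for (r in nb)
        err <- err + 0.5 * (ang_diff(get_phi(u, r), base_phi[r])^2 +
                            ang_diff(get_psi(u, r), base_psi[r])^2)
      err
    }
    starts <- as.matrix(expand.grid(rep(list(c(-pi / 2, pi / 2)),
                                        length(ue))))
    starts <- rbind(starts, tau[ue])
    best <- NULL
    for (si in seq_len(nrow(starts))) {
      o <- stats::optim(starts[si, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
      if (is.null(best) || o$value < best$value) best <- o
    }
    tau[ue] <- best$par
    for (ii in seq_along(ue))
      units[[ue[ii]]] <- unit_atoms(ue[ii], best$par[ii])
  }
  tau
}

# Outward wall-normal reference for the peptide unit starting at chain
# position i (0 = virtual pre-terminal unit).  Strand residues use the
# cross-section normal stored at sculpt time; loops and termini fall
# back to the radial direction from the barrel axis.
wall_normal <- function(model, i, mid) {
  rs <- model$residues
  if (i >= 1 && i <= nrow(rs) && rs$label[i] == "strand" &&
      !is.na(rs$nx[i])) {
    return(c(rs$nx[i], rs$ny[i], 0))
  }
  r <- c(mid[1], mid[2], 0)
  if (vnorm(r) < 1e-6) r <- c(1, 0, 0)
  vunit(r)
}

#' Generate a complete designed barrel backbone
#'
#' Runs the full backbone-design pipeline: Calpha lattice, glycine-kink
#' placement for the requested cross-section, sculpting, beta-hairpin
#' closure and full-backbone completion.
#'
#' @param spec a [barrel_spec()], or an integer strand count which is
#'   passed to [barrel_spec()] with the remaining arguments.
#' @param ... forwarded to [barrel_spec()] when `spec` is a strand count.
#' @return a full-atom (backbone) `tmb_backbone`.
#' @examples
#' m <- design_backbone(barrel_spec(12, cross_section = "square"))
#' compute_shear(m)   # 14
#' @export
design_backbone <- function(spec, ...) {
  if (!inherits(spec, "barrel_spec")) spec <- barrel_spec(spec, ...)
  model <- build_calpha_lattice(spec)
  km <- place_glycine_kinks(spec)
  model <- sculpt_cross_section(model, km)
  model <- close_hairpins(model)
  build_full_backbone(model)
}

#' @export
print.tmb_backbone <- function(x, ...) {
  rs <- x$residues
  cat(sprintf("TMB backbone (%s): %d residues, %d strands, %s cross-section\n",
              x$stage, nrow(rs),
              length(unique(rs$strand[rs$label == "strand"])),
              x$spec$cross_section))
  cat(sprintf("  %d loop residues, %d glycine kinks, TM z-range %.1f..%.1f A\n",
              sum(rs$label == "loop"), sum(rs$kink),
              x$tm_z[1], x$tm_z[2]))
  invisible(x)
}

#' @export
summary.tmb_backbone <- function(object, ...) {
  ca <- ca_coords(object, tm_only = TRUE)
  r <- sqrt(rowSums(ca[, 1:2]^2))
  out <- list(
    n_residues = nrow(object$residues),
    n_kinks = sum(object$residues$kink),
    mean_diameter = 2 * mean(r),
    shear = tryCatch(compute_shear(object), error = function(e) NA_integer_),
    stage = object$stage
  )
  class(out) <- "summary.tmb_backbone"
  out
}

#' @export
print.summary.tmb_backbone <- function(x, ...) {
  cat(sprintf(paste0("TMB backbone summary: %d residues, %d kinks, ",
                     "mean TM diameter %.1f A, shear %s\n"),
              x$n_residues, x$n_kinks, x$mean_diameter,
              ifelse(is.na(x$shear), "?", x$shear)))
  invisible(x)
}
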