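# Lumen packing-strain proxy.
#
# Cylindrical beta-sheet configurations are strained because the side
# chains packing the barrel lumen converge and repel; glycine kinks
# relieve this by flattening the wall into faces.  The proxy scores each
# lumen-facing Cbeta by a soft truncated inverse-power repulsion summed
# over its lumen-facing neighbors:
#   s_ij = (r0 / r_ij)^12 - 1   for r_ij < r0,   0 otherwise
# with r0 = 5.5 Angstrom.  Kink columns and their immediate register
# neighbors are excluded: glycine kinks carry no side chain, and the
# corner positions flanking them are small-residue territory by the
# patterning rules, so their virtual Cbeta contacts do not represent
# side-chain packing.  This is a geometric stand-in, not a force field:
# only the ordering between cross-section variants is meaningful.

#' Lumen repulsion strain proxy
#'
#' @param model a full-backbone `tmb_backbone` (Cbeta present).
#' @param envs optional [classify_facing()] result.
#' @param cutoff truncation radius r0 in Angstrom (default 5.5).
#' @return a `strain_report` list: `per_residue` (nonnegative scores,
#'   one per residue; zero for non-lumen and kink positions) and
#'   `total`.
#' @examples
#' cyl <- design_backbone(barrel_spec(12, cross_section = "cylinder"))
#' sq  <- design_backbone(barrel_spec(12, cross_section = "square"))
#' strain_proxy(cyl)$total >= strain_proxy(sq)$total   # TRUE
#' @export
strain_proxy <- function(model, envs = classify_facing(model), cutoff = 5.5) {
  stopifnot(inherits(model, "tmb_backbone"))
  if (is.null(model$xyz$cb)) stop("strain proxy needs Cbeta atoms")
  N <- nrow(model$residues)
  lum <- which(envs$facing == "lumen" & !model$residues$kink &
               !envs$near_kink)
  per <- numeric(N)
  if (length(lum) > 1) {
    cb <- model$xyz$cb[lum, , drop = FALSE]
    D <- as.matrix(stats::dist(cb))
    S <- ifelse(D < cutoff & D > 0, (cutoff / D)^12 - 1, 0)
    diag(S) <- 0
    per[lum] <- rowSums(S)
  }
  structure(list(per_residue = per, total = sum(per)),
            class = "strain_report")
}

#' @export
print.strain_report <- function(x, ...) {
  cat(sprintf("Lumen strain proxy: total %.1f over %d contributing residues\n",
              x$total, sum(x$per_residue > 0)))
  invisible(x)
}
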