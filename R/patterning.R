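# Rule-based sequence patterning for designed TMB nanopores.
#
# The patterning logic operationalizes the design rules for
# water-accessible barrels: a polar lumen organized around
# Tyr-Gly-Asp/Glu folding motifs that pin the beta-register, interrupted
# by patches of small disorder-promoting residues (local secondary
# structure frustration) so that no strand carries a long uninterrupted
# beta-optimal segment; a hydrophobic lipid-facing surface that admits
# Ser/Thr next to glycine kinks (where the hydroxyl can hydrogen-bond
# the bent strand backbone) and charged residues only in the membrane
# interface band.

#' Classify residue environments on a barrel backbone
#'
#' Labels each residue as lumen-facing, lipid-facing or loop.  A strand
#' residue faces the lumen iff its Calpha-to-Cbeta vector has a negative
#' component along the local outward wall normal (the cross-section
#' normal for generated models, the radial direction from the barrel
#' axis otherwise).  Also records the axial position and whether the
#' residue sits within one register step of a glycine-kink column.
#'
#' @param model a full-backbone `tmb_backbone` (Cbeta atoms required).
#' @return a data frame of class `residue_env` with columns `index`,
#'   `facing`, `z`, `near_kink`, `strand`.
#' @export
classify_facing <- function(model) {
  stopifnot(inherits(model, "tmb_backbone"))
  if (is.null(model$xyz$cb))
    stop("Cbeta atoms missing: run build_full_backbone() first")
  rs <- model$residues
  N <- nrow(rs)
  facing <- character(N)
  vcb <- model$xyz$cb - model$xyz$ca
  for (i in seq_len(N)) {
    if (rs$label[i] == "loop") { facing[i] <- "loop"; next }
    nrm <- if (!is.na(rs$nx[i])) c(rs$nx[i], rs$ny[i], 0) else {
      p <- model$xyz$ca[i, ]
      vunit(c(p[1], p[2], 0))
    }
    facing[i] <- if (sum(vcb[i, ] * nrm) < 0) "lumen" else "lipid"
  }
  # near-kink: within one register step of a kink column (same-strand
  # register neighbors of a kink, or circumferentially adjacent to a
  # kink column)
  near <- rep(FALSE, N)
  kk <- which(rs$kink)
  if (length(kk)) {
    spec <- model$spec
    ustep <- spec$rise_per_residue^2 * spec$shear / barrel_circumference(spec)
    C <- barrel_circumference(spec)
    for (i in seq_len(N)) {
      if (rs$label[i] == "loop") next
      same <- kk[rs$strand[kk] == rs$strand[i]]
      if (length(same) && any(abs(rs$k[same] - rs$k[i]) <= 1)) near[i] <- TRUE
      du <- abs(((rs$u[kk] - rs$u[i] + C / 2) %% C) - C / 2)
      if (any(du <= 1.2 * ustep)) near[i] <- TRUE
    }
  }
  out <- data.frame(index = rs$index, facing = facing, z = rs$z,
                    near_kink = near, strand = rs$strand)
  class(out) <- c("residue_env", "data.frame")
  out
}

# Register partner of residue i on a neighboring strand, by nearest
# pleat-smoothed Calpha (same pairing rule as compute_shear()).
register_partner <- function(model, i, strand_to) {
  rs <- model$residues
  ca <- model$xyz$ca
  idx <- which(rs$strand %in% strand_to)
  sm_i <- smooth_ca(model, i)
  dd <- vapply(idx, function(q) vnorm(smooth_ca(model, q) - sm_i), numeric(1))
  idx[which.min(dd)]
}

smooth_ca <- function(model, i) {
  rs <- model$residues; ca <- model$xyz$ca
  idx <- which(rs$strand %in% rs$strand[i])
  ii <- match(i, idx)
  lo <- idx[max(ii - 1, 1)]; hi <- idx[min(ii + 1, length(idx))]
  (ca[lo, ] + 2 * ca[i, ] + ca[hi, ]) / 4
}

#' Assign per-position amino-acid constraints
#'
#' Emits rule-based allowed amino-acid sets for every residue of a
#' designed barrel:
#' \itemize{
#'   \item glycine kinks are constrained to exactly `G`;
#'   \item one Tyr-Gly-Asp/Glu folding-motif triad is placed per
#'     adjacent-strand interface where geometry permits (Tyr lumen-facing,
#'     Gly its cross-strand register partner, Asp/Glu the neighboring
#'     lumen position on the partner strand, all Calpha pairs within
#'     8 Angstrom);
#'   \item remaining lumen positions carry polar-network sets, broken by
#'     frustration patches of small disorder-promoting residues
#'     (`G`/`A`/`S`) spaced so no beta-optimal run exceeds `max_run`
#'     residues, plus a bounded seeded fraction of hydrophobic-in-lumen
#'     positions;
#'   \item lipid-facing positions carry the hydrophobic surface set, with
#'     Ser/Thr added next to kinks and charged residues allowed only in
#'     the membrane interface band;
#'   \item loop residues carry a turn-favoring set.
#' }
#'
#' @param model a full-backbone `tmb_backbone`.
#' @param envs result of [classify_facing()]; computed if missing.
#' @param seed integer seed controlling the hydrophobic-in-lumen draw.
#' @param hydrophobic_frac maximum fraction of non-motif lumen positions
#'   assigned hydrophobic-in-lumen sets (default 0.15).
#' @param max_run audit threshold: maximum allowed run of beta-optimal
#'   residues per strand (default 6).
#' @param interface_band width (Angstrom) of the membrane interface band
#'   in which charged residues are allowed on the lipid face (default 3).
#' @return a data frame of class `sequence_constraints` with columns
#'   `index`, `facing`, `allowed`, `tag`; motif triads are attached as
#'   `attr(, "motifs")`.
#' @export
assign_pattern <- function(model, envs = classify_facing(model), seed = 1,
                           hydrophobic_frac = 0.15, max_run = 6,
                           interface_band = 3) {
  stopifnot(inherits(model, "tmb_backbone"))
  rs <- model$residues
  N <- nrow(rs)
  allowed <- character(N)
  tag <- character(N)

  half_span <- max(abs(model$tm_z))

  # (i) kinks
  kk <- which(rs$kink)
  allowed[kk] <- "G"; tag[kk] <- "kink"

  # (ii) folding motifs, one per strand interface where permitted
  motifs <- list()
  strands <- sort(unique(rs$strand[rs$label == "strand"]))
  n <- length(strands)
  ca <- model$xyz$ca
  for (jj in seq_len(n)) {
    j <- strands[jj]; jn <- strands[(jj %% n) + 1]
    cand <- which(rs$strand %in% j & envs$facing == "lumen" &
                  allowed == "")
    cand <- cand[order(abs(rs$z[cand]))]
    placed <- FALSE
    for (y in cand) {
      g <- register_partner(model, y, jn)
      # the cross-strand glycine may coincide with a glycine kink
      g_ok <- (allowed[g] == "" && envs$facing[g] == "lumen") ||
              allowed[g] == "G"
      if (!g_ok) next
      # neighboring lumen slot on the partner strand, two registers away
      idx2 <- which(rs$strand %in% jn)
      de_cand <- idx2[!is.na(rs$k[idx2]) & abs(rs$k[idx2] - rs$k[g]) == 2 &
                      envs$facing[idx2] == "lumen"]
      de_cand <- de_cand[allowed[de_cand] == ""]
      if (!length(de_cand)) next
      dmax <- vapply(de_cand, function(de)
        max(vnorm(ca[y, ] - ca[g, ]), vnorm(ca[y, ] - ca[de, ]),
            vnorm(ca[g, ] - ca[de, ])), numeric(1))
      de <- de_cand[which.min(dmax)]
      if (min(dmax) >= 8) next
      allowed[y] <- "Y"; tag[y] <- "motif"
      allowed[g] <- "G"; tag[g] <- "motif"
      allowed[de] <- "DE"; tag[de] <- "motif"
      motifs[[length(motifs) + 1]] <-
        list(interface = c(j, jn), tyr = y, gly = g, asp_glu = de)
      placed <- TRUE
      break
    }
    if (!placed)
      warning("no geometrically valid folding-motif site on strand pair ",
              j, "-", jn)
  }

  # (iii) frustration patches: walk each strand and break any
  # beta-optimal run before it exceeds max_run residues
  breaks_run <- function(i) allowed[i] != "" &&
    all(strsplit(allowed[i], "")[[1]] %in% c("G", "A", "S"))
  for (j in strands) {
    idx <- which(rs$strand %in% j)
    run <- 0L; last_patchable <- NA_integer_
    for (i in idx) {
      if (breaks_run(i)) { run <- 0L; last_patchable <- NA_integer_; next }
      run <- run + 1L
      if (allowed[i] == "" && envs$facing[i] == "lumen")
        last_patchable <- i
      if (run >= max_run && !is.na(last_patchable)) {
        allowed[last_patchable] <- "GAS"
        tag[last_patchable] <- "frustration"
        run <- sum(idx > last_patchable & idx <= i)
        last_patchable <- NA_integer_
      }
    }
  }

  # hydrophobic-in-lumen positions (seeded, bounded fraction)
  free_lumen <- which(allowed == "" & envs$facing == "lumen")
  n_hyd <- floor(hydrophobic_frac * length(free_lumen))
  if (n_hyd > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    hyd <- sort(sample(free_lumen, n_hyd))
    .Random.seed_restore(old)
    allowed[hyd] <- "AVLM"; tag[hyd] <- "frustration-hydrophobic"
  }

  # remaining lumen: polar network
  rest <- which(allowed == "" & envs$facing == "lumen")
  allowed[rest] <- "DENQSTRKHY"; tag[rest] <- "polar-network"

  # (iv) lipid face
  lip <- which(allowed == "" & envs$facing == "lipid")
  for (i in lip) {
    aa <- "AVILFMWY"
    if (envs$near_kink[i]) aa <- paste0(aa, "ST")
    if (abs(rs$z[i]) > half_span - interface_band) aa <- paste0(aa, "DEKR")
    allowed[i] <- aa
    tag[i] <- "lipid"
  }

  # loops: turn-favoring set
  lp <- which(allowed == "" & envs$facing == "loop")
  allowed[lp] <- "GNDSTP"; tag[lp] <- "loop"

  stopifnot(all(allowed != ""))
  out <- data.frame(index = rs$index, facing = envs$facing,
                    allowed = allowed, tag = tag)
  attr(out, "motifs") <- motifs
  class(out) <- c("sequence_constraints", "data.frame")
  out
}

# save/restore the RNG state so seeded draws do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Audit local secondary-structure frustration
#'
#' Computes, per strand, the fraction of frustration positions (allowed
#' sets restricted to small disorder-promoting residues `G`/`A`/`S`) and
#' the longest run of beta-optimal residues; strands whose longest run
#' exceeds `max_run` are flagged as aggregation-prone.  An all-polar
#' "optimal" lumen assignment flags every strand; the default
#' [assign_pattern()] output flags none.
#'
#' @param constraints a `sequence_constraints` data frame.
#' @param envs matching [classify_facing()] result.
#' @param max_run flag threshold on the longest beta-optimal run
#'   (residues; default 6).
#' @return data frame with one row per strand: `strand`,
#'   `frustration_frac`, `longest_run`, `flagged`.
#' @export
frustration_audit <- function(constraints, envs, max_run = 6) {
  stopifnot(inherits(constraints, "sequence_constraints"))
  brk <- vapply(seq_len(nrow(constraints)), function(i)
    all(strsplit(constraints$allowed[i], "")[[1]] %in% c("G", "A", "S")),
    logical(1))
  strands <- sort(unique(envs$strand[!is.na(envs$strand)]))
  out <- do.call(rbind, lapply(strands, function(j) {
    idx <- which(envs$strand %in% j)
    b <- brk[idx]
    runs <- rle(!b)
    longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    data.frame(strand = j,
               frustration_frac = mean(b),
               longest_run = longest,
               flagged = longest > max_run)
  }))
  rownames(out) <- NULL
  out
}

#' Sample a concrete sequence from constraints
#'
#' Draws one amino acid uniformly from each position's allowed set.
#' This is a fixture generator, not a sequence optimizer.
#'
#' @param constraints a `sequence_constraints` data frame.
#' @param seed integer seed.
#' @return character vector of one-letter codes (length = positions).
#' @export
sample_sequence <- function(constraints, seed = 1) {
  stopifnot(inherits(constraints, "sequence_constraints"))
  old <- .Random.seed_save()
  set.seed(seed)
  seq <- vapply(constraints$allowed, function(a) {
    ch <- strsplit(a, "")[[1]]
    ch[sample.int(length(ch), 1)]
  }, character(1), USE.NAMES = FALSE)
  .Random.seed_restore(old)
  seq
}
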