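# Lazily built, cached design models shared across test files.
.model_cache <- new.env(parent = emptyenv())

get_model <- function(n, shape = "cylinder") {
  key <- paste0(n, "_", shape)
  if (is.null(.model_cache[[key]]))
    .model_cache[[key]] <- design_backbone(barrel_spec(n, cross_section = shape))
  .model_cache[[key]]
}

# Independent register-traversal oracle: explicit partner-graph
# traversal with modal per-interface offsets, written without reusing
# any compute_shear() internals.
oracle_shear <- function(model) {
  rs <- model$residues
  ca <- model$xyz$ca
  strands <- sort(unique(rs$strand[rs$label == "strand"]))
  n <- length(strands)
  # de-pleat by averaging each residue with its strand neighbors
  dep <- ca
  for (j in strands) {
    idx <- which(rs$strand %in% j)
    P <- ca[idx, , drop = FALSE]
    Q <- P
    for (q in seq_len(nrow(P))) {
      w <- unique(pmax(1, pmin(nrow(P), (q - 1):(q + 1))))
      Q[q, ] <- colMeans(P[w, , drop = FALSE]) * 0.5 + P[q, ] * 0.5
    }
    dep[idx, ] <- Q
  }
  total <- 0
  for (jj in seq_len(n)) {
    j <- strands[jj]; jn <- strands[(jj %% n) + 1]
    i1 <- which(rs$strand %in% j); i2 <- which(rs$strand %in% jn)
    r1 <- rank(ca[i1, 3]); r2 <- rank(ca[i2, 3])
    offs <- c()
    for (q in seq_along(i1)[r1 > 2 & r1 < length(i1) - 1]) {
      dd <- sqrt(colSums((t(dep[i2, , drop = FALSE]) - dep[i1[q], ])^2))
      offs <- c(offs, r2[which.min(dd)] - r1[q])
    }
    ux <- unique(offs)
    total <- total + ux[which.max(tabulate(match(offs, ux)))]
  }
  as.integer(abs(total))
}
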