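test_that("facing alternates along ideal strands and splits the wall evenly", {
  m <- get_model(10)
  envs <- classify_facing(m)
  rs <- m$residues
  tm <- envs$facing != "loop"
  # roughly half the TM residues face the lumen
  expect_lt(abs(sum(envs$facing[tm] == "lumen") - sum(tm) / 2),
            m$spec$n_strands)
  # strict alternation on the kink-free cylinder (interior positions;
  # the turn-flanking terminal residues take their frames from the
  # loops and may break parity)
  for (j in 0:9) {
    f <- envs$facing[which(rs$strand %in% j)]
    f <- f[2:(length(f) - 1)]
    expect_true(all(f[-1] != f[-length(f)]),
                label = paste("alternation strand", j))
  }
  # loop residues are labeled loop and never near a kink
  expect_true(all(envs$facing[rs$label == "loop"] == "loop"))
  expect_true(all(!envs$near_kink[rs$label == "loop"]))
})

test_that("facing classification is invariant under rigid rotation", {
  m <- get_model(10)
  envs <- classify_facing(m)
  th <- 1.1
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mr <- m
  mr$xyz <- lapply(m$xyz, function(x) if (is.null(x)) NULL else x %*% t(Rz))
  nrm <- cbind(m$residues$nx, m$residues$ny, 0) %*% t(Rz)
  mr$residues$nx <- nrm[, 1]; mr$residues$ny <- nrm[, 2]
  expect_identical(classify_facing(mr)$facing, envs$facing)
})

test_that("register partners across the barrel share lumen facing", {
  m <- get_model(10)
  envs <- classify_facing(m)
  rs <- m$residues
  lum <- which(envs$facing == "lumen" & rs$strand %in% 0)
  for (i in lum[2:4]) {
    p <- tmbarrel:::register_partner(m, i, 1)
    # oracle: explicit radial component of the partner's CA->CB vector
    vcb <- m$xyz$cb[p, ] - m$xyz$ca[p, ]
    nrm <- c(rs$nx[p], rs$ny[p], 0)
    expect_lt(sum(vcb * nrm), 0)
    expect_identical(envs$facing[p], "lumen")
  }
})

test_that("kink positions are constrained to glycine only", {
  m <- get_model(12, "square")
  cons <- suppressWarnings(assign_pattern(m))
  kk <- which(m$residues$kink)
  expect_true(all(cons$allowed[kk] == "G"))
})

test_that("folding motifs contain Tyr, Gly and Asp/Glu and verify geometrically", {
  m <- get_model(12, "square")
  cons <- suppressWarnings(assign_pattern(m))
  motifs <- attr(cons, "motifs")
  # motifs are placed on at least half the strand interfaces
  expect_gte(length(motifs), m$spec$n_strands / 2)
  ca <- m$xyz$ca
  for (mo in motifs) {
    expect_identical(cons$allowed[mo$tyr], "Y")
    expect_identical(cons$allowed[mo$gly], "G")
    expect_true(cons$allowed[mo$asp_glu] %in% c("DE"))
    ps <- rbind(ca[mo$tyr, ], ca[mo$gly, ], ca[mo$asp_glu, ])
    expect_lt(max(dist(ps)), 8)
  }
  # the kink-free cylinder sites a motif on every interface
  m10 <- get_model(10)
  cons10 <- assign_pattern(m10)
  expect_identical(length(attr(cons10, "motifs")), 10L)
})

test_that("lipid-facing positions follow the surface rules", {
  m <- get_model(12, "square")
  envs <- classify_facing(m)
  cons <- suppressWarnings(assign_pattern(m, envs))
  lip <- which(cons$tag == "lipid")
  half <- max(abs(m$tm_z))
  for (i in lip) {
    aa <- strsplit(cons$allowed[i], "")[[1]]
    if (envs$near_kink[i]) {
      expect_true(all(c("S", "T") %in% aa))
    } else if (abs(m$residues$z[i]) <= half - 3) {
      # core lipid face: hydrophobic only, no charges, no Ser/Thr
      expect_true(all(aa %in% strsplit("AVILFMWY", "")[[1]]))
    }
  }
})

test_that("patterning is reproducible and never leaves a position empty", {
  m <- get_model(12, "square")
  envs <- classify_facing(m)
  c1 <- suppressWarnings(assign_pattern(m, envs, seed = 42))
  c2 <- suppressWarnings(assign_pattern(m, envs, seed = 42))
  expect_identical(c1, c2)
  expect_true(all(nchar(c1$allowed) >= 1))
  c3 <- suppressWarnings(assign_pattern(m, envs, seed = 43))
  expect_false(identical(c1$allowed, c3$allowed))
})

test_that("the default assignment audits clean, an all-polar lumen does not", {
  m <- get_model(12, "square")
  envs <- classify_facing(m)
  cons <- suppressWarnings(assign_pattern(m, envs))
  aud <- frustration_audit(cons, envs)
  expect_identical(sum(aud$flagged), 0L)
  # "optimal" design: polar lumen, hydrophobic exterior, no patches
  opt <- cons
  opt$allowed <- ifelse(opt$facing == "lumen", "DENQ",
                        ifelse(opt$facing == "lipid", "AVILF", "G"))
  aud_opt <- frustration_audit(opt, envs)
  expect_true(all(aud_opt$flagged))
})

test_that("audit accounting matches the per-position categories", {
  m <- get_model(10)
  envs <- classify_facing(m)
  cons <- assign_pattern(m, envs)
  aud <- frustration_audit(cons, envs)
  rs <- m$residues
  for (j in aud$strand) {
    idx <- which(envs$strand %in% j)
    brk <- vapply(idx, function(i)
      all(strsplit(cons$allowed[i], "")[[1]] %in% c("G", "A", "S")),
      logical(1))
    expect_equal(aud$frustration_frac[aud$strand == j], mean(brk))
  }
})

test_that("denser frustration patches never increase the audit flag count", {
  m <- get_model(10)
  envs <- classify_facing(m)
  flags <- vapply(c(3, 4, 6, 9, 20), function(run) {
    cons <- suppressWarnings(assign_pattern(m, envs, max_run = run))
    sum(frustration_audit(cons, envs, max_run = 6)$flagged)
  }, numeric(1))
  expect_true(all(diff(flags) >= 0))
})

test_that("sampled sequences respect constraints and the seed", {
  m <- get_model(12, "square")
  cons <- suppressWarnings(assign_pattern(m))
  s1 <- sample_sequence(cons, seed = 7)
  s2 <- sample_sequence(cons, seed = 7)
  expect_identical(s1, s2)
  ok <- mapply(function(a, s) grepl(s, a, fixed = TRUE), cons$allowed, s1)
  expect_true(all(ok))
})
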