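# Structure, blueprint and configuration I/O.

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

#' Write a backbone model as PDB
#'
#' Emits standard ATOM records (chain A, 1-based residue numbering,
#' occupancy 1.00, element column set) for the backbone atoms N, CA, C,
#' O and CB.  The virtual Cbeta of glycine residues is omitted.
#'
#' @param model a full-backbone `tmb_backbone`.
#' @param path output file.
#' @param sequence optional one-letter sequence (length = residues);
#'   defaults to alanine with glycine at kinks and loops.
#' @return the path, invisibly.
#' @export
write_pdb <- function(model, path, sequence = NULL) {
  stopifnot(inherits(model, "tmb_backbone"))
  if (is.null(model$xyz$n)) stop("write_pdb needs a full backbone model")
  rs <- model$residues
  N <- nrow(rs)
  if (is.null(sequence)) {
    sequence <- ifelse(rs$kink | rs$label == "loop", "G", "A")
  }
  stopifnot(length(sequence) == N)
  res3 <- .aa3[sequence]
  atn <- c("N", "CA", "C", "O", "CB")
  mats <- list(model$xyz$n, model$xyz$ca, model$xyz$c, model$xyz$o,
               model$xyz$cb)
  ele <- c("N", "C", "C", "O", "C")
  rows <- list()
  for (i in seq_len(N)) {
    for (a in seq_along(atn)) {
      if (atn[a] == "CB" && sequence[i] == "G") next
      rows[[length(rows) + 1]] <- data.frame(
        elety = atn[a], resid = res3[i], resno = i,
        x = mats[[a]][i, 1], y = mats[[a]][i, 2], z = mats[[a]][i, 3],
        elesy = ele[a])
    }
  }
  df <- do.call(rbind, rows)
  na <- nrow(df)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(df[, c("x", "y", "z")]))),
                   resno = df$resno, resid = df$resid, elety = df$elety,
                   chain = rep("A", na), o = rep(1.00, na),
                   b = rep(0.00, na), elesy = df$elesy)
  invisible(path)
}

#' Read a structure from PDB
#'
#' Parses ATOM records into an atom table suitable for
#' [profile_pore()]; Cbeta atoms missing from glycine (or Calpha-only)
#' records are left absent.  A file with no ATOM records yields an empty
#' table with a warning.
#'
#' @param path PDB file.
#' @return data frame of class `atom_set` with columns `atom`, `resid`,
#'   `resno`, `chain`, `x`, `y`, `z`, `element`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  at <- grep("^ATOM", lines)
  for (ln in at) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[ln], 31, 38),
                                         substr(lines[ln], 39, 46),
                                         substr(lines[ln], 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM record at line ", ln, " of ", path)
  }
  if (!length(at)) {
    warning("no ATOM records in ", path)
    out <- data.frame(atom = character(), resid = character(),
                      resno = integer(), chain = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      element = character())
    class(out) <- c("atom_set", "data.frame")
    return(out)
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom[pdb$atom$type == "ATOM", ]
  el <- a$elesy
  miss <- is.na(el) | el == ""
  el[miss] <- substr(gsub("[0-9]", "", a$elety[miss]), 1, 1)
  out <- data.frame(atom = a$elety, resid = a$resid, resno = a$resno,
                    chain = a$chain, x = a$x, y = a$y, z = a$z,
                    element = el)
  class(out) <- c("atom_set", "data.frame")
  out
}

#' Write / read a design blueprint
#'
#' One line per residue: `index`, strand label (`S<j>` or `loop`),
#' secondary-structure code (`E` strand / `L` loop), kink flag (0/1);
#' header lines carry `n`, `shear` and `shape`.
#'
#' @param model a `tmb_backbone`.
#' @param path file path.
#' @return `write_blueprint` the path; `read_blueprint` a data frame
#'   with attributes `n`, `shear`, `shape`.
#' @export
write_blueprint <- function(model, path) {
  stopifnot(inherits(model, "tmb_backbone"))
  rs <- model$residues
  hdr <- c(sprintf("# n\t%d", model$spec$n_strands),
           sprintf("# shear\t%d", model$spec$shear),
           sprintf("# shape\t%s", model$spec$cross_section))
  body <- sprintf("%d\t%s\t%s\t%d", rs$index,
                  ifelse(rs$label == "loop", "loop",
                         paste0("S", rs$strand)),
                  ifelse(rs$label == "loop", "L", "E"),
                  as.integer(rs$kink))
  writeLines(c(hdr, "# index\tstrand\tss\tkink", body), path)
  invisible(path)
}

#' @rdname write_blueprint
#' @export
read_blueprint <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) sub(".*\t", "", grep(paste0("^# ", key, "\t"),
                                             hdr, value = TRUE)[1])
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                           col.names = c("index", "strand", "ss", "kink"))
  dat$kink <- as.logical(dat$kink)
  attr(dat, "n") <- as.integer(getv("n"))
  attr(dat, "shear") <- as.integer(getv("shear"))
  attr(dat, "shape") <- getv("shape")
  dat
}

#' Write / read sequence constraints
#'
#' Tab-separated, one line per position: `index`, `facing`, allowed
#' amino-acid string, annotation tag.
#'
#' @param constraints a `sequence_constraints` data frame.
#' @param path file path.
#' @export
write_constraints <- function(constraints, path) {
  writeLines(c("# index\tfacing\tallowed\ttag",
               sprintf("%d\t%s\t%s\t%s", constraints$index,
                       constraints$facing, constraints$allowed,
                       constraints$tag)), path)
  invisible(path)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(path) {
  lines <- readLines(path)
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                           col.names = c("index", "facing", "allowed", "tag"),
                           colClasses = c("integer", "character",
                                          "character", "character"))
  class(dat) <- c("sequence_constraints", "data.frame")
  dat
}

#' Write sequences as FASTA
#'
#' @param sequences named list (or character vector) of one-letter
#'   sequences.
#' @param path file path.
#' @param width line wrap (default 60).
#' @export
write_fasta <- function(sequences, path, width = 60) {
  if (is.character(sequences) && is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    s <- paste(sequences[[nm]], collapse = "")
    writeLines(paste0(">", nm), con)
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(seq(1, nchar(s), width) + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}

#' Package configuration
#'
#' Bundles the tunable defaults of every module; serializes losslessly
#' to JSON.
#'
#' @param ... overrides of the default fields.
#' @return a `tmb_config` list.
#' @export
tmb_config <- function(...) {
  cfg <- list(
    geometry = list(rise_per_residue = 3.32, interstrand_distance = 4.6,
                    strand_length = 10L, kink_phi = 75, kink_psi = -150),
    conductance = list(length_m = 3.5e-9, salt_M = 0.5, temperature_C = 25),
    profiler = list(step = 1.0),
    ephys = list(min_step = 5, window = 0.02, k = 5),
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && nm %in% names(cfg))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "tmb_config")
}

#' @rdname tmb_config
#' @param config a `tmb_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname tmb_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$geometry$strand_length <- as.integer(cfg$geometry$strand_length)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "tmb_config")
}
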