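#' Conformer bead model
#'
#' A labelled 3D point set in Angstrom with per-point scattering weights.
#' This is the unit of conformational sampling and SAXS scoring: one bead per
#' scatterer (typically one per residue for a coarse-grained protein model).
#'
#' @param points numeric matrix with 3 columns (x, y, z) in Angstrom.
#' @param id character identifier.
#' @param weights per-point scattering weights \eqn{f_i \ge 0}; default 1.
#' @param labels optional data.frame with columns `chain`, `resno`, `resid`
#'   (one row per point).
#' @return An object of class `conformer_model` with elements `id`, `points`,
#'   `weights`, `labels`.
#' @export
conformer_model <- function(points, id = "model", weights = NULL, labels = NULL) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L || nrow(points) < 1L)
    stop("`points` must be a non-empty numeric matrix with 3 columns")
  if (!all(is.finite(points))) stop("coordinates must be finite")
  if (is.null(weights)) weights <- rep(1, nrow(points))
  weights <- as.numeric(weights)
  if (length(weights) != nrow(points)) stop("`weights` length must match number of points")
  if (any(!is.finite(weights)) || any(weights < 0)) stop("weights must be finite and >= 0")
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    stopifnot(all(c("chain", "resno", "resid") %in% names(labels)),
              nrow(labels) == nrow(points))
  }
  structure(list(id = as.character(id), points = unname(points),
                 weights = weights, labels = labels),
            class = "conformer_model")
}

#' @export
print.conformer_model <- function(x, ...) {
  cat(sprintf("<conformer_model '%s': %d beads, Rg = %.2f A>\n",
              x$id, nrow(x$points), rg_from_coords(x)))
  invisible(x)
}

n_points <- function(model) nrow(model$points)

#' Scattering curve
#'
#' A set of (q, I, sigma) triples on a strictly increasing momentum-transfer
#' grid, with \eqn{q = 4\pi \sin\theta / \lambda} in inverse Angstrom.
#' Experimental curves carry per-point uncertainties; back-calculated curves
#' may omit them.
#'
#' @param q strictly increasing, non-negative momentum transfer grid (1/A).
#' @param I intensities (arbitrary units).
#' @param sigma optional per-point uncertainties, all > 0.
#' @return An object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, I, sigma = NULL) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) < 1L || length(I) != length(q)) stop("q and I must be equal-length")
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  if (any(diff(q) <= 0)) stop("q grid must be strictly increasing")
  if (any(!is.finite(I))) stop("I must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length must match q")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("all sigma must be finite and > 0")
  }
  structure(list(q = q, I = I, sigma = sigma), class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve: %d points, q in [%.4g, %.4g] 1/A%s>\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with sigma"))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$q) == length(b$q) && all(abs(a$q - b$q) <= tol * pmax(1, abs(a$q)))
}

#' NMR peak list
#'
#' Amide (1H, 15N) chemical shifts per residue, as picked from an HSQC
#' spectrum. Residue numbers must be unique.
#'
#' @param residue integer residue numbers (unique).
#' @param name residue names (one-letter or three-letter codes, free text).
#' @param dH_ppm proton chemical shifts (ppm).
#' @param dN_ppm nitrogen chemical shifts (ppm).
#' @return An object of class `peak_list` (a data.frame).
#' @export
peak_list <- function(residue, name, dH_ppm, dN_ppm) {
  residue <- as.integer(residue)
  if (anyDuplicated(residue)) stop("duplicate residue number in peak list")
  if (any(!is.finite(dH_ppm)) || any(!is.finite(dN_ppm)))
    stop("chemical shifts must be finite")
  structure(data.frame(residue = residue, name = as.character(name),
                       dH_ppm = as.numeric(dH_ppm), dN_ppm = as.numeric(dN_ppm),
                       stringsAsFactors = FALSE),
            class = c("peak_list", "data.frame"))
}

#' RNA sequence
#'
#' @param bases character string over the alphabet ACGU. DNA-style T is
#'   normalized to U (with a message).
#' @param id identifier.
#' @return An object of class `rna_sequence` with elements `id`, `bases`.
#' @export
rna_sequence <- function(bases, id = "rna") {
  bases <- toupper(as.character(bases))
  if (length(bases) != 1L || nchar(bases) < 1L) stop("empty RNA sequence")
  if (grepl("T", bases, fixed = TRUE)) {
    message("normalizing T -> U in RNA sequence '", id, "'")
    bases <- gsub("T", "U", bases, fixed = TRUE)
  }
  if (grepl("[^ACGU]", bases)) stop("RNA sequence contains non-ACGU(T) characters")
  structure(list(id = as.character(id), bases = bases), class = "rna_sequence")
}

#' Read a bead/CA model from a PDB file
#'
#' Parses ATOM/HETATM records (first altloc kept; occupancy and B-factor
#' ignored) into a [conformer_model()]. Intended for CA-only and bead models.
#'
#' @param path PDB file path.
#' @param ca_only keep only CA atoms (default TRUE).
#' @return A [conformer_model()] with labels carrying chain/residue metadata.
#' @export
read_pdb_model <- function(path, ca_only = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path, "': ",
                                           conditionMessage(e)))
  atoms <- pdb$atom
  # keep first altloc only
  if ("alt" %in% names(atoms)) {
    keep <- is.na(atoms$alt) | atoms$alt %in% c("", "A")
    atoms <- atoms[keep, , drop = FALSE]
  }
  if (ca_only) atoms <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("no atoms left after filtering (ca_only = ", ca_only, ") in '", path, "'")
  conformer_model(
    points = cbind(atoms$x, atoms$y, atoms$z),
    id = sub("\\.pdb$", "", basename(path)),
    labels = data.frame(chain = atoms$chain, resno = atoms$resno,
                        resid = atoms$resid, stringsAsFactors = FALSE)
  )
}

#' Write a bead model as PDB ATOM records
#'
#' Coordinates are written to 3 decimals in fixed-width columns; models
#' without labels get chain "A", sequential residue numbers and residue name
#' "ALA".
#'
#' @param model a [conformer_model()].
#' @param path output file path.
#' @export
write_pdb_model <- function(model, path) {
  stopifnot(inherits(model, "conformer_model"))
  n <- n_points(model)
  if (any(abs(model$points) >= 1e4))
    stop("coordinate magnitude exceeds PDB fixed-width field (|x| >= 10000 A)")
  lab <- model$labels
  if (is.null(lab))
    lab <- data.frame(chain = rep("A", n), resno = seq_len(n),
                      resid = rep("ALA", n), stringsAsFactors = FALSE)
  bio3d::write.pdb(file = path, xyz = as.vector(t(model$points)),
                   type = rep("ATOM", n), eleno = seq_len(n),
                   elety = rep("CA", n), resid = lab$resid, chain = lab$chain,
                   resno = lab$resno, o = rep(1, n), b = rep(0, n),
                   elesy = rep("C", n))
  invisible(path)
}

#' Read a SAXS curve from whitespace-delimited ASCII
#'
#' Accepts the common beamline export dialect: optional '#'-prefixed comment
#' or non-numeric header lines, then 2 or 3 numeric columns (q, I\[, sigma\]).
#'
#' @param path file path.
#' @param q_unit `"A^-1"` (default) or `"nm^-1"`; nm^-1 grids are converted
#'   to 1/A by dividing q by 10.
#' @return A [scattering_curve()]; `sigma` populated iff a third column exists.
#' @export
read_saxs_dat <- function(path, q_unit = c("A^-1", "nm^-1")) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[[:space:]]+")
  numeric_row <- vapply(fields, function(f)
    length(f) >= 2L && !anyNA(suppressWarnings(as.numeric(f[1:2]))), logical(1))
  fields <- fields[numeric_row]
  if (length(fields) == 0L) stop("no numeric data rows in '", path, "'")
  ncols <- min(vapply(fields, length, integer(1)))
  if (ncols > 3L) ncols <- 3L
  m <- t(vapply(fields, function(f) suppressWarnings(as.numeric(f[seq_len(ncols)])),
                numeric(ncols)))
  q <- m[, 1]
  if (q_unit == "nm^-1") q <- q / 10
  if (any(diff(q) <= 0)) stop("q column is not strictly increasing in '", path, "'")
  sigma <- if (ncols == 3L) m[, 3] else NULL
  if (!is.null(sigma) && any(sigma <= 0)) stop("non-positive sigma in '", path, "'")
  scattering_curve(q, m[, 2], sigma)
}

#' Write a SAXS curve as 3-column (or 2-column) ASCII
#'
#' @param curve a [scattering_curve()].
#' @param path output path.
#' @param header optional comment written as a leading '#' line.
#' @export
write_saxs_dat <- function(curve, path, header = NULL) {
  stopifnot(inherits(curve, "scattering_curve"))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (is.null(curve$sigma)) {
    writeLines(sprintf("%.8e %.8e", curve$q, curve$I), con)
  } else {
    writeLines(sprintf("%.8e %.8e %.8e", curve$q, curve$I, curve$sigma), con)
  }
  invisible(path)
}

#' Read an amide peak list from TSV
#'
#' Expected header: `residue`, `name`, `dH_ppm`, `dN_ppm` (tab-separated).
#'
#' @param path TSV file path.
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("residue", "name", "dH_ppm", "dN_ppm")
  if (!all(need %in% names(df)))
    stop("peak list must have columns: ", paste(need, collapse = ", "))
  peak_list(df$residue, df$name, df$dH_ppm, df$dN_ppm)
}

#' Write an amide peak list as TSV
#'
#' @param peaks a [peak_list()].
#' @param path output path.
#' @export
write_peak_list <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read RNA sequences from a FASTA file
#'
#' T characters are normalized to U (a note is emitted).
#'
#' @param path FASTA file path.
#' @return A list of [rna_sequence()] objects.
#' @export
read_rna_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fa <- bio3d::read.fasta(path)
  ids <- rownames(fa$ali)
  lapply(seq_along(ids), function(i) {
    bases <- paste0(fa$ali[i, fa$ali[i, ] != "-"], collapse = "")
    rna_sequence(bases, id = ids[i])
  })
}

#' Length of a residue range, endpoints inclusive
#'
#' Small helper for construct arithmetic, e.g. a domain spanning residues
#' 56-144 contains 89 residues.
#'
#' @param first,last first and last residue numbers (1-based, inclusive).
#' @return integer count `last - first + 1`.
#' @export
residue_range_length <- function(first, last) {
  first <- as.integer(first); last <- as.integer(last)
  if (last < first) stop("last residue before first")
  last - first + 1L
}
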