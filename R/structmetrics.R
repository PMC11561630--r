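# Structural verification toolkit: least-squares superposition, NMR-ensemble
# precision, NOE restraint accounting and in-silico PCR.

#' Construct a structure ensemble
#'
#' @param coords numeric array `n_atoms x 3 x n_models` (Angstrom).
#' @param atoms data.frame with one row per atom: `resno` (1-based residue
#'   index), `elety` (atom name, e.g. "CA"), optionally `resid` (residue
#'   name). Atom ordering must be identical across models, which the array
#'   layout enforces.
#' @return object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(coords, atoms) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            nrow(atoms) == dim(coords)[1])
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  structure(list(coords = coords, atoms = atoms,
                 n_models = dim(coords)[3]),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d models, %d atoms, residues %d-%d\n",
              x$n_models, nrow(x$atoms), min(x$atoms$resno),
              max(x$atoms$resno)))
  invisible(x)
}

#' Read a multi-model PDB file as a structure ensemble
#'
#' Parsing is delegated to [bio3d::read.pdb()] (`multi = TRUE`); residue
#' numbering is taken verbatim from the file.
#'
#' @param path PDB file (one or more MODEL blocks).
#' @return `structure_ensemble`.
#' @export
read_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                       # n_models x (3 * n_atoms)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(n_atoms, 3L, n_models))
  for (m in seq_len(n_models))
    coords[, , m] <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
  atoms <- data.frame(resno = pdb$atom$resno, elety = pdb$atom$elety,
                      resid = pdb$atom$resid, stringsAsFactors = FALSE)
  structure_ensemble(coords, atoms)
}

#' Write a structure ensemble as a multi-model PDB file
#'
#' Minimal fixed-width ATOM/MODEL/ENDMDL records; used to materialise
#' synthetic ensembles as plain-text fixtures.
#'
#' @param ensemble a `structure_ensemble`.
#' @param path output path.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- ensemble$atoms
  for (m in seq_len(ensemble$n_models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(at))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, sprintf(" %-3s", at$elety[i]), at$resid[i], at$resno[i],
        ensemble$coords[i, 1, m], ensemble$coords[i, 2, m],
        ensemble$coords[i, 3, m]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Kabsch least-squares superposition
#'
#' Returns the proper rotation (determinant +1) and translation that
#' superpose `coords_b` onto `coords_a` with minimal RMSD, via SVD of the
#' cross-covariance matrix with the usual sign correction.
#'
#' @param coords_a,coords_b `n x 3` matrices, `n >= 3`, not rank-deficient.
#' @return list: `rotation` (3x3, applied to centred b), `translation`,
#'   `rmsd`, and `transformed` (b after superposition onto a).
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  stopifnot(ncol(coords_a) == 3L, ncol(coords_b) == 3L,
            nrow(coords_a) == nrow(coords_b))
  n <- nrow(coords_a)
  if (n < 3L) stop("need at least 3 points for superposition")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- crossprod(B, A)                  # 3x3 cross-covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10)
    stop("rank-deficient coordinates: superposition is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transformed <- sweep(B %*% t(R), 2, ca, "+")
  rmsd <- sqrt(sum((transformed - coords_a)^2) / n)
  list(rotation = R, translation = ca - as.vector(R %*% cb),
       rmsd = rmsd, transformed = transformed)
}

select_atoms <- function(ensemble, residue_range, atoms) {
  sel <- ensemble$atoms$resno >= residue_range[1] &
    ensemble$atoms$resno <= residue_range[2] &
    ensemble$atoms$elety %in% atoms
  if (!any(sel))
    stop("no atoms in residue range ", residue_range[1], "-",
         residue_range[2], " with names ", paste(atoms, collapse = ","))
  sel
}

#' Ensemble precision: RMSD to the iteratively refined mean structure
#'
#' Each model is superposed onto the coordinate-mean structure over the
#' selected backbone atoms; the mean is recomputed and the procedure
#' repeated until the mean per-model RMSD changes by less than `tol`
#' (an all-pairs mean RMSD is also reported for comparison, since ensemble
#' RMSD conventions differ between packages).
#'
#' @param ensemble a `structure_ensemble`.
#' @param residue_range `c(first, last)` residue numbers (file numbering).
#' @param atoms atom names to include (default backbone N, CA, C).
#' @param tol convergence tolerance on the mean RMSD (Angstrom).
#' @return list: `mean`, `sd` (per-model RMSD to mean structure),
#'   `per_model`, `pairwise_mean`, `n_atoms`.
#' @export
ensemble_rmsd <- function(ensemble, residue_range,
                          atoms = c("N", "CA", "C"), tol = 1e-6) {
  rr <- range(ensemble$atoms$resno)
  if (residue_range[1] < rr[1] || residue_range[2] > rr[2])
    stop("residue range ", residue_range[1], "-", residue_range[2],
         " outside ensemble residues ", rr[1], "-", rr[2])
  sel <- select_atoms(ensemble, residue_range, atoms)
  M <- ensemble$n_models
  X <- lapply(seq_len(M), function(m) ensemble$coords[sel, , m, drop = FALSE][, , 1])
  mean_str <- Reduce("+", X) / M
  prev <- Inf
  for (iter in 1:100) {
    fits <- lapply(X, function(xm) kabsch_superpose(mean_str, xm))
    X <- lapply(fits, `[[`, "transformed")
    per_model <- vapply(fits, `[[`, numeric(1), "rmsd")
    mean_str <- Reduce("+", X) / M
    # recompute deviation to the updated mean
    per_model <- vapply(X, function(xm)
      sqrt(sum((xm - mean_str)^2) / nrow(mean_str)), numeric(1))
    cur <- mean(per_model)
    if (abs(prev - cur) < tol) break
    prev <- cur
  }
  pw <- c()
  if (M > 1L) {
    for (i in seq_len(M - 1L)) for (j in (i + 1L):M)
      pw <- c(pw, kabsch_superpose(X[[i]], X[[j]])$rmsd)
  } else pw <- 0
  list(mean = mean(per_model),
       sd = if (M > 1L) stats::sd(per_model) else 0,
       per_model = per_model, pairwise_mean = mean(pw),
       n_atoms = sum(sel))
}

#' Tally NOE distance restraints by residue separation
#'
#' `|i - j|`: 0 intraresidue, 1 sequential, 2-4 medium range, >= 5 long
#' range. The categories are disjoint and exhaustive, so the total equals
#' the restraint count.
#'
#' @param restraints data.frame with integer columns `i`, `j` (1-based
#'   residue indices).
#' @return named integer vector: intraresidue, sequential, medium, long,
#'   total.
#' @export
tally_restraints <- function(restraints) {
  d <- abs(restraints$i - restraints$j)
  c(intraresidue = sum(d == 0L), sequential = sum(d == 1L),
    medium = sum(d >= 2L & d <= 4L), long = sum(d >= 5L),
    total = length(d))
}

#' Read a distance-restraint list
#'
#' Three formats: `"tsv"` -- two integer columns i, j (header optional);
#' `"upl"` -- CYANA upper-limit rows `resno_i resname_i atom_i resno_j
#' resname_j atom_j dist`; `"star"` -- a minimal NMR-STAR
#' `_Gen_dist_constraint` loop from which the two `Seq_ID` columns are
#' taken. Ambiguous restraints are counted once per restraint row.
#'
#' @param path restraint file.
#' @param format `"tsv"`, `"upl"` or `"star"` (guessed from the extension
#'   by default).
#' @return data.frame with columns `i`, `j`.
#' @export
read_restraints <- function(path, format = c("auto", "tsv", "upl", "star")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "upl") "upl"
      else if (ext %in% c("str", "star")) "star" else "tsv"
  }
  if (format == "tsv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    if (length(lines) && grepl("[A-Za-z]", lines[1])) lines <- lines[-1]
    if (!length(lines)) return(data.frame(i = integer(0), j = integer(0)))
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    data.frame(i = as.integer(vapply(parts, `[`, character(1), 1L)),
               j = as.integer(vapply(parts, `[`, character(1), 2L)))
  } else if (format == "upl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    if (!length(lines)) return(data.frame(i = integer(0), j = integer(0)))
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    ok <- lengths(parts) >= 7L
    if (any(!ok)) stop("malformed .upl row(s): ",
                       paste(which(!ok), collapse = ", "))
    data.frame(i = as.integer(vapply(parts, `[`, character(1), 1L)),
               j = as.integer(vapply(parts, `[`, character(1), 4L)))
  } else {
    read_star_distance_loop(path)
  }
}

# Minimal NMR-STAR reader: finds the loop containing _Gen_dist_constraint
# tags, locates the two Comp_index_ID (or Seq_ID) columns and returns them.
read_star_distance_loop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^\\s*_Gen_dist_constraint\\.", lines)
  if (!length(tag_idx)) stop("no _Gen_dist_constraint loop found")
  tags <- sub("^\\s*", "", lines[tag_idx])
  pick <- function(patterns) {
    for (p in patterns) {
      hit <- grep(p, tags)
      if (length(hit)) return(hit[1])
    }
    stop("no residue-index tags in _Gen_dist_constraint loop")
  }
  col_i <- pick(c("Comp_index_ID_1", "Seq_ID_1"))
  col_j <- pick(c("Comp_index_ID_2", "Seq_ID_2"))
  body_start <- max(tag_idx) + 1L
  rows <- list()
  for (k in body_start:length(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    if (ln %in% c("stop_", "loop_") || startsWith(ln, "_")) break
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < length(tags)) next
    rows[[length(rows) + 1L]] <- c(f[col_i], f[col_j])
  }
  if (!length(rows)) return(data.frame(i = integer(0), j = integer(0)))
  m <- do.call(rbind, rows)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
}

#' In-silico PCR with exact primer matching
#'
#' Locates exact matches of the forward primer on the plus strand and of the
#' reverse-complemented reverse primer downstream of it; every
#' forward/reverse site combination yields a product. Product length spans
#' from the start of the forward site to the end of the reverse site,
#' inclusive.
#'
#' @param template nucleotide string or single-row nucleotide record.
#' @param fwd_primer,rev_primer primer sequences (5'->3', >= 15 nt).
#' @return data.frame of class `insilico_pcr` with columns `start`, `end`,
#'   `length`; zero rows (a `NO_PRODUCT` result, not an error) when either
#'   primer has no usable site.
#' @export
insilico_pcr <- function(template, fwd_primer, rev_primer) {
  if (is.data.frame(template)) template <- template$residues
  if (nchar(fwd_primer) < 15L || nchar(rev_primer) < 15L)
    stop("primers must be at least 15 nt")
  subject <- Biostrings::DNAString(toupper(template))
  fwd_hits <- Biostrings::matchPattern(Biostrings::DNAString(toupper(fwd_primer)),
                                       subject)
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(toupper(rev_primer)))
  rev_hits <- Biostrings::matchPattern(rc, subject)
  out <- data.frame(start = integer(0), end = integer(0), length = integer(0))
  for (fs in Biostrings::start(fwd_hits)) {
    for (re in Biostrings::end(rev_hits)) {
      if (re >= fs + nchar(fwd_primer)) {
        out <- rbind(out, data.frame(start = fs, end = re,
                                     length = re - fs + 1L))
      }
    }
  }
  class(out) <- c("insilico_pcr", class(out))
  attr(out, "no_product") <- nrow(out) == 0L
  out
}
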