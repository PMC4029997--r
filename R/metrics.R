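#' Structural comparison metrics
#'
#' Fraction of native contacts (f_N) and optimal-superposition RMSD. Native
#' contacts are all side-chain-center pairs (i, j), j > i, closer than a
#' cutoff (6.5 angstroms by default) in the reference structure; f_N of a
#' decoy is the fraction of those pairs that are also within the cutoff in
#' the decoy. Contacts are defined by the native structure only.
#'
#' @name metrics
NULL

#' Mass-weighted side-chain centers per residue
#'
#' Collapses an all-atom structure to one bead per residue at the side
#' chain's center of mass. Glycine (no side-chain atoms) falls back to its
#' CA atom.
#'
#' @param atoms data frame with columns \code{resno} (residue number),
#'   \code{atom} (atom name), \code{x}, \code{y}, \code{z}, and optionally
#'   \code{mass} (defaults to 12 per atom when absent).
#' @return a \code{bead_structure} in residue-number order.
#' @export
side_chain_centers <- function(atoms) {
  need <- c("resno", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms))) stop("atoms must have columns resno, atom, x, y, z")
  if (is.null(atoms$mass)) atoms$mass <- 12
  backbone <- c("N", "CA", "C", "O", "OXT", "H", "HA", "HN")
  res_ids <- sort(unique(atoms$resno))
  coords <- t(vapply(res_ids, function(r) {
    a <- atoms[atoms$resno == r, , drop = FALSE]
    if (nrow(a) == 0L) stop(sprintf("invalid structure: empty residue %s", r))
    sc <- a[!(a$atom %in% backbone), , drop = FALSE]
    if (nrow(sc) == 0L) sc <- a[a$atom == "CA", , drop = FALSE]
    if (nrow(sc) == 0L)
      stop(sprintf("invalid structure: residue %s has no side-chain or CA atoms", r))
    w <- sc$mass / sum(sc$mass)
    c(sum(w * sc$x), sum(w * sc$y), sum(w * sc$z))
  }, numeric(3)))
  bead_structure(coords, labels = res_ids)
}

#' Native contact set of a reference structure
#'
#' @param native a \code{bead_structure}.
#' @param cutoff contact cutoff in angstroms; pairs at a distance exactly
#'   equal to the cutoff are excluded (strict inequality).
#' @param min_sep minimum sequence separation j - i (default 0: all j > i
#'   pairs count).
#' @return a data frame with columns \code{i}, \code{j} (1-based, j > i) and
#'   attribute \code{cutoff}.
#' @export
native_contacts <- function(native, cutoff = 6.5, min_sep = 0L) {
  stopifnot(inherits(native, "bead_structure"))
  if (cutoff <= 0) stop("cutoff must be positive")
  dm <- as.matrix(stats::dist(native$coords))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  keep <- dm[idx] < cutoff & (idx[, 2L] - idx[, 1L]) > min_sep
  out <- data.frame(i = idx[keep, 1L], j = idx[keep, 2L])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Fraction of native contacts of a decoy
#'
#' @param decoy,native \code{bead_structure}s with equal residue counts.
#' @param cutoff contact cutoff in angstroms (strict inequality).
#' @param min_sep minimum sequence separation (see
#'   \code{\link{native_contacts}}).
#' @return f_N in \code{[0, 1]}.
#' @export
fraction_native_contacts <- function(decoy, native, cutoff = 6.5,
                                     min_sep = 0L) {
  stopifnot(inherits(decoy, "bead_structure"),
            inherits(native, "bead_structure"))
  if (decoy$n_res != native$n_res) stop("residue counts differ")
  con <- native_contacts(native, cutoff, min_sep)
  if (nrow(con) == 0L)
    stop("undefined metric: native structure has no contacts")
  dd <- sqrt(rowSums((decoy$coords[con$i, , drop = FALSE] -
                        decoy$coords[con$j, , drop = FALSE])^2))
  mean(dd < cutoff)
}

#' Minimal RMSD under optimal rigid superposition (Kabsch)
#'
#' Centers both point sets, finds the optimal proper rotation by SVD of the
#' covariance (reflections removed via the determinant correction), and
#' returns the root-mean-square deviation of the superposed coordinates.
#'
#' @param a,b \code{bead_structure}s (or n x 3 matrices) with equal counts;
#'   at least 3 non-collinear points for a unique rotation.
#' @return RMSD in the coordinate units (angstroms).
#' @export
kabsch_rmsd <- function(a, b) {
  A <- if (inherits(a, "bead_structure")) a$coords else as.matrix(a)
  B <- if (inherits(b, "bead_structure")) b$coords else as.matrix(b)
  if (!all(dim(A) == dim(B))) stop("point counts differ")
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  H <- crossprod(Bc, Ac)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  diffs <- Ac - Bc %*% t(R)
  sqrt(mean(rowSums(diffs^2)))
}

#' Metric report for a decoy set
#'
#' @param decoys a \code{decoy_set} (or list of \code{bead_structure}s with a
#'   separate \code{native}).
#' @param native reference structure; taken from the decoy set when omitted.
#' @param cutoff contact cutoff, angstroms.
#' @return data frame (decoy_id, f_N, rmsd_A).
#' @export
metric_report <- function(decoys, native = NULL, cutoff = 6.5) {
  if (inherits(decoys, "decoy_set")) {
    if (is.null(native)) native <- decoys$native
    decoys <- decoys$decoys
  }
  if (is.null(native)) stop("native reference required")
  data.frame(
    decoy_id = seq_along(decoys),
    f_N = vapply(decoys, fraction_native_contacts, numeric(1),
                 native = native, cutoff = cutoff),
    rmsd_A = vapply(decoys, kabsch_rmsd, numeric(1), b = native))
}

# ---- plain-text structure I/O (no R PDB reader is available upstream) ----

#' Read and write bead/atom structures
#'
#' Minimal fixed-column PDB support: \code{read_pdb_atoms} parses ATOM
#' records into a data frame (\code{resno}, \code{atom}, \code{resname},
#' \code{x}, \code{y}, \code{z}, \code{model}); \code{read_pdb_beads} reads
#' CA-only (or single-bead) records as a \code{bead_structure};
#' \code{write_pdb_beads} writes one bead per residue as CA ATOM records,
#' multi-model when given a list or \code{decoy_set}. XYZ files carry one
#' structure per frame.
#'
#' @param path file path.
#' @name structure_io
NULL

#' @rdname structure_io
#' @export
read_pdb_atoms <- function(path) {
  lines <- readLines(path)
  model <- 0L
  cur <- 1L
  rows <- list()
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "MODEL ") { model <- model + 1L; cur <- model }
    if (tag == "ATOM  " || tag == "HETATM") {
      rows[[length(rows) + 1L]] <- data.frame(
        model = max(cur, 1L),
        atom = trimws(substr(ln, 13, 16)),
        resname = trimws(substr(ln, 18, 20)),
        resno = as.integer(trimws(substr(ln, 23, 26))),
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)))
    }
  }
  if (length(rows) == 0L) stop("no ATOM records in ", path)
  do.call(rbind, rows)
}

#' @rdname structure_io
#' @export
read_pdb_beads <- function(path) {
  at <- read_pdb_atoms(path)
  out <- lapply(split(at, at$model), function(m) {
    ca <- m[m$atom == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) ca <- m
    ca <- ca[order(ca$resno), , drop = FALSE]
    bead_structure(cbind(ca$x, ca$y, ca$z), labels = ca$resno)
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' @rdname structure_io
#' @param structures a \code{bead_structure}, list of them, or a
#'   \code{decoy_set}.
#' @export
write_pdb_beads <- function(structures, path) {
  if (inherits(structures, "decoy_set")) structures <- structures$decoys
  if (inherits(structures, "bead_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(structures) > 1L
  for (mi in seq_along(structures)) {
    s <- structures[[mi]]
    if (multi) writeLines(sprintf("MODEL %8d", mi), con)
    for (i in seq_len(s$n_res)) {
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, s$coords[i, 1L], s$coords[i, 2L], s$coords[i, 3L]), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname structure_io
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- as.integer(trimws(lines[i]))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), function(p)
      as.numeric(p[2:4])))
    out[[length(out) + 1L]] <- bead_structure(parts)
    i <- i + 2L + n
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' @rdname structure_io
#' @export
write_xyz <- function(structures, path) {
  if (inherits(structures, "decoy_set")) structures <- structures$decoys
  if (inherits(structures, "bead_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    writeLines(as.character(s$n_res), con)
    writeLines("bead structure", con)
    for (i in seq_len(s$n_res))
      writeLines(sprintf("C %12.6f %12.6f %12.6f", s$coords[i, 1L],
                         s$coords[i, 2L], s$coords[i, 3L]), con)
  }
  invisible(path)
}
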