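#' Read an atom-map file
#'
#' Atom maps pair template atoms with target atoms for common-substructure
#' alignment. The file format is whitespace-separated
#' `template_idx target_idx` lines with **0-based** indices; `#` starts a
#' comment. Indices are converted to 1-based internally.
#'
#' @param path Path to the map file.
#' @return Integer matrix with columns `template`, `target` (1-based).
#' @export
read_atom_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (!length(lines)) stop("empty atom map: ", path)
  tok <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(tok, length, integer(1L)) != 2L
  if (any(bad)) stop("atom map lines must be 'template_idx target_idx': ", path)
  m <- t(vapply(tok, function(t) as.integer(t) + 1L, integer(2L)))
  colnames(m) <- c("template", "target")
  validate_atom_map(m)
  m
}

validate_atom_map <- function(map) {
  if (nrow(map) < 3L)
    stop("atom map needs >= 3 mapped atom pairs, got ", nrow(map))
  if (anyDuplicated(map[, 1L]) || anyDuplicated(map[, 2L]))
    stop("atom map indices must be unique within each side")
  if (any(map < 1L)) stop("atom map indices out of bounds")
  invisible(map)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rotation and translation minimising the RMSD between
#' mapped atom pairs, via the SVD of the cross-covariance of the centred
#' coordinate sets. The aligned mobile coordinates are
#' `sweep(mobile, ...) %*% rotation + translation` — see
#' [apply_superposition()].
#'
#' @param mobile Numeric n x 3 coordinate matrix to be moved.
#' @param reference Numeric n x 3 coordinate matrix of the template.
#' @param map Optional atom map (matrix with columns `template`, `target`,
#'   1-based, as from [read_atom_map()]); by default rows are paired 1:1.
#' @return An object of class `superposition`: list with `rotation` (3 x 3
#'   proper rotation, det +1), `translation` (length-3), and `rmsd` (Angstrom,
#'   over mapped atoms after fitting).
#' @export
kabsch_superpose <- function(mobile, reference, map = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(map)) {
    if (nrow(mobile) != nrow(reference))
      stop("without a map, mobile and reference need equal atom counts")
    map <- cbind(template = seq_len(nrow(reference)),
                 target = seq_len(nrow(mobile)))
  }
  validate_atom_map(map)
  if (max(map[, "template"]) > nrow(reference) ||
      max(map[, "target"]) > nrow(mobile))
    stop("atom map index exceeds atom count")
  A <- mobile[map[, "target"], , drop = FALSE]
  B <- reference[map[, "template"], , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  sv <- svd(crossprod(A0, B0))
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1))
    stop("degenerate geometry: mapped reference atoms are collinear")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  translation <- as.numeric(cb - ca %*% R)
  fitted <- sweep(A0 %*% R, 2L, cb, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A over mapped atoms\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param xyz Numeric n x 3 matrix.
#' @param sp A `superposition` from [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, sp) {
  out <- sweep(as.matrix(xyz) %*% sp$rotation, 2L, sp$translation, `+`)
  dimnames(out) <- dimnames(xyz)
  out
}

#' Align a molecule set onto a template
#'
#' Superposes every molecule onto the template molecule using its atom map
#' (common-substructure alignment). The template itself is returned
#' unchanged. Molecules without a map are excluded and listed in the failure
#' report.
#'
#' @param mols List of [molecule()] objects.
#' @param template_id Id of the template molecule (must be present).
#' @param maps Named list of atom maps (columns `template`, `target`,
#'   1-based), one per non-template molecule; names are molecule ids. The
#'   special value `"identity"` uses a 1:1 map over all template atoms.
#' @return List with `molecules` (aligned, template frame), `rmsd` (named
#'   numeric, Angstrom), and `failures` (named character, reasons for
#'   excluded molecules).
#' @export
align_set <- function(mols, template_id, maps = "identity") {
  ids <- vapply(mols, `[[`, character(1L), "id")
  ti <- match(template_id, ids)
  if (is.na(ti)) stop("template '", template_id, "' not in molecule set")
  template <- mols[[ti]]
  aligned <- list()
  rmsd <- numeric(0)
  failures <- character(0)
  for (m in mols) {
    if (m$id == template_id) {
      aligned[[m$id]] <- m
      rmsd[m$id] <- 0
      next
    }
    map <- if (identical(maps, "identity")) {
      if (n_atoms(m) < n_atoms(template))
        cbind(template = seq_len(n_atoms(m)), target = seq_len(n_atoms(m)))
      else
        cbind(template = seq_len(n_atoms(template)),
              target = seq_len(n_atoms(template)))
    } else maps[[m$id]]
    if (is.null(map)) {
      failures[m$id] <- "no atom map supplied"
      next
    }
    sp <- tryCatch(kabsch_superpose(m$xyz, template$xyz, map),
                   error = function(e) e)
    if (inherits(sp, "error")) {
      failures[m$id] <- conditionMessage(sp)
      next
    }
    m$xyz <- apply_superposition(m$xyz, sp)
    aligned[[m$id]] <- m
    rmsd[m$id] <- sp$rmsd
  }
  list(molecules = aligned, rmsd = rmsd, failures = failures)
}
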