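#' @keywords internal
#' @importClassesFrom ChemmineR SDF SDFset
"_PACKAGE"

#' CoMSIA physicochemical property kinds
#'
#' The five atomic property types used by CoMSIA similarity-index fields, in
#' the canonical order used throughout the package.
#'
#' @format Character vector of length 5.
#' @export
PROPERTY_KINDS <- c("steric", "electrostatic", "hydrophobic", "donor", "acceptor")

#' All supported molecular-field kinds
#'
#' The two CoMFA probe-interaction fields plus the five CoMSIA
#' similarity-index fields.
#'
#' @format Character vector of length 7.
#' @export
FIELD_KINDS <- c("comfa_steric", "comfa_electrostatic",
                 paste0("comsia_", PROPERTY_KINDS))

#' Construct a molecule
#'
#' A `molecule` is the package's light-weight container for one aligned
#' 3D structure: element symbols, Cartesian coordinates (Angstrom), optional
#' partial charges (elementary charge units), optional bonds, and an optional
#' n_atoms x 5 matrix of per-atom CoMSIA property weights.
#'
#' @param id Character scalar, unique compound identifier.
#' @param elements Character vector of element symbols (length >= 1).
#' @param xyz Numeric matrix, n_atoms x 3, coordinates in Angstrom.
#' @param charges Optional numeric vector of partial charges, one per atom.
#' @param bonds Optional integer matrix with columns `i`, `j`, `order`
#'   (1-based atom indices; order 4 denotes aromatic).
#' @param weights Optional numeric n_atoms x 5 matrix with columns
#'   [PROPERTY_KINDS].
#' @return An object of class `molecule`.
#' @examples
#' m <- molecule("methane", c("C", "H", "H", "H", "H"),
#'               rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.03, 0),
#'                     c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89)))
#' n_atoms(m)
#' @export
molecule <- function(id, elements, xyz, charges = NULL, bonds = NULL,
                     weights = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  elements <- as.character(elements)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (length(elements) < 1L)
    stop("molecule '", id, "': atom count must be >= 1")
  if (nrow(xyz) != length(elements) || ncol(xyz) != 3L)
    stop("molecule '", id, "': xyz must be n_atoms x 3")
  if (!all(is.finite(xyz)))
    stop("molecule '", id, "': non-finite coordinates")
  if (!is.null(charges)) {
    charges <- as.numeric(charges)
    if (length(charges) != length(elements))
      stop("molecule '", id, "': charges length mismatch")
  }
  if (!is.null(bonds)) {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) < 2L) stop("bonds must have columns i, j[, order]")
    if (ncol(bonds) == 2L) bonds <- cbind(bonds, 1L)
    colnames(bonds) <- c("i", "j", "order")
    storage.mode(bonds) <- "integer"
    if (nrow(bonds) &&
        (min(bonds[, 1:2]) < 1L || max(bonds[, 1:2]) > length(elements)))
      stop("molecule '", id, "': bond atom index out of range")
  }
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    storage.mode(weights) <- "double"
    if (nrow(weights) != length(elements) ||
        ncol(weights) != length(PROPERTY_KINDS))
      stop("molecule '", id, "': weights must be n_atoms x ",
           length(PROPERTY_KINDS))
    colnames(weights) <- PROPERTY_KINDS
    if (!all(is.finite(weights)))
      stop("molecule '", id, "': non-finite property weights")
  }
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(id = id, elements = elements, xyz = xyz,
                 charges = charges, bonds = bonds, weights = weights),
            class = "molecule")
}

#' Number of atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$id, ": ", n_atoms(x), " atoms",
      if (!is.null(x$charges)) sprintf(", net charge %.3f", sum(x$charges))
      else ", charges unassigned",
      if (!is.null(x$weights)) ", CoMSIA weights assigned" else "",
      "\n", sep = "")
  invisible(x)
}

#' Test whether partial charges are assigned
#' @param mol A `molecule`.
#' @return Logical scalar.
#' @export
has_charges <- function(mol) !is.null(mol$charges)

# Run an expression under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

qsar3d_extdata <- function(file) {
  path <- system.file("extdata", file, package = "qsar3d")
  if (!nzchar(path)) stop("bundled data file not found: ", file)
  path
}
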