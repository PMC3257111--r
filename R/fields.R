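#' Default CoMSIA/CoMFA probe
#'
#' The CoMSIA probe carries weight +1 for every property kind (radius 1.0
#' Angstrom is recorded as metadata only; the Gaussian similarity index does
#' not use a probe radius). The CoMFA probe is an sp3 carbon with charge +1.
#'
#' @param comsia_weights Named numeric vector over [PROPERTY_KINDS]
#'   (default all +1).
#' @param comfa_radius,comfa_epsilon Probe Lennard-Jones parameters
#'   (sp3 carbon defaults, Angstrom / kcal/mol).
#' @param comfa_charge Probe charge in elementary charge units (default +1).
#' @return Object of class `probe`.
#' @export
default_probe <- function(comsia_weights = stats::setNames(rep(1, 5), PROPERTY_KINDS),
                          comfa_radius = 1.70, comfa_epsilon = 0.107,
                          comfa_charge = 1.0) {
  structure(list(comsia_weights = comsia_weights, comsia_radius = 1.0,
                 comfa_radius = comfa_radius, comfa_epsilon = comfa_epsilon,
                 comfa_charge = comfa_charge),
            class = "probe")
}

#' Assign per-atom CoMSIA property weights
#'
#' Property weights follow the conventions of the CoMSIA similarity-index
#' formulation: steric weight is the atomic van der Waals volume relative to
#' carbon (`(r/r_C)^3`); electrostatic weight is the partial charge;
#' hydrophobic weight is an element-based increment; donor weight is 1 for
#' N/O atoms bearing at least one hydrogen; acceptor weight is 1 for N/O
#' atoms with a lone pair (N with four connections is excluded). The element
#' tables ship in `extdata/comsia_atom_params.csv` and can be overridden.
#'
#' @param mol A [molecule()] with charges assigned and (for donor/acceptor
#'   rules) bonds present.
#' @param params Optional data.frame with columns `element`, `vdw_radius`,
#'   `hydrophobicity` overriding the bundled table.
#' @return The molecule with its `weights` matrix filled in.
#' @export
comsia_atom_weights <- function(mol, params = NULL) {
  if (is.null(params))
    params <- utils::read.csv(qsar3d_extdata("comsia_atom_params.csv"),
                              comment.char = "#", stringsAsFactors = FALSE)
  idx <- match(mol$elements, params$element)
  if (anyNA(idx))
    stop("no CoMSIA atom parameters for element(s): ",
         paste(unique(mol$elements[is.na(idx)]), collapse = ", "))
  if (!has_charges(mol))
    stop("molecule '", mol$id,
         "': partial charges required for the electrostatic property")
  r_c <- params$vdw_radius[params$element == "C"][1L]
  steric <- (params$vdw_radius[idx] / r_c)^3
  hydroph <- params$hydrophobicity[idx]
  n <- n_atoms(mol)
  donor <- acceptor <- numeric(n)
  if (!is.null(mol$bonds) && nrow(mol$bonds)) {
    nb <- lapply(seq_len(n), function(i) {
      b <- mol$bonds
      c(b[b[, 1L] == i, 2L], b[b[, 2L] == i, 1L])
    })
    deg <- lengths(nb)
    for (i in seq_len(n)) {
      if (!(mol$elements[i] %in% c("N", "O"))) next
      if (any(mol$elements[nb[[i]]] == "H")) donor[i] <- 1
      if (!(mol$elements[i] == "N" && deg[i] >= 4L)) acceptor[i] <- 1
    }
  }
  mol$weights <- cbind(steric = steric, electrostatic = mol$charges,
                       hydrophobic = hydroph, donor = donor,
                       acceptor = acceptor)
  mol
}

#' CoMSIA similarity-index field of one molecule
#'
#' Evaluates, at every lattice point q, the Gaussian-attenuated similarity
#' index
#' \deqn{A_{F,k}^q = -\sum_i \omega_{probe,k}\, \omega_{ik}\,
#'   e^{-\alpha \gamma_{iq}^2}}
#' where \eqn{\omega_{ik}} is the atomic property weight of kind `k`,
#' \eqn{\gamma_{iq}} the Euclidean atom-to-point distance in Angstrom, and
#' \eqn{\alpha} the attenuation factor (default 0.3 per square Angstrom).
#' No distance cutoff is applied; the Gaussian decays smoothly.
#'
#' @param mol A [molecule()] with property weights assigned (see
#'   [comsia_atom_weights()]); for synthetic molecules the weights may be set
#'   directly.
#' @param grid A `field_grid`.
#' @param kind One of [PROPERTY_KINDS].
#' @param alpha Attenuation factor, 1/Angstrom^2, > 0 (default 0.3).
#' @param probe A [default_probe()] (its weight for `kind` scales the field).
#' @return Numeric vector of length `n_grid_points(grid)`, dimensionless.
#' @export
comsia_field <- function(mol, grid, kind, alpha = 0.3,
                         probe = default_probe()) {
  kind <- match.arg(kind, PROPERTY_KINDS)
  if (alpha <= 0) stop("alpha must be > 0")
  if (is.null(mol$weights))
    stop("molecule '", mol$id, "': property weights for kind '", kind,
         "' are not assigned")
  w <- mol$weights[, kind]
  pts <- grid_points(grid)
  d2 <- grid_dist2(pts, mol$xyz)
  as.numeric(-(exp(-alpha * d2) %*% w) * probe$comsia_weights[[kind]])
}

#' CoMFA probe-interaction fields of one molecule
#'
#' Steric field: Lennard-Jones 6-12 interaction between an sp3-carbon probe
#' and every atom, \eqn{\sum_i \epsilon_i [(R_i/r)^{12} - 2 (R_i/r)^6]} with
#' Lorentz combination \eqn{R_i = r_{vdW,i} + r_{probe}} and
#' \eqn{\epsilon_i = \sqrt{\epsilon_{vdW,i}\,\epsilon_{probe}}} (kcal/mol).
#' Electrostatic field: Coulomb term \eqn{\sum_i 332.0\, q_i q_{probe} /
#' (D(r)\, r)} with distance-dependent dielectric \eqn{D(r) = r} by default.
#' Both fields are clamped to `[-cutoff, +cutoff]`.
#'
#' Points where the steric term reaches the positive cutoff lie inside the
#' molecular core; their raw electrostatic values are meaningless and are
#' flagged in `steric_at_cutoff` so [field_block()] can replace them by the
#' column mean over molecules not at cutoff.
#'
#' @param mol A [molecule()] with charges assigned.
#' @param grid A `field_grid`.
#' @param probe A [default_probe()].
#' @param cutoff Energy cutoff, kcal/mol (default 30).
#' @param dielectric `"distance"` for D(r) = r (default) or `"constant"`
#'   for D = 1.
#' @param vdw Optional data.frame `element,radius,epsilon` overriding the
#'   bundled Tripos-style parameter table.
#' @return List with numeric vectors `steric`, `electrostatic` (kcal/mol)
#'   and logical `steric_at_cutoff`.
#' @export
comfa_fields <- function(mol, grid, probe = default_probe(), cutoff = 30,
                         dielectric = c("distance", "constant"), vdw = NULL) {
  dielectric <- match.arg(dielectric)
  if (is.null(vdw))
    vdw <- utils::read.csv(qsar3d_extdata("tripos_vdw.csv"),
                           comment.char = "#", stringsAsFactors = FALSE)
  idx <- match(mol$elements, vdw$element)
  if (anyNA(idx))
    stop("no van der Waals parameters for element(s): ",
         paste(unique(mol$elements[is.na(idx)]), collapse = ", "))
  if (!has_charges(mol))
    stop("molecule '", mol$id, "': charges required for the CoMFA ",
         "electrostatic field")
  pts <- grid_points(grid)
  d2 <- pmax(grid_dist2(pts, mol$xyz), 1e-12)
  rmin <- vdw$radius[idx] + probe$comfa_radius
  eps <- sqrt(vdw$epsilon[idx] * probe$comfa_epsilon)
  s6 <- sweep(1 / d2, 2L, rmin^2, `*`)^3          # (Rmin/r)^6
  steric <- as.numeric((s6 * (s6 - 2)) %*% eps)
  r <- sqrt(d2)
  denom <- if (dielectric == "distance") d2 else r
  elec <- as.numeric((332.0 * probe$comfa_charge / denom) %*% mol$charges)
  list(steric = pmin(pmax(steric, -cutoff), cutoff),
       electrostatic = pmin(pmax(elec, -cutoff), cutoff),
       steric_at_cutoff = steric >= cutoff)
}

#' Compute one field block over a molecule set
#'
#' Builds the n_molecules x n_gridpoints value matrix for a single field
#' kind. For `comfa_electrostatic`, entries of molecules whose steric field
#' reaches the positive cutoff at a point are replaced by the column mean of
#' the molecules not at cutoff there (0 when all molecules are at cutoff) —
#' the standard treatment of in-core Coulomb values.
#'
#' @param mols List of [molecule()] objects, all aligned to the same frame.
#' @param grid A `field_grid`.
#' @param kind One of [FIELD_KINDS].
#' @param alpha CoMSIA attenuation factor (1/Angstrom^2).
#' @param probe A [default_probe()].
#' @param cutoff CoMFA energy cutoff, kcal/mol.
#' @param dielectric CoMFA dielectric mode, see [comfa_fields()].
#' @return Object of class `field_block`: list with `kind`, `values`
#'   (matrix, rownames = molecule ids), `grid`.
#' @export
field_block <- function(mols, grid, kind, alpha = 0.3,
                        probe = default_probe(), cutoff = 30,
                        dielectric = "distance") {
  kind <- match.arg(kind, FIELD_KINDS)
  ids <- vapply(mols, `[[`, character(1L), "id")
  if (startsWith(kind, "comsia_")) {
    prop <- sub("^comsia_", "", kind)
    values <- do.call(rbind, lapply(mols, comsia_field, grid = grid,
                                    kind = prop, alpha = alpha,
                                    probe = probe))
  } else {
    per <- lapply(mols, comfa_fields, grid = grid, probe = probe,
                  cutoff = cutoff, dielectric = dielectric)
    if (kind == "comfa_steric") {
      values <- do.call(rbind, lapply(per, `[[`, "steric"))
    } else {
      values <- do.call(rbind, lapply(per, `[[`, "electrostatic"))
      atcut <- do.call(rbind, lapply(per, `[[`, "steric_at_cutoff"))
      for (j in which(colSums(atcut) > 0L)) {
        okrows <- !atcut[, j]
        fill <- if (any(okrows)) mean(values[okrows, j]) else 0
        values[!okrows, j] <- fill
      }
    }
  }
  rownames(values) <- ids
  structure(list(kind = kind, values = values, grid = grid),
            class = "field_block")
}

#' Compute several field blocks at once
#'
#' @inheritParams field_block
#' @param kinds Character vector of field kinds (default: the five CoMSIA
#'   kinds plus the two CoMFA kinds).
#' @return Named list of `field_block` objects.
#' @export
compute_field_blocks <- function(mols, grid, kinds = FIELD_KINDS,
                                 alpha = 0.3, probe = default_probe(),
                                 cutoff = 30, dielectric = "distance") {
  stats::setNames(lapply(kinds, function(k)
    field_block(mols, grid, k, alpha = alpha, probe = probe,
                cutoff = cutoff, dielectric = dielectric)), kinds)
}
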