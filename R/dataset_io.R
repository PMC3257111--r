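#' Read 3D structures from an SDF or MOL2 file
#'
#' SDF (V2000/V3000) files are parsed with ChemmineR; MOL2 files with a
#' built-in reader for the `@<TRIPOS>MOLECULE/ATOM/BOND` sections (MOL2 is the
#' only common format that carries partial charges natively, so they are read
#' from the charge column). For SDF input, partial charges are restored from a
#' `PARTIAL_CHARGES` data field and CoMSIA property weights from
#' `COMSIA_<KIND>` fields when present (the conventions used by
#' [write_structures()]); otherwise charges are flagged unassigned.
#'
#' Records with zero atoms (or otherwise unparseable records) are dropped and
#' reported in the `errors` attribute rather than aborting the whole read.
#'
#' @param path Path to a `.sdf`/`.sd`/`.mol` or `.mol2` file.
#' @return A list of [molecule()] objects, record order preserved, with a
#'   character attribute `errors` naming any skipped records.
#' @export
load_structures <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  is_mol2 <- grepl("\\.mol2$", path, ignore.case = TRUE) ||
    any(grepl("^@<TRIPOS>", first))
  if (is_mol2) read_mol2(path) else read_sdf(path)
}

read_sdf <- function(path) {
  raw <- methods::as(ChemmineR::read.SDFstr(path), "list")
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
  errors <- character(0)
  mols <- list()
  for (i in seq_along(raw)) {
    lines <- raw[[i]]
    id <- trimws(lines[1L])
    if (!nzchar(id)) id <- sprintf("record_%d", i)
    natoms <- suppressWarnings(as.integer(substr(lines[4L], 1L, 3L)))
    nbonds <- suppressWarnings(as.integer(substr(lines[4L], 4L, 6L)))
    if (is.na(natoms) || natoms < 1L) {
      errors <- c(errors,
                  sprintf("record %d ('%s'): empty record (0 atoms)", i, id))
      next
    }
    ab <- if (i <= length(sdfset)) ChemmineR::atomblock(sdfset[[i]]) else NULL
    bb <- if (i <= length(sdfset)) ChemmineR::bondblock(sdfset[[i]]) else NULL
    ab_ok <- is.matrix(ab) && ncol(ab) >= 3L && nrow(ab) == natoms &&
      all(is.finite(ab[, 1:3]))
    bb_ok <- is.na(nbonds) || nbonds == 0L ||
      (is.matrix(bb) && ncol(bb) >= 3L && nrow(bb) == nbonds)
    if (ab_ok && bb_ok) {
      elements <- sub("_.*$", "", rownames(ab))
      xyz <- ab[, 1:3, drop = FALSE]
      bonds <- if (is.matrix(bb) && ncol(bb) >= 3L && nrow(bb) > 0L)
        cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
              order = as.integer(bb[, 3]))
      else NULL
    } else {
      # ChemmineR's parse is inconsistent with the counts line (it chokes
      # on single-atom and bond-less records); parse the V2000 blocks from
      # the raw record lines instead
      parsed <- parse_v2000_block(lines, natoms, nbonds, i, id)
      if (is.character(parsed)) { errors <- c(errors, parsed); next }
      elements <- parsed$elements; xyz <- parsed$xyz; bonds <- parsed$bonds
    }
    db <- parse_sdf_datafields(lines)
    charges <- parse_num_field(db, "PARTIAL_CHARGES", length(elements))
    weights <- NULL
    wcols <- lapply(PROPERTY_KINDS, function(k)
      parse_num_field(db, paste0("COMSIA_", toupper(k)), length(elements)))
    if (all(!vapply(wcols, is.null, logical(1L))))
      weights <- do.call(cbind, wcols)
    mols[[length(mols) + 1L]] <-
      molecule(id, elements, xyz, charges = charges, bonds = bonds,
               weights = weights)
  }
  structure(mols, errors = errors)
}

parse_v2000_block <- function(lines, natoms, nbonds, i, id) {
  if (length(lines) < 4L + natoms)
    return(sprintf("record %d ('%s'): truncated atom block", i, id))
  tok <- strsplit(trimws(lines[5L:(4L + natoms)]), "[[:space:]]+")
  bad <- vapply(tok, length, integer(1L)) < 4L
  if (any(bad))
    return(sprintf("record %d ('%s'): malformed atom line", i, id))
  xyz <- t(vapply(tok, function(t) as.numeric(t[1:3]), numeric(3L)))
  elements <- vapply(tok, `[[`, character(1L), 4L)
  bonds <- NULL
  if (!is.na(nbonds) && nbonds > 0L &&
      length(lines) >= 4L + natoms + nbonds) {
    bt <- strsplit(trimws(lines[(5L + natoms):(4L + natoms + nbonds)]),
                   "[[:space:]]+")
    bonds <- t(vapply(bt, function(t) as.integer(t[1:3]), integer(3L)))
    colnames(bonds) <- c("i", "j", "order")
  }
  list(elements = elements, xyz = xyz, bonds = bonds)
}

parse_sdf_datafields <- function(lines) {
  at <- grep("^>", lines)
  if (!length(at)) return(character(0))
  nm <- sub("^>.*<([^>]+)>.*$", "\\1", lines[at])
  vals <- vapply(at, function(j)
    if (j + 1L <= length(lines)) lines[j + 1L] else "", character(1L))
  stats::setNames(vals, nm)
}

parse_num_field <- function(db, name, n) {
  if (is.null(db) || !length(db) || !(name %in% names(db))) return(NULL)
  v <- as.numeric(strsplit(trimws(db[[name]]), "[[:space:]]+")[[1]])
  if (length(v) != n || anyNA(v)) return(NULL)
  v
}

read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(starts)) stop("not a MOL2 file (no @<TRIPOS>MOLECULE): ", path)
  bounds <- c(starts, length(lines) + 1L)
  mols <- list()
  errors <- character(0)
  for (r in seq_along(starts)) {
    block <- lines[bounds[r]:(bounds[r + 1L] - 1L)]
    id <- trimws(block[2L])
    if (!nzchar(id)) id <- sprintf("record_%d", r)
    atom_at <- grep("^@<TRIPOS>ATOM", block)
    if (!length(atom_at)) {
      errors <- c(errors, sprintf("record %d ('%s'): no ATOM section", r, id))
      next
    }
    sec_ends <- c(grep("^@<TRIPOS>", block), length(block) + 1L)
    atom_end <- min(sec_ends[sec_ends > atom_at[1L]]) - 1L
    atom_lines <- block[(atom_at[1L] + 1L):atom_end]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    if (!length(atom_lines)) {
      errors <- c(errors, sprintf("record %d ('%s'): empty record", r, id))
      next
    }
    tok <- strsplit(trimws(atom_lines), "[[:space:]]+")
    elements <- vapply(tok, function(t) sub("\\..*$", "", t[6L]), character(1L))
    xyz <- t(vapply(tok, function(t) as.numeric(t[3:5]), numeric(3L)))
    charges <- vapply(tok, function(t)
      if (length(t) >= 9L) suppressWarnings(as.numeric(t[9L])) else NA_real_,
      numeric(1L))
    if (anyNA(charges)) charges <- NULL
    bond_at <- grep("^@<TRIPOS>BOND", block)
    bonds <- NULL
    if (length(bond_at)) {
      bond_end <- min(sec_ends[sec_ends > bond_at[1L]]) - 1L
      if (bond_end > bond_at[1L]) {
        bl <- block[(bond_at[1L] + 1L):bond_end]
        bl <- bl[nzchar(trimws(bl))]
        bt <- strsplit(trimws(bl), "[[:space:]]+")
        ord <- vapply(bt, function(t) {
          o <- t[4L]
          if (o %in% c("ar", "Ar")) 4L
          else if (o == "am") 1L
          else suppressWarnings(as.integer(o))
        }, integer(1L))
        bonds <- cbind(i = vapply(bt, function(t) as.integer(t[2L]), integer(1L)),
                       j = vapply(bt, function(t) as.integer(t[3L]), integer(1L)),
                       order = ord)
      }
    }
    mols[[length(mols) + 1L]] <- molecule(id, elements, xyz,
                                          charges = charges, bonds = bonds)
  }
  structure(mols, errors = errors)
}

#' Write molecules to an SDF (V2000) file
#'
#' Coordinates are written at the format's 4-decimal precision. Partial
#' charges and CoMSIA property weights, when present, are stored in
#' `PARTIAL_CHARGES` and `COMSIA_<KIND>` data fields so that
#' [load_structures()] round-trips them.
#'
#' @param mols A list of [molecule()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  sdfs <- lapply(mols, function(m) {
    n <- n_atoms(m)
    ab <- cbind(round(m$xyz, 4L), matrix(0, n, 12L))
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
    rownames(ab) <- paste(m$elements, seq_len(n), sep = "_")
    bonds <- m$bonds
    if (is.null(bonds) || !nrow(bonds))
      bb <- matrix(integer(0), 0L, 7L,
                   dimnames = list(NULL, paste0("C", 1:7)))
    else {
      bb <- cbind(bonds[, 1L], bonds[, 2L], bonds[, 3L], 0L, 0L, 0L, 0L)
      dimnames(bb) <- list(seq_len(nrow(bb)), paste0("C", 1:7))
    }
    db <- character(0)
    if (has_charges(m))
      db["PARTIAL_CHARGES"] <- paste(sprintf("%.6f", m$charges), collapse = " ")
    if (!is.null(m$weights))
      for (k in PROPERTY_KINDS)
        db[paste0("COMSIA_", toupper(k))] <-
          paste(sprintf("%.6f", m$weights[, k]), collapse = " ")
    if (!length(db)) db <- c(NO_DATA = "none")
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      n, nrow(bb))
    methods::new("SDF",
                 header = c(Molecule_Name = m$id, Source = "qsar3d",
                            Comment = "", Counts_Line = counts),
                 atomblock = ab, bondblock = bb, datablock = db)
  })
  sdfset <- methods::new("SDFset", SDF = sdfs,
                         ID = vapply(mols, `[[`, character(1L), "id"))
  suppressWarnings(ChemmineR::write.SDF(sdfset, path))
  invisible(path)
}

#' Convert an inhibition constant in nM to pKi
#'
#' `pKi = -log10(Ki * 1e-9)`, i.e. the negative decadic logarithm of the
#' inhibition constant expressed in molar units. The nM input unit is fixed
#' by the activity-file format.
#'
#' @param ki_nM Numeric vector of Ki values in nanomolar, all > 0.
#' @return Numeric vector of pKi values (dimensionless).
#' @examples
#' ki_to_pki(10.8)  # 7.9666
#' ki_to_pki(1)     # 9
#' @export
ki_to_pki <- function(ki_nM) {
  ki_nM <- as.numeric(ki_nM)
  if (any(!is.finite(ki_nM)) || any(ki_nM <= 0))
    stop("Ki must be finite and strictly positive (nM)")
  -log10(ki_nM * 1e-9)
}

#' Inverse of [ki_to_pki()]
#' @param pki Numeric vector of pKi values.
#' @return Ki in nM.
#' @export
pki_to_ki <- function(pki) 10^(-as.numeric(pki)) * 1e9

#' Read an activity table
#'
#' Expects a CSV with header `id,ki_nM` (extra columns are kept). Lines
#' beginning with `#` are treated as comments. A `pki` column is added.
#'
#' @param path CSV file path.
#' @return A data.frame with columns `id` (character), `ki_nM`, `pki`, plus
#'   any extra input columns.
#' @export
read_activities <- function(path) {
  act <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("id", "ki_nM") %in% names(act)))
    stop("activity file must have columns id, ki_nM: ", path)
  act$id <- as.character(act$id)
  if (anyDuplicated(act$id))
    stop("duplicate compound ids in activity file: ",
         paste(unique(act$id[duplicated(act$id)]), collapse = ", "))
  act$pki <- ki_to_pki(act$ki_nM)
  act
}

#' Activity-stratified train/test split
#'
#' Assigns exactly `n_train` records to the training set. The `n - n_train`
#' test compounds are drawn one per equal-frequency pKi bin (records sorted by
#' pKi and cut into `n - n_train` contiguous bins of near-equal size, one
#' random draw per bin), so test activities are spread uniformly over the
#' observed activity range. Deterministic for a given `seed`.
#'
#' @param activities Data.frame with columns `id` and `pki` (see
#'   [read_activities()]).
#' @param n_train Number of training compounds, `0 < n_train <= nrow`.
#' @param seed Integer seed controlling the within-bin draws.
#' @return The input data.frame with an added `subset` factor
#'   (`"train"`/`"test"`).
#' @export
split_train_test <- function(activities, n_train, seed = 1L) {
  n <- nrow(activities)
  if (anyDuplicated(activities$id))
    stop("duplicate compound ids")
  if (n_train <= 0 || n_train > n)
    stop("n_train must be in (0, ", n, "]")
  n_test <- n - n_train
  subset <- rep("train", n)
  if (n_test > 0L) {
    ord <- order(activities$pki, activities$id)
    grp <- if (n_test == 1L) rep(1L, n)
           else cut(seq_len(n), breaks = n_test, labels = FALSE)
    bins <- split(ord, grp)
    picks <- with_seed(seed, vapply(bins, function(b)
      if (length(b) == 1L) b else b[sample.int(length(b), 1L)], numeric(1L)))
    subset[picks] <- "test"
  }
  activities$subset <- factor(subset, levels = c("train", "test"))
  activities
}
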