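#' stdev*coeff contribution field
#'
#' For every lattice point of a given field kind, the product of the
#' descriptor column's standard deviation over the training molecules and
#' its PLS regression coefficient. Columns dropped during descriptor
#' assembly contribute 0. This is the quantity conventionally contoured in
#' CoMFA/CoMSIA maps.
#'
#' @param model A `pls_model` fitted from a `descriptor_matrix`.
#' @param x Optional training `descriptor_matrix` (defaults to the column
#'   sds stored in the model).
#' @param kind A field kind present in the model.
#' @return Numeric vector over all lattice points of the model's grid.
#' @export
stdev_coeff_field <- function(model, x = NULL, kind) {
  col_map <- model$col_map
  if (is.null(col_map)) stop("model carries no column-to-field mapping")
  if (!(kind %in% col_map$kind))
    stop("unknown field kind for this model: ", kind)
  sds <- if (!is.null(x)) apply(as_x_matrix(x), 2L, stats::sd) else model$x_sd
  sel <- col_map$kind == kind
  vals <- numeric(n_grid_points(model$grid))
  vals[col_map$point[sel]] <- sds[sel] * model$coefficients[sel]
  vals
}

#' Extract favored/disfavored contour point sets
#'
#' In the default `"minmax"` mode, values are min-max scaled to [0, 1];
#' lattice points with scaled value strictly above `high` form the favored
#' set, strictly below `low` the disfavored set (the conventional "greater
#' than 80% / less than 20%" contour levels). Note that with this
#' convention a positively skewed field maps its near-zero background close
#' to 0, i.e. into the disfavored set. The `"percentile"` mode instead
#' thresholds at the `high`/`low` quantiles of the value distribution. A
#' constant field yields empty sets with `degenerate = TRUE` and a warning.
#'
#' @param values Numeric vector of per-lattice-point values (e.g. from
#'   [stdev_coeff_field()]).
#' @param grid The `field_grid` the values live on (optional; enables
#'   coordinates in the output).
#' @param high,low Scaled thresholds (defaults 0.80 / 0.20).
#' @param kind Field-kind label stored in the result.
#' @param mode `"minmax"` (default) or `"percentile"`, see above.
#' @return Object of class `contour_set`: list with `favored` and
#'   `disfavored` data.frames (`point`, `x`, `y`, `z`, `value`), `levels`,
#'   `raw_cutoffs` (values of the thresholds on the raw scale), `kind`,
#'   `degenerate`.
#' @export
extract_contours <- function(values, grid = NULL, high = 0.80, low = 0.20,
                             kind = NA_character_,
                             mode = c("minmax", "percentile")) {
  mode <- match.arg(mode)
  if (high <= low) stop("high threshold must exceed low threshold")
  values <- as.numeric(values)
  rng <- range(values)
  pts <- if (!is.null(grid)) grid_points(grid) else
    matrix(NA_real_, length(values), 3L,
           dimnames = list(NULL, c("x", "y", "z")))
  mk <- function(idx) data.frame(point = idx,
                                 x = pts[idx, 1L], y = pts[idx, 2L],
                                 z = pts[idx, 3L], value = values[idx])
  if (rng[1L] == rng[2L]) {
    warning("constant field: no contours extracted")
    return(structure(list(favored = mk(integer(0)),
                          disfavored = mk(integer(0)),
                          levels = c(high = high, low = low),
                          raw_cutoffs = c(high = NA_real_, low = NA_real_),
                          kind = kind, degenerate = TRUE),
                     class = "contour_set"))
  }
  cuts <- if (mode == "minmax")
    c(high = rng[1L] + high * diff(rng), low = rng[1L] + low * diff(rng))
  else
    c(high = unname(stats::quantile(values, high)),
      low = unname(stats::quantile(values, low)))
  structure(list(favored = mk(which(values > cuts[["high"]])),
                 disfavored = mk(which(values < cuts[["low"]])),
                 levels = c(high = high, low = low),
                 raw_cutoffs = cuts,
                 kind = kind, degenerate = FALSE),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set>%s %d favored / %d disfavored points (levels %.0f%%/%.0f%%)%s\n",
              if (is.na(x$kind)) "" else paste0(" [", x$kind, "]"),
              nrow(x$favored), nrow(x$disfavored),
              100 * x$levels[["high"]], 100 * x$levels[["low"]],
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Write a contour set as a labelled CSV point list
#'
#' @param contours A `contour_set`.
#' @param path Output CSV path (columns `x`, `y`, `z`, `value`, `label`).
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  fav <- contours$favored; dis <- contours$disfavored
  fav$label <- rep("favored", nrow(fav))
  dis$label <- rep("disfavored", nrow(dis))
  out <- rbind(fav, dis)[, c("x", "y", "z", "value", "label")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a lattice field as an OpenDX grid file
#'
#' Writes a scalar field over a `field_grid` in the OpenDX "regular
#' positions, regular connections" format readable by PyMOL, VMD and
#' Chimera. Values are reordered from the package's x-fastest enumeration
#' to the z-fastest order OpenDX expects.
#'
#' @param values Numeric vector over the grid points.
#' @param grid The `field_grid`.
#' @param path Output `.dx` path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(values, grid, path) {
  stopifnot(length(values) == n_grid_points(grid))
  d <- grid$dims
  arr <- array(values, dim = d)                 # x fastest
  vz <- as.numeric(aperm(arr, c(3L, 2L, 1L)))   # z fastest for dx
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0 0", grid$spacing),
    sprintf("delta 0 %.6f 0", grid$spacing),
    sprintf("delta 0 0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(values))), con)
  full <- length(vz) %/% 3L
  if (full > 0L)
    writeLines(sprintf("%.6e %.6e %.6e",
                       vz[3 * seq_len(full) - 2L],
                       vz[3 * seq_len(full) - 1L],
                       vz[3 * seq_len(full)]), con)
  rem <- length(vz) %% 3L
  if (rem > 0L)
    writeLines(paste(sprintf("%.6e", vz[(length(vz) - rem + 1L):length(vz)]),
                     collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
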