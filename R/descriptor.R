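#' Assemble a filtered, block-scaled descriptor matrix
#'
#' Concatenates field blocks column-wise after (i) dropping columns whose
#' standard deviation falls below the block's minimum-sigma threshold
#' (constant columns are always dropped), and (ii) rescaling every retained
#' block so all blocks contribute equal total variance ("CoMFA standard
#' scaling" at the block level: each block is divided by the square root of
#' its summed column variances). Column order within a block follows the
#' lattice enumeration; block order follows the input list.
#'
#' @param blocks List of `field_block` objects sharing molecule ordering and
#'   grid.
#' @param min_sigma Named numeric: per-class minimum column standard
#'   deviation. Defaults to 2.0 kcal/mol for CoMFA blocks and 0 for CoMSIA
#'   blocks. A single unnamed number applies to all blocks.
#' @param fit_rows Optional row selector (indices, logical, or molecule ids):
#'   the rows on which filtering and scaling statistics are computed
#'   (typically the training set). All rows are kept in the output matrix;
#'   by default statistics use every row.
#' @return Object of class `descriptor_matrix`: list with `x` (matrix),
#'   `col_map` (data.frame: `kind`, `point` — lattice point index of each
#'   column), `dropped` (named list of dropped point indices per block),
#'   `scale_factors` (named numeric per block), `grid`.
#' @export
assemble_descriptor_matrix <- function(blocks,
                                       min_sigma = c(comfa = 2.0, comsia = 0),
                                       fit_rows = NULL) {
  if (inherits(blocks, "field_block")) blocks <- list(blocks)
  n <- unique(vapply(blocks, function(b) nrow(b$values), integer(1L)))
  if (length(n) != 1L) stop("field blocks have mismatched molecule counts")
  ids <- rownames(blocks[[1L]]$values)
  for (b in blocks)
    if (!identical(rownames(b$values), ids))
      stop("field blocks have mismatched molecule ordering")
  xs <- list(); maps <- list()
  dropped <- list(); scale_factors <- numeric(0)
  for (b in blocks) {
    cls <- if (startsWith(b$kind, "comfa")) "comfa" else "comsia"
    ms <- if (length(min_sigma) == 1L && is.null(names(min_sigma)))
      min_sigma else min_sigma[[cls]]
    fit_v <- if (is.null(fit_rows)) b$values
             else b$values[fit_rows, , drop = FALSE]
    sds <- apply(fit_v, 2L, stats::sd)
    keep <- sds >= ms & sds > 0
    dropped[[b$kind]] <- which(!keep)
    v <- b$values[, keep, drop = FALSE]
    tot_var <- sum(sds[keep]^2)
    f <- if (tot_var > 0) 1 / sqrt(tot_var) else 1
    scale_factors[b$kind] <- f
    xs[[b$kind]] <- v * f
    maps[[b$kind]] <- data.frame(kind = rep(b$kind, sum(keep)),
                                 point = which(keep))
  }
  x <- do.call(cbind, xs)
  col_map <- do.call(rbind, maps)
  rownames(col_map) <- NULL
  if (is.null(x)) stop("no retained columns")
  colnames(x) <- paste(col_map$kind, col_map$point, sep = ".")
  rownames(x) <- ids
  structure(list(x = x, col_map = col_map, dropped = dropped,
                 scale_factors = scale_factors, grid = blocks[[1L]]$grid),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d molecules x %d columns (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(unique(x$col_map$kind), collapse = ", ")))
  invisible(x)
}

#' Subset the rows (molecules) of a descriptor matrix
#' @param dm A `descriptor_matrix`.
#' @param rows Row index vector (integer, logical, or molecule ids).
#' @return A `descriptor_matrix` with the selected rows.
#' @export
dm_rows <- function(dm, rows) {
  dm$x <- dm$x[rows, , drop = FALSE]
  dm
}
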