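# fixture molecules built in code

make_methane <- function() {
  molecule("methane", c("C", "H", "H", "H", "H"),
           rbind(c(0, 0, 0),
                 c(0.6293, 0.6293, 0.6293),
                 c(-0.6293, -0.6293, 0.6293),
                 c(-0.6293, 0.6293, -0.6293),
                 c(0.6293, -0.6293, -0.6293)),
           bonds = cbind(i = 1L, j = 2:5, order = 1L))
}

# atom order matches the reference PEOE charge vector in helper-oracles.R:
# C, C, O, then methyl H x3, methylene H x2, hydroxyl H
make_ethanol <- function() {
  molecule("ethanol", c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
           rbind(c(-0.888, 0.168, -0.010), c(0.468, -0.447, -0.296),
                 c(1.434, 0.600, -0.231), c(-1.648, -0.602, 0.135),
                 c(-0.880, 0.878, 0.818), c(-1.201, 0.717, -0.901),
                 c(0.442, -0.947, -1.271), c(0.747, -1.191, 0.457),
                 c(2.306, 0.212, -0.364)),
           bonds = cbind(i = c(1L, 2L, 1L, 1L, 1L, 2L, 2L, 3L),
                         j = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
                         order = 1L))
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# a small random field_block for PLS-level tests (grid is a 1D stub whose
# point count matches the column count)
stub_block <- function(n, p, kind = "comsia_steric", sd_scale = 1) {
  g <- structure(list(origin = c(0, 0, 0), spacing = 1,
                      dims = c(as.integer(p), 1L, 1L)),
                 class = "field_grid")
  v <- matrix(stats::rnorm(n * p, sd = sd_scale), n, p)
  rownames(v) <- sprintf("m%02d", seq_len(n))
  structure(list(kind = kind, values = v, grid = g), class = "field_block")
}

write_sdf_text <- function(lines, path = tempfile(fileext = ".sdf")) {
  writeLines(lines, path)
  path
}

# minimal V2000 record text
sdf_record <- function(id, xyz, elements, bonds = NULL) {
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  out <- c(id, "  test", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(xyz), nb))
  out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0",
                        xyz[, 1], xyz[, 2], xyz[, 3], elements))
  if (nb > 0)
    out <- c(out, sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2],
                          bonds[, 3]))
  c(out, "M  END", "$$$$")
}
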