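#' Specification for a synthetic pre-aligned molecule set
#'
#' The generator emulates the statistical structure of a ligand-based QSAR
#' series: every molecule shares a rigid scaffold (so common-substructure
#' atom maps are trivial) and carries substituents at a fixed set of
#' attachment sites around the scaffold — each site is independently
#' occupied per molecule by a small group of atoms (position jittered around
#' the site) with random physicochemical property weights, the way an
#' R-group series varies substituents at numbered positions. Activities
#' follow a planted linear model in the molecules' CoMSIA lattice fields: a
#' sparse set of "hotspot" lattice points (each adjacent to a distinct
#' site) of one property kind carries positive weights, and
#' \deqn{pKi_i = intercept + \sum_q w_q A_{k,q}(mol_i) + \epsilon_i,\;
#'   \epsilon_i \sim N(0, noise\_sd^2).}
#' Chemistry realism is deliberately sacrificed for exact ground truth:
#' atoms are points with explicit property weights (all carbon, charges set
#' equal to the electrostatic weight).
#'
#' Defaults mirror the study conditions the package targets: 103 molecules,
#' activity signal spread of 0.8 pKi units around a centre of 7.8, and
#' residual noise of 0.25 pKi units.
#'
#' @param n_molecules Number of molecules (default 103).
#' @param n_scaffold Scaffold atom count (default 8; scaffold geometry and
#'   weights are fixed across molecules).
#' @param n_sites Number of substituent attachment sites (default 10, max
#'   24; site positions are fixed across molecules on a shell of radius
#'   ~4.5 Angstrom coinciding with default lattice points).
#' @param p_occupied Probability that a site carries a substituent in a
#'   given molecule (default 0.5).
#' @param atoms_per_site Integer range (min, max) of heavy atoms per
#'   occupied site (default 3..5, the typical size of the substituents such
#'   a series varies).
#' @param jitter_sd Positional jitter of substituent atoms around their
#'   site, Angstrom (default 0.4, on the order of alignment noise).
#' @param planted_kind Property kind carrying the activity signal
#'   (default `"steric"`).
#' @param n_hotspots Number of planted lattice support points (default 8),
#'   each the lattice point nearest a distinct attachment site.
#' @param signal_sd Standard deviation of the noiseless activity signal,
#'   pKi units (default 0.8).
#' @param noise_sd Gaussian activity noise, pKi units (default 0.25).
#' @param pki_center Mean activity level (default 7.8).
#' @param spacing,margin Lattice parameters used to plant the weights (must
#'   match the pipeline defaults for exact recovery; defaults 2 / 4).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules = 103L, n_scaffold = 8L,
                           n_sites = 10L,
                           p_occupied = 0.5, atoms_per_site = c(3L, 5L),
                           jitter_sd = 0.4,
                           planted_kind = "steric", n_hotspots = 8L,
                           signal_sd = 0.8, noise_sd = 0.25,
                           pki_center = 7.8, spacing = 2.0, margin = 4.0,
                           seed = 1L) {
  planted_kind <- match.arg(planted_kind, PROPERTY_KINDS)
  stopifnot(n_molecules >= 0L, n_scaffold >= 5L, n_hotspots >= 1L,
            n_sites >= n_hotspots, n_sites <= 24L, noise_sd >= 0,
            signal_sd > 0, p_occupied > 0, p_occupied <= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_scaffold = as.integer(n_scaffold),
                 n_sites = as.integer(n_sites),
                 p_occupied = p_occupied,
                 atoms_per_site = as.integer(atoms_per_site),
                 jitter_sd = jitter_sd,
                 planted_kind = planted_kind,
                 n_hotspots = as.integer(n_hotspots),
                 signal_sd = signal_sd, noise_sd = noise_sd,
                 pki_center = pki_center, spacing = spacing, margin = margin,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic, well-separated point shell (Fibonacci sphere) for the
# scaffold cloud, so every dataset shares the same template substructure
fib_shell <- function(n, radius) {
  i <- seq_len(n)
  golden <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / golden
  z <- (2 * i - n - 1) / n           # in (-1, 1)
  r <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

# fixed attachment-site positions: even-integer coordinate points at radius
# sqrt(20) ~ 4.47 A (so they coincide with 2-A lattice points of the default
# grid), chosen greedily for maximal pairwise separation
site_positions <- function(n) {
  perms <- unique(do.call(rbind, lapply(list(c(4, 2, 0), c(4, 0, 2),
                                             c(2, 4, 0), c(2, 0, 4),
                                             c(0, 4, 2), c(0, 2, 4)),
    function(base) {
      signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
      sweep(signs, 2L, base, `*`)
    })))
  chosen <- 1L
  while (length(chosen) < n) {
    d <- apply(perms, 1L, function(p)
      min(sqrt(rowSums(sweep(perms[chosen, , drop = FALSE], 2L, p)^2))))
    d[chosen] <- -Inf
    chosen <- c(chosen, which.max(d))
  }
  out <- perms[chosen, , drop = FALSE]
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Generate a synthetic QSAR dataset with planted ground truth
#'
#' See [synthetic_spec()] for the generative model. The returned truth
#' record carries everything needed to score recovery: the lattice, the
#' planted weight vector over lattice points, and the noiseless activities.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `molecules` (list of [molecule()]; weights assigned),
#'   `activities` (data.frame `id`, `ki_nM`, `pki`), `maps` (named list of
#'   identity atom maps over the scaffold atoms), and `truth` (list:
#'   `grid`, `planted_kind`, `support` (lattice point indices), `weights`
#'   (numeric over all lattice points), `intercept`, `noiseless_pki`,
#'   `spec`).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_molecules == 0L)
    return(list(molecules = list(),
                activities = data.frame(id = character(0),
                                        ki_nM = numeric(0),
                                        pki = numeric(0)),
                maps = list(), truth = NULL))
  with_seed(spec$seed, {
    # scaffold cloud plus two fixed anchor atoms that pin the bounding box
    # (and hence the default lattice) to the same frame in every dataset
    scaf <- rbind(fib_shell(spec$n_scaffold - 2L, 2.5),
                  c(-6, -6, -6), c(6, 6, 6))
    sites <- site_positions(spec$n_sites)
    ns <- nrow(scaf)
    scaf_w <- cbind(steric = rep(1, ns),
                    electrostatic = rep(0.1, ns),
                    hydrophobic = rep(0.3, ns),
                    donor = rep(0, ns),
                    acceptor = rep(0, ns))
    ids <- sprintf("syn%03d", seq_len(spec$n_molecules))
    mols <- lapply(ids, function(id) {
      occ <- which(stats::runif(spec$n_sites) < spec$p_occupied)
      if (!length(occ)) occ <- sample.int(spec$n_sites, 1L)
      xyz <- scaf
      w <- scaf_w
      for (s in occ) {
        na <- sample(seq(spec$atoms_per_site[1L], spec$atoms_per_site[2L]),
                     1L)
        jit <- matrix(stats::rnorm(3L * na, 0, spec$jitter_sd), na, 3L)
        jit <- pmin(pmax(jit, -1.5), 1.5)   # keep atoms inside the anchors
        pos <- sweep(jit, 2L, sites[s, ], `+`)
        sw <- cbind(steric = stats::runif(na, 0.3, 1.5),
                    electrostatic = stats::runif(na, -0.5, 0.5),
                    hydrophobic = stats::runif(na, -0.6, 0.7),
                    donor = stats::rbinom(na, 1L, 0.3),
                    acceptor = stats::rbinom(na, 1L, 0.4))
        xyz <- rbind(xyz, pos)
        w <- rbind(w, sw)
      }
      molecule(id, rep("C", nrow(xyz)), xyz,
               charges = w[, "electrostatic"], weights = w)
    })
    grid <- build_grid(mols, spacing = spec$spacing, margin = spec$margin)
    pts <- grid_points(grid)
    # hotspot support: the lattice point nearest each of n_hotspots
    # randomly chosen attachment sites (the sites coincide with lattice
    # points under the default spacing, so recovery targets are exact)
    hot_sites <- sample.int(spec$n_sites, spec$n_hotspots)
    support <- vapply(hot_sites, function(s)
      which.min(rowSums(sweep(pts, 2L, sites[s, ])^2)), integer(1L))
    support <- unique(support)
    fb <- field_block(mols, grid, paste0("comsia_", spec$planted_kind))
    A <- fb$values[, support, drop = FALSE]
    w_raw <- rep(1, length(support))
    signal <- as.numeric(A %*% w_raw)
    s <- stats::sd(signal)
    if (s == 0) stop("degenerate synthetic signal (no field variance)")
    w_scaled <- w_raw * spec$signal_sd / s
    signal <- signal * spec$signal_sd / s
    intercept <- spec$pki_center - mean(signal)
    noiseless <- intercept + signal
    pki <- noiseless + stats::rnorm(spec$n_molecules, 0, spec$noise_sd)
    weights_full <- numeric(nrow(pts))
    weights_full[support] <- w_scaled
    maps <- stats::setNames(lapply(ids[-1L], function(id)
      cbind(template = seq_len(spec$n_scaffold),
            target = seq_len(spec$n_scaffold))), ids[-1L])
    list(molecules = mols,
         activities = data.frame(id = ids, ki_nM = pki_to_ki(pki),
                                 pki = pki, stringsAsFactors = FALSE),
         maps = maps,
         truth = list(grid = grid, planted_kind = spec$planted_kind,
                      support = sort(support),
                      weights = weights_full, intercept = intercept,
                      noiseless_pki = noiseless, spec = spec))
  })
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Emits `structures.sdf` (with charges and property weights in data
#' fields), `activities.csv` (`id,ki_nM`), one atom-map file per
#' non-template molecule under `maps/` (0-based indices), and the truth
#' record as `truth.json`.
#'
#' @param ds A dataset from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_structures(ds$molecules, file.path(dir, "structures.sdf"))
  utils::write.csv(ds$activities[, c("id", "ki_nM")],
                   file.path(dir, "activities.csv"), row.names = FALSE)
  mapdir <- file.path(dir, "maps")
  dir.create(mapdir, showWarnings = FALSE)
  for (id in names(ds$maps)) {
    m <- ds$maps[[id]]
    writeLines(sprintf("%d %d", m[, 1L] - 1L, m[, 2L] - 1L),
               file.path(mapdir, paste0(id, ".map")))
  }
  if (!is.null(ds$truth)) {
    tr <- ds$truth
    jsonlite::write_json(
      list(planted_kind = tr$planted_kind, support = tr$support,
           weights = tr$weights[tr$support], intercept = tr$intercept,
           noiseless_pki = tr$noiseless_pki,
           grid = list(origin = tr$grid$origin, spacing = tr$grid$spacing,
                       dims = tr$grid$dims),
           spec = unclass(tr$spec)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Score pipeline recovery against the planted truth
#'
#' Runs the modelling stages on a generated dataset and reports how well
#' the planted structure is recovered, in two parts. Predictivity: the
#' leave-one-out Q2 and external R2_pred of the best model from the
#' field-combination search on an activity-stratified train/test split.
#' Map recovery: a PLS model is fitted on the generating field block over
#' the **full** dataset (the target is the generative map, not held-out
#' prediction, so all molecules inform it) with the component count
#' maximising LOO Q2; reported are the cosine similarity between its
#' coefficients mapped back to the lattice and the planted weights, and
#' the Jaccard overlap between its favored stdev*coeff contour and the
#' planted support.
#'
#' @param ds A dataset from [generate_dataset()] (with a truth record).
#' @param n_train Training-set size (default 4:1 split as in the pipeline).
#' @param split_seed Seed for the activity-stratified split.
#' @param max_components PLS component bound for the field-combination
#'   search (default 10).
#' @param recovery_components Component bound for the map-recovery fit
#'   (default 20; resolving correlated neighbour columns takes more latent
#'   directions than prediction does).
#' @param kinds Field kinds searched (default: the five CoMSIA kinds).
#' @return List with `q2`, `r2_pred`, `ncomp`, `best_model`,
#'   `coefficient_cosine`, `favored_jaccard`, and the underlying
#'   `search` object.
#' @export
recovery_report <- function(ds, n_train = NULL, split_seed = 1L,
                            max_components = 10L,
                            recovery_components = 20L,
                            kinds = paste0("comsia_", PROPERTY_KINDS)) {
  if (is.null(ds$truth)) stop("dataset has no truth record")
  n <- length(ds$molecules)
  if (is.null(n_train)) n_train <- max(2L, round(n * 4 / 5))
  act <- split_train_test(ds$activities, n_train, seed = split_seed)
  train <- act$subset == "train"
  grid <- build_grid(ds$molecules, spacing = ds$truth$spec$spacing,
                     margin = ds$truth$spec$margin)
  blocks <- compute_field_blocks(ds$molecules, grid, kinds)
  train_blocks <- lapply(blocks, function(b) {
    b$values <- b$values[train, , drop = FALSE]; b
  })
  search <- model_search(train_blocks, act$pki[train],
                         max_components = max_components)
  best <- search$table$model[1L]
  # test-set predictions: re-assemble with training-row statistics
  dm_all <- assemble_descriptor_matrix(
    blocks[strsplit(search$table$fields[1L], ",")[[1L]]], fit_rows = train)
  refit <- pls_fit(dm_rows(dm_all, train), act$pki[train],
                   search$table$ncomp[1L])
  yhat_test <- predict(refit, dm_rows(dm_all, !train))
  r2p <- r2_pred(act$pki[!train], yhat_test, mean(act$pki[train]))
  # map recovery: fit the generating field block on the full dataset
  planted <- paste0("comsia_", ds$truth$planted_kind)
  dmk <- assemble_descriptor_matrix(blocks[planted])
  cvk <- loo_q2(dmk, act$pki, seq_len(min(recovery_components, n - 2L)))
  fitk <- pls_fit(dmk, act$pki, cvk$ncomp[which.max(cvk$q2)])
  coef_lattice <- numeric(n_grid_points(grid))
  sel <- fitk$col_map$kind == planted
  # undo block scaling so coefficients are on the raw field scale
  coef_lattice[fitk$col_map$point[sel]] <-
    fitk$coefficients[sel] * dmk$scale_factors[[planted]]
  w <- ds$truth$weights
  cosine <- sum(coef_lattice * w) /
    sqrt(sum(coef_lattice^2) * sum(w^2))
  sc <- stdev_coeff_field(fitk, kind = planted)
  ct <- extract_contours(sc, grid = grid)
  fav <- ct$favored$point
  jac <- length(intersect(fav, ds$truth$support)) /
    length(union(fav, ds$truth$support))
  list(q2 = search$table$q2[1L], r2_pred = r2p,
       ncomp = search$table$ncomp[1L], best_model = best,
       coefficient_cosine = cosine, favored_jaccard = jac,
       search = search)
}

#' Y-scrambling permutation reference for Q2
#'
#' Recomputes the leave-one-out Q2 after randomly permuting the activities,
#' repeated `n_permutations` times. A sound model's real Q2 should far
#' exceed the permuted values, whose median is expected at or below zero.
#'
#' @param x Descriptors (matrix or `descriptor_matrix`).
#' @param y Response vector.
#' @param ncomp Component count used for every permuted refit (convention:
#'   the component count of the real model).
#' @param n_permutations Number of permutations (default 20).
#' @param seed Integer seed.
#' @return Numeric vector of permuted-Q2 values.
#' @export
permutation_q2 <- function(x, y, ncomp, n_permutations = 20L, seed = 1L) {
  with_seed(seed, {
    vapply(seq_len(n_permutations), function(i)
      loo_q2(x, sample(y), ncomp)$q2, numeric(1L))
  })
}
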