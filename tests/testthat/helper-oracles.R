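# Independent oracles and small fixture builders used across the suite.

# --- rotation-minimization oracle for superposition -------------------------
# Minimizes the mean squared deviation over proper rotations parameterized by
# Euler angles, with multiple optimizer starts; independent of the SVD path.

rot_euler <- function(p) {
  ca <- cos(p[1]); sa <- sin(p[1])
  cb <- cos(p[2]); sb <- sin(p[2])
  cg <- cos(p[3]); sg <- sin(p[3])
  rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3)
  rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3)
  rz1 %*% ry %*% rz2
}

oracle_rmsd <- function(mobile, fixed, n_starts = 8) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(fixed, 2, colMeans(fixed))
  msd <- function(p) mean(rowSums((A %*% rot_euler(p) - B)^2))
  starts <- rbind(c(0, 0, 0), c(pi, 0, 0), c(0, pi / 2, 0), c(0, 0, pi),
                  matrix(stats::runif(3 * n_starts, -pi, pi), ncol = 3))
  best <- Inf
  for (k in seq_len(nrow(starts))) {
    r <- stats::optim(starts[k, ], msd, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 500))
    r <- stats::optim(r$par, msd, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 2000))
    best <- min(best, r$value)
  }
  sqrt(best)
}

random_points <- function(n, spread = 10) {
  matrix(stats::rnorm(3 * n, sd = spread), ncol = 3)
}

random_rotation <- function() {
  rot_euler(stats::runif(3, -pi, pi))
}

# --- exhaustive re-implementation of the greedy clustering ------------------
# Plain double loops, no adjacency matrix tricks; same tie-break convention
# (neighbor count desc, then rank, then lexicographic id).

oracle_cluster <- function(vals, ids, cutoff, ranks = rep(0L, length(ids))) {
  n <- length(ids)
  un <- rep(TRUE, n)
  out <- list()
  while (any(un)) {
    ui <- which(un)
    cnt <- vapply(ui, function(i)
      sum(vapply(ui, function(j) j != i && vals[i, j] < cutoff, TRUE)), 0L)
    med <- ui[order(-cnt, ranks[ui], ids[ui])][1L]
    nb <- ui[ui != med & vals[med, ui] < cutoff]
    memb <- c(med, nb[order(vals[med, nb], ranks[nb], ids[nb])])
    out[[length(out) + 1L]] <- list(medoid = ids[med], members = ids[memb])
    un[memb] <- FALSE
  }
  out
}

random_dist_matrix <- function(n, max_d = 10) {
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- stats::runif(n * (n - 1) / 2, 0, max_d)
  v <- v + t(v)
  ids <- sprintf("m%03d", seq_len(n))
  dimnames(v) <- list(ids, ids)
  structure(list(ids = ids, values = v), class = "dist_matrix")
}

# distance matrix from 3D cluster centers: satisfies the triangle inequality
geometric_dist_matrix <- function(n, n_centers = 3, spread = 1, sep = 10) {
  centers <- matrix(stats::rnorm(3 * n_centers, sd = sep), ncol = 3)
  lab <- sample.int(n_centers, n, replace = TRUE)
  pts <- centers[lab, , drop = FALSE] +
    matrix(stats::rnorm(3 * n, sd = spread), ncol = 3)
  v <- as.matrix(stats::dist(pts))
  ids <- sprintf("m%03d", seq_len(n))
  dimnames(v) <- list(ids, ids)
  list(dm = structure(list(ids = ids, values = v), class = "dist_matrix"),
       labels = lab)
}

# --- small structure fixtures ------------------------------------------------

toy_model <- function(coords, res_names = NULL, atoms_per_res = NULL,
                      model_id = "toy", homolog = "target", rank = 1L) {
  # coords: list of per-residue named n x 3 matrices
  residues <- lapply(seq_along(coords), function(k)
    list(res_name = if (is.null(res_names)) "A" else res_names[k],
         atoms = coords[[k]]))
  rna_model(residues, model_id = model_id, homolog = homolog, rank = rank)
}

# a small rigid motion applied to an rna_model or a coordinate matrix
apply_rigid <- function(x, R = random_rotation(), t = stats::rnorm(3, sd = 5)) {
  if (is.matrix(x)) return(sweep(x %*% R, 2, -t))
  for (k in seq_along(x$residues))
    x$residues[[k]]$atoms <- sweep(x$residues[[k]]$atoms %*% R, 2, -t)
  x
}

# cached medium synthetic fixture shared by tests in one session
fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, spec) {
  if (!is.null(fixture_cache[[key]])) return(fixture_cache[[key]])
  dir <- file.path(tempdir(), paste0("fix_", key))
  fx <- make_fixture(spec, dir)
  fx$spec <- spec
  fixture_cache[[key]] <- fx
  fx
}

small_fixture <- function() {
  cached_fixture("small", synthetic_spec(
    n_homologs = 3, core_len = 20, n_models_per_homolog = 10,
    n_clusters = 2, within_sigma = 0.6, between_shift = 10, seed = 11))
}

full_fixture <- function(seed = 1) {
  cached_fixture(paste0("full", seed), synthetic_spec(seed = seed))
}

# run the whole pipeline in memory on a fixture, reusing cached stages
pipeline_on <- function(fx, mode = "one_of_six", limit = 1000L) {
  models <- load_model_set(fx$models_dir, fx$mapping, per_homolog_limit = limit)
  aln <- read_alignment(fx$alignment)
  core <- conserved_core(aln, selected = unique(
    vapply(models$models, function(m) m$homolog, "")))
  dm <- all_vs_all(models, core)
  ranks <- vapply(models$models, function(m) m$rank, 0L)
  clusters <- autocluster(dm, mode = mode, ranks = ranks)
  sel <- select_final(clusters, models)
  list(models = models, aln = aln, core = core, dm = dm,
       clusters = clusters, sel = sel)
}
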