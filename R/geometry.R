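#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of two paired point sets by the
#' covariance-SVD construction with determinant sign correction, so the
#' returned rotation is always proper (no reflection). The reported RMSD is
#' the global minimum of `sqrt(mean(delta_i^2))` over all proper rigid
#' motions of `mobile`, where `delta_i` is the distance between paired
#' points.
#'
#' @param mobile,fixed Numeric n x 3 matrices of paired coordinates
#'   (rows = points), n >= 3 and not all collinear.
#' @return List with `rotation` (3 x 3, det = +1), `translation`
#'   (length-3), and `rmsd` (Angstrom). The fitted mobile coordinates are
#'   `mobile %*% rotation + translation` (row-vector convention).
#' @export
superpose <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (ncol(mobile) != 3L || ncol(fixed) != 3L)
    stop("coordinates must be n x 3 matrices")
  n <- nrow(mobile)
  if (n != nrow(fixed))
    stop("point count mismatch: ", n, " vs ", nrow(fixed))
  if (n < 3L) stop("degenerate geometry: need at least 3 points")
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2L, cm); B <- sweep(fixed, 2L, cf)
  if (is_collinear(A) || is_collinear(B))
    stop("degenerate geometry: points are collinear")
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  e0 <- sum(A * A) + sum(B * B)
  msd <- max(0, (e0 - 2 * (s$d[1L] + s$d[2L] + d * s$d[3L])) / n)
  list(rotation = R,
       translation = as.numeric(cf - cm %*% R),
       rmsd = sqrt(msd))
}

is_collinear <- function(centered, tol = 1e-8) {
  sv <- svd(centered, nu = 0L, nv = 0L)$d
  sv[2L] <= tol * max(sv[1L], 1e-12)
}

#' All-heavy-atom RMSD between two models of the same sequence
#'
#' Pairs residues positionally (both models must have the same residue
#' count), intersects heavy-atom names per residue pair — decoys differ in
#' atom completeness, so only atoms present in both residues are compared —
#' and returns the RMSD after optimal superposition over all paired heavy
#' atoms. Hydrogens (atom names starting with H, or digit-prefixed like
#' `1H5'`) are excluded.
#'
#' @param model,reference [rna_model] objects with equal residue counts.
#' @return RMSD in Angstrom.
#' @export
rmsd_heavy <- function(model, reference) {
  stopifnot(inherits(model, "rna_model"), inherits(reference, "rna_model"))
  if (length(model$residues) != length(reference$residues))
    stop("residue count mismatch (", length(model$residues), " vs ",
         length(reference$residues),
         "): heavy-atom RMSD needs models of the same sequence")
  xs <- list(); ys <- list()
  for (k in seq_along(model$residues)) {
    am <- model$residues[[k]]$atoms
    ar <- reference$residues[[k]]$atoms
    common <- intersect(heavy_names(rownames(am)), heavy_names(rownames(ar)))
    if (length(common)) {
      xs[[length(xs) + 1L]] <- am[common, , drop = FALSE]
      ys[[length(ys) + 1L]] <- ar[common, , drop = FALSE]
    }
  }
  X <- do.call(rbind, xs); Y <- do.call(rbind, ys)
  if (is.null(X) || nrow(X) < 3L)
    stop("fewer than 3 shared heavy atoms between models")
  superpose(X, Y)$rmsd
}

heavy_names <- function(nms) {
  nms[!grepl("^[0-9]*H", nms)]
}

#' Extract the C3' core trace of a model
#'
#' One C3' coordinate per conserved-core column, in core-column order. This
#' is the representation on which core RMSD and hence the whole clustering
#' operate: the same number of atoms for every model regardless of sequence
#' length.
#'
#' @param model An [rna_model] whose `homolog` appears in `core$per_seq`.
#' @param core A `core_map` from [conserved_core()].
#' @return Object of class `core_trace`: list with `model_id` and `points`
#'   (k x 3 matrix, k = number of core columns).
#' @export
core_trace <- function(model, core) {
  stopifnot(inherits(model, "rna_model"), inherits(core, "core_map"))
  h <- model$homolog
  if (is.na(h) || !h %in% names(core$per_seq))
    stop("model '", model$model_id, "': homolog '", h,
         "' not present in the core map")
  resi <- core$per_seq[[h]]
  pts <- matrix(NA_real_, nrow = length(resi), ncol = 3L)
  for (k in seq_along(resi)) {
    i <- resi[k]
    if (is.na(i))
      stop("model '", model$model_id, "': sequence gapped at core column ",
           core$columns[k])
    if (i > length(model$residues))
      stop("model '", model$model_id, "': residue ", i,
           " (core column ", core$columns[k], ") missing from structure")
    at <- model$residues[[i]]$atoms
    pts[k, ] <- at["C3'", ]
  }
  structure(list(model_id = model$model_id, points = pts),
            class = "core_trace")
}

#' Core RMSD between two traces
#'
#' RMSD over the C3' atoms of the conserved core after optimal proper-rigid
#' superposition. Defined between models of different homologs because core
#' traces always have the same number of points.
#'
#' @param a,b `core_trace` objects of equal length.
#' @return RMSD in Angstrom.
#' @export
core_rmsd <- function(a, b) {
  stopifnot(inherits(a, "core_trace"), inherits(b, "core_trace"))
  superpose(a$points, b$points)$rmsd
}

#' All-vs-all core RMSD matrix
#'
#' Computes the symmetric matrix of pairwise core RMSDs over every model in
#' the set; each pair is computed once and mirrored. Any model that cannot
#' be traced (missing residue or C3') aborts the computation with its id.
#'
#' @param models A `model_set` (or plain list of [rna_model]).
#' @param core A `core_map` covering every model's homolog.
#' @return Object of class `dist_matrix`: list with `ids` and `values`
#'   (symmetric numeric matrix, zero diagonal, Angstrom).
#' @export
all_vs_all <- function(models, core) {
  mods <- if (inherits(models, "model_set")) models$models else models
  n <- length(mods)
  if (n == 0L) stop("no models")
  traces <- lapply(mods, core_trace, core = core)
  ids <- unname(vapply(traces, function(t) t$model_id, ""))
  # precenter and cache squared norms; pair cost is then one 3x3 crossprod + svd
  centered <- lapply(traces, function(t) sweep(t$points, 2L, colMeans(t$points)))
  e <- vapply(centered, function(m) sum(m * m), 0)
  npts <- nrow(centered[[1L]])
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    Ai <- centered[[i]]
    for (j in (i + 1L):n) {
      H <- crossprod(Ai, centered[[j]])
      s <- svd(H, nu = 0L, nv = 0L)$d
      dt <- det(H)
      tr <- if (dt < 0) s[1L] + s[2L] - s[3L] else sum(s)
      r <- sqrt(max(0, (e[i] + e[j] - 2 * tr) / npts))
      vals[i, j] <- r
      vals[j, i] <- r
    }
  }
  structure(list(ids = ids, values = vals), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat("dist_matrix: ", length(x$ids), " models; core RMSD range [",
      sprintf("%.2f", min(v)), ", ", sprintf("%.2f", max(v)), "] A\n", sep = "")
  invisible(x)
}

#' Write / read a distance matrix as whitespace-separated text
#'
#' Line 1 holds the model ids; the following n lines hold n values each at
#' 3-decimal precision. The reader tolerates extra whitespace and
#' re-symmetrizes nothing: the file is expected to be symmetric as written.
#'
#' @param dm A `dist_matrix`.
#' @param path Output path.
#' @export
write_dist_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "dist_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(dm$ids, collapse = " "), con)
  writeLines(apply(dm$values, 1L, function(r)
    paste(sprintf("%.3f", r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  n <- length(ids)
  if (length(lines) < n + 1L) stop("truncated distance matrix file: ", path)
  vals <- do.call(rbind, lapply(lines[2:(n + 1L)], function(l)
    as.numeric(strsplit(trimws(l), "[ \t]+")[[1L]])))
  if (ncol(vals) != n) stop("distance matrix is not ", n, " x ", n, ": ", path)
  dimnames(vals) <- list(ids, ids)
  structure(list(ids = ids, values = vals), class = "dist_matrix")
}
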