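#' Specification of a synthetic decoy-set fixture
#'
#' Bundles and validates the parameters of the synthetic generator. The
#' generated fixture emulates the exact input layout of the real pipeline:
#' an alignment over a target and homologs sharing an ungapped conserved
#' core, a directory of ranked decoy models per homolog, and a mapping
#' file — plus ground-truth planted cluster labels, which real inputs never
#' have.
#'
#' Decoys are perturbed ground-truth conformations, not physically folded
#' structures: cluster `k` hinges the second half of the core by a rigid
#' motion of magnitude `(k-1) * between_shift` (a whole-structure rigid
#' motion would be invisible to a superposition-based metric), and each
#' decoy adds isotropic per-coordinate Gaussian jitter of sd `within_sigma`
#' on every atom.
#'
#' @param n_homologs Total number of sequences including the target (>= 2).
#' @param core_len Conserved-core length in residues (>= 8).
#' @param insert_lens Integer vector of per-homolog non-core insertion
#'   lengths (recycled); default a small varied series.
#' @param n_models_per_homolog Decoys generated per homolog.
#' @param n_clusters Number of planted conformational clusters.
#' @param within_sigma Per-atom, per-coordinate Gaussian jitter sd (Angstrom).
#' @param between_shift Rigid hinge displacement separating consecutive
#'   planted clusters (Angstrom). A warning is issued when
#'   `between_shift <= 4 * within_sigma` (clusters may not be separable).
#' @param helix_fraction Fraction of core residues that are helical
#'   (paired); default 0.6.
#' @param seed Integer RNG seed; the fixture is deterministic given it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_homologs = 5, core_len = 40, insert_lens = NULL,
                           n_models_per_homolog = 100, n_clusters = 3,
                           within_sigma = 1, between_shift = 12,
                           helix_fraction = 0.6, seed = 1) {
  if (n_homologs < 2) stop("n_homologs must be >= 2")
  if (core_len < 8) stop("core_len must be >= 8")
  if (n_models_per_homolog < 1 || n_clusters < 1)
    stop("model and cluster counts must be positive")
  if (within_sigma < 0 || between_shift < 0)
    stop("within_sigma and between_shift must be non-negative")
  if (helix_fraction < 0 || helix_fraction > 1)
    stop("helix_fraction must be in [0, 1]")
  if (is.null(insert_lens)) insert_lens <- (seq_len(n_homologs) * 2L) %% 7L + 1L
  insert_lens <- rep_len(as.integer(insert_lens), n_homologs)
  if (n_clusters > 1 && between_shift <= 4 * within_sigma)
    warning("between_shift <= 4 * within_sigma: planted clusters may overlap")
  structure(list(n_homologs = as.integer(n_homologs),
                 core_len = as.integer(core_len),
                 insert_lens = insert_lens,
                 n_models_per_homolog = as.integer(n_models_per_homolog),
                 n_clusters = as.integer(n_clusters),
                 within_sigma = within_sigma, between_shift = between_shift,
                 helix_fraction = helix_fraction, seed = as.integer(seed)),
            class = "synthetic_spec")
}

cyl <- function(radius, angle_deg, z) {
  a <- angle_deg * pi / 180
  c(radius * cos(a), radius * sin(a), z)
}

# residue atom stub at a helical position: backbone (P, C3'), glycosidic
# anchor (C1') and a planar base ring whose innermost atom is the WC-edge
# atom (N1 for purines, N3 for pyrimidines)
helical_residue <- function(letter, angle, z, rise) {
  purine <- letter %in% c("A", "G")
  inner <- if (purine) "N1" else "N3"
  outer <- if (purine) "N9" else "N1"
  mid1 <- "C2"
  mid2 <- if (purine) "C6" else "C4"
  atoms <- rbind(
    "P"   = cyl(9.8, angle + 8, z + 0.4 * rise),
    "C3'" = cyl(9.4, angle, z),
    "C1'" = cyl(5.4, angle, z))
  base <- rbind(cyl(1.7, angle, z), cyl(2.6, angle + 12, z),
                cyl(2.6, angle - 12, z), cyl(3.6, angle, z))
  rownames(base) <- c(inner, mid1, mid2, outer)
  list(res_name = letter, atoms = rbind(atoms, base))
}

# residue stub on an extended (unpaired) segment centered at `center`
extended_residue <- function(letter, center) {
  purine <- letter %in% c("A", "G")
  inner <- if (purine) "N1" else "N3"
  outer <- if (purine) "N9" else "N1"
  mid2 <- if (purine) "C6" else "C4"
  off <- rbind(
    "P"   = c(1.5, 0.0, 0.8),
    "C3'" = c(0.0, 0.0, 0.0),
    "C1'" = c(-1.2, 0.9, 0.0))
  base <- rbind(c(-2.2, 1.4, 0.0), c(-2.9, 0.6, 0.6),
                c(-2.9, 2.2, 0.6), c(-3.7, 1.4, 1.2))
  rownames(base) <- c(inner, "C2", mid2, outer)
  all <- rbind(off, base)
  list(res_name = letter,
       atoms = sweep(all, 2L, -center))  # add center to every offset
}

#' Parametric A-form-like backbone with planted pairing
#'
#' Builds an idealized helical trace for the paired fraction of the chain
#' — rise 2.8 Angstrom and twist 32.7 degrees per base-pair step, C3'
#' radius 9.4 Angstrom about the helix axis, the complementary strand
#' offset by 150 degrees so that paired C1'-C1' distances match A-form
#' (~10.4 Angstrom) — plus an extended linker for the unpaired remainder.
#' Each residue carries C3', C1', P and a planar base-atom stub at
#' idealized offsets; the innermost base atom sits on the Watson-Crick
#' edge, so planted pairs are recoverable by [detect_interactions()].
#'
#' With `helix_fraction = f`, the first `P = floor(core_len * f / 2)`
#' residues pair with the last `P` in reverse order, recorded in the
#' dot-bracket attached as attribute `"ss"`.
#'
#' @param core_len Number of residues (>= 8).
#' @param helix_fraction Fraction of residues that are paired.
#' @param sequence Optional residue letters (length `core_len`); default
#'   alternating G/C in the helix, A in the linker.
#' @param rise,twist,radius Helix parameters (Angstrom, degrees/residue,
#'   Angstrom).
#' @return An [rna_model] with attribute `"ss"` (dot-bracket string).
#' @export
make_backbone <- function(core_len, helix_fraction = 0.6, sequence = NULL,
                          rise = 2.8, twist = 32.7, radius = 9.4) {
  if (core_len < 8) stop("core_len must be >= 8")
  npair <- floor(core_len * helix_fraction / 2)
  if (is.null(sequence)) {
    sequence <- rep("A", core_len)
    if (npair > 0) {
      sequence[seq_len(npair)] <- rep(c("G", "C"), length.out = npair)
      sequence[core_len + 1 - seq_len(npair)] <-
        rep(c("C", "G"), length.out = npair)
    }
  }
  stopifnot(length(sequence) == core_len)
  residues <- vector("list", core_len)
  ztop <- if (npair > 0) (npair - 1) * rise else 0
  for (i in seq_len(core_len)) {
    if (npair > 0 && i <= npair) {            # 5' strand
      residues[[i]] <- helical_residue(sequence[i], (i - 1) * twist,
                                       (i - 1) * rise, rise)
    } else if (npair > 0 && i > core_len - npair) {   # 3' strand, antiparallel
      p <- core_len + 1 - i
      residues[[i]] <- helical_residue(sequence[i], (p - 1) * twist + 150,
                                       (p - 1) * rise, rise)
    } else {                                  # unpaired linker above the helix
      l <- i - npair
      residues[[i]] <- extended_residue(sequence[i],
                                        c(0, 0, ztop + 2 + 6.5 * l))
    }
  }
  ss <- rep(".", core_len)
  if (npair > 0) {
    ss[seq_len(npair)] <- "("
    ss[core_len + 1 - seq_len(npair)] <- ")"
  }
  m <- rna_model(residues, model_id = "backbone")
  attr(m, "ss") <- paste(ss, collapse = "")
  m
}

# unit displacement directions for consecutive planted clusters
cluster_direction <- function(k) {
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
               c(0, 1, 1) / sqrt(2))
  dirs[[(k - 1L) %% length(dirs) + 1L]]
}

# hinge the atoms of residues `moved` by the cluster-k rigid motion:
# rotation about z through the moved block's centroid, then a translation
# of magnitude (k-1) * shift
apply_cluster_motion <- function(model, moved, k, shift) {
  if (k == 1L || length(moved) == 0L) return(model)
  ang <- (k - 1L) * 20 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3L, 3L)
  allxyz <- do.call(rbind, lapply(model$residues[moved], `[[`, "atoms"))
  ctr <- colMeans(allxyz)
  tr <- (k - 1L) * shift * cluster_direction(k)
  for (i in moved) {
    at <- model$residues[[i]]$atoms
    model$residues[[i]]$atoms <-
      sweep(sweep(at, 2L, ctr) %*% R, 2L, -(ctr + tr))
  }
  model
}

jitter_model <- function(model, sigma) {
  if (sigma <= 0) return(model)
  for (i in seq_along(model$residues)) {
    at <- model$residues[[i]]$atoms
    model$residues[[i]]$atoms <-
      at + matrix(stats::rnorm(length(at), sd = sigma), nrow = nrow(at),
                  dimnames = dimnames(at))
  }
  model
}

#' Generate a complete synthetic input fixture
#'
#' Writes, under `dir`: `alignment.fasta` (aligned FASTA over the target
#' and homologs, each homolog's insertions gapped out in all other rows so
#' the conserved core is exactly the planted core columns), `decoys/` with
#' `<homolog>_<rank>.pdb` decoy models, `mapping.tsv`
#' (`sequence_name<TAB>glob`), `reference.pdb` (the unperturbed target
#' conformation — a synthetic stand-in for an experimental structure),
#' `reference_ss.txt` (its dot-bracket) and `ground_truth.json` (planted
#' cluster label per model id, planted core columns, reference paths).
#'
#' Deterministic for a fixed `spec$seed`: two runs produce byte-identical
#' files. The caller's RNG state is left untouched.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `alignment`, `models_dir`, `mapping`,
#'   `reference`, `reference_ss`, `truth_json` (paths), `target`,
#'   and `truth` (list: `labels` named by model id, `core_columns`,
#'   `reference_ss` string).
#' @export
make_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(file.path(dir, "decoys"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(file.path(dir, "decoys")))
    stop("cannot create fixture directory: ", dir)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(spec$seed)

  K <- spec$n_homologs
  L <- spec$core_len
  homs <- c("target", if (K > 1) paste0("hom", seq_len(K - 1L) + 1L))
  mid <- floor(L / 2)

  # core sequences: shared ancestor, 20% substitutions per homolog
  anc <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
  core_seq <- lapply(seq_len(K), function(h) {
    s <- anc
    mut <- stats::runif(L) < 0.2
    s[mut] <- sample(c("A", "C", "G", "U"), sum(mut), replace = TRUE)
    s
  })
  ins_seq <- lapply(seq_len(K), function(h)
    sample(c("A", "C", "G", "U"), spec$insert_lens[h], replace = TRUE))

  # gapped alignment rows: core halves flank per-homolog private insert blocks
  ins_tot <- sum(spec$insert_lens)
  rows <- vapply(seq_len(K), function(h) {
    blocks <- vapply(seq_len(K), function(g) {
      if (g == h) paste(ins_seq[[g]], collapse = "")
      else strrep("-", spec$insert_lens[g])
    }, "")
    paste0(paste(core_seq[[h]][seq_len(mid)], collapse = ""),
           paste(blocks, collapse = ""),
           paste(core_seq[[h]][(mid + 1):L], collapse = ""))
  }, "")
  names(rows) <- homs
  aln_path <- file.path(dir, "alignment.fasta")
  writeLines(as.vector(rbind(paste0(">", homs), rows)), aln_path)
  core_columns <- c(seq_len(mid), mid + ins_tot + seq_len(L - mid))

  # per-homolog ground-truth chains: shared core conformation + own inserts.
  # The backbone is rebuilt per homolog so base-atom names follow each
  # sequence's purine/pyrimidine identity; the geometry is identical.
  core_bb <- make_backbone(L, spec$helix_fraction)
  chains <- lapply(seq_len(K), function(h) {
    res <- make_backbone(L, spec$helix_fraction,
                         sequence = core_seq[[h]])$residues
    nins <- spec$insert_lens[h]
    ins <- lapply(seq_len(nins), function(l)
      extended_residue(ins_seq[[h]][l], c(15 + 6.5 * l, 4 * h, -10)))
    rna_model(c(res[seq_len(mid)], ins, res[(mid + 1):L]),
              model_id = homs[h], homolog = homs[h])
  })
  # chain indices hinged by the cluster motion: second half of the core
  moved <- lapply(seq_len(K), function(h)
    (mid + spec$insert_lens[h] + 1L):(L + spec$insert_lens[h]))

  digits <- max(3L, nchar(as.character(spec$n_models_per_homolog)))
  fmt <- paste0("%s_%0", digits, "d")
  labels <- integer(0)
  map_lines <- character(0)
  for (h in seq_len(K)) {
    lab <- sample.int(spec$n_clusters, spec$n_models_per_homolog,
                      replace = TRUE)
    for (r in seq_len(spec$n_models_per_homolog)) {
      id <- sprintf(fmt, homs[h], r)
      m <- chains[[h]]
      m$model_id <- id
      m$rank <- r
      m <- apply_cluster_motion(m, moved[[h]], lab[r], spec$between_shift)
      m <- jitter_model(m, spec$within_sigma)
      write_pdb_model(m, file.path(dir, "decoys", paste0(id, ".pdb")))
      labels[id] <- lab[r]
    }
    map_lines <- c(map_lines, paste0(homs[h], "\t", homs[h], "_*.pdb"))
  }
  map_path <- file.path(dir, "mapping.tsv")
  writeLines(map_lines, map_path)

  # unperturbed target conformation = synthetic reference structure
  ref <- chains[[1L]]
  ref$model_id <- "reference"
  ref_path <- file.path(dir, "reference.pdb")
  write_pdb_model(ref, ref_path)
  core_ss <- strsplit(attr(core_bb, "ss"), "")[[1L]]
  ref_ss <- paste(c(core_ss[seq_len(mid)], rep(".", spec$insert_lens[1L]),
                    core_ss[(mid + 1):L]), collapse = "")
  ss_path <- file.path(dir, "reference_ss.txt")
  writeLines(ref_ss, ss_path)

  truth <- list(labels = as.list(labels), core_columns = core_columns,
                reference_ss = ref_ss, target = "target", seed = spec$seed)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(alignment = aln_path, models_dir = file.path(dir, "decoys"),
                 mapping = map_path, reference = ref_path,
                 reference_ss = ss_path, truth_json = truth_path,
                 target = "target",
                 truth = list(labels = labels, core_columns = core_columns,
                              reference_ss = ref_ss)))
}
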