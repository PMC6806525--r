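test_that("superpose recovers exact zero on rigid copies", {
  set.seed(1)
  A <- random_points(12)
  expect_equal(superpose(A, A)$rmsd, 0, tolerance = 1e-10)
  # 90-degree rotation about z plus a translation
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  B <- sweep(A %*% R90, 2, -c(5, 0, 0))
  s <- superpose(A, B)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(s$rotation), 1, tolerance = 1e-10)
  # the fitted coordinates land on the target
  expect_equal(sweep(A %*% s$rotation, 2, -s$translation), B,
               tolerance = 1e-8)
})

test_that("superpose rejects degenerate input", {
  A <- random_points(5)
  expect_error(superpose(A, A[1:4, ]), "mismatch")
  expect_error(superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("superpose matches the numerical rotation-minimization oracle", {
  set.seed(20)
  for (rep in 1:8) {
    n <- sample(4:20, 1)
    A <- random_points(n)
    B <- random_points(n)
    expect_equal(superpose(A, B)$rmsd, oracle_rmsd(A, B), tolerance = 1e-6)
  }
})

test_that("superpose never returns a reflection", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    s <- superpose(random_points(n), random_points(n))
    expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  }
})

test_that("superpose agrees with bio3d's fitted RMSD", {
  set.seed(22)
  for (rep in 1:5) {
    A <- random_points(15)
    B <- random_points(15)
    ours <- superpose(A, B)$rmsd
    theirs <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
    expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d rounds to 3 decimals
  }
})

test_that("rmsd_heavy: zero on self and rigid copies, exact on a displaced atom", {
  set.seed(30)
  coords <- lapply(1:2, function(k) {
    at <- matrix(stats::rnorm(12, sd = 8), ncol = 3)
    rownames(at) <- c("P", "C3'", "N1", "C2")
    at
  })
  m <- toy_model(coords)
  expect_equal(rmsd_heavy(m, m), 0, tolerance = 1e-10)
  expect_equal(rmsd_heavy(m, apply_rigid(m)), 0, tolerance = 1e-8)
})

test_that("rmsd_heavy with a single 2 A displacement over 5 shared atoms is 2/sqrt(5)", {
  # 5 paired heavy atoms; one moved 2 A along x; optimal superposition is
  # re-minimized by the oracle, which confirms the analytic value
  base1 <- matrix(c(0, 0, 0, 4, 0, 0, 0, 4, 0), ncol = 3, byrow = TRUE)
  rownames(base1) <- c("P", "C3'", "N1")
  base2 <- matrix(c(10, 0, 0, 10, 4, 0), ncol = 3, byrow = TRUE)
  rownames(base2) <- c("C3'", "C2")
  m_ref <- toy_model(list(base1, base2))
  moved2 <- base2
  moved2["C2", 1] <- moved2["C2", 1] + 2
  m_pred <- toy_model(list(base1, moved2))
  direct <- rmsd_heavy(m_pred, m_ref)
  oracle <- oracle_rmsd(rbind(base1, moved2), rbind(base1, base2))
  expect_equal(direct, oracle, tolerance = 1e-6)
  expect_lt(direct, 2 / sqrt(5) + 1e-9)   # superposition can only improve
  expect_gt(direct, 0.8 * 2 / sqrt(5))    # but not by much for this geometry
  # hydrogens never enter
  h <- base2
  rownames(h) <- c("C3'", "H5'")
  expect_equal(rmsd_heavy(toy_model(list(base1, h)), m_ref), 0,
               tolerance = 1e-8)
  expect_error(rmsd_heavy(m_ref, toy_model(list(base1))), "mismatch")
})

test_that("core_trace picks C3' of mapped residues and errors on gaps", {
  fx <- small_fixture()
  ms <- load_model_set(fx$models_dir, fx$mapping, per_homolog_limit = 2)
  core <- conserved_core(read_alignment(fx$alignment))
  tr <- core_trace(ms$models[[1]], core)
  expect_s3_class(tr, "core_trace")
  expect_equal(nrow(tr$points), length(core$columns))
  m <- ms$models[[1]]
  resi <- core$per_seq[[m$homolog]]
  expect_equal(tr$points[3, ],
               unname(m$residues[[resi[3]]]$atoms["C3'", ]))
  # homolog absent from the map
  m$homolog <- "nobody"
  expect_error(core_trace(m, core), "nobody")
})

test_that("core_rmsd is symmetric, rigid-invariant, and matches the oracle", {
  set.seed(40)
  a <- structure(list(model_id = "a", points = random_points(15)),
                 class = "core_trace")
  b <- structure(list(model_id = "b", points = random_points(15)),
                 class = "core_trace")
  expect_equal(core_rmsd(a, a), 0, tolerance = 1e-10)
  expect_equal(core_rmsd(a, b), core_rmsd(b, a), tolerance = 1e-12)
  expect_equal(core_rmsd(a, b), oracle_rmsd(a$points, b$points),
               tolerance = 1e-6)
  for (rep in 1:5) {
    b2 <- b
    b2$points <- apply_rigid(b$points)
    expect_equal(core_rmsd(a, b2), core_rmsd(a, b), tolerance = 1e-6)
  }
})

test_that("traces of homologs with different lengths but one core compare fine", {
  fx <- small_fixture()
  ms <- load_model_set(fx$models_dir, fx$mapping, per_homolog_limit = 1)
  core <- conserved_core(read_alignment(fx$alignment))
  lens <- vapply(ms$models, length, 0L)
  expect_gt(length(unique(lens)), 1L)  # inserts differ per homolog
  trs <- lapply(ms$models, core_trace, core = core)
  d <- core_rmsd(trs[[1]], trs[[2]])
  expect_true(is.finite(d))
})

test_that("all_vs_all is symmetric with zero diagonal and matches pairwise calls", {
  fx <- small_fixture()
  ms <- load_model_set(fx$models_dir, fx$mapping, per_homolog_limit = 4)
  core <- conserved_core(read_alignment(fx$alignment))
  dm <- all_vs_all(ms, core)
  n <- length(dm$ids)
  expect_identical(dm$values, t(dm$values))
  expect_equal(unname(diag(dm$values)), rep(0, n))
  expect_true(all(is.finite(dm$values)) && all(dm$values >= 0))
  trs <- lapply(ms$models, core_trace, core = core)
  for (p in list(c(1, 2), c(3, 9), c(5, 12))) {
    expect_equal(dm$values[p[1], p[2]],
                 core_rmsd(trs[[p[1]]], trs[[p[2]]]), tolerance = 1e-9)
  }
})

test_that("core RMSD satisfies the triangle inequality on random traces", {
  set.seed(50)
  trs <- lapply(1:6, function(i)
    structure(list(model_id = paste0("t", i), points = random_points(10)),
              class = "core_trace"))
  d <- matrix(0, 6, 6)
  for (i in 1:5) for (j in (i + 1):6)
    d[i, j] <- d[j, i] <- core_rmsd(trs[[i]], trs[[j]])
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
})

test_that("distance matrix round-trips through its text format", {
  fx <- small_fixture()
  ms <- load_model_set(fx$models_dir, fx$mapping, per_homolog_limit = 3)
  core <- conserved_core(read_alignment(fx$alignment))
  dm <- all_vs_all(ms, core)
  path <- withr::local_tempfile()
  write_dist_matrix(dm, path)
  back <- read_dist_matrix(path)
  expect_equal(back$ids, dm$ids)
  expect_equal(back$values, dm$values, tolerance = 6e-4)  # 3-decimal format
})
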