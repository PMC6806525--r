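test_that("interaction_set canonicalizes and validates", {
  s <- interaction_set(c(5, 1), c(2, 4), c("base_pair", "stacking"))
  expect_equal(s$i, c(1L, 2L))
  expect_equal(s$j, c(4L, 5L))
  expect_error(interaction_set(1, 1, "base_pair"), "self")
  expect_error(interaction_set(1, 2, "hbond"), "kind")
  # duplicates collapse (set semantics)
  d <- interaction_set(c(1, 2, 1), c(3, 4, 3), "base_pair")
  expect_equal(nrow(d), 2L)
})

test_that("inf_score closed forms: identity 1, disjoint 0, (3,1,1) -> 0.75", {
  a <- interaction_set(1:4, 6:9, "base_pair")
  r <- inf_score(a, a)
  expect_equal(r$inf, 1)
  expect_equal(c(r$tp, r$fp, r$fn), c(4L, 0L, 0L))

  b <- interaction_set(1:3, 11:13, "base_pair")
  expect_equal(inf_score(a, b)$inf, 0)

  pred <- interaction_set(c(1, 2, 3, 4), c(10, 20, 30, 40), "base_pair")
  ref <- interaction_set(c(1, 2, 3, 5), c(10, 20, 30, 50), "base_pair")
  r2 <- inf_score(pred, ref)
  expect_equal(c(r2$tp, r2$fp, r2$fn), c(3L, 1L, 1L))
  expect_equal(r2$inf, sqrt(0.75 * 0.75))
})

test_that("inf is NA (not 0) for empty denominators", {
  e <- interaction_set()
  a <- interaction_set(1, 5, "base_pair")
  expect_true(is.na(inf_score(e, a)$inf))
  expect_true(is.na(inf_score(a, e)$inf))
  both <- inf_score(e, e)
  expect_true(is.na(both$inf))
  expect_equal(c(both$tp, both$fp, both$fn), c(0L, 0L, 0L))
})

test_that("inf is symmetric under pred/ref swap with fp and fn exchanged", {
  set.seed(80)
  for (rep in 1:20) {
    u <- t(utils::combn(10, 2))
    pick <- function() {
      rows <- u[sample(nrow(u), sample(0:8, 1)), , drop = FALSE]
      interaction_set(rows[, 1], rows[, 2],
                      sample(c("base_pair", "stacking"), nrow(rows),
                             replace = TRUE))
    }
    p <- pick(); r <- pick()
    a <- inf_score(p, r); b <- inf_score(r, p)
    expect_equal(a$inf, b$inf)
    expect_equal(a$fp, b$fn)
    expect_equal(a$fn, b$fp)
    if (!is.na(a$inf)) expect_true(a$inf >= 0 && a$inf <= 1)
  }
})

test_that("parse_dotbracket matches brackets including pseudoknot layers", {
  s <- parse_dotbracket("((..))")
  expect_equal(s$i, c(1L, 2L))
  expect_equal(s$j, c(6L, 5L))
  pk <- parse_dotbracket("([)]")
  expect_equal(nrow(pk), 2L)
  expect_true(all(c("1|3|base_pair", "2|4|base_pair") %in%
                  paste(pk$i, pk$j, pk$kind, sep = "|")))
  expect_equal(nrow(parse_dotbracket("....")), 0L)
  expect_error(parse_dotbracket("(()"), "position 1")
  expect_error(parse_dotbracket("())."), "position 3")
})

test_that("detector: far-apart residues yield no interactions", {
  at1 <- rbind("C3'" = c(0, 0, 0), "C1'" = c(1, 0, 0), "N1" = c(2, 0, 0),
               "C2" = c(2.5, 1, 0), "C6" = c(2.5, -1, 0), "N9" = c(3.5, 0, 0.2))
  at2 <- sweep(at1, 2, -c(40, 0, 0))
  m <- toy_model(list(at1, at2), res_names = c("A", "A"))
  expect_equal(nrow(detect_interactions(m)), 0L)
})

test_that("detector recovers the planted helix pairing of the generator", {
  bb <- make_backbone(20, helix_fraction = 1)
  planted <- parse_dotbracket(attr(bb, "ss"))
  expect_equal(nrow(planted), 10L)
  got <- detect_interactions(bb)
  bp <- got[got$kind == "base_pair", ]
  expect_equal(paste(bp$i, bp$j), paste(planted$i, planted$j))

  # partial helix: planted pairs still recovered exactly
  bb2 <- make_backbone(24, helix_fraction = 0.5)
  planted2 <- parse_dotbracket(attr(bb2, "ss"))
  got2 <- detect_interactions(bb2)
  bp2 <- got2[got2$kind == "base_pair", ]
  expect_equal(paste(bp2$i, bp2$j), paste(planted2$i, planted2$j))
})

test_that("interaction TSV round-trips", {
  s <- interaction_set(c(1, 2, 7), c(9, 8, 11),
                       c("base_pair", "base_pair", "stacking"))
  path <- withr::local_tempfile()
  write_interactions(s, path)
  expect_equal(read_interactions(path), s)
})

test_that("evaluate_model on identical structures gives 0 RMSD and INF 1", {
  fx <- small_fixture()
  ms <- load_model_set(fx$models_dir, fx$mapping)
  core <- conserved_core(read_alignment(fx$alignment))
  # pick a decoy from planted cluster 1 (unhinged: helix intact, so the
  # geometric detector finds a nonempty interaction set)
  id <- names(fx$truth$labels)[fx$truth$labels == 1 &
                               startsWith(names(fx$truth$labels), "target")][1]
  m <- ms$models[[id]]
  rep <- evaluate_model(m, m, core)
  expect_equal(rep$rmsd_heavy, 0, tolerance = 1e-8)
  expect_equal(rep$core_rmsd, 0, tolerance = 1e-8)
  expect_equal(rep$inf_all, 1)
  expect_equal(rep$fp + rep$fn, 0L)
})

test_that("evaluate_model skips heavy-atom RMSD across different lengths", {
  fx <- small_fixture()
  ms <- load_model_set(fx$models_dir, fx$mapping, per_homolog_limit = 1)
  core <- conserved_core(read_alignment(fx$alignment))
  homs <- vapply(ms$models, function(m) m$homolog, "")
  a <- ms$models[[which(homs == "target")[1]]]
  b <- ms$models[[which(homs != "target")[1]]]
  expect_true(length(a) != length(b))
  rep <- evaluate_model(a, b, core)
  expect_true(is.na(rep$rmsd_heavy))
  expect_true(is.finite(rep$core_rmsd))
})

test_that("evaluate_model uses dot-bracket sets when provided", {
  fx <- small_fixture()
  ms <- load_model_set(fx$models_dir, fx$mapping, per_homolog_limit = 1)
  core <- conserved_core(read_alignment(fx$alignment))
  m <- ms$models[[1]]
  n <- length(m)
  ss1 <- paste(c("((", strrep(".", n - 4), "))"), collapse = "")
  ss2 <- paste(c("(.", strrep(".", n - 4), ".)"), collapse = "")
  rep <- evaluate_model(m, m, core, pred_ss = ss1, ref_ss = ss2)
  expect_equal(c(rep$tp, rep$fp, rep$fn), c(1L, 1L, 0L))
  expect_equal(rep$inf_all, sqrt(0.5 * 1))
})
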