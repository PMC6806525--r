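test_that("read_alignment parses the three dialects and normalizes", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "a.fasta")
  writeLines(c(">s1", "ACGU-", ">s2", "AC-GU"), fa)
  a <- read_alignment(fa)
  expect_s3_class(a, "rna_alignment")
  expect_equal(a$width, 5L)
  expect_equal(unname(a$seqs), c("ACGU-", "AC-GU"))

  # lowercase + T normalized on the FASTA path
  writeLines(c(">x", "acgt"), fa)
  expect_equal(unname(read_alignment(fa)$seqs), "ACGU")

  sto <- file.path(dir, "a.sto")
  writeLines(c("# STOCKHOLM 1.0", "#=GF ID toy", "s1 ACGU.ACG",
               "s2 AC.UUACG", "#=GC SS_cons <<..>>..", "//"), sto)
  b <- read_alignment(sto)
  expect_equal(unname(b$seqs), c("ACGU-ACG", "AC-UUACG"))

  aln <- file.path(dir, "a.aln")
  writeLines(c("CLUSTAL format alignment", "", "",
               "s1              acguacga", "s2              acuuacga",
               "                ** *****"), aln)
  cl <- read_alignment(aln)
  expect_equal(unname(cl$seqs), c("ACGUACGA", "ACUUACGA"))
})

test_that("ragged and empty alignments are rejected with the record named", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "bad.fasta")
  writeLines(c(">s1", "ACGUA", ">s2", "ACGUAC"), fa)
  expect_error(read_alignment(fa), "ragged.*s2")
  empty <- file.path(dir, "empty.fasta")
  file.create(empty)
  expect_error(read_alignment(empty), "empty")
  expect_error(rna_alignment(c(a = "ACGU", a = "ACGU")), "duplicate")
})

test_that("pair identity uses the shared-coverage denominator", {
  # gap-gap columns ignored; one-sided gaps count in the denominator
  expect_equal(pair_identity("AC-G--", "ACUG--"), 3 / 4)
  expect_equal(pair_identity("ACGU", "ACGU"), 1)
  expect_equal(pair_identity("A---", "-CGU"), 0)
  expect_equal(pair_identity("----", "----"), 0)
  # ambiguity codes count as mismatches even when equal
  expect_equal(pair_identity("ANGU", "ANGU"), 3 / 4)
})

test_that("reduce_redundancy drops near-duplicates greedily in order", {
  a <- rna_alignment(c(s1 = "ACGUACGU", s2 = "ACGUACGU", s3 = "UGCAUGCA"))
  r <- reduce_redundancy(a, 0.9)
  expect_equal(r$names, c("s1", "s3"))
  # zero-identity pair: both kept even at the lowest threshold
  b <- rna_alignment(c(x = "AAAA", y = "CCCC"))
  expect_equal(reduce_redundancy(b, 0.01)$names, c("x", "y"))
  expect_error(reduce_redundancy(a, 0), "threshold")
  expect_error(reduce_redundancy(a, 1.2), "threshold")
})

test_that("reduce_redundancy matches a brute-force greedy oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 6
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "U", "-"), 30, replace = TRUE,
                   prob = c(rep(0.22, 4), 0.12)), collapse = ""), "")
    names(seqs) <- paste0("s", seq_len(n))
    aln <- rna_alignment(seqs)
    thr <- stats::runif(1, 0.2, 0.9)

    # oracle: explicit pairwise identity table + greedy scan
    ident <- function(a, b) {
      ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
      den <- sum(ca != "-" | cb != "-")
      if (den == 0) return(0)
      sum(ca == cb & ca != "-") / den
    }
    kept <- character(0)
    for (nm in names(seqs)) {
      if (!any(vapply(kept, function(k)
        ident(seqs[[nm]], seqs[[k]]) >= thr, TRUE)))
        kept <- c(kept, nm)
    }
    expect_equal(reduce_redundancy(aln, thr)$names, kept)
  }
})

test_that("threshold 1.0 removes only exact duplicates", {
  a <- rna_alignment(c(s1 = "ACGU-A", s2 = "ACGU-A", s3 = "ACGU-C"))
  expect_equal(reduce_redundancy(a, 1)$names, c("s1", "s3"))
})

test_that("conserved_core finds all-ungapped columns and residue indices", {
  # gap-free alignment: identity map
  a <- rna_alignment(c(x = "ACGUACG", y = "GCUAGCU"))
  cm <- conserved_core(a)
  expect_equal(cm$columns, 1:7)
  expect_equal(cm$per_seq$x, 1:7)

  # forced by the definition: one gap in y
  b <- rna_alignment(c(x = "ACGU", y = "A-GU"))
  cm <- conserved_core(b)
  expect_equal(cm$columns, c(1L, 3L, 4L))
  expect_equal(cm$per_seq$x, c(1L, 3L, 4L))
  expect_equal(cm$per_seq$y, c(1L, 2L, 3L))

  # empty core errors with advice
  c0 <- rna_alignment(c(x = "AC--", y = "--GU"))
  expect_error(conserved_core(c0), "revise")
  expect_error(conserved_core(a, selected = "x"), "at least 2")
  expect_error(conserved_core(a, selected = c("x", "zz")), "zz")
})

test_that("conserved_core matches a brute-force column scan on random input", {
  set.seed(7)
  for (rep in 1:10) {
    seqs <- vapply(1:6, function(i)
      paste(sample(c("A", "C", "G", "U", "-"), 25, replace = TRUE,
                   prob = c(rep(0.2, 4), 0.2)), collapse = ""), "")
    names(seqs) <- paste0("s", 1:6)
    aln <- rna_alignment(seqs)
    sel <- sample(names(seqs), sample(2:6, 1))
    rows <- lapply(seqs[sel], function(s) strsplit(s, "")[[1]])
    cols <- which(Reduce(`&`, lapply(rows, function(r) r != "-")))
    if (length(cols) == 0) {
      expect_error(conserved_core(aln, sel))
      next
    }
    cm <- conserved_core(aln, sel)
    expect_equal(cm$columns, cols)
    for (nm in sel) {
      r <- rows[[nm]]
      expect_equal(cm$per_seq[[nm]], cumsum(r != "-")[cols])
    }
  }
})

test_that("conserved_core invariants: order-invariance, monotone shrinking, character round-trip", {
  set.seed(99)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "U", "-"), 30, replace = TRUE), collapse = ""), "")
  names(seqs) <- paste0("s", 1:5)
  aln <- rna_alignment(seqs)

  c123 <- conserved_core(aln, c("s1", "s2", "s3"))
  c321 <- conserved_core(aln, c("s3", "s2", "s1"))
  expect_equal(c123$columns, c321$columns)
  expect_equal(c123$per_seq[order(names(c123$per_seq))],
               c321$per_seq[order(names(c321$per_seq))])

  c4 <- conserved_core(aln, c("s1", "s2", "s3", "s4"))
  expect_true(all(c4$columns %in% c123$columns))

  # applying per_seq to the ungapped string reproduces the gapped columns
  for (nm in c("s1", "s2", "s3")) {
    gapped <- strsplit(seqs[[nm]], "")[[1]]
    ungapped <- gapped[gapped != "-"]
    expect_equal(ungapped[c123$per_seq[[nm]]], gapped[c123$columns])
  }
})

test_that("core map round-trips through its TSV serialization", {
  a <- rna_alignment(c(x = "ACGU-ACG", y = "AC-UUACG", z = "ACGUUA-G"))
  cm <- conserved_core(a)
  path <- withr::local_tempfile()
  write_core_map(cm, path)
  back <- read_core_map(path)
  expect_equal(back$columns, cm$columns)
  expect_equal(back$per_seq, cm$per_seq)
})
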