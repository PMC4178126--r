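# The central 1 - M/N computation and the all-pairs matrix.

test_that("pair counts and small identities follow the definitions", {
  expect_equal(num_pairs(1), 0)
  expect_equal(num_pairs(2), 1)
  expect_equal(num_pairs(0), 0)

  pr <- pair_identity(gapped_aln("a", "b", "ACGT", "ACGA"))
  expect_equal(pr$M, 1L)
  expect_equal(pr$N, 4L)
  expect_equal(pr$identity, 0.75)

  # gap columns are excluded from both M and N
  pr <- pair_identity(gapped_aln("a", "b", "AC-GT", "ACCGT"))
  expect_equal(pr$M, 0L)
  expect_equal(pr$N, 4L)
  expect_equal(pr$identity, 1)

  pr <- pair_identity(gapped_aln("a", "b", "A-CG", "ATCG"))
  expect_equal(pr$N, 3L)
  expect_equal(pr$identity, 1)

  # ids come back lexicographically ordered
  pr <- pair_identity(gapped_aln("zz", "aa", "AC", "AC"))
  expect_equal(c(pr$id_a, pr$id_b), c("aa", "zz"))

  expect_error(pair_identity(gapped_aln("a", "b", "A-", "-A")),
               "no comparable columns")
})

test_that("all_pairs covers every unique pair with a valid matrix", {
  ds <- tiny_dataset(c(s1 = "ACGTACGT", s2 = "ACGTACGT", s3 = "ACGTACGT"))
  session <- all_pairs(ds)
  expect_equal(nrow(session$pairs), 3)
  m <- identity_matrix(session)
  expect_true(all(m == 1))
  expect_equal(rownames(m), c("s1", "s2", "s3"))

  fam <- make_synthetic_family(8, 200, seed = 2)
  session <- all_pairs(fam)
  expect_equal(nrow(session$pairs), num_pairs(8))
  m <- identity_matrix(session)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 1))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(rownames(m), fam$ids)   # input order preserved
})

test_that("alignment failures are reported with the offending pair", {
  ds <- pairid:::new_dataset(c("ok", "bad"), c(ok = "ACGT", bad = ""),
                             "nucleotide")
  expect_error(all_pairs(ds), "pair \\(bad, ok\\)|pair \\(ok, bad\\)")
})

test_that("to_distance is the entrywise complement", {
  fam <- make_synthetic_family(6, 150, seed = 11)
  m <- identity_matrix(all_pairs(fam))
  d <- to_distance(m)
  expect_equal(d, 1 - m)
  expect_true(all(diag(d) == 0))
  expect_identical(d, t(d))
  expect_error(to_distance(matrix(2, 2, 2, dimnames = list(1:2, 1:2))),
               "\\[0, 1\\]")
})

test_that("a pair's identity is invariant to the dataset containing it", {
  # each pair is aligned independently, so embedding the same sequences in
  # ever larger datasets must not move any identity by a single bit
  famA <- make_synthetic_family(6, 300, seed = 21, prefix = "a")
  famB <- make_synthetic_family(8, 300, seed = 22, prefix = "b")
  famC <- make_synthetic_family(10, 300, seed = 23, prefix = "c")
  sup1 <- all_pairs(famA)
  union2 <- pairid:::new_dataset(c(famA$ids, famB$ids),
                                 c(famA$residues, famB$residues), "nucleotide")
  union3 <- pairid:::new_dataset(c(union2$ids, famC$ids),
                                 c(union2$residues, famC$residues),
                                 "nucleotide")
  sup2 <- all_pairs(union2)
  sup3 <- all_pairs(union3)
  key <- function(s) paste(s$pairs$id_a, s$pairs$id_b)
  inA <- function(s) {
    sel <- s$pairs$id_a %in% famA$ids & s$pairs$id_b %in% famA$ids
    p <- s$pairs[sel, ]
    p[order(p$id_a, p$id_b), c("id_a", "id_b", "M", "N", "identity")]
  }
  ref <- inA(sup1)
  rownames(ref) <- NULL
  for (s in list(sup2, sup3)) {
    got <- inA(s)
    rownames(got) <- NULL
    expect_identical(got, ref)
  }
})

test_that("worker count does not change any output byte", {
  fam <- make_synthetic_family(10, 200, seed = 31)
  s1 <- all_pairs(fam, workers = 1)
  s4 <- all_pairs(fam, workers = 4)
  f1 <- tempfile(); f4 <- tempfile()
  write_pairs_csv(s1, f1)
  write_pairs_csv(s4, f4)
  expect_identical(read_bytes(f1), read_bytes(f4))
})

test_that("CSV exports have the documented shape", {
  fam <- make_synthetic_family(5, 120, seed = 8)
  session <- all_pairs(fam)
  f <- tempfile(fileext = ".csv")
  write_pairs_csv(session, f)
  lines <- readLines(f)
  expect_equal(lines[1], "id_a,id_b,mismatches,gapfree_columns,identity_pct")
  expect_equal(length(lines), 1 + num_pairs(5))
  body <- read.csv(f)
  expect_false(is.unsorted(body$id_a))
  expect_true(all(grepl("^\\d+\\.\\d{2}$", sub(".*,", "", lines[-1]))))

  fm <- tempfile(fileext = ".csv")
  write_matrix_csv(identity_matrix(session), fm)
  mat_lines <- readLines(fm)
  expect_equal(length(mat_lines), 6)
  expect_equal(strsplit(mat_lines[1], ",")[[1]][-1], fam$ids)
  # ids with commas survive CSV quoting
  ds <- tiny_dataset(setNames(c("ACGT", "ACGA"), c("x, strain 1", "y")))
  f2 <- tempfile()
  write_pairs_csv(all_pairs(ds), f2)
  expect_equal(read.csv(f2)$id_a, "x, strain 1")
})
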