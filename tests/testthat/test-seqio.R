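# Reading, validating and writing FASTA; synthetic fixture generation.

write_fasta_text <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

test_that("FASTA reading upper-cases residues and keeps file order", {
  f <- write_fasta_text(c(">a", "ACGT", ">b", "acga"))
  ds <- read_fasta(f)
  expect_equal(ds$ids, c("a", "b"))
  expect_equal(unname(ds$residues), c("ACGT", "ACGA"))
  expect_equal(ds$alphabet, "nucleotide")
})

test_that("FASTA reading handles wrapped lines and gzip", {
  seq200 <- random_dna(200)
  f <- write_fasta_text(c(">long", substring(seq200, 1, 60),
                          substring(seq200, 61, 120),
                          substring(seq200, 121, 200), ">s", "ACGT"))
  ds <- read_fasta(f)
  expect_equal(unname(ds$residues[["long"]]), seq200)
  gz <- tempfile(fileext = ".fasta.gz")
  con <- gzfile(gz, "w")
  writeLines(c(">x", "acgtacgt"), con)
  close(con)
  expect_equal(unname(read_fasta(gz)$residues), "ACGTACGT")
})

test_that("malformed input is rejected with a useful message", {
  expect_error(read_fasta(write_fasta_text(c(">a", "ACGT", ">a", "ACGT"))),
               "duplicate sequence id 'a'")
  expect_error(read_fasta(write_fasta_text(character(0))), "no sequences")
  expect_error(read_fasta(write_fasta_text(c(">a", "AC!T"))),
               "record 'a' contains character '!'")
  expect_error(read_fasta(write_fasta_text(c(">a", "AC-T"))), "ungapped")
  expect_error(read_fasta(tempfile()), "does not exist")
})

test_that("alphabet detection uses the 90% nucleotide-core rule", {
  expect_equal(detect_alphabet("ACGTACGT"), "nucleotide")
  expect_equal(detect_alphabet("MKVLWAALL"), "amino-acid")
  # exactly 90% of residues in {A,C,G,T,U,N} -> nucleotide
  expect_equal(detect_alphabet(c("ACGTACGTA", "R")), "nucleotide")
  # just under the threshold -> amino-acid
  expect_equal(detect_alphabet(c("ACGTACGT", "RR")), "amino-acid")
  # the flag overrides detection
  f <- write_fasta_text(c(">p", "ACGTACGTCA"))
  expect_equal(read_fasta(f, alphabet = "amino-acid")$alphabet, "amino-acid")
})

test_that("U is canonicalised to T for nucleotide data only", {
  ds <- read_fasta(write_fasta_text(c(">rna", "ACGU")))
  expect_equal(unname(ds$residues), "ACGT")
  aa <- read_fasta(write_fasta_text(c(">sel", "MKUV")), alphabet = "amino-acid")
  expect_equal(unname(aa$residues), "MKUV")
})

test_that("FASTA write round-trips exactly, wrapped at 70 columns", {
  expect_error(write_fasta(character(0), tempfile()), "empty")
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(2:25, 1)
    residues <- setNames(
      vapply(seq_len(n), function(i) random_dna(sample(c(5, 69:72, 200), 1)),
             ""),
      paste0("s", seq_len(n)))
    f <- tempfile(fileext = ".fasta")
    write_fasta(tiny_dataset(residues), f)
    lines <- readLines(f)
    expect_true(all(nchar(lines) <= 70))
    expect_equal(sum(startsWith(lines, ">")), n)
    back <- read_fasta(f)
    expect_equal(back$ids, names(residues))
    expect_equal(back$residues, residues)
  }
})

test_that("synthetic family generator is seeded and honours zero rates", {
  fam <- make_synthetic_family(5, 100, divergence = 0, indel_rate = 0, seed = 1)
  expect_equal(n_seq(fam), 5)
  expect_equal(length(unique(unname(fam$residues))), 1)

  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(make_synthetic_family(8, 300, seed = 99), f1)
  write_fasta(make_synthetic_family(8, 300, seed = 99), f2)
  expect_identical(read_bytes(f1), read_bytes(f2))

  expect_error(make_synthetic_family(8, 300, divergence = 1.2, seed = 1),
               "divergence")
  expect_error(make_synthetic_family(8, 300, indel_rate = -0.1, seed = 1),
               "indel_rate")
  expect_error(make_synthetic_family(1, 300, seed = 1))
})

test_that("family divergence produces the expected identity band", {
  # two descendants at substitution fraction 0.1 from one ancestor differ at
  # ~2 * 0.1 of sites less coincident hits: mean identity well inside 0.75-0.95
  fam <- make_synthetic_family(25, 2000, divergence = 0.1, indel_rate = 0.005,
                               seed = 7)
  expect_equal(n_seq(fam), 25)
  session <- all_pairs(fam)
  expect_equal(nrow(session$pairs), 300)
  expect_gt(mean(session$pairs$identity), 0.75)
  expect_lt(mean(session$pairs$identity), 0.95)
})

test_that("a generated 400-record FASTA reads back with 400 records", {
  fam <- make_synthetic_family(400, 60, seed = 3)
  f <- tempfile(fileext = ".fasta")
  write_fasta(fam, f)
  ds <- read_fasta(f)
  expect_equal(n_seq(ds), 400)
  expect_equal(ds$ids, fam$ids)
})
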