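# Matrix reordering, identity histograms, deterministic rendering.

fake_pairs <- function(identities) {
  n <- length(identities)
  data.frame(id_a = sprintf("p%d", seq_len(n)), id_b = sprintf("q%d", seq_len(n)),
             M = rep(NA_integer_, n), N = rep(NA_integer_, n),
             identity = identities)
}

test_that("reordering permutes rows and columns together", {
  fam <- make_synthetic_family(6, 150, seed = 3)
  m <- identity_matrix(all_pairs(fam))
  expect_identical(reorder_matrix(m, rownames(m)), m)
  rev_ord <- rev(rownames(m))
  twice <- reorder_matrix(reorder_matrix(m, rev_ord), rev(rev_ord))
  expect_identical(twice, m)
  set.seed(2)
  p <- sample(rownames(m))
  mp <- reorder_matrix(m, p)
  expect_identical(mp, t(mp))
  expect_equal(sort(mp[upper.tri(mp)]), sort(m[upper.tri(m)]))
  expect_error(reorder_matrix(m, rownames(m)[-1]), "permutation")
  expect_error(reorder_matrix(m, c(rownames(m)[-1], "nope")), "permutation")
})

test_that("histogram bins are half-open with 100 in the last bin", {
  h <- identity_histogram(fake_pairs(c(1, 1, 1)))
  expect_equal(h$proportions[100], 1)
  expect_equal(sum(h$proportions), 1)

  h <- identity_histogram(fake_pairs(c(0.75, 0.75, 0.80)))
  expect_equal(h$proportions[76], 2 / 3)  # bin [75, 76)
  expect_equal(h$proportions[81], 1 / 3)  # bin [80, 81)
  expect_equal(sum(h$proportions), 1)
  expect_equal(length(h$proportions), length(h$bin_edges) - 1)

  h5 <- identity_histogram(fake_pairs(c(0.9, 0.99, 1)), bin_width = 5)
  expect_equal(length(h5$proportions), 20)
  expect_equal(h5$proportions[19], 1 / 3)
  expect_equal(h5$proportions[20], 2 / 3)

  set.seed(12)
  h <- identity_histogram(fake_pairs(runif(500)))
  expect_equal(sum(h$proportions), 1, tolerance = 1e-12)

  expect_error(identity_histogram(fake_pairs(numeric(0))), "no pairs")
  expect_error(identity_histogram(fake_pairs(0.5), bin_width = 3), "divisor")
})

test_that("two families produce a bimodal distribution with a trough", {
  famA <- make_synthetic_family(6, 400, divergence = 0.02, seed = 61,
                                prefix = "a")
  famB <- make_synthetic_family(6, 400, divergence = 0.02, seed = 62,
                                prefix = "b")
  both <- pairid:::new_dataset(c(famA$ids, famB$ids),
                               c(famA$residues, famB$residues), "nucleotide")
  session <- all_pairs(both)
  within <- with(session$pairs, substr(id_a, 1, 1) == substr(id_b, 1, 1))
  lo <- 100 * max(session$pairs$identity[!within])  # top of the between mode
  hi <- 100 * min(session$pairs$identity[within])   # bottom of the within mode
  expect_gt(hi, lo)  # families are separable at all
  h <- identity_histogram(session, bin_width = 1)
  mode_between <- max(h$proportions[h$bin_edges[-101] < lo])
  mode_within <- max(h$proportions[h$bin_edges[-101] >= hi - 1])
  trough_bins <- h$bin_edges[-101] >= lo & h$bin_edges[-101] < hi - 1
  trough <- min(h$proportions[trough_bins])
  expect_lt(trough, mode_between)
  expect_lt(trough, mode_within)
})

test_that("histogram CSV export has one row per bin", {
  h <- identity_histogram(fake_pairs(c(0.75, 0.75, 0.80)))
  f <- tempfile(fileext = ".csv")
  write_histogram_csv(h, f)
  df <- read.csv(f)
  expect_equal(names(df), c("bin_lo", "bin_hi", "proportion"))
  expect_equal(nrow(df), 100)
  expect_equal(df$proportion[df$bin_lo == 75], 2 / 3, tolerance = 1e-9)
  expect_equal(sum(df$proportion), 1, tolerance = 1e-9)
})

test_that("colour schemes validate their thresholds", {
  expect_error(colour_scheme("thresholded"), "threshold")
  expect_error(colour_scheme("thresholded", thresholds = c(90, 80)),
               "ascending")
  expect_error(colour_scheme("thresholded", thresholds = c(0, 90)),
               "ascending|within")
  sc <- colour_scheme("thresholded", thresholds = 94)
  expect_equal(length(sc$colours), 2)
})

test_that("matrix rendering is deterministic and format-aware", {
  fam <- make_synthetic_family(5, 150, seed = 9)
  m <- identity_matrix(all_pairs(fam))
  f1 <- tempfile(fileext = ".svg")
  f2 <- tempfile(fileext = ".svg")
  render_matrix(m, colour_scheme(), f1)
  render_matrix(m, colour_scheme(), f2)
  expect_identical(read_bytes(f1), read_bytes(f2))

  f3 <- tempfile(fileext = ".png")
  render_matrix(m, colour_scheme("thresholded", thresholds = 94), f3)
  expect_gt(file.size(f3), 0)
  expect_error(render_matrix(m, colour_scheme(), tempfile(fileext = ".bmp")),
               "unsupported")
})

test_that("histogram rendering is deterministic", {
  h <- identity_histogram(fake_pairs(c(0.7, 0.72, 0.9, 0.95, 1)))
  f1 <- tempfile(fileext = ".svg")
  f2 <- tempfile(fileext = ".svg")
  render_histogram(h, f1, thresholds = 94)
  render_histogram(h, f2, thresholds = 94)
  expect_identical(read_bytes(f1), read_bytes(f2))
})
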