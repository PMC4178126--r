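# Independent oracles and small fixture helpers shared across tests.

# Pure-R exhaustive alignment scorer: explores every global alignment
# (no gap-gap columns) by unmemoised recursion. Written independently of the
# package's DP; usable only for very short strings.
r_enum_score <- function(a, b, params = align_params()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  op <- params$gap_open
  ex <- params$gap_extend
  sc <- function(x, y) pair_score(x, y, params)
  rec <- function(i, j, last) {
    if (i == 0 && j == 0) return(if (last == 0) 0 else -Inf)
    best <- -Inf
    if (last == 0) {
      if (i > 0 && j > 0) {
        for (p in 0:2) {
          v <- rec(i - 1, j - 1, p)
          if (is.finite(v)) best <- max(best, v + sc(av[i], bv[j]))
        }
      }
    } else if (last == 1) {
      if (i > 0) {
        for (p in 0:2) {
          v <- rec(i - 1, j, p)
          if (is.finite(v)) best <- max(best, v - if (p == 1) ex else op)
        }
      }
    } else {
      if (j > 0) {
        for (p in 0:2) {
          v <- rec(i, j - 1, p)
          if (is.finite(v)) best <- max(best, v - if (p == 2) ex else op)
        }
      }
    }
    best
  }
  max(rec(length(av), length(bv), 0),
      rec(length(av), length(bv), 1),
      rec(length(av), length(bv), 2))
}

# C++ exhaustive enumerator shipped with the package (validated against
# r_enum_score on tiny cases, then used at scale).
cpp_enum_score <- function(a, b, params = align_params()) {
  pairid:::.nw_enum_score_cpp(a, b, pairid:::score_table(params),
                              params$gap_open, params$gap_extend)
}

# Biostrings global-alignment score with the gap convention mapped: their
# gap of length L costs gapOpening + L * gapExtension, ours costs
# open + extend * (L - 1), so gapOpening = open - extend.
biostrings_score <- function(a, b, params = align_params()) {
  if (params$alphabet == "nucleotide") {
    bases <- c("A", "C", "G", "T")
    mat <- matrix(params$mismatch, 4, 4, dimnames = list(bases, bases))
    diag(mat) <- params$match
  } else {
    mat <- params$substitution_table
  }
  Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = params$gap_open - params$gap_extend,
    gapExtension = params$gap_extend, scoreOnly = TRUE)
}

# Brute-force union-find over an edge list; independent of igraph.
uf_components <- function(ids, edges_a, edges_b) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[[k]])
    rb <- find(edges_b[[k]])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, "")
  split(ids, roots)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

record <- function(id, residues) list(id = id, residues = residues)

gapped_aln <- function(id_a, id_b, ga, gb) {
  pairid:::new_pairwise_alignment(id_a, id_b, ga, gb, NA_real_)
}

tiny_dataset <- function(residues) {
  pairid:::new_dataset(names(residues), residues, "nucleotide")
}

read_bytes <- function(path) readBin(path, "raw", file.size(path))

# Every subtree's leaves must be contiguous in the tree's leaf order.
check_contiguity <- function(node, ord) {
  if (is.null(node$children)) return(TRUE)
  leaves <- pairid:::collect_leaves(node)
  pos <- match(leaves, ord)
  ok <- identical(sort(pos), seq(min(pos), max(pos)))
  ok && all(vapply(node$children, check_contiguity, TRUE, ord = ord))
}
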