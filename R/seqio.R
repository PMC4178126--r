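# Sequence input/output and synthetic fixture generation.

# IUPAC character sets (gap characters excluded: records never carry gaps).
NT_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")
AA_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
              "B", "J", "O", "U", "Z", "X", "*")
# Unambiguous-ish core used for alphabet detection
NT_CORE <- c("A", "C", "G", "T", "U", "N")

ALPHABETS <- c("nucleotide", "amino-acid")

new_dataset <- function(ids, residues, alphabet) {
  stopifnot(length(ids) == length(residues))
  structure(list(ids = as.character(ids),
                 residues = setNames(as.character(residues), ids),
                 alphabet = alphabet),
            class = "seq_dataset")
}

#' Number of sequences in a dataset
#' @param x A `seq_dataset`.
#' @return Integer count of records.
#' @export
n_seq <- function(x) length(x$ids)

#' @export
print.seq_dataset <- function(x, ...) {
  cat(sprintf("<seq_dataset> %d %s sequence(s), lengths %d-%d\n",
              n_seq(x), x$alphabet,
              min(nchar(x$residues)), max(nchar(x$residues))))
  invisible(x)
}

#' Detect whether sequences are nucleotide or amino acid
#'
#' Sequences are called nucleotide when at least 90% of all residues (pooled
#' across records) fall in the set `A,C,G,T,U,N`; otherwise amino acid. The
#' threshold is a heuristic: datasets with many ambiguity codes can be forced
#' to either alphabet with the `alphabet` argument of [read_fasta()].
#'
#' @param residues Character vector of (upper-case) residue strings.
#' @return `"nucleotide"` or `"amino-acid"`.
#' @export
detect_alphabet <- function(residues) {
  stopifnot(length(residues) >= 1)
  chars <- strsplit(paste(residues, collapse = ""), "")[[1]]
  if (length(chars) == 0) stop("cannot detect alphabet of empty sequences")
  frac_nt <- mean(chars %in% NT_CORE)
  if (frac_nt >= 0.9) "nucleotide" else "amino-acid"
}

validate_residues <- function(ids, residues, alphabet) {
  allowed <- if (alphabet == "nucleotide") NT_CHARS else AA_CHARS
  for (k in seq_along(residues)) {
    chars <- unique(strsplit(residues[[k]], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0) {
      stop(sprintf("record '%s' contains character '%s' not in the %s alphabet",
                   ids[[k]], bad[[1]], alphabet), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a FASTA file into a validated dataset
#'
#' Reads a multi-record FASTA file (plain or gzip-compressed, wrapped or
#' unwrapped lines). Residues are upper-cased; for nucleotide data `U` is
#' mapped to `T` so that scoring works over one canonical alphabet. IUPAC
#' ambiguity codes (and `X` for protein) are accepted and retained verbatim;
#' during alignment they score as ordinary characters (see [pair_score()]).
#'
#' @param path Path to a FASTA file (`.gz` accepted).
#' @param alphabet `"auto"` (default) detects via [detect_alphabet()];
#'   `"nucleotide"`/`"amino-acid"` override the detection.
#' @return A `seq_dataset` with records in file order.
#' @export
read_fasta <- function(path, alphabet = c("auto", "nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop(sprintf("no sequences found in '%s'", path))
  ids <- trimws(names(set))
  if (any(ids == "")) stop("FASTA contains a record with an empty header")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate sequence id '%s' in '%s'", dup[[1]], path))
  }
  residues <- toupper(as.character(set))
  if (any(nchar(residues) == 0)) {
    stop(sprintf("record '%s' has an empty sequence",
                 ids[which(nchar(residues) == 0)[1]]))
  }
  if (any(grepl("-", residues, fixed = TRUE))) {
    stop("input sequences must be ungapped (found '-')")
  }
  if (alphabet == "auto") alphabet <- detect_alphabet(residues)
  if (alphabet == "nucleotide") residues <- chartr("U", "T", residues)
  validate_residues(ids, residues, alphabet)
  new_dataset(ids, residues, alphabet)
}

#' Write a dataset to a FASTA file
#'
#' Output is wrapped at 70 columns with LF line endings;
#' `read_fasta(write_fasta(x))` reproduces ids and residues exactly.
#'
#' @param x A `seq_dataset`, or a named character vector of residues.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  residues <- if (inherits(x, "seq_dataset")) x$residues else x
  if (length(residues) == 0) stop("cannot write an empty sequence set")
  if (is.null(names(residues)) || any(names(residues) == "")) {
    stop("all sequences must be named")
  }
  set <- Biostrings::BStringSet(residues)
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

random_residues <- function(length, alphabet = "nucleotide") {
  letters <- if (alphabet == "nucleotide") c("A", "C", "G", "T") else
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(letters, length, replace = TRUE), collapse = "")
}

#' Generate independent uniform-random sequences
#'
#' Each record is an independent i.i.d.-uniform sequence — by construction the
#' records share no common ancestry, which makes this the right fixture for
#' asking what identity scores global alignment assigns to completely
#' unrelated sequences.
#'
#' @param n Number of sequences (>= 1).
#' @param length Sequence length.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG stream.
#' @param alphabet `"nucleotide"` (default) or `"amino-acid"`.
#' @param prefix Id prefix.
#' @return A `seq_dataset`.
#' @export
make_random_dataset <- function(n, length, seed = NULL,
                                alphabet = "nucleotide", prefix = "rnd") {
  stopifnot(n >= 1, length >= 1)
  with_rng_seed(seed, {
    residues <- vapply(seq_len(n), function(i) random_residues(length, alphabet),
                       character(1))
    ids <- sprintf("%s_%03d", prefix, seq_len(n))
    new_dataset(ids, residues, alphabet)
  })
}

# Apply substitutions then indels to one ancestor copy. Events are applied
# back-to-front so indices stay valid.
mutate_descendant <- function(anc, divergence, indel_rate, mean_indel_len) {
  bases <- c("A", "C", "G", "T")
  x <- anc
  sub_at <- which(stats::runif(length(x)) < divergence)
  for (i in sub_at) x[i] <- sample(setdiff(bases, x[i]), 1)
  ind_at <- which(stats::runif(length(x)) < indel_rate)
  for (i in rev(ind_at)) {
    len <- stats::rgeom(1, 1 / mean_indel_len) + 1
    if (stats::runif(1) < 0.5) {                      # insertion after site i
      ins <- sample(bases, len, replace = TRUE)
      x <- append(x, ins, after = i)
    } else {                                          # deletion from site i
      drop <- i:min(i + len - 1, length(x))
      if (length(drop) < length(x)) x <- x[-drop]
    }
  }
  paste(x, collapse = "")
}

#' Generate a synthetic sequence family
#'
#' Emulates a small virus-like sequence family: one seeded uniform-random
#' ancestor, from which each of `n` descendants is derived independently by
#' per-site substitutions (probability `divergence`, replacement drawn
#' uniformly from the other three bases) and indels (a per-site event
#' probability of `indel_rate`, geometric length with mean
#' `mean_indel_len`, insertion or deletion with equal probability). Two
#' descendants therefore differ at roughly `2 * divergence` of sites, less
#' coincident substitutions. Output is deterministic for a fixed seed.
#'
#' @param n Number of descendant sequences (>= 2).
#' @param length Ancestor length in bases.
#' @param divergence Per-site substitution probability in `[0, 1)`.
#' @param indel_rate Per-site indel event probability in `[0, 1)`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param mean_indel_len Mean geometric indel length (default 3).
#' @param prefix Id prefix.
#' @return A `seq_dataset` of `n` nucleotide records.
#' @export
make_synthetic_family <- function(n, length, divergence = 0.1,
                                  indel_rate = 0.005, seed = NULL,
                                  mean_indel_len = 3, prefix = "fam") {
  stopifnot(n >= 2, length >= 1)
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  if (indel_rate < 0 || indel_rate >= 1) stop("indel_rate must be in [0, 1)")
  if (mean_indel_len < 1) stop("mean_indel_len must be >= 1")
  with_rng_seed(seed, {
    anc <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    residues <- vapply(seq_len(n), function(i) {
      mutate_descendant(anc, divergence, indel_rate, mean_indel_len)
    }, character(1))
    ids <- sprintf("%s_%02d", prefix, seq_len(n))
    new_dataset(ids, residues, "nucleotide")
  })
}
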