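# Gap-excluded pairwise identity: the central 1 - M/N computation.

#' Number of unique sequence pairs
#'
#' `S` sequences yield `S * (S - 1) / 2` unique pairs, each requiring one
#' pairwise alignment.
#'
#' @param S Sequence count (>= 0).
#' @return The pair count as a double.
#' @export
num_pairs <- function(S) {
  stopifnot(S >= 0)
  S * (S - 1) / 2
}

#' Gap-excluded identity of one alignment
#'
#' Scores a pairwise alignment as `1 - M/N`, where `N` is the number of
#' alignment columns at which neither sequence has a gap character and `M` is
#' the number of those columns at which the two residues differ. Columns with
#' a gap in either row are ignored entirely, which removes the largest source
#' of disagreement between identity-calculation conventions.
#'
#' @param alignment A `pairwise_alignment` from [global_align()].
#' @return A `pair_record`: list with `id_a`, `id_b` (lexicographically
#'   ordered), integer `M` and `N`, and `identity = 1 - M/N`.
#' @export
pair_identity <- function(alignment) {
  ra <- charToRaw(alignment$gapped_a)
  rb <- charToRaw(alignment$gapped_b)
  stopifnot(length(ra) == length(rb))
  gap <- charToRaw("-")
  keep <- ra != gap & rb != gap
  N <- sum(keep)
  if (N == 0) {
    stop(sprintf("no comparable columns between '%s' and '%s'",
                 alignment$id_a, alignment$id_b))
  }
  M <- sum(ra[keep] != rb[keep])
  ids <- sort_c(c(alignment$id_a, alignment$id_b))
  structure(list(id_a = ids[[1]], id_b = ids[[2]],
                 M = as.integer(M), N = as.integer(N),
                 identity = 1 - M / N),
            class = "pair_record")
}

pairs_df <- function(records) {
  data.frame(id_a = vapply(records, `[[`, "", "id_a"),
             id_b = vapply(records, `[[`, "", "id_b"),
             M = vapply(records, `[[`, 0L, "M"),
             N = vapply(records, `[[`, 0L, "N"),
             identity = vapply(records, `[[`, 0, "identity"),
             stringsAsFactors = FALSE)
}

align_one_pair <- function(dataset, i, j, params) {
  a <- list(id = dataset$ids[[i]], residues = unname(dataset$residues[[i]]))
  b <- list(id = dataset$ids[[j]], residues = unname(dataset$residues[[j]]))
  tryCatch(pair_identity(global_align(a, b, params)),
           error = function(e) {
             stop(sprintf("pair (%s, %s): %s", a$id, b$id, conditionMessage(e)),
                  call. = FALSE)
           })
}

compute_pairs <- function(dataset, index_pairs, params, workers = 1) {
  task <- function(k) {
    align_one_pair(dataset, index_pairs[[k]][1], index_pairs[[k]][2], params)
  }
  ks <- seq_along(index_pairs)
  if (workers > 1 && .Platform$OS.type == "unix") {
    out <- parallel::mclapply(ks, task, mc.cores = workers,
                              mc.preschedule = TRUE)
    err <- vapply(out, inherits, TRUE, "try-error")
    if (any(err)) stop(attr(out[[which(err)[1]]], "condition"))
  } else {
    out <- lapply(ks, task)
  }
  out
}

#' Identity for every unique pair of sequences
#'
#' Aligns each of the `S * (S - 1) / 2` unique pairs independently with
#' [global_align()] and scores each with [pair_identity()]. Pairs are
#' independent tasks: the result is bit-identical for any `workers` value,
#' and — because every pair is aligned on its own — each pair's identity is
#' unchanged by the presence or absence of any other sequence in the dataset.
#'
#' @param dataset A `seq_dataset` with at least 2 records.
#' @param params An [align_params()] object matching the dataset alphabet.
#' @param workers Number of parallel worker processes (forked; `1` = serial).
#' @return An `identity_session`: list with `dataset`, `params`, a `pairs`
#'   data frame (`id_a`, `id_b`, `M`, `N`, `identity`) and `format_version`.
#' @seealso [identity_matrix()], [save_session()], [extend_session()]
#' @export
all_pairs <- function(dataset, params = NULL, workers = 1) {
  stopifnot(inherits(dataset, "seq_dataset"))
  if (n_seq(dataset) < 2) stop("all-pairs computation needs >= 2 sequences")
  if (is.null(params)) params <- align_params(alphabet = dataset$alphabet)
  S <- n_seq(dataset)
  idx <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  index_pairs <- lapply(seq_len(nrow(idx)),
                        function(k) c(idx[k, "row"], idx[k, "col"]))
  records <- compute_pairs(dataset, index_pairs, params, workers)
  new_session(params, dataset, pairs_df(records))
}

new_session <- function(params, dataset, pairs) {
  stopifnot(nrow(pairs) == num_pairs(n_seq(dataset)))
  structure(list(params = params, dataset = dataset, pairs = pairs,
                 format_version = SESSION_FORMAT_VERSION),
            class = "identity_session")
}

#' @export
print.identity_session <- function(x, ...) {
  cat(sprintf("<identity_session> %d sequences, %d pairs, %s\n",
              n_seq(x$dataset), nrow(x$pairs), x$dataset$alphabet))
  invisible(x)
}

#' Symmetric all-pairs identity matrix
#'
#' @param session An `identity_session` from [all_pairs()].
#' @return An S x S numeric matrix of identity fractions with unit diagonal,
#'   rows/columns named by sequence id in input order.
#' @export
identity_matrix <- function(session) {
  ids <- session$dataset$ids
  S <- length(ids)
  m <- matrix(1, S, S, dimnames = list(ids, ids))
  ia <- match(session$pairs$id_a, ids)
  ib <- match(session$pairs$id_b, ids)
  m[cbind(ia, ib)] <- session$pairs$identity
  m[cbind(ib, ia)] <- session$pairs$identity
  m
}

#' Convert an identity matrix to distances
#'
#' Entry-wise `1 - identity` (the Hamming-style distance used when comparing
#' identity distributions with evolutionary-distance methods, and the input to
#' [neighbor_joining()]).
#'
#' @param matrix A symmetric identity matrix with unit diagonal.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
to_distance <- function(matrix) {
  check_identity_matrix(matrix)
  1 - matrix
}

check_identity_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("identity matrix must have matching row/column names")
  }
  if (any(is.na(m)) || any(m < 0) || any(m > 1)) {
    stop("identity values must lie in [0, 1]")
  }
  if (max(abs(m - t(m))) > 0) stop("identity matrix must be symmetric")
  if (any(diag(m) != 1)) stop("identity matrix diagonal must be exactly 1")
  invisible(TRUE)
}

# Minimal CSV field quoting (RFC-style): quote when the value contains a
# comma, quote or newline; double embedded quotes.
csv_field <- function(x) {
  need <- grepl('[",\n]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

#' Write the long-form pair table as CSV
#'
#' Columns `id_a,id_b,mismatches,gapfree_columns,identity_pct` with identity
#' printed as a percentage to 2 decimals; rows sorted lexicographically by
#' `id_a` then `id_b`. The byte content is a pure function of the pair set,
#' which makes this export the package's determinism witness.
#'
#' @param x An `identity_session` or a pairs data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(x, path) {
  pairs <- if (inherits(x, "identity_session")) x$pairs else x
  ord <- order_c(pairs$id_a, pairs$id_b)
  pairs <- pairs[ord, , drop = FALSE]
  lines <- c("id_a,id_b,mismatches,gapfree_columns,identity_pct",
             paste(csv_field(pairs$id_a), csv_field(pairs$id_b),
                   pairs$M, pairs$N,
                   sprintf("%.2f", 100 * pairs$identity), sep = ","))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Write a square identity matrix as CSV
#'
#' First row and first column carry the sequence ids (in the matrix's current
#' order); cells are percent identities to 2 decimals.
#'
#' @param matrix An identity matrix (fractions in `[0, 1]`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(matrix, path) {
  check_identity_matrix(matrix)
  ids <- csv_field(rownames(matrix))
  header <- paste(c("", ids), collapse = ",")
  rows <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(ids[[i]], sprintf("%.2f", 100 * matrix[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path, sep = "\n")
  invisible(path)
}
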