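# Saving, loading and incrementally extending analysis sessions.
#
# A session archive is a plain uncompressed tar (written by R's built-in tar
# implementation, so no external tools are needed) holding three inspectable
# members: manifest.json (format version, alphabet, alignment parameters, md5
# checksums), sequences.fasta, and pairs.csv with the exact integer M and N
# counts per pair. Identities are reconstructed from M and N on load, so a
# round trip is exact. Recommended extension: ".sdt.tar".

SESSION_FORMAT_VERSION <- "1.0"

#' Save an analysis session
#'
#' @param session An `identity_session` from [all_pairs()] /
#'   [extend_session()].
#' @param path Output archive path (conventionally `*.sdt.tar`).
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "identity_session"))
  stage <- tempfile("session_stage_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  write_fasta(session$dataset, file.path(stage, "sequences.fasta"))
  pairs <- session$pairs[order_c(session$pairs$id_a, session$pairs$id_b), ]
  pcsv <- data.frame(id_a = pairs$id_a, id_b = pairs$id_b,
                     M = pairs$M, N = pairs$N,
                     identity = sprintf("%.12f", pairs$identity))
  write.csv(pcsv, file.path(stage, "pairs.csv"), row.names = FALSE)

  p <- session$params
  manifest <- list(
    format_version = session$format_version,
    alphabet = session$dataset$alphabet,
    params = list(alphabet = p$alphabet, match = p$match,
                  mismatch = p$mismatch,
                  substitution_table = p$substitution_table,
                  gap_open = p$gap_open, gap_extend = p$gap_extend),
    n_sequences = n_seq(session$dataset),
    n_pairs = nrow(session$pairs),
    checksums = list(
      sequences.fasta = unname(tools::md5sum(file.path(stage, "sequences.fasta"))),
      pairs.csv = unname(tools::md5sum(file.path(stage, "pairs.csv")))))
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  out <- normalizePath(path, mustWork = FALSE)
  oldwd <- setwd(stage)
  on.exit(setwd(oldwd), add = TRUE)
  utils::tar(out, files = c("manifest.json", "sequences.fasta", "pairs.csv"),
             tar = "internal")
  invisible(path)
}

#' Load an analysis session
#'
#' Verifies the archive's format version and md5 checksums before rebuilding
#' the session; a truncated or altered archive raises a corruption error.
#'
#' @param path Archive written by [save_session()].
#' @return An `identity_session`.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop(sprintf("session file '%s' does not exist", path))
  ex <- tempfile("session_load_")
  dir.create(ex)
  on.exit(unlink(ex, recursive = TRUE), add = TRUE)
  con_before <- rownames(showConnections(all = TRUE))
  ok <- tryCatch({
    untar(path, exdir = ex, tar = "internal")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    # a failed extraction can leave a member's output connection open
    leaked <- setdiff(rownames(showConnections(all = TRUE)), con_before)
    for (n in leaked) try(close(getConnection(as.integer(n))), silent = TRUE)
  }
  members <- c("manifest.json", "sequences.fasta", "pairs.csv")
  if (!ok || !all(file.exists(file.path(ex, members)))) {
    stop(sprintf("'%s' is not a readable session archive (corrupted?)", path))
  }
  manifest <- jsonlite::read_json(file.path(ex, "manifest.json"))
  if (!identical(manifest$format_version, SESSION_FORMAT_VERSION)) {
    stop(sprintf("unsupported session format version '%s' (expected '%s')",
                 manifest$format_version, SESSION_FORMAT_VERSION))
  }
  for (f in c("sequences.fasta", "pairs.csv")) {
    want <- manifest$checksums[[f]]
    got <- unname(tools::md5sum(file.path(ex, f)))
    if (!identical(want, got)) {
      stop(sprintf("checksum mismatch for '%s': session archive is corrupted", f))
    }
  }
  alpha <- manifest$alphabet
  dataset <- read_fasta(file.path(ex, "sequences.fasta"), alphabet = alpha)
  mp <- manifest$params
  params <- align_params(alphabet = mp$alphabet,
                         match = as.numeric(mp$match),
                         mismatch = as.numeric(mp$mismatch),
                         substitution_table = mp$substitution_table,
                         gap_open = as.numeric(mp$gap_open),
                         gap_extend = as.numeric(mp$gap_extend))
  pairs <- read.csv(file.path(ex, "pairs.csv"),
                    colClasses = c("character", "character", "integer",
                                   "integer", "NULL"))
  pairs$identity <- 1 - pairs$M / pairs$N
  if (!all(pairs$id_a %in% dataset$ids) || !all(pairs$id_b %in% dataset$ids)) {
    stop("session pair table names ids absent from its sequence set")
  }
  new_session(params, dataset, pairs)
}

#' Add sequences to a session without recomputing existing pairs
#'
#' For `k` new sequences added to `S` existing ones, exactly
#' `k * S + k * (k - 1) / 2` new alignments are computed (the pairs that
#' involve at least one new sequence); all previously computed pairs are
#' reused unchanged. Because every pair is aligned independently, the result
#' is pair-for-pair identical to a from-scratch [all_pairs()] run on the
#' union.
#'
#' @param session An `identity_session`.
#' @param new_records A `seq_dataset` of sequences to add; ids must be
#'   disjoint from the session's and the alphabet must match.
#' @param workers Parallel workers for the new alignments.
#' @return The extended `identity_session`; the number of alignments actually
#'   computed is recorded in `attr(, "n_new_alignments")`.
#' @export
extend_session <- function(session, new_records, workers = 1) {
  stopifnot(inherits(session, "identity_session"),
            inherits(new_records, "seq_dataset"))
  if (new_records$alphabet != session$dataset$alphabet) {
    stop(sprintf("alphabet mismatch: session is %s, new records are %s",
                 session$dataset$alphabet, new_records$alphabet))
  }
  clash <- intersect(new_records$ids, session$dataset$ids)
  if (length(clash) > 0) {
    stop(sprintf("sequence id '%s' already exists in the session", clash[[1]]))
  }
  old <- session$dataset
  union <- new_dataset(c(old$ids, new_records$ids),
                       c(old$residues, new_records$residues),
                       old$alphabet)
  S <- n_seq(old)
  k <- n_seq(new_records)
  new_idx <- (S + 1):(S + k)
  index_pairs <- c(
    unlist(lapply(new_idx, function(j) lapply(seq_len(S), function(i) c(i, j))),
           recursive = FALSE),
    if (k >= 2) {
      cmb <- utils::combn(new_idx, 2)
      lapply(seq_len(ncol(cmb)), function(q) cmb[, q])
    })
  records <- compute_pairs(union, index_pairs, session$params, workers)
  pairs <- rbind(session$pairs, pairs_df(records))
  out <- new_session(session$params, union, pairs)
  attr(out, "n_new_alignments") <- length(index_pairs)
  out
}
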