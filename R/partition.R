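# Splitting a dataset into non-overlapping FASTA files by identity range.

#' Identity-range specification
#'
#' @param min_identity,max_identity Inclusive percent bounds,
#'   `0 <= min <= max <= 100`.
#' @return A `partition_spec` object.
#' @export
partition_spec <- function(min_identity, max_identity) {
  if (min_identity < 0 || max_identity > 100 || min_identity > max_identity) {
    stop("need 0 <= min_identity <= max_identity <= 100")
  }
  structure(list(min_identity = min_identity, max_identity = max_identity),
            class = "partition_spec")
}

#' Partition a dataset by pairwise identity range
#'
#' Builds a graph with one vertex per sequence and an edge for every pair
#' whose percent identity lies within `[min, max]` (both bounds inclusive,
#' compared with a 1e-9 tolerance against floating-point representation of
#' exact rational identities). Each connected component with at least two
#' members becomes one FASTA file (`partition_001.fasta`, ... — members in
#' input order); sequences with no in-range edge are collected in
#' `unassigned.fasta` (written only when non-empty). The files are pairwise
#' disjoint and jointly cover the dataset. Grouping is single-linkage:
#' within a component, pairs connected only transitively are not guaranteed
#' to be in range themselves.
#'
#' @param dataset A `seq_dataset`.
#' @param pairs Pairs data frame (or `identity_session`) covering every
#'   unique pair of the dataset.
#' @param spec A [partition_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `files` (named list of FASTA paths and
#'   member ids), `unassigned` ids, `manifest` path and `assignments`
#'   (named character vector id -> file name).
#' @export
partition_by_identity <- function(dataset, pairs, spec, out_dir) {
  stopifnot(inherits(dataset, "seq_dataset"), inherits(spec, "partition_spec"))
  if (inherits(pairs, "identity_session")) pairs <- pairs$pairs
  if (n_seq(dataset) == 0) stop("empty dataset")
  if (nrow(pairs) != num_pairs(n_seq(dataset)) ||
      !all(c(pairs$id_a, pairs$id_b) %in% dataset$ids)) {
    stop("pair set is incomplete for this dataset")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  eps <- 1e-9
  pct <- 100 * pairs$identity
  in_range <- pct >= spec$min_identity - eps & pct <= spec$max_identity + eps
  edges <- pairs[in_range, c("id_a", "id_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = dataset$ids))
  comp <- igraph::components(g)
  membership <- comp$membership[dataset$ids]

  assignments <- setNames(rep(NA_character_, n_seq(dataset)), dataset$ids)
  files <- list()
  n_file <- 0
  for (cid in unique(membership)) {         # unique() keeps input-order
    members <- dataset$ids[membership == cid]
    if (length(members) >= 2) {
      n_file <- n_file + 1
      fname <- sprintf("partition_%03d.fasta", n_file)
      write_fasta(dataset$residues[members], file.path(out_dir, fname))
      assignments[members] <- fname
      files[[fname]] <- members
    }
  }
  unassigned <- dataset$ids[is.na(assignments)]
  if (length(unassigned) > 0) {
    write_fasta(dataset$residues[unassigned],
                file.path(out_dir, "unassigned.fasta"))
    assignments[unassigned] <- "unassigned.fasta"
  }
  manifest <- file.path(out_dir, "partition_manifest.csv")
  writeLines(c("id,file",
               paste(csv_field(dataset$ids), assignments[dataset$ids],
                     sep = ",")),
             manifest, sep = "\n")
  invisible(list(files = files, unassigned = unassigned,
                 manifest = manifest, assignments = assignments))
}
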