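# Neighbour-joining tree and the deterministic leaf order used to arrange
# the identity matrix.
#
# Classical Saitou-Nei NJ, implemented here rather than delegated so that the
# rooting and every tie-break are pinned down: input rows are canonicalized
# to C-locale lexicographic id order before the NJ loop (permutation
# invariance is then exact, not floating-point dependent), Q-matrix ties are
# broken by scan order over that canonical ordering, the tree is rooted at
# the final join (the last remaining edge is split in half), and children are
# ladderized by decreasing subtree leaf count, then by ascending smallest
# contained leaf id. Only the leaf ORDER feeds downstream computations;
# negative branch-length estimates are clamped to zero for display.

nj_leaf <- function(id) {
  list(label = id, children = NULL, edges = NULL, nleaf = 1L, minleaf = id)
}

nj_join <- function(a, b, la, lb) {
  kids <- list(a, b)
  lens <- c(max(la, 0), max(lb, 0))
  list(label = NULL, children = kids, edges = lens,
       nleaf = a$nleaf + b$nleaf,
       minleaf = sort_c(c(a$minleaf, b$minleaf))[1])
}

ladderize_node <- function(node) {
  if (is.null(node$children)) return(node)
  node$children <- lapply(node$children, ladderize_node)
  nl <- vapply(node$children, `[[`, 0L, "nleaf")
  ml <- vapply(node$children, `[[`, "", "minleaf")
  ord <- order_c(-nl, ml)
  node$children <- node$children[ord]
  node$edges <- node$edges[ord]
  node
}

collect_leaves <- function(node) {
  if (is.null(node$children)) return(node$label)
  unlist(lapply(node$children, collect_leaves))
}

#' Neighbour-joining tree from a distance matrix
#'
#' @param dist Symmetric numeric matrix with zero diagonal and matching
#'   row/column names (typically [to_distance()] of an identity matrix).
#' @return An `ordered_tree`: rooted, ladderized NJ tree with non-negative
#'   branch lengths and a deterministic `leaf_order`.
#' @export
neighbor_joining <- function(dist) {
  stopifnot(is.matrix(dist))
  if (nrow(dist) != ncol(dist)) stop("distance matrix must be square")
  if (is.null(rownames(dist)) || !identical(rownames(dist), colnames(dist))) {
    stop("distance matrix must have matching row/column names")
  }
  if (any(is.na(dist)) || any(!is.finite(dist))) {
    stop("distance matrix contains NA/NaN/Inf")
  }
  if (max(abs(dist - t(dist))) > 1e-8) stop("distance matrix is asymmetric")
  if (any(diag(dist) != 0)) stop("distance matrix diagonal must be zero")
  S <- nrow(dist)
  if (S < 2) stop("need at least 2 leaves")

  ord <- order_c(rownames(dist))
  D <- dist[ord, ord, drop = FALSE]
  clusters <- lapply(rownames(D), nj_leaf)

  while (length(clusters) > 2) {
    k <- length(clusters)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- dij - li
    node <- nj_join(clusters[[i]], clusters[[j]], li, lj)

    others <- setdiff(seq_len(k), c(i, j))
    dnew <- (D[i, others] + D[j, others] - dij) / 2
    D2 <- rbind(cbind(D[others, others, drop = FALSE], dnew),
                c(dnew, 0))
    keep <- clusters[others]
    # insert the new cluster keeping the list sorted by minleaf
    ml <- c(vapply(keep, `[[`, "", "minleaf"), node$minleaf)
    pos <- order_c(ml)
    clusters <- c(keep, list(node))[pos]
    labs <- ml[pos]
    D <- D2[pos, pos, drop = FALSE]
    dimnames(D) <- list(labs, labs)
  }

  d12 <- D[1, 2]
  root <- nj_join(clusters[[1]], clusters[[2]], d12 / 2, d12 / 2)
  root <- ladderize_node(root)
  structure(list(root = root, leaf_order = collect_leaves(root)),
            class = "ordered_tree")
}

#' @export
print.ordered_tree <- function(x, ...) {
  cat(sprintf("<ordered_tree> %d leaves: %s%s\n", length(x$leaf_order),
              paste(utils::head(x$leaf_order, 5), collapse = ", "),
              if (length(x$leaf_order) > 5) ", ..." else ""))
  invisible(x)
}

#' Deterministic leaf order of a tree
#'
#' Depth-first, left-to-right traversal of the ladderized rooted tree; this is
#' the order in which sequences are arranged along the axes of the identity
#' matrix, so that evolutionarily related sequences cluster together.
#'
#' @param tree An `ordered_tree`.
#' @return Character vector of leaf ids.
#' @export
leaf_order <- function(tree) {
  stopifnot(inherits(tree, "ordered_tree"))
  collect_leaves(tree$root)
}

#' Patristic distances on an ordered tree
#'
#' Sums of branch lengths along the tree path between every pair of leaves,
#' at full floating-point precision (unlike distances re-derived from the
#' 6-decimal Newick export).
#'
#' @param tree An `ordered_tree`.
#' @return A symmetric leaf-by-leaf distance matrix in `leaf_order`.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "ordered_tree"))
  ids <- tree$leaf_order
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  depths <- function(node) {
    if (is.null(node$children)) return(setNames(0, node$label))
    groups <- lapply(seq_along(node$children), function(i) {
      depths(node$children[[i]]) + node$edges[[i]]
    })
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i < j) {
          cross <- outer(groups[[i]], groups[[j]], `+`)
          D[names(groups[[i]]), names(groups[[j]])] <<- cross
          D[names(groups[[j]]), names(groups[[i]])] <<- t(cross)
        }
      }
    }
    unlist(groups)
  }
  depths(tree$root)
  D
}

newick_label <- function(id) {
  if (grepl("[^A-Za-z0-9_.|/-]", id)) {
    paste0("'", gsub("'", "''", id), "'")
  } else {
    id
  }
}

newick_node <- function(node) {
  if (is.null(node$children)) return(newick_label(node$label))
  inner <- vapply(seq_along(node$children), function(i) {
    sprintf("%s:%.6f", newick_node(node$children[[i]]), node$edges[[i]])
  }, character(1))
  paste0("(", paste(inner, collapse = ","), ")")
}

#' Write a tree in Newick format
#'
#' Branch lengths are printed to 6 decimals; labels containing characters
#' outside `[A-Za-z0-9_.|/-]` are single-quoted per the Newick convention.
#'
#' @param tree An `ordered_tree`.
#' @param path Output path, or `NULL` to return the Newick string only.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "ordered_tree"))
  s <- paste0(newick_node(tree$root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path, sep = "\n")
  invisible(s)
}
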