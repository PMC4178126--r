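# Colour-coded identity matrix rendering and identity-frequency
# distributions.

#' Reorder an identity matrix
#'
#' Applies the same permutation to rows and columns (typically the
#' [leaf_order()] of the neighbour-joining tree), preserving values and
#' symmetry.
#'
#' @param matrix An identity matrix.
#' @param order Character vector: a permutation of the matrix ids.
#' @return The permuted matrix.
#' @export
reorder_matrix <- function(matrix, order) {
  check_identity_matrix(matrix)
  ids <- rownames(matrix)
  if (length(order) != length(ids) || anyDuplicated(order) ||
      !setequal(order, ids)) {
    stop("order must be a permutation of the matrix ids")
  }
  matrix[order, order, drop = FALSE]
}

#' Frequency distribution of pairwise identities
#'
#' Bins percent identities into half-open bins `[lo, hi)` — except the last
#' bin, which also includes 100 — counting each unique pair once. Troughs of
#' this distribution mark identity thresholds that would classify the dataset
#' with the least ambiguity, which is how demarcation cut-offs are chosen.
#'
#' @param x An `identity_session` or a pairs data frame.
#' @param bin_width Bin width in percentage points; must divide 100.
#' @return An `identity_histogram`: list with `bin_edges` (percent),
#'   `counts`, `proportions` and `n_pairs`.
#' @export
identity_histogram <- function(x, bin_width = 1) {
  pairs <- if (inherits(x, "identity_session")) x$pairs else x
  if (is.null(pairs) || nrow(pairs) == 0) stop("no pairs to bin")
  if (bin_width <= 0 || (100 %% bin_width) != 0) {
    stop("bin_width must be a positive divisor of 100")
  }
  edges <- seq(0, 100, by = bin_width)
  nbin <- length(edges) - 1
  pct <- 100 * pairs$identity
  idx <- pmin(floor(pct / bin_width) + 1, nbin)
  counts <- tabulate(idx, nbins = nbin)
  structure(list(bin_edges = edges, counts = counts,
                 proportions = counts / nrow(pairs),
                 n_pairs = nrow(pairs)),
            class = "identity_histogram")
}

#' @export
print.identity_histogram <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat(sprintf("<identity_histogram> %d pairs in %d bins; occupied range %g-%g%%\n",
              x$n_pairs, length(x$counts),
              x$bin_edges[min(nz)], x$bin_edges[max(nz) + 1]))
  invisible(x)
}

#' Write histogram values as CSV
#' @param hist An `identity_histogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "identity_histogram"))
  lines <- c("bin_lo,bin_hi,proportion",
             sprintf("%g,%g,%.10g",
                     hist$bin_edges[-length(hist$bin_edges)],
                     hist$bin_edges[-1], hist$proportions))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Colour scheme for matrix rendering
#'
#' Two modes. `"continuous"`: a smooth colour ramp spanning (by default) only
#' the observed identity range, maximising contrast. `"thresholded"`: one
#' discrete colour per interval between the given percent cut-offs — e.g. a
#' single ICTV species-demarcation threshold gives a two-colour matrix in
#' which above-threshold (conspecific) and below-threshold pairs are
#' immediately distinguishable.
#'
#' @param mode `"continuous"` or `"thresholded"`.
#' @param thresholds Strictly ascending percent cut-offs in (0, 100)
#'   (thresholded mode).
#' @param colours Optional colour vector: a ramp (continuous) or one colour
#'   per interval, i.e. `length(thresholds) + 1` (thresholded).
#' @return A `colour_scheme` object.
#' @export
colour_scheme <- function(mode = c("continuous", "thresholded"),
                          thresholds = numeric(), colours = NULL) {
  mode <- match.arg(mode)
  if (mode == "thresholded") {
    if (length(thresholds) == 0) stop("thresholded mode needs >= 1 threshold")
    if (any(thresholds <= 0) || any(thresholds >= 100) ||
        is.unsorted(thresholds, strictly = TRUE)) {
      stop("thresholds must be strictly ascending, within (0, 100)")
    }
    if (is.null(colours)) {
      colours <- grDevices::hcl.colors(length(thresholds) + 1, "Blue-Red 2")
    }
    if (length(colours) != length(thresholds) + 1) {
      stop("need one colour per interval (length(thresholds) + 1)")
    }
  } else {
    if (is.null(colours)) colours <- grDevices::hcl.colors(64, "Spectral")
  }
  structure(list(mode = mode, thresholds = thresholds, colours = colours),
            class = "colour_scheme")
}

plot_device <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg,
         pdf = grDevices::pdf,
         png = function(filename, width, height, ...) {
           grDevices::png(filename, width = width, height = height,
                          units = "in", res = 150, type = "cairo")
         },
         stop(sprintf("unsupported figure format '.%s' (png/svg/pdf)", ext)))
}

save_plot <- function(p, path, width, height) {
  dev <- plot_device(path)
  dev(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Render a colour-coded identity matrix
#'
#' Draws the (tree-ordered) matrix as a square heat map with sequence labels
#' written horizontally on the left and vertically along the bottom, plus a
#' colour key. Percent values are printed inside the cells for matrices of up
#' to 30 sequences. Output format follows the file extension (`.png`, `.svg`,
#' `.pdf`); vector output contains no timestamps, so re-rendering the same
#' matrix reproduces the file byte-for-byte.
#'
#' @param matrix An identity matrix, already reordered by the caller (see
#'   [reorder_matrix()]).
#' @param scheme A [colour_scheme()].
#' @param path Output image path.
#' @param show_values Print percent values in cells; default `NULL` means
#'   automatic (matrices with <= 30 sequences).
#' @return `path`, invisibly.
#' @export
render_matrix <- function(matrix, scheme = colour_scheme(), path,
                          show_values = NULL) {
  check_identity_matrix(matrix)
  stopifnot(inherits(scheme, "colour_scheme"))
  ids <- rownames(matrix)
  S <- length(ids)
  if (is.null(show_values)) show_values <- S <= 30
  df <- data.frame(row = factor(rep(ids, times = S), levels = rev(ids)),
                   col = factor(rep(ids, each = S), levels = ids),
                   pct = 100 * as.vector(matrix))
  if (scheme$mode == "thresholded") {
    breaks <- c(0, scheme$thresholds, 100 + 1e-9)
    labs <- sprintf("[%g, %g%s", breaks[-length(breaks)],
                    c(scheme$thresholds, 100),
                    c(rep(")", length(scheme$thresholds)), "]"))
    df$band <- cut(df$pct, breaks = breaks, labels = labs,
                   right = FALSE, include.lowest = TRUE)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row))
  if (scheme$mode == "continuous") {
    # raster = FALSE keeps the colour key vectorial, so repeated SVG renders
    # are byte-identical (no process-global raster ids embedded)
    p <- p + ggplot2::geom_tile(ggplot2::aes(fill = .data$pct)) +
      ggplot2::scale_fill_gradientn(
        colours = scheme$colours, limits = range(df$pct),
        name = "% identity",
        guide = ggplot2::guide_colourbar(display = "rectangles"))
  } else {
    p <- p + ggplot2::geom_tile(ggplot2::aes(fill = .data$band)) +
      ggplot2::scale_fill_manual(values = setNames(scheme$colours, labs),
                                 name = "% identity", drop = FALSE)
  }
  if (show_values) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$pct)),
                                size = 2.2)
  }
  p <- p +
    ggplot2::scale_x_discrete(position = "bottom") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5),
                   panel.grid = ggplot2::element_blank())
  side <- max(4, min(12, 0.28 * S + 2.5))
  save_plot(p, path, width = side + 1.5, height = side)
}

#' Render a pairwise identity frequency distribution
#'
#' Bar plot of the proportion of pairs per percent-identity bin, with
#' optional vertical marker lines at candidate demarcation thresholds. Peaks
#' flag threshold values that would produce many ambiguous classifications;
#' troughs flag values that would produce few.
#'
#' @param hist An [identity_histogram()].
#' @param path Output image path (`.png`, `.svg`, `.pdf`).
#' @param thresholds Optional percent values to mark with vertical lines.
#' @return `path`, invisibly.
#' @export
render_histogram <- function(hist, path, thresholds = NULL) {
  stopifnot(inherits(hist, "identity_histogram"))
  mids <- (hist$bin_edges[-1] + hist$bin_edges[-length(hist$bin_edges)]) / 2
  df <- data.frame(mid = mids, prop = hist$proportions)
  w <- diff(hist$bin_edges)[1]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$prop)) +
    ggplot2::geom_col(width = w, fill = "#3B6FB6") +
    ggplot2::labs(x = "Pairwise identity (%)", y = "Proportion of pairs") +
    ggplot2::theme_minimal(base_size = 10)
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_vline(xintercept = thresholds,
                                 linetype = "dashed", colour = "#B63B3B")
  }
  save_plot(p, path, width = 7, height = 4)
}
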