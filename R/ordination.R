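# Population-structure views of the Rst matrix: classical (Torgerson)
# multidimensional scaling and the Saitou-Nei neighbor-joining tree.

as_dist_matrix <- function(D) {
  if (inherits(D, "ystr_rst_matrix")) D <- D$rst
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) abort("distance matrix must be symmetric")
  if (any(diag(D) != 0)) abort("distance matrix must have a zero diagonal")
  if (any(D < 0)) abort("distances must be non-negative")
  if (is.null(rownames(D))) {
    dimnames(D) <- list(paste0("T", seq_len(nrow(D))),
                        paste0("T", seq_len(nrow(D))))
  }
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Squares the distances, double-centers `B = -1/2 J D^2 J`, and
#' eigendecomposes. Coordinates are eigenvectors scaled by the square root of
#' the top `dims` positive eigenvalues; negative eigenvalues are excluded
#' from the coordinates but reported. Each axis's sign is fixed so its
#' largest-magnitude entry is positive, making plots reproducible.
#'
#' @param D symmetric non-negative matrix with zero diagonal (e.g. the
#'   clamped Rst matrix), or an `ystr_rst_matrix`.
#' @param dims requested embedding dimension; reduced (with a warning) if
#'   fewer positive eigenvalues exist.
#' @return An `ystr_mds`: `coordinates` (populations x dims, column-centered),
#'   `eigenvalues` (all, descending), `goodness` (share of positive-eigenvalue
#'   mass captured).
#' @export
classical_mds <- function(D, dims = 2) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- 1e-12 * max(1, abs(e$values[1]))
  pos <- which(e$values > tol)
  if (dims > length(pos)) {
    warn(sprintf("only %d positive eigenvalues; reducing dims from %d",
                 length(pos), dims))
    dims <- length(pos)
  }
  coords <- matrix(0, n, dims)
  dimnames(coords) <- list(rownames(D),
                           if (dims > 0) paste0("dim", seq_len(dims)))
  if (dims > 0) {
    for (k in seq_len(dims)) {
      v <- e$vectors[, pos[k]]
      if (v[which.max(abs(v))] < 0) v <- -v
      coords[, k] <- v * sqrt(e$values[pos[k]])
    }
  }
  goodness <- if (length(pos)) sum(e$values[pos[seq_len(dims)]]) / sum(e$values[pos]) else 1
  structure(list(coordinates = coords, eigenvalues = e$values,
                 goodness = goodness, dims = dims),
            class = "ystr_mds")
}

#' @export
print.ystr_mds <- function(x, ...) {
  cat(sprintf("<ystr_mds> %d populations in %d dimensions (goodness %.3f)\n",
              nrow(x$coordinates), x$dims, x$goodness))
  print(round(x$coordinates, 4))
  invisible(x)
}

#' Tidy methods for MDS results
#'
#' @param x an `ystr_mds`.
#' @param ... unused.
#' @return `tidy()`: one row per population with its coordinates; `glance()`:
#'   one-row summary (dims, goodness, leading eigenvalues).
#' @export
tidy.ystr_mds <- function(x, ...) {
  out <- as_tibble(x$coordinates)
  out$population <- rownames(x$coordinates)
  select(out, "population", dplyr::everything())
}

#' @rdname tidy.ystr_mds
#' @export
glance.ystr_mds <- function(x, ...) {
  tibble(n = nrow(x$coordinates), dims = x$dims, goodness = x$goodness,
         eigenvalue_1 = x$eigenvalues[1],
         eigenvalue_2 = if (length(x$eigenvalues) > 1) x$eigenvalues[2] else NA_real_)
}

quote_newick_label <- function(x) {
  bad <- grepl("[^A-Za-z0-9_.-]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step join the pair minimizing
#' `Q(i,j) = (m-2) d(i,j) - R_i - R_j`, with branch lengths from the standard
#' three-point formulas; the final three nodes close onto one internal node.
#' Ties in Q break toward the smallest (row, column) index pair; negative
#' branch lengths are clamped to 0 without redistribution. Exact on additive
#' matrices.
#'
#' @param D symmetric distance matrix with labelled rows (>= 2 taxa), or an
#'   `ystr_rst_matrix`.
#' @return An unrooted `ape::phylo` tree. Two taxa give the degenerate
#'   single-edge tree (total path length `d(1,2)`).
#' @export
neighbor_joining <- function(D) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  labels <- quote_newick_label(rownames(D))
  br <- function(x) sprintf("%.12g", max(x, 0))
  if (n == 2) {
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1], br(D[1, 2] / 2),
                   labels[2], br(D[1, 2] / 2))
    return(unquote_tips(ape::read.tree(text = nwk)))
  }
  frag <- labels
  d <- D
  while (nrow(d) > 3) {
    m <- nrow(d)
    R <- rowSums(d)
    Q <- (m - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    # smallest (row, column) pair among ties, i < j
    best <- Inf; bi <- bj <- 1L
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (Q[i, j] < best - 1e-12) { best <- Q[i, j]; bi <- i; bj <- j }
      }
    }
    bl_i <- d[bi, bj] / 2 + (R[bi] - R[bj]) / (2 * (m - 2))
    bl_j <- d[bi, bj] - bl_i
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[bi], br(bl_i), frag[bj], br(bl_j))
    new_d <- (d[bi, ] + d[bj, ] - d[bi, bj]) / 2
    keep <- setdiff(seq_len(m), c(bi, bj))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], new_d[keep]),
                c(new_d[keep], 0))
    frag <- c(frag[keep], new_frag)
    d <- d2
  }
  # close out the last three nodes onto one internal vertex
  x1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  x2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  x3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], br(x1), frag[2], br(x2), frag[3], br(x3))
  unquote_tips(ape::read.tree(text = nwk))
}

# ape keeps the quote characters of quoted Newick labels; strip them
unquote_tips <- function(tree) {
  q <- grepl("^'.*'$", tree$tip.label)
  tree$tip.label[q] <- gsub("''", "'",
                            sub("^'(.*)'$", "\\1", tree$tip.label[q]))
  tree
}

#' Plot MDS coordinates
#'
#' @param object an `ystr_mds`.
#' @param ... unused.
#' @return A ggplot of the first two embedding dimensions, labelled by
#'   population.
#' @export
autoplot.ystr_mds <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$population),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Dimension 1", y = "Dimension 2",
                  title = "Classical MDS of pairwise Rst") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise Rst matrix
#'
#' @param object an `ystr_rst_matrix`.
#' @param ... unused.
#' @return A ggplot tile map of clamped pairwise Rst.
#' @export
autoplot.ystr_rst_matrix <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(object$rst, responseName = "rst"))
  names(df)[1:2] <- c("pop_a", "pop_b")
  ggplot2::ggplot(df, ggplot2::aes(.data$pop_a, .data$pop_b, fill = .data$rst)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Rst") +
    ggplot2::labs(x = NULL, y = NULL, title = "Pairwise Rst") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of per-locus gene diversity
#'
#' @param object an `ystr_forensic`.
#' @param ... unused.
#' @return A ggplot bar chart of GD per locus, ascending.
#' @export
autoplot.ystr_forensic <- function(object, ...) {
  df <- arrange(tidy(object), .data$gd)
  df$locus <- factor(df$locus, levels = df$locus)
  ggplot2::ggplot(df, ggplot2::aes(.data$locus, .data$gd)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Gene diversity (GD)",
                  title = "Per-locus gene diversity") +
    ggplot2::theme_minimal()
}
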