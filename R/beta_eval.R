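.as_square_matrix <- function(D) {
  M <- if (inherits(D, "diss_matrix")) D$D else if (inherits(D, "dist")) {
    as.matrix(D)
  } else {
    as.matrix(D)
  }
  if (nrow(M) != ncol(M)) stop("dissimilarity matrix must be square")
  if (is.null(rownames(M))) {
    rownames(M) <- colnames(M) <- paste0("S", seq_len(nrow(M)))
  }
  M
}

#' UPGMA hierarchical clustering
#'
#' Average-linkage agglomerative clustering of a symmetric dissimilarity
#' matrix: at each step the closest pair of clusters is merged at node
#' height `d/2` and the distance from the merged cluster to every other
#' cluster is the size-weighted mean of the members' distances, i.e. the
#' arithmetic mean over all cross pairs.  Ties are broken
#' deterministically by the smallest row index, then smallest column
#' index, in the current matrix ordering.  The resulting tree is rooted,
#' binary and ultrametric (merge heights never decrease).
#'
#' @param D a `diss_matrix`, `dist` or symmetric numeric matrix with at
#'   least 2 samples and no `NA`/`NaN`.
#' @return object of class `cluster_tree`: list with `merge` (hclust-style
#'   `(n-1) x 2` matrix, negative entries = leaves), `height` (node
#'   heights, `d/2` at each merge), and `labels`.
#' @export
#' @examples
#' D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(D)$height  # 1 3
upgma <- function(D) {
  M <- .as_square_matrix(D)
  if (any(is.na(M))) stop("NA/NaN in dissimilarity matrix")
  n <- nrow(M)
  if (n < 2L) stop("need at least 2 samples")
  labels <- rownames(M)
  d <- M
  size <- rep(1L, n)
  id <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    dd <- d
    dd[lower.tri(dd, diag = TRUE)] <- Inf
    m <- min(dd)
    hits <- which(dd == m, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]
    j <- hits[1L, 2L]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- m / 2
    newd <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    d[i, ] <- newd
    d[, i] <- newd
    d[i, i] <- 0
    d <- d[-j, -j, drop = FALSE]
    size[i] <- size[i] + size[j]
    size <- size[-j]
    id[i] <- step
    id <- id[-j]
  }
  structure(list(merge = merge, height = height, labels = labels,
                 method = "upgma"),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster_tree> UPGMA,", length(x$labels), "leaves, root height",
      signif(max(x$height), 4L), "\n")
  invisible(x)
}

#' Newick export of a cluster tree
#'
#' Branch lengths are height differences between a node and its parent
#' (leaves sit at height 0), so path lengths reproduce the ultrametric
#' tree heights.
#'
#' @param tree a `cluster_tree`.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string (terminated by `;`).
#' @export
as_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "cluster_tree"))
  node_str <- function(idx, parent_h) {
    if (idx < 0L) {
      sprintf("%s:%s", tree$labels[-idx], format(parent_h, digits = digits))
    } else {
      h <- tree$height[idx]
      sprintf("(%s,%s):%s",
              node_str(tree$merge[idx, 1L], h),
              node_str(tree$merge[idx, 2L], h),
              format(parent_h - h, digits = digits))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  sprintf("(%s,%s);",
          node_str(tree$merge[root, 1L], h),
          node_str(tree$merge[root, 2L], h))
}

#' @exportS3Method ape::as.phylo
#' @rdname as_newick
#' @param x a `cluster_tree`.
#' @param ... unused.
as.phylo.cluster_tree <- function(x, ...) {
  ape::read.tree(text = as_newick(x))
}

#' Cophenetic distances of a cluster tree
#'
#' The tree-implied dissimilarity between two leaves is twice the height
#' of their lowest common ancestor.
#'
#' @param tree a `cluster_tree`.
#' @return symmetric matrix with leaf labels as dimnames.
#' @export
cophenetic_dist <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  n <- length(tree$labels)
  D <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  members <- vector("list", nrow(tree$merge))
  for (m in seq_len(nrow(tree$merge))) {
    kids <- lapply(tree$merge[m, ], function(ch) {
      if (ch < 0L) -ch else members[[ch]]
    })
    D[kids[[1L]], kids[[2L]]] <- D[kids[[2L]], kids[[1L]]] <-
      2 * tree$height[m]
    members[[m]] <- c(kids[[1L]], kids[[2L]])
  }
  D
}

# leaf states as bit masks (one bit per group level), in tree label order
.leaf_bits <- function(tree, labels) {
  if (is.null(names(labels))) {
    if (length(labels) != length(tree$labels)) {
      stop("labels must be named by sample id or match the leaf count")
    }
    names(labels) <- tree$labels
  }
  miss <- setdiff(tree$labels, names(labels))
  if (length(miss)) {
    stop("unlabeled leaves: ", paste(miss, collapse = ", "))
  }
  grp <- factor(unname(labels[tree$labels]))
  if (nlevels(grp) > 30L) stop("more than 30 groups not supported")
  bitwShiftL(1L, as.integer(grp) - 1L)
}

.fitch_count <- function(merge, leaf_bits) {
  nint <- nrow(merge)
  states <- integer(nint)
  score <- 0L
  for (m in seq_len(nint)) {
    a <- merge[m, 1L]
    b <- merge[m, 2L]
    s1 <- if (a < 0L) leaf_bits[-a] else states[a]
    s2 <- if (b < 0L) leaf_bits[-b] else states[b]
    inter <- bitwAnd(s1, s2)
    if (inter != 0L) {
      states[m] <- inter
    } else {
      states[m] <- bitwOr(s1, s2)
      score <- score + 1L
    }
  }
  score
}

#' Fitch parsimony score of group labels on a tree
#'
#' Minimum number of group-label changes needed on the rooted binary tree
#' to explain the leaf labels (unordered states, unit cost; Fitch small
#' parsimony).  When each group forms a clade the score is `c - 1` for
#' `c` groups -- the best attainable value -- and it grows as the tree
#' mixes the groups.
#'
#' @param tree a `cluster_tree`.
#' @param labels group labels, named by sample id (or unnamed in leaf
#'   order).
#' @return non-negative integer `<= leaves - 1`.
#' @export
parsimony_score <- function(tree, labels) {
  stopifnot(inherits(tree, "cluster_tree"))
  .fitch_count(tree$merge, .leaf_bits(tree, labels))
}

#' Monte Carlo parsimony test of group structure
#'
#' Permutes the leaf-to-label assignment on the *fixed* observed tree
#' (preserving group sizes) and reports
#' `p = #(permuted score <= observed) / n_perm`, the plain
#' fraction; `add_one = TRUE` gives the `(r+1)/(n+1)` variant that cannot
#' return 0.
#'
#' @param tree a `cluster_tree`.
#' @param labels group labels named by sample id.
#' @param n_perm number of label permutations (default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @param add_one use the add-one p-value form.
#' @return object of class `parsimony_result`: list with `score`,
#'   `p_value`, `n_permutations`, `perm_scores`.
#' @export
parsimony_test <- function(tree, labels, n_perm = 1000L, seed = NULL,
                           add_one = FALSE) {
  stopifnot(inherits(tree, "cluster_tree"))
  n_perm <- .as_count(n_perm, "n_perm")
  if (!is.null(seed)) set.seed(seed)
  bits <- .leaf_bits(tree, labels)
  obs <- .fitch_count(tree$merge, bits)
  perm <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    perm[b] <- .fitch_count(tree$merge, sample(bits))
  }
  r <- sum(perm <= obs)
  p <- if (add_one) (r + 1) / (n_perm + 1) else r / n_perm
  structure(list(score = obs, p_value = p, n_permutations = n_perm,
                 perm_scores = perm),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("<parsimony_result> score:", x$score, " Monte Carlo p:",
      format(x$p_value, digits = 4L), "(", x$n_permutations,
      "permutations )\n")
  invisible(x)
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centres the squared dissimilarities, `B = -J (D*D) J / 2` with
#' `J = I - 11'/n`, and eigendecomposes `B`.  Coordinates are the
#' eigenvectors scaled by the square root of their (positive) eigenvalues,
#' ordered by decreasing eigenvalue; axes with non-positive eigenvalues
#' are dropped.
#'
#' @param D a `diss_matrix`, `dist` or symmetric matrix.
#' @return object of class `ordination`: list with `coordinates`
#'   (samples x axes, axes named `PC1..`), and `eigenvalues` (all
#'   eigenvalues of `B`, sorted descending).
#' @export
pcoa_ord <- function(D) {
  M <- .as_square_matrix(D)
  if (any(is.na(M))) stop("NA/NaN in dissimilarity matrix")
  n <- nrow(M)
  A <- -0.5 * M^2
  B <- A - matrix(rowMeans(A), n, n) -
    matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values), 1e-12) * 1e-9
  pos <- e$values > tol
  if (!any(pos)) stop("degenerate ordination: no positive eigenvalue")
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = sum(pos))
  dimnames(coords) <- list(rownames(M), paste0("PC", seq_len(sum(pos))))
  structure(list(coordinates = coords, eigenvalues = e$values),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  ev <- x$eigenvalues[x$eigenvalues > 0]
  cat("<ordination>", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "axes; PC1 explains",
      sprintf("%.1f%%", 100 * ev[1L] / sum(ev)), "of positive inertia\n")
  invisible(x)
}

#' Gradient correlation of the first principal coordinate
#'
#' Absolute Pearson correlation between PC1 and a known gradient (e.g.
#' sample index or an environmental variable).  The absolute value
#' absorbs the arbitrary sign of eigenvectors.
#'
#' @param ord an `ordination`.
#' @param gradient numeric vector, one value per sample, in the row order
#'   of `ord$coordinates`.
#' @return `|PCC|` in `[0, 1]`.
#' @export
gradient_pcc <- function(ord, gradient) {
  stopifnot(inherits(ord, "ordination"))
  if (length(gradient) != nrow(ord$coordinates)) {
    stop("gradient length must equal the sample count")
  }
  pc1 <- ord$coordinates[, 1L]
  if (stats::sd(pc1) == 0 || stats::sd(gradient) == 0) {
    stop("zero variance in PC1 or gradient")
  }
  abs(cor(pc1, gradient))
}
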