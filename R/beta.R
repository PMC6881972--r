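#' UPGMA clustering of a dissimilarity matrix
#'
#' Standard unweighted pair-group agglomeration: the closest pair of clusters
#' is merged at height d/2 and the distance from the new cluster to any other
#' is the size-weighted average of its members' distances. Ties are broken by
#' the lexicographically smallest pair of cluster labels (a cluster is
#' labeled by its smallest leaf), so the tree is deterministic. The result is
#' an ultrametric rooted \code{ape::phylo} tree whose branch lengths are
#' height differences.
#'
#' @param dm symmetric zero-diagonal labeled matrix (e.g. from
#'   [pairwise_dissimilarity()]).
#' @return a rooted \code{phylo} tree.
#' @examples
#' m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' upgma(m)
#' @export
upgma <- function(dm) {
  m <- unclass(as.matrix(dm))
  if (anyNA(m)) stop("dissimilarity matrix contains NA/NaN")
  n <- nrow(m)
  if (n < 2) stop("need at least 2 samples")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  if (max(abs(m - t(m))) > 1e-12) stop("matrix is not symmetric")
  # active clusters: newick fragment, height, size, smallest leaf label
  nwk <- labels
  height <- numeric(n)
  size <- rep(1L, n)
  key <- labels
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        i <- active[ii]; j <- active[jj]
        pk <- sort(c(key[i], key[j]))
        if (is.null(best) || m[i, j] < best$d - 1e-15 ||
            (abs(m[i, j] - best$d) <= 1e-15 &&
             (pk[1] < best$pk[1] ||
              (pk[1] == best$pk[1] && pk[2] < best$pk[2])))) {
          best <- list(i = i, j = j, d = m[i, j], pk = pk)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    kids <- c(i, j)[base::order(c(key[i], key[j]))]
    frag <- sprintf("(%s:%.12g,%s:%.12g)",
                    nwk[kids[1]], max(h - height[kids[1]], 0),
                    nwk[kids[2]], max(h - height[kids[2]], 0))
    # weighted average distance to every other active cluster
    others <- setdiff(active, c(i, j))
    newd <- (size[i] * m[i, others] + size[j] * m[j, others]) /
      (size[i] + size[j])
    m[i, others] <- newd
    m[others, i] <- newd
    nwk[i] <- frag
    height[i] <- h
    size[i] <- size[i] + size[j]
    key[i] <- min(key[i], key[j])
    active <- setdiff(active, j)
  }
  ape::read.tree(text = paste0(nwk[active], ";"))
}

#' Reference tree for a known grouping
#'
#' Builds the gold-standard rooted tree against which clustering results are
#' scored: one polytomous node per group (its samples as leaves) attached to
#' the root, so within-group order carries no topology. Groups with a single
#' sample attach that leaf directly to the root. Branch lengths are 1.
#'
#' @param groups named character vector or factor: sample id -> group label.
#' @return a rooted \code{phylo} tree.
#' @export
reference_tree <- function(groups) {
  if (is.null(names(groups))) stop("groups must be named by sample id")
  groups <- setNames(as.character(groups), names(groups))
  split_ids <- split(names(groups), groups)
  if (any(lengths(split_ids) == 0)) stop("every group needs >= 1 member")
  if (length(split_ids) < 2) stop("need at least 2 groups")
  frag <- vapply(split_ids, function(ids) {
    if (length(ids) == 1) paste0(ids, ":1")
    else paste0("(", paste0(sort(ids), ":1", collapse = ","), "):1")
  }, character(1))
  ape::read.tree(text = paste0("(", paste(frag, collapse = ","), ");"))
}

# Depth in edges from the root for every node of a rooted phylo tree.
node_depths <- function(tree) {
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  depth <- integer(max(tree$edge))
  root <- length(tree$tip.label) + 1L
  depth[root] <- 0L
  for (e in seq_len(nrow(tree$edge)))
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + 1L
  depth
}

# Topology code of every leaf triplet (rows of idx, 0-based over `labels`):
# 1 = ab|c, 2 = ac|b, 3 = bc|a, 0 = unresolved star.
triplet_codes <- function(tree, labels, idx) {
  tip <- match(labels, tree$tip.label)
  mr <- ape::mrca(tree)
  depth <- node_depths(tree)
  a <- tip[idx[1, ]]; b <- tip[idx[2, ]]; c3 <- tip[idx[3, ]]
  dab <- depth[mr[cbind(a, b)]]
  dac <- depth[mr[cbind(a, c3)]]
  dbc <- depth[mr[cbind(b, c3)]]
  code <- integer(ncol(idx))
  code[dab > dac & dab > dbc] <- 1L
  code[dac > dab & dac > dbc] <- 2L
  code[dbc > dab & dbc > dac] <- 3L
  code
}

#' Rooted triplet distance between two trees
#'
#' Counts the 3-leaf subsets whose induced rooted topologies differ between
#' the trees. A triplet resolves as xy|z when the most recent common ancestor
#' of x and y is a strict descendant of that of all three; if all three
#' leaves coalesce in one node the triplet is an unresolved star. Two
#' conventions are offered for scoring a resolved triplet against an
#' unresolved star: \code{"compatible"} (the default) treats the star as
#' consistent with any resolution, so only triplets resolved differently in
#' both trees count — the convention under which a perfect binary clustering
#' of a polytomous reference grouping scores 0; \code{"mismatch"} counts
#' resolved-versus-unresolved as different too. The maximum is
#' \code{choose(n, 3)}.
#'
#' @param t1,t2 rooted \code{phylo} trees on the same leaf-label set (n >= 3);
#'   polytomies allowed.
#' @param unresolved "compatible" or "mismatch" (see above).
#' @return nonnegative integer distance.
#' @examples
#' a <- ape::read.tree(text = "((A,B),(C,D));")
#' b <- ape::read.tree(text = "((A,C),(B,D));")
#' triplet_distance(a, b)
#' @export
triplet_distance <- function(t1, t2, unresolved = c("compatible", "mismatch")) {
  unresolved <- match.arg(unresolved)
  labels <- sort(t1$tip.label)
  if (!identical(labels, sort(t2$tip.label)))
    stop("trees have different leaf-label sets")
  n <- length(labels)
  if (n < 3) stop("triplet distance needs >= 3 leaves")
  if (anyDuplicated(labels)) stop("leaf labels must be unique")
  idx <- combn(n, 3)
  c1 <- triplet_codes(t1, labels, idx)
  c2 <- triplet_codes(t2, labels, idx)
  if (unresolved == "mismatch") sum(c1 != c2)
  else sum(c1 != c2 & c1 > 0L & c2 > 0L)
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric multidimensional scaling (Gower double-centering of
#' \eqn{-D^2/2} followed by eigendecomposition); coordinates are eigenvectors
#' scaled by the square roots of the positive eigenvalues, axes ordered by
#' non-increasing eigenvalue. Axes with non-positive eigenvalues are dropped;
#' if fewer positive axes exist than requested, the available ones are
#' returned with a warning.
#'
#' @param dm symmetric zero-diagonal labeled matrix.
#' @param dims number of requested axes (>= 1).
#' @return an object of class \code{d2_ordination}: list with
#'   \code{coordinates} (samples x axes), \code{eigenvalues} (all
#'   eigenvalues, non-increasing) and \code{labels}.
#' @export
pcoa <- function(dm, dims = 2) {
  m <- unclass(as.matrix(dm))
  if (anyNA(m)) stop("dissimilarity matrix contains NA/NaN")
  if (dims < 1) stop("dims must be >= 1")
  n <- nrow(m)
  fit <- cmdscale(stats::as.dist(m), k = min(dims, n - 1), eig = TRUE)
  pts <- fit$points
  npos <- sum(fit$eig > 1e-12)
  if (npos < dims) {
    warning("only ", npos, " positive eigenvalue axis/axes available (",
            dims, " requested)")
    pts <- pts[, seq_len(min(ncol(pts), npos)), drop = FALSE]
  }
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  rownames(pts) <- labels
  colnames(pts) <- paste0("PC", seq_len(ncol(pts)))
  structure(list(coordinates = pts, eigenvalues = fit$eig, labels = labels),
            class = "d2_ordination")
}

#' @export
print.d2_ordination <- function(x, ...) {
  ev <- x$eigenvalues
  rel <- pmax(ev, 0) / sum(pmax(ev, 0))
  cat("PCoA ordination:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "axis/axes\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of positive inertia\n",
              100 * rel[1], if (length(rel) > 1) 100 * rel[2] else 0))
  invisible(x)
}

#' Correlation between the first principal coordinate and a gradient
#'
#' Pearson correlation between PC1 and a known gradient (for example, the
#' abundance-decay exponent of a simulated series or an environmental
#' variable). Because a PCoA axis has arbitrary sign, the absolute value is
#' returned by default; \code{signed = TRUE} gives the raw correlation for
#' exploratory use.
#'
#' @param ord a \code{d2_ordination}.
#' @param gradient numeric vector, one value per sample in the ordination's
#'   sample order.
#' @param signed return the signed correlation instead of its magnitude.
#' @return correlation coefficient (in [0, 1] unless \code{signed}).
#' @export
gradient_correlation <- function(ord, gradient, signed = FALSE) {
  pc1 <- ord$coordinates[, 1]
  if (length(gradient) != length(pc1))
    stop("gradient length must match the number of samples")
  if (stats::sd(pc1) == 0 || stats::sd(gradient) == 0)
    stop("undefined correlation: zero variance in PC1 or the gradient")
  r <- cor(pc1, gradient)
  if (signed) r else abs(r)
}

#' Write a PCoA ordination as TSV
#'
#' One row per sample (label then axis coordinates), plus a companion
#' \code{<path>.eig} file listing the eigenvalues.
#'
#' @param ord a \code{d2_ordination}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_ordination <- function(ord, path) {
  df <- data.frame(sample = ord$labels, ord$coordinates, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(format(ord$eigenvalues, digits = 17), paste0(path, ".eig"))
  invisible(path)
}
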