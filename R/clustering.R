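#' Agglomerative hierarchical clustering of chapters
#'
#' `complete_linkage()` performs standard agglomerative clustering on a
#' dissimilarity matrix: every chapter starts in its own cluster and at each
#' step the two clusters with the smallest maximum inter-cluster distance are
#' merged, the merge height being that distance. `ward_linkage()` uses the
#' Ward criterion through the Lance-Williams update applied to squared
#' distances; its heights are on Ward's own (squared-distance) scale. Ties
#' are broken deterministically toward the pair occupying the lowest matrix
#' positions (a merged cluster keeps the position of its first member), so
#' identical inputs always give identical trees.
#'
#' @param distance Square symmetric numeric matrix with zero diagonal and
#'   finite entries; row/column names become leaf labels.
#' @return Object of class `merge_tree`: `merge` (hclust convention:
#'   negatives are leaves, positives earlier merge steps), `height`
#'   (one per merge, non-decreasing for complete linkage), `labels`,
#'   `method`.
#' @seealso [cut_tree()], [to_newick()], [as.hclust.merge_tree()]
#' @export
#' @examples
#' d <- matrix(c(0, .1, .9, .9,
#'               .1, 0, .9, .9,
#'               .9, .9, 0, .2,
#'               .9, .9, .2, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' complete_linkage(d)$height   # 0.1 0.2 0.9
complete_linkage <- function(distance) {
  agglomerate(distance, method = "complete")
}

#' @rdname complete_linkage
#' @export
ward_linkage <- function(distance) {
  agglomerate(distance, method = "ward")
}

agglomerate <- function(distance, method = c("complete", "ward")) {
  method <- match.arg(method)
  validate_distance(distance)
  n <- nrow(distance)
  labels <- rownames(distance)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 1) {
    return(structure(list(merge = matrix(integer(), 0, 2), height = numeric(),
                          labels = labels, method = method),
                     class = "merge_tree"))
  }
  D <- if (method == "ward") distance^2 else distance
  id <- -seq_len(n)            # hclust ids of active clusters
  size <- rep(1, n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    pos <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (ii in seq_along(pos)[-length(pos)]) {
      i <- pos[ii]
      js <- pos[(ii + 1):length(pos)]
      dij <- D[i, js]
      m <- min(dij)
      if (m < best_d) {               # strict: earliest pair wins ties
        best_d <- m
        best <- c(i, js[which.min(dij)])
      }
    }
    i <- best[1]; j <- best[2]
    height[step] <- best_d
    merge[step, ] <- merge_row(id[i], id[j])
    others <- setdiff(pos, c(i, j))
    if (length(others)) {
      if (method == "complete") {
        D[i, others] <- D[others, i] <- pmax(D[i, others], D[j, others])
      } else {
        ni <- size[i]; nj <- size[j]; nk <- size[others]
        D[i, others] <- D[others, i] <-
          ((ni + nk) * D[i, others] + (nj + nk) * D[j, others] -
             nk * D[i, j]) / (ni + nj + nk)
      }
    }
    # merged cluster replaces position i (created now: latest in scan order
    # is irrelevant because its id is the step number); j retires
    size[i] <- size[i] + size[j]
    id[i] <- step
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = height, labels = labels,
                 method = method),
            class = "merge_tree")
}

# hclust row convention: leaves (negative) before merge nodes, each ascending
merge_row <- function(a, b) {
  v <- c(a, b)
  as.integer(v[order(v >= 0, abs(v))])
}

validate_distance <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance must be a square matrix", call. = FALSE)
  }
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero", call. = FALSE)
  invisible(d)
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("%s-linkage merge tree, %d leaves\n",
              x$method, length(x$labels)))
  if (length(x$height)) {
    cat("  merge heights:", paste(signif(x$height, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a merge tree to an `hclust` object
#'
#' @param x A `merge_tree`.
#' @param ... Unused.
#' @return A base-R `hclust` object (plottable with [stats::plot.hclust]).
#' @export
as.hclust.merge_tree <- function(x, ...) {
  n <- length(x$labels)
  if (n < 2) stop("cannot convert a single-leaf tree to hclust", call. = FALSE)
  ord <- leaf_order(x$merge, n)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = "jaccard"),
            class = "hclust")
}

leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' @export
plot.merge_tree <- function(x, cut_height = NULL, ...) {
  stats::plot.hclust(stats::as.hclust(x), ...)
  if (!is.null(cut_height)) graphics::abline(h = cut_height, lty = 2, col = "red")
  invisible(x)
}

#' Cut a merge tree into clusters
#'
#' Clusters are the connected components formed by all merges at height
#' *strictly below* `cut_height`. With Jaccard distances and the 30%
#' co-occurrence convention, the headline cut is `cut_height = 0.70`:
#' chapters cluster together when their (complete-linkage) co-occurrence
#' probability exceeds 30%. Singletons are allowed.
#'
#' @param tree A `merge_tree`.
#' @param cut_height Cut height; strict (merges exactly at the cut do not
#'   join).
#' @return Named integer vector mapping each leaf label to a cluster number
#'   (clusters numbered by first leaf in label order), with attribute
#'   `cut_height`.
#' @export
#' @examples
#' d <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("A","B"), c("A","B")))
#' cut_tree(complete_linkage(d), 0.70)  # A and B cluster together
cut_tree <- function(tree, cut_height) {
  stopifnot(inherits(tree, "merge_tree"))
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_members <- vector("list", max(0L, n - 1L))   # leaves under each merge node
  for (step in seq_along(tree$height)) {
    mem <- c(if (tree$merge[step, 1] < 0) -tree$merge[step, 1] else node_members[[tree$merge[step, 1]]],
             if (tree$merge[step, 2] < 0) -tree$merge[step, 2] else node_members[[tree$merge[step, 2]]])
    node_members[[step]] <- mem
    if (tree$height[step] < cut_height) {
      r <- find(mem[1])
      for (m in mem[-1]) parent[find(m)] <- r
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels_first <- !duplicated(roots)
  cl <- match(roots, roots[labels_first])
  structure(stats::setNames(cl, tree$labels), cut_height = cut_height)
}

#' Serialise a merge tree as a Newick string
#'
#' Branch lengths split each merge height at its midpoint, so the tree is
#' ultrametric with every leaf at depth half the root height; two leaves
#' merged at 0.4 give `"(A:0.2,B:0.2);"`. Cophenetic distances of the parsed
#' tree therefore reproduce the merge heights exactly.
#'
#' @param tree A `merge_tree`.
#' @return Single Newick string ending in `";"`.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  n <- length(tree$labels)
  if (n == 1) return(paste0(tree$labels, ";"))
  node_h <- tree$height
  render <- function(node, parent_h) {
    if (node < 0) {
      return(sprintf("%s:%.10g", tree$labels[-node], parent_h / 2))
    }
    h <- node_h[node]
    kids <- vapply(tree$merge[node, ], render, character(1), parent_h = h)
    sprintf("(%s):%.10g", paste(kids, collapse = ","), (parent_h - h) / 2)
  }
  h_root <- node_h[n - 1]
  kids <- vapply(tree$merge[n - 1, ], render, character(1), parent_h = h_root)
  paste0("(", paste(kids, collapse = ","), ");")
}

#' Write a merge tree to disk
#'
#' `write_newick()` writes the Newick serialisation; `write_merge_table()`
#' writes a CSV of merge steps (`step`, `left`, `right`, `height`; negative
#' node numbers are leaves in label order).
#'
#' @param tree A `merge_tree`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(to_newick(tree), path)
  invisible(path)
}

#' @rdname write_newick
#' @export
write_merge_table <- function(tree, path) {
  df <- data.frame(step = seq_along(tree$height),
                   left = tree$merge[, 1], right = tree$merge[, 2],
                   height = formatC(tree$height, format = "f", digits = 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Partition agreement between two cluster assignments
#'
#' Rand index between two assignments over the same leaves; used by the
#' linkage sensitivity harness to quantify how much switching from complete
#' to Ward linkage changes the clusters.
#'
#' @param a,b Cluster assignments as returned by [cut_tree()] (same leaves).
#' @return Rand index in `[0, 1]` (1 = identical partitions).
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}
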