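#' Spearman correlation matrix of symptom severities
#'
#' Pairwise Spearman rank correlation (midranks for ties) between the 16
#' corrected symptom-severity columns of one duration group. A constant
#' column makes rho undefined; such entries are set to 0 with a warning.
#'
#' @param scores n x 16 matrix (or data frame) of corrected scores; at
#'   least 3 rows.
#' @return A symmetric 16 x 16 matrix with unit diagonal, item labels as
#'   dimnames and the number of participants in attribute `n_participants`.
#' @export
spearman_matrix <- function(scores) {
  m <- as.matrix(scores)
  if (nrow(m) < 3) stop("at least 3 participants are required")
  lab <- colnames(m)
  if (is.null(lab) && ncol(m) == 16) lab <- rpq_items()$item
  const <- apply(m, 2, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  if (any(const)) {
    warning("constant column(s) ", paste(lab[const], collapse = ", "),
            ": undefined Spearman correlations set to 0")
    rho[is.na(rho)] <- 0
  }
  diag(rho) <- 1
  dimnames(rho) <- list(lab, lab)
  attr(rho, "n_participants") <- nrow(m)
  rho
}

#' Euclidean distances between correlation profiles
#'
#' Distance between two symptoms is the Euclidean distance between their
#' full rows of the correlation matrix, self-correlations included — the
#' row-clustering semantics of clustering "on the correlation matrix".
#' Note the unit diagonal entries take part in the distances; excluding
#' them would change the geometry.
#'
#' @param corr Symmetric correlation matrix (e.g. from [spearman_matrix()]).
#' @return A [stats::dist] object over the items.
#' @export
profile_distances <- function(corr) {
  m <- as.matrix(corr)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("correlation matrix must be symmetric")
  stats::dist(m, method = "euclidean")
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Bottom-up agglomeration over a distance table. Under the default
#' unweighted average linkage (UPGMA) the distance between two groups is
#' the arithmetic mean of all cross-pair leaf distances, so merge heights
#' are monotone non-decreasing (asserted on every run). When two pairs are
#' exactly equidistant the pair whose first group entered the active list
#' earliest is merged (then the second) — deterministic and documented.
#'
#' @param d A [stats::dist] object or symmetric distance matrix.
#' @param method Linkage: "average" (default), "single", "complete" or
#'   "ward" (ward.D2 convention).
#' @return An object of classes `rpq_tree` and [stats::hclust]: `merge`
#'   (hclust convention), `height`, `order`, `labels`.
#' @export
upgma <- function(d, method = c("average", "single", "complete", "ward")) {
  method <- match.arg(method)
  dm <- as.matrix(d)
  if (any(is.na(dm))) stop("distance table contains NA")
  n <- nrow(dm)
  if (n < 2) stop("need at least two leaves")
  lab <- rownames(dm)
  if (is.null(lab)) lab <- as.character(seq_len(n))

  # active groups in creation order; id < 0 leaf, > 0 merge step
  act <- -seq_len(n)
  size <- rep(1, n)
  cur <- dm
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (s in seq_len(n - 1)) {
    k <- length(act)
    best <- Inf; bi <- bj <- 0L
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (cur[i, j] < best) { best <- cur[i, j]; bi <- i; bj <- j }
    }
    pair <- c(act[bi], act[bj])
    # hclust convention: leaves before clusters, each ascending
    merge[s, ] <- pair[order(pair >= 0, abs(pair))]
    height[s] <- best
    si <- size[bi]; sj <- size[bj]
    new <- numeric(k)
    for (m in seq_len(k)) {
      if (m == bi || m == bj) next
      new[m] <- switch(method,
        average = (si * cur[bi, m] + sj * cur[bj, m]) / (si + sj),
        single = min(cur[bi, m], cur[bj, m]),
        complete = max(cur[bi, m], cur[bj, m]),
        ward = sqrt(((si + size[m]) * cur[bi, m]^2 +
                     (sj + size[m]) * cur[bj, m]^2 -
                     size[m] * best^2) / (si + sj + size[m])))
    }
    cur[bi, ] <- new; cur[, bi] <- new; cur[bi, bi] <- 0
    keep <- setdiff(seq_len(k), bj)
    cur <- cur[keep, keep, drop = FALSE]
    act[bi] <- s
    size[bi] <- si + sj
    act <- act[keep]; size <- size[keep]
  }

  if (method %in% c("average", "complete", "ward") &&
      any(diff(height) < -1e-9))
    stop("internal error: non-monotone merge heights under ", method, " linkage")

  tree <- structure(list(
    merge = merge, height = height,
    order = tree_leaf_order(merge),
    labels = lab, method = method,
    dist.method = "euclidean",
    call = match.call()
  ), class = c("rpq_tree", "hclust"))
  tree
}

# leaf order for plotting: left-to-right traversal of the merge matrix
tree_leaf_order <- function(merge) {
  res <- function(i) {
    if (i < 0) return(-i)
    c(res(merge[i, 1]), res(merge[i, 2]))
  }
  res(nrow(merge))
}

# partition of the leaves after the first k merges, as a list of integer
# vectors (singletons included)
partition_after <- function(tree, k) {
  n <- length(tree$labels)
  groups <- as.list(seq_len(n))     # group per leaf
  gid <- seq_len(n)                 # active group id per merged entity
  merged_groups <- vector("list", k)
  for (s in seq_len(k)) {
    pick <- function(e) if (e < 0) -e else attr(merged_groups[[e]], "leaves")
    a <- pick(tree$merge[s, 1]); b <- pick(tree$merge[s, 2])
    merged_groups[[s]] <- structure(list(), leaves = c(a, b))
  }
  # active groups: merges 1..k not absorbed by a later merge <= k, plus
  # leaves never referenced in merges 1..k
  absorbed <- tree$merge[seq_len(k), , drop = FALSE]
  absorbed <- absorbed[absorbed > 0]
  active_merges <- setdiff(seq_len(k), absorbed)
  used_leaves <- -tree$merge[seq_len(k), , drop = FALSE][tree$merge[seq_len(k), , drop = FALSE] < 0]
  out <- lapply(active_merges, function(s) sort(attr(merged_groups[[s]], "leaves")))
  singletons <- setdiff(seq_len(n), used_leaves)
  c(out, as.list(singletons))
}

#' Form symptom clusters from a merge tree
#'
#' Implements the cluster-formation rule: the partition is taken
#' immediately after the earliest merge at which no symptom remains
#' unpaired (every leaf belongs to a group of at least two), i.e. in as few
#' hierarchical levels as possible. For a 16-leaf tree with formation level
#' K the partition has 16 - K clusters. Merges above the cut are recorded
#' as supercluster annotations (which formed clusters join next, in merge
#' order). A warning is issued when the merge heights at and just above the
#' cut are tied, since "levels" are then ambiguous.
#'
#' @param tree An `rpq_tree` / [stats::hclust] object.
#' @return An [rpq_partition] with attributes `formation_level` (the merge
#'   index K) and `superclusters` (list of cluster-name sets, one per merge
#'   above the cut).
#' @export
form_clusters <- function(tree) {
  n <- length(tree$labels)
  # a leaf is paired once it appears (as a negative entry) in some merge;
  # K = index of the last merge that still introduces a leaf
  leaf_rows <- apply(tree$merge < 0, 1, any)
  K <- max(which(leaf_rows))
  if (K < n - 1 && abs(tree$height[K] - tree$height[K + 1]) < 1e-12)
    warning("tied merge heights at the formation cut; partition taken by merge index")
  groups <- partition_after(tree, K)
  stopifnot(all(lengths(groups) >= 2))
  if (n == 16) groups <- name_clusters(groups) else
    names(groups) <- paste0("cluster_", seq_along(groups))

  # map each merge above the cut to the set of formed clusters it unites
  base_of <- integer(n)
  for (i in seq_along(groups)) base_of[groups[[i]]] <- i
  leaves_of <- function(e) if (e < 0) -e else
    c(leaves_of(tree$merge[e, 1]), leaves_of(tree$merge[e, 2]))
  supers <- list()
  if (K < n - 1) {
    for (s in (K + 1):(n - 1)) {
      supers[[length(supers) + 1]] <-
        names(groups)[sort(unique(base_of[leaves_of(s)]))]
    }
  }
  out <- if (n == 16) rpq_partition(groups) else structure(groups, class = "rpq_partition")
  attr(out, "formation_level") <- K
  attr(out, "superclusters") <- supers
  out
}

#' Newick export of a merge tree
#'
#' Serialises the tree as a rooted Newick string with branch lengths equal
#' to the difference between parent and child merge heights (leaves sit at
#' height 0), so the string parses back to an identical tree.
#'
#' @param tree An `rpq_tree` / [stats::hclust] object.
#' @param file Optional path; when given the string is written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
to_newick <- function(tree, file = NULL) {
  h <- c(tree$height)
  fmt <- function(x) sprintf("%.12g", x)
  node <- function(e, parent_h) {
    if (e < 0) return(paste0(tree$labels[-e], ":", fmt(parent_h)))
    paste0("(", node(tree$merge[e, 1], h[e]), ",",
           node(tree$merge[e, 2], h[e]), "):", fmt(parent_h - h[e]))
  }
  root <- nrow(tree$merge)
  s <- paste0("(", node(tree$merge[root, 1], h[root]), ",",
              node(tree$merge[root, 2], h[root]), ");")
  if (!is.null(file)) { writeLines(s, file); return(invisible(s)) }
  s
}

#' Adjusted Rand agreement between two partitions
#'
#' Chance-corrected agreement between two partitions of the same item set;
#' 1 exactly for identical partitions, 0 in expectation under independent
#' random partitions.
#'
#' @param a,b Two [rpq_partition] objects (or plain lists of index vectors)
#'   over the same items.
#' @return The adjusted Rand index, in `[-1, 1]`.
#' @export
partition_agreement <- function(a, b) {
  ia <- sort(unlist(a, use.names = FALSE)); ib <- sort(unlist(b, use.names = FALSE))
  if (!identical(as.integer(ia), as.integer(ib)))
    stop("partitions are over different item sets")
  lab <- function(p) {
    v <- integer(length(ia))
    for (i in seq_along(p)) v[match(p[[i]], ia)] <- i
    v
  }
  mclust::adjustedRandIndex(lab(a), lab(b))
}

#' Fit the symptom-cluster model to a cohort
#'
#' The end-to-end clustering fit: corrected scores -> Spearman correlation
#' matrix -> Euclidean distances between correlation profiles ->
#' agglomerative clustering -> cluster formation at the earliest
#' singleton-free level. Accepts a cohort data frame (raw `rpq_*` or scored
#' `cor_*` columns) or a corrected-score matrix.
#'
#' Cohorts with fewer than 50 participants trigger a "preliminary, small n"
#' warning: the correlation matrix is then poorly determined and the
#' recovered structure should be treated as exploratory.
#'
#' @param x Cohort data frame or n x 16 corrected-score matrix.
#' @param linkage Linkage method passed to [upgma()].
#' @return An object of class `rpq_clust` with components `corr`, `dist`,
#'   `tree`, `clusters`, `formation_level`, `superclusters`, `n`, `linkage`.
#' @seealso [form_clusters()], [to_newick()], [assign_membership()]
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(n_participants = 300), seed = 7)
#' fit <- rpq_cluster(cohort)
#' fit
rpq_cluster <- function(x, linkage = "average") {
  if (is.data.frame(x)) {
    cc <- sub("rpq_", "cor_", rpq_score_cols())
    if (all(cc %in% names(x))) {
      m <- as.matrix(x[cc])
    } else if (all(rpq_score_cols() %in% names(x))) {
      m <- correct_scores(as.matrix(x[rpq_score_cols()]))
    } else stop("cohort lacks RPQ score columns")
    colnames(m) <- rpq_items()$item
  } else {
    m <- as.matrix(x)
    if (ncol(m) != 16) stop("expected 16 score columns")
    if (is.null(colnames(m))) colnames(m) <- rpq_items()$item
  }
  if (nrow(m) < 50)
    warning("preliminary, small n: only ", nrow(m),
            " participants; clustering may be unstable")
  corr <- spearman_matrix(m)
  d <- profile_distances(corr)
  tree <- upgma(d, method = linkage)
  clusters <- form_clusters(tree)
  structure(list(
    corr = corr, dist = d, tree = tree, clusters = clusters,
    formation_level = attr(clusters, "formation_level"),
    superclusters = attr(clusters, "superclusters"),
    n = nrow(m), linkage = linkage
  ), class = "rpq_clust")
}

#' @export
print.rpq_clust <- function(x, ...) {
  cat("Symptom-cluster fit (", x$linkage, " linkage, n = ", x$n, ")\n", sep = "")
  cat("Formation level: merge ", x$formation_level, " of ",
      nrow(x$tree$merge), " -> ", length(x$clusters), " clusters\n\n", sep = "")
  print(x$clusters)
  invisible(x)
}

#' @export
summary.rpq_clust <- function(object, ...) {
  cat("Symptom-cluster fit\n")
  cat("  participants:      ", object$n, "\n")
  cat("  linkage:           ", object$linkage, "\n")
  cat("  clusters:          ", length(object$clusters), "\n")
  cat("  formation level:   ", object$formation_level, "\n")
  cat("  merge height range: [", sprintf("%.3f", min(object$tree$height)),
      ", ", sprintf("%.3f", max(object$tree$height)), "]\n", sep = "")
  r <- object$corr[upper.tri(object$corr)]
  cat("  off-diagonal Spearman rho: median ", sprintf("%.3f", stats::median(r)),
      ", range [", sprintf("%.3f", min(r)), ", ", sprintf("%.3f", max(r)), "]\n",
      sep = "")
  invisible(object)
}

#' @export
plot.rpq_clust <- function(x, ...) {
  plot(x$tree, hang = -1, xlab = "", sub = "",
       main = "RPQ-16 symptom dendrogram", ...)
  stats::rect.hclust(x$tree, k = length(x$clusters))
  invisible(x)
}

#' @export
labels.rpq_clust <- function(object, ...) object$tree$labels

#' Parse a Newick dendrogram back into heights and groupings
#'
#' Reads a Newick string or file (via \pkg{ape}) and returns the leaf
#' labels and, for each internal node, its height above the leaves and
#' leaf set — the information [to_newick()] serialises, enabling
#' round-trip identity checks.
#'
#' @param text Newick string, or `NULL` when `file` is given.
#' @param file Optional path to a Newick file.
#' @return List with `labels` and a data-frame-free list `nodes`, each
#'   element holding `height` and the sorted leaf labels under that node.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  phy <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  depths <- ape::node.depth.edgelength(phy)
  total <- max(depths)
  ntip <- length(phy$tip.label)
  nodes <- lapply((ntip + 1):(ntip + phy$Nnode), function(nd) {
    tips <- ape::extract.clade(phy, nd)$tip.label
    list(height = total - depths[nd], leaves = sort(tips))
  })
  ord <- order(vapply(nodes, `[[`, numeric(1), "height"))
  list(labels = phy$tip.label, nodes = nodes[ord])
}
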