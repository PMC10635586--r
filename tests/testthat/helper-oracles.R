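# Independent oracles used across the suite. Each re-derives a quantity by
# a route different from the package implementation.

# Naive agglomeration: at every step re-scan ALL cross-pair leaf distances
# of the ORIGINAL matrix (O(n^3) overall), same lowest-index tie-break.
naive_linkage <- function(dm, method = "average") {
  n <- nrow(dm)
  groups <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    k <- length(groups)
    best <- Inf; bi <- bj <- 0L
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      cross <- dm[groups[[i]], groups[[j]], drop = FALSE]
      d <- switch(method, average = mean(cross), single = min(cross),
                  complete = max(cross))
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    heights[s] <- best
    groups[[bi]] <- sort(c(groups[[bi]], groups[[bj]]))
    groups[[bj]] <- NULL
    partitions[[s]] <- lapply(groups, identity)
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition (list of index vectors) for set comparison
canon_partition <- function(p) {
  p <- lapply(unname(p), function(g) sort(as.integer(unname(g))))
  p[order(vapply(p, min, integer(1)))]
}

# partition of upgma() output after each merge, via the package's tree
tree_partitions <- function(tree) {
  n <- nrow(tree$merge) + 1
  lapply(seq_len(n - 1), function(k) {
    rec <- function(e) if (e < 0) -e else
      c(rec(tree$merge[e, 1]), rec(tree$merge[e, 2]))
    member <- lapply(seq_len(k), function(s) sort(rec(s)))
    absorbed <- tree$merge[seq_len(k), , drop = FALSE]
    active <- setdiff(seq_len(k), absorbed[absorbed > 0])
    used <- -tree$merge[seq_len(k), ][tree$merge[seq_len(k), ] < 0]
    canon_partition(c(member[active], as.list(setdiff(seq_len(n), used))))
  })
}

# two-sided Fisher p by direct hypergeometric summation (float-tie
# tolerance 1e-7 relative, the standard convention)
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  x <- max(0, k - n_):min(k, m)
  pr <- dhyper(x, m, n_, k)
  pobs <- dhyper(a, m, n_, k)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# adjusted Rand index from the contingency table, closed form
ari_closed_form <- function(la, lb) {
  tab <- table(la, lb)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(sum(tab), 2)
  (sij - e) / ((sa + sb) / 2 - e)
}

# exact two-sided Mann-Whitney p by brute-force enumeration of all
# assignments of the pooled values to the first group (combn route)
mw_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y); N <- nx + ny
  r <- rank(pooled)
  mu <- nx * ny / 2
  uobs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sel <- utils::combn(N, nx)
  us <- apply(sel, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  mean(abs(us - mu) >= abs(uobs - mu) - 1e-9)
}

# small deterministic corrected-score matrix fixture
toy_corrected <- function(n = 40, seed = 99) {
  set.seed(seed)
  m <- matrix(sample(c(0L, 2L, 3L, 4L), n * 16, replace = TRUE), n, 16)
  colnames(m) <- rpq_items()$item
  m
}

# tiny cohort with fully observed impairment answers
toy_cohort <- function(n = 120, seed = 7, ...) {
  generate_cohort(synth_config(n_participants = n, p_impairment_data = 1, ...),
                  seed = seed)
}
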