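test_that("Spearman matrix equals Pearson on midranks and handles exact monotone pairs", {
  x <- c(0, 2, 3, 4); y <- c(4, 3, 2, 0)
  m <- cbind(a = x, b = y, c = x)
  rho <- spearman_matrix(rbind(m, m))  # duplicate rows to pass n >= 3
  expect_equal(unname(rho["a", "a"]), 1)
  expect_equal(unname(rho["a", "b"]), -1)
  expect_equal(unname(rho["a", "c"]), 1)

  x2 <- c(2, 0, 4, 2); y2 <- c(0, 2, 3, 3)
  rho2 <- spearman_matrix(cbind(x = c(x2, x2), y = c(y2, y2)))
  expect_equal(unname(rho2["x", "y"]),
               unname(cor(rank(c(x2, x2)), rank(c(y2, y2)))))
  expect_true(isSymmetric(unname(rho2)))
})

test_that("constant columns give a warning and zeroed correlations", {
  m <- cbind(a = c(0, 2, 3, 4), b = rep(2, 4), c = c(4, 3, 0, 2))
  expect_warning(rho <- spearman_matrix(m), "constant")
  expect_equal(unname(rho["a", "b"]), 0)
  expect_equal(unname(diag(rho)), rep(1, 3))
})

test_that("profile distances are Euclidean over full correlation rows", {
  corr <- diag(3)
  d <- as.matrix(profile_distances(corr))
  expect_equal(d[1, 2], sqrt(2))  # rows (1,0,0) vs (0,1,0)
  same <- matrix(0.5, 3, 3); diag(same) <- 1
  expect_equal(as.matrix(profile_distances(same))[1, 2],
               sqrt(2) * 0.5)  # rows differ only in entries 1 and 2
  # metric laws on random valid matrices
  set.seed(2)
  for (i in 1:10) {
    r <- cov2cor(crossprod(matrix(rnorm(49), 7)))
    dm <- as.matrix(profile_distances(r))
    expect_equal(dm, t(dm))
    for (a in 1:5) expect_lte(dm[1, 2], dm[1, a] + dm[a, 2] + 1e-12)
  }
})

test_that("average linkage reproduces hand-computed merges", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 3)
  expect_identical(t2$merge, matrix(c(-1L, -2L), 1))

  dm <- matrix(10, 4, 4, dimnames = rep(list(LETTERS[1:4]), 2))
  dm["A", "B"] <- dm["B", "A"] <- 1
  dm["C", "D"] <- dm["D", "C"] <- 2
  diag(dm) <- 0
  tr <- upgma(dm)
  expect_equal(tr$height, c(1, 2, 10))  # cross-average stays 10
  parts <- tree_partitions(tr)
  expect_identical(parts[[2]], canon_partition(list(c(1, 2), c(3, 4))))
})

test_that("merge heights and partitions match a naive re-scan oracle on random instances", {
  set.seed(42)
  for (i in 1:50) {
    n <- 8
    dm <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    dimnames(dm) <- list(as.character(1:n), as.character(1:n))
    tr <- upgma(dm)
    or <- naive_linkage(dm)
    expect_equal(tr$height, or$heights, tolerance = 1e-10)
    tp <- tree_partitions(tr)
    for (s in seq_len(n - 1))
      expect_identical(tp[[s]], canon_partition(or$partitions[[s]]))
    expect_true(all(diff(tr$height) >= -1e-12))
  }
})

test_that("average linkage agrees with the standard hclust implementation", {
  set.seed(7)
  for (i in 1:10) {
    d <- dist(matrix(rnorm(60), 12))
    mine <- upgma(d)
    ref <- hclust(d, method = "average")
    expect_equal(mine$height, ref$height, tolerance = 1e-10)
    expect_identical(tree_partitions(mine), tree_partitions(ref))
  }
})

test_that("single and complete linkage follow their group-distance definitions", {
  set.seed(9)
  dm <- as.matrix(dist(matrix(rnorm(21), 7)))
  for (mtd in c("single", "complete")) {
    tr <- upgma(dm, method = mtd)
    or <- naive_linkage(dm, method = mtd)
    expect_equal(tr$height, or$heights, tolerance = 1e-10)
  }
})

test_that("cluster formation takes the earliest singleton-free partition", {
  # merges (A,B), (C,D), then all: no singleton after merge 2
  dm <- matrix(10, 4, 4, dimnames = rep(list(LETTERS[1:4]), 2))
  dm["A", "B"] <- dm["B", "A"] <- 1
  dm["C", "D"] <- dm["D", "C"] <- 2
  diag(dm) <- 0
  cl <- form_clusters(upgma(dm))
  expect_equal(attr(cl, "formation_level"), 2)
  expect_identical(canon_partition(cl), canon_partition(list(1:2, 3:4)))

  # chain (A,B), (AB,C), (ABC,D): singleton D persists until the last merge
  ch <- matrix(0, 4, 4, dimnames = rep(list(LETTERS[1:4]), 2))
  ch["A", "B"] <- 1; ch["A", "C"] <- 3; ch["B", "C"] <- 3
  ch["A", "D"] <- 9; ch["B", "D"] <- 9; ch["C", "D"] <- 9
  ch <- ch + t(ch)
  cl2 <- form_clusters(upgma(ch))
  expect_equal(attr(cl2, "formation_level"), 3)
  expect_length(cl2, 1)
  expect_identical(sort(cl2[[1]]), 1:4)

  # any 2-leaf tree forms a single cluster
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = rep(list(c("A", "B")), 2))
  expect_length(form_clusters(upgma(d2)), 1)
})

test_that("formed clusters always cover all items in groups of at least two", {
  set.seed(31)
  for (i in 1:20) {
    dm <- as.matrix(dist(matrix(rnorm(16 * 4), 16)))
    cl <- form_clusters(upgma(dm))
    expect_identical(sort(unname(unlist(cl))), 1:16)
    expect_true(all(lengths(cl) >= 2))
  }
})

test_that("Newick export round-trips heights and groupings through ape", {
  d2 <- matrix(c(0, 1.5, 1.5, 0), 2, dimnames = rep(list(c("A", "B")), 2))
  expect_identical(to_newick(upgma(d2)), "(A:1.5,B:1.5);")

  set.seed(12)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    dm <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    dimnames(dm) <- list(paste0("L", 1:n), paste0("L", 1:n))
    tr <- upgma(dm)
    rt <- read_newick(text = to_newick(tr))
    expect_setequal(rt$labels, tr$labels)
    # every internal node's height and leaf set must match a merge
    rec <- function(e) if (e < 0) tr$labels[-e] else
      c(rec(tr$merge[e, 1]), rec(tr$merge[e, 2]))
    orig <- lapply(order(tr$height), function(s)
      list(height = tr$height[s], leaves = sort(rec(s))))
    for (s in seq_along(orig)) {
      expect_equal(rt$nodes[[s]]$height, orig[[s]]$height, tolerance = 1e-9)
      expect_identical(rt$nodes[[s]]$leaves, orig[[s]]$leaves)
    }
  }
})

test_that("full RPQ trees export 16 leaves", {
  fit <- rpq_cluster(toy_cohort(n = 200, seed = 2))
  nw <- to_newick(fit$tree)
  expect_length(read_newick(text = nw)$labels, 16)
})

test_that("adjusted Rand agreement matches the closed form and its fixed points", {
  a <- rpq_default_clusters()
  expect_equal(partition_agreement(a, a), 1)
  singletons <- setNames(as.list(1:16), paste0("s", 1:16))
  block <- list(all = 1:16)
  expect_equal(partition_agreement(singletons, block), 0)
  b <- rpq_partition(list(x = 1:8, y = 9:16))
  expect_equal(partition_agreement(a, b), partition_agreement(b, a))
  la <- rep(seq_along(a), lengths(a))[order(unlist(a))]
  lb <- rep(1:2, c(8, 8))
  expect_equal(partition_agreement(a, b), ari_closed_form(la, lb))
  expect_error(partition_agreement(a, list(1:15)), "different item sets")
})

test_that("the model fit recovers planted structure and reports it coherently", {
  cfg <- synth_config(n_participants = 600, prolonged_fraction = 1)
  fit <- rpq_cluster(generate_cohort(cfg, seed = 17))
  expect_s3_class(fit, "rpq_clust")
  expect_length(fit$clusters, 5)
  expect_equal(partition_agreement(fit$clusters, planted_partition(cfg)), 1)
  expect_equal(fit$formation_level, 11)
  expect_named(fit$clusters, names(rpq_default_clusters()), ignore.order = TRUE)
  expect_output(print(fit), "5 clusters")
  expect_output(summary(fit), "formation level")
})

test_that("small cohorts trigger the preliminary warning", {
  cfg <- synth_config(n_participants = 22, prolonged_fraction = 1)
  expect_warning(rpq_cluster(generate_cohort(cfg, seed = 1)),
                 "preliminary, small n")
})
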