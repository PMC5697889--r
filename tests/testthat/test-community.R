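test_that("filter_taxa applies the 0.05% floor and logs removals", {
  df <- data.frame(lineage = c("k__B;p__X", "k__B;p__Y", "k__B;p__Z"),
                   s1 = c(0.0004, 0.0006, 0.3),
                   s2 = c(0.0004, 0.0001, 0.2))
  tp <- taxon_profile(df)
  out <- filter_taxa(tp)
  expect_setequal(out$lineage, c("k__B;p__Y", "k__B;p__Z"))  # Y: one sample over
  expect_equal(attr(out, "n_removed"), 1)
  expect_equal(unname(attr(out, "removed_mass")), c(0.0004, 0.0004))
  empty <- filter_taxa(taxon_profile(df[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("bray_curtis matches the hand formula and vegan on random profiles", {
  expect_equal(bray_curtis(c(0.6, 0.4), c(0.2, 0.8)), 0.4)
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_warning(z <- bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 0)
  expect_error(bray_curtis(c(-1, 2), c(1, 2)), "non-negative")

  skip_if_not_installed("vegan")
  set.seed(42)
  for (k in 1:25) {
    x <- runif(12); y <- runif(12)
    expect_equal(bray_curtis(x, y),
                 as.numeric(vegan::vegdist(rbind(x, y), method = "bray")),
                 tolerance = 1e-12)
  }
})

test_that("UPGMA matches the hand agglomeration and stats::hclust", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- hierarchical_cluster(d)
  expect_equal(hc$height, c(0.1, 0.9))
  expect_equal(hc$merge[1, ], c(-2, -1))  # a and b join first
  # duplicate samples join at height 0
  d0 <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(hierarchical_cluster(d0)$height, 0)
  expect_error(hierarchical_cluster(d[1, 1, drop = FALSE]), "at least 2")

  # oracle: stats::hclust average linkage heights on tie-free random matrices
  set.seed(7)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    ours <- hierarchical_cluster(m)
    ref <- stats::hclust(as.dist(m), method = "average")
    expect_equal(ours$height, ref$height, tolerance = 1e-12)
    co_ours <- as.matrix(stats::cophenetic(ours))
    co_ref <- as.matrix(stats::cophenetic(ref))
    expect_equal(co_ours[letters[1:n], letters[1:n]],
                 co_ref[letters[1:n], letters[1:n]], tolerance = 1e-12)
  }
})

test_that("clustering is invariant to sample input order", {
  set.seed(3)
  n <- 6
  m <- matrix(runif(n * n), n)
  m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(letters[1:n], letters[1:n])
  hc1 <- hierarchical_cluster(m)
  perm <- sample(n)
  hc2 <- hierarchical_cluster(m[perm, perm])
  expect_identical(hc1$merge, hc2$merge)
  expect_identical(hc1$height, hc2$height)
  expect_identical(hc1$labels, hc2$labels)
})

test_that("host-separated profiles put the host split at the dendrogram top", {
  sim_profile <- function(seed) {
    set.seed(seed)
    base_a <- c(0.5, 0.3, 0.1, 0.05, 0.05)
    base_b <- c(0.05, 0.05, 0.1, 0.3, 0.5)
    cols <- cbind(sapply(1:3, function(i) base_a * runif(5, 0.9, 1.1)),
                  sapply(1:4, function(i) base_b * runif(5, 0.9, 1.1)))
    cols <- sweep(cols, 2, colSums(cols), "/")
    colnames(cols) <- c(paste0("A", 1:3), paste0("B", 1:4))
    data.frame(lineage = sprintf("k__B;p__P%d", 1:5), cols,
               check.names = FALSE)
  }
  tp <- taxon_profile(sim_profile(1))
  d <- bray_curtis_matrix(tp)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  hc <- hierarchical_cluster(d)
  top <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(top[paste0("A", 1:3)])), 1)
  expect_equal(length(unique(top[paste0("B", 1:4)])), 1)
})

test_that("family aggregation collapses lineages and labels unclassified", {
  df <- data.frame(
    lineage = c("k__B;p__X;c__C;o__O;f__F1;g__G1",
                "k__B;p__X;c__C;o__O;f__F1;g__G2",
                "k__B;p__X;c__C;o__O;f__;g__",
                "k__B;p__X;c__C;o__O"),
    s1 = c(0.1, 0.2, 0.05, 0.02))
  tp <- taxon_profile(df)
  agg <- aggregate_taxa(tp, "family")
  expect_setequal(agg$lineage, c("k__B;p__X;c__C;o__O;f__F1",
                                 "k__B;p__X;c__C;o__O;f__unc"))
  expect_equal(agg$s1[agg$lineage == "k__B;p__X;c__C;o__O;f__F1"], 0.3)
  expect_equal(agg$s1[agg$lineage == "k__B;p__X;c__C;o__O;f__unc"], 0.07)
})

test_that("discriminating lineages rank constructed signals first", {
  m <- data.frame(
    lineage = c("f__S24-7", "f__Other1", "f__Other2"),
    a1 = c(0.12, 0.2, 0.1), a2 = c(0.12, 0.21, 0.1), a3 = c(0.12, 0.2, 0.11),
    b1 = c(0, 0.2, 0.1), b2 = c(0, 0.21, 0.1), b3 = c(0, 0.2, 0.11),
    b4 = c(0, 0.2, 0.1), b5 = c(0, 0.21, 0.1))
  tp <- taxon_profile(m)
  ga <- sample_group("koala", paste0("a", 1:3))
  gb <- sample_group("wombat", paste0("b", 1:5))
  res <- discriminating_lineages(tp, ga, gb)
  expect_equal(res$feature[1], "f__S24-7")
  expect_equal(res$effect[1], 0.12)
  expect_true(res$flagged[1])

  # identical groups: nothing flagged
  m2 <- m; m2[paste0("b", 1:3)] <- m2[paste0("a", 1:3)]
  res2 <- discriminating_lineages(
    taxon_profile(m2[, 1:7]),
    sample_group("x", paste0("a", 1:3)),
    sample_group("y", paste0("b", 1:3)))
  expect_false(any(res2$flagged))
})

test_that("simulated differential lineage is recovered with its effect size", {
  # one family at ~0.12 in host A vs ~0.02 in host B (effect 0.10), CV 0.2
  recover <- function(seed) {
    set.seed(seed)
    n_taxa <- 20
    base <- rep(1 / n_taxa, n_taxa)
    prof <- function(p_target, n) sapply(seq_len(n), function(i) {
      x <- base * exp(rnorm(n_taxa, 0, 0.2))
      x[1] <- p_target * exp(rnorm(1, 0, 0.2))
      x / sum(x) * min(1, sum(x))  # keep fractions legal
    })
    cols <- cbind(prof(0.12, 3), prof(0.02, 5))
    cols <- sweep(cols, 2, colSums(cols), "/")
    colnames(cols) <- c(paste0("a", 1:3), paste0("b", 1:5))
    tp <- taxon_profile(data.frame(lineage = sprintf("f__T%02d", 1:n_taxa),
                                   cols, check.names = FALSE))
    res <- discriminating_lineages(tp, sample_group("A", paste0("a", 1:3)),
                                   sample_group("B", paste0("b", 1:5)))
    res[res$feature == "f__T01", ]
  }
  hit <- recover(3)
  expect_true(hit$flagged)
  expect_lt(abs(hit$effect - 0.10), 0.03)
})

test_that("newick export writes a readable tree with all sample labels", {
  d <- bray_curtis_matrix(taxon_profile(data.frame(
    lineage = c("p__A", "p__B"), s1 = c(0.8, 0.2), s2 = c(0.3, 0.7),
    s3 = c(0.5, 0.5))))
  hc <- hierarchical_cluster(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, c("s1", "s2", "s3"))
})
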