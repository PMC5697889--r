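make_bins <- function(comp, cont) {
  n <- length(comp)
  genome_bins(
    stats::setNames(sprintf("b%d", seq_len(n)), sprintf("ctg%d", seq_len(n))),
    data.frame(bin_id = sprintf("b%d", seq_len(n)), completeness = comp,
               contamination = cont, taxonomy = "t",
               stringsAsFactors = FALSE),
    lengths = stats::setNames(rep(1000, n), sprintf("ctg%d", seq_len(n))))
}

test_that("bin quality thresholds are inclusive at 50% and 10%", {
  bins <- make_bins(c(50.0, 49.9, 95.0, 80), c(10.0, 0.0, 10.1, 3))
  out <- filter_bins(bins)
  expect_setequal(out$bins$bin_id, c("b1", "b4"))
  rej <- attr(out, "rejected")
  expect_equal(rej$reason[rej$bin_id == "b2"], "completeness")
  expect_equal(rej$reason[rej$bin_id == "b3"], "contamination")
})

test_that("genome abundance is the length-weighted depth fraction", {
  # equal-length contigs, depths 10 (binned) and 30 (unbinned) -> 0.25
  cov <- coverage_table(matrix(c(10, 30), 2, 1,
                               dimnames = list(c("c1", "c2"), "s1")),
                        c(c1 = 1000, c2 = 1000))
  bins <- genome_bins(c(c1 = "b1"),
                      data.frame(bin_id = "b1", completeness = 90,
                                 contamination = 0, taxonomy = "t"),
                      lengths = c(c1 = 1000, c2 = 1000))
  expect_equal(genome_abundance(bins, "b1", cov, "s1"), 0.25)

  # a bin containing every contig has abundance 1
  bins_all <- genome_bins(c(c1 = "b1", c2 = "b1"),
                          data.frame(bin_id = "b1", completeness = 90,
                                     contamination = 0, taxonomy = "t"),
                          lengths = c(c1 = 1000, c2 = 1000))
  expect_equal(genome_abundance(bins_all, "b1", cov, "s1"), 1.0)

  cov0 <- coverage_table(matrix(0, 2, 1,
                                dimnames = list(c("c1", "c2"), "s1")),
                         c(c1 = 1000, c2 = 1000))
  expect_error(genome_abundance(bins, "b1", cov0, "s1"), "zero")

  # brute-force oracle on random micro-communities
  for (seed in 71:90) {
    mc <- random_micro_community(seed)
    for (s in coverage_samples(mc$cov)) {
      tot <- sum(as.numeric(mc$cov$lengths) * mc$cov$depth[, s])
      if (tot == 0) next
      for (b in mc$bins$bins$bin_id) {
        expect_equal(genome_abundance(mc$bins, b, mc$cov, s),
                     brute_genome_abundance(mc$bins, b, mc$cov, s),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("bin abundances plus the unbinned fraction sum to 1 per sample", {
  sim <- simulate_community(sim_config(seed = 17, n_genomes = 5))
  m <- genome_abundance_matrix(sim$bins, sim$cov)
  expect_equal(unname(colSums(m) + attr(m, "unbinned")),
               rep(1, ncol(m)), tolerance = 1e-12)
})

test_that("zero-noise abundances equal truth and recover the truth ranking", {
  cfg <- sim_config(seed = 29, n_genomes = 6, coverage_noise_cv = 0,
                    completeness_range = c(100, 100),
                    contamination_range = c(0, 0))
  sim <- simulate_community(cfg)
  m <- genome_abundance_matrix(sim$bins, sim$cov)
  want <- sim$truth$read_fraction[sub("^bin_", "", rownames(m)), ]
  expect_equal(as.numeric(m), as.numeric(as.matrix(want)),
               tolerance = 1e-12)
  expect_equal(unname(attr(m, "unbinned")), rep(0, ncol(m)),
               tolerance = 1e-12)
  top <- top_n_genomes(m, n = 6)
  truth_rank <- names(sort(apply(want, 1, stats::median), decreasing = TRUE))
  expect_equal(sub("^bin_", "", top$bin_id[1:3]), truth_rank[1:3])
})

test_that("top-N ordering breaks median ties by mean then bin id", {
  m <- rbind(b_high = c(0.05, 0.05, 0.05),
             b_zero_mean_big = c(0, 0, 0.03),
             b_zero_mean_small = c(0, 0, 0.006),
             b_low = c(0.01, 0.01, 0.01))
  colnames(m) <- paste0("s", 1:3)
  top <- top_n_genomes(m, n = 2)
  expect_equal(top$bin_id, c("b_high", "b_low"))
  all4 <- suppressWarnings(top_n_genomes(m, n = 10))
  expect_equal(all4$bin_id[3:4], c("b_zero_mean_big", "b_zero_mean_small"))
  expect_warning(top_n_genomes(m, n = 10), "available")
  expect_equal(nrow(top_n_genomes(m, n = 0)), 0)
})

test_that("pathway coverage uses the cross-dataset KO universe", {
  cat1 <- function_catalog(list(K1 = "pwyX", K2 = "pwyX", K3 = "pwyX",
                                K4 = "pwyX", K9 = "pwyY"))
  ko_sets <- list(binA = c("K1", "K3"), binB = c("K1", "K2", "K3", "K4"),
                  binC = character(0))
  pc <- pathway_coverage(ko_sets, cat1)
  expect_equal(pc["binB", "pwyX"], 1.0)
  expect_equal(pc["binA", "pwyX"], 0.5)
  expect_equal(pc["binC", "pwyX"], 0.0)
  expect_false("pwyY" %in% colnames(pc))  # empty universe omitted

  # monotonicity: adding a KO never decreases any coverage
  ko_sets2 <- ko_sets
  ko_sets2$binA <- c(ko_sets2$binA, "K2")
  pc2 <- pathway_coverage(ko_sets2, cat1)
  expect_true(all(pc2["binA", ] >= pc["binA", ]))
})

test_that("pathway PCA centers columns, orders variance, fixes signs", {
  # two clusters separated on the first pathway axis (4 x 2 toy)
  x <- rbind(g1 = c(1, 0.5), g2 = c(1, 0.5), g3 = c(0, 0.5), g4 = c(0, 0.5))
  p <- genome_pathway_pca(x)
  expect_equal(p$variance_fraction[1], 1)  # all variance on one axis
  expect_equal(sum(p$variance_fraction), 1)
  expect_equal(abs(p$scores[, 1]), c(g1 = 0.5, g2 = 0.5, g3 = 0.5, g4 = 0.5))
  expect_gt(p$scores["g1", 1], 0)  # sign convention: top loading positive
  expect_true(all(p$scores[c("g3", "g4"), 1] < 0))

  same <- matrix(0.25, 3, 4, dimnames = list(paste0("g", 1:3), NULL))
  p0 <- genome_pathway_pca(same)
  expect_true(all(p0$variance_fraction == 0))
  expect_true(all(p0$scores == 0))
})

test_that("contributor score divides qualifying KO count by completeness", {
  kos <- sprintf("K%05d", 1:40)
  cat1 <- function_catalog(stats::setNames(as.list(rep("pwyD", 40)), kos))
  expect_equal(contributor_score(kos, "pwyD", cat1, completeness = 80), 50)
  expect_equal(contributor_score(kos, "pwyD", cat1, completeness = 100), 40)
  expect_equal(contributor_score(character(0), "pwyD", cat1, 80), 0)
  expect_equal(contributor_score(c("K99999"), "pwyD", cat1, 80), 0)
  expect_error(contributor_score(kos, "pwyD", cat1, 0), "completeness")
})

test_that("urea screen distinguishes transport, ureolysis, and full suite", {
  cfg <- urea_ko_config()
  full <- c(cfg$urt_subunits, cfg$urease_structural, cfg$urease_accessory)
  expect_equal(urea_screen(full)$status, "full_suite")
  expect_equal(urea_screen(cfg$urease_structural)$status, "ureolysis_only")
  expect_equal(urea_screen(c(cfg$utp))$status, "transport_only")
  expect_equal(urea_screen(cfg$urt_subunits[1:4])$status, "none")
  expect_equal(urea_screen(c(cfg$utp, cfg$urease_structural))$status,
               "full_suite")
  scr <- urea_screen(c(cfg$urease_structural, cfg$urease_accessory[1:2]))
  expect_equal(scr$accessory_fraction, 0.5)
  expect_error(urea_screen("K1", list(urt_subunits = "a")), "must define")
})

test_that("genome size summary corrects by completeness and weights by abundance", {
  bins <- genome_bins(
    c(c1 = "b1", c2 = "b2"),
    data.frame(bin_id = c("b1", "b2"), completeness = c(50, 100),
               contamination = 0, taxonomy = "t"),
    lengths = c(c1 = 2e6, c2 = 4e6))
  expect_equal(community_genome_size_summary(
    genome_bins(c(c1 = "b1"),
                data.frame(bin_id = "b1", completeness = 50,
                           contamination = 0, taxonomy = "t"),
                lengths = c(c1 = 2e6)),
    c(b1 = 0.2)), 4e6)
  bins_eq <- genome_bins(
    c(c1 = "b1", c2 = "b2"),
    data.frame(bin_id = c("b1", "b2"), completeness = 100,
               contamination = 0, taxonomy = "t"),
    lengths = c(c1 = 2e6, c2 = 4e6))
  expect_equal(community_genome_size_summary(bins_eq, c(b1 = 0.3, b2 = 0.3)),
               3e6)
  expect_error(community_genome_size_summary(bins_eq, c(b1 = 0.3)), "missing")
})
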