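test_that("weighted profile matches the hand enumeration", {
  toy <- toy_community()  # denominators: 10+10+30+30 = 80
  prof <- weighted_feature_profile(toy$cds, toy$cov, "s1", "cazy")
  expect_equal(prof[["GH5"]], 40 / 80)
  expect_equal(prof[["GH10"]], 10 / 80)
  expect_equal(attr(prof, "normalization_scope"), "all_cds")

  # single CDS, single contig: self-normalizes to 1 for any depth
  for (d in c(0.2, 5, 1234)) {
    one <- toy_community(depth1 = d)
    cds1 <- validate_cds_table(as.data.frame(one$cds[1, ]))
    p <- weighted_feature_profile(cds1, one$cov, "s1", "cazy")
    expect_equal(unname(p["GH5"]), 1)
  }

  # scale invariance
  scaled <- toy_community(depth1 = 70, depth2 = 210)
  p2 <- weighted_feature_profile(scaled$cds, scaled$cov, "s1", "cazy")
  expect_equal(as.numeric(p2[names(prof)]), as.numeric(prof))

  expect_error(weighted_feature_profile(toy$cds[0, ], toy$cov, "s1", "cazy"),
               "empty")
  expect_error(weighted_feature_profile(toy$cds, toy$cov, "nope", "cazy"),
               "sample")
})

test_that("repeated domains of one family count once; distinct families each", {
  cds <- validate_cds_table(data.frame(
    cds_id = c("a", "b"), contig_id = "ctg1", start = c(1, 101),
    end = c(90, 190), strand = "+", ko = "",
    cazy_domains = c("GH5;GH5;GH10", ""), stringsAsFactors = FALSE))
  cov <- coverage_table(matrix(8, 1, 1, dimnames = list("ctg1", "s1")),
                        c(ctg1 = 500))
  p <- weighted_feature_profile(cds, cov, "s1", "cazy")
  expect_equal(p[["GH5"]], 0.5)   # counted once despite two GH5 domains
  expect_equal(p[["GH10"]], 0.5)
})

test_that("micro-communities equal brute-force enumeration to 1e-12", {
  for (seed in 1:40) {
    mc <- random_micro_community(seed)
    for (s in coverage_samples(mc$cov)) {
      for (feat in c("cazy", "ko")) {
        got <- weighted_feature_profile(mc$cds, mc$cov, s, feat)
        want <- brute_feature_profile(mc$cds, mc$cov, s, feat)
        got <- got[order(names(got))]
        expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
        expect_equal(names(got), names(want))
      }
    }
  }
})

test_that("pathway profile sums member KO weights and applies the size filter", {
  toy <- toy_community()
  # catalog where pwy1 has 3 observed-able KOs but only 2 observed
  cat3 <- function_catalog(
    list(K00001 = c("pwy1", "pwy2"), K00002 = "pwy1", K00003 = "pwy1",
         K00004 = "pwy2", K00005 = "pwy2"),
    min_kos_per_pathway = 3L)
  # observed KOs: K00001 (ctg1 + ctg2), K00002 (ctg1): pwy1 has 2 observed -> excluded
  p <- pathway_cumulative_profile(toy$cds, toy$cov, cat3, "s1")
  expect_false("pwy1" %in% names(p))
  expect_false("pwy2" %in% names(p))  # only K00001 observed

  cat1 <- toy_catalog(min_kos = 1L)
  p1 <- pathway_cumulative_profile(toy$cds, toy$cov, cat1, "s1")
  # K00001 weight (10+30)/80, K00002 10/80; KO in both pathways counts fully in each
  expect_equal(p1[["pwy1"]], 50 / 80)
  expect_equal(p1[["pwy2"]], 40 / 80)
})

test_that("pathway profiles equal brute force on random micro-communities", {
  cat1 <- toy_catalog(min_kos = 2L)
  for (seed in 41:70) {
    mc <- random_micro_community(seed)
    for (s in coverage_samples(mc$cov)) {
      got <- pathway_cumulative_profile(mc$cds, mc$cov, cat1, s)
      want <- brute_pathway_profile(mc$cds, mc$cov, cat1, s)
      got <- got[order(names(got))]
      expect_equal(names(got), names(want))
      expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
    }
  }
})

test_that("GH relative profile renormalizes the four categories to 100", {
  # two equal-depth CDSs GH5 and GH2: 50/50 across cellulase/oligosaccharide
  cds <- validate_cds_table(data.frame(
    cds_id = c("a", "b"), contig_id = c("c1", "c2"), start = 1, end = 90,
    strand = "+", ko = "", cazy_domains = c("GH5", "GH2"),
    stringsAsFactors = FALSE))
  cov <- coverage_table(matrix(c(4, 4), 2, 1,
                               dimnames = list(c("c1", "c2"), "s1")),
                        c(c1 = 100, c2 = 100))
  gh <- gh_relative_profile(cds, cov, function_catalog())
  expect_equal(gh$family_percent[["GH5"]], 50)
  expect_equal(gh$family_percent[["GH2"]], 50)
  expect_equal(unname(gh$subtotals["cellulase"]), 50)
  expect_equal(unname(gh$subtotals["oligosaccharide_degrading"]), 50)
  expect_equal(sum(gh$subtotals), 100)

  # single GH5 community
  gh1 <- gh_relative_profile(validate_cds_table(as.data.frame(cds[1, ])),
                             cov, function_catalog())
  expect_equal(gh1$family_percent[["GH5"]], 100)
  expect_equal(unname(gh1$subtotals["cellulase"]), 100)
})

test_that("percent of CDSs counts unique lignocellulolytic CDSs", {
  n <- 400
  cds <- validate_cds_table(data.frame(
    cds_id = sprintf("c%03d", 1:n), contig_id = "ctg1",
    start = 1 + 100 * (0:(n - 1)), end = 90 + 100 * (0:(n - 1)),
    strand = "+", ko = "",
    cazy_domains = c("GH5;GH10", "GH2", "GH3", rep("", n - 3)),
    stringsAsFactors = FALSE))
  cov <- coverage_table(matrix(2, 1, 1, dimnames = list("ctg1", "s1")),
                        c(ctg1 = 50000))
  gh <- gh_relative_profile(cds, cov, function_catalog())
  expect_equal(gh$n_lignocellulolytic_cds, 3)
  expect_equal(gh$percent_of_cds, 0.75)
})

test_that("CAZy class comparison separates constructed AA enrichment", {
  sim <- simulate_community(sim_config(seed = 11, aa_effect = 3,
                                       aa_rate = 0.02))
  cc <- cazy_class_comparison(sim$cds, sim$cov, sim$catalog,
                              sim$groups[[1]], sim$groups[[2]])
  expect_equal(dim(cc$fractions)[1], 5)
  aa_row <- cc$tests[cc$tests$feature == "auxiliary_activity", ]
  expect_gt(aa_row$effect, 0)          # enriched in host A
  expect_lt(aa_row$p, 0.05)

  # identical groups: all between-group effects are zero
  ga <- sample_group("x", c("A_t1", "A_t2"))
  gb <- sample_group("y", c("A_t1", "A_t2"))
  cc0 <- cazy_class_comparison(sim$cds, sim$cov, sim$catalog, ga, gb)
  expect_true(all(cc0$tests$effect == 0))
})
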