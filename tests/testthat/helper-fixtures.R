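# In-code fixtures and independent brute-force oracles used across tests.

# the two-contig hand-enumeration community:
# ctg1 depth 10 carries CDSs annotated GH5 and GH10; ctg2 depth 30 carries
# one GH5 CDS and one unannotated CDS. Denominator 10+10+30+30 = 80.
toy_community <- function(depth1 = 10, depth2 = 30) {
  cds <- validate_cds_table(data.frame(
    cds_id = c("c1", "c2", "c3", "c4"),
    contig_id = c("ctg1", "ctg1", "ctg2", "ctg2"),
    start = c(1, 501, 1, 501), end = c(400, 900, 400, 900),
    strand = "+",
    ko = c("K00001", "K00002", "K00001", ""),
    cazy_domains = c("GH5", "GH10", "GH5", ""),
    stringsAsFactors = FALSE))
  cov <- coverage_table(
    depth = matrix(c(depth1, depth2), 2, 1,
                   dimnames = list(c("ctg1", "ctg2"), "s1")),
    lengths = c(ctg1 = 1000, ctg2 = 1000))
  list(cds = cds, cov = cov)
}

toy_catalog <- function(min_kos = 1L) {
  function_catalog(
    ko_to_pathways = list(
      K00001 = c("pwy1", "pwy2"), K00002 = "pwy1", K00003 = "pwy1",
      K00004 = "pwy2", K00005 = "pwy2"),
    min_kos_per_pathway = min_kos)
}

# random micro-community (<= 10 CDSs) for oracle-equivalence checks
random_micro_community <- function(seed) {
  set.seed(seed)
  n_contigs <- sample(1:4, 1)
  contigs <- sprintf("ctg%d", seq_len(n_contigs))
  samples <- sprintf("s%d", seq_len(sample(1:3, 1)))
  depth <- matrix(round(stats::runif(n_contigs * length(samples), 0.5, 50), 3),
                  n_contigs, length(samples),
                  dimnames = list(contigs, samples))
  lengths <- stats::setNames(sample(500:5000, n_contigs, replace = TRUE),
                             contigs)
  n_cds <- sample(1:10, 1)
  kos <- c("", "K00001", "K00002", "K00003", "K00004", "K00005")
  fams <- c("", "GH5", "GH10", "GH2", "AA2", "GH5;GH10", "GH13")
  cds <- validate_cds_table(data.frame(
    cds_id = sprintf("cds%02d", seq_len(n_cds)),
    contig_id = sample(contigs, n_cds, replace = TRUE),
    start = 1L + 100L * (seq_len(n_cds) - 1L),
    end = 60L + 100L * (seq_len(n_cds) - 1L),
    strand = sample(c("+", "-"), n_cds, replace = TRUE),
    ko = sample(kos, n_cds, replace = TRUE),
    cazy_domains = sample(fams, n_cds, replace = TRUE),
    stringsAsFactors = FALSE))
  n_bins <- min(n_contigs, sample(1:2, 1))
  membership <- stats::setNames(
    sprintf("bin%d", rep_len(seq_len(n_bins), n_contigs)), contigs)
  bins <- genome_bins(membership,
                      data.frame(bin_id = sprintf("bin%d", seq_len(n_bins)),
                                 completeness = 90, contamination = 1,
                                 taxonomy = "t", stringsAsFactors = FALSE),
                      lengths = lengths)
  list(cds = cds, cov = coverage_table(depth, lengths), bins = bins)
}

# brute-force oracles: plain loops, no shared code with the implementation
brute_feature_profile <- function(cds, cov, sample, feature_of) {
  denom <- 0
  acc <- list()
  for (r in seq_len(nrow(cds))) {
    d <- cov$depth[cds$contig_id[r], sample]
    denom <- denom + d
    feats <- if (feature_of == "ko") {
      if (nzchar(cds$ko[r])) cds$ko[r] else character(0)
    } else {
      unique(setdiff(strsplit(cds$cazy_domains[r], ";")[[1]], ""))
    }
    for (f in feats) acc[[f]] <- (if (is.null(acc[[f]])) 0 else acc[[f]]) + d
  }
  if (!length(acc)) return(stats::setNames(numeric(0), character(0)))
  out <- unlist(acc) / denom
  out[order(names(out))]
}

brute_pathway_profile <- function(cds, cov, catalog, sample) {
  kw <- brute_feature_profile(cds, cov, sample, "ko")
  members <- list()
  for (ko in names(catalog$ko_to_pathways))
    for (pw in catalog$ko_to_pathways[[ko]])
      members[[pw]] <- union(members[[pw]], ko)
  observed <- unique(cds$ko[nzchar(cds$ko)])
  out <- numeric(0)
  for (pw in names(members)) {
    obs <- intersect(members[[pw]], observed)
    if (length(obs) < catalog$min_kos_per_pathway) next
    out[pw] <- sum(kw[intersect(obs, names(kw))])
  }
  if (!length(out)) return(stats::setNames(numeric(0), character(0)))
  out[order(names(out))]
}

brute_genome_abundance <- function(bins, bin_id, cov, sample) {
  num <- 0; den <- 0
  for (ctg in rownames(cov$depth)) {
    lw <- cov$lengths[[ctg]] * cov$depth[ctg, sample]
    den <- den + lw
    if (!is.na(bins$membership[ctg]) && bins$membership[ctg] == bin_id)
      num <- num + lw
  }
  num / den
}

# brute-force RBH enumeration from full alignment matrices
brute_orthologs <- function(pa, pb, min_id = 0.30, min_cov = 0.70) {
  mats <- mgprofiler:::sw_all(pa, pb)
  best_dir <- function(score, ident, cover, qn, sn) {
    hits <- character(0)
    for (i in seq_along(qn)) {
      ok <- which(ident[i, ] / 100 >= min_id & cover[i, ] >= min_cov &
                    score[i, ] > 0)
      if (!length(ok)) next
      ord <- ok[order(-score[i, ok], -ident[i, ok], sn[ok])]
      hits[qn[i]] <- sn[ord[1]]
    }
    hits
  }
  fwd <- best_dir(mats$score, mats$identity, mats$coverage,
                  names(pa), names(pb))
  rev <- best_dir(t(mats$score), t(mats$identity), t(mats$coverage),
                  names(pb), names(pa))
  mutual <- names(fwd)[!is.na(rev[fwd]) & rev[fwd] == names(fwd)]
  data.frame(protein_a = mutual, protein_b = unname(fwd[mutual]),
             identity = mats$identity[cbind(mutual, fwd[mutual])],
             stringsAsFactors = FALSE)
}
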