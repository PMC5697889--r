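## Coverage-weighted functional profiling of an assembled metagenome.
## Every feature weight is the summed mean contig depth of the CDSs carrying
## the feature, normalised to the total contig depth over ALL CDSs
## (annotated or not), per sample. Weights are therefore scale-invariant in
## depth and comparable across time-points.

cds_depth <- function(cds, cov, sample) {
  if (!nrow(cds)) stop("empty CDS table")
  if (!sample %in% colnames(cov$depth))
    stop("sample not in coverage table: ", sample)
  check_contig_consistency(cov, cds = cds)
  cov$depth[cds$contig_id, sample]
}

#' Coverage-weighted feature profile
#'
#' Weight of a feature in a sample = sum of mean contig depths over CDSs
#' annotated with the feature, divided by the summed contig depth of all
#' CDSs. For CAZy features, a CDS with domains of k distinct families
#' contributes its contig depth once to each family; repeated domains of the
#' same family within one CDS count once (prevents domain-count inflation).
#'
#' @param cds A `cds_table`.
#' @param cov A `coverage_table`.
#' @param sample Sample id.
#' @param feature_of `"cazy"` or `"ko"`.
#' @return Named numeric vector of weights with attributes
#'   `normalization_scope = "all_cds"` and `total_depth`.
#' @export
weighted_feature_profile <- function(cds, cov, sample,
                                     feature_of = c("cazy", "ko")) {
  feature_of <- match.arg(feature_of)
  d <- cds_depth(cds, cov, sample)
  denom <- sum(d)
  if (feature_of == "ko") {
    keep <- nzchar(cds$ko)
    feat <- cds$ko[keep]
    w <- d[keep]
  } else {
    doms <- cds_cazy_list(cds)
    doms <- lapply(doms, unique)  # same family repeated in one CDS: once
    n <- lengths(doms)
    feat <- unlist(doms, use.names = FALSE)
    w <- rep(d, n)
  }
  if (!length(feat)) {
    prof <- stats::setNames(numeric(0), character(0))
  } else {
    prof <- vapply(split(w, feat), sum, numeric(1))
    prof <- if (denom > 0) prof / denom else prof * 0
  }
  structure(prof, normalization_scope = "all_cds", total_depth = denom)
}

#' Cumulative pathway profile of a sample
#'
#' Each KO weight (see [weighted_feature_profile()]) is assigned to all
#' pathways the KO belongs to; a pathway's weight is the sum over its
#' observed member KOs. Pathways with fewer than
#' `catalog$min_kos_per_pathway` distinct KOs observed anywhere in the CDS
#' table are excluded.
#'
#' @param cds A `cds_table`.
#' @param cov A `coverage_table`.
#' @param catalog A `function_catalog`.
#' @param sample Sample id.
#' @return Named numeric vector: pathway -> cumulative normalized abundance.
#' @export
pathway_cumulative_profile <- function(cds, cov, catalog, sample) {
  stopifnot(inherits(catalog, "function_catalog"))
  ko_w <- weighted_feature_profile(cds, cov, sample, "ko")
  members <- pathway_members(catalog)
  observed <- unique(cds$ko[nzchar(cds$ko)])
  keep <- vapply(members, function(kos)
    sum(kos %in% observed) >= catalog$min_kos_per_pathway, logical(1))
  members <- members[keep]
  vapply(members, function(kos)
    sum(ko_w[intersect(kos, names(ko_w))]), numeric(1))
}

#' Pathway profile matrix across samples
#'
#' @inheritParams pathway_cumulative_profile
#' @param samples Sample ids; default all samples in `cov`.
#' @return Numeric matrix, pathways x samples.
#' @export
pathway_profile_matrix <- function(cds, cov, catalog,
                                   samples = coverage_samples(cov)) {
  cols <- lapply(samples, function(s)
    pathway_cumulative_profile(cds, cov, catalog, s))
  pw <- sort(unique(unlist(lapply(cols, names))))
  m <- matrix(0, length(pw), length(samples),
              dimnames = list(pw, samples))
  for (i in seq_along(cols)) m[names(cols[[i]]), i] <- cols[[i]]
  m
}

#' Relative lignocellulolytic GH profile (reference-table layout)
#'
#' Restricts the CAZy profile to the four lignocellulose categories,
#' renormalises per-family weights within that scope so the four category
#' subtotals sum to 100% per sample, and averages across samples
#' (arithmetic mean of per-sample profiles). Also reports the number of
#' unique lignocellulolytic CDSs (a CDS with several GH domains counts
#' once) and their percentage of all CDSs.
#'
#' @param cds A `cds_table`.
#' @param cov A `coverage_table`.
#' @param catalog A `function_catalog`.
#' @param samples Sample ids to average over; default all.
#' @return List with `family_percent` (named numeric, percent), `category`
#'   (named character: family -> category), `subtotals` (named numeric, one
#'   per category), `n_lignocellulolytic_cds`, `percent_of_cds`.
#' @export
gh_relative_profile <- function(cds, cov, catalog,
                                samples = coverage_samples(cov)) {
  cat_map <- catalog$gh_category
  per_sample <- lapply(samples, function(s) {
    prof <- weighted_feature_profile(cds, cov, s, "cazy")
    ligno <- prof[names(prof) %in% names(cat_map)]
    if (!length(ligno) || sum(ligno) <= 0)
      stop("no lignocellulolytic GH coverage in sample ", s)
    100 * ligno / sum(ligno)
  })
  fams <- sort(unique(unlist(lapply(per_sample, names))))
  m <- matrix(0, length(fams), length(samples),
              dimnames = list(fams, samples))
  for (i in seq_along(per_sample))
    m[names(per_sample[[i]]), i] <- per_sample[[i]]
  fam_pct <- rowMeans(m)
  category <- cat_map[names(fam_pct)]
  subtotals <- vapply(gh_categories(), function(ct)
    category_subtotal(fam_pct, catalog, ct), numeric(1))

  doms <- lapply(cds_cazy_list(cds), function(x)
    any(x %in% names(cat_map)))
  n_ligno <- sum(unlist(doms))
  list(family_percent = fam_pct,
       category = category,
       subtotals = subtotals,
       n_lignocellulolytic_cds = n_ligno,
       percent_of_cds = 100 * n_ligno / nrow(cds))
}

#' Category subtotal of per-family percentages
#'
#' Sums per-family percentages over the families the catalog assigns to a
#' lignocellulose category. Families not in the map are excluded.
#'
#' @param family_percentages Named numeric vector family -> percent.
#' @param catalog A `function_catalog`.
#' @param category One of [gh_categories()].
#' @return The subtotal (percent). Empty input gives 0.
#' @export
category_subtotal <- function(family_percentages, catalog, category) {
  stopifnot(category %in% gh_categories())
  map <- catalog$gh_category
  fams <- names(map)[map == category]
  sum(family_percentages[names(family_percentages) %in% fams])
}

#' CAZy class comparison between two sample groups
#'
#' Per-sample weighted fractions (all-CDS scope) of five CAZyme classes:
#' cellulose-targeting GHs, hemicellulose-targeting GHs (endo- plus
#' accessory), oligosaccharide-degrading GHs, auxiliary-activity (AA)
#' enzymes, and other (non-lignocellulolytic) GHs — followed by a Welch test
#' per class between the two groups.
#'
#' @param cds A `cds_table`.
#' @param cov A `coverage_table`.
#' @param catalog A `function_catalog`.
#' @param group_a,group_b `sample_group`s with >= 2 samples each.
#' @return List with `fractions` (classes x samples matrix) and `tests`
#'   (data.frame from [differential_features()], taxon_p mode).
#' @export
cazy_class_comparison <- function(cds, cov, catalog, group_a, group_b) {
  stopifnot(length(group_a$sample_ids) >= 2, length(group_b$sample_ids) >= 2)
  samples <- c(group_a$sample_ids, group_b$sample_ids)
  classes <- c("cellulose_gh", "hemicellulose_gh", "oligosaccharide_gh",
               "auxiliary_activity", "other_gh")
  class_of <- function(fams) {
    ct <- classify_cazy_family(fams, catalog)
    out <- rep(NA_character_, length(ct))
    out[ct == "cellulase"] <- "cellulose_gh"
    out[ct %in% c("endohemicellulase", "accessory_hemicellulase")] <-
      "hemicellulose_gh"
    out[ct == "oligosaccharide_degrading"] <- "oligosaccharide_gh"
    out[ct == "auxiliary_activity"] <- "auxiliary_activity"
    out[ct == "other_gh"] <- "other_gh"
    out
  }
  m <- matrix(0, length(classes), length(samples),
              dimnames = list(classes, samples))
  for (s in samples) {
    prof <- weighted_feature_profile(cds, cov, s, "cazy")
    cls <- class_of(names(prof))
    for (k in classes) m[k, s] <- sum(prof[!is.na(cls) & cls == k])
  }
  tests <- differential_features(m, group_a, group_b, mode = "taxon_p")
  list(fractions = m, tests = tests)
}
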