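## Population-genome analytics: quality filtering, abundance estimation,
## top-N selection, per-genome pathway coverage, PCA of pathway profiles,
## the completeness-weighted differential-metabolism contributor score, the
## urea-processing screen, and an abundance-weighted genome-size summary.

#' Filter bins on completeness and contamination
#'
#' Inclusive thresholds: a bin passes iff completeness >= `completeness_min`
#' and contamination <= `contamination_max`. Rejected bins and the reason are
#' reported in the `rejected` attribute.
#'
#' @param bins A `genome_bins`.
#' @param completeness_min Percent, default 50.
#' @param contamination_max Percent, default 10.
#' @return A `genome_bins` restricted to passing bins.
#' @export
filter_bins <- function(bins, completeness_min = 50,
                        contamination_max = 10) {
  stopifnot(inherits(bins, "genome_bins"))
  meta <- bins$bins
  pass <- meta$completeness >= completeness_min &
    meta$contamination <= contamination_max
  reason <- ifelse(meta$completeness < completeness_min, "completeness",
                   ifelse(meta$contamination > contamination_max,
                          "contamination", ""))
  keep_ids <- meta$bin_id[pass]
  out <- structure(
    list(membership = bins$membership[bins$membership %in% keep_ids],
         bins = meta[pass, , drop = FALSE]),
    class = "genome_bins")
  attr(out, "rejected") <- data.frame(
    bin_id = meta$bin_id[!pass], reason = reason[!pass],
    stringsAsFactors = FALSE)
  out
}

#' Relative abundance of a genome bin in one sample
#'
#' Length-weighted depth fraction: the sum of `length * depth` over the
#' bin's contigs divided by the same sum over all contigs in the coverage
#' table — the bin's share of sequenced bases in that sample.
#'
#' @param bins A `genome_bins`.
#' @param bin_id Bin identifier.
#' @param cov A `coverage_table` containing every bin contig.
#' @param sample Sample id.
#' @return Relative abundance in \[0,1\].
#' @export
genome_abundance <- function(bins, bin_id, cov, sample) {
  check_contig_consistency(cov, bins = bins)
  if (!sample %in% colnames(cov$depth))
    stop("sample not in coverage table: ", sample)
  lw <- as.numeric(cov$lengths) * cov$depth[, sample]
  total <- sum(lw)
  if (total == 0) stop("total contig coverage is zero in sample ", sample)
  ctgs <- bin_contigs(bins, bin_id)
  sum(lw[rownames(cov$depth) %in% ctgs]) / total
}

#' Abundance matrix of all bins across samples
#'
#' @param bins A `genome_bins`.
#' @param cov A `coverage_table`.
#' @param samples Sample ids; default all.
#' @return Numeric matrix, bins x samples, plus an `"unbinned"` attribute
#'   with the per-sample unbinned fraction.
#' @export
genome_abundance_matrix <- function(bins, cov,
                                    samples = coverage_samples(cov)) {
  ids <- bins$bins$bin_id
  m <- matrix(0, length(ids), length(samples),
              dimnames = list(ids, samples))
  for (s in samples) {
    lw <- as.numeric(cov$lengths) * cov$depth[, s]
    total <- sum(lw)
    if (total == 0) stop("total contig coverage is zero in sample ", s)
    share <- lw / total
    in_bin <- rownames(cov$depth) %in% names(bins$membership)
    grp <- bins$membership[rownames(cov$depth)[in_bin]]
    agg <- rowsum(share[in_bin], grp)
    m[rownames(agg), s] <- agg
  }
  attr(m, "unbinned") <- 1 - colSums(m)
  m
}

#' Select the top-N bins by median abundance
#'
#' Sorts by median per-sample abundance (descending); ties break by mean
#' abundance (descending), then by bin id. Asking for more bins than exist
#' returns all of them with a warning.
#'
#' @param abundance Bins x samples matrix from [genome_abundance_matrix()].
#' @param n Number of bins to keep (default 15).
#' @return data.frame `bin_id`, `median_abundance`, `mean_abundance`,
#'   `rank`, restricted to the top n.
#' @export
top_n_genomes <- function(abundance, n = 15L) {
  stopifnot(is.matrix(abundance))
  if (is.null(rownames(abundance))) stop("abundance matrix must name bins")
  med <- vapply(seq_len(nrow(abundance)), function(i)
    stats::median(abundance[i, ]), numeric(1))
  mn <- rowMeans(abundance)
  ord <- order(-med, -mn, rownames(abundance))
  out <- data.frame(bin_id = rownames(abundance)[ord],
                    median_abundance = med[ord], mean_abundance = mn[ord],
                    rank = seq_along(ord), row.names = NULL,
                    stringsAsFactors = FALSE)
  if (n > nrow(out)) {
    warning("requested ", n, " bins but only ", nrow(out), " available")
    n <- nrow(out)
  }
  out[seq_len(n), , drop = FALSE]
}

#' KO sets per bin
#'
#' @param cds A `cds_table`.
#' @param bins A `genome_bins`.
#' @return Named list bin_id -> character vector of distinct KOs on the
#'   bin's contigs.
#' @export
bin_ko_sets <- function(cds, bins) {
  bin_of <- bins$membership[cds$contig_id]
  keep <- !is.na(bin_of) & nzchar(cds$ko)
  sets <- lapply(split(cds$ko[keep], bin_of[keep]), unique)
  out <- stats::setNames(vector("list", nrow(bins$bins)), bins$bins$bin_id)
  out[names(sets)] <- sets
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' Relative pathway coverage of bins
#'
#' For each pathway, the KO universe is the union of that pathway's KOs
#' observed across ALL supplied bins (both communities); a bin's coverage is
#' the fraction of that universe it carries. Pathways with an empty universe
#' are omitted.
#'
#' @param ko_sets Named list bin -> KO character vector (see
#'   [bin_ko_sets()]); include bins from both communities.
#' @param catalog A `function_catalog`.
#' @return Numeric matrix, bins x pathways, values in \[0,1\].
#' @export
pathway_coverage <- function(ko_sets, catalog) {
  members <- pathway_members(catalog)
  all_kos <- unique(unlist(ko_sets, use.names = FALSE))
  universe <- lapply(members, function(kos) intersect(kos, all_kos))
  universe <- universe[lengths(universe) > 0]
  m <- matrix(0, length(ko_sets), length(universe),
              dimnames = list(names(ko_sets), names(universe)))
  for (b in names(ko_sets)) {
    m[b, ] <- vapply(universe, function(u)
      length(intersect(ko_sets[[b]], u)) / length(u), numeric(1))
  }
  m
}

#' PCA of genome pathway profiles
#'
#' Column-centred SVD (covariance PCA, no scaling) of a genomes x pathways
#' proportion matrix; each genome is treated as a collection of metabolic
#' pathways with varying relative abundance. Sign convention: within each
#' component the largest-magnitude loading is made positive.
#'
#' @param profiles Numeric matrix, genomes (rows) x pathways (columns).
#' @return List with `scores` (genomes x PCs), `loadings`,
#'   `variance_fraction`.
#' @export
genome_pathway_pca <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 3)
  x <- scale(profiles, center = TRUE, scale = FALSE)
  sv <- svd(x)
  d2 <- sv$d^2
  if (sum(d2) <= 1e-12 * length(x)) {
    k <- min(dim(x))
    return(list(scores = matrix(0, nrow(x), k,
                                dimnames = list(rownames(x),
                                                paste0("PC", seq_len(k)))),
                loadings = matrix(0, ncol(x), k),
                variance_fraction = rep(0, k)))
  }
  flip <- vapply(seq_along(sv$d), function(k) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(x %*% sv$v, 2, flip, "*")
  loadings <- sweep(sv$v, 2, flip, "*")
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(sv$d))
  rownames(scores) <- rownames(profiles)
  rownames(loadings) <- colnames(profiles)
  list(scores = scores, loadings = loadings,
       variance_fraction = d2 / sum(d2))
}

#' Differential-metabolism contributor score
#'
#' The number of distinct KOs of a bin that belong to at least one
#' differential pathway, divided by the bin's estimated completeness as a
#' fraction — so an incompletely recovered genome's observed KO count is
#' scaled up to its expected full-genome count. Higher score = greater
#' inferred contribution to the differential metabolism.
#'
#' @param ko_set Character vector of the bin's KOs.
#' @param differential_pathways Character vector of pathway ids.
#' @param catalog A `function_catalog`.
#' @param completeness Percent in (0, 100\].
#' @return Non-negative numeric score.
#' @export
contributor_score <- function(ko_set, differential_pathways, catalog,
                              completeness) {
  if (completeness <= 0 || completeness > 100)
    stop("completeness must be in (0, 100]")
  members <- pathway_members(catalog)
  qual <- unique(unlist(members[intersect(differential_pathways,
                                          names(members))],
                        use.names = FALSE))
  length(intersect(unique(ko_set), qual)) / (completeness / 100)
}

#' Urea-processing capability screen
#'
#' Transport-capable iff all five Urt subunits are present OR the Utp
#' transporter is present; ureolysis-capable iff all three structural urease
#' subunits are present. Accessory-protein completeness is reported
#' separately and does not gate the call.
#'
#' @param ko_set Character vector of a bin's KOs.
#' @param urea_config Named KO sets as from [urea_ko_config()].
#' @return List with `status` (one of `"full_suite"`, `"transport_only"`,
#'   `"ureolysis_only"`, `"none"`), `transport`, `ureolysis`,
#'   `accessory_fraction`.
#' @export
urea_screen <- function(ko_set, urea_config = urea_ko_config()) {
  need <- c("urt_subunits", "utp", "urease_structural", "urease_accessory")
  if (!all(need %in% names(urea_config)))
    stop("urea_config must define: ", paste(need, collapse = ", "))
  if (length(urea_config$urt_subunits) != 5 ||
      length(urea_config$urease_structural) != 3)
    stop("urea_config must define 5 urt subunits and 3 structural urease KOs")
  transport <- all(urea_config$urt_subunits %in% ko_set) ||
    any(urea_config$utp %in% ko_set)
  ureolysis <- all(urea_config$urease_structural %in% ko_set)
  status <- if (transport && ureolysis) "full_suite" else
    if (transport) "transport_only" else
      if (ureolysis) "ureolysis_only" else "none"
  acc <- urea_config$urease_accessory
  list(status = status, transport = transport, ureolysis = ureolysis,
       accessory_fraction = if (length(acc))
         mean(acc %in% ko_set) else NA_real_)
}

#' Abundance-weighted mean estimated-complete genome size
#'
#' Each bin's observed size is corrected to an estimated complete size by
#' dividing by its completeness fraction, then averaged with the supplied
#' abundances as weights.
#'
#' @param bins A `genome_bins` (typically after [filter_bins()]).
#' @param abundances Named numeric vector bin_id -> abundance weight (e.g.
#'   median across samples).
#' @return Estimated mean genome size in bp.
#' @export
community_genome_size_summary <- function(bins, abundances) {
  meta <- bins$bins
  if (!nrow(meta)) stop("no bins to summarise")
  if (any(meta$completeness <= 0))
    stop("completeness must be positive for all bins")
  w <- abundances[meta$bin_id]
  if (any(is.na(w))) stop("missing abundance for bin(s): ",
                          paste(meta$bin_id[is.na(w)], collapse = ", "))
  if (sum(w) <= 0) stop("abundance weights must sum to a positive value")
  est <- meta$size_bp / (meta$completeness / 100)
  sum(w * est) / sum(w)
}
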