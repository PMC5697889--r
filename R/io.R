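## Validated readers/writers for the tabular and sequence formats the
## workflow consumes. TSV dialect: UTF-8, tab-separated, '#' comment lines,
## header row required.

read_tsv_checked <- function(path, required_cols = character()) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-CDS annotation table
#'
#' Expects a TSV with columns `cds_id`, `contig_id`, `start`, `end`,
#' `strand`, `ko` (empty allowed), `cazy_domains` (semicolon-separated CAZy
#' family labels, empty allowed). Coordinates are 1-based inclusive.
#'
#' @param path Path to the TSV file.
#' @return A `cds_table`: data.frame with one row per CDS and a
#'   `cazy_domains` character column (semicolon-separated). Use
#'   [cds_cazy_list()] to split domains.
#' @export
read_cds_table <- function(path) {
  cols <- c("cds_id", "contig_id", "start", "end", "strand", "ko",
            "cazy_domains")
  df <- read_tsv_checked(path, cols)
  df <- df[, cols]
  df$ko[is.na(df$ko)] <- ""
  df$cazy_domains[is.na(df$cazy_domains)] <- ""
  validate_cds_table(df)
}

#' Validate (and class) a CDS table
#' @param df data.frame with the `cds_table` columns.
#' @return The validated `cds_table`.
#' @export
validate_cds_table <- function(df) {
  stopifnot(is.data.frame(df))
  df$cds_id <- as.character(df$cds_id)
  df$contig_id <- as.character(df$contig_id)
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$start < 1 |
                 df$end < df$start)
  if (length(bad))
    stop("malformed coordinates at row(s): ", paste(bad, collapse = ", "))
  dup <- unique(df$cds_id[duplicated(df$cds_id)])
  if (length(dup))
    stop("duplicate cds_id: ", paste(dup, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' at row(s): ",
         paste(which(!df$strand %in% c("+", "-")), collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  class(df) <- c("cds_table", "data.frame")
  df
}

#' Split the semicolon-joined CAZy domain column
#'
#' @param cds A `cds_table`.
#' @return Named list (by `cds_id`) of character vectors of CAZy families;
#'   empty vector for unannotated CDSs.
#' @export
cds_cazy_list <- function(cds) {
  out <- strsplit(cds$cazy_domains, ";", fixed = TRUE)
  out <- lapply(out, function(x) x[nzchar(x)])
  names(out) <- cds$cds_id
  out
}

#' Write a CDS table
#' @param cds A `cds_table`.
#' @param path Output path.
#' @export
write_cds_table <- function(cds, path) {
  write_tsv(as.data.frame(cds), path)
}

#' Read a contig coverage table
#'
#' TSV with columns `contig_id`, `length`, then one column per sample holding
#' the mean read depth (reads-per-base average) of the contig in that sample.
#'
#' @param path Path to the TSV file.
#' @return A `coverage_table`: list with `depth` (numeric matrix, contigs x
#'   samples, ordered as in the file) and `lengths` (named integer vector).
#' @export
read_coverage_table <- function(path) {
  df <- read_tsv_checked(path, c("contig_id", "length"))
  samples <- setdiff(names(df), c("contig_id", "length"))
  if (!length(samples)) stop("coverage table has no sample columns")
  coverage_table(
    depth = as.matrix(`rownames<-`(df[, samples, drop = FALSE],
                                   df$contig_id)),
    lengths = stats::setNames(df$length, df$contig_id))
}

#' Construct/validate a coverage table
#' @param depth Numeric matrix, contigs (rows, named) x samples (cols, named).
#' @param lengths Named numeric vector of contig lengths (bp).
#' @return A `coverage_table`.
#' @export
coverage_table <- function(depth, lengths) {
  depth <- as.matrix(depth)
  if (is.null(rownames(depth)) || is.null(colnames(depth)))
    stop("depth matrix must have contig rownames and sample colnames")
  if (any(!is.finite(depth)) || any(depth < 0))
    stop("coverage depths must be finite and >= 0")
  if (any(is.na(lengths[rownames(depth)])))
    stop("missing length for contig(s): ",
         paste(rownames(depth)[is.na(lengths[rownames(depth)])],
               collapse = ", "))
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  lengths <- lengths[rownames(depth)]
  storage.mode(lengths) <- "integer"
  structure(list(depth = depth, lengths = lengths),
            class = "coverage_table")
}

#' @export
print.coverage_table <- function(x, ...) {
  cat("coverage_table:", nrow(x$depth), "contigs x", ncol(x$depth),
      "samples\n")
  invisible(x)
}

#' Samples of a coverage table
#' @param cov A `coverage_table`.
#' @return Character vector of sample ids, in file order.
#' @export
coverage_samples <- function(cov) colnames(cov$depth)

#' Write a coverage table
#' @param cov A `coverage_table`.
#' @param path Output path.
#' @export
write_coverage_table <- function(cov, path) {
  df <- data.frame(contig_id = rownames(cov$depth),
                   length = unname(cov$lengths),
                   cov$depth, check.names = FALSE)
  write_tsv(df, path)
}

#' Read genome bins
#'
#' Two TSVs: a membership table (`contig_id`, `bin_id`) and a per-bin
#' metadata table (`bin_id`, `completeness`, `contamination`, `taxonomy`).
#' Contigs absent from the membership table are unbinned. Bin sizes are
#' computed from `lengths` when given.
#'
#' @param membership_path Path to the contig -> bin TSV.
#' @param metadata_path Path to the per-bin metadata TSV.
#' @param lengths Optional named vector of contig lengths (bp), e.g.
#'   `cov$lengths`.
#' @return A `genome_bins` object (see [genome_bins()]).
#' @export
read_bins <- function(membership_path, metadata_path, lengths = NULL) {
  mem <- read_tsv_checked(membership_path, c("contig_id", "bin_id"))
  meta <- read_tsv_checked(metadata_path,
                           c("bin_id", "completeness", "contamination",
                             "taxonomy"))
  genome_bins(stats::setNames(as.character(mem$bin_id),
                              as.character(mem$contig_id)),
              meta, lengths = lengths)
}

#' Construct/validate genome bins
#'
#' @param membership Named character vector: contig_id -> bin_id. A contig
#'   may belong to at most one bin (duplicated contig names are an error).
#' @param metadata data.frame with `bin_id`, `completeness`, `contamination`
#'   (percent, in \[0,100\]) and `taxonomy`.
#' @param lengths Optional named contig lengths; when given, `size_bp` is the
#'   sum of member contig lengths.
#' @return A `genome_bins` object: list with `membership` and `bins`
#'   (metadata data.frame with `size_bp`).
#' @export
genome_bins <- function(membership, metadata, lengths = NULL) {
  dup <- unique(names(membership)[duplicated(names(membership))])
  if (length(dup))
    stop("contig assigned to more than one bin: ", paste(dup, collapse = ", "))
  metadata$bin_id <- as.character(metadata$bin_id)
  if (anyDuplicated(metadata$bin_id)) stop("duplicate bin_id in metadata")
  if (any(metadata$completeness < 0 | metadata$completeness > 100))
    stop("completeness out of [0,100] for bin(s): ",
         paste(metadata$bin_id[metadata$completeness < 0 |
                                 metadata$completeness > 100],
               collapse = ", "))
  if (any(metadata$contamination < 0 | metadata$contamination > 100))
    stop("contamination out of [0,100] for bin(s): ",
         paste(metadata$bin_id[metadata$contamination < 0 |
                                 metadata$contamination > 100],
               collapse = ", "))
  extra <- setdiff(unique(membership), metadata$bin_id)
  if (length(extra))
    stop("bin(s) in membership missing from metadata: ",
         paste(extra, collapse = ", "))
  if (!is.null(lengths)) {
    miss <- setdiff(names(membership), names(lengths))
    if (length(miss))
      stop("no length for binned contig(s): ", paste(miss, collapse = ", "))
    sz <- tapply(as.numeric(lengths[names(membership)]), membership, sum)
    metadata$size_bp <- as.numeric(sz[metadata$bin_id])
    metadata$size_bp[is.na(metadata$size_bp)] <- 0
  } else if (is.null(metadata$size_bp)) {
    metadata$size_bp <- NA_real_
  }
  structure(list(membership = membership, bins = metadata),
            class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  cat("genome_bins:", nrow(x$bins), "bins,", length(x$membership),
      "binned contigs\n")
  invisible(x)
}

#' Contigs of one bin
#' @param bins A `genome_bins`.
#' @param bin_id Bin identifier.
#' @return Character vector of contig ids.
#' @export
bin_contigs <- function(bins, bin_id) {
  names(bins$membership)[bins$membership == bin_id]
}

#' Write genome bins to membership + metadata TSVs
#' @param bins A `genome_bins`.
#' @param membership_path,metadata_path Output paths.
#' @export
write_bins <- function(bins, membership_path, metadata_path) {
  write_tsv(data.frame(contig_id = names(bins$membership),
                       bin_id = unname(bins$membership)), membership_path)
  write_tsv(bins$bins, metadata_path)
}

#' Define a sample group
#' @param group_id Host/group label.
#' @param sample_ids Ordered character vector of sample ids (time-points).
#' @return A `sample_group` list.
#' @export
sample_group <- function(group_id, sample_ids) {
  stopifnot(length(sample_ids) >= 1, !anyDuplicated(sample_ids))
  structure(list(group_id = group_id, sample_ids = as.character(sample_ids)),
            class = "sample_group")
}

#' Read a taxon relative-abundance profile
#'
#' TSV with a `lineage` column (rank-prefixed, semicolon-separated, e.g.
#' `"k__Bacteria;p__Firmicutes;...;f__S24-7"`) and one numeric column per
#' sample holding relative abundances as fractions in \[0,1\].
#'
#' @param path Path to the TSV file.
#' @return A `taxon_profile`: data.frame (lineage + sample columns) with
#'   attribute `min_abundance` (default 0.0005).
#' @export
read_taxon_profile <- function(path) {
  df <- read_tsv_checked(path, "lineage")
  taxon_profile(df)
}

#' Construct/validate a taxon profile
#' @param df data.frame with `lineage` plus numeric sample columns.
#' @param min_abundance Detection floor used by [filter_taxa()]; default
#'   0.0005 (i.e. 0.05%).
#' @return A `taxon_profile`.
#' @export
taxon_profile <- function(df, min_abundance = 0.0005) {
  stopifnot(is.data.frame(df), "lineage" %in% names(df))
  samples <- setdiff(names(df), "lineage")
  if (!length(samples)) stop("taxon profile has no sample columns")
  vals <- as.matrix(df[, samples, drop = FALSE])
  if (any(vals < 0 | vals > 1)) stop("relative abundances must be in [0,1]")
  sums <- colSums(vals)
  if (any(sums > 1 + 1e-8))
    stop("per-sample abundances sum to more than 1: ",
         paste(samples[sums > 1 + 1e-8], collapse = ", "))
  structure(df, class = c("taxon_profile", "data.frame"),
            min_abundance = min_abundance)
}

#' Write a taxon profile
#' @param profile A `taxon_profile`.
#' @param path Output path.
#' @export
write_taxon_profile <- function(profile, path) {
  write_tsv(as.data.frame(profile), path)
}

#' Read a KO -> pathway catalog table
#'
#' TSV with columns `ko`, `pathway`, and optionally `category` (the
#' metabolism-hierarchy label); one row per (KO, pathway) assignment.
#'
#' @param path Path to the TSV file.
#' @param min_kos_per_pathway Passed to [function_catalog()].
#' @return A `function_catalog`.
#' @export
read_catalog_table <- function(path, min_kos_per_pathway = 3L) {
  df <- read_tsv_checked(path, c("ko", "pathway"))
  k2p <- lapply(split(as.character(df$pathway), as.character(df$ko)), unique)
  pc <- NULL
  if ("category" %in% names(df)) {
    first <- !duplicated(df$pathway)
    pc <- stats::setNames(as.character(df$category[first]),
                          as.character(df$pathway[first]))
  }
  function_catalog(k2p, pathway_category = pc,
                   min_kos_per_pathway = min_kos_per_pathway)
}

#' Write a function catalog's KO -> pathway table
#' @param catalog A `function_catalog`.
#' @param path Output path.
#' @export
write_catalog_table <- function(catalog, path) {
  ko <- rep(names(catalog$ko_to_pathways),
            lengths(catalog$ko_to_pathways))
  pw <- unlist(catalog$ko_to_pathways, use.names = FALSE)
  df <- data.frame(ko = ko, pathway = pw, stringsAsFactors = FALSE)
  if (!is.null(catalog$pathway_category))
    df$category <- unname(catalog$pathway_category[pw])
  write_tsv(df, path)
}

#' Read a protein FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

#' Write proteins to FASTA
#' @param proteins Named character vector of amino-acid sequences.
#' @param path Output path.
#' @export
write_proteins <- function(proteins, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(proteins), path, width = 70)
  invisible(path)
}

# Cross-table consistency: every contig referenced by a CDS or bin must be
# present in the coverage table.
check_contig_consistency <- function(cov, cds = NULL, bins = NULL) {
  known <- rownames(cov$depth)
  if (!is.null(cds)) {
    miss <- setdiff(unique(cds$contig_id), known)
    if (length(miss))
      stop("CDS contig(s) absent from coverage table: ",
           paste(miss, collapse = ", "))
  }
  if (!is.null(bins)) {
    miss <- setdiff(names(bins$membership), known)
    if (length(miss))
      stop("binned contig(s) absent from coverage table: ",
           paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
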