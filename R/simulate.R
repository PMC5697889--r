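## Synthetic two-host community generator. Emulates the study design the
## workflow targets: two host-labelled communities of binned population
## genomes (3 and 5 fecal time-points), lognormal genome abundances that
## persist across time-points, multiplicative lognormal coverage noise per
## contig per sample, shared core pathways plus host-differential pathway
## content, bin completeness/contamination corruption, and divergent
## proteome pairs with controlled amino-acid divergence.

# Approximate natural amino-acid background frequencies (20 letters).
aa_background <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
  E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
  M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
  Y = 0.032, V = 0.065)

#' Simulation configuration
#'
#' Defaults mirror the targeted study design: 15 population genomes per host
#' (the per-host analysis depth of the genome-centric stage), 3 time-points
#' for host A and 5 for host B, and moderate ecological noise. Genome
#' abundances are lognormal and persistent: a base abundance is drawn once
#' per genome and jittered per time-point, reflecting the temporal
#' autocorrelation of gut communities.
#'
#' @param n_genomes Genomes per host.
#' @param n_samples_a,n_samples_b Time-points for host A / host B.
#' @param contigs_per_genome,cds_per_contig Integer ranges (length-2).
#' @param depth_mean Community-wide mean depth scale (reads per base).
#' @param coverage_noise_cv Coefficient of variation of the multiplicative
#'   lognormal depth noise, per contig per sample. 0 disables noise.
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of genome
#'   base abundances (before per-sample normalisation).
#' @param abundance_sample_cv CV of the per-sample jitter on base abundance.
#' @param n_shared_pathways Pathways carried by both hosts' gene pools.
#' @param n_differential_pathways Host-specific differential pathways, per
#'   host.
#' @param kos_per_pathway KOs defined per pathway.
#' @param ko_carriage Baseline per-genome, per-KO carriage probability.
#' @param differential_effect Fold increase of carriage probability for a
#'   host's differential pathways in that host's genomes.
#' @param cazy_rate Probability that a CDS carries a glycoside hydrolase
#'   domain.
#' @param aa_rate Probability that a CDS carries an auxiliary-activity (AA)
#'   domain in host B; host A uses `aa_rate * aa_effect`.
#' @param aa_effect Fold enrichment of AA domains in host A.
#' @param completeness_range,contamination_range Percent ranges from which
#'   bin corruption targets are drawn uniformly.
#' @param proteome_divergence Numeric vector of per-site divergence levels;
#'   the i-th host-B genome is generated as a structural clone of the i-th
#'   host-A genome with its proteome mutated at that level.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genomes = 15L,
                       n_samples_a = 3L,
                       n_samples_b = 5L,
                       contigs_per_genome = c(6L, 12L),
                       cds_per_contig = c(25L, 45L),
                       depth_mean = 20,
                       coverage_noise_cv = 0.2,
                       abundance_meanlog = 0,
                       abundance_sdlog = 1,
                       abundance_sample_cv = 0.3,
                       n_shared_pathways = 40L,
                       n_differential_pathways = 5L,
                       kos_per_pathway = 8L,
                       ko_carriage = 0.25,
                       differential_effect = 3,
                       cazy_rate = 0.05,
                       aa_rate = 0.01,
                       aa_effect = 1,
                       completeness_range = c(60, 95),
                       contamination_range = c(0, 8),
                       proteome_divergence = numeric(),
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_genomes = as.integer(n_genomes),
              n_samples_a = as.integer(n_samples_a),
              n_samples_b = as.integer(n_samples_b),
              contigs_per_genome = as.integer(contigs_per_genome),
              cds_per_contig = as.integer(cds_per_contig),
              depth_mean = depth_mean,
              coverage_noise_cv = coverage_noise_cv,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              abundance_sample_cv = abundance_sample_cv,
              n_shared_pathways = as.integer(n_shared_pathways),
              n_differential_pathways = as.integer(n_differential_pathways),
              kos_per_pathway = as.integer(kos_per_pathway),
              ko_carriage = ko_carriage,
              differential_effect = differential_effect,
              cazy_rate = cazy_rate,
              aa_rate = aa_rate,
              aa_effect = aa_effect,
              completeness_range = completeness_range,
              contamination_range = contamination_range,
              proteome_divergence = proteome_divergence,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genomes >= 1, n_samples_a >= 1, n_samples_b >= 1,
              length(contigs_per_genome) == 2, length(cds_per_contig) == 2,
              all(contigs_per_genome >= 1), all(cds_per_contig >= 1),
              depth_mean > 0, coverage_noise_cv >= 0,
              abundance_sample_cv >= 0,
              n_shared_pathways >= 0, n_differential_pathways >= 0,
              kos_per_pathway >= 1,
              ko_carriage >= 0, ko_carriage <= 1,
              differential_effect >= 0, cazy_rate >= 0, cazy_rate <= 1,
              aa_rate >= 0, aa_rate <= 1, aa_effect >= 0,
              all(completeness_range >= 0), all(completeness_range <= 100),
              all(contamination_range >= 0), all(contamination_range <= 100),
              all(proteome_divergence >= 0), all(proteome_divergence < 1),
              length(proteome_divergence) <= n_genomes)
  })
  class(cfg) <- "sim_config"
  cfg
}

rlnorm_cv <- function(n, cv) {
  # lognormal multiplicative noise with mean 1 and the given CV
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

random_protein <- function(len) {
  paste(sample(names(aa_background), len, replace = TRUE,
               prob = aa_background), collapse = "")
}

#' Generate a random proteome
#'
#' Proteins are i.i.d. residues from a fixed amino-acid background
#' frequency — adequate for testing identity recovery, not for benchmarking
#' aligners against real proteins.
#'
#' @param n_proteins Number of proteins.
#' @param length Protein length (residues); recycled.
#' @param seed RNG seed.
#' @param prefix Protein id prefix.
#' @return Named character vector of sequences.
#' @export
simulate_proteome <- function(n_proteins, length = 300L, seed,
                              prefix = "prot") {
  set.seed(seed)
  len <- rep_len(length, n_proteins)
  stats::setNames(vapply(len, random_protein, character(1)),
                  sprintf("%s_%03d", prefix, seq_len(n_proteins)))
}

#' Mutate a proteome at a controlled per-site divergence
#'
#' Each residue is substituted, independently with probability `divergence`,
#' by a residue drawn uniformly from the 19 alternatives, so expected
#' per-protein identity is `1 - divergence` and lengths are preserved.
#'
#' @param proteome Named character vector of sequences.
#' @param divergence Per-site substitution probability in \[0, 1).
#' @param seed RNG seed.
#' @return Mutated proteome (same names, same lengths).
#' @export
mutate_proteome <- function(proteome, divergence, seed) {
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)")
  set.seed(seed)
  if (divergence == 0) return(proteome)
  alphabet <- names(aa_background)
  out <- vapply(proteome, function(p) {
    s <- strsplit(p, "")[[1]]
    hit <- stats::runif(length(s)) < divergence
    if (any(hit)) {
      repl <- vapply(s[hit], function(orig) {
        sample(setdiff(alphabet, orig), 1L)
      }, character(1))
      s[hit] <- repl
    }
    paste(s, collapse = "")
  }, character(1))
  stats::setNames(out, names(proteome))
}

#' Simulate a two-host community with known ground truth
#'
#' See [sim_config()] for the generative model. Returns every table the
#' downstream stages consume, in the exact containers the readers produce,
#' plus a `truth` record: true per-sample abundances (both cell fractions
#' and read fractions), the true differential pathway sets, the
#' pre-corruption bin membership, true genome sizes, and any proteome
#' divergence pairs.
#'
#' @param config A `sim_config`.
#' @return List with elements `cds` (`cds_table`), `cov`
#'   (`coverage_table`), `bins` (`genome_bins`, corruption applied),
#'   `proteomes` (named list genome -> named character vector), `catalog`
#'   (`function_catalog` over the simulated pathway universe), `groups`
#'   (list of two `sample_group`s), and `truth`.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  hosts <- c("hostA", "hostB")
  n_g <- cfg$n_genomes
  genome_ids <- c(sprintf("gA%02d", seq_len(n_g)),
                  sprintf("gB%02d", seq_len(n_g)))
  genome_host <- rep(hosts, each = n_g)
  samples_a <- sprintf("A_t%d", seq_len(cfg$n_samples_a))
  samples_b <- sprintf("B_t%d", seq_len(cfg$n_samples_b))
  samples <- c(samples_a, samples_b)
  sample_host <- rep(hosts, c(cfg$n_samples_a, cfg$n_samples_b))

  ## pathway universe
  n_pw <- cfg$n_shared_pathways + 2L * cfg$n_differential_pathways
  pw_ids <- character(0); pw_role <- character(0)
  if (cfg$n_shared_pathways > 0) {
    pw_ids <- sprintf("path_s%03d", seq_len(cfg$n_shared_pathways))
    pw_role <- rep("shared", cfg$n_shared_pathways)
  }
  if (cfg$n_differential_pathways > 0) {
    pw_ids <- c(pw_ids,
                sprintf("path_a%02d", seq_len(cfg$n_differential_pathways)),
                sprintf("path_b%02d", seq_len(cfg$n_differential_pathways)))
    pw_role <- c(pw_role, rep(c("hostA", "hostB"),
                              each = cfg$n_differential_pathways))
  }
  ko_ids <- sprintf("K%05d", 20000L + seq_len(n_pw * cfg$kos_per_pathway))
  pw_kos <- split(ko_ids, rep(seq_len(max(n_pw, 1L)),
                              each = cfg$kos_per_pathway)[
                                seq_along(ko_ids)])
  names(pw_kos) <- pw_ids
  ko_to_pathways <- stats::setNames(
    as.list(rep(pw_ids, each = cfg$kos_per_pathway)), ko_ids)
  pathway_category <- stats::setNames(
    sprintf("1.%d", (seq_len(n_pw) - 1L) %% 11L + 1L), pw_ids)
  catalog <- function_catalog(ko_to_pathways, pathway_category,
                              gh_category = gh_category_map())

  ## genome structure: contigs and CDS slots
  gh_pool <- c(names(gh_category_map()),
               "GH13", "GH20", "GH31", "GH36", "GH77")
  aa_pool <- sprintf("AA%d", 1:6)
  n_div <- length(cfg$proteome_divergence)

  structure_of <- function() {
    nc <- sample(seq(cfg$contigs_per_genome[1], cfg$contigs_per_genome[2]),
                 1L)
    n_cds <- sample(seq(cfg$cds_per_contig[1], cfg$cds_per_contig[2]), nc,
                    replace = TRUE)
    cds_len <- lapply(n_cds, function(k) 3L * sample(100:500, k,
                                                     replace = TRUE))
    list(n_contigs = nc, cds_len = cds_len)
  }
  structures <- vector("list", 2L * n_g)
  names(structures) <- genome_ids
  for (i in seq_len(2L * n_g)) {
    g <- genome_ids[i]
    if (genome_host[i] == "hostB" && (i - n_g) <= n_div && i > n_g) {
      structures[[g]] <- structures[[genome_ids[i - n_g]]]  # clone layout
    } else {
      structures[[g]] <- structure_of()
    }
  }

  cds_rows <- vector("list", 2L * n_g)
  contig_len <- list()
  contig_genome <- character(0)
  for (i in seq_len(2L * n_g)) {
    g <- genome_ids[i]
    st <- structures[[g]]
    rows <- list()
    for (ci in seq_len(st$n_contigs)) {
      contig <- sprintf("%s_c%02d", g, ci)
      lens <- st$cds_len[[ci]]
      gap <- 100L
      starts <- gap + c(0L, cumsum(lens + gap))[seq_along(lens)]
      ends <- starts + lens - 1L
      clen <- ends[length(ends)] + gap
      contig_len[[contig]] <- clen
      contig_genome[contig] <- g
      rows[[ci]] <- data.frame(
        cds_id = sprintf("%s_g%03d", contig, seq_along(lens)),
        contig_id = contig, start = starts, end = ends,
        strand = sample(c("+", "-"), length(lens), replace = TRUE),
        ko = "", cazy_domains = "", stringsAsFactors = FALSE)
    }
    cds_rows[[i]] <- do.call(rbind, rows)
  }
  cds <- do.call(rbind, cds_rows)
  rownames(cds) <- NULL
  contig_lengths <- unlist(contig_len)

  ## KO content per genome
  carriage_for <- function(host) {
    p <- rep(cfg$ko_carriage, n_pw)
    p[pw_role == host] <- pmin(1, cfg$ko_carriage * cfg$differential_effect)
    p
  }
  cds_by_genome <- split(seq_len(nrow(cds)),
                         contig_genome[cds$contig_id])
  for (i in seq_len(2L * n_g)) {
    g <- genome_ids[i]
    p_pw <- carriage_for(genome_host[i])
    p_ko <- rep(p_pw, each = cfg$kos_per_pathway)[seq_along(ko_ids)]
    carried <- ko_ids[stats::runif(length(ko_ids)) < p_ko]
    slots <- cds_by_genome[[g]]
    if (length(carried) > length(slots))
      stop("infeasible config: genome ", g, " needs ", length(carried),
           " KO-bearing CDSs but has only ", length(slots))
    if (length(carried))
      cds$ko[sample(slots, length(carried))] <- carried
  }

  ## CAZy domains
  for (i in seq_len(2L * n_g)) {
    g <- genome_ids[i]
    slots <- cds_by_genome[[g]]
    gh_hit <- slots[stats::runif(length(slots)) < cfg$cazy_rate]
    if (length(gh_hit))
      cds$cazy_domains[gh_hit] <- sample(gh_pool, length(gh_hit),
                                         replace = TRUE)
    aa_p <- cfg$aa_rate * if (genome_host[i] == "hostA") cfg$aa_effect else 1
    aa_hit <- slots[stats::runif(length(slots)) < min(1, aa_p)]
    if (length(aa_hit)) {
      fam <- sample(aa_pool, length(aa_hit), replace = TRUE)
      has <- nzchar(cds$cazy_domains[aa_hit])
      cds$cazy_domains[aa_hit] <- ifelse(
        has, paste(cds$cazy_domains[aa_hit], fam, sep = ";"), fam)
    }
  }
  cds <- validate_cds_table(cds)

  ## abundances: persistent lognormal base + per-sample jitter
  base_ab <- stats::rlnorm(2L * n_g, cfg$abundance_meanlog,
                           cfg$abundance_sdlog)
  names(base_ab) <- genome_ids
  cell_ab <- matrix(0, 2L * n_g, length(samples),
                    dimnames = list(genome_ids, samples))
  for (s in seq_along(samples)) {
    in_host <- genome_host == sample_host[s]
    a <- base_ab[in_host] * rlnorm_cv(sum(in_host), cfg$abundance_sample_cv)
    cell_ab[in_host, s] <- a / sum(a)
  }
  genome_size <- vapply(genome_ids, function(g)
    sum(contig_lengths[contig_genome == g]), numeric(1))
  read_frac <- cell_ab * genome_size
  read_frac <- sweep(read_frac, 2, colSums(read_frac), "/")

  ## coverage: depth = depth_mean * cell abundance * lognormal noise
  depth <- matrix(0, length(contig_lengths), length(samples),
                  dimnames = list(names(contig_lengths), samples))
  g_of_contig <- contig_genome[rownames(depth)]
  for (s in seq_along(samples)) {
    a <- cell_ab[g_of_contig, s]
    noise <- rlnorm_cv(nrow(depth), cfg$coverage_noise_cv)
    depth[, s] <- cfg$depth_mean * a * noise
  }
  cov <- coverage_table(depth, contig_lengths)

  ## bins: truth membership, then completeness/contamination corruption
  truth_membership <- stats::setNames(
    paste0("bin_", contig_genome), names(contig_genome))
  membership <- as.list(split(names(contig_genome), contig_genome))
  comp_target <- stats::runif(2L * n_g, cfg$completeness_range[1],
                              cfg$completeness_range[2])
  cont_target <- stats::runif(2L * n_g, cfg$contamination_range[1],
                              cfg$contamination_range[2])
  kept <- membership
  for (i in seq_len(2L * n_g)) {
    g <- genome_ids[i]
    ctgs <- sample(membership[[g]])
    frac <- cumsum(contig_lengths[ctgs]) / genome_size[g]
    # whole-contig granularity: keep the prefix whose size fraction is
    # closest to the completeness target
    keep_n <- max(1L, which.min(abs(frac - comp_target[i] / 100)))
    kept[[g]] <- ctgs[seq_len(keep_n)]
  }
  # contamination: adopt foreign contigs from the pool removed by the
  # completeness corruption (donor bins stay intact, disjointness holds);
  # whole-contig granularity, so each bin lands as close to its target as
  # the pool allows
  pool <- unlist(lapply(genome_ids, function(g)
    setdiff(membership[[g]], kept[[g]])), use.names = FALSE)
  foreign <- stats::setNames(vector("list", 2L * n_g), genome_ids)
  for (i in seq_len(2L * n_g)) {
    g <- genome_ids[i]
    if (cont_target[i] <= 0) next
    candidates <- pool[contig_genome[pool] != g]
    if (!length(candidates)) {
      if (cfg$contamination_range[1] > 0)
        stop("infeasible config: no donor contigs available for ",
             "contamination of ", g)
      next
    }
    own_sz <- sum(contig_lengths[kept[[g]]])
    want <- cont_target[i] / 100 * own_sz
    got <- 0
    repeat {
      if (!length(candidates)) break
      sz <- contig_lengths[candidates]
      pick <- which.min(abs((got + sz) - want))
      if (abs((got + sz[pick]) - want) >= abs(got - want)) break
      ctg <- candidates[pick]
      foreign[[g]] <- c(foreign[[g]], ctg)
      pool <- setdiff(pool, ctg)
      candidates <- candidates[candidates != ctg]
      got <- got + sz[pick]
    }
  }
  member_vec <- character(0)
  comp_real <- cont_real <- numeric(2L * n_g)
  for (i in seq_len(2L * n_g)) {
    g <- genome_ids[i]
    own <- kept[[g]]
    all_ctgs <- c(own, foreign[[g]])
    member_vec[all_ctgs] <- paste0("bin_", g)
    own_sz <- sum(contig_lengths[own])
    comp_real[i] <- 100 * own_sz / genome_size[g]
    cont_real[i] <- if (own_sz > 0)
      min(100, 100 * sum(contig_lengths[foreign[[g]]]) / own_sz) else 0
  }
  meta <- data.frame(
    bin_id = paste0("bin_", genome_ids),
    completeness = round(comp_real, 2),
    contamination = round(cont_real, 2),
    taxonomy = sprintf("k__Bacteria;p__P%02d;c__C%02d;o__O%02d;f__F%02d;g__%s",
                       (seq_len(2L * n_g) - 1L) %% 4L + 1L,
                       (seq_len(2L * n_g) - 1L) %% 6L + 1L,
                       (seq_len(2L * n_g) - 1L) %% 8L + 1L,
                       (seq_len(2L * n_g) - 1L) %% 10L + 1L,
                       genome_ids),
    stringsAsFactors = FALSE)
  bins <- genome_bins(member_vec, meta, lengths = contig_lengths)

  ## proteomes
  proteomes <- vector("list", 2L * n_g)
  names(proteomes) <- genome_ids
  for (i in seq_len(2L * n_g)) {
    g <- genome_ids[i]
    idx <- cds_by_genome[[g]]
    plen <- (cds$end[idx] - cds$start[idx] + 1L) %/% 3L
    proteomes[[g]] <- stats::setNames(
      vapply(plen, random_protein, character(1)), cds$cds_id[idx])
  }
  div_pairs <- NULL
  if (n_div > 0) {
    div_pairs <- data.frame(genome_a = genome_ids[seq_len(n_div)],
                            genome_b = genome_ids[n_g + seq_len(n_div)],
                            divergence = cfg$proteome_divergence)
    for (k in seq_len(n_div)) {
      pa <- proteomes[[div_pairs$genome_a[k]]]
      pb <- mutate_proteome(pa, div_pairs$divergence[k],
                            seed = cfg$seed + 7919L * k)
      names(pb) <- names(proteomes[[div_pairs$genome_b[k]]])
      proteomes[[div_pairs$genome_b[k]]] <- pb
    }
  }

  groups <- list(sample_group("hostA", samples_a),
                 sample_group("hostB", samples_b))
  truth <- list(
    cell_abundance = cell_ab,
    read_fraction = read_frac,
    genome_host = stats::setNames(genome_host, genome_ids),
    genome_size = genome_size,
    membership = truth_membership,
    differential_pathways = list(
      hostA = pw_ids[pw_role == "hostA"],
      hostB = pw_ids[pw_role == "hostB"]),
    divergence_pairs = div_pairs)

  list(cds = cds, cov = cov, bins = bins, proteomes = proteomes,
       catalog = catalog, groups = groups, truth = truth, config = cfg)
}

#' Spike a differential pathway into one host's genomes
#'
#' Raises per-KO carriage of `pathway` in the genomes of `host` by the fold
#' factor `effect` relative to the baseline carriage the community was
#' generated with: each absent (genome, KO) assignment is added with
#' probability `(min(1, p*effect) - p) / (1 - p)`, placed on a random
#' unannotated CDS of the genome. The truth record is updated.
#'
#' @param sim A community from [simulate_community()].
#' @param pathway Pathway id present in `sim$catalog`.
#' @param host `"hostA"` or `"hostB"`.
#' @param effect Fold effect (>= 1); 1 is a no-op.
#' @param seed RNG seed for the spike draws.
#' @return The modified community list.
#' @export
spike_differential <- function(sim, pathway, host = "hostA", effect,
                               seed = sim$config$seed + 1L) {
  members <- pathway_members(sim$catalog)
  if (!pathway %in% names(members)) stop("unknown pathway: ", pathway)
  stopifnot(host %in% c("hostA", "hostB"), effect >= 1)
  if (effect == 1) return(sim)
  set.seed(seed)
  p <- sim$config$ko_carriage
  p2 <- min(1, p * effect)
  p_add <- if (p < 1) (p2 - p) / (1 - p) else 0
  kos <- members[[pathway]]
  cds <- sim$cds
  contig_genome <- sim$truth$membership  # contig -> bin_<genome>
  genome_of <- sub("^bin_", "", contig_genome[cds$contig_id])
  host_genomes <- names(sim$truth$genome_host)[
    sim$truth$genome_host == host]
  for (g in host_genomes) {
    rows <- which(genome_of == g)
    have <- cds$ko[rows]
    for (ko in kos) {
      if (ko %in% have) next
      if (stats::runif(1) < p_add) {
        free <- rows[!nzchar(cds$ko[rows])]
        if (!length(free))
          stop("infeasible spike: no unannotated CDS left in ", g)
        cds$ko[sample(free, 1L)] <- ko
      }
    }
  }
  sim$cds <- validate_cds_table(cds)
  sim$truth$differential_pathways[[host]] <-
    union(sim$truth$differential_pathways[[host]], pathway)
  sim
}

#' Write a simulated community to disk
#'
#' Emits the TSV/FASTA formats of the readers plus `truth.yaml`.
#'
#' @param sim A community from [simulate_community()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cds_table(sim$cds, file.path(dir, "cds.tsv"))
  write_coverage_table(sim$cov, file.path(dir, "coverage.tsv"))
  write_bins(sim$bins, file.path(dir, "bin_membership.tsv"),
             file.path(dir, "bin_metadata.tsv"))
  write_proteins(unlist(unname(sim$proteomes)),
                 file.path(dir, "proteins.faa"))
  write_catalog_table(sim$catalog, file.path(dir, "catalog.tsv"))
  truth <- sim$truth
  # yaml drops names from atomic vectors; emit named structures explicitly
  truth$cell_abundance <- cbind(
    data.frame(genome = rownames(truth$cell_abundance)),
    as.data.frame(truth$cell_abundance, row.names = NULL))
  truth$read_fraction <- cbind(
    data.frame(genome = rownames(truth$read_fraction)),
    as.data.frame(truth$read_fraction, row.names = NULL))
  truth$genome_host <- as.list(truth$genome_host)
  truth$genome_size <- as.list(truth$genome_size)
  truth$membership <- as.list(truth$membership)
  truth$divergence_pairs <- if (is.null(truth$divergence_pairs)) NULL else
    as.list(truth$divergence_pairs)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
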