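#' Configuration for the single-cell count simulator
#'
#' Describes a synthetic DRG-like experiment: `n_clusters` transcriptomic
#' cell types, each with a disjoint program of `markers_per_cluster` marker
#' genes whose expected expression in the home cluster is
#' `marker_fold_change` times their baseline. Counts are negative binomial
#' with variance `mu + mu^2 / nb_dispersion`, per-cell sequencing depth is a
#' log-normal multiplier with sigma `library_size_spread`, and cells are
#' assigned to `n_animals` animals (cyclically within cluster) whose sexes
#' come from `sex_assignment`. Animals alternate between two platforms.
#' Optional log-scale batch shifts (`animal_effect_sd`, `sex_effect`) let
#' the generator create confounding on purpose, to test its removal
#' downstream; both default to 0.
#'
#' @param n_clusters,cells_per_cluster,n_genes,markers_per_cluster integer
#'   counts (all >= 1).
#' @param marker_fold_change positive mean multiplier of a marker gene in
#'   its home cluster; 1 gives a null dataset with no cluster structure.
#' @param nb_dispersion negative-binomial size parameter theta
#'   (variance = mu + mu^2/theta).
#' @param n_animals number of animals cells are distributed over.
#' @param sex_assignment character vector of length `n_animals` with values
#'   `"F"`/`"M"`; default alternates.
#' @param library_size_spread log-normal sigma of the per-cell depth
#'   multiplier.
#' @param animal_effect_sd sd of a per-animal log-scale expression shift.
#' @param sex_effect additive log-scale shift applied to male cells.
#' @param seed integer seed; the simulator is a pure function of
#'   (config, seed).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_clusters = 4, cells_per_cluster = 50,
                       n_genes = 2000, markers_per_cluster = 20,
                       marker_fold_change = 8, nb_dispersion = 2,
                       n_animals = 4, sex_assignment = NULL,
                       library_size_spread = 0.3,
                       animal_effect_sd = 0, sex_effect = 0,
                       seed = 1L) {
  cfg <- list(
    n_clusters = check_count(n_clusters, "n_clusters"),
    cells_per_cluster = check_count(cells_per_cluster, "cells_per_cluster"),
    n_genes = check_count(n_genes, "n_genes"),
    markers_per_cluster = check_count(markers_per_cluster,
                                      "markers_per_cluster"),
    marker_fold_change = check_positive(marker_fold_change,
                                        "marker_fold_change"),
    nb_dispersion = check_positive(nb_dispersion, "nb_dispersion"),
    n_animals = check_count(n_animals, "n_animals"),
    library_size_spread = check_positive(library_size_spread,
                                         "library_size_spread"),
    animal_effect_sd = animal_effect_sd,
    sex_effect = sex_effect,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (is.null(sex_assignment)) {
    sex_assignment <- rep(c("F", "M"), length.out = cfg$n_animals)
  }
  if (length(sex_assignment) != cfg$n_animals ||
      !all(sex_assignment %in% c("F", "M"))) {
    stop("`sex_assignment` must map each of the ", cfg$n_animals,
         " animals to \"F\" or \"M\"", call. = FALSE)
  }
  cfg$sex_assignment <- sex_assignment
  if (cfg$markers_per_cluster * cfg$n_clusters > cfg$n_genes) {
    stop("`markers_per_cluster` x `n_clusters` exceeds `n_genes`; ",
         "marker sets must be disjoint within the gene universe",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a single-cell count matrix with cluster marker programs
#'
#' Draws negative-binomial counts gene by cell. Baseline per-gene means are
#' log-normal; a marker gene's mean in its home cluster is multiplied by
#' `marker_fold_change`. Marker sets are the first
#' `markers_per_cluster * n_clusters` genes, in disjoint consecutive blocks
#' (cluster 1 owns the first block, and so on); the assignment is recorded
#' in `rowData` and in `metadata(sce)$marker_sets`.
#'
#' @param cfg a [sim_config()].
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay and `colData` columns `cluster`, `animal`, `sex`,
#'   `platform`.
#' @export
simulate_counts <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, as.list(cfg))
  with_seed(cfg$seed, {
    n_cells <- cfg$n_clusters * cfg$cells_per_cluster
    gene_id <- sprintf("gene%05d", seq_len(cfg$n_genes))
    cell_id <- sprintf("cell%05d", seq_len(n_cells))
    cluster <- factor(rep(sprintf("cluster%02d", seq_len(cfg$n_clusters)),
                          each = cfg$cells_per_cluster))

    marker_cluster <- rep(NA_integer_, cfg$n_genes)
    idx <- seq_len(cfg$markers_per_cluster * cfg$n_clusters)
    marker_cluster[idx] <- rep(seq_len(cfg$n_clusters),
                               each = cfg$markers_per_cluster)

    animal <- integer(n_cells)
    for (k in seq_len(cfg$n_clusters)) {  # cycle animals within a cluster
      pos <- which(as.integer(cluster) == k)
      animal[pos] <- rep(seq_len(cfg$n_animals), length.out = length(pos))
    }
    sex <- cfg$sex_assignment[animal]
    platform <- c("STRT", "SS2")[(animal %% 2L) + 1L]

    # log-normal baseline means: deep-coverage regime in which a tail of
    # ubiquitous high-expression genes is detected in every cell, as in
    # well-sequenced DRG data (anchors median-of-ratios size factors)
    base_mean <- rlnorm(cfg$n_genes, meanlog = 0.5, sdlog = 1.5)
    depth <- rlnorm(n_cells, meanlog = 0, sdlog = cfg$library_size_spread)
    animal_shift <- if (cfg$animal_effect_sd > 0)
      rnorm(cfg$n_animals, 0, cfg$animal_effect_sd) else numeric(cfg$n_animals)
    cell_shift <- exp(animal_shift[animal] + cfg$sex_effect * (sex == "M"))

    fc <- matrix(1, nrow = cfg$n_genes, ncol = cfg$n_clusters)
    for (k in seq_len(cfg$n_clusters)) {
      fc[which(marker_cluster == k), k] <- cfg$marker_fold_change
    }
    mu <- (base_mean * fc[, as.integer(cluster)]) *
      rep(depth * cell_shift, each = cfg$n_genes)
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
      nrow = cfg$n_genes, dimnames = list(gene_id, cell_id)
    )

    marker_sets <- lapply(seq_len(cfg$n_clusters), function(k)
      gene_id[which(marker_cluster == k)])
    names(marker_sets) <- levels(cluster)

    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                         "CsparseMatrix")),
      colData = S4Vectors::DataFrame(
        cell_id = cell_id,
        cluster = cluster,
        animal = sprintf("animal%02d", animal),
        sex = sex,
        platform = platform,
        row.names = cell_id
      ),
      rowData = S4Vectors::DataFrame(
        gene_id = gene_id,
        marker_cluster = ifelse(is.na(marker_cluster), NA_character_,
                                sprintf("cluster%02d", marker_cluster)),
        row.names = gene_id
      )
    )
    S4Vectors::metadata(sce)$marker_sets <- marker_sets
    S4Vectors::metadata(sce)$config <- unclass(cfg)
    sce
  })
}

#' Configuration for gene-level GWAS summary simulation
#'
#' Stands in for gene-level association output (e.g. MAGMA z-statistics):
#' non-causal genes draw z from N(0, 1), genes in `causal_set` from
#' N(`causal_shift`, 1).
#'
#' @param genes character vector of gene ids (the universe); if `NULL`,
#'   generated as `gene00001..` from `n_genes` to match [simulate_counts()].
#' @param n_genes universe size when `genes` is `NULL`.
#' @param causal_set character vector, must be a subset of the universe.
#' @param causal_shift mean shift of z for causal genes.
#' @param seed integer seed.
#' @export
gwas_sim_config <- function(genes = NULL, n_genes = NULL,
                            causal_set = character(), causal_shift = 0,
                            seed = 1L) {
  if (is.null(genes)) {
    n_genes <- check_count(n_genes, "n_genes")
    genes <- sprintf("gene%05d", seq_len(n_genes))
  }
  if (anyDuplicated(genes)) stop("`genes` must be unique", call. = FALSE)
  missing <- setdiff(causal_set, genes)
  if (length(missing)) {
    stop("`causal_set` contains genes outside the universe: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(genes = as.character(genes),
                 causal_set = as.character(causal_set),
                 causal_shift = as.numeric(causal_shift),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "gwas_sim_config")
}

#' Simulate gene-level GWAS z-statistics
#'
#' @param cfg a [gwas_sim_config()].
#' @return A data.frame with columns `gene_id`, `zstat`, `n_snps`.
#' @export
simulate_gwas_gene_stats <- function(cfg) {
  if (!inherits(cfg, "gwas_sim_config"))
    cfg <- do.call(gwas_sim_config, as.list(cfg))
  with_seed(cfg$seed, {
    z <- rnorm(length(cfg$genes))
    z[cfg$genes %in% cfg$causal_set] <-
      z[cfg$genes %in% cfg$causal_set] + cfg$causal_shift
    data.frame(gene_id = cfg$genes, zstat = z,
               n_snps = sample(5:50, length(cfg$genes), replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a pathway collection (GMT-writable)
#'
#' Uniformly samples gene sets from `universe`, with sizes uniform on
#' `size_range`.
#'
#' @param universe character vector of gene ids.
#' @param n_pathways number of sets.
#' @param size_range length-2 integer vector (min, max) set size; must lie
#'   within `[1, length(universe)]`.
#' @param seed integer seed.
#' @return Named list of character vectors (class `pathway_db`), one entry
#'   per pathway, with a `description` attribute per set.
#' @export
simulate_pathways <- function(universe, n_pathways, size_range, seed = 1L) {
  n_pathways <- check_count(n_pathways, "n_pathways")
  if (length(size_range) != 2L || size_range[1] > size_range[2] ||
      size_range[1] < 1L || size_range[2] > length(universe)) {
    stop("`size_range` must be (min, max) within [1, |universe|]",
         call. = FALSE)
  }
  with_seed(seed, {
    size_pool <- seq(size_range[1], size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_pathways,
                                  replace = TRUE)]
    db <- lapply(sizes, function(s) sort(sample(universe, s)))
    names(db) <- sprintf("pathway%04d", seq_len(n_pathways))
    structure(db, class = "pathway_db")
  })
}

#' Simulate gene coordinates and a SNP map for annotation building
#'
#' Places genes on `n_chrom` chromosomes with 0-based half-open coordinates
#' and scatters SNPs uniformly along each chromosome; this is the toy input
#' for [build_gene_set_annotation()].
#'
#' @param genes character vector of gene ids.
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_snps total number of SNPs.
#' @param gene_length fixed gene footprint in bp.
#' @param seed integer seed.
#' @return List with `genes` (gene_id, chrom, start, end) and `snps`
#'   (snp_id, chrom, pos) data.frames.
#' @export
simulate_snp_map <- function(genes, n_chrom = 2, chrom_length = 1e6,
                             n_snps = 1000, gene_length = 2000, seed = 1L) {
  n_chrom <- check_count(n_chrom, "n_chrom")
  n_snps <- check_count(n_snps, "n_snps")
  with_seed(seed, {
    chrom <- sprintf("chr%d", sample(seq_len(n_chrom), length(genes),
                                     replace = TRUE))
    start <- floor(runif(length(genes), 0, chrom_length - gene_length))
    gene_tab <- data.frame(gene_id = genes, chrom = chrom,
                           start = as.integer(start),
                           end = as.integer(start + gene_length),
                           stringsAsFactors = FALSE)
    snp_chrom <- sprintf("chr%d", sample(seq_len(n_chrom), n_snps,
                                         replace = TRUE))
    snp_tab <- data.frame(snp_id = sprintf("rs%06d", seq_len(n_snps)),
                          chrom = snp_chrom,
                          pos = as.integer(floor(runif(n_snps, 0,
                                                       chrom_length))),
                          stringsAsFactors = FALSE)
    list(genes = gene_tab, snps = snp_tab)
  })
}
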