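# Readers and writers for the pipeline's on-disk formats, plus the
# end-to-end driver. Conventions: MatrixMarket with 1-based indices on
# disk; BED-style gene coordinates 0-based half-open; TSVs are
# tab-separated UTF-8 with '.' decimals; TSV writers emit a '#' header
# comment carrying the tool version, which readers skip.

tsv_header <- function() {
  sprintf("# paincell %s",
          as.character(utils::packageVersion("paincell")))
}

write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header(), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Write / read a count matrix with cell metadata
#'
#' `write_counts()` stores a SingleCellExperiment as `matrix.mtx`
#' (MatrixMarket, 1-based indices), `genes.tsv` (gene_id) and `cells.tsv`
#' (cell_id, cluster, animal, sex, platform) in `dir`; `read_counts()`
#' inverts it exactly. Dimension mismatches between the matrix and its
#' sidecars are an error reporting both counts.
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param dir directory (created if needed).
#' @return `write_counts()` returns `dir` invisibly; `read_counts()`
#'   returns a SingleCellExperiment.
#' @export
write_counts <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  write_tsv(data.frame(gene_id = rownames(sce)),
            file.path(dir, "genes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  cd$cluster <- as.character(cd$cluster)
  write_tsv(cd, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_counts
#' @export
read_counts <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  m <- Matrix::readMM(mtx_path)
  # cross-check the declared entry count; a truncated file must not read
  # back as silent zeros
  hdr <- readLines(mtx_path, n = 50)
  dims <- scan(text = hdr[grep("^%", hdr, invert = TRUE)[1]], quiet = TRUE)
  if (length(m@x) != dims[3]) {
    stop("matrix.mtx is truncated: header declares ", dims[3],
         " entries but ", length(m@x), " were read", call. = FALSE)
  }
  genes <- read_tsv(file.path(dir, "genes.tsv"))
  cells <- read_tsv(file.path(dir, "cells.tsv"))
  if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m)) {
    stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
         " but sidecars list ", nrow(genes), " genes and ", nrow(cells),
         " cells", call. = FALSE)
  }
  dimnames(m) <- list(genes$gene_id, cells$cell_id)
  cells$cluster <- factor(cells$cluster)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(m, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(cells, row.names = cells$cell_id))
}

#' Write / read gene-level GWAS statistics
#' @param stats data.frame `gene_id`, `zstat`, `n_snps`.
#' @param path TSV path.
#' @export
write_gwas_stats <- function(stats, path) write_tsv(stats, path)

#' @rdname write_gwas_stats
#' @export
read_gwas_stats <- function(path) read_tsv(path)

#' Write / read gene sets in GMT format
#'
#' One pathway per line: name, description, then member genes, all
#' tab-separated. The reader tolerates a missing description field (lines
#' with only a name and genes).
#'
#' @param db named list of character vectors.
#' @param path GMT path.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db), function(id) {
    desc <- attr(db[[id]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(id, desc, db[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # field 2 is the (possibly empty) description; genes start at field 3
  db <- lapply(parts, function(p) {
    g <- p[-(1:2)]
    g[nzchar(g)]
  })
  names(db) <- vapply(parts, `[`, character(1), 1)
  structure(db, class = "pathway_db")
}

#' Write gene coordinates as BED (0-based half-open)
#' @param gene_coords data.frame `gene_id`, `chrom`, `start`, `end`.
#' @param path BED path.
#' @export
write_gene_bed <- function(gene_coords, path) {
  write.table(gene_coords[, c("chrom", "start", "end", "gene_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  names(d)[1:4] <- c("chrom", "start", "end", "gene_id")
  d[, c("gene_id", "chrom", "start", "end")]
}

#' Write an annotation track in LDSC-style `.annot` text form
#'
#' SNP order is preserved; membership columns are 0/1.
#' @param track output of [build_gene_set_annotation()].
#' @param path output path.
#' @export
write_annot <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-annotation heritability coefficient estimates
#' @param path TSV with columns `cell_type`, `phenotype`, `coefficient`,
#'   `se`.
#' @export
read_heritability_estimates <- function(path) read_tsv(path)

#' Pipeline configuration with the package's documented defaults
#'
#' Collects every tunable the end-to-end driver uses: the top fraction
#' `q` (0.10), the FDR gate (0.20), `k_folds` (3), permutation count `B`,
#' annotation `window` (100 kb), the GWAS shift planted in the target
#' cluster's markers, and one master `seed` from which all stage seeds are
#' drawn. The object is a plain list of scalars and round-trips through
#' JSON unchanged.
#'
#' @param q top fraction of cluster-specific genes.
#' @param fdr FDR gate for the gene-area stage.
#' @param k_folds cross-validation folds.
#' @param B permutations for the identity scorer's significance test.
#' @param window annotation window, bp.
#' @param causal_shift mean z-shift of GWAS signal planted in the target
#'   cluster's markers.
#' @param sim a [sim_config()] list for the expression simulator.
#' @param seed master seed.
#' @export
pipeline_config <- function(q = 0.10, fdr = 0.20, k_folds = 3, B = 99,
                            window = 100000, causal_shift = 3,
                            sim = sim_config(), seed = 1L) {
  list(q = q, fdr = fdr, k_folds = k_folds, B = check_count(B, "B"),
       window = window, causal_shift = causal_shift,
       sim = unclass(sim), seed = check_count(seed, "seed", min = 0L))
}

#' Run the whole pipeline on synthetic data
#'
#' Executes simulate -> specificity -> classify -> enrich -> pathways ->
#' meta in order and returns a machine-readable report of every stage's
#' headline numbers. Fully deterministic given the config seeds. GWAS
#' signal is planted in the first cluster's marker genes, so the report's
#' enrichment block shows what end-to-end recovery looks like.
#'
#' @param config a [pipeline_config()].
#' @param out_json optional path; when given the report is serialized
#'   there.
#' @return Nested list report (invisibly serialized to `out_json` if
#'   requested).
#' @export
run_pipeline <- function(config = pipeline_config(), out_json = NULL) {
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max %/% 2L, 6L))
  sim <- do.call(sim_config, c(config$sim[setdiff(names(config$sim),
                                                  "seed")],
                               list(seed = seeds[1])))
  sce <- simulate_counts(sim)
  clusters <- levels(SummarizedExperiment::colData(sce)$cluster)
  sf <- estimate_size_factors(sce)

  spec_tabs <- lapply(clusters, function(cl)
    regress_cluster_specificity(sce, cl, size_factors = sf, q = config$q))
  names(spec_tabs) <- clusters
  top_sets <- lapply(spec_tabs, select_top_fraction, q = config$q)

  # classify: platform 1 cells as reference, platform 2 as query
  cd <- SummarizedExperiment::colData(sce)
  platforms <- unique(cd$platform)
  ref_cells <- cd$platform == platforms[1]
  markers <- head(rank_markers(sce)$gene_id, 100)
  feats <- preprocess_features(
    SummarizedExperiment::assay(sce, "counts")[, ref_cells, drop = FALSE],
    SummarizedExperiment::assay(sce, "counts")[, !ref_cells, drop = FALSE],
    markers)
  cv <- cross_validate(feats$reference, cd$cluster[ref_cells],
                       k = config$k_folds, seed = seeds[2])
  perm <- suppressWarnings(permutation_significance(
    feats$reference, cd$cluster[ref_cells], feats$query,
    cd$cluster[!ref_cells], B = config$B, seed = seeds[3]))

  # enrich: plant GWAS signal in cluster 1's markers
  causal <- S4Vectors::metadata(sce)$marker_sets[[1]]
  gwas <- simulate_gwas_gene_stats(gwas_sim_config(
    genes = rownames(sce), causal_set = causal,
    causal_shift = config$causal_shift, seed = seeds[4]))
  area_tabs <- lapply(clusters, function(cl)
    gene_area_test(spec_tabs[[cl]], gwas, cluster_id = cl,
                   fdr = config$fdr))
  names(area_tabs) <- clusters
  gated <- lapply(area_tabs, function(t) t$gene_id[t$significant])

  # pathways on the target cluster's gated list
  universe <- area_tabs[[1]]$gene_id
  db <- filter_pathways_by_size(
    simulate_pathways(rownames(sce), n_pathways = 50,
                      size_range = c(10, 200), seed = seeds[5]),
    universe)
  if (length(gated[[1]])) {
    pw <- hypergeom_overrepresentation(gated[[1]], db, universe)
  } else {
    warning("no genes pass the FDR gate; pathway stage skipped")
    pw <- hypergeom_overrepresentation(character(0), db, universe)
  }

  # annotation track for the target cluster's top set
  maps <- simulate_snp_map(rownames(sce), seed = seeds[6])
  annot <- build_gene_set_annotation(top_sets[[1]], maps$genes, maps$snps,
                                     window = config$window)

  # meta-analysis of toy per-phenotype heritability coefficients
  est <- with_seed(seeds[6], data.frame(
    cell_type = rep(clusters, each = 3),
    phenotype = rep(c("back", "neck", "knee"), length(clusters)),
    coefficient = rnorm(3 * length(clusters), 0, 0.1),
    se = runif(3 * length(clusters), 0.05, 0.15)))
  meta <- meta_analyze_heritability(est)

  report <- list(
    n_cells = ncol(sce), n_genes = nrow(sce),
    size_factor_range = range(sf),
    top_set_size = lengths(top_sets)[[1]],
    cv_mean_accuracy = cv$mean_accuracy,
    permutation = perm,
    bessel_sigma = vapply(area_tabs,
                          function(t) attr(t, "null")$sigma, numeric(1)),
    n_significant = lengths(gated),
    pathway_top = head(pw, 5),
    n_snps_flagged = sum(annot$annot),
    meta = meta
  )
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  report
}
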