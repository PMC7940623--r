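# The genetics stage: gene "areas" joining cluster specificity to
# gene-level GWAS statistics, the product-of-normals (Bessel K0) null,
# FDR gating, SNP annotation tracks, leave-one-site-out bookkeeping, and
# fixed-effect meta-analysis of heritability coefficients.

#' Gene areas: cluster specificity times GWAS association
#'
#' For genes shared between a cluster-specificity table and a gene-level
#' GWAS table, the signed "area" spanned by a gene in the
#' specificity-by-GWAS scatter is the product of its two scores. Only
#' genes with positive cell-type specificity are retained (specificity
#' below zero means depletion, not enrichment, in the cell type); the
#' number dropped is recorded in `attr(, "n_dropped_nonpositive")`.
#'
#' @param spec_table output of [regress_cluster_specificity()] (columns
#'   `gene_id`, `t_statistic`).
#' @param gwas_stats data.frame with `gene_id` and `zstat`.
#' @param cluster_id optional label stored in the output.
#' @return data.frame: `gene_id`, `z_cell`, `z_gwas`, `area`.
#' @export
compute_gene_area <- function(spec_table, gwas_stats, cluster_id = NULL) {
  merged <- merge(spec_table[, c("gene_id", "t_statistic")],
                  gwas_stats[, c("gene_id", "zstat")], by = "gene_id")
  if (!nrow(merged)) {
    stop("no genes shared between the specificity table and GWAS stats",
         call. = FALSE)
  }
  keep <- merged$t_statistic > 0
  n_dropped <- sum(!keep)
  merged <- merged[keep, , drop = FALSE]
  out <- data.frame(gene_id = merged$gene_id,
                    z_cell = merged$t_statistic,
                    z_gwas = merged$zstat,
                    area = merged$t_statistic * merged$zstat,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(cluster_id)) out$cluster_id <- cluster_id
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "n_dropped_nonpositive") <- n_dropped
  out
}

# log density of the product-of-normals null at |z|, scale sigma:
# f(z) = K0(|z|/sigma) / (pi * sigma); besselK's exponential scaling keeps
# the log finite for large |z|.
bessel_log_density <- function(z, sigma) {
  x <- abs(z) / sigma
  log(besselK(x, 0, expon.scaled = TRUE)) - x - log(pi * sigma)
}

#' Fit the Bessel (product-of-normals) null to gene areas
#'
#' The product of two independent zero-mean normals with scales s1, s2 has
#' density K0(|z| / sigma) / (pi * sigma) with sigma = s1 * s2, where K0 is
#' the modified Bessel function of the second kind, order 0. The single
#' scale parameter is fitted by maximum likelihood with a bounded 1-D
#' search (tolerance 1e-6 on sigma); location is fixed at 0 by symmetry.
#' Areas exactly equal to zero sit on the density's log-singularity and
#' are excluded from the fit with a warning.
#'
#' @param areas numeric vector of gene areas; at least 50, not all zero.
#' @return Object of class `bessel_null` with elements `sigma`, `n`, and
#'   `logLik`.
#' @export
fit_bessel_null <- function(areas) {
  areas <- as.numeric(areas)
  if (length(areas) < 50) stop("need >= 50 areas to fit the null",
                               call. = FALSE)
  nz <- areas[areas != 0]
  if (!length(nz) || sd(nz) == 0) stop("degenerate areas: no spread",
                                       call. = FALSE)
  if (length(nz) < length(areas)) {
    warning(length(areas) - length(nz),
            " zero area(s) excluded from the fit (density singularity)")
  }
  s0 <- sd(nz)
  nll <- function(sigma) -sum(bessel_log_density(nz, sigma))
  opt <- optimize(nll, interval = c(s0 / 100, s0 * 100), tol = 1e-8)
  structure(list(sigma = opt$minimum, n = length(nz),
                 logLik = -opt$objective),
            class = "bessel_null")
}

#' @export
print.bessel_null <- function(x, ...) {
  cat("Product-of-normals (Bessel K0) null: sigma =",
      format(x$sigma, digits = 6), "fitted on", x$n, "areas\n")
  invisible(x)
}

# (1/pi) * integral of K0 from 0 to t, by adaptive quadrature split at
# u = 1 (z = sigma) to keep the log-singularity at 0 in its own panel.
bessel_mass_0_to <- function(t) {
  k0 <- function(u) besselK(u, 0)
  if (t <= 0) return(0)
  m <- integrate(k0, 0, min(t, 1), abs.tol = 1e-10)$value
  if (t > 1) m <- m + integrate(k0, 1, t, abs.tol = 1e-10)$value
  m / pi
}

#' Lower-tail p-value under the Bessel null
#'
#' p = integral of the fitted density from minus infinity to -|area|; by
#' symmetry this is 0.5 minus the mass between 0 and |area|, so p lies in
#' (0, 0.5], equals 0.5 exactly at area = 0, and decreases monotonically
#' in |area|.
#'
#' @param null a [fit_bessel_null()] object.
#' @param area numeric vector of areas.
#' @return Numeric vector of p-values.
#' @export
area_pvalue <- function(null, area) {
  stopifnot(inherits(null, "bessel_null"))
  vapply(area, function(a) {
    if (a == 0) return(0.5)
    p <- 0.5 - bessel_mass_0_to(abs(a) / null$sigma)
    max(p, 1e-300)
  }, numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin validating wrapper
#' around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Full gene-area test for one cluster
#'
#' Convenience wrapper: computes areas ([compute_gene_area()]), fits the
#' Bessel null to them, assigns tail p-values and BH q-values, and flags
#' genes passing the FDR gate (default 20%).
#'
#' @inheritParams compute_gene_area
#' @param fdr FDR gate for the `significant` flag.
#' @return data.frame with `gene_id`, `z_cell`, `z_gwas`, `area`, `p`,
#'   `q`, `significant`; the fitted null in `attr(, "null")`.
#' @export
gene_area_test <- function(spec_table, gwas_stats, cluster_id = NULL,
                           fdr = 0.20) {
  res <- compute_gene_area(spec_table, gwas_stats, cluster_id)
  null <- fit_bessel_null(res$area)
  res$p <- area_pvalue(null, res$area)
  res$q <- bh_fdr(res$p)
  res$significant <- res$q <= fdr
  attr(res, "null") <- null
  res
}

#' Binary SNP annotation track for a gene set
#'
#' Flags each SNP that falls in the windowed footprint of any gene in the
#' set: position in \[start - window, end + window) on the same chromosome
#' (coordinates 0-based half-open). Overlapping genes flag a SNP once. An
#' optional control gene list produces a second track built identically.
#' SNP order is preserved.
#'
#' @param gene_set character vector of gene ids.
#' @param gene_coords data.frame `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param snp_map data.frame `snp_id`, `chrom`, `pos` (0-based).
#' @param window flanking window in bp (default 100000).
#' @param control_set optional control gene list.
#' @return data.frame: `snp_id`, `chrom`, `pos`, `annot` (0/1) and, with a
#'   control set, `control` (0/1).
#' @export
build_gene_set_annotation <- function(gene_set, gene_coords, snp_map,
                                      window = 100000, control_set = NULL) {
  if (window < 0) stop("`window` must be >= 0", call. = FALSE)
  snp_gr <- GenomicRanges::GRanges(
    snp_map$chrom, IRanges::IRanges(start = snp_map$pos + 1L, width = 1L))

  flag_track <- function(set) {
    present <- set %in% gene_coords$gene_id
    if (!all(present)) {
      warning(sum(!present), " gene(s) in the set have no coordinates ",
              "and are excluded: ",
              paste(head(set[!present], 5), collapse = ", "))
      set <- set[present]
    }
    if (!length(set)) return(integer(nrow(snp_map)))
    gc <- gene_coords[gene_coords$gene_id %in% set, , drop = FALSE]
    # 0-based half-open [start - w, end + w) -> 1-based closed ranges
    gr <- GenomicRanges::GRanges(
      gc$chrom,
      IRanges::IRanges(start = pmax(gc$start - window, 0) + 1L,
                       end = gc$end + window))
    as.integer(IRanges::overlapsAny(snp_gr, gr))
  }

  out <- data.frame(snp_id = snp_map$snp_id, chrom = snp_map$chrom,
                    pos = snp_map$pos, annot = flag_track(gene_set),
                    stringsAsFactors = FALSE)
  if (!is.null(control_set)) out$control <- flag_track(control_set)
  out
}

#' Leave-one-site-out GWAS design
#'
#' For pain-site comorbidity control, every site is re-analyzed once per
#' other site, excluding cases comorbid for that other site: all ordered
#' (target, excluded) pairs with target != excluded, n^2 - n runs for n
#' sites.
#'
#' @param sites character vector of site names (>= 2, unique).
#' @return data.frame with columns `target_site`, `excluded_site`.
#' @export
loso_design <- function(sites) {
  if (anyDuplicated(sites)) stop("duplicate site names", call. = FALSE)
  if (length(sites) < 2L) stop("need >= 2 sites", call. = FALSE)
  grid <- expand.grid(excluded_site = sites, target_site = sites,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, 2:1]
  grid <- grid[grid$target_site != grid$excluded_site, , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Minimum effective minor-allele count
#'
#' The product of the minor-allele-frequency floor, the imputation INFO
#' floor, the sample size, and the ploidy factor — the expected count of
#' well-imputed minor alleles at the filtering threshold.
#'
#' @param maf_min minor-allele-frequency threshold (e.g. 0.001).
#' @param info_min INFO-score threshold (e.g. 0.9).
#' @param n sample size.
#' @param ploidy_factor alleles per individual (2 for autosomes).
#' @return The effective count (a real number).
#' @export
effective_mac <- function(maf_min, info_min, n, ploidy_factor = 2) {
  for (nm in c("maf_min", "info_min", "n", "ploidy_factor")) {
    check_positive(get(nm), nm)
  }
  maf_min * info_min * n * ploidy_factor
}

#' Fixed-effect meta-analysis of heritability coefficients
#'
#' Inverse-variance (equivalently inverse-squared-standard-error) pooling:
#' weights 1/se^2, pooled coefficient the weighted mean, pooled
#' se = (sum of weights)^(-1/2), z = coefficient / se, two-sided normal p.
#' With a `cell_type` column, estimates are pooled per cell type across
#' phenotypes.
#'
#' @param estimates data.frame with `coefficient` and `se` (> 0) columns,
#'   optionally `cell_type`.
#' @return data.frame: `cell_type` (if supplied), `coefficient`, `se`,
#'   `z`, `p`, `k` (number pooled).
#' @export
meta_analyze_heritability <- function(estimates) {
  if (!nrow(estimates)) stop("need >= 1 estimate", call. = FALSE)
  if (any(estimates$se <= 0)) stop("all `se` must be > 0", call. = FALSE)
  pool <- function(d) {
    w <- 1 / d$se^2
    beta <- sum(w * d$coefficient) / sum(w)
    se <- 1 / sqrt(sum(w))
    data.frame(coefficient = beta, se = se, z = beta / se,
               p = 2 * pnorm(-abs(beta / se)), k = nrow(d))
  }
  if ("cell_type" %in% names(estimates)) {
    parts <- split(estimates, estimates$cell_type)
    out <- do.call(rbind, lapply(parts, pool))
    out <- cbind(cell_type = names(parts), out)
    rownames(out) <- NULL
    out
  } else {
    pool(estimates)
  }
}
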