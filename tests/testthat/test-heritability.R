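test_that("gene areas are products, gated on positive specificity", {
  spec_tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                         t_statistic = c(2.0, -1.0, 1.5))
  gwas <- data.frame(gene_id = c("g1", "g2", "g3"),
                     zstat = c(1.5, 2.0, 0))
  res <- compute_gene_area(spec_tab, gwas)
  expect_equal(res$area[res$gene_id == "g1"], 3.0)
  expect_false("g2" %in% res$gene_id)  # non-positive specificity dropped
  expect_equal(attr(res, "n_dropped_nonpositive"), 1L)
  expect_equal(res$area[res$gene_id == "g3"], 0)
  expect_error(compute_gene_area(spec_tab,
                                 data.frame(gene_id = "zz", zstat = 1)),
               "no genes shared")
})

test_that("the Bessel null recovers the product-normal scale", {
  set.seed(101)
  areas <- rnorm(10000) * rnorm(10000)    # true sigma = 1
  null <- fit_bessel_null(areas)
  expect_gt(null$sigma, 0.95)
  expect_lt(null$sigma, 1.05)
  # scale equivariance
  null3 <- fit_bessel_null(areas * 3)
  expect_equal(null3$sigma, 3 * null$sigma, tolerance = 1e-4)
  expect_error(fit_bessel_null(areas[1:10]), ">= 50")
  expect_error(fit_bessel_null(rep(2, 100)), "degenerate")
})

test_that("the fitted density integrates to one", {
  null <- structure(list(sigma = 1.7), class = "bessel_null")
  f <- function(z) besselK(abs(z) / null$sigma, 0) / (pi * null$sigma)
  total <- 2 * (integrate(f, 0, null$sigma, abs.tol = 1e-12)$value +
                integrate(f, null$sigma, Inf, abs.tol = 1e-12)$value)
  expect_equal(total, 1, tolerance = 1e-6)
  # half-line mass of K0 has the closed form pi/2
  k0_mass <- integrate(function(x) besselK(x, 0), 0, 1,
                       abs.tol = 1e-12)$value +
    integrate(function(x) besselK(x, 0), 1, Inf, abs.tol = 1e-12)$value
  expect_equal(k0_mass, pi / 2, tolerance = 1e-8)
})

test_that("area p-values are 0.5 at zero and strictly decreasing in |area|", {
  null <- structure(list(sigma = 1), class = "bessel_null")
  expect_identical(area_pvalue(null, 0), 0.5)
  grid <- c(0.01, 0.1, 0.5, 1, 2, 5, 10, 20)
  p <- area_pvalue(null, grid)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 0.5))
  expect_equal(area_pvalue(null, -1), area_pvalue(null, 1))  # symmetry
  # sigma = 1, area = 1 sits near the worked value 0.10
  expect_equal(area_pvalue(null, 1), 0.1045, tolerance = 1e-3)
})

test_that("null areas give calibrated tail p-values after fitting", {
  set.seed(55)
  areas <- rnorm(20000) * rnorm(20000)
  null <- fit_bessel_null(areas)
  p <- area_pvalue(null, areas)
  # P(p <= t) = 2t for t <= 0.5 under the null (one-sided symmetric tail)
  for (t in c(0.05, 0.1, 0.25)) {
    frac <- mean(p <= t)
    se <- sqrt(2 * t * (1 - 2 * t) / length(areas))
    expect_lt(abs(frac - 2 * t), 3 * se + 1e-3)
  }
})

test_that("BH adjustment matches hand computation", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("annotation tracks respect half-open windowed footprints", {
  coords <- data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
                       start = c(1000, 1500), end = c(2000, 2500))
  snps <- data.frame(snp_id = paste0("rs", 1:6),
                     chrom = c("chr1", "chr1", "chr1", "chr1", "chr1",
                               "chr2"),
                     pos = c(900, 2100, 999, 1000, 1800, 1500))
  t100 <- build_gene_set_annotation("gA", coords, snps, window = 100)
  expect_equal(t100$annot, c(1, 0, 1, 1, 1, 0))  # 900 in, 2100 out
  t0 <- build_gene_set_annotation("gA", coords, snps, window = 0)
  expect_equal(t0$annot[3:4], c(0, 1))           # 999 out, 1000 in
  # overlapping genes flag a SNP once; union stays binary
  both <- build_gene_set_annotation(c("gA", "gB"), coords, snps, window = 0)
  expect_true(all(both$annot %in% c(0L, 1L)))
  expect_equal(both$annot[5], 1L)                # covered by both genes
  # order invariance of gene and SNP input
  shuf <- build_gene_set_annotation(c("gB", "gA"),
                                    coords[2:1, ], snps, window = 0)
  expect_equal(shuf$annot, both$annot)
  expect_warning(
    res <- build_gene_set_annotation(c("gA", "ghost"), coords, snps, 0),
    "no coordinates")
  expect_equal(res$annot, t0$annot)
  # control track built identically
  ctrl <- build_gene_set_annotation("gA", coords, snps, window = 0,
                                    control_set = "gB")
  expect_equal(ctrl$control,
               build_gene_set_annotation("gB", coords, snps, 0)$annot)
})

test_that("leave-one-site-out design enumerates ordered pairs", {
  d3 <- loso_design(c("a", "b", "c"))
  expect_equal(nrow(d3), 6)
  expect_setequal(paste(d3$target_site, d3$excluded_site),
                  c("a b", "a c", "b a", "b c", "c a", "c b"))
  expect_equal(nrow(loso_design(c("x", "y"))), 2)
  expect_error(loso_design(c("a", "a")), "duplicate")
  expect_error(loso_design("a"), ">= 2")
})

test_that("effective minor-allele count is the plain product", {
  expect_equal(effective_mac(0.5, 1, 2, 2), 2.0)
  expect_equal(effective_mac(0.01, 0.9, 1000, 2), 18.0)
  expect_error(effective_mac(-0.1, 0.9, 10, 2), "maf_min")
})

test_that("fixed-effect meta-analysis matches hand values and metafor", {
  two <- data.frame(coefficient = c(1, 1), se = c(1, 1))
  m <- meta_analyze_heritability(two)
  expect_equal(m$coefficient, 1)
  expect_equal(m$se, 1 / sqrt(2), tolerance = 1e-12)
  m2 <- meta_analyze_heritability(data.frame(coefficient = c(0, 2),
                                             se = c(1, 1)))
  expect_equal(m2$coefficient, 1)
  expect_equal(m2$se, 1 / sqrt(2), tolerance = 1e-12)
  one <- meta_analyze_heritability(data.frame(coefficient = 0.3, se = 0.07))
  expect_equal(one$coefficient, 0.3)
  expect_equal(one$se, 0.07)
  # k identical estimates pool to (beta, se / sqrt(k))
  k5 <- data.frame(coefficient = rep(0.4, 5), se = rep(0.2, 5))
  mk <- meta_analyze_heritability(k5)
  expect_equal(mk$coefficient, 0.4)
  expect_equal(mk$se, 0.2 / sqrt(5))
  # independent cross-check against metafor's fixed-effect model
  est <- data.frame(coefficient = c(0.1, 0.3, -0.2),
                    se = c(0.1, 0.2, 0.15))
  ours <- meta_analyze_heritability(est)
  ref <- metafor::rma(yi = est$coefficient, sei = est$se, method = "FE")
  expect_equal(ours$coefficient, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$se, ref$se, tolerance = 1e-10)
  expect_error(meta_analyze_heritability(data.frame(coefficient = 1,
                                                    se = 0)), "se")
  # per-cell-type pooling preserves the pooled-se bound
  grp <- data.frame(cell_type = c("PEP1", "PEP1", "NP2"),
                    coefficient = c(0.2, 0.4, 0.1),
                    se = c(0.1, 0.3, 0.2))
  mg <- meta_analyze_heritability(grp)
  expect_equal(nrow(mg), 2)
  expect_lte(mg$se[mg$cell_type == "PEP1"], 0.1)
})
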