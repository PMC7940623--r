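test_that("median-of-ratios size factors match the hand-worked example", {
  # genes (10, 30, 5) vs the exactly doubled sample: geometric means are
  # sqrt(2) * (10, 30, 5)/sqrt(2)... each ratio is 1/sqrt(2) resp. sqrt(2)
  m <- cbind(s1 = c(10, 30, 5), s2 = c(20, 60, 10))
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # identical samples
  expect_equal(unname(estimate_size_factors(cbind(c(3, 7), c(3, 7)))),
               c(1, 1))
})

test_that("size factors are equivariant and order-invariant", {
  set.seed(11)
  m <- matrix(rpois(200, 20) + 1, nrow = 20)
  sf <- estimate_size_factors(m)
  m3 <- m; m3[, 2] <- m3[, 2] * 3
  sf3 <- estimate_size_factors(m3)
  # factors are defined up to the shared geometric-mean reference, so
  # equivariance holds exactly on factor ratios
  expect_equal(sf3[2] / sf3[1], 3 * sf[2] / sf[1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sf3[-2] / sf3[1], sf[-2] / sf[1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(estimate_size_factors(m[sample(20), ])), unname(sf))
})

test_that("size factors agree with DESeq2's estimator", {
  set.seed(5)
  m <- matrix(rpois(300, 30) + 1, nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("strict mode errors when no gene is expressed everywhere", {
  m <- cbind(c(0, 5), c(3, 0))
  expect_error(estimate_size_factors(m), "pseudo-reference")
})

test_that("membership regression matches the closed-form OLS oracle", {
  # 6 cells: 3 in-cluster at 10, 3 out at 0; unit size factors, same sex
  counts <- rbind(toy = c(10, 10, 10, 0, 0, 0),
                  noisy = c(9, 12, 10, 1, 0, 2),
                  flat = rep(4, 6))
  cov <- data.frame(cluster = rep(c("A", "B"), each = 3),
                    sex = rep("F", 6))
  expect_warning(
    tab <- regress_cluster_specificity(counts, "A", size_factors = rep(1, 6),
                                       covariates = cov),
    "constant design column")
  # the cleanly separated gene: coefficient is the in/out mean difference
  # on the transformed scale (and the fit is exact, so t diverges)
  row <- tab[tab$gene_id == "toy", ]
  expect_equal(row$coefficient, log1p(10), tolerance = 1e-12)
  expect_identical(row$t_statistic, Inf)
  # normal-equation oracle on the log1p scale for the noisy gene
  y <- log1p(counts["noisy", ])
  X <- cbind(1, c(1, 1, 1, 0, 0, 0))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (6 - 2)
  t_oracle <- beta[2] / sqrt(s2 * solve(t(X) %*% X)[2, 2])
  row2 <- tab[tab$gene_id == "noisy", ]
  expect_equal(row2$coefficient, unname(beta[2]), tolerance = 1e-12)
  expect_equal(row2$t_statistic, unname(t_oracle), tolerance = 1e-12)
  # a gene identical in all cells scores exactly zero
  expect_equal(tab$t_statistic[tab$gene_id == "flat"], 0)
})

test_that("regression agrees with lm() on simulated data with covariates", {
  sce <- default_sce()
  sf <- estimate_size_factors(sce)
  tab <- regress_cluster_specificity(sce, "cluster02", size_factors = sf)
  cd <- sce_coldata(sce)
  g <- tab$gene_id[5]
  y <- log1p(sce_counts(sce)[g, ] / sf)
  fit <- lm(y ~ member + sex,
            data = data.frame(y = y,
                              member = as.numeric(cd$cluster == "cluster02"),
                              sex = as.numeric(cd$sex == "M")))
  sm <- summary(fit)$coefficients
  expect_equal(tab$coefficient[tab$gene_id == g], sm["member", 1],
               tolerance = 1e-9)
  expect_equal(tab$t_statistic[tab$gene_id == g], sm["member", 3],
               tolerance = 1e-9)
})

test_that("t-statistics are invariant to relabeling non-member clusters", {
  sce <- default_sce()
  sf <- estimate_size_factors(sce)
  cd <- sce_coldata(sce)
  tab1 <- regress_cluster_specificity(sce_counts(sce), "cluster01",
                                      size_factors = sf,
                                      covariates = cd[, c("cluster", "sex")])
  cd2 <- cd
  cd2$cluster <- as.character(cd2$cluster)
  cd2$cluster[cd2$cluster %in% c("cluster03", "cluster04")] <- "merged"
  tab2 <- regress_cluster_specificity(sce_counts(sce), "cluster01",
                                      size_factors = sf,
                                      covariates = cd2[, c("cluster", "sex")])
  expect_equal(tab1$t_statistic, tab2$t_statistic)
})

test_that("simulated FC=8 markers land in the top decile", {
  sce <- default_sce()   # defaults: FC = 8, 50 cells/cluster
  sf <- estimate_size_factors(sce)
  markers <- S4Vectors::metadata(sce)$marker_sets
  for (cl in c("cluster01", "cluster03")) {
    tab <- regress_cluster_specificity(sce, cl, size_factors = sf)
    top <- select_top_fraction(tab, 0.10)
    expect_gte(mean(markers[[cl]] %in% top), 0.90)
  }
})

test_that("null simulation (FC=1) gives no marker enrichment in the top set", {
  sce0 <- simulate_counts(sim_config(marker_fold_change = 1, seed = 9))
  tab <- regress_cluster_specificity(sce0, "cluster01")
  top <- select_top_fraction(tab, 0.10)
  markers <- S4Vectors::metadata(sce0)$marker_sets[["cluster01"]]
  # a quantile rule, not a test: ~10% of null "markers" fall in by chance
  expect_lte(mean(markers %in% top), 0.35)
})

test_that("top-fraction selection follows the fixed rounding and tie rules", {
  tab <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    t_statistic = 10:1)
  expect_length(select_top_fraction(tab, 0.10), 1)
  expect_identical(select_top_fraction(tab, 1), tab$gene_id)
  # monotone transform of t leaves the selected set unchanged
  tab2 <- tab; tab2$t_statistic <- atan(tab2$t_statistic)
  expect_identical(select_top_fraction(tab, 0.3),
                   select_top_fraction(tab2, 0.3))
  # boundary tie: lexicographically earlier gene id wins
  tie <- data.frame(gene_id = c("gB", "gA", "gC"),
                    t_statistic = c(1, 1, 5))
  expect_identical(select_top_fraction(tie, 2 / 3), c("gC", "gA"))
  expect_error(select_top_fraction(tab[0, ], 0.1), "non-empty")
  expect_error(select_top_fraction(tab, 0), "0, 1")
})

test_that("marker ranking excludes constant genes and tops perfect markers", {
  set.seed(21)
  n <- 40
  labels <- rep(c("A", "B"), each = n / 2)
  m <- matrix(rpois(50 * n, 5), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  m["g01", ] <- 7                                   # constant
  m["g02", ] <- c(rpois(n / 2, 30), rep(0, n / 2))  # perfect A marker
  rk <- rank_markers(m, labels)
  expect_false("g01" %in% rk$gene_id)
  row <- rk[rk$gene_id == "g02", ]
  expect_equal(row$enrichment_score_change, 1.0)
  expect_equal(row$combined_rank, 1L)
  expect_equal(row$cluster, "A")
  expect_error(rank_markers(m, rep("A", n)), "2 clusters")
})

test_that("true markers rank above non-markers in simulated data", {
  sce <- default_sce()
  rk <- rank_markers(sce)
  truth <- unlist(S4Vectors::metadata(sce)$marker_sets)
  is_marker <- rk$gene_id %in% truth
  expect_gt(sum(is_marker), 10)
  w <- wilcox.test(rk$combined_rank[is_marker],
                   rk$combined_rank[!is_marker], alternative = "less")
  expect_lt(w$p.value, 0.01)
})
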