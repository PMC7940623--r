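# Cluster-specificity scoring: size factors, membership regression,
# top-fraction selection, and marker-ranking heuristics.

get_counts <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    as.matrix(SummarizedExperiment::assay(x, "counts"))
  } else {
    as.matrix(x)
  }
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants correcting sequencing-depth differences:
#' each sample's factor is the median, over genes with a positive geometric
#' mean across samples, of that sample's count divided by the gene's
#' geometric mean. Factors are equivariant: scaling one sample's counts by
#' c scales its factor by exactly c.
#'
#' This is strict median-of-ratios; if no gene is expressed in every
#' sample the estimator is undefined and an error is raised (no
#' pseudo-reference fallback is applied).
#'
#' @param counts genes x samples count matrix, or a SingleCellExperiment
#'   with a `counts` assay.
#' @return Named numeric vector of positive per-sample factors.
#' @export
estimate_size_factors <- function(counts) {
  m <- get_counts(counts)
  log_geo <- rowMeans(log(m))        # -Inf for genes with any zero
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop("no gene has positive counts in every sample; strict ",
         "median-of-ratios is undefined (a pseudo-reference fallback is ",
         "deliberately not applied)", call. = FALSE)
  }
  sf <- apply(log(m[use, , drop = FALSE]) - log_geo[use], 2, median)
  sf <- exp(sf)
  names(sf) <- colnames(m)
  sf
}

n_top_genes <- function(q, n) {
  # fixed convention: round half away from zero, minimum 1
  max(1L, as.integer(round_half_up(q * n)))
}

#' Per-gene cluster-specificity regression
#'
#' For one cluster, regresses (transformed) expression of every cell on a
#' cluster-membership indicator (in = 1, out = 0) with sex as a covariate,
#' and returns per-gene membership coefficients and t-statistics sorted by
#' decreasing t. Size factors enter either by pre-dividing counts before a
#' `log1p` transform (`sf_mode = "pre_divide"`, the default) or as a
#' `log(size factor)` covariate on `log1p(raw counts)`
#' (`sf_mode = "covariate"`).
#'
#' Genes with zero residual variance and zero membership coefficient get
#' t = 0. Ties in t are broken by ascending gene id, so output order is
#' deterministic.
#'
#' @param counts genes x cells counts (matrix or SingleCellExperiment).
#' @param cluster_id the cluster whose specificity is scored.
#' @param size_factors optional; computed by [estimate_size_factors()] if
#'   missing.
#' @param covariates data.frame with columns `cluster` and `sex` aligned to
#'   cells; taken from `colData` when `counts` is a SingleCellExperiment.
#' @param q top fraction used to flag `in_top_fraction` (default 0.10).
#' @param sf_mode how size factors enter the model (see above).
#' @param log_transform apply `log1p` to normalized counts (default TRUE);
#'   FALSE fits OLS on the raw scale.
#' @return data.frame: `gene_id`, `cluster_id`, `coefficient`,
#'   `t_statistic`, `rank` (1 = most specific), `in_top_fraction`.
#' @export
regress_cluster_specificity <- function(counts, cluster_id,
                                        size_factors = NULL,
                                        covariates = NULL, q = 0.10,
                                        sf_mode = c("pre_divide",
                                                    "covariate"),
                                        log_transform = TRUE) {
  sf_mode <- match.arg(sf_mode)
  m <- get_counts(counts)
  if (is.null(covariates)) {
    if (!methods::is(counts, "SummarizedExperiment")) {
      stop("`covariates` (cluster, sex) required for a plain matrix",
           call. = FALSE)
    }
    covariates <- as.data.frame(
      SummarizedExperiment::colData(counts))[, c("cluster", "sex")]
  }
  if (nrow(covariates) != ncol(m)) {
    stop("covariates (", nrow(covariates), " rows) not aligned to cells (",
         ncol(m), ")", call. = FALSE)
  }
  if (!cluster_id %in% covariates$cluster) {
    stop("cluster `", cluster_id, "` not present in cell labels",
         call. = FALSE)
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(m)

  member <- as.numeric(covariates$cluster == cluster_id)
  sex_m <- as.numeric(covariates$sex == "M")
  X <- cbind(intercept = 1, member = member, sex = sex_m)
  if (sf_mode == "pre_divide") {
    y <- sweep(m, 2, size_factors, "/")
  } else {
    y <- m
    X <- cbind(X, log_sf = log(size_factors))
  }
  if (log_transform) y <- log1p(y)

  keep <- colnames(X) == "intercept" | apply(X, 2, function(v) sd(v) > 0)
  if (!all(keep)) {
    warning("dropping constant design column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    if (!"member" %in% colnames(X)) {
      stop("membership indicator is constant; cannot score cluster `",
           cluster_id, "`", call. = FALSE)
    }
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("fewer cells (", n, ") than free parameters (", p,
                   "); regression is underdetermined", call. = FALSE)

  qr_x <- qr(X)
  coefs <- qr.coef(qr_x, t(y))            # p x genes
  fitted <- X %*% coefs
  res <- t(y) - fitted
  sigma2 <- colSums(res^2) / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_x))
  j <- which(colnames(X) == "member")
  se <- sqrt(sigma2 * xtx_inv[j, j])
  beta <- coefs[j, ]
  tstat <- beta / se
  # an (numerically) exact fit has no residual information: t is 0 for a
  # null coefficient, +-Inf for a perfectly separating one
  exact <- sigma2 < 1e-20 * pmax(colMeans(t(y)^2), 1)
  tstat[exact] <- ifelse(abs(beta[exact]) < 1e-8, 0,
                         sign(beta[exact]) * Inf)

  out <- data.frame(gene_id = rownames(m), cluster_id = cluster_id,
                    coefficient = beta, t_statistic = tstat,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$t_statistic, out$gene_id), ]
  out$rank <- seq_len(nrow(out))
  out$in_top_fraction <- out$rank <= n_top_genes(q, nrow(out))
  rownames(out) <- NULL
  out
}

#' Retain the top fraction of cluster-specific genes
#'
#' Returns the `round(q * n_genes)` genes (half away from zero, minimum 1)
#' with the largest specificity t-statistics. Ties at the boundary are
#' broken deterministically: larger t first, then ascending gene id.
#'
#' @param table a specificity table from [regress_cluster_specificity()].
#' @param q fraction in (0, 1].
#' @return Character vector of retained gene ids.
#' @export
select_top_fraction <- function(table, q = 0.10) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("`table` must be a non-empty specificity table", call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1) {
    stop("`q` must be in (0, 1]", call. = FALSE)
  }
  ord <- order(-table$t_statistic, table$gene_id)
  table$gene_id[ord][seq_len(n_top_genes(q, nrow(table)))]
}

#' Rank candidate marker genes by specificity heuristics
#'
#' Over-dispersed genes are found by comparing each gene's squared
#' coefficient of variation (CV^2) to the median CV^2 of its mean-expression
#' bin (20 bins); genes above the trend qualify. Each qualifying gene is
#' assigned to the cluster maximizing its fold change
#' (in-cluster mean / out-cluster mean) and ranked by the average of its
#' fold-change rank and its enrichment-score-change rank, where the
#' enrichment score change is the fraction of in-cluster cells expressing
#' the gene minus the fraction of out-cluster cells expressing it.
#'
#' @param counts genes x cells counts (matrix or SingleCellExperiment).
#' @param labels cluster label per cell; taken from `colData(counts)$cluster`
#'   if missing.
#' @param n_bins number of mean-expression bins for the CV^2 trend.
#' @return data.frame of over-dispersed genes sorted by `combined_rank`:
#'   `gene_id`, `cluster`, `overdispersion_score`, `fold_change`,
#'   `enrichment_score_change`, `combined_rank`.
#' @export
rank_markers <- function(counts, labels = NULL, n_bins = 20) {
  m <- get_counts(counts)
  if (is.null(labels)) {
    if (!methods::is(counts, "SummarizedExperiment")) {
      stop("`labels` required for a plain matrix", call. = FALSE)
    }
    labels <- SummarizedExperiment::colData(counts)$cluster
  }
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("marker ranking needs at least 2 clusters", call. = FALSE)
  }

  mu <- rowMeans(m)
  v <- apply(m, 1, stats::var)
  expressed <- mu > 0 & v > 0
  cv2 <- ifelse(expressed, v / mu^2, 0)

  bins <- cut(rank(mu[expressed], ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  trend <- stats::ave(cv2[expressed], bins, FUN = median)
  score <- cv2[expressed] - trend
  od_genes <- rownames(m)[expressed][score > 0]
  od_score <- score[score > 0]
  if (!length(od_genes)) {
    return(data.frame(gene_id = character(), cluster = character(),
                      overdispersion_score = numeric(),
                      fold_change = numeric(),
                      enrichment_score_change = numeric(),
                      combined_rank = integer()))
  }

  sub <- m[od_genes, , drop = FALSE]
  lvls <- levels(droplevels(labels))
  in_mean <- sapply(lvls, function(k) rowMeans(sub[, labels == k,
                                                   drop = FALSE]))
  out_mean <- sapply(lvls, function(k) rowMeans(sub[, labels != k,
                                                    drop = FALSE]))
  in_frac <- sapply(lvls, function(k) rowMeans(sub[, labels == k,
                                                   drop = FALSE] > 0))
  out_frac <- sapply(lvls, function(k) rowMeans(sub[, labels != k,
                                                    drop = FALSE] > 0))
  eps <- 1e-9
  fc <- (in_mean + eps) / (out_mean + eps)
  best <- max.col(fc, ties.method = "first")
  pick <- cbind(seq_along(od_genes), best)

  out <- data.frame(
    gene_id = od_genes,
    cluster = lvls[best],
    overdispersion_score = od_score,
    fold_change = fc[pick],
    enrichment_score_change = (in_frac - out_frac)[pick],
    stringsAsFactors = FALSE
  )
  r_fc <- rank(-out$fold_change, ties.method = "average")
  r_esc <- rank(-out$enrichment_score_change, ties.method = "average")
  out <- out[order((r_fc + r_esc) / 2, out$gene_id), ]
  out$combined_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
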