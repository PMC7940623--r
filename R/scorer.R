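# Probabilistic cell-identity scorer: a single-hidden-layer classifier
# (ReLU hidden layer, softmax output, dropout, Nesterov-momentum SGD)
# trained on a labelled reference and used to score query cells, with
# permutation significance and a radar embedding of the probabilities.

#' Scorer architecture and training hyper-parameters
#'
#' The network has `n_input` input nodes (one per marker gene), a hidden
#' layer of `round(0.2 * n_input)` ReLU nodes (minimum 4; below that the
#' bottleneck interacts badly with dropout), and a softmax
#' output layer with one node per reference cell type. Dropout (default
#' rate 0.30) regularizes the hidden layer during training; the optimizer
#' is stochastic gradient descent with Nesterov momentum. Learning rate,
#' momentum, epoch count and batch size are configuration with the stated
#' defaults — in practice they are tuned by inspecting the learning curve,
#' which [cross_validate()] automates via early stopping.
#'
#' @param n_input number of marker-gene features.
#' @param n_output number of reference cell types.
#' @param dropout_rate hidden-layer dropout rate in \[0, 1).
#' @param learning_rate,momentum SGD parameters.
#' @param n_epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @export
scorer_spec <- function(n_input, n_output, dropout_rate = 0.30,
                        learning_rate = 0.1, momentum = 0.9,
                        n_epochs = 100, batch_size = 64) {
  n_input <- check_count(n_input, "n_input")
  n_output <- check_count(n_output, "n_output", min = 2L)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must be in [0, 1)", call. = FALSE)
  }
  structure(list(
    n_input = n_input,
    n_hidden = max(4L, as.integer(round_half_up(0.2 * n_input))),
    n_output = n_output,
    dropout_rate = dropout_rate,
    learning_rate = check_positive(learning_rate, "learning_rate"),
    momentum = momentum,
    n_epochs = check_count(n_epochs, "n_epochs"),
    batch_size = check_count(batch_size, "batch_size")
  ), class = "scorer_spec")
}

#' Log + min-max scaling of marker features, reference-anchored
#'
#' Subsets both datasets to the shared marker genes, applies `log1p`, then
#' min-max scales each gene using the reference's min and max only; query
#' values are clipped to \[0, 1\]. Markers with zero variance in the
#' reference are dropped with a warning. The result carries a guard flag so
#' that scaled features cannot be scaled a second time (min-max is not
#' idempotent).
#'
#' @param reference,query genes x cells matrices (or SingleCellExperiments)
#'   on a shared gene namespace (orthologs already renamed upstream).
#' @param marker_genes character vector of marker gene ids.
#' @return List of class `scaled_features`: `reference` and `query` as
#'   cells x markers matrices in \[0, 1\], plus the per-gene `stats` used.
#' @export
preprocess_features <- function(reference, query, marker_genes) {
  if (inherits(reference, "scaled_features") ||
      isTRUE(attr(reference, "paincell_scaled")) ||
      isTRUE(attr(query, "paincell_scaled"))) {
    stop("features are already scaled; min-max scaling must be applied ",
         "exactly once", call. = FALSE)
  }
  ref <- get_counts(reference)
  qry <- get_counts(query)
  shared <- intersect(intersect(marker_genes, rownames(ref)), rownames(qry))
  if (!length(shared)) {
    stop("no marker genes shared between reference and query", call. = FALSE)
  }
  ref_l <- log1p(t(ref[shared, , drop = FALSE]))   # cells x markers
  qry_l <- log1p(t(qry[shared, , drop = FALSE]))
  mins <- apply(ref_l, 2, min)
  maxs <- apply(ref_l, 2, max)
  keep <- maxs > mins
  if (!all(keep)) {
    warning("dropping ", sum(!keep),
            " zero-variance marker(s) in the reference: ",
            paste(head(shared[!keep], 5), collapse = ", "))
  }
  shared <- shared[keep]
  if (!length(shared)) stop("all shared markers have zero variance",
                            call. = FALSE)
  mins <- mins[keep]; maxs <- maxs[keep]
  scale01 <- function(x) sweep(sweep(x, 2, mins), 2, maxs - mins, "/")
  ref_s <- scale01(ref_l[, keep, drop = FALSE])
  qry_s <- pmin(pmax(scale01(qry_l[, keep, drop = FALSE]), 0), 1)
  attr(ref_s, "paincell_scaled") <- TRUE
  attr(qry_s, "paincell_scaled") <- TRUE
  structure(list(reference = ref_s, query = qry_s,
                 stats = data.frame(gene_id = shared, min = mins,
                                    max = maxs, row.names = NULL)),
            class = "scaled_features")
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

nn_forward <- function(w, x, dropout_rate = 0, training = FALSE) {
  h <- relu(sweep(x %*% w$W1, 2, w$b1, "+"))
  if (training && dropout_rate > 0) {
    mask <- matrix(runif(length(h)) >= dropout_rate, nrow(h), ncol(h))
    h <- h * mask / (1 - dropout_rate)   # inverted dropout
  } else {
    mask <- NULL
  }
  p <- softmax_rows(sweep(h %*% w$W2, 2, w$b2, "+"))
  list(h = h, p = p, mask = mask)
}

nn_gradients <- function(w, x, y_onehot, dropout_rate) {
  fwd <- nn_forward(w, x, dropout_rate, training = TRUE)
  n <- nrow(x)
  d_out <- (fwd$p - y_onehot) / n                 # softmax + cross-entropy
  g_w2 <- t(fwd$h) %*% d_out
  g_b2 <- colSums(d_out)
  d_h <- d_out %*% t(w$W2)
  if (!is.null(fwd$mask)) d_h <- d_h * fwd$mask / (1 - dropout_rate)
  d_h <- d_h * (fwd$h > 0)
  list(W1 = t(x) %*% d_h, b1 = colSums(d_h), W2 = g_w2, b2 = g_b2)
}

init_weights <- function(spec) {
  u <- function(nr, nc) {                         # scaled uniform fan-in
    lim <- 1 / sqrt(nr)
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  list(W1 = u(spec$n_input, spec$n_hidden), b1 = numeric(spec$n_hidden),
       W2 = u(spec$n_hidden, spec$n_output), b2 = numeric(spec$n_output))
}

#' Train the cell-identity scorer
#'
#' Minimizes multinomial cross-entropy with minibatch SGD and Nesterov
#' momentum (gradients evaluated at the look-ahead parameters). Fully
#' deterministic given `seed`. With a validation set, training stops early
#' once validation accuracy has not improved by more than `min_delta` for
#' `patience` consecutive epochs.
#'
#' @param features cells x markers matrix in \[0, 1\] (from
#'   [preprocess_features()]).
#' @param labels cell-type label per cell; >= 2 classes, >= 2 cells each.
#' @param spec a [scorer_spec()]; a default is built from the data if NULL.
#' @param seed integer seed for weight init, shuffling and dropout.
#' @param validation optional list(features, labels) for early stopping.
#' @param patience,min_delta early-stopping parameters.
#' @return `trained_scorer` object with weights, class levels, feature
#'   names, per-epoch `loss_history` and (if validated) `val_accuracy`.
#' @export
train_scorer <- function(features, labels, spec = NULL, seed = 1L,
                         validation = NULL, patience = 20,
                         min_delta = 0.001) {
  x <- as.matrix(features)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 classes", call. = FALSE)
  tab <- table(labels)
  if (any(tab < 2L)) {
    stop("class(es) with a single cell: ",
         paste(names(tab)[tab < 2], collapse = ", "),
         "; merge or remove them before training", call. = FALSE)
  }
  if (is.null(spec)) spec <- scorer_spec(ncol(x), nlevels(labels))
  if (spec$n_input != ncol(x) || spec$n_output != nlevels(labels)) {
    stop("spec dimensions do not match the data", call. = FALSE)
  }
  y <- diag(nlevels(labels))[as.integer(labels), , drop = FALSE]

  with_seed(seed, {
    w <- init_weights(spec)
    v <- lapply(w, function(p) p * 0)
    loss_hist <- numeric(0)
    val_hist <- numeric(0)
    best_val <- -Inf; stall <- 0L
    n <- nrow(x)
    for (epoch in seq_len(spec$n_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = spec$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + spec$batch_size - 1L, n)]
        look <- Map(function(p, vel) p + spec$momentum * vel, w, v)
        g <- nn_gradients(look, x[idx, , drop = FALSE],
                          y[idx, , drop = FALSE], spec$dropout_rate)
        v <- Map(function(vel, grad)
          spec$momentum * vel - spec$learning_rate * grad, v, g)
        w <- Map(`+`, w, v)
      }
      p_all <- nn_forward(w, x)$p
      loss_hist <- c(loss_hist,
                     -mean(log(pmax(rowSums(p_all * y), 1e-12))))
      if (!is.null(validation)) {
        pv <- nn_forward(w, as.matrix(validation$features))$p
        acc <- mean(levels(labels)[max.col(pv)] ==
                      as.character(validation$labels))
        val_hist <- c(val_hist, acc)
        if (acc > best_val + min_delta) {
          best_val <- acc; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      }
    }
    structure(list(weights = w, classes = levels(labels),
                   features = colnames(x), spec = spec,
                   loss_history = loss_hist,
                   val_accuracy = if (length(val_hist)) val_hist else NULL),
              class = "trained_scorer")
  })
}

#' Class probabilities for query cells
#'
#' Forward pass with dropout disabled; each row is a softmax distribution
#' over the reference cell types (rows sum to 1 within 1e-6).
#'
#' @param scorer a [train_scorer()] result.
#' @param query_features cells x markers matrix with columns matching the
#'   training features.
#' @return cells x reference-types probability matrix.
#' @export
predict_probabilities <- function(scorer, query_features) {
  x <- as.matrix(query_features)
  if (!is.null(scorer$features)) {
    if (is.null(colnames(x))) {
      if (ncol(x) != length(scorer$features)) {
        stop("query has ", ncol(x), " features; scorer expects ",
             length(scorer$features), call. = FALSE)
      }
    } else {
      missing <- setdiff(scorer$features, colnames(x))
      if (length(missing)) {
        stop("query is missing trained marker gene(s): ",
             paste(head(missing, 10), collapse = ", "), call. = FALSE)
      }
      x <- x[, scorer$features, drop = FALSE]
    }
  }
  p <- nn_forward(scorer$weights, x)$p
  dimnames(p) <- list(rownames(x), scorer$classes)
  p
}

stratified_folds <- function(labels, k) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Stratified k-fold cross-validated accuracy
#'
#' Splits cells into `k` stratified folds (default k = 3), trains on k-1
#' folds with the held-out fold doubling as the early-stopping validation
#' set, and reports per-fold and mean accuracy.
#'
#' @inheritParams train_scorer
#' @param k number of folds; every class must have at least `k` cells.
#' @return List with `fold_accuracy` (length k) and `mean_accuracy`.
#' @export
cross_validate <- function(features, labels, spec = NULL, k = 3, seed = 1L,
                           patience = 20, min_delta = 0.001) {
  labels <- droplevels(as.factor(labels))
  k <- check_count(k, "k", min = 2L)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("class(es) smaller than k = ", k, ": ",
         paste(names(tab)[tab < k], collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(features)
  with_seed(seed, {
    fold <- stratified_folds(labels, k)
    seeds <- sample.int(.Machine$integer.max, k)
    acc <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      sc <- train_scorer(x[tr, , drop = FALSE], labels[tr], spec = spec,
                         seed = seeds[f],
                         validation = list(features = x[!tr, , drop = FALSE],
                                           labels = labels[!tr]),
                         patience = patience, min_delta = min_delta)
      p <- predict_probabilities(sc, x[!tr, , drop = FALSE])
      mean(sc$classes[max.col(p)] == as.character(labels[!tr]))
    }, numeric(1))
    list(fold_accuracy = acc, mean_accuracy = mean(acc))
  })
}

#' Permutation significance of query-to-reference assignments
#'
#' The observed statistic for each (query cluster, reference type) pair is
#' the mean predicted probability of that type over the cluster's cells.
#' The null is built at the dataset level: reference labels are shuffled
#' and the scorer retrained `B` times; the empirical p-value uses the
#' add-one rule p = (1 + #\{null >= observed\}) / (B + 1), and q-values are
#' Benjamini-Hochberg across all pairs.
#'
#' @param features,labels scaled reference features and labels.
#' @param query scaled query features.
#' @param query_clusters cluster label per query cell.
#' @param spec a [scorer_spec()] (optional).
#' @param B number of permutations; >= 99 recommended (warned below),
#'   < 19 is an error.
#' @param seed integer seed.
#' @return data.frame: `query_cluster`, `reference_type`, `observed`,
#'   `p`, `q`.
#' @export
permutation_significance <- function(features, labels, query,
                                     query_clusters, spec = NULL, B = 199,
                                     seed = 1L) {
  B <- check_count(B, "B")
  if (B < 19) stop("B < 19 gives unusably coarse p-values", call. = FALSE)
  if (B < 99) warning("B < 99: p-value granularity is coarse")
  labels <- droplevels(as.factor(labels))
  query_clusters <- as.factor(query_clusters)

  cluster_means <- function(p) {
    t(vapply(levels(query_clusters),
             function(cl) colMeans(p[query_clusters == cl, , drop = FALSE]),
             numeric(ncol(p))))
  }

  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, B + 1L)
    sc <- train_scorer(features, labels, spec = spec, seed = seeds[1])
    obs <- cluster_means(predict_probabilities(sc, query))
    exceed <- matrix(0L, nrow(obs), ncol(obs))
    for (b in seq_len(B)) {
      perm <- sample(labels)
      sc_b <- train_scorer(features, perm, spec = spec, seed = seeds[b + 1L])
      null_b <- cluster_means(predict_probabilities(sc_b, query))
      exceed <- exceed + (null_b >= obs)
    }
    p <- (1 + exceed) / (B + 1)
    out <- data.frame(
      query_cluster = rep(levels(query_clusters), times = ncol(obs)),
      reference_type = rep(sc$classes, each = nrow(obs)),
      observed = as.vector(obs),
      p = as.vector(p),
      stringsAsFactors = FALSE
    )
    out$q <- bh_fdr(out$p)
    out
  })
}

#' Radar embedding of class probabilities
#'
#' Places each cell at the probability-weighted combination of the vertices
#' of a regular polygon on the unit circle, one vertex per reference type,
#' the first at 90 degrees and proceeding counter-clockwise. Every point
#' lies in the convex hull of the vertices; a one-hot probability sits
#' exactly on its class vertex and a uniform one at the centroid.
#'
#' @param probs cells x types probability matrix (rows sum to 1).
#' @return List with `coordinates` (cells x 2) and `vertices` (types x 2).
#' @export
radar_embed <- function(probs) {
  p <- as.matrix(probs)
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  k <- ncol(p)
  theta <- pi / 2 + 2 * pi * (seq_len(k) - 1) / k
  vertices <- cbind(x = cos(theta), y = sin(theta))
  rownames(vertices) <- colnames(p)
  coords <- p %*% vertices
  list(coordinates = coords, vertices = vertices)
}
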