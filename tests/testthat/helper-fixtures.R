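# Shared fixture builders: everything is generated in code at test time.

# Gaussian class blobs min-max scaled per feature (as pipeline features
# always are), linearly separable when `sep` is large relative to `noise`.
make_blobs <- function(n_per_class = 20, n_classes = 3, n_features = 12,
                       sep = 1, noise = 0.1, seed = 1) {
  set.seed(seed)
  centers <- matrix(runif(n_classes * n_features), n_classes)
  x <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
    sweep(matrix(rnorm(n_per_class * n_features, sd = noise), n_per_class),
          2, sep * centers[k, ], "+")
  }))
  x <- apply(x, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  colnames(x) <- paste0("f", seq_len(n_features))
  list(x = x,
       y = factor(rep(paste0("class", seq_len(n_classes)),
                      each = n_per_class)))
}

# Small default simulated experiment reused across tests.
default_sce <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_counts(sim_config(seed = 1))
    cache
  }
})

sce_counts <- function(sce) {
  as.matrix(SummarizedExperiment::assay(sce, "counts"))
}

sce_coldata <- function(sce) {
  as.data.frame(SummarizedExperiment::colData(sce))
}
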