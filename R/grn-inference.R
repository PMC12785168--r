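# Tree-ensemble (GENIE3-style) inference of a ranked, directed TF->target
# edge list, and top-percent thresholding.

#' Infer a ranked regulatory network from expression
#'
#' For each gene, its (unit-variance scaled) expression is regressed on the
#' expression of all candidate transcription factors except itself with an
#' ensemble of `n_trees` regression trees (bootstrap resampling per tree;
#' `ceiling(sqrt(p))` candidate predictors per split under the default
#' `k_rule = "sqrt"`). The weight of edge TF->gene is the mean per-tree
#' variance (impurity) reduction attributed to that TF divided by the
#' sample count, so weights of an informative target sum to ~1 (the
#' fraction of response variance explained). All target-wise weights are
#' pooled and sorted descending; ties break on (regulator id, target id)
#' so the ranking is fully deterministic. Each target's fit is seeded by
#' `seed` plus a stable hash of the gene id, making results independent of
#' target order.
#'
#' Constant-expression targets are skipped with a warning. Raw counts are
#' the conventional input; any nonnegative expression unit is accepted.
#'
#' @param expr an `expr_matrix` (or plain genes x samples matrix).
#' @param tfs character vector of candidate regulator gene ids.
#' @param n_trees trees per target ensemble (default 2000).
#' @param k_rule "sqrt" (default) or "all" candidate predictors per split.
#' @param seed base RNG seed (default 123).
#' @return a `ranked_edges` data frame (regulator, target, weight), sorted
#'   by weight descending, with provenance attributes.
#' @export
infer_grn <- function(expr, tfs, n_trees = 2000L, k_rule = c("sqrt", "all"),
                      seed = 123L) {
  k_rule <- match.arg(k_rule)
  v <- values_of(expr)
  tfs <- intersect(tfs, rownames(v))
  if (length(tfs) < 2L) stop("need at least 2 TFs present in the matrix")
  if (ncol(v) < 10L) stop("need at least 10 samples")
  n <- ncol(v)

  tf_expr <- t(v[tfs, , drop = FALSE])
  res <- vector("list", nrow(v))
  skipped <- character()
  for (gi in seq_len(nrow(v))) {
    g <- rownames(v)[gi]
    y <- v[gi, ]
    sdy <- stats::sd(y)
    if (!is.finite(sdy) || sdy == 0) { skipped <- c(skipped, g); next }
    preds <- setdiff(tfs, g)
    if (!length(preds)) next
    y <- (y - mean(y)) / sdy
    X <- tf_expr[, preds, drop = FALSE]
    p <- ncol(X)
    mtry <- if (k_rule == "sqrt") ceiling(sqrt(p)) else p
    dat <- data.frame(..y = y, X, check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = "..y", data = dat,
      num.trees = n_trees, mtry = mtry, importance = "impurity",
      replace = TRUE, num.threads = 1L,
      seed = (seed + stable_hash(g)) %% .Machine$integer.max)
    w <- fit$variable.importance / n
    res[[gi]] <- data.frame(regulator = preds, target = g,
                            weight = as.numeric(w[preds]),
                            stringsAsFactors = FALSE)
  }
  if (length(skipped))
    grn_log("warn", "skipped ", length(skipped), " constant-expression gene(s)")
  edges <- do.call(rbind, res)
  if (is.null(edges) || !nrow(edges)) stop("no edges could be inferred")
  edges <- edges[order(-edges$weight, edges$regulator, edges$target), ]
  rownames(edges) <- NULL
  structure(edges, class = c("ranked_edges", "data.frame"),
            provenance = list(n_trees = n_trees, k_rule = k_rule, seed = seed,
                              n_samples = n, n_tfs = length(tfs)))
}

#' Threshold a ranked edge list to its top percent
#'
#' Retains the first `ceiling(percent/100 * N)` records of the
#' deterministically sorted list (weight descending, then regulator and
#' target id), attaching 1-based ranks.
#'
#' @param edges a `ranked_edges` data frame (or any data frame with
#'   regulator/target/weight columns).
#' @param percent percentage of edges to keep, in (0, 100].
#' @return a `grn` data frame (regulator, target, weight, rank) with a
#'   `threshold_percent` attribute and summary counts.
#' @export
threshold_top_percent <- function(edges, percent) {
  stopifnot(percent > 0, percent <= 100)
  if (!nrow(edges)) stop("empty edge list")
  edges <- as.data.frame(edges)
  edges <- edges[order(-edges$weight, edges$regulator, edges$target), ]
  n_keep <- ceiling(percent / 100 * nrow(edges))
  out <- edges[seq_len(n_keep), , drop = FALSE]
  out$rank <- seq_len(n_keep)
  rownames(out) <- NULL
  structure(out, class = c("grn", "data.frame"),
            threshold_percent = percent,
            summary = list(n_tfs = length(unique(out$regulator)),
                           n_genes = length(unique(c(out$regulator, out$target))),
                           n_edges = nrow(out)))
}
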