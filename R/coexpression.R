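# Per-study co-expression: Pearson correlations -> per-gene descending
# ranks -> highest reciprocal rank (HRR) retention, then cross-study
# frequency aggregation and TF->target pair extraction.

#' Restrict an FPKM matrix to one study and drop silent genes
#'
#' Genes with FPKM below `min_fpkm` in every sample of the study are
#' discarded before correlation.
#'
#' @param fpkm an `expr_matrix` with study metadata.
#' @param study study identifier.
#' @param min_fpkm threshold (default 0.5).
#' @return an `expr_matrix` restricted to the study's samples and
#'   surviving genes.
#' @export
study_filter <- function(fpkm, study, min_fpkm = 0.5) {
  sel <- fpkm$samples$study_id == study
  if (!any(sel)) stop("study '", study, "' has no samples")
  v <- fpkm$values[, sel, drop = FALSE]
  keep <- rowSums(v >= min_fpkm) > 0
  expr_matrix(v[keep, , drop = FALSE], fpkm$samples$organ[sel],
              fpkm$samples$study_id[sel], fpkm$unit)
}

#' Per-gene descending Pearson-correlation ranks
#'
#' For each gene A, all partners are ranked 1..(n-1) by PCC descending;
#' ties break on partner id so the rank table is deterministic. Constant
#' genes (undefined correlations) are dropped with a warning.
#'
#' @param expr an `expr_matrix` or genes x samples matrix.
#' @return integer matrix R where `R[A, B]` is the rank of B among A's
#'   partners (diagonal NA).
#' @export
pcc_rank <- function(expr) {
  v <- values_of(expr)
  sds <- apply(v, 1, stats::sd)
  flat <- !is.finite(sds) | sds == 0
  if (any(flat)) {
    grn_log("warn", "dropping ", sum(flat), " constant gene(s) from correlation")
    v <- v[!flat, , drop = FALSE]
  }
  n <- nrow(v)
  if (n < 3L) stop("need at least 3 non-constant genes")
  cc <- stats::cor(t(v))
  ids <- rownames(v)
  R <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ord <- order(-cc[i, -i], ids[-i])
    R[i, ids[-i][ord]] <- seq_len(n - 1L)
  }
  R
}

#' Highest-reciprocal-rank matrix with top-percent retention
#'
#' `HRR(A, B) = max(rank(A, B), rank(B, A))`; a pair is retained only when
#' at least one of the two directed ranks is within the top
#' `ceiling(top_frac * (n - 1))` (minimum 1) best ranks of that gene.
#'
#' @param ranks rank matrix from [pcc_rank()].
#' @param top_frac per-gene retention fraction (default 0.01).
#' @return an `hrr_set`: list with `genes` and `pairs` (data frame
#'   gene_a < gene_b, hrr).
#' @export
hrr <- function(ranks, top_frac = 0.01) {
  n <- nrow(ranks)
  cutoff <- max(1L, ceiling(top_frac * (n - 1L)))
  keep <- (ranks <= cutoff) | (t(ranks) <= cutoff)
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  h <- pmax(ranks[idx], t(ranks)[idx])
  ids <- rownames(ranks)
  pairs <- data.frame(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
                      hrr = as.integer(h), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(genes = ids, pairs = pairs, cutoff = cutoff),
            class = "hrr_set")
}

#' Aggregate per-study HRR sets into a co-expression network
#'
#' The frequency of a pair is the number of study HRR sets retaining it.
#' A per-gene noise filter then keeps a pair when its frequency is within
#' the top `top_frac` frequencies (>= the per-gene cutoff value, ties at
#' the boundary kept) for at least one of its two endpoints.
#'
#' @param hrr_list list of `hrr_set` objects (one per study).
#' @param top_frac per-gene frequency retention fraction (default 0.01).
#' @return an `aggregated_gcn`: list with `pairs` (gene_a, gene_b,
#'   frequency) after filtering and `all_pairs` (before filtering).
#' @export
aggregate_gcn <- function(hrr_list, top_frac = 0.01) {
  if (!length(hrr_list)) stop("empty HRR list")
  tabs <- lapply(hrr_list, function(h) h$pairs[, c("gene_a", "gene_b")])
  all_tab <- do.call(rbind, tabs)
  key <- paste(all_tab$gene_a, all_tab$gene_b, sep = "\t")
  freq <- table(key)
  parts <- do.call(rbind, strsplit(names(freq), "\t", fixed = TRUE))
  pairs <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                      frequency = as.integer(freq), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL

  # per-gene top-fraction frequency cutoff, OR semantics over endpoints
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  inc <- rbind(data.frame(g = pairs$gene_a, f = pairs$frequency, i = seq_len(nrow(pairs))),
               data.frame(g = pairs$gene_b, f = pairs$frequency, i = seq_len(nrow(pairs))))
  keep <- logical(nrow(pairs))
  for (g in genes) {
    sub <- inc[inc$g == g, , drop = FALSE]
    k <- max(1L, ceiling(top_frac * nrow(sub)))
    thr <- sort(sub$f, decreasing = TRUE)[k]
    keep[sub$i[sub$f >= thr]] <- TRUE
  }
  structure(list(pairs = pairs[keep, , drop = FALSE], all_pairs = pairs,
                 n_studies = length(hrr_list)),
            class = "aggregated_gcn")
}

#' Extract directed TF->target pairs from a co-expression network
#'
#' Every undirected pair with at least one TF endpoint contributes the
#' directed pair(s) TF -> partner; TF-TF pairs contribute both directions.
#'
#' @param gcn an `aggregated_gcn` (or data frame with gene_a/gene_b).
#' @param tfs character vector of TF ids.
#' @return data frame (regulator, target) of directed pairs.
#' @export
tf_target_pairs <- function(gcn, tfs) {
  pairs <- if (inherits(gcn, "aggregated_gcn")) gcn$pairs else as.data.frame(gcn)
  a_tf <- pairs$gene_a %in% tfs
  b_tf <- pairs$gene_b %in% tfs
  out <- rbind(
    data.frame(regulator = pairs$gene_a[a_tf], target = pairs$gene_b[a_tf],
               stringsAsFactors = FALSE),
    data.frame(regulator = pairs$gene_b[b_tf], target = pairs$gene_a[b_tf],
               stringsAsFactors = FALSE)
  )
  out <- unique(out[order(out$regulator, out$target), , drop = FALSE])
  rownames(out) <- NULL
  out
}
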