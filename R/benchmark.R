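# Gold-standard construction, Fisher enrichment, AUROC/AUPR with
# permutation nulls, and the overlap-percentage arithmetic used in
# results summaries.

#' Gold standard of TF target sets
#'
#' @param sets named list TF -> character vector of target gene ids.
#' @param min_targets qualifying threshold recorded with the object.
#' @param provenance free-text source description.
#' @return a `gold_standard` object.
#' @export
gold_standard <- function(sets, min_targets = NA_integer_, provenance = "") {
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  keep <- lengths(sets) > 0L
  structure(sets[keep], class = "gold_standard",
            min_targets = min_targets, provenance = provenance)
}

#' Build a gold standard from peak-to-gene assignments
#'
#' Deduplicates targets per TF across experiments and retains only TFs
#' whose assigned-target count strictly exceeds `min_targets` (mirroring a
#' "more than 1000 mapped gene targets" qualifying rule).
#'
#' @param assignments data frame with columns `tf` and `target` (an
#'   optional `experiment` column is kept as provenance).
#' @param min_targets strict lower bound on per-TF target counts
#'   (default 1000).
#' @return a `gold_standard`.
#' @export
build_gold_standard <- function(assignments, min_targets = 1000L) {
  if (!nrow(assignments)) stop("empty assignment table")
  stopifnot(all(c("tf", "target") %in% names(assignments)))
  sets <- lapply(split(assignments$target, assignments$tf),
                 function(s) sort(unique(s)))
  sets <- sets[lengths(sets) > min_targets]
  prov <- if ("experiment" %in% names(assignments))
    paste(sort(unique(assignments$experiment)), collapse = ",") else ""
  gold_standard(sets, min_targets = min_targets, provenance = prov)
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard: %d TFs, %d targets total (min_targets=%s)\n",
              length(x), sum(lengths(x)), attr(x, "min_targets")))
  invisible(x)
}

as_pair_keys <- function(x) {
  if (inherits(x, "gold_standard"))
    return(unlist(lapply(names(x), function(tf) pair_key(tf, x[[tf]])),
                  use.names = FALSE))
  x <- as.data.frame(x)
  pair_key(x$regulator, x$target)
}

#' Fisher enrichment of predicted pairs in a gold standard
#'
#' Builds the 2x2 contingency table `a = |pred & gold|`,
#' `b = |pred \ gold|`, `c = |gold \ pred|`, `d` the remainder of the
#' universe, and reports the two-sided exact p together with the sample
#' odds ratio `(a d)/(b c)` (Haldane–Anscombe 0.5 added to every cell when
#' any cell is zero). Several comparisons passed as a named list are
#' BH-adjusted together.
#'
#' @param pred directed pair set (data frame regulator/target or
#'   `gold_standard`), or a named list of such sets for a batch.
#' @param gold reference pair set (same forms).
#' @param universe pair set defining the universe; must contain `pred` and
#'   `gold`.
#' @return data frame with one row per comparison: a, b, c, d, overlap,
#'   odds_ratio, log2_odds_ratio, p_value, p_adj.
#' @export
fisher_enrichment <- function(pred, gold, universe) {
  batch <- if (is.data.frame(pred) || inherits(pred, "gold_standard"))
    list(comparison = pred) else pred
  uni <- unique(as_pair_keys(universe))
  if (!length(uni)) stop("empty universe")
  gold_keys <- unique(as_pair_keys(gold))
  if (!all(gold_keys %in% uni)) stop("gold set not contained in universe")
  rows <- lapply(names(batch), function(nm) {
    pk <- unique(as_pair_keys(batch[[nm]]))
    if (!all(pk %in% uni)) stop("predicted set not contained in universe")
    a <- sum(pk %in% gold_keys)
    b <- length(pk) - a
    c_ <- length(gold_keys) - a
    d <- length(uni) - a - b - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                            alternative = "two.sided")$p.value
    cells <- c(a, b, c_, d)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    data.frame(comparison = nm, a = a, b = b, c = c_, d = d, overlap = a,
               odds_ratio = or, log2_odds_ratio = log2(or), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

# Filter a ranked list against a gold standard: keep edges whose regulator
# occurs in both networks, label each edge by gold membership.
labeled_edges <- function(ranked, gold) {
  ranked <- as.data.frame(ranked)
  shared <- intersect(unique(ranked$regulator), names(gold))
  sub <- ranked[ranked$regulator %in% shared, , drop = FALSE]
  if (!nrow(sub)) stop("no edges with regulators shared between network and gold")
  gk <- unlist(lapply(shared, function(tf) pair_key(tf, gold[[tf]])),
               use.names = FALSE)
  sub$label <- pair_key(sub$regulator, sub$target) %in% gk
  sub
}

auroc_from <- function(weight, label) {
  n_pos <- sum(label); n_neg <- sum(!label)
  r <- rank(weight, ties.method = "average")
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

aupr_from <- function(weight, label, regulator = NULL, target = NULL) {
  ord <- if (is.null(regulator)) order(-weight)
         else order(-weight, regulator, target)
  lab <- label[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / sum(lab)
  sum(prec * c(rec[1], diff(rec)))
}

#' AUROC and AUPR of a ranked network against a gold standard
#'
#' Edges are filtered to regulators present in both the ranked network and
#' the gold standard; an edge is a positive iff its (regulator, target)
#' pair is in the gold standard. AUROC is the Mann–Whitney rank statistic
#' (ties count one half); AUPR is the step integration of the
#' precision–recall sweep in descending weight order.
#'
#' @param ranked a `ranked_edges`/`grn` data frame with weights.
#' @param gold a `gold_standard`.
#' @return list with `auroc`, `aupr`, `n_pos`, `n_neg`, `n_edges`.
#' @export
roc_pr <- function(ranked, gold) {
  if (!length(gold)) stop("empty gold standard")
  sub <- labeled_edges(ranked, gold)
  n_pos <- sum(sub$label); n_neg <- sum(!sub$label)
  if (n_pos == 0L) stop("no positive edges after filtering")
  if (n_neg == 0L) stop("no negative edges after filtering")
  list(auroc = auroc_from(sub$weight, sub$label),
       aupr = aupr_from(sub$weight, sub$label, sub$regulator, sub$target),
       n_pos = n_pos, n_neg = n_neg, n_edges = nrow(sub))
}

#' Permutation null for AUROC/AUPR
#'
#' Shuffles the edge weights over the fixed edge set `n_perm` times,
#' recomputing both metrics, and compares the observed values with the
#' upper percentile of the null.
#'
#' @param ranked a ranked edge list.
#' @param gold a `gold_standard`.
#' @param n_perm number of permutations (default 1000; fewer than 20
#'   triggers a warning).
#' @param percentiles lower/upper percentiles of the null (default
#'   c(2.5, 97.5)).
#' @param seed RNG seed.
#' @return list with `observed` (from [roc_pr()]), `null_auroc` /
#'   `null_aupr` summaries (mean, lower, upper), `significant_auroc`,
#'   `significant_aupr`, `n_perm`, `seed`.
#' @export
permutation_test <- function(ranked, gold, n_perm = 1000L,
                             percentiles = c(2.5, 97.5), seed = 1L) {
  if (n_perm < 20L)
    grn_log("warn", "n_perm < 20: percentile estimates will be unstable")
  obs <- roc_pr(ranked, gold)
  sub <- labeled_edges(ranked, gold)
  null_roc <- numeric(n_perm); null_pr <- numeric(n_perm)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      w <- sample(sub$weight)
      null_roc[i] <- auroc_from(w, sub$label)
      null_pr[i] <- aupr_from(w, sub$label)
    }
  })
  summ <- function(x) c(mean = mean(x),
                        lower = unname(stats::quantile(x, percentiles[1] / 100)),
                        upper = unname(stats::quantile(x, percentiles[2] / 100)))
  nr <- summ(null_roc); np <- summ(null_pr)
  list(observed = obs, null_auroc = nr, null_aupr = np,
       null_auroc_values = null_roc, null_aupr_values = null_pr,
       significant_auroc = obs$auroc > nr[["upper"]],
       significant_aupr = obs$aupr > np[["upper"]],
       n_perm = n_perm, seed = seed, percentiles = percentiles)
}

#' Printed overlap percentage
#'
#' `100 * k / n` rounded half away from zero, the convention behind
#' summaries like "(369 of 607 targets, 61%)".
#'
#' @param k overlap count (0 <= k <= n).
#' @param n set size (> 0).
#' @param digits decimal digits (default 0).
#' @return the percentage as a number.
#' @export
overlap_percentage <- function(k, n, digits = 0) {
  if (any(n <= 0)) stop("set size must be positive")
  if (any(k < 0 | k > n)) stop("overlap must lie in [0, n]")
  round_half_away(100 * k / n, digits)
}
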