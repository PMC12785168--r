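# Network analytics: integrated value of influence (IVI) hub ranking,
# target-conservation vs connectivity, subnetwork extraction, and GO
# over-representation.

grn_igraph <- function(edges) {
  edges <- as.data.frame(edges)
  igraph::graph_from_data_frame(edges[, c("regulator", "target")],
                                directed = TRUE)
}

#' Integrated value of influence of network nodes
#'
#' Combines five centralities on the directed network: degree centrality
#' (in + out), neighborhood connectivity (mean total degree of neighbors),
#' betweenness, ClusterRank
#' `CR(i) = 10^(-cc_i) * sum over out-neighbors j of (out-degree(j) + 1)`
#' with `cc_i` the local clustering coefficient of the undirected
#' projection, and collective influence at radius `l`,
#' `CI_l(i) = (k_i - 1) * sum over nodes j at undirected distance l of
#' (k_j - 1)` with `k` the undirected degree. Each metric is min–max
#' normalized to \[0, 1\]; hubness = DC' + NC', spreading = BC' + CR' +
#' CI'; IVI = 1 + 99 x minmax(hubness x spreading), so scores live in
#' \[1, 100\].
#'
#' @param grn a `grn`/edge data frame (>= 3 nodes).
#' @param l collective-influence radius (default 2).
#' @return a `data.frame` with per-node raw metrics, normalized
#'   components and `ivi`, sorted by IVI descending.
#' @export
ivi <- function(grn, l = 2L) {
  g <- grn_igraph(grn)
  n <- igraph::vcount(g)
  if (n < 3L) stop("IVI needs at least 3 nodes")
  gu <- igraph::as_undirected(g, mode = "collapse")
  nodes <- igraph::V(g)$name

  deg_all <- igraph::degree(g, mode = "all")
  deg_out <- igraph::degree(g, mode = "out")
  deg_u <- igraph::degree(gu)

  adj <- igraph::as_adjacency_matrix(gu, sparse = FALSE)
  nc <- as.numeric(adj %*% deg_all) / pmax(deg_u, 1)

  bc <- igraph::betweenness(g, directed = TRUE)

  cc <- igraph::transitivity(gu, type = "local", isolates = "zero")
  cr <- vapply(seq_len(n), function(i) {
    nb <- igraph::neighbors(g, i, mode = "out")
    10^(-cc[i]) * sum(deg_out[nb] + 1)
  }, numeric(1))

  dmat <- igraph::distances(gu)
  ci <- vapply(seq_len(n), function(i) {
    ring <- which(dmat[i, ] == l)
    (deg_u[i] - 1) * sum(deg_u[ring] - 1)
  }, numeric(1))

  hubness <- minmax01(deg_all) + minmax01(nc)
  spreading <- minmax01(bc) + minmax01(cr) + minmax01(ci)
  score <- 1 + 99 * minmax01(hubness * spreading)

  out <- data.frame(node = nodes, out_degree = deg_out,
                    in_degree = igraph::degree(g, mode = "in"),
                    degree = deg_all, neighborhood_connectivity = nc,
                    betweenness = bc, cluster_rank = cr,
                    collective_influence = ci,
                    hubness = hubness, spreading = spreading, ivi = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ivi, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target conservation versus connectivity across organ networks
#'
#' For every TF present in at least two organ networks: conserved targets
#' are those present in every organ network containing the TF; the
#' conservation percentage divides by the union of the TF's targets across
#' those organs (so 100% means identical sets); mean connectivity is the
#' mean out-degree. An ordinary least squares fit of conservation on mean
#' connectivity summarizes the trend.
#'
#' @param networks named list organ -> `grn`/edge data frame.
#' @return list with `table` (per-TF mean_connectivity, conservation,
#'   n_organs; TFs in a single organ carry NA conservation) and `fit`
#'   (slope, intercept, r_squared, p_value) or NULL when fewer than 3 TFs
#'   qualify.
#' @export
target_conservation <- function(networks) {
  tgt_sets <- lapply(networks, function(g) {
    g <- as.data.frame(g)
    split(g$target, g$regulator)
  })
  tfs <- sort(unique(unlist(lapply(tgt_sets, names))))
  rows <- lapply(tfs, function(tf) {
    per_organ <- lapply(tgt_sets, function(s) unique(s[[tf]]))
    per_organ <- per_organ[!vapply(per_organ, is.null, logical(1))]
    k <- length(per_organ)
    conn <- mean(vapply(per_organ, length, numeric(1)))
    cons <- if (k >= 2L) {
      100 * length(Reduce(intersect, per_organ)) /
        length(unique(unlist(per_organ)))
    } else NA_real_
    data.frame(tf = tf, mean_connectivity = conn, conservation = cons,
               n_organs = k, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  usable <- tab[!is.na(tab$conservation), , drop = FALSE]
  fit <- NULL
  if (nrow(usable) >= 3L) {
    m <- stats::lm(conservation ~ mean_connectivity, data = usable)
    sm <- summary(m)
    fit <- list(slope = unname(stats::coef(m)[2]),
                intercept = unname(stats::coef(m)[1]),
                r_squared = sm$r.squared,
                p_value = sm$coefficients[2, 4])
  }
  list(table = tab, fit = fit)
}

#' Extract a subnetwork around a gene list
#'
#' @param net an `evidence_network`/`grn`/edge data frame.
#' @param genes character vector of gene ids.
#' @param mode "targets_of" keeps edges leaving the listed TFs,
#'   "regulators_of" keeps edges entering the listed genes, "induced"
#'   keeps edges with both endpoints listed.
#' @return the filtered edge data frame (all columns preserved).
#' @export
extract_subnetwork <- function(net, genes,
                               mode = c("targets_of", "regulators_of", "induced")) {
  mode <- match.arg(mode)
  net <- as.data.frame(net)
  keep <- switch(mode,
    targets_of = net$regulator %in% genes,
    regulators_of = net$target %in% genes,
    induced = net$regulator %in% genes & net$target %in% genes)
  out <- net[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation of GO terms
#'
#' Upper-tail hypergeometric test of each annotation term's overlap with a
#' target set against a gene universe, BH-adjusted across the tested
#' terms. Only terms hitting at least one target are tested.
#'
#' @param target_set character vector of genes (must be inside
#'   `universe`).
#' @param annotation data frame with columns `gene_id` and `term`.
#' @param universe character vector of background genes.
#' @param fdr significance threshold on adjusted p (default 0.05).
#' @return data frame (term, term_size, set_size, overlap, p_value, p_adj,
#'   significant) sorted by p.
#' @export
ora <- function(target_set, annotation, universe, fdr = 0.05) {
  universe <- unique(universe)
  target_set <- unique(target_set)
  if (!length(universe)) stop("empty universe")
  if (!length(target_set)) stop("empty target set")
  if (!all(target_set %in% universe))
    stop("target set must be contained in the universe")
  anno <- unique(annotation[annotation$gene_id %in% universe,
                            c("gene_id", "term")])
  term_genes <- split(anno$gene_id, anno$term)
  rows <- lapply(names(term_genes), function(tm) {
    K <- length(term_genes[[tm]])
    k <- sum(target_set %in% term_genes[[tm]])
    if (k == 0L) return(NULL)
    p <- stats::phyper(k - 1, K, length(universe) - K, length(target_set),
                       lower.tail = FALSE)
    data.frame(term = tm, term_size = K, set_size = length(target_set),
               overlap = k, p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term = character(), term_size = integer(),
                      set_size = integer(), overlap = integer(),
                      p_value = numeric(), p_adj = numeric(),
                      significant = logical()))
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adj < fdr
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
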