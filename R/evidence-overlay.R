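# Annotate inferred GRN edges with auxiliary evidence layers without
# touching the topology, plus the evidence / organ-overlap summaries.

#' Overlay auxiliary evidence onto a GRN
#'
#' Flags each edge of the network by membership in three directed
#' TF->target evidence sets: aggregated co-expression, promoter motifs and
#' open-chromatin motifs. The edge set itself is never altered — auxiliary
#' pairs absent from the GRN are ignored. `evidence_count` is 1 (the
#' inference itself) plus the number of supporting layers.
#'
#' @param grn a `grn` (or data frame with regulator/target columns).
#' @param coexp_pairs,promoter_pairs,ocs_pairs data frames of directed
#'   pairs (regulator, target); may be empty.
#' @return an `evidence_network` data frame: the GRN columns plus logical
#'   `coexp`, `promoter_motif`, `ocs_motif` and integer `evidence_count`.
#' @export
overlay <- function(grn, coexp_pairs = NULL, promoter_pairs = NULL,
                    ocs_pairs = NULL) {
  net <- as.data.frame(grn)
  key <- pair_key(net$regulator, net$target)
  flag <- function(pairs) {
    if (is.null(pairs) || !nrow(pairs)) return(rep(FALSE, nrow(net)))
    key %in% pair_key(pairs$regulator, pairs$target)
  }
  net$coexp <- flag(coexp_pairs)
  net$promoter_motif <- flag(promoter_pairs)
  net$ocs_motif <- flag(ocs_pairs)
  net$evidence_count <- 1L + net$coexp + net$promoter_motif + net$ocs_motif
  structure(net, class = c("evidence_network", "data.frame"))
}

#' Evidence-support histogram of an annotated network
#'
#' @param net an `evidence_network`.
#' @return list with `by_count` (proportions of edges at evidence count
#'   1..4, summing to 1) and `by_layer` (fraction of edges supported by
#'   each auxiliary layer).
#' @export
evidence_histogram <- function(net) {
  n <- nrow(net)
  if (!n) stop("empty network")
  by_count <- as.numeric(table(factor(net$evidence_count, levels = 1:4))) / n
  names(by_count) <- as.character(1:4)
  list(by_count = by_count,
       by_layer = c(coexp = mean(net$coexp),
                    promoter_motif = mean(net$promoter_motif),
                    ocs_motif = mean(net$ocs_motif)),
       any_support = mean(net$evidence_count > 1L))
}

#' Edge overlap across organ networks
#'
#' Labels every edge of the union of the organ GRNs with the number of
#' organ networks containing it.
#'
#' @param networks named list organ -> `grn` (or edge data frame).
#' @return list with `edges` (regulator, target, n_organs) and
#'   `distribution` (proportion of union edges shared by 1..n organs).
#' @export
organ_overlap <- function(networks) {
  if (!length(networks)) stop("empty network list")
  keys <- lapply(networks, function(g) {
    g <- as.data.frame(g)
    unique(pair_key(g$regulator, g$target))
  })
  all_keys <- sort(unique(unlist(keys)))
  counts <- rowSums(vapply(keys, function(k) all_keys %in% k,
                           logical(length(all_keys))))
  parts <- do.call(rbind, strsplit(all_keys, "\t", fixed = TRUE))
  dist <- as.numeric(table(factor(counts, levels = seq_along(networks)))) /
    length(all_keys)
  names(dist) <- as.character(seq_along(networks))
  list(edges = data.frame(regulator = parts[, 1], target = parts[, 2],
                          n_organs = as.integer(counts),
                          stringsAsFactors = FALSE),
       distribution = dist)
}
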