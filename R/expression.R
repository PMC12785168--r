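# Expression containers, normalization, and the expression/organ-specificity
# filters that decide which genes enter each organ-level network.

#' Expression matrix with sample metadata
#'
#' A light container: a genes x samples numeric matrix plus per-sample
#' organ and study labels and a unit tag. All values must be nonnegative
#' and every sample needs an organ label.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param organ character vector of organ labels, one per column.
#' @param study_id character vector of study labels, one per column
#'   (defaults to a single study).
#' @param unit one of "counts", "TPM", "FPKM", "arbitrary".
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, organ, study_id = "study1",
                        unit = c("counts", "TPM", "FPKM", "arbitrary")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique gene rownames")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (any(values < 0)) stop("expression values must be nonnegative")
  organ <- rep_len(as.character(organ), ncol(values))
  if (anyNA(organ)) stop("every sample needs an organ label")
  meta <- data.frame(sample_id = colnames(values), organ = organ,
                     study_id = rep_len(as.character(study_id), ncol(values)),
                     stringsAsFactors = FALSE)
  structure(list(values = values, samples = meta, unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples; organs: %s\n",
              x$unit, nrow(x$values), ncol(x$values),
              paste(unique(x$samples$organ), collapse = ", ")))
  invisible(x)
}

#' Subset an expression matrix by sample
#'
#' @param em an `expr_matrix`.
#' @param idx logical/integer index, or use `organ`/`study` to select by
#'   metadata.
#' @param organ,study optional label filters applied before `idx`.
#' @return an `expr_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(em, idx = NULL, organ = NULL, study = NULL) {
  sel <- rep(TRUE, ncol(em$values))
  if (!is.null(organ)) sel <- sel & em$samples$organ %in% organ
  if (!is.null(study)) sel <- sel & em$samples$study_id %in% study
  sel <- which(sel)
  if (!is.null(idx)) sel <- sel[idx]
  expr_matrix(em$values[, sel, drop = FALSE], em$samples$organ[sel],
              em$samples$study_id[sel], em$unit)
}

values_of <- function(x) if (inherits(x, "expr_matrix")) x$values else as.matrix(x)

check_lengths <- function(counts, lengths) {
  if (is.null(names(lengths))) stop("gene lengths must be named")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop("missing length for gene: ", paste(utils::head(missing, 5), collapse = ", "))
  if (any(lengths[rownames(counts)] <= 0)) stop("gene lengths must be positive")
  lengths[rownames(counts)]
}

#' Convert raw counts to TPM
#'
#' Per sample, `rate_g = count_g / length_g` and
#' `TPM_g = 1e6 * rate_g / sum(rates)`, so every nonzero sample's TPM
#' column sums to one million. All-zero samples stay all-zero with a
#' warning.
#'
#' @param counts `expr_matrix` (unit counts) or plain counts matrix.
#' @param lengths named vector of per-gene lengths in bases.
#' @return an `expr_matrix` with unit "TPM" (metadata preserved when the
#'   input carried it; otherwise single-organ defaults).
#' @export
counts_to_tpm <- function(counts, lengths) {
  v <- values_of(counts)
  len <- check_lengths(v, lengths)
  rate <- v / len
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    grn_log("warn", sum(zero), " all-zero sample(s) left all-zero in TPM")
    tot[zero] <- 1
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  wrap_like(counts, tpm, "TPM")
}

#' Convert raw counts to FPKM
#'
#' `FPKM_g = 1e9 * count_g / (length_g * sum(counts in sample))`.
#'
#' @inheritParams counts_to_tpm
#' @return an `expr_matrix` with unit "FPKM".
#' @export
counts_to_fpkm <- function(counts, lengths) {
  v <- values_of(counts)
  len <- check_lengths(v, lengths)
  lib <- colSums(v)
  zero <- lib == 0
  if (any(zero)) {
    grn_log("warn", sum(zero), " all-zero sample(s) left all-zero in FPKM")
    lib[zero] <- 1
  }
  fpkm <- sweep(v / len, 2, lib, "/") * 1e9
  wrap_like(counts, fpkm, "FPKM")
}

wrap_like <- function(template, values, unit) {
  if (inherits(template, "expr_matrix"))
    expr_matrix(values, template$samples$organ, template$samples$study_id, unit)
  else
    expr_matrix(values, organ = "organ1", unit = unit)
}

#' Flag genes expressed in an organ
#'
#' A gene counts as expressed when it reaches `threshold` TPM in at least
#' `ceiling(fraction * n_samples)` of the organ's samples; both comparisons
#' are inclusive, so "at least 10% of 14 libraries" means 2 libraries.
#'
#' @param tpm an `expr_matrix` (or matrix) restricted to one organ's
#'   samples.
#' @param threshold TPM cutoff (default 5).
#' @param fraction minimum fraction of samples (default 0.10).
#' @return character vector of expressed gene ids.
#' @export
flag_expressed <- function(tpm, threshold = 5, fraction = 0.10) {
  v <- values_of(tpm)
  if (ncol(v) == 0L) stop("flag_expressed needs at least one sample")
  need <- ceiling(fraction * ncol(v))
  hits <- rowSums(v >= threshold)
  rownames(v)[hits >= need]
}

#' Summarize organ specificity of expression
#'
#' Given per-organ expressed-gene sets, classes every gene by the number of
#' organs it is expressed in (1..n_organs) and flags single-organ genes as
#' organ-specific.
#'
#' @param sets named list: organ -> character vector of expressed genes.
#' @return list with `organ_count` (named integer per gene),
#'   `class_histogram` (table over 1..n_organs), `specific` (class-1 gene
#'   ids) and `sets` (the input).
#' @export
organ_specificity <- function(sets) {
  if (!length(sets)) stop("empty organ set mapping")
  genes <- sort(unique(unlist(sets)))
  counts <- vapply(genes, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), integer(1))
  hist <- table(factor(counts, levels = seq_along(sets)))
  list(organ_count = counts, class_histogram = hist,
       specific = genes[counts == 1L], sets = sets)
}

#' Z-scale the rows of a mean-expression table
#'
#' Each row is centered and scaled to population (divide-by-n) standard
#' deviation, the convention for display heatmaps. Constant rows map to
#' all zeros with a warning.
#'
#' @param table numeric matrix (genes x organs).
#' @return matrix of the same shape with row mean 0 and population sd 1.
#' @export
zscore_rows <- function(table) {
  table <- as.matrix(table)
  mu <- rowMeans(table)
  sd_pop <- sqrt(rowMeans((table - mu)^2))
  flat <- sd_pop == 0
  if (any(flat)) {
    grn_log("warn", sum(flat), " constant row(s) z-scaled to zero")
    sd_pop[flat] <- 1
  }
  (table - mu) / sd_pop
}
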