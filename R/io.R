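# Readers and writers for the standard formats the pipeline consumes and
# produces. GFF3 goes through rtracklayer, FASTA through Biostrings; the
# simple tabular formats (BED4+/narrowPeak, TSV edge lists, JASPAR text)
# use plain table I/O so round-trips are exact.

#' Read gene models from GFF3
#'
#' Only `gene` features are used. GFF3 coordinates (1-based inclusive) are
#' converted to the internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default "gene").
#' @return a `gene_models` table.
#' @export
read_gene_models <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  if (length(gr) == 0L) stop("no '", feature, "' features in ", path)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) ids <- gr$Name
  gene_models(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write gene models to GFF3
#'
#' @param genes a `gene_models` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$contig,
    IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$Name <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read/write BED intervals
#'
#' BED is 0-based half-open, matching the internal convention, so fields map
#' directly. narrowPeak files (BED6+4) are accepted; the extra columns are
#' ignored. Missing name/score/strand columns become NA/".".
#'
#' @param path BED file.
#' @return a `genomic_intervals` table.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  genomic_intervals(
    contig = tab[[1]], start = tab[[2]], end = tab[[3]],
    name = if (ncol(tab) >= 4) tab[[4]] else NA_character_,
    score = if (ncol(tab) >= 5) suppressWarnings(as.numeric(tab[[5]])) else NA_real_,
    strand = if (ncol(tab) >= 6) ifelse(tab[[6]] %in% c("+", "-"), tab[[6]], ".") else "."
  )
}

#' @rdname read_bed
#' @param intervals a `genomic_intervals` table.
#' @export
write_bed <- function(intervals, path) {
  out <- data.frame(
    intervals$contig, intervals$start, intervals$end,
    ifelse(is.na(intervals$name), ".", intervals$name),
    ifelse(is.na(intervals$score), 0, intervals$score),
    intervals$strand
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write FASTA sequence sets
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read/write ranked edge lists as TSV
#'
#' Columns: `regulator`, `target`, `weight`, plus any extra columns present
#' (evidence flags, rank). Read/write round-trips exactly.
#'
#' @param path TSV file.
#' @return data frame of edges.
#' @export
read_edge_list <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_edge_list
#' @param edges data frame with at least `regulator` and `target` columns.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Accepts the JASPAR 2016+ bracket format:
#' \preformatted{>MA0001.1 NAME
#' A [ 4 19 0 ]
#' C [16  0 20 ]
#' ...}
#' Rows may also be unbracketed whitespace-separated counts in A/C/G/T
#' order. Motif ids map to TF ids via the header's second token when
#' present, else the id itself.
#'
#' @param path JASPAR-format text file.
#' @return list of `pfm` objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no motif headers in ", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(body[seq_len(min(4, length(body)))], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[i]] <- pfm(m, id = hdr[1], tf = if (length(hdr) > 1) hdr[2] else hdr[1])
  }
  names(out) <- vapply(out, function(p) p$id, character(1))
  out
}

#' @rdname read_jaspar
#' @param pfms list of `pfm` objects.
#' @export
write_jaspar <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(sprintf(">%s %s", p$id, p$tf), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$matrix[b, ], trim = TRUE), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable constant of the pipeline with its default:
#' the 5-TPM/10% expression filter, the 0.5-FPKM co-expression filter, the
#' top-percent GRN thresholds, the 1e-4 motif p-value, the 0.05 FDR, 1000
#' permutations, the 1000-target gold-standard cutoff, the 2-kb promoter,
#' the (-2000, +500) TSS assignment window, the (2.5, 97.5) percentile
#' interval and the stage seeds (inference defaults to seed 123).
#'
#' @param ... named overrides of any default field.
#' @return a classed list of configuration values.
#' @export
run_config <- function(...) {
  cfg <- list(
    seeds = list(inference = 123L, permutation = 1L, simulation = 1L),
    tpm = 5, tpm_fraction = 0.10, fpkm = 0.5,
    top_percent = c(1, 2, 5, 8, 10),
    motif_p = 1e-4, fdr = 0.05, permutations = 1000L,
    gold_min_targets = 1000L, promoter_len = 2000L,
    dap_window = c(-2000, 500), ci_percentiles = c(2.5, 97.5),
    paths = list(), log_level = "info"
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  num <- c(cfg$tpm, cfg$tpm_fraction, cfg$fpkm, cfg$top_percent, cfg$motif_p,
           cfg$fdr, cfg$permutations, cfg$gold_min_targets, cfg$promoter_len)
  if (any(num <= 0)) stop("all thresholds must be positive")
  if (diff(cfg$ci_percentiles) <= 0) stop("ci_percentiles must be increasing")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML or JSON file of configuration overrides.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}
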