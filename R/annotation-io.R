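# Genomic data model and annotation operations.
#
# Internal coordinate convention: 0-based, half-open [start, end), the BED
# convention. GFF3 I/O (1-based, inclusive) converts at the boundary.

#' Construct a gene-model table
#'
#' Gene models are plain data frames with one row per gene and 0-based
#' half-open coordinates. The transcription start site (TSS) is the
#' strand-aware 5' end: `start` for `+` genes, `end - 1` for `-` genes.
#' `length` is the (exonic or span) length in bases used for TPM/FPKM
#' normalization; it defaults to the genomic span.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param contig character vector of contig names.
#' @param start,end integer vectors, 0-based half-open span.
#' @param strand character vector, each "+" or "-".
#' @param length optional positive lengths for normalization (defaults to
#'   `end - start`).
#' @return a `data.frame` of class `gene_models` with columns `gene_id`,
#'   `contig`, `start`, `end`, `strand`, `tss`, `length`.
#' @examples
#' gene_models("g1", "chr1", 100, 600, "+")
#' @export
gene_models <- function(gene_id, contig, start, end, strand, length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == length(end), length(gene_id) == length(start))
  contig <- rep_len(as.character(contig), length(gene_id))
  strand <- rep_len(as.character(strand), length(gene_id))
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(start < 0) || any(start >= end))
    stop("gene spans must satisfy 0 <= start < end")
  if (!all(strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  length <- if (is.null(length)) end - start else as.integer(length)
  if (any(length < 1)) stop("gene length must be >= 1")
  out <- data.frame(
    gene_id = as.character(gene_id), contig = as.character(contig),
    start = start, end = end, strand = as.character(strand),
    tss = ifelse(strand == "+", start, end - 1L),
    length = length, stringsAsFactors = FALSE
  )
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Construct a genomic-interval table
#'
#' 0-based half-open intervals (BED convention) with optional name, score
#' and strand columns.
#'
#' @param contig,start,end interval coordinates (0-based half-open).
#' @param strand "+", "-" or "." (unstranded, the default).
#' @param name optional identifiers.
#' @param score optional numeric scores.
#' @return a `data.frame` of class `genomic_intervals`.
#' @export
genomic_intervals <- function(contig, start, end, strand = ".",
                              name = NA_character_, score = NA_real_) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end")
  n <- length(start)
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-", ".")))
    stop("interval strand must be '+', '-' or '.'")
  out <- data.frame(
    contig = rep_len(as.character(contig), n), start = start, end = end,
    strand = strand, name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n), stringsAsFactors = FALSE
  )
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Merge a secondary gene annotation into a primary one
#'
#' Keeps every primary gene and adds only those secondary genes whose span
#' overlaps (shares at least one base with) no primary gene span on the same
#' contig. Overlap is strand-ignorant: two models of the same locus on
#' opposite strands would otherwise both survive. The result is ordered by
#' contig, start and gene id, so merging is deterministic.
#'
#' @param primary,secondary `gene_models` tables.
#' @return a `gene_models` table containing all primary genes plus the
#'   non-overlapping secondary genes.
#' @export
merge_gene_models <- function(primary, secondary) {
  stopifnot(inherits(primary, "gene_models"), inherits(secondary, "gene_models"))
  if (nrow(secondary) == 0L) {
    keep <- secondary
  } else {
    pr <- GenomicRanges::GRanges(primary$contig,
                                 IRanges::IRanges(primary$start + 1L, primary$end))
    se <- GenomicRanges::GRanges(secondary$contig,
                                 IRanges::IRanges(secondary$start + 1L, secondary$end))
    hits <- suppressWarnings(
      GenomicRanges::countOverlaps(se, pr, ignore.strand = TRUE))
    keep <- secondary[hits == 0L, , drop = FALSE]
  }
  merged <- rbind(as.data.frame(primary), as.data.frame(keep))
  dup <- merged$gene_id[duplicated(merged$gene_id)]
  if (length(dup))
    stop("duplicate gene_id after merge: ", paste(unique(dup), collapse = ", "))
  merged <- merged[order(merged$contig, merged$start, merged$gene_id), , drop = FALSE]
  rownames(merged) <- NULL
  class(merged) <- c("gene_models", "data.frame")
  merged
}

#' Curate transcription factors by an evidence vote
#'
#' A gene is called a TF when it is supported by at least `min_sources`
#' independent evidence sources (annotation keywords, curated catalogs,
#' domain scans, orthology, ...) and is not on an exclusion list.
#'
#' @param evidence data frame with columns `gene_id` and `source`; one row
#'   per (gene, evidence-source) claim. Duplicated claims count once.
#' @param min_sources minimum number of distinct sources (default 3).
#' @param exclusion_list gene ids to remove regardless of the vote.
#' @return sorted character vector of TF gene ids.
#' @export
classify_tfs <- function(evidence, min_sources = 3L, exclusion_list = character()) {
  stopifnot(min_sources >= 1L,
            all(c("gene_id", "source") %in% names(evidence)))
  ev <- unique(evidence[, c("gene_id", "source")])
  counts <- table(ev$gene_id)
  tfs <- names(counts)[counts >= min_sources]
  sort(setdiff(tfs, exclusion_list))
}

#' Extract promoter sequences upstream of each TSS
#'
#' For a `+` strand gene the promoter is the genomic slice
#' `[max(0, tss - length), tss)`; for a `-` strand gene it is the reverse
#' complement of `[tss + 1, min(contig_end, tss + 1 + length))`. Either way
#' the returned string reads 5'->3' on the gene's own strand: position one
#' is promoter-distal and the last base abuts the TSS. Promoters truncated
#' to zero length at a contig boundary are omitted with a warning.
#'
#' @param genes a `gene_models` table.
#' @param genome named character vector (or `Biostrings::DNAStringSet`) of
#'   contig sequences.
#' @param length promoter length in bases (default 2000).
#' @return a `promoter_set`: list with `sequences` (named character, one
#'   per gene) and `source` (data frame of the genomic slices used).
#' @export
extract_promoters <- function(genes, genome, length = 2000L) {
  stopifnot(inherits(genes, "gene_models"), length >= 1L)
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  missing <- setdiff(unique(genes$contig), names(genome))
  if (base::length(missing)) {
    bad <- genes$gene_id[genes$contig %in% missing][1]
    stop("contig '", genes$contig[genes$gene_id == bad][1],
         "' for gene '", bad, "' not present in genome")
  }
  n <- nrow(genes)
  seqs <- character(n); s0 <- integer(n); e0 <- integer(n); keep <- logical(n)
  for (i in seq_len(n)) {
    ctg <- genome[[genes$contig[i]]]
    clen <- nchar(ctg)
    if (genes$strand[i] == "+") {
      s <- max(0L, genes$tss[i] - as.integer(length)); e <- genes$tss[i]
    } else {
      s <- genes$tss[i] + 1L; e <- min(clen, genes$tss[i] + 1L + as.integer(length))
    }
    s0[i] <- s; e0[i] <- e
    if (e <= s) next
    piece <- substr(ctg, s + 1L, e)  # 0-based half-open -> 1-based substr
    if (genes$strand[i] == "-") piece <- revcomp(piece)
    seqs[i] <- toupper(piece); keep[i] <- TRUE
  }
  if (any(!keep)) {
    grn_log("warn", "omitting ", sum(!keep), " gene(s) with zero-length promoters: ",
            paste(utils::head(genes$gene_id[!keep], 5), collapse = ", "))
  }
  promoter_set(
    sequences = stats::setNames(seqs[keep], genes$gene_id[keep]),
    source = data.frame(gene_id = genes$gene_id[keep], contig = genes$contig[keep],
                        start = s0[keep], end = e0[keep], strand = genes$strand[keep],
                        stringsAsFactors = FALSE)
  )
}

#' @rdname extract_promoters
#' @param sequences named character vector of promoter sequences.
#' @param source data frame of genomic slices (one row per sequence).
#' @export
promoter_set <- function(sequences, source) {
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            all(names(sequences) == source$gene_id))
  structure(list(sequences = sequences, source = source), class = "promoter_set")
}

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string (A/C/G/T/N, either case).
#' @return the reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Assign genomic intervals to genes
#'
#' Two assignment modes used when mapping peaks or open-chromatin sites to
#' genes:
#' \describe{
#'   \item{closest}{each interval maps to the gene(s) on the same contig
#'     minimizing the edge-to-edge genomic distance (0 when overlapping);
#'     equidistant genes are all returned.}
#'   \item{tss_window}{the interval midpoint must fall inside
#'     `[tss + window[1], tss + window[2]]` in strand-oriented coordinates
#'     (upstream negative); otherwise the interval is unassigned.}
#' }
#' Intervals on contigs without genes get an empty assignment.
#'
#' @param intervals a `genomic_intervals` table.
#' @param genes a `gene_models` table (non-empty).
#' @param mode "closest" or "tss_window".
#' @param window length-2 numeric, `(upstream, downstream)` offsets relative
#'   to the TSS for `tss_window` mode; default `c(-2000, 500)`.
#' @return a list, one element per interval row, each a character vector of
#'   assigned gene ids (possibly empty).
#' @export
assign_intervals_to_genes <- function(intervals, genes,
                                      mode = c("closest", "tss_window"),
                                      window = c(-2000, 500)) {
  mode <- match.arg(mode)
  stopifnot(inherits(genes, "gene_models"), nrow(genes) > 0)
  out <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    g <- genes[genes$contig == intervals$contig[i], , drop = FALSE]
    if (nrow(g) == 0L) { out[[i]] <- character(); next }
    if (mode == "closest") {
      # edge-to-edge gap between [s1,e1) and [s2,e2); 0 if overlapping/adjacent
      d <- pmax(g$start - intervals$end[i], intervals$start[i] - g$end, 0L)
      out[[i]] <- sort(g$gene_id[d == min(d)])
    } else {
      mid <- floor((intervals$start[i] + intervals$end[i] - 1L) / 2)
      off <- ifelse(g$strand == "+", mid - g$tss, g$tss - mid)
      out[[i]] <- sort(g$gene_id[off >= window[1] & off <= window[2]])
    }
  }
  names(out) <- if (all(!is.na(intervals$name)) &&
                    !anyDuplicated(intervals$name)) intervals$name
                else as.character(seq_len(nrow(intervals)))
  out
}
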