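# PWM construction, exact null p-values on a discretized score lattice,
# and FIMO-style scanning of promoter / open-chromatin sequences.

BASES <- c("A", "C", "G", "T")

#' Position frequency matrix
#'
#' @param matrix 4 x W nonnegative matrix of base counts or probabilities,
#'   rows A, C, G, T.
#' @param id motif identifier.
#' @param tf identifier of the TF the motif belongs to.
#' @return a `pfm` object.
#' @export
pfm <- function(matrix, id = "motif", tf = id) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) stop("PFM must have 4 rows (A, C, G, T)")
  rownames(matrix) <- BASES
  if (any(matrix < 0)) stop("PFM entries must be nonnegative")
  if (any(colSums(matrix) == 0)) stop("PFM has an all-zero column")
  structure(list(matrix = matrix, id = id, tf = tf, width = ncol(matrix)),
            class = "pfm")
}

#' Convert a PFM to a log-odds PWM
#'
#' Per column, `p = (count + pseudocount * bg) / (total + pseudocount)` and
#' the log-odds entry is `log2(p / bg)`. The PWM also carries an integer
#' discretization of its entries (bin width `eps` bits) that the exact
#' p-value machinery and the scanner share, so scores and their null tail
#' live on the same lattice.
#'
#' @param x a `pfm`.
#' @param background length-4 base composition summing to 1.
#' @param pseudocount pseudocount mass (default 0.01).
#' @param eps score-lattice bin width in bits (default 1e-3).
#' @return a `pwm` object with fields `matrix` (log-odds), `int_matrix`,
#'   `eps`, `background`, `min_score`, `max_score`.
#' @export
pfm_to_pwm <- function(x, background = c(0.25, 0.25, 0.25, 0.25),
                       pseudocount = 0.01, eps = 1e-3) {
  stopifnot(inherits(x, "pfm"))
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  background <- stats::setNames(as.numeric(background), BASES)
  tot <- colSums(x$matrix)
  p <- sweep(x$matrix, 2, tot + pseudocount, "/") +
    (pseudocount * background) / rep(tot + pseudocount, each = 4)
  lo <- log2(p / background)
  int <- round(lo / eps)
  structure(list(matrix = lo, int_matrix = int, eps = eps,
                 background = background, pseudocount = pseudocount,
                 id = x$id, tf = x$tf, width = ncol(lo),
                 min_score = sum(apply(lo, 2, min)),
                 max_score = sum(apply(lo, 2, max))),
            class = "pwm")
}

# Exact distribution of the integer lattice score of a random W-mer under
# the background model: dynamic programming column by column. Returns
# offset (the minimum achievable integer score) and the tail vector
# tail[k] = P(int score >= offset + k - 1).
pwm_score_tail <- function(pwm) {
  int <- pwm$int_matrix
  bg <- pwm$background
  lo <- sum(apply(int, 2, min)); hi <- sum(apply(int, 2, max))
  probs <- numeric(hi - lo + 1L)  # index = score - lo + 1
  # running distribution over partial sums
  cur_lo <- 0L
  cur <- 1
  for (w in seq_len(ncol(int))) {
    v <- int[, w]
    new_lo <- cur_lo + min(v)
    new_hi <- cur_lo + length(cur) - 1L + max(v)
    nxt <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- cur_lo + v[b] - new_lo
      idx <- seq_along(cur) + sh
      nxt[idx] <- nxt[idx] + cur * bg[b]
    }
    cur <- nxt; cur_lo <- new_lo
  }
  probs[(cur_lo - lo + 1L):(cur_lo - lo + length(cur))] <- cur
  list(offset = lo, tail = rev(cumsum(rev(probs))))
}

#' Exact p-value of a PWM score
#'
#' `P(score of a random W-mer under the background >= score)`, computed by
#' dynamic programming over the PWM's discretized score lattice. Monotone
#' nonincreasing in the score. A score above the maximum achievable gives
#' the smallest representable tail with a warning.
#'
#' @param pwm a `pwm` object.
#' @param score numeric score(s) in bits.
#' @return p-value(s) in (0, 1].
#' @export
score_pvalue <- function(pwm, score) {
  d <- pwm_score_tail(pwm)
  t <- as.integer(round(score / pwm$eps)) - d$offset + 1L
  over <- t > length(d$tail)
  if (any(over)) {
    grn_log("warn", "score above maximum achievable; returning smallest tail")
    t[over] <- length(d$tail)
  }
  t[t < 1L] <- 1L
  d$tail[t]
}

# Reverse-complement PWM: reverse the columns and swap A<->T, C<->G rows.
pwm_revcomp <- function(pwm) {
  flip <- function(m) m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE][BASES, , drop = FALSE]
  rc <- pwm
  m <- pwm$matrix[4:1, rev(seq_len(ncol(pwm$matrix))), drop = FALSE]
  rownames(m) <- BASES
  i <- pwm$int_matrix[4:1, rev(seq_len(ncol(pwm$int_matrix))), drop = FALSE]
  rownames(i) <- BASES
  rc$matrix <- m; rc$int_matrix <- i
  rc
}

# Integer window scores of a coded sequence (values 1..4, NA for N) for
# every offset; windows touching an NA score NA.
window_scores_int <- function(int_matrix, codes) {
  W <- ncol(int_matrix); L <- length(codes)
  if (L < W) return(integer(0))
  n_win <- L - W + 1L
  sc <- numeric(n_win)
  for (w in seq_len(W)) {
    col <- int_matrix[, w]
    sc <- sc + col[codes[w:(n_win + w - 1L)]]
  }
  sc
}

#' Scan a sequence for motif occurrences
#'
#' Scores every offset on both strands on the PWM's discretized lattice and
#' reports positions whose exact null p-value is at or below the
#' threshold. Windows containing N are skipped. Hits carry the
#' forward-strand 0-based start coordinate.
#'
#' @param pwm a `pwm`.
#' @param seq a DNA string (A/C/G/T/N).
#' @param p_threshold maximum p-value (default 1e-4, the conventional
#'   scanning default).
#' @param seq_id identifier recorded in the hit table.
#' @return data frame (motif, seq_id, start, strand, score, p_value);
#'   zero rows when the sequence is shorter than the motif.
#' @export
scan_sequence <- function(pwm, seq, p_threshold = 1e-4, seq_id = "seq") {
  codes <- match(strsplit(toupper(seq), "")[[1]], BASES)
  W <- pwm$width
  empty <- data.frame(motif = character(), seq_id = character(),
                      start = integer(), strand = character(),
                      score = numeric(), p_value = numeric())
  if (length(codes) < W) return(empty)
  d <- pwm_score_tail(pwm)
  fwd <- window_scores_int(pwm$int_matrix, codes)
  rev_ <- window_scores_int(pwm_revcomp(pwm)$int_matrix, codes)
  tail_at <- function(s) {
    t <- pmin(pmax(s - d$offset + 1L, 1L), length(d$tail))
    d$tail[t]
  }
  rows <- list()
  for (strand in c("+", "-")) {
    sc <- if (strand == "+") fwd else rev_
    ok <- which(!is.na(sc) & tail_at(sc) <= p_threshold)
    if (length(ok))
      rows[[strand]] <- data.frame(
        motif = pwm$id, seq_id = seq_id, start = ok - 1L, strand = strand,
        score = sc[ok] * pwm$eps, p_value = tail_at(sc[ok]),
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Normalize "pwms per TF" input: a named list whose elements are a pwm, a
# pfm, or a list of either; pfms are converted with default background.
normalize_tf_pwms <- function(pwms_by_tf) {
  lapply(pwms_by_tf, function(x) {
    if (inherits(x, "pwm")) list(x)
    else if (inherits(x, "pfm")) list(pfm_to_pwm(x))
    else lapply(x, function(m) if (inherits(m, "pfm")) pfm_to_pwm(m) else m)
  })
}

#' Motif-evidence TF->gene pairs from promoter scans
#'
#' A pair (TF, gene) is emitted when any of the TF's motifs hits the gene's
#' promoter at `p <= p_threshold` (multiple motifs per TF are OR-combined).
#' Promoters shorter than 50 bases are excluded from scanning.
#'
#' @param pwms_by_tf named list TF -> `pwm`/`pfm` (or list of them).
#' @param promoters a `promoter_set`.
#' @param p_threshold scan threshold (default 1e-4).
#' @return data frame (regulator, target).
#' @export
motif_edges_promoter <- function(pwms_by_tf, promoters, p_threshold = 1e-4) {
  pwms <- normalize_tf_pwms(pwms_by_tf)
  seqs <- promoters$sequences
  short <- nchar(seqs) < 50L
  if (any(short)) {
    grn_log("warn", sum(short), " promoter(s) shorter than 50 b excluded from scan")
    seqs <- seqs[!short]
  }
  rows <- list()
  for (tf in names(pwms)) {
    for (pw in pwms[[tf]]) {
      d <- pwm_score_tail(pw)
      ok_t <- which(d$tail <= p_threshold)
      if (!length(ok_t)) next
      t_star <- min(ok_t) + d$offset - 1L  # minimal significant lattice score
      rc <- pwm_revcomp(pw)
      for (g in names(seqs)) {
        codes <- match(strsplit(seqs[[g]], "")[[1]], BASES)
        if (length(codes) < pw$width) next
        sc <- pmax(window_scores_int(pw$int_matrix, codes),
                   window_scores_int(rc$int_matrix, codes))
        if (any(!is.na(sc) & sc >= t_star)) {
          rows[[length(rows) + 1L]] <- data.frame(regulator = tf, target = g,
                                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(regulator = character(), target = character()))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif-evidence TF->gene pairs from open-chromatin scans
#'
#' Extracts the sequence of each open-chromatin interval from the genome,
#' scans it with every TF's motifs, and maps hit-bearing intervals to
#' gene(s) by closest-gene assignment.
#'
#' @param pwms_by_tf named list TF -> `pwm`/`pfm` (or list of them).
#' @param ocs a `genomic_intervals` table of open-chromatin sites.
#' @param genome named character vector of contig sequences.
#' @param genes a `gene_models` table.
#' @param p_threshold scan threshold (default 1e-4).
#' @return data frame (regulator, target).
#' @export
motif_edges_ocs <- function(pwms_by_tf, ocs, genome, genes, p_threshold = 1e-4) {
  missing <- setdiff(unique(ocs$contig), names(genome))
  if (length(missing))
    stop("interval contig(s) outside the genome: ", paste(missing, collapse = ", "))
  seqs <- vapply(seq_len(nrow(ocs)), function(i)
    toupper(substr(genome[[ocs$contig[i]]], ocs$start[i] + 1L, ocs$end[i])),
    character(1))
  assigned <- assign_intervals_to_genes(ocs, genes, mode = "closest")
  pwms <- normalize_tf_pwms(pwms_by_tf)
  rows <- list()
  for (tf in names(pwms)) {
    for (pw in pwms[[tf]]) {
      d <- pwm_score_tail(pw)
      ok_t <- which(d$tail <= p_threshold)
      if (!length(ok_t)) next
      t_star <- min(ok_t) + d$offset - 1L
      rc <- pwm_revcomp(pw)
      for (i in seq_along(seqs)) {
        codes <- match(strsplit(seqs[[i]], "")[[1]], BASES)
        if (length(codes) < pw$width) next
        sc <- pmax(window_scores_int(pw$int_matrix, codes),
                   window_scores_int(rc$int_matrix, codes))
        if (any(!is.na(sc) & sc >= t_star) && length(assigned[[i]])) {
          rows[[length(rows) + 1L]] <- data.frame(regulator = tf,
                                                  target = assigned[[i]],
                                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(regulator = character(), target = character()))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
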