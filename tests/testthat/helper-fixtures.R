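# Shared fixture builders. Everything is generated in code at test time.

# Deterministic random DNA string.
random_dna <- function(n, seed = 1) {
  with_test_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = ""))
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Tiny gene-model fixture: three genes on two contigs.
toy_genes <- function() {
  gene_models(
    gene_id = c("gA", "gB", "gC"),
    contig = c("chr1", "chr1", "chr2"),
    start = c(1000L, 5000L, 2000L),
    end = c(2000L, 6200L, 3500L),
    strand = c("+", "-", "+")
  )
}

# A small fully specified PFM (counts) for hand calculations.
toy_pfm <- function() {
  m <- matrix(c(
    8, 0, 1, 2,
    1, 9, 1, 2,
    1, 0, 7, 2,
    0, 1, 1, 4
  ), nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm(m, id = "toy", tf = "TFtoy")
}

# Random PFM of width W with one strong base per column.
random_pfm <- function(W, seed, id = "rnd") {
  with_test_seed(seed, {
    m <- matrix(stats::runif(4 * W, 0.5, 3), 4, W,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    dom <- sample(4, W, replace = TRUE)
    m[cbind(dom, seq_len(W))] <- m[cbind(dom, seq_len(W))] + 10
    pfm(m, id = id)
  })
}

# Small ranked edge list with known labels for benchmarking tests.
toy_ranked <- function(weights, regulator = NULL, target = NULL) {
  n <- length(weights)
  data.frame(
    regulator = regulator %||% rep("tf1", n),
    target = target %||% sprintf("g%02d", seq_len(n)),
    weight = weights, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force AUROC: fraction of (pos, neg) pairs ranked
# concordantly, ties counting one half.
bruteforce_auroc <- function(weight, label) {
  pos <- weight[label]; neg <- weight[!label]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Direct-summation two-sided Fisher p for a 2x2 table with fixed margins.
bruteforce_fisher_p <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
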