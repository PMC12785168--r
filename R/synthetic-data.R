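# Ground-truth regulatory systems with every downstream input the pipeline
# consumes: expression + counts, a synthetic genome with promoters and
# planted motifs, open-chromatin intervals, and noisy ChIP-like gold
# standards. Everything is deterministic under the configured seed.

#' Simulation configuration
#'
#' Defaults describe a scaled-down organ-level study: five organs, 20 TFs
#' among 100 genes, heavy-tailed regulons of ~10 targets, strong signed
#' effects, multi-study sample blocks, ~1.5 bit/column motifs of width 8,
#' and a gold standard that keeps 90% of true edges and adds 10% false
#' pairs.
#'
#' @param ... named overrides. Fields: `n_tf`, `n_gene`,
#'   `n_samples_per_organ`, `n_studies`, `organs`, `mean_outdegree`,
#'   `effect_sd`, `noise_sd`, `organ_share` (fraction of edges active in
#'   every organ), `motif_plant_rate`, `ocs_cover_rate`,
#'   `gold_sensitivity`, `gold_fp_rate`, `gold_min_targets` (scaled-down
#'   qualifying cutoff), `nb_dispersion`, `study_sd`, `motif_width`,
#'   `ocs_width`, `background`, `seed`.
#' @return a classed list of simulation parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_tf = 20L, n_gene = 100L, n_samples_per_organ = 100L, n_studies = 4L,
    organs = c("root", "leaf", "flower", "fruit", "seed"),
    mean_outdegree = 10, effect_sd = 2, noise_sd = 0.5, organ_share = 0.25,
    motif_plant_rate = 0.8, ocs_cover_rate = 0.6,
    gold_sensitivity = 0.9, gold_fp_rate = 0.1, gold_min_targets = 5L,
    nb_dispersion = 0.3, study_sd = 0.2,
    motif_width = 8L, ocs_width = 150L,
    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config field: ", paste(unknown, collapse = ", "))
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  rates <- c(cfg$organ_share, cfg$motif_plant_rate, cfg$ocs_cover_rate,
             cfg$gold_sensitivity, cfg$gold_fp_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(c(cfg$n_tf, cfg$n_gene, cfg$n_samples_per_organ, cfg$n_studies) < 1))
    stop("counts must be positive")
  structure(cfg, class = "sim_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Generate a ground-truth regulatory system
#'
#' Draws per-TF out-degrees from a log-normal-mixed Poisson (heavy-tailed,
#' mean ~ `mean_outdegree`), samples distinct non-TF targets per TF with
#' signed effect sizes, splits edges into a fraction active in every organ
#' (`organ_share`) and the remainder active in exactly one organ, and
#' attaches one position frequency matrix per TF (a single dominant base
#' per column, ~1.5 bits) plus per-gene transcript lengths.
#'
#' @param cfg a `sim_config`.
#' @return a `synthetic_truth`: list with `tf_ids`, `gene_ids`, `edges`
#'   (data frame regulator/target/effect), `organ_masks` (organ -> edge row
#'   indices), `pfm_by_tf`, `lengths`, `seed`.
#' @export
generate_truth <- function(cfg = sim_config()) {
  stopifnot(cfg$n_tf >= 1L, cfg$n_gene > cfg$n_tf)
  n_targets <- cfg$n_gene - cfg$n_tf
  if (cfg$mean_outdegree >= cfg$n_gene)
    stop("infeasible degree demand: mean_outdegree >= n_gene")
  with_seed(cfg$seed, {
    tf_ids <- sprintf("TF%03d", seq_len(cfg$n_tf))
    tgt_ids <- sprintf("G%04d", seq_len(n_targets))
    gene_ids <- c(tf_ids, tgt_ids)

    lam <- stats::rlnorm(cfg$n_tf, 0, 0.5)
    lam <- lam / mean(lam) * cfg$mean_outdegree
    deg <- pmin(n_targets, pmax(1L, stats::rpois(cfg$n_tf, lam)))
    edges <- do.call(rbind, lapply(seq_len(cfg$n_tf), function(i) {
      tg <- sample(tgt_ids, deg[i])
      sign <- sample(c(1, -1), deg[i], replace = TRUE, prob = c(0.7, 0.3))
      eff <- sign * pmax(abs(stats::rnorm(deg[i], 0, cfg$effect_sd)),
                         0.1 * cfg$effect_sd)
      data.frame(regulator = tf_ids[i], target = tg, effect = eff,
                 stringsAsFactors = FALSE)
    }))
    rownames(edges) <- NULL

    shared <- stats::runif(nrow(edges)) < cfg$organ_share
    own <- sample(cfg$organs, nrow(edges), replace = TRUE)
    organ_masks <- lapply(cfg$organs, function(o)
      which(shared | own == o))
    names(organ_masks) <- cfg$organs

    pfm_by_tf <- lapply(tf_ids, function(tf) {
      m <- matrix(5, 4, cfg$motif_width, dimnames = list(c("A", "C", "G", "T"), NULL))
      dom <- sample(4, cfg$motif_width, replace = TRUE)
      m[cbind(dom, seq_len(cfg$motif_width))] <- 85
      pfm(m, id = paste0(tf, "_motif"), tf = tf)
    })
    names(pfm_by_tf) <- tf_ids

    lengths <- stats::setNames(
      pmax(200L, as.integer(round(stats::rlnorm(cfg$n_gene, log(1500), 0.3)))),
      gene_ids)

    structure(list(tf_ids = tf_ids, gene_ids = gene_ids, edges = edges,
                   organ_masks = organ_masks, pfm_by_tf = pfm_by_tf,
                   lengths = lengths, seed = cfg$seed),
              class = "synthetic_truth")
  })
}

#' Simulate organ expression from a ground truth
#'
#' TF abundances are log-normal per sample. Each non-TF gene's abundance is
#' `softplus(sum of active-edge effect x regulator abundance)` plus
#' Gaussian noise (`noise_sd`), truncated at zero; genes without active
#' regulators sit near `softplus(0)`. Samples are split into `n_studies`
#' blocks and every (study, gene) pair receives a multiplicative
#' log-normal scale factor (`study_sd` on the log scale), giving
#' per-study co-expression something nontrivial to aggregate over. Counts
#' are negative binomial with mean proportional to abundance x transcript
#' length x per-sample depth.
#'
#' @param truth a `synthetic_truth`.
#' @param organ one of the organs in `truth$organ_masks`.
#' @param cfg the `sim_config` used to generate the truth.
#' @return list with `abundance` (an `expr_matrix`, unit "arbitrary"),
#'   `counts` (unit "counts") and `lengths`.
#' @export
simulate_expression <- function(truth, organ, cfg = sim_config()) {
  if (!organ %in% names(truth$organ_masks))
    stop("unknown organ: ", organ)
  oi <- match(organ, names(truth$organ_masks))
  n <- cfg$n_samples_per_organ
  with_seed(cfg$seed + 7919L * oi, {
    study <- sort(rep_len(seq_len(cfg$n_studies), n))
    study_id <- sprintf("%s_study%02d", organ, study)
    sample_id <- sprintf("%s_s%04d", organ, seq_len(n))

    n_tf <- length(truth$tf_ids)
    tf_log <- matrix(stats::rnorm(n_tf * n, 2, 1), n_tf, n,
                     dimnames = list(truth$tf_ids, sample_id))
    tf_ab <- exp(tf_log)

    A <- matrix(0, length(truth$gene_ids), n,
                dimnames = list(truth$gene_ids, sample_id))
    A[truth$tf_ids, ] <- tf_ab

    act <- truth$edges[truth$organ_masks[[organ]], , drop = FALSE]
    non_tf <- setdiff(truth$gene_ids, truth$tf_ids)
    mean_ab <- exp(2 + 1 / 2)  # analytic mean of the log-normal TF abundance
    for (g in non_tf) {
      e <- act[act$target == g, , drop = FALSE]
      if (nrow(e)) {
        # basal transcription input sized to the expected regulatory input,
        # so repression produces a graded decrease instead of silence
        basal <- sum(abs(e$effect)) * mean_ab
        s <- basal + colSums(e$effect * tf_ab[e$regulator, , drop = FALSE])
      } else {
        s <- rep(0, n)
      }
      A[g, ] <- softplus(s)
    }

    sf <- matrix(exp(stats::rnorm(length(truth$gene_ids) * cfg$n_studies,
                                  0, cfg$study_sd)),
                 length(truth$gene_ids), cfg$n_studies,
                 dimnames = list(truth$gene_ids, NULL))
    A <- A * sf[, study, drop = FALSE]
    if (cfg$noise_sd > 0)
      A <- pmax(A + matrix(stats::rnorm(length(A), 0, cfg$noise_sd),
                           nrow(A), ncol(A)), 0)

    depth <- stats::rlnorm(n, log(20), 0.3)
    mu <- sweep(A * (truth$lengths[rownames(A)] / 1000), 2, depth, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$nb_dispersion),
                     nrow(mu), ncol(mu), dimnames = dimnames(mu))

    list(abundance = expr_matrix(A, organ, study_id, "arbitrary"),
         counts = expr_matrix(counts, organ, study_id, "counts"),
         lengths = truth$lengths)
  })
}

# Consensus (maximum-scoring) word of a PFM: per-column argmax base.
consensus_word <- function(p) {
  paste(rownames(p$matrix)[apply(p$matrix, 2, which.max)], collapse = "")
}

#' Plant true-edge motifs into promoters
#'
#' For every true edge, with probability `q` the maximum-scoring word of
#' the regulator's PWM is written at a uniform random position of the
#' target promoter. Promoters shorter than the motif are skipped with a
#' warning. The returned set carries a `placements` attribute (regulator,
#' target, 1-based position within the promoter string).
#'
#' @param truth a `synthetic_truth`.
#' @param promoters a `promoter_set` (background sequences).
#' @param q planting rate in \[0, 1\].
#' @param seed RNG seed.
#' @return the edited `promoter_set`.
#' @export
plant_motifs <- function(truth, promoters, q, seed = truth$seed) {
  stopifnot(q >= 0, q <= 1)
  seqs <- promoters$sequences
  placed <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(truth$edges))) {
      if (stats::runif(1) >= q) next
      reg <- truth$edges$regulator[i]; tgt <- truth$edges$target[i]
      if (!tgt %in% names(seqs)) next
      word <- consensus_word(truth$pfm_by_tf[[reg]])
      W <- nchar(word); P <- nchar(seqs[[tgt]])
      if (P < W) {
        grn_log("warn", "promoter of ", tgt, " shorter than motif; skipped")
        next
      }
      pos <- sample.int(P - W + 1L, 1L)
      substr(seqs[[tgt]], pos, pos + W - 1L) <- word
      placed[[length(placed) + 1L]] <-
        data.frame(regulator = reg, target = tgt, pos = pos, width = W,
                   stringsAsFactors = FALSE)
    }
  })
  out <- promoter_set(seqs, promoters$source)
  attr(out, "placements") <- if (length(placed)) do.call(rbind, placed)
                             else data.frame(regulator = character(),
                                             target = character(),
                                             pos = integer(), width = integer())
  out
}

#' Build a synthetic genome hosting the truth's genes
#'
#' Genes are laid out on contigs of 20 slots of 6 kb each, alternating
#' strands, with 2 kb of clear promoter space upstream of every TSS and at
#' least 2.8 kb separating a promoter from the nearest neighboring gene
#' body (so closest-gene assignment of promoter-resident intervals is
#' unambiguous). Sequence is i.i.d. background.
#'
#' @param truth a `synthetic_truth`.
#' @param cfg the matching `sim_config`.
#' @return list with `genome` (named character contigs) and `genes` (a
#'   `gene_models` table whose `length` column is the transcript length
#'   used for normalization).
#' @export
simulate_genome <- function(truth, cfg = sim_config()) {
  n <- length(truth$gene_ids)
  slot <- 6000L; per_ctg <- 20L
  ctg_of <- (seq_len(n) - 1L) %/% per_ctg + 1L
  slot_of <- (seq_len(n) - 1L) %% per_ctg
  base <- slot_of * slot
  strand <- rep(c("+", "-"), length.out = n)
  start <- ifelse(strand == "+", base + 2500L, base + 2300L)
  end <- start + 1200L
  with_seed(cfg$seed + 104729L, {
    n_ctg <- max(ctg_of)
    genome <- stats::setNames(vapply(seq_len(n_ctg), function(i) {
      len <- sum(ctg_of == i) * slot
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                   prob = cfg$background), collapse = "")
    }, character(1)), sprintf("ctg%02d", seq_len(n_ctg)))
    genes <- gene_models(truth$gene_ids, sprintf("ctg%02d", ctg_of),
                         start, end, strand,
                         length = truth$lengths[truth$gene_ids])
    list(genome = genome, genes = genes)
  })
}

# Write (possibly edited) promoter sequences back into genome contigs,
# reverse-complementing for minus-strand genes.
write_promoters_to_genome <- function(genome, promoters) {
  src <- promoters$source
  for (i in seq_len(nrow(src))) {
    s <- promoters$sequences[[src$gene_id[i]]]
    if (src$strand[i] == "-") s <- revcomp(s)
    substr(genome[[src$contig[i]]], src$start[i] + 1L, src$end[i]) <- s
  }
  genome
}

# Genomic 0-based start of a motif planted at 1-based promoter-string
# position `pos` (strand-aware).
placement_genome_start <- function(src_row, pos, width) {
  if (src_row$strand == "+") src_row$start + pos - 1L
  else src_row$end - (pos - 1L) - width
}

#' Derive open-chromatin intervals covering planted motifs
#'
#' A fraction `ocs_cover_rate` of planted motif instances receives an
#' open-chromatin interval of width `ocs_width` centered on the motif;
#' half as many background intervals are scattered uniformly.
#'
#' @param truth a `synthetic_truth`.
#' @param promoters planted `promoter_set` (with `placements` attribute).
#' @param genes the `gene_models` from [simulate_genome()].
#' @param genome the contig sequences.
#' @param cfg the `sim_config`.
#' @return a `genomic_intervals` table.
#' @export
simulate_ocs <- function(truth, promoters, genes, genome, cfg = sim_config()) {
  pl <- attr(promoters, "placements")
  src <- promoters$source
  with_seed(cfg$seed + 15485863L, {
    rows <- list()
    if (nrow(pl)) {
      covered <- which(stats::runif(nrow(pl)) < cfg$ocs_cover_rate)
      for (i in covered) {
        sr <- src[src$gene_id == pl$target[i], , drop = FALSE][1, ]
        g0 <- placement_genome_start(sr, pl$pos[i], pl$width[i])
        mid <- g0 + pl$width[i] %/% 2L
        s <- max(0L, mid - cfg$ocs_width %/% 2L)
        e <- min(nchar(genome[[sr$contig]]), s + cfg$ocs_width)
        rows[[length(rows) + 1L]] <- data.frame(contig = sr$contig, start = s,
                                                end = e, stringsAsFactors = FALSE)
      }
    }
    n_bg <- max(1L, round(length(rows) / 2))
    for (j in seq_len(n_bg)) {
      ctg <- sample(names(genome), 1L)
      s <- sample.int(nchar(genome[[ctg]]) - cfg$ocs_width, 1L) - 1L
      rows[[length(rows) + 1L]] <- data.frame(contig = ctg, start = s,
                                              end = s + cfg$ocs_width,
                                              stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    genomic_intervals(tab$contig, tab$start, tab$end,
                      name = sprintf("ocs_%04d", seq_len(nrow(tab))))
  })
}

#' Corrupt the truth into a ChIP-like gold standard
#'
#' Keeps each organ-active true edge with probability `sensitivity`, adds
#' false TF->target pairs at `fp_rate` relative to the kept count, and
#' retains only TFs whose resulting target count strictly exceeds
#' `min_targets` (the production-scale qualifying cutoff of 1000 mapped
#' targets, scaled down for synthetic runs).
#'
#' @param truth a `synthetic_truth`.
#' @param organ organ whose active edges define the reference.
#' @param sensitivity,fp_rate rates in \[0, 1\].
#' @param seed RNG seed.
#' @param min_targets qualifying cutoff (strict >).
#' @return a `gold_standard` (named list TF -> target set).
#' @export
corrupt_gold <- function(truth, organ, sensitivity, fp_rate,
                         seed = truth$seed, min_targets = 5L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_rate >= 0, fp_rate <= 1)
  act <- truth$edges[truth$organ_masks[[organ]], , drop = FALSE]
  true_keys <- pair_key(truth$edges$regulator, truth$edges$target)
  with_seed(seed + 97L, {
    kept <- act[stats::runif(nrow(act)) < sensitivity, , drop = FALSE]
    pairs <- kept[, c("regulator", "target")]
    n_fp <- round(fp_rate * nrow(kept))
    tries <- 0L
    while (n_fp > 0 && tries < 50L) {
      cand <- data.frame(
        regulator = sample(truth$tf_ids, n_fp, replace = TRUE),
        target = sample(truth$gene_ids, n_fp, replace = TRUE),
        stringsAsFactors = FALSE)
      ok <- cand$regulator != cand$target &
        !pair_key(cand$regulator, cand$target) %in%
          c(true_keys, pair_key(pairs$regulator, pairs$target))
      pairs <- rbind(pairs, cand[ok, , drop = FALSE])
      n_fp <- n_fp - sum(ok); tries <- tries + 1L
    }
    gold_standard(split(pairs$target, pairs$regulator),
                  min_targets = min_targets,
                  provenance = paste0("synthetic:", organ))
  })
}

#' Simulate a complete study
#'
#' One call producing everything the pipeline stages consume: truth,
#' genome + gene models, planted promoters, open-chromatin intervals,
#' per-organ expression/counts and per-organ gold standards.
#'
#' @param cfg a `sim_config`.
#' @return a named list (`truth`, `genome`, `genes`, `promoters`, `ocs`,
#'   `expression` per organ, `gold` per organ, `cfg`).
#' @export
simulate_system <- function(cfg = sim_config()) {
  truth <- generate_truth(cfg)
  gen <- simulate_genome(truth, cfg)
  prom_bg <- extract_promoters(gen$genes, gen$genome, 2000L)
  prom <- plant_motifs(truth, prom_bg, cfg$motif_plant_rate, seed = cfg$seed + 31L)
  genome <- write_promoters_to_genome(gen$genome, prom)
  ocs <- simulate_ocs(truth, prom, gen$genes, genome, cfg)
  expression <- lapply(cfg$organs, function(o) simulate_expression(truth, o, cfg))
  names(expression) <- cfg$organs
  gold <- lapply(cfg$organs, function(o)
    corrupt_gold(truth, o, cfg$gold_sensitivity, cfg$gold_fp_rate,
                 seed = cfg$seed, min_targets = cfg$gold_min_targets))
  names(gold) <- cfg$organs
  list(truth = truth, genome = genome, genes = gen$genes, promoters = prom,
       ocs = ocs, expression = expression, gold = gold, cfg = cfg)
}

#' Write a simulated study to disk
#'
#' Emits counts + lengths + abundance + sample metadata TSVs per organ,
#' truth edges TSV, promoter FASTA, OCS BED, per-TF PFMs in JASPAR text
#' and per-organ gold-standard TSVs.
#'
#' @param sim result of [simulate_system()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_edge_list(sim$truth$edges, p("truth_edges.tsv"))
  write_fasta(sim$promoters$sequences, p("promoters.fasta"))
  write_bed(sim$ocs, p("ocs.bed"))
  write_jaspar(sim$truth$pfm_by_tf, p("motifs.jaspar"))
  utils::write.table(
    data.frame(gene_id = names(sim$truth$lengths), length = sim$truth$lengths),
    p("gene_lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$tf_ids, p("tf_list.txt"))
  for (o in names(sim$expression)) {
    ex <- sim$expression[[o]]
    utils::write.table(ex$counts$values, p(sprintf("counts_%s.tsv", o)),
                       sep = "\t", quote = FALSE)
    utils::write.table(ex$counts$samples, p(sprintf("samples_%s.tsv", o)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gs <- sim$gold[[o]]
    gold_df <- data.frame(
      regulator = rep(names(gs), lengths(gs)),
      target = unlist(gs, use.names = FALSE), stringsAsFactors = FALSE)
    write_edge_list(gold_df, p(sprintf("gold_%s.tsv", o)))
  }
  invisible(dir)
}
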