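# PWM construction, exact p-value lattice, scanning, and motif evidence.

test_that("pfm_to_pwm matches the log-odds construction by hand", {
  # uniform PFM + uniform background: all log-odds zero
  uni <- pfm(matrix(1, 4, 4), id = "uni")
  expect_equal(unname(pfm_to_pwm(uni)$matrix), matrix(0, 4, 4))

  # single-base column: positive for the base, negative elsewhere
  col <- pfm(matrix(c(1, 0, 0, 0), 4, 4), id = "a")
  pw <- pfm_to_pwm(col)
  expect_true(all(pw$matrix["A", ] > 0))
  expect_true(all(pw$matrix[c("C", "G", "T"), ] < 0))

  # 2-column toy vs direct arithmetic
  m <- matrix(c(3, 1, 0, 0,
                0, 0, 2, 2), 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pw2 <- pfm_to_pwm(pfm(m, id = "toy2"), pseudocount = 0.01)
  p_manual <- (m + 0.01 * 0.25) / rep(colSums(m) + 0.01, each = 4)
  expect_equal(unname(pw2$matrix), unname(log2(p_manual / 0.25)), tolerance = 1e-12)
  expect_error(pfm_to_pwm(uni, background = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("score_pvalue endpoints: minimum scores at p = 1, unique maximum at 4^-W", {
  pw <- pfm_to_pwm(toy_pfm())
  expect_equal(score_pvalue(pw, pw$min_score), 1)
  # toy_pfm has a unique argmax in every column -> single max-scoring word
  expect_equal(score_pvalue(pw, pw$max_score), (1 / 4)^4, tolerance = 1e-12)
  expect_message(p_over <- score_pvalue(pw, pw$max_score + 5), "maximum")
  expect_lte(p_over, (1 / 4)^4)
})

test_that("DP tail equals exhaustive enumeration for 20 random PWMs (W <= 6)", {
  for (trial in 1:20) {
    W <- 4L + (trial %% 3L)  # widths 4, 5, 6
    pw <- pfm_to_pwm(random_pfm(W, seed = 100 + trial))
    words <- expand.grid(rep(list(1:4), W))
    int_scores <- as.matrix(words)
    total <- numeric(nrow(words))
    for (w in seq_len(W)) total <- total + pw$int_matrix[int_scores[, w], w]
    probs <- rep((1 / 4)^W, nrow(words))
    # evaluate the tail at every distinct achievable score
    for (s in sample(unique(total), min(12, length(unique(total))))) {
      p_enum <- sum(probs[total >= s])
      expect_equal(score_pvalue(pw, s * pw$eps), p_enum, tolerance = 1e-9)
    }
  }
})

test_that("score_pvalue is monotone nonincreasing in the score", {
  pw <- pfm_to_pwm(random_pfm(6, seed = 77))
  grid <- seq(pw$min_score, pw$max_score, length.out = 60)
  ps <- score_pvalue(pw, grid)
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("scan_sequence finds planted words on both strands at the right offsets", {
  p <- random_pfm(8, seed = 42)
  pw <- pfm_to_pwm(p)
  word <- paste(rownames(p$matrix)[apply(p$matrix, 2, which.max)], collapse = "")
  bg <- random_dna(100, seed = 6)
  seq_fwd <- paste0(substr(bg, 1, 10), word, substr(bg, 19, 100))
  hits <- scan_sequence(pw, seq_fwd, p_threshold = 1e-4)
  expect_true(any(hits$start == 10 & hits$strand == "+"))

  seq_rev <- paste0(substr(bg, 1, 10), revcomp(word), substr(bg, 19, 100))
  hits_rev <- scan_sequence(pw, seq_rev, p_threshold = 1e-4)
  expect_true(any(hits_rev$start == 10 & hits_rev$strand == "-"))

  # too-short sequence: empty hit table
  expect_equal(nrow(scan_sequence(pw, "ACGT")), 0L)
  # windows with N are skipped
  seqN <- paste0(substr(bg, 1, 10), sub("^.", "N", word), substr(bg, 19, 100))
  hitsN <- scan_sequence(pw, seqN, p_threshold = 1e-4)
  expect_false(any(hitsN$start == 10))
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  pw <- pfm_to_pwm(random_pfm(6, seed = 55))
  s <- random_dna(300, seed = 56)
  h_fwd <- scan_sequence(pw, s, p_threshold = 5e-3)
  h_rc <- scan_sequence(pw, revcomp(s), p_threshold = 5e-3)
  # a + hit at start k maps to a - hit at L - k - W and vice versa
  L <- nchar(s); W <- pw$width
  mapped <- data.frame(start = L - h_rc$start - W,
                       strand = ifelse(h_rc$strand == "+", "-", "+"))
  expect_setequal(paste(h_fwd$start, h_fwd$strand),
                  paste(mapped$start, mapped$strand))
})

test_that("background hit counts land inside the Poisson band of the analytic rate", {
  pw <- pfm_to_pwm(random_pfm(7, seed = 91))
  p_thr <- 1e-3
  n_seq <- 60; len <- 500
  # attained per-window significant mass (the lattice makes it <= p_thr);
  # expected hits = 2 strands * n_windows * attained * n_seqs
  d <- organgrn:::pwm_score_tail(pw)
  attained <- max(d$tail[d$tail <= p_thr])
  lambda <- 2 * (len - pw$width + 1) * attained * n_seq
  hits <- sum(vapply(seq_len(n_seq), function(i)
    nrow(scan_sequence(pw, random_dna(len, seed = 200 + i), p_threshold = p_thr)),
    numeric(1)))
  expect_gte(hits, stats::qpois(0.005, lambda))
  expect_lte(hits, stats::qpois(0.995, lambda))
})

test_that("promoter motif evidence recalls q=1 planted edges", {
  cfg <- sim_config(n_tf = 6L, n_gene = 40L, seed = 71L)
  truth <- generate_truth(cfg)
  gen <- simulate_genome(truth, cfg)
  prom <- plant_motifs(truth, extract_promoters(gen$genes, gen$genome, 2000L),
                       q = 1, seed = 72L)
  pairs <- motif_edges_promoter(truth$pfm_by_tf, prom, p_threshold = 1e-4)
  got <- paste(pairs$regulator, pairs$target)
  want <- paste(truth$edges$regulator, truth$edges$target)
  expect_gte(mean(want %in% got), 0.95)
  # TF without a PWM contributes nothing
  pairs2 <- motif_edges_promoter(truth$pfm_by_tf["TF001"], prom)
  expect_true(all(pairs2$regulator == "TF001"))
})

test_that("background-only promoters yield few false motif pairs", {
  cfg <- sim_config(n_tf = 4L, n_gene = 30L, seed = 81L)
  truth <- generate_truth(cfg)
  gen <- simulate_genome(truth, cfg)
  prom <- extract_promoters(gen$genes, gen$genome, 2000L)  # nothing planted
  pairs <- motif_edges_promoter(truth$pfm_by_tf, prom, p_threshold = 1e-5)
  # per-promoter false-hit probability ~ 2 * 1993 * 1e-5 < 0.04
  expect_lt(nrow(pairs), 0.05 * length(prom$sequences) * length(truth$pfm_by_tf))
})

test_that("OCS scanning maps hit-bearing intervals to their closest gene", {
  cfg <- sim_config(n_tf = 6L, n_gene = 40L, ocs_cover_rate = 1, seed = 61L)
  truth <- generate_truth(cfg)
  gen <- simulate_genome(truth, cfg)
  prom <- plant_motifs(truth, extract_promoters(gen$genes, gen$genome, 2000L),
                       q = 1, seed = 62L)
  genome <- organgrn:::write_promoters_to_genome(gen$genome, prom)
  ocs <- simulate_ocs(truth, prom, gen$genes, genome, cfg)
  pairs <- motif_edges_ocs(truth$pfm_by_tf, ocs, genome, gen$genes)
  got <- paste(pairs$regulator, pairs$target)
  want <- paste(truth$edges$regulator, truth$edges$target)
  # every covered placement lies inside its target promoter slice
  expect_gt(mean(want %in% got), 0.8)
  expect_error(motif_edges_ocs(truth$pfm_by_tf,
                               genomic_intervals("chrX", 1L, 100L),
                               genome, gen$genes), "outside")
})

test_that("JASPAR text round-trips PFMs", {
  dir <- withr::local_tempdir()
  pfms <- list(a = random_pfm(5, 1, id = "MA0001"), b = random_pfm(6, 2, id = "MA0002"))
  path <- file.path(dir, "m.jaspar")
  write_jaspar(pfms, path)
  back <- read_jaspar(path)
  expect_equal(names(back), c("MA0001", "MA0002"))
  expect_equal(back$MA0001$matrix, pfms$a$matrix, tolerance = 1e-6)
})
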