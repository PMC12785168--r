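# Ground-truth generator: reproducibility, degree structure, expression
# model, motif planting and gold-standard corruption.

small_cfg <- function(...) {
  args <- list(n_tf = 5L, n_gene = 30L, n_samples_per_organ = 30L,
               n_studies = 2L, organs = c("leaf", "fruit"), seed = 42L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

test_that("generators are bit-reproducible under a seed and vary across seeds", {
  cfg <- small_cfg()
  t1 <- generate_truth(cfg); t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  t3 <- generate_truth(small_cfg(seed = 43L))
  expect_false(identical(t1$edges, t3$edges))

  e1 <- simulate_expression(t1, "leaf", cfg)
  e2 <- simulate_expression(t1, "leaf", cfg)
  expect_identical(e1$counts$values, e2$counts$values)
  expect_false(identical(e1$counts$values,
                         simulate_expression(t1, "fruit", cfg)$counts$values))
})

test_that("truth structure: no self-edges, TF regulators, valid organ masks", {
  truth <- generate_truth(small_cfg())
  expect_true(all(truth$edges$regulator %in% truth$tf_ids))
  expect_false(any(truth$edges$regulator == truth$edges$target))
  expect_true(all(truth$edges$effect != 0))
  for (m in truth$organ_masks)
    expect_true(all(m %in% seq_len(nrow(truth$edges))))
})

test_that("single-TF truth assigns every edge to that TF; organ_share=1 unifies masks", {
  t1 <- generate_truth(sim_config(n_tf = 1L, n_gene = 20L, seed = 5L))
  expect_true(all(t1$edges$regulator == t1$tf_ids))
  t2 <- generate_truth(small_cfg(organ_share = 1))
  expect_identical(t2$organ_masks[[1]], t2$organ_masks[[2]])
  expect_error(generate_truth(sim_config(n_tf = 5, n_gene = 20, mean_outdegree = 30)),
               "infeasible")
})

test_that("total edge count stays within 3-sigma Poisson bounds of the mean demand", {
  truth <- generate_truth(sim_config(n_tf = 20L, n_gene = 200L,
                                     mean_outdegree = 10, seed = 9L))
  expect_gt(nrow(truth$edges), 200 - 3 * sqrt(200))
  expect_lt(nrow(truth$edges), 200 + 3 * sqrt(200))
})

test_that("noise-free single-parent targets track their regulator linearly", {
  cfg <- sim_config(n_tf = 2L, n_gene = 10L, n_samples_per_organ = 50L,
                    organs = "leaf", noise_sd = 0, study_sd = 0,
                    mean_outdegree = 2, seed = 7L)
  truth <- generate_truth(cfg)
  # rewrite the regulon: one target with a single unit-effect parent
  truth$edges <- data.frame(regulator = "TF001", target = "G0001", effect = 1)
  truth$organ_masks <- list(leaf = 1L)
  ex <- simulate_expression(truth, "leaf", cfg)
  a <- ex$abundance$values
  expect_gt(stats::cor(a["TF001", ], a["G0001", ]), 1 - 1e-6)
})

test_that("counts are nonnegative integers and abundances nonnegative reals", {
  cfg <- small_cfg()
  ex <- simulate_expression(generate_truth(cfg), "leaf", cfg)
  expect_true(all(ex$counts$values >= 0))
  expect_true(all(ex$counts$values == round(ex$counts$values)))
  expect_true(all(ex$abundance$values >= 0))
  expect_equal(ex$counts$samples$organ, rep("leaf", cfg$n_samples_per_organ))
  expect_equal(length(unique(ex$counts$samples$study_id)), cfg$n_studies)
})

test_that("true parent-child pairs correlate more than random non-edges", {
  cfg <- sim_config(n_tf = 10L, n_gene = 60L, n_samples_per_organ = 80L,
                    organs = "leaf", organ_share = 1, seed = 3L)
  truth <- generate_truth(cfg)
  a <- simulate_expression(truth, "leaf", cfg)$abundance$values
  true_pcc <- mapply(function(r, t) abs(stats::cor(a[r, ], a[t, ])),
                     truth$edges$regulator, truth$edges$target)
  key <- paste(truth$edges$regulator, truth$edges$target)
  rand_pcc <- with_test_seed(11, {
    vapply(seq_len(1000), function(i) {
      repeat {
        r <- sample(truth$tf_ids, 1); t <- sample(truth$gene_ids, 1)
        if (r != t && !paste(r, t) %in% key) break
      }
      abs(stats::cor(a[r, ], a[t, ]))
    }, numeric(1))
  })
  expect_gt(mean(true_pcc), mean(rand_pcc))
})

test_that("plant_motifs q=1 stamps the consensus everywhere, q=0 nowhere", {
  cfg <- small_cfg()
  truth <- generate_truth(cfg)
  gen <- simulate_genome(truth, cfg)
  prom <- extract_promoters(gen$genes, gen$genome, 500L)
  p1 <- plant_motifs(truth, prom, q = 1, seed = 2L)
  pl <- attr(p1, "placements")
  expect_equal(nrow(pl), nrow(truth$edges))
  # later plants may overwrite earlier overlapping ones; verify every
  # placement not clobbered by a later placement in the same promoter
  for (i in seq_len(nrow(pl))) {
    later <- pl[-seq_len(i), , drop = FALSE]
    later <- later[later$target == pl$target[i], , drop = FALSE]
    clobbered <- any(later$pos <= pl$pos[i] + pl$width[i] - 1L &
                     later$pos + later$width - 1L >= pl$pos[i])
    if (clobbered) next
    word <- substr(p1$sequences[[pl$target[i]]], pl$pos[i], pl$pos[i] + pl$width[i] - 1L)
    cons <- paste(rownames(truth$pfm_by_tf[[pl$regulator[i]]]$matrix)[
      apply(truth$pfm_by_tf[[pl$regulator[i]]]$matrix, 2, which.max)], collapse = "")
    expect_equal(word, cons)
  }
  p0 <- plant_motifs(truth, prom, q = 0, seed = 2L)
  expect_identical(p0$sequences, prom$sequences)
  expect_equal(nrow(attr(p0, "placements")), 0L)
})

test_that("planting rate lands within binomial bounds", {
  cfg <- sim_config(n_tf = 20L, n_gene = 220L, mean_outdegree = 10,
                    organs = "leaf", seed = 13L)
  truth <- generate_truth(cfg)
  gen <- simulate_genome(truth, cfg)
  prom <- extract_promoters(gen$genes, gen$genome, 500L)
  planted <- nrow(attr(plant_motifs(truth, prom, q = 0.5, seed = 4L), "placements"))
  n <- nrow(truth$edges)
  expect_gt(planted, stats::qbinom(0.005, n, 0.5))
  expect_lt(planted, stats::qbinom(0.995, n, 0.5))
})

test_that("corrupt_gold reproduces the truth at sensitivity 1 / fp 0", {
  cfg <- small_cfg(organ_share = 1)
  truth <- generate_truth(cfg)
  gold <- corrupt_gold(truth, "leaf", sensitivity = 1, fp_rate = 0,
                       min_targets = 0L)
  truth_sets <- lapply(split(truth$edges$target, truth$edges$regulator),
                       function(s) sort(unique(s)))
  expect_equal(gold[order(names(gold))],
               truth_sets[order(names(truth_sets))],
               ignore_attr = TRUE)
  empty <- corrupt_gold(truth, "leaf", sensitivity = 0, fp_rate = 0)
  expect_length(empty, 0L)
  re <- toy_ranked(c(0.9, 0.5), target = c("G0001", "G0002"))
  expect_error(roc_pr(re, empty), "empty gold")
})

test_that("gold sensitivity lands within binomial bounds", {
  cfg <- sim_config(n_tf = 25L, n_gene = 300L, mean_outdegree = 20,
                    organs = "leaf", organ_share = 1, seed = 21L)
  truth <- generate_truth(cfg)
  gold <- corrupt_gold(truth, "leaf", sensitivity = 0.8, fp_rate = 0,
                       min_targets = 0L)
  kept <- sum(lengths(gold))
  n <- nrow(truth$edges)
  expect_gt(kept, stats::qbinom(0.005, n, 0.8))
  expect_lt(kept, stats::qbinom(0.995, n, 0.8))
})

test_that("the synthetic genome hosts unambiguous promoters", {
  cfg <- small_cfg()
  truth <- generate_truth(cfg)
  gen <- simulate_genome(truth, cfg)
  prom <- extract_promoters(gen$genes, gen$genome, 2000L)
  expect_setequal(names(prom$sequences), truth$gene_ids)
  expect_true(all(nchar(prom$sequences) == 2000L))
  # a promoter-resident interval always assigns back to its own gene
  src <- prom$source[3, ]
  mid <- genomic_intervals(src$contig, src$start + 900L, src$start + 1100L)
  expect_equal(assign_intervals_to_genes(mid, gen$genes)[[1]], src$gene_id)
})
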