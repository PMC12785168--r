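# IVI hub scores, target conservation, subnetworks and GO enrichment.

test_that("the hub of a star digraph attains the maximal IVI of 100", {
  star <- data.frame(regulator = "hub", target = sprintf("t%02d", 1:20),
                     weight = 1)
  tab <- ivi(star)
  expect_equal(tab$node[1], "hub")
  expect_equal(tab$ivi[1], 100)
  expect_true(all(tab$ivi >= 1 & tab$ivi <= 100))
  expect_true(all(is.finite(as.matrix(tab[, -1]))))
})

test_that("automorphically equivalent nodes share IVI; relabeling is neutral", {
  # two disjoint identical stars: the two hubs are equivalent
  e <- rbind(data.frame(regulator = "h1", target = sprintf("a%d", 1:4)),
             data.frame(regulator = "h2", target = sprintf("b%d", 1:4)))
  e$weight <- 1
  tab <- ivi(e)
  expect_equal(tab$ivi[tab$node == "h1"], tab$ivi[tab$node == "h2"])

  # relabeling nodes permutes, but does not change, the scores
  relab <- e
  map <- c(h1 = "x1", h2 = "x2",
           stats::setNames(sprintf("y%d", 1:8), c(sprintf("a%d", 1:4), sprintf("b%d", 1:4))))
  relab$regulator <- unname(map[relab$regulator])
  relab$target <- unname(map[relab$target])
  tab2 <- ivi(relab)
  expect_equal(sort(tab$ivi), sort(tab2$ivi))
})

test_that("IVI components on a 6-node toy digraph match hand computation", {
  # a -> b, a -> c, b -> c, c -> d, d -> e, d -> f
  e <- data.frame(regulator = c("a", "a", "b", "c", "d", "d"),
                  target = c("b", "c", "c", "d", "e", "f"), weight = 1)
  tab <- ivi(e, l = 2)
  row <- function(n) tab[tab$node == n, ]
  # degrees
  expect_equal(row("a")$out_degree, 2); expect_equal(row("a")$in_degree, 0)
  expect_equal(row("c")$degree, 3); expect_equal(row("d")$degree, 3)
  # neighborhood connectivity of a: neighbors b (deg 2), c (deg 3) -> 2.5
  expect_equal(row("a")$neighborhood_connectivity, 2.5)
  # betweenness (directed): c sits on paths a->d,a->e,a->f,b->d,b->e,b->f
  expect_equal(row("c")$betweenness, 6)
  # ClusterRank of a: cc(a) on undirected projection = 1 (b-c edge closes
  # the triangle); out-neighbors b, c with out-degrees 1 and 1
  expect_equal(row("a")$cluster_rank, 10^(-1) * ((1 + 1) + (1 + 1)))
  # collective influence of d at l=2 (undirected): nodes at distance 2 from
  # d are a and b (via c); k_d = 3, k_a = 2, k_b = 2
  expect_equal(row("d")$collective_influence, (3 - 1) * ((2 - 1) + (2 - 1)))
  expect_error(ivi(e[1, ]), "3 nodes")
})

test_that("adding out-edges to a node never lowers its own IVI", {
  with_test_seed(29, {
    for (trial in 1:5) {
      n <- 12
      base <- data.frame(
        regulator = sprintf("n%02d", sample(n, 25, replace = TRUE)),
        target = sprintf("n%02d", sample(n, 25, replace = TRUE)))
      base <- unique(base[base$regulator != base$target, ])
      base$weight <- 1
      node <- base$regulator[1]
      absent <- setdiff(sprintf("n%02d", 1:n),
                        c(node, base$target[base$regulator == node]))
      if (!length(absent)) next
      grown <- rbind(base, data.frame(regulator = node, target = absent[1], weight = 1))
      before <- ivi(base); after <- ivi(grown)
      expect_gte(after$ivi[after$node == node], before$ivi[before$node == node] - 1e-9)
    }
  })
})

test_that("target conservation percentages and OLS match closed forms", {
  nets <- list(
    root = data.frame(regulator = c("tfA", "tfA", "tfB", "tfB", "tfC"),
                      target = c("g1", "g2", "g1", "g2", "g1"), weight = 1),
    leaf = data.frame(regulator = c("tfA", "tfA", "tfB", "tfB", "tfB"),
                      target = c("g1", "g2", "g3", "g4", "g5"), weight = 1))
  tc <- target_conservation(nets)
  row <- function(tf) tc$table[tc$table$tf == tf, ]
  expect_equal(row("tfA")$conservation, 100)         # identical sets
  expect_equal(row("tfB")$conservation, 0)           # disjoint sets
  expect_equal(row("tfB")$mean_connectivity, 2.5)    # (2 + 3) / 2
  expect_true(is.na(row("tfC")$conservation))        # single organ
  expect_equal(row("tfC")$n_organs, 1L)

  # three-TF toy with hand-solvable OLS
  nets2 <- list(
    o1 = data.frame(regulator = rep(c("t1", "t2", "t3"), c(2, 3, 4)),
                    target = c("a", "b", "a", "b", "c", "a", "b", "c", "d"), weight = 1),
    o2 = data.frame(regulator = rep(c("t1", "t2", "t3"), c(2, 3, 4)),
                    target = c("a", "b", "a", "b", "d", "a", "b", "c", "e"), weight = 1))
  tc2 <- target_conservation(nets2)
  x <- tc2$table$mean_connectivity; y <- tc2$table$conservation
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(tc2$fit$slope, beta, tolerance = 1e-12)
  expect_equal(tc2$fit$intercept, mean(y) - beta * mean(x), tolerance = 1e-12)
  yhat <- mean(y) + beta * (x - mean(x))
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(tc2$fit$r_squared, r2, tolerance = 1e-12)
})

test_that("duplicating an organ network leaves conservation unchanged", {
  nets <- list(
    root = data.frame(regulator = c("tfA", "tfA", "tfB"),
                      target = c("g1", "g2", "g3"), weight = 1),
    leaf = data.frame(regulator = c("tfA", "tfB"),
                      target = c("g1", "g3"), weight = 1))
  tc1 <- target_conservation(nets)
  tc2 <- target_conservation(c(nets, list(leaf2 = nets$leaf)))
  expect_equal(tc1$table$conservation, tc2$table$conservation)
})

test_that("extract_subnetwork filters by the three modes", {
  en <- overlay(threshold_top_percent(data.frame(
    regulator = c("tf1", "tf1", "tf2", "tf3"),
    target = c("g1", "g2", "g1", "tf1"), weight = 4:1 / 4), 100))
  t_of <- extract_subnetwork(en, "tf1", "targets_of")
  expect_setequal(t_of$target, c("g1", "g2"))
  r_of <- extract_subnetwork(en, "g1", "regulators_of")
  expect_setequal(r_of$regulator, c("tf1", "tf2"))
  expect_equal(nrow(extract_subnetwork(en, "g3", "regulators_of")), 0L)
  ind <- extract_subnetwork(en, c("tf1", "tf3", "g2"), "induced")
  expect_equal(paste(ind$regulator, ind$target), c("tf1 g2", "tf3 tf1"))
  # induced on every node is the identity
  all_nodes <- unique(c(en$regulator, en$target))
  expect_equal(nrow(extract_subnetwork(en, all_nodes, "induced")), nrow(en))
  expect_true("evidence_count" %in% names(ind))
})

test_that("ora matches direct hypergeometric summation and flags extremes", {
  # toy: universe 50, term size 10, set 10, overlap 5
  universe <- sprintf("g%02d", 1:50)
  anno <- data.frame(gene_id = universe[1:10], term = "GO:0001")
  target <- c(universe[1:5], universe[41:45])
  tab <- ora(target, anno, universe)
  p_direct <- sum(stats::dhyper(5:10, 10, 40, 10))
  expect_equal(tab$p_value, p_direct, tolerance = 1e-12)

  # random toys vs direct summation
  with_test_seed(37, {
    for (trial in 1:10) {
      N <- sample(50:200, 1)
      uni <- sprintf("u%03d", seq_len(N))
      K <- sample(5:30, 1); n <- sample(5:30, 1)
      anno <- data.frame(gene_id = sample(uni, K), term = "T")
      set <- sample(uni, n)
      k <- sum(set %in% anno$gene_id)
      if (k == 0) next
      tab <- ora(set, anno, uni)
      expect_equal(tab$p_value, sum(stats::dhyper(k:min(K, n), K, N - K, n)),
                   tolerance = 1e-10)
    }
  })

  # extreme enrichment is flagged; proportional representation is not
  uni2 <- sprintf("x%05d", 1:10000)
  anno2 <- data.frame(gene_id = uni2[1:25], term = "GO:RARE")
  hit <- ora(uni2[1:20], anno2, uni2)
  expect_true(hit$significant)
  anno3 <- data.frame(gene_id = uni2[seq(1, 10000, by = 2)], term = "GO:HALF")
  prop <- ora(uni2[1:200], anno3, uni2)  # set hits the term at its base rate
  expect_gte(prop$p_value, 0.4)
  expect_false(prop$significant)
  expect_error(ora(character(), anno2, uni2), "empty")
  expect_error(ora("nope", anno2, uni2), "contained")
})

test_that("high-out-degree truth TFs score higher IVI in the inferred GRN", {
  cfg <- sim_config(n_tf = 15L, n_gene = 80L, n_samples_per_organ = 100L,
                    organs = "leaf", organ_share = 1, noise_sd = 0.2,
                    mean_outdegree = 8, seed = 47L)
  truth <- generate_truth(cfg)
  ex <- simulate_expression(truth, "leaf", cfg)
  re <- infer_grn(ex$abundance, truth$tf_ids, n_trees = 100, seed = 123)
  g5 <- threshold_top_percent(re, 5)
  tab <- ivi(g5)
  outdeg <- table(factor(truth$edges$regulator, levels = truth$tf_ids))
  qs <- stats::quantile(outdeg, c(0.3, 0.7))
  top_tfs <- names(outdeg)[outdeg >= qs[2]]
  bot_tfs <- names(outdeg)[outdeg <= qs[1]]
  med <- function(tfs) stats::median(tab$ivi[tab$node %in% tfs], na.rm = TRUE)
  expect_gt(med(top_tfs), med(bot_tfs))
})
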