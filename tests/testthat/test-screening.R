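test_that("cell_type_means averages within types and validates labels", {
  m <- matrix(c(2, 4, 1, 3), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  lab <- data.frame(sample_id = paste0("s", 1:4),
                    cell_type = c("A", "A", "B", "B"))
  prof <- cell_type_means(m, lab)
  expect_equal(unname(prof$means["g1", ]), c(3, 2))
  expect_error(cell_type_means(m, lab[1:3, ]), "unlabeled")

  # single replicate per type: profile equals the input columns
  lab1 <- data.frame(sample_id = paste0("s", 1:4),
                     cell_type = paste0("t", 1:4))
  expect_equal(unname(cell_type_means(m, lab1)$means), unname(m))
})

test_that("cell_type_means equals a brute-force per-type mean loop", {
  set.seed(42)
  m <- matrix(rnorm(50 * 20, 5), 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  lab <- data.frame(sample_id = paste0("s", 1:20),
                    cell_type = sample(c("A", "B", "C"), 20, replace = TRUE))
  prof <- cell_type_means(m, lab)
  for (ct in unique(lab$cell_type)) {
    for (g in rownames(m)) {
      ref <- mean(m[g, lab$sample_id[lab$cell_type == ct]])
      expect_equal(prof$means[g, ct], ref)
    }
  }
})

test_that("top-decile selection matches a sort-and-slice oracle with ties", {
  # 100 genes, one type, distinct values -> the 10 largest
  v <- sample(seq(1, 100))
  prof <- make_profile(cbind(ct1 = v))
  sel <- top_decile_candidates(prof, 0.10)
  expect_length(sel$per_type$ct1, 10)
  expect_setequal(sel$per_type$ct1, prof$genes[order(v, decreasing = TRUE)][1:10])

  # disjoint top deciles union
  m <- matrix(0, 200, 2, dimnames = list(paste0("g", 1:200), c("A", "B")))
  m[1:20, "A"] <- 10 + seq_len(20)
  m[101:120, "B"] <- 10 + seq_len(20)
  sel2 <- top_decile_candidates(make_profile(m), 0.10)
  expect_length(sel2$candidates, 40)

  # randomized oracle including boundary ties
  set.seed(9)
  for (rep in 1:20) {
    G <- sample(30:80, 1)
    vals <- matrix(sample(0:9, G * 3, replace = TRUE), G, 3)
    prof <- make_profile(vals)
    sel <- top_decile_candidates(prof, 0.10)
    k <- ceiling(0.10 * G)
    for (j in 1:3) {
      cutoff <- sort(vals[, j], decreasing = TRUE)[k]
      expect_setequal(sel$per_type[[j]], prof$genes[vals[, j] >= cutoff])
    }
  }
})

test_that("TSI reproduces its analytic values", {
  # expressed in exactly one of 19 types -> TSI = 1
  single <- rep(0, 19); single[7] <- 8
  prof <- make_profile(rbind(g_single = single,
                             g_flat = rep(5, 19)))
  tab <- compute_tsi(prof)
  expect_equal(unname(tab$tsi["g_single"]), 1)
  expect_equal(unname(tab$tsi["g_flat"]), 0)

  # N = 3, means (4, 2, 0): x = (1, 0.5, 0), TSI = 0.75
  tab3 <- compute_tsi(make_profile(rbind(g = c(4, 2, 0))))
  expect_equal(unname(tab3$tsi["g"]), 0.75)
  expect_equal(unname(tab3$x["g", ]), c(1, 0.5, 0))
})

test_that("TSI is bounded, scale-invariant and monotone; zero genes drop", {
  set.seed(21)
  for (rep in 1:50) {
    N <- sample(2:19, 1)
    means <- matrix(stats::rexp(10 * N), 10, N)
    prof <- make_profile(means)
    tsi <- compute_tsi(prof)$tsi
    expect_true(all(tsi >= 0 & tsi <= 1))
    scaled <- compute_tsi(make_profile(means * runif(1, 0.1, 50)))$tsi
    expect_equal(tsi, scaled)
  }
  # raising a non-maximal mean strictly decreases TSI
  base <- c(10, 2, 1)
  up <- c(10, 5, 1)
  expect_lt(compute_tsi(make_profile(rbind(g = up)))$tsi,
            compute_tsi(make_profile(rbind(g = base)))$tsi)
  # all-zero genes are excluded and reported
  prof0 <- make_profile(rbind(g1 = c(1, 2), g0 = c(0, 0)))
  expect_message(tab <- compute_tsi(prof0), "all-zero")
  expect_identical(tab$dropped, "g0")
  expect_false("g0" %in% names(tab$tsi))
  expect_error(compute_tsi(make_profile(rbind(g = 3))), "2 cell types")
})

test_that("bh_adjust equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  for (rep in 1:200) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("differential screen flags direction, power and degeneracy", {
  set.seed(4)
  genes <- c("up_in_tumor", "up_in_immune", "flat")
  immune <- rbind(rnorm(114, 4), rnorm(114, 8), rep(5, 114))
  tumor <- rbind(rnorm(34, 8), rnorm(34, 4), rep(5, 34))
  rownames(immune) <- rownames(tumor) <- genes
  colnames(immune) <- paste0("i", 1:114)
  colnames(tumor) <- paste0("t", 1:34)
  res <- differential_screen(immune, tumor, genes)
  expect_false(res$is_ti_lncrna[res$gene == "up_in_tumor"])
  expect_true(res$is_ti_lncrna[res$gene == "up_in_immune"])
  expect_equal(res$p_value[res$gene == "flat"], 1)  # zero variance, equal means
  expect_true(all(res$fdr >= res$p_value))
  expect_error(differential_screen(immune[, 1, drop = FALSE], tumor, genes),
               "2 samples")
})

test_that("differential screen controls false flags under the global null", {
  set.seed(33)
  n_genes <- 1000
  genes <- paste0("g", seq_len(n_genes))
  immune <- matrix(rnorm(n_genes * 40, 5), n_genes, 40,
                   dimnames = list(genes, paste0("i", 1:40)))
  tumor <- matrix(rnorm(n_genes * 20, 5), n_genes, 20,
                  dimnames = list(genes, paste0("t", 1:20)))
  res <- differential_screen(immune, tumor, genes)
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / n_genes)
  expect_lte(mean(res$is_ti_lncrna), bound)
})

test_that("run_screen recovers planted genes and satisfies its invariant", {
  cfg <- small_config(seed = 1)
  panel <- generate_immune_panel(cfg)
  tumor <- generate_tumor_panel(cfg, panel$truth)
  res <- run_screen(panel$expr, panel$labels, tumor)
  rec <- evaluate_recovery(panel$truth, res)
  expect_gte(rec$sensitivity, 0.9)
  expect_gte(rec$precision, 0.9)

  # flag implication invariant
  flagged <- res[res$is_ti_lncrna, ]
  params <- attr(res, "params")
  expect_true(all(flagged$in_top_decile))
  expect_true(all(flagged$tsi > params$tsi_threshold))
  expect_true(all(flagged$fdr < params$fdr_threshold))
  expect_true(all(flagged$diff > 0))

  # deterministic re-run
  res2 <- run_screen(panel$expr, panel$labels, tumor)
  expect_identical(res, res2)

  # tsi_threshold = 1 empties the screen (strict inequality)
  expect_warning(res1 <- run_screen(panel$expr, panel$labels, tumor,
                                    tsi_threshold = 1.0), "empty candidate")
  expect_equal(sum(res1$is_ti_lncrna), 0)
})

test_that("run_screen applies the biotype filter first", {
  cfg <- small_config(seed = 2)
  panel <- generate_immune_panel(cfg)
  tumor <- generate_tumor_panel(cfg, panel$truth)
  bio <- data.frame(gene = rownames(panel$expr),
                    biotype = rep(c("lncRNA", "protein_coding"),
                                  length.out = nrow(panel$expr)))
  res <- run_screen(panel$expr, panel$labels, tumor, biotypes = bio)
  expect_setequal(res$gene, bio$gene[bio$biotype == "lncRNA"])
  bad <- data.frame(gene = rownames(panel$expr), biotype = "protein_coding")
  expect_error(run_screen(panel$expr, panel$labels, tumor, biotypes = bad),
               "no lncRNA")
})
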