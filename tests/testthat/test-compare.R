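test_that("imbalance ratio is the mat:pat DeMA gene-count quotient", {
  cl <- make_classes(c(setNames(rep("DeMA_mat", 550), paste0("m", 1:550)),
                       setNames(rep("DeMA_pat", 100), paste0("p", 1:100)),
                       setNames(rep("biallelic", 350), paste0("b", 1:350))))
  imb <- imbalance_ratio(cl, seed = 1)
  expect_equal(imb$ratio, 5.5)
  expect_equal(imb$n_mat, 550L)
  expect_true(imb$ci[1] <= 5.5 && imb$ci[2] >= 5.5)

  even <- make_classes(c(setNames(rep("DeMA_mat", 10), paste0("m", 1:10)),
                         setNames(rep("DeMA_pat", 10), paste0("p", 1:10))))
  expect_equal(imbalance_ratio(even, seed = 1)$ratio, 1.0)

  none <- make_classes(c(setNames(rep("DeMA_mat", 5), paste0("m", 1:5)),
                         g1 = "biallelic"))
  und <- imbalance_ratio(none, seed = 1)
  expect_true(is.na(und$ratio))
  expect_equal(und$n_mat, 5L)
  expect_equal(und$n_pat, 0L)
})

test_that("imbalance bootstrap is seed-deterministic", {
  cl <- make_classes(c(setNames(rep("DeMA_mat", 40), paste0("m", 1:40)),
                       setNames(rep("DeMA_pat", 10), paste0("p", 1:10)),
                       setNames(rep("biallelic", 50), paste0("b", 1:50))))
  a <- imbalance_ratio(cl, seed = 5)
  b <- imbalance_ratio(cl, seed = 5)
  expect_identical(a$ci, b$ci)
})

test_that("status changes partition the genes classified in both tables", {
  a <- make_classes(c(g1 = "DeMA_mat", g2 = "DeMA_mat", g3 = "biallelic",
                      g4 = "DeMA_pat", g5 = "biallelic", g6 = "RaMA",
                      g7 = "DeMA_mat"), population = "A")
  b <- make_classes(c(g1 = "DeMA_pat", g2 = "biallelic", g3 = "DeMA_mat",
                      g4 = "DeMA_pat", g5 = "biallelic", g6 = "DeMA_mat",
                      g7 = "inconclusive"), population = "B")
  chg <- status_change(a, b)
  expect_equal(chg$counts[["mono_switched_allele"]], 1L)
  expect_equal(chg$switched_alleles, "g1")
  expect_equal(chg$counts[["mono_to_biallelic"]], 1L)
  expect_equal(chg$genes$mono_to_biallelic, "g2")
  expect_equal(chg$counts[["biallelic_to_mono"]], 1L)
  expect_equal(chg$counts[["mono_same_allele"]], 1L)
  expect_equal(chg$counts[["biallelic_stable"]], 1L)
  expect_equal(chg$n_excluded, 2L) # g6 (RaMA in A), g7 (inconclusive in B)
  expect_equal(sum(chg$counts) + chg$n_excluded, chg$n_shared)

  disjoint <- make_classes(c(z1 = "biallelic"), population = "B")
  expect_error(status_change(a, disjoint), "disjoint gene universes")
})

test_that("status changes match simulator truth counts", {
  genes <- paste0("g", 1:300)
  cls_a <- setNames(c(rep("DeMA_mat", 200), rep("DeMA_pat", 100)), genes)
  cls_b <- cls_a
  cls_b[1:100] <- "biallelic" # 100 of A's 300 DeMA genes regenerate biallelic
  chg <- status_change(make_classes(cls_a, "A"), make_classes(cls_b, "B"))
  expect_equal(chg$counts[["mono_to_biallelic"]], 100L)
  expect_equal(chg$counts[["mono_same_allele"]], 200L)
})

test_that("exclusive intersections cover the union exactly once", {
  a <- make_classes(setNames(rep("DeMA_mat", 3), c("a", "b", "c")), "P1")
  b <- make_classes(setNames(rep("DeMA_mat", 3), c("b", "c", "d")), "P2")
  rep_ <- intersect_classes(list(a, b), "DeMA_mat")
  combos <- rep_$combos
  expect_equal(combos$count[combos$combo == "P1&P2"], 2L)
  expect_equal(combos$count[combos$combo == "P1"], 1L)
  expect_equal(combos$count[combos$combo == "P2"], 1L)
  expect_equal(sum(combos$count), nrow(rep_$membership))
  expect_equal(rep_$genes[["P1&P2"]], c("b", "c"))

  # identical sets collapse onto the full intersection
  c2 <- make_classes(setNames(rep("DeMA_mat", 3), c("a", "b", "c")), "P2")
  rep2 <- intersect_classes(list(a, c2), "DeMA_mat")
  expect_equal(rep2$combos$combo, "P1&P2")
  expect_equal(rep2$combos$count, 3L)

  expect_error(intersect_classes(list(a, b), "DeMA"), "unknown class")
  expect_error(intersect_classes(list(a), "DeMA_mat"), ">= 2 populations")
})

test_that("intersections across simulated populations match shared truth", {
  pops <- paste0("pop", 1:4)
  tables <- list()
  truths <- list()
  for (i in seq_along(pops)) {
    sim <- simulate_cells(deep_params(n_genes = 300, n_cells = 50, seed = 400),
                          pops[i])
    tables[[i]] <- classify_population(sim$counts)
    truths[[i]] <- sim$truth
  }
  # same seed => same truth: every DeMA gene is shared by all populations
  rep_ <- intersect_classes(tables, c("DeMA_mat", "DeMA_pat"))
  all_pops <- paste(pops, collapse = "&")
  n_dema <- sum(truths[[1]]$table$class %in% c("DeMA_mat", "DeMA_pat"))
  expect_equal(rep_$combos$count[rep_$combos$combo == all_pops], n_dema)
  expect_equal(sum(rep_$combos$count), n_dema)
})

test_that("transcripts-per-gene summaries and one-sample t-test", {
  ann <- data.frame(
    gene = c(rep("r1", 1), rep("r2", 2), rep("r3", 3), rep("r4", 4),
             rep("b1", 5), rep("b2", 5), rep("missing_cls", 2)),
    transcript_id = paste0("t", 1:22),
    coding = rep(c(TRUE, FALSE), 11))
  cl <- make_classes(c(r1 = "RaMA", r2 = "RaMA", r3 = "RaMA", r4 = "RaMA",
                       b1 = "biallelic", b2 = "biallelic", b3 = "biallelic"))
  expect_message(out <- transcripts_per_gene_summary(cl, ann,
                                                     reference_mean = 0),
                 "absent from annotation")
  rama <- out[out$class == "RaMA", ]
  # counts 1,2,3,4 against reference 0: t = mean/(sd/sqrt(n))
  expect_equal(rama$mean_tx, 2.5)
  expect_equal(rama$t, 2.5 / (sd(1:4) / 2))
  expect_equal(rama$p, 2 * pt(-abs(rama$t), df = 3))
  bi <- out[out$class == "biallelic", ]
  expect_equal(bi$mean_tx, 5)
  expect_equal(bi$sd_tx, 0)
  # constant values on the reference: t = 0, p = 1
  out5 <- transcripts_per_gene_summary(cl, ann, reference_mean = 5)
  expect_equal(out5[out5$class == "biallelic", ]$t, 0)
  expect_equal(out5[out5$class == "biallelic", ]$p, 1)
  # symmetric counts on the reference: t = 0, p = 1
  cl2 <- make_classes(c(r2 = "RaMA", r3 = "RaMA", r4 = "RaMA"))
  out2 <- transcripts_per_gene_summary(cl2, ann, reference_mean = 3)
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
})
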