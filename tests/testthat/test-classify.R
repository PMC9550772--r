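test_that("per-sample allele calls follow the fraction thresholds", {
  th <- call_thresholds(min_total = 5, mono_fraction = 0.98)
  cases <- list(
    list(mat = 100, pat = 0, state = "mono_mat", f = 1.0),
    list(mat = 0, pat = 0, state = "not_expressed", f = NA_real_),
    list(mat = 60, pat = 40, state = "biallelic", f = 0.6),
    list(mat = 99, pat = 1, state = "mono_mat", f = 0.99),   # 99/100 >= 0.98
    list(mat = 1, pat = 99, state = "mono_pat", f = 0.01),
    list(mat = 49, pat = 1, state = "mono_mat", f = 0.98),   # tie goes mono
    list(mat = 3, pat = 1, state = "not_expressed", f = 0.75) # below min_total
  )
  for (cs in cases) {
    call <- call_allele(cs$mat, cs$pat, th)
    expect_equal(call$state, cs$state,
                 label = sprintf("(%d, %d)", cs$mat, cs$pat))
    expect_equal(call$f, cs$f)
  }
  expect_error(call_allele(-1, 2, th), "non-negative")
})

test_that("bulk DeMA filter demands exclusivity in every replicate", {
  th <- call_thresholds()
  rules <- list(
    list(mat = c(50, 50, 50), pat = c(0, 0, 0), strict = "DeMA_mat"),
    list(mat = c(0, 0, 0), pat = c(50, 50, 50), strict = "DeMA_pat"),
    list(mat = c(30, 25, 40), pat = c(30, 30, 35), strict = "biallelic"),
    # mono, mono, biallelic: violates unanimity
    list(mat = c(50, 50, 30), pat = c(0, 0, 30), strict = "inconclusive",
         lenient = "biallelic"),
    # mixed mono directions
    list(mat = c(50, 0, 0), pat = c(0, 50, 50), strict = "inconclusive",
         lenient = "biallelic"),
    list(mat = c(0, 0, 0), pat = c(0, 0, 0), strict = "not_expressed"),
    # expressed in only some replicates
    list(mat = c(50, 0, 50), pat = c(0, 0, 0), strict = "inconclusive")
  )
  mat <- do.call(rbind, lapply(rules, `[[`, "mat"))
  pat <- do.call(rbind, lapply(rules, `[[`, "pat"))
  counts <- make_counts(mat, pat, population = "bulk", modality = "bulk")
  strict <- classify_bulk(counts, th)
  expect_equal(strict$class, vapply(rules, `[[`, "", "strict"))
  lenient <- classify_bulk(counts, th, mode = "lenient")
  for (i in seq_along(rules)) {
    want <- rules[[i]]$lenient
    if (!is.null(want)) expect_equal(lenient$class[i], want)
  }
  expect_true(all(strict$class != "RaMA")) # bulk never yields RaMA
  one_rep <- make_counts(mat[, 1, drop = FALSE], pat[, 1, drop = FALSE],
                         modality = "bulk")
  expect_error(classify_bulk(one_rep, th), ">= 2 replicates")
})

test_that("single-cell filter separates DeMA, RaMA and biallelic patterns", {
  th <- call_thresholds(min_total = 5, mono_fraction = 0.98, min_cells = 5,
                        rama_min_cells = 3, max_biallelic_frac = 0.10)
  n <- 20
  mk_cells <- function(n_mm, n_mp, n_bi, n_off = 0) {
    mat <- c(rep(50, n_mm), rep(0, n_mp), rep(30, n_bi), rep(0, n_off))
    pat <- c(rep(0, n_mm), rep(50, n_mp), rep(30, n_bi), rep(0, n_off))
    rbind(mat = mat, pat = pat)
  }
  rules <- list(
    list(cells = mk_cells(20, 0, 0), want = "DeMA_mat"),
    list(cells = mk_cells(0, 20, 0), want = "DeMA_pat"),
    list(cells = mk_cells(9, 11, 0), want = "RaMA"),
    list(cells = mk_cells(5, 0, 15), want = "biallelic"),   # 0.75 > beta
    # fails DeMA purity (2 pat cells) and the RaMA floor (2 < k)
    list(cells = mk_cells(16, 2, 0, 2), want = "inconclusive"),
    list(cells = mk_cells(0, 0, 0, 20), want = "not_expressed"),
    list(cells = mk_cells(18, 0, 1, 1), want = "DeMA_mat"), # 1/19 <= beta
    list(cells = mk_cells(5, 5, 1, 9), want = "RaMA")       # 1/11 <= beta
  )
  mat <- do.call(rbind, lapply(rules, function(r) r$cells["mat", ]))
  pat <- do.call(rbind, lapply(rules, function(r) r$cells["pat", ]))
  counts <- make_counts(mat, pat, population = "sc")
  got <- classify_population(counts, th)
  expect_equal(got$class, vapply(rules, `[[`, "", "want"))
  # evidence counts reported
  expect_equal(got$n_mono_mat[3], 9L)
  expect_equal(got$n_mono_pat[3], 11L)
  expect_equal(got$n_expressed[3], 20L)
  expect_error(classify_population(counts, th, population = "nope"),
               "empty population")
})

test_that("noise-free single-cell classification recovers the truth exactly", {
  p <- deep_params(n_genes = 400, n_cells = 60, seed = 13)
  sim <- simulate_cells(p, "ESC")
  got <- classify_population(sim$counts)
  expect_equal(got$class, sim$truth$table$class)
})

test_that("allele relabeling mirrors classes", {
  p <- sim_params(n_genes = 300, n_cells = 80, seed = 17)
  sim <- simulate_cells(p, "x")
  swapped <- allele_counts(sim$counts$pat, sim$counts$mat,
                           gene_ids = sim$counts$gene_ids,
                           sample_ids = sim$counts$sample_ids,
                           meta = sim$counts$meta)
  a <- classify_population(sim$counts)
  b <- classify_population(swapped)
  mirror <- c(biallelic = "biallelic", DeMA_mat = "DeMA_pat",
              DeMA_pat = "DeMA_mat", RaMA = "RaMA",
              not_expressed = "not_expressed", inconclusive = "inconclusive")
  expect_equal(b$class, unname(mirror[a$class]))
  expect_equal(b$n_mono_mat, a$n_mono_pat)
  expect_equal(b$n_biallelic, a$n_biallelic)
})

test_that("raising the mono threshold never converts biallelic to mono", {
  set.seed(99)
  mat <- matrix(rpois(600, 30), 30)
  pat <- matrix(rpois(600, 10), 30)
  counts <- make_counts(mat, pat)
  thetas <- c(0.6, 0.75, 0.9, 0.98, 1.0)
  prev_cells <- NULL
  for (th in thetas) {
    # the set of mono-called (gene, sample) pairs shrinks as theta rises
    calls <- call_allele(as.vector(mat), as.vector(pat),
                         call_thresholds(mono_fraction = th))
    mono_cells <- calls$state %in% c("mono_mat", "mono_pat")
    bi_cells <- calls$state == "biallelic"
    if (!is.null(prev_cells)) {
      expect_true(all(mono_cells <= prev_cells$mono))
      expect_true(all(bi_cells >= prev_cells$bi))
    }
    prev_cells <- list(mono = mono_cells, bi = bi_cells)
  }
})

test_that("a bulk-simulated DeMA gene is never classified RaMA from bulk", {
  for (s in 1:3) {
    sim <- simulate_bulk(sim_params(n_genes = 400, seed = s))
    cl <- classify_bulk(sim$counts)
    dema <- sim$truth$table$class %in% c("DeMA_mat", "DeMA_pat")
    expect_true(all(cl$class[dema] != "RaMA"))
    expect_true(all(cl$class != "RaMA"))
  }
})

test_that("CPM normalization uses the combined allele library", {
  counts <- make_counts(matrix(c(10, 0), 1), matrix(c(0, 0), 1))
  expect_error(cpm_normalize(counts), "zero-total sample.*s2")
  counts2 <- make_counts(rbind(c(10), c(15)), rbind(c(40), c(35)))
  cpm <- cpm_normalize(counts2)
  expect_equal(sum(cpm$mat[, 1]) + sum(cpm$pat[, 1]), 1e6)
  expect_equal(cpm$mat[1, 1], 10 / 100 * 1e6)
  # single gene fully maternal
  counts3 <- make_counts(matrix(10, 1), matrix(0, 1))
  expect_equal(cpm_normalize(counts3)$mat[1, 1], 1e6)
  # two genes, 25/75 split on one allele
  counts4 <- make_counts(rbind(25, 75), rbind(0, 0))
  expect_equal(as.vector(cpm_normalize(counts4)$mat), c(2.5e5, 7.5e5))
})
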