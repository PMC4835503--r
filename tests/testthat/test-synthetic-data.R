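# the seeded generator: determinism, exact composition, implanted structure

test_that("same seed gives byte-identical datasets on disk", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_dataset(d1, seed = 11)
  r2 <- simulate_dataset(d2, seed = 11)
  for (f in basename(r1$files)) {
    m1 <- unname(tools::md5sum(file.path(d1, f)))
    m2 <- unname(tools::md5sum(file.path(d2, f)))
    expect_identical(m1, m2, info = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_dataset(d3, seed = 12)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genes.tsv"))),
                         unname(tools::md5sum(file.path(d3, "genes.tsv")))))
})

test_that("genome composition and category counts are exact", {
  g <- generate_genome(seed = 5)
  expect_equal(nrow(g$genes), 10635L)
  expect_equal(length(g$core_ids), 3297L)
  expect_equal(length(g$truth$orphan_ids), 640L)
  parts <- classify_genes(g$hits, g$core_ids)
  expect_equal(length(parts$remaining), 6698L)
  expect_true(all(g$hits[parts$orphan] == 1L))
  expect_true(all(g$hits >= 1L))
  expect_equal(length(category_members(g$genes, "TF")), 216L)
  expect_equal(length(category_members(g$genes, "NLR")), 77L)
  smmap <- sm_cluster_map(g$genes)
  expect_equal(length(smmap), 470L)
  expect_equal(length(unique(smmap)), 35L)
  expect_equal(sum(g$genes$is_secreted), 801L)
  expect_equal(nrow(g$truth$regions), 19L)
  expect_equal(sum(g$truth$regions$telomeric), 8L)
  expect_equal(sum(g$truth$regions$hotspot), 13L)
})

test_that("implanted regions hold the low tail of the hit-count range", {
  spec <- data.frame(chromosome = "2", start = 200L, end = 259L,
                     stringsAsFactors = FALSE)
  g <- generate_genome(n_genes = 2000L, n_core = 600L, n_orphan = 100L,
                       region_spec = spec,
                       category_counts = list(TF = 40L),
                       n_sm_clusters = 5L, n_sm_genes = 60L,
                       n_secreted = 150L, seed = 9)
  inside <- g$genes$chromosome == "2" & g$genes$ordinal >= 200L &
    g$genes$ordinal <= 259L
  non_core <- !(g$genes$gene_id %in% g$core_ids)
  in_hits <- g$hits[g$genes$gene_id[inside & non_core]]
  expect_true(all(in_hits < stats::median(g$hits)))
})

test_that("expression limit cases behave as constructed", {
  g <- generate_genome(seed = 2)
  # no regulation at all
  e0 <- generate_expression(g, params = list(base_up_rate = 0,
                                             base_down_rate = 0,
                                             hotspot_up_rate = 0),
                            seed = 2)
  for (cond in names(e0$records)) for (dir in c("up", "down"))
    expect_length(build_response_set(e0$records[[cond]], dir)$members, 0L)

  # fully shared bacterial responses: identical pooled regulated sets
  e1 <- generate_expression(g, params = list(sf_specific_up = 0,
                                             sf_specific_down = 0,
                                             sm_only_up_frac = 0,
                                             sm_only_down_frac = 0),
                            seed = 2)
  expect_setequal_chr(e1$truth$up$VsSf, e1$truth$up$VsSm)
  expect_setequal_chr(e1$truth$down$VsSf, e1$truth$down$VsSm)
})

test_that("pipeline recovers the generator's specific fraction and sizes", {
  # truth targets ~21% VsSf-specific up genes at ~1,850 regulated genes
  specs <- vapply(1:5, function(s) {
    g <- generate_genome(seed = s)
    e <- generate_expression(g, seed = s)
    up <- lapply(c("VsSf2h", "VsSf6h", "VsSm2h", "VsSm6h"), function(cond)
      build_response_set(e$records[[cond]], "up"))
    sf <- pool_conditions(up[[1L]], up[[2L]])
    sm <- pool_conditions(up[[3L]], up[[4L]])
    expect_equal(length(sf$members), length(e$truth$up$VsSf))
    specific_fraction(sf, sm)
  }, numeric(1L))
  expect_true(all(abs(specs - 21) <= 2))
})

test_that("similarity tables recover the true ortholog map", {
  g <- generate_genome(n_genes = 1200L, n_core = 300L, n_orphan = 80L,
                       category_counts = list(), n_sm_clusters = 2L,
                       n_sm_genes = 20L, n_secreted = 100L, seed = 4)
  sim0 <- generate_similarity(g, n_other = 400L, noise = 0, seed = 4)
  pairs <- reciprocal_best_hits(sim0$ab, sim0$ba)
  expect_setequal_chr(paste(pairs$gene_a, pairs$gene_b),
                      paste(sim0$ortholog_map$gene_a,
                            sim0$ortholog_map$gene_b))

  # no orthologs: no reciprocal pairs at all
  simz <- generate_similarity(g, n_other = 400L, ortholog_frac = 0,
                              seed = 4)
  expect_equal(nrow(reciprocal_best_hits(simz$ab, simz$ba)), 0L)

  # moderate (default) noise: precision and recall at least 0.9
  simn <- generate_similarity(g, n_other = 400L, seed = 4)
  pn <- reciprocal_best_hits(simn$ab, simn$ba)
  tk <- paste(simn$ortholog_map$gene_a, simn$ortholog_map$gene_b)
  rk <- paste(pn$gene_a, pn$gene_b)
  expect_gte(mean(rk %in% tk), 0.9)
  expect_gte(mean(tk %in% rk), 0.9)
})

test_that("truth file suffices to recompute expected summaries", {
  d <- withr::local_tempdir()
  r <- simulate_dataset(d, seed = 21)
  truth <- yaml::read_yaml(file.path(d, "truth.yaml"))
  expect_equal(truth$seed, 21L)
  # set sizes and the specific fraction recomputed from truth alone
  expect_equal(length(truth$expression$up$VsSf),
               round(truth$expression$params$base_up_rate * 10635))
  sf <- truth$expression$up$VsSf
  sm <- truth$expression$up$VsSm
  expect_equal(100 * length(setdiff(sf, sm)) / length(sf),
               truth$expression$sf_specific_up_pct, tolerance = 1e-8)
})
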