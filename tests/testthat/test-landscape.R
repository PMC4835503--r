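# sliding-window profiles and region calling

make_chrom <- function(n, index, chromosome = "1") {
  genes <- toy_gene_table(n, chromosome)
  list(genes = genes, assignment = fake_assignment(genes, index))
}

test_that("window counts, constant profiles and parameter checks", {
  ch <- make_chrom(100L, rep(5L, 100L))
  prof <- window_profiles(ch$genes, ch$assignment, window = 100L)
  expect_equal(nrow(prof), 1L)           # n - w + 1
  expect_equal(prof$mean_index, 5)
  ch2 <- make_chrom(120L, rep(5L, 120L))
  prof2 <- window_profiles(ch2$genes, ch2$assignment, window = 100L)
  expect_equal(nrow(prof2), 21L)
  expect_true(all(prof2$mean_index == 5))
  expect_true(all(prof2$end - prof2$start + 1L == 100L))
  expect_error(window_profiles(ch$genes, ch$assignment, window = 1L),
               "window")
  # a chromosome shorter than the window is skipped with a warning
  g2 <- toy_gene_table(10L, "2")
  g2$gene_id <- sub("^g", "h", g2$gene_id)
  a2 <- structure(rbind(ch$assignment, fake_assignment(g2, rep(5L, 10L))),
                  n_bins = 10L)
  expect_warning(window_profiles(rbind(ch$genes, g2), a2, window = 100L),
                 "skipped")
})

test_that("window means match naive recomputation and the rolling identity", {
  withr::local_seed(11)
  n <- 300L
  idx <- sample(0:11, n, replace = TRUE)
  ch <- make_chrom(n, idx)
  up <- response_set(sample(ch$genes$gene_id, 60L), "U", "up")
  prof <- window_profiles(ch$genes, ch$assignment, list(U = up),
                          window = 50L)
  in_up <- ch$genes$gene_id %in% up$members
  for (i in seq_len(nrow(prof))) {     # naive oracle at every offset
    w <- prof$start[i]:prof$end[i]
    expect_equal(prof$mean_index[i], mean(idx[w]))
    expect_equal(prof$U[i], mean(in_up[w]))
  }
  # rolling-update identity for step 1
  w <- 50L
  lhs <- prof$mean_index[-1L]
  rhs <- prof$mean_index[-nrow(prof)] +
    (idx[prof$start[-1L] + w - 1L] - idx[prof$start[-nrow(prof)]]) / w
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("implanted low-index blocks are recovered as troughs", {
  # one 60-gene block of index 1 on an index-8 background
  idx <- rep(8L, 500L); idx[201:260] <- 1L
  ch <- make_chrom(500L, idx)
  prof <- window_profiles(ch$genes, ch$assignment, window = 100L)
  tr <- call_versatility_troughs(prof)
  expect_equal(nrow(tr), 1L)
  expect_lte(abs(tr$start - 201L), 100L)    # boundary error within window
  expect_lte(abs(tr$end - 260L), 100L)
  expect_true(tr$start <= 260L && tr$end >= 201L)

  # gene mode calls the block at gene resolution
  trg <- call_versatility_troughs(genes = ch$genes,
                                  assignment = ch$assignment,
                                  mode = "gene")
  expect_equal(trg$start, 201L)
  expect_equal(trg$end, 260L)

  # two blocks separated by more than a window give two regions
  idx2 <- rep(8L, 700L); idx2[101:160] <- 1L; idx2[461:520] <- 1L
  ch2 <- make_chrom(700L, idx2)
  tr2 <- call_versatility_troughs(
    window_profiles(ch2$genes, ch2$assignment, window = 100L))
  expect_equal(nrow(tr2), 2L)
  expect_equal(tr2$label, c("a", "b"))

  # uniform chromosome: sd = 0 path, no regions, a warning
  chu <- make_chrom(200L, rep(4L, 200L))
  expect_warning(tru <- call_versatility_troughs(
    window_profiles(chu$genes, chu$assignment, window = 100L)),
    "zero variance")
  expect_equal(nrow(tru), 0L)
})

test_that("region calls are invariant to chromosome processing order", {
  withr::local_seed(5)
  idx1 <- rep(8L, 400L); idx1[51:110] <- 0L
  idx2 <- rep(7L, 400L); idx2[301:360] <- 0L
  g1 <- toy_gene_table(400L, "1"); g2 <- toy_gene_table(400L, "2")
  g2$gene_id <- sub("^g", "h", g2$gene_id)
  a12 <- structure(rbind(fake_assignment(g1, idx1),
                         fake_assignment(g2, idx2)), n_bins = 10L)
  fwd <- call_versatility_troughs(window_profiles(rbind(g1, g2), a12))
  rev <- call_versatility_troughs(window_profiles(rbind(g2, g1), a12))
  expect_equal(fwd, rev)
})

test_that("merging is idempotent and trough regions never overlap", {
  m <- nonself:::merge_intervals(c(1L, 5L, 20L), c(6L, 10L, 30L))
  expect_equal(m$start, c(1L, 20L))
  expect_equal(m$end, c(10L, 30L))
  expect_equal(nonself:::merge_intervals(m$start, m$end), m)
  # adjacency merges too
  m2 <- nonself:::merge_intervals(c(1L, 11L), c(10L, 15L))
  expect_equal(nrow(m2), 1L)
})

test_that("implanted up-regulated blocks are recovered as hotspots", {
  withr::local_seed(9)
  n <- 600L
  idx <- sample(3:8, n, replace = TRUE)
  ch <- make_chrom(n, idx)
  base <- stats::runif(n) < 0.10
  base[301:350] <- stats::runif(50L) < 0.80   # 50-gene hot block
  up <- response_set(ch$genes$gene_id[base], "U", "up")
  prof <- window_profiles(ch$genes, ch$assignment, list(U = up),
                          window = 100L)
  hs <- call_expression_hotspots(prof, "U")
  expect_equal(nrow(hs), 1L)
  expect_true(hs$start <= 350L && hs$end >= 301L)
  expect_equal(hs$condition, "U")

  # no regulated genes at all: no hotspots
  none <- response_set(character(0), "N", "up")
  profn <- window_profiles(ch$genes, ch$assignment, list(N = none),
                           window = 100L)
  expect_warning(hn <- call_expression_hotspots(profn, "N"),
                 "zero variance")
  expect_equal(nrow(hn), 0L)

  # shuffling the gene order destroys the spatial signal: the block is no
  # longer recovered (the statistic detects clustering, not composition)
  block_cover <- function(regions) {
    if (!nrow(regions)) return(0L)
    sum(pmax(0L, pmin(regions$end, 350L) - pmax(regions$start, 301L) + 1L))
  }
  expect_gte(block_cover(hs), 50L)
  shuffled <- base[sample.int(n)]
  up_s <- response_set(ch$genes$gene_id[shuffled], "U", "up")
  prof_s <- window_profiles(ch$genes, ch$assignment, list(U = up_s),
                            window = 100L)
  hs_s <- call_expression_hotspots(prof_s, "U")
  expect_lt(block_cover(hs_s), 40L)
})

test_that("coincidence counting and telomere flags work on known layouts", {
  tr <- data.frame(chromosome = c("1", "1", "2"),
                   start = c(1L, 200L, 120L), end = c(60L, 260L, 180L),
                   n_genes = c(60L, 61L, 61L), kind = "versatility_trough",
                   label = c("a", "b", "c"), stringsAsFactors = FALSE)
  far <- data.frame(chromosome = "1", start = 400L, end = 450L,
                    n_genes = 51L, kind = "expression_hotspot",
                    label = "x", condition = "c1",
                    stringsAsFactors = FALSE)
  co0 <- region_coincidence(tr, list(c1 = far))
  expect_equal(co0$n_coincident, 0L)

  co1 <- region_coincidence(tr, list(c1 = tr))   # identical layouts
  expect_equal(co1$n_coincident, 3L)
  expect_equal(co1$fraction, 1)

  near <- data.frame(chromosome = "1", start = 255L, end = 300L,
                     n_genes = 46L, kind = "expression_hotspot",
                     label = "y", condition = "c2",
                     stringsAsFactors = FALSE)
  co2 <- region_coincidence(tr, list(c1 = far, c2 = near))
  expect_equal(co2$n_coincident, 1L)
  expect_equal(co2$per_trough$conditions[2L], "c2")
  # min_overlap above the actual 6-gene overlap suppresses the call
  co3 <- region_coincidence(tr, list(c2 = near), min_overlap = 10L)
  expect_equal(co3$n_coincident, 0L)
  # both hotspots overlap nothing from the other condition: specific
  expect_equal(nrow(co2$specific_hotspots), 2L)

  genes <- rbind(toy_gene_table(300L, "1"), {
    g <- toy_gene_table(300L, "2"); g$gene_id <- sub("^g", "h", g$gene_id); g
  })
  fl <- flag_telomeric(tr, genes, k = 100L)
  expect_equal(fl$telomeric, c(TRUE, TRUE, FALSE))
})

test_that("the default genome yields 19 troughs, 13 coincident", {
  g <- generate_genome(seed = 17)
  e <- generate_expression(g, seed = 17)
  a <- assign_versatility(g$hits, g$core_ids)
  pool_up <- function(c1, c2)
    pool_conditions(build_response_set(e$records[[c1]], "up"),
                    build_response_set(e$records[[c2]], "up"))
  sets <- list(VsSf = pool_up("VsSf2h", "VsSf6h"),
               VsSm = pool_up("VsSm2h", "VsSm6h"))
  prof <- window_profiles(g$genes, a, sets)
  tr <- call_versatility_troughs(prof)
  expect_equal(nrow(tr), 19L)
  tr <- flag_telomeric(tr, g$genes)
  expect_equal(sum(tr$telomeric), 8L)
  hot <- list(VsSf = call_expression_hotspots(prof, "VsSf"),
              VsSm = call_expression_hotspots(prof, "VsSm"))
  co <- region_coincidence(tr, hot)
  expect_equal(co$n_coincident, 13L)
})
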