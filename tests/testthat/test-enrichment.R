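# categorical enrichment, threshold sweeps, cluster summaries and
# up/down bias

test_that("enrichment fold and p behave at the analytic anchors", {
  u <- sprintf("u%03d", 1:100)
  set <- response_set(u[1:10], "S", "up")

  # category = universe: fold 1, p 1
  r <- category_enrichment(set, u, 100, label = "all")
  expect_equal(r$fold, 1)
  expect_equal(r$p_two_tail, 1)

  # complete overlap of a 10-gene category: fold 10, extreme-tail p
  r2 <- category_enrichment(set, u[1:10], 100, label = "same")
  expect_equal(r2$fold, 10)
  expect_equal(r2$p_two_tail, fisher_oracle(10L, 0L, 0L, 90L),
               tolerance = 1e-9)

  # overlap exactly at expectation: fold exactly 1
  r3 <- category_enrichment(response_set(u[1:20], "S", "up"),
                            c(u[1:10], u[21:60]), 100, label = "e")
  expect_equal(r3$observed, 10L)     # 20 * 50 / 100
  expect_equal(r3$fold, 1)

  # depletion is reported with the same two-tail p
  r4 <- category_enrichment(response_set(u[1:40], "S", "up"),
                            u[41:100], 100, label = "d")
  expect_equal(r4$direction, "depleted")
  expect_lt(r4$fold, 1)

  expect_warning(r5 <- category_enrichment(set, character(0), 100, "none"),
                 "undefined")
  expect_true(is.na(r5$fold))
})

test_that("fisher p is invariant under transposing the 2x2 table", {
  withr::local_seed(2)
  for (rep in 1:20) {
    m <- matrix(sample(0:15, 4L, replace = TRUE), 2L)
    expect_equal(nonself:::contingency_test(m, "fisher_exact"),
                 nonself:::contingency_test(t(m), "fisher_exact"),
                 tolerance = 1e-12)
  }
})

test_that("enrichment_table emits BH-adjusted p per set", {
  u <- sprintf("u%03d", 1:200)
  sets <- list(A = response_set(u[1:40], "A", "up"),
               B = response_set(u[51:90], "B", "up"))
  cats <- list(c1 = u[1:30], c2 = u[101:140], c3 = u[31:60])
  tab <- enrichment_table(sets, cats, 200)
  expect_equal(nrow(tab), 6L)
  expect_true(all(c("p_two_tail", "p_adjusted") %in% names(tab)))
  for (s in c("A", "B")) {
    sub <- tab[tab$set == s, ]
    expect_equal(sub$p_adjusted, stats::p.adjust(sub$p_two_tail, "BH"))
  }
})

test_that("threshold sweeps nest: observed counts never increase", {
  withr::local_seed(4)
  n <- 400L
  ids <- sprintf("g%03d", seq_len(n))
  rec <- toy_expression(ids, log2fc = stats::rnorm(n, 3, 2.5),
                        p_value = stats::runif(n, 0, 0.02))
  cat_ids <- sample(ids, 60L)
  sw <- sweep_thresholds(rec, "up", cat_ids, c(2, 4, 6, 8),
                         max_p = 0.01, universe_size = n)
  expect_equal(sw$threshold, c(2, 4, 6, 8))
  expect_true(all(diff(sw$observed) <= 0L))
  # category absent from all sets: folds 0
  absent <- sprintf("z%03d", 1:10)
  sw0 <- sweep_thresholds(rec, "up", absent, c(2, 4), max_p = 0.01,
                          universe_size = n + 10L)
  expect_true(all(sw0$fold == 0))
  expect_error(sweep_thresholds(rec, "up", cat_ids, c(4, 2), 0.01, n),
               "ascending")
})

test_that("SSP enrichment grows with the fold-change threshold on synthetic data", {
  g <- generate_genome(seed = 14)
  e <- generate_expression(g, seed = 14)
  rec <- pool_records(e$records$VsSf2h, e$records$VsSf6h)
  sw <- sweep_thresholds(rec, "up", ssp_genes(g$genes), c(2, 4, 6),
                         max_p = 0.01, universe_size = nrow(g$genes),
                         label = "SSP")
  expect_gt(sw$fold[sw$threshold == 6], sw$fold[sw$threshold == 2])
})

test_that("cluster summaries match a direct group-by recount", {
  withr::local_seed(6)
  cl <- stats::setNames(rep(sprintf("SM:%02d", 1:5), times = c(4, 3, 5, 2, 6)),
                        sprintf("s%02d", 1:20))
  other <- sprintf("o%02d", 1:80)
  up <- response_set(c(sample(names(cl), 8L), sample(other, 10L)), "U", "up")
  res <- sm_cluster_summary(cl, list(U = up), universe_size = 100L)
  counts <- table(factor(cl[names(cl) %in% up$members],
                         levels = sort(unique(cl))))
  expect_equal(res$per_cluster$U, as.integer(counts))
  expect_equal(res$summary$clusters_ge1, sum(counts >= 1L))
  expect_equal(res$summary$clusters_ge3, sum(counts >= 3L))
  expect_equal(res$summary$n_genes_up, sum(counts))

  # nothing regulated: zero summaries
  res0 <- sm_cluster_summary(cl, list(U = response_set(other[1:5], "U",
                                                       "up")), 100L)
  expect_equal(res0$summary$clusters_ge1, 0L)
  expect_equal(res0$summary$clusters_ge3, 0L)

  # one whole cluster regulated: present in both summaries
  full <- response_set(names(cl)[cl == "SM:03"], "U", "up")
  resf <- sm_cluster_summary(cl, list(U = full), 100L)
  expect_equal(resf$summary$clusters_ge1, 1L)
  expect_equal(resf$summary$clusters_ge3, 1L)
})

test_that("up/down bias follows the closed-form binomial", {
  up <- response_set(sprintf("u%02d", 1:10), "U", "up")
  down <- response_set(sprintf("d%02d", 1:10), "D", "down")
  # equal split, even n: p = 1
  r <- updown_bias(c("u01", "u02", "d01", "d02"), up, down)
  expect_equal(r$p_two_tail, 1)
  expect_equal(r$ratio, 1)
  # (3, 0): p = 2 * (1/2)^3
  r2 <- updown_bias(c("u01", "u02", "u03"), up, down)
  expect_equal(r2$n_up, 3L)
  expect_equal(r2$p_two_tail, 0.25)
  # large imbalance like 1493/995: ratio 1.5, p far below 1e-3
  big_up <- response_set(sprintf("b%04d", 1:1493), "U", "up")
  big_down <- response_set(sprintf("c%04d", 1:995), "D", "down")
  r3 <- updown_bias(c(big_up$members, big_down$members), big_up, big_down)
  expect_equal(round(r3$ratio, 1), 1.5)
  expect_lt(r3$p_two_tail, 1e-10)
  expect_equal(r3$p_two_tail,
               stats::binom.test(1493L, 2488L, 0.5)$p.value)

  expect_warning(r4 <- updown_bias("nope", up, down), "undefined")
  expect_true(is.na(r4$ratio))
  expect_error(updown_bias("x", up, response_set("u01", "D", "down")),
               "disjoint")
})

test_that("common-core report counts terms in the all-condition intersections", {
  mk <- function(ids, d = "up") response_set(ids, paste(ids[1L], d), d)
  core <- sprintf("k%02d", 1:10)
  ups <- list(mk(c(core, "x1")), mk(c(core, "x2")), mk(c(core, "x3")))
  downs <- list(mk("y1", "down"), mk("y1", "down"), mk("y1", "down"))
  ann <- data.frame(gene_id = c(core, core[1:4], "y1"),
                    term = c(rep("PF1", 10L), rep("PF2", 4L), "GO9"),
                    stringsAsFactors = FALSE)
  rep5 <- common_core_report(ups, downs, ann, min_occurrence = 5L)
  expect_equal(rep5$term, "PF1")          # PF2 occurs 4 times, GO9 once
  expect_equal(rep5$n_up_core, 10L)

  # boundary: exactly five occurrences is included
  ann5 <- data.frame(gene_id = core[1:5], term = "PF5")
  expect_equal(common_core_report(ups, downs, ann5)$term, "PF5")

  # empty intersections give an empty report
  disj <- list(mk("a1"), mk("a2"), mk("a3"))
  expect_equal(nrow(common_core_report(disj, downs, ann)), 0L)

  # random annotations match a brute-force recount
  withr::local_seed(8)
  ids <- sprintf("r%03d", 1:60)
  ups_r <- list(mk(sample(ids, 40L)), mk(sample(ids, 40L)),
                mk(sample(ids, 40L)))
  ann_r <- data.frame(gene_id = sample(ids, 120L, replace = TRUE),
                      term = sample(c("T1", "T2", "T3"), 120L,
                                    replace = TRUE),
                      stringsAsFactors = FALSE)
  got <- common_core_report(ups_r, downs, ann_r, min_occurrence = 1L)
  core_up <- Reduce(intersect, lapply(ups_r, function(s) s$members))
  for (i in seq_len(nrow(got)))
    expect_equal(got$n_up_core[i],
                 sum(ann_r$term == got$term[i] &
                       ann_r$gene_id %in% core_up))
  expect_error(common_core_report(ups[1:2], downs, ann), "three")
})

test_that("enrichment of large random sets is unbiased (fold near 1)", {
  withr::local_seed(10)
  u <- sprintf("u%05d", 1:10000)
  cat_ids <- u[1:800]
  folds <- replicate(15, {
    category_enrichment(sample(u, 2000L), cat_ids, 10000L)$fold
  })
  expect_gt(mean(folds), 0.9)
  expect_lt(mean(folds), 1.1)
})
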