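# response-set construction and cross-condition overlap statistics

test_that("selection is strict on both thresholds", {
  rec <- toy_expression(sprintf("g%d", 1:6),
                        log2fc = c(3, -3, 1, 4, 5, -5),
                        p_value = c(0.001, 0.001, 0.001, 0.001, 0.5, 0.5))
  up <- build_response_set(rec, "up", 2, 0.01)
  down <- build_response_set(rec, "down", 2, 0.01)
  expect_setequal_chr(up$members, c("g1", "g4"))
  expect_equal(down$members, "g2")
  expect_length(intersect(up$members, down$members), 0L)

  # boundary: log2fc exactly at the threshold is excluded
  rec2 <- toy_expression("b1", 2.0, 1e-6)
  expect_length(build_response_set(rec2, "up", 2, 0.01)$members, 0L)
  # p exactly at the threshold is excluded too
  rec3 <- toy_expression("b2", 5, 0.01)
  expect_length(build_response_set(rec3, "up", 2, 0.01)$members, 0L)
  # max_p = 0 empties everything
  expect_length(build_response_set(rec, "up", 2, 0)$members, 0L)
  expect_error(build_response_set(rec, "up", -1, 0.01), "min_abs_log2fc")
  expect_error(build_response_set(rec[c(1, 1), ], "up"), "duplicate")
})

test_that("pooling is a union with provenance and matches inclusion-exclusion", {
  a <- response_set(c("g1", "g2", "g3"), "A", "up")
  b <- response_set(c("g4", "g5", "g6", "g7"), "B", "up")
  expect_length(pool_conditions(a, b)$members, 7L)
  expect_setequal_chr(pool_conditions(a, a)$members, a$members)  # idempotent
  expect_error(pool_conditions(a, response_set("x", "C", "down")),
               "mixed directions")

  withr::local_seed(1)
  for (rep in 1:10) {
    u <- sprintf("u%03d", 1:200)
    x <- response_set(sample(u, 60), "X", "up")
    y <- response_set(sample(u, 80), "Y", "up")
    expect_equal(length(pool_conditions(x, y)$members),
                 length(x$members) + length(y$members) -
                   length(intersect(x$members, y$members)))
  }
})

test_that("venn regions are exhaustive, exclusive and match enumeration", {
  mk <- function(ids, lab) response_set(ids, lab, "up")
  # three pairwise-disjoint sets
  v <- venn(list(mk(c("a", "b"), "A"), mk(c("c"), "B"), mk(c("d", "e"), "C")))
  expect_equal(sum(v$count), 5L)
  expect_true(all(v$count[grepl("&", v$region)] == 0L))

  # nested A in B in C
  v2 <- venn(list(mk("a", "A"), mk(c("a", "b"), "B"),
                  mk(c("a", "b", "c"), "C")))
  expect_equal(v2$count[v2$region == "A&B&C"], 1L)
  expect_equal(v2$count[v2$region == "B&C"], 1L)
  expect_equal(v2$count[v2$region == "C only"], 1L)
  expect_equal(v2$count[v2$region == "A only"], 0L)

  # random 100-gene universe vs brute-force membership enumeration
  withr::local_seed(7)
  u <- sprintf("u%03d", 1:100)
  sets <- list(mk(sample(u, 40), "A"), mk(sample(u, 30), "B"),
               mk(sample(u, 50), "C"))
  v3 <- venn(sets)
  member <- sapply(sets, function(s) u %in% s$members)
  for (i in seq_len(nrow(v3))) {
    inc <- strsplit(sub(" only$", "", v3$region[i]), "&")[[1L]]
    want <- colnames(member) <- c("A", "B", "C")
    pat <- want %in% inc
    expect_equal(v3$count[i],
                 sum(apply(member, 1L, function(r) all(r == pat))))
  }
  # region counts reconstruct each input set's size
  for (lab in c("A", "B", "C")) {
    tot <- sum(v3$count[sapply(strsplit(sub(" only$", "", v3$region), "&"),
                               function(x) lab %in% x)])
    expect_equal(tot, length(sets[[match(lab, c("A", "B", "C"))]]$members))
  }
  expect_error(venn(list(mk("a", "A"))), "2 or 3")
})

test_that("specific fraction is |A \\ B| / |A| and complements the overlap", {
  a <- response_set(sprintf("g%d", 1:10), "A", "up")
  expect_equal(specific_fraction(a, a), 0)
  b <- response_set(sprintf("g%d", 6:20), "B", "up")
  expect_equal(specific_fraction(a, b) + 100 *
                 length(intersect(a$members, b$members)) /
                 length(a$members), 100)
  empty <- response_set(character(0), "E", "up")
  expect_warning(res <- specific_fraction(empty, a), "undefined")
  expect_true(is.na(res))
})

test_that("overlap test builds the right table and matches the oracle", {
  # identical sets: fold = universe / |A|, minimal attainable p
  a <- response_set(sprintf("g%d", 1:20), "A", "up")
  r <- overlap_test(a, a, 400)
  expect_equal(r$fold, 400 / 20)
  expect_equal(r$counts[1L, 1L], 20)
  expect_lt(r$p_two_tail, 1e-20)

  # worked table (20, 30, 10, 940): p equals the hypergeometric tail sum
  s <- sets_from_table(20L, 30L, 10L, 940L)
  r2 <- overlap_test(s$A, s$B, s$universe)
  expect_equal(unname(as.vector(t(r2$counts))), c(20, 30, 10, 940))
  expect_equal(r2$p_two_tail, fisher_oracle(20L, 30L, 10L, 940L),
               tolerance = 1e-9)
  expect_equal(r2$fold, 20 / (50 * 30 / 1000))

  # fold is symmetric in A and B
  r3 <- overlap_test(s$B, s$A, s$universe)
  expect_equal(r3$fold, r2$fold)
  expect_equal(r3$p_two_tail, r2$p_two_tail)

  expect_error(overlap_test(a, response_set(sprintf("h%d", 1:30), "B", "up"),
                            universe_size = 40), "universe")

  # chi-square variant agrees with stats::chisq.test
  r4 <- overlap_test(s$A, s$B, s$universe, method = "chi_square")
  expect_equal(r4$p_two_tail,
               suppressWarnings(stats::chisq.test(r2$counts,
                                                  correct = FALSE)$p.value))
})

test_that("independent random sets give fold near 1 and roughly uniform p", {
  withr::local_seed(3)
  u <- sprintf("u%04d", 1:10000)
  res <- replicate(40, {
    r <- overlap_test(sample(u, 100), sample(u, 100), 10000)
    c(r$fold, r$p_two_tail)
  })
  expect_equal(mean(res[1L, ]), 1, tolerance = 0.35)
  expect_gt(mean(res[2L, ] > 0.05), 0.6)   # far from systematic significance
})

test_that("magnitude bias counts and sign test follow closed forms", {
  rec <- toy_expression(c("g1", "g2", "g3"), c(3, 4, 5), rep(1e-4, 3L))
  mb_tie <- magnitude_bias(rec, rec, c("g1", "g2", "g3"))
  expect_equal(mb_tie$n_tied, 3L)
  expect_equal(mb_tie$test$p_two_tail, 1)

  rec_b <- toy_expression(c("g1", "g2", "g3"), c(2, 3, 4), rep(1e-4, 3L))
  mb <- magnitude_bias(rec, rec_b, c("g1", "g2", "g3"))
  expect_equal(mb$n_greater_in_a, 3L)
  expect_equal(mb$test$p_two_tail, 2 * 0.5^3)   # 0.25
  expect_equal(mb$n_greater_in_a + mb$n_greater_in_b + mb$n_tied, 3L)

  # down-regulation compares absolute values
  mb_dn <- magnitude_bias(toy_expression("g1", -6, 1e-4),
                          toy_expression("g1", -2, 1e-4), "g1")
  expect_equal(mb_dn$n_greater_in_a, 1L)

  expect_error(magnitude_bias(rec, rec_b, character(0)), "empty")
  expect_s3_class(magnitude_bias(rec, rec_b, c("g1", "g2", "g3"),
                                 test = "fisher")$test,
                  "contingency_result")
})

test_that("generator magnitude ratio is detected by the sign test", {
  g <- generate_genome(seed = 6)
  e <- generate_expression(g, params = list(magnitude_ratio = 1.5),
                           seed = 6)
  rec_sf <- pool_records(e$records$VsSf2h, e$records$VsSf6h)
  rec_sm <- pool_records(e$records$VsSm2h, e$records$VsSm6h)
  shared <- intersect(e$truth$up$VsSf, e$truth$up$VsSm)[1:500]
  mb <- magnitude_bias(rec_sf, rec_sm, shared)
  expect_gt(mb$n_greater_in_a, mb$n_greater_in_b)
  expect_lt(mb$test$p_two_tail, 0.01)
})

test_that("fold-change concordance matches the textbook formula", {
  rec <- toy_expression(sprintf("g%d", 1:5), c(1, 2, 3, 4, 10),
                        rep(1e-4, 5L))
  ids <- rec$gene_id
  expect_equal(fc_concordance(rec, rec, ids), 1)
  neg <- rec; neg$log2fc <- -neg$log2fc
  expect_equal(fc_concordance(rec, neg, ids), -1)
  other <- toy_expression(ids, c(2, 1, 5, 4, 7), rep(1e-4, 5L))
  r <- fc_concordance(rec, other, ids, method = "pearson")
  x <- rec$log2fc; y <- other$log2fc
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, hand)
  flat <- toy_expression(ids, rep(2, 5L), rep(1e-4, 5L))
  expect_warning(expect_true(is.na(fc_concordance(rec, flat, ids))),
                 "zero variance")
})

test_that("threshold profile hits 100% on a universal reference and flags empties", {
  rec <- toy_expression(sprintf("g%d", 1:8),
                        c(3, 4, 5, 6, -3, -4, 1, 0.5), rep(1e-4, 8L))
  ref <- list(up = sprintf("g%d", 1:8), down = sprintf("g%d", 1:8))
  prof <- threshold_profile_overlap(list(c1 = rec), c(2, 4), ref)
  filled <- prof[!prof$empty, ]
  expect_true(all(filled$pct_overlap == 100))
  # a threshold above the maximum |log2fc| flags the row
  prof2 <- threshold_profile_overlap(list(c1 = rec), c(2, 50), ref)
  expect_true(all(prof2$empty[prof2$threshold == 50]))
  expect_true(all(is.na(prof2$pct_overlap[prof2$threshold == 50])))
  expect_error(threshold_profile_overlap(list(c1 = rec), c(4, 2), ref),
               "ascending")
})

test_that("generator VI overlap decays as the fold-change threshold rises", {
  g <- generate_genome(seed = 13)
  e <- generate_expression(g, seed = 13)
  rec_sf <- pool_records(e$records$VsSf2h, e$records$VsSf6h)
  ref <- list(up = e$truth$up$VI, down = e$truth$down$VI)
  prof <- threshold_profile_overlap(list(VsSf = rec_sf), c(2, 4, 6, 8), ref)
  up <- prof[prof$direction == "up" & !prof$empty, ]
  expect_gt(up$pct_overlap[up$threshold == 2],
            up$pct_overlap[up$threshold == 8])
})
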