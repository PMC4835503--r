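# fixtures built in code: tiny gene tables, expression tables and an
# independent hypergeometric oracle for two-tail Fisher p-values

toy_gene_table <- function(n = 6L, chromosome = "1") {
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             chromosome = chromosome,
             ordinal = seq_len(n),
             protein_length = 100L + seq_len(n),
             is_secreted = rep(c(TRUE, FALSE), length.out = n),
             categories = "",
             stringsAsFactors = FALSE)
}

toy_expression <- function(gene_ids, log2fc, p_value, condition = "cond") {
  data.frame(gene_id = gene_ids, condition = condition,
             log2fc = log2fc, p_value = p_value, stringsAsFactors = FALSE)
}

# a hand-built versatility assignment (index per gene, in gene order)
fake_assignment <- function(genes, index, n_bins = 10L) {
  structure(data.frame(gene_id = genes$gene_id,
                       n_hits = pmax(1L, index * 10L),
                       category = ifelse(index == 0L, "orphan",
                                  ifelse(index == n_bins + 1L, "core",
                                         paste0("bin", index))),
                       index = as.integer(index),
                       stringsAsFactors = FALSE),
            n_bins = n_bins)
}

# independent oracle: two-tail Fisher p as the sum of hypergeometric point
# probabilities no larger than that of the observed table
fisher_oracle <- function(a, b, c, d) {
  K <- a + b; n <- a + c; N <- a + b + c + d
  lo <- max(0L, K + n - N); hi <- min(K, n)
  probs <- stats::dhyper(lo:hi, K, N - K, n)
  obs <- stats::dhyper(a, K, N - K, n)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# realize a 2x2 overlap table as explicit gene-id sets
sets_from_table <- function(a, b, c, d) {
  ids <- sprintf("u%04d", seq_len(a + b + c + d))
  list(A = ids[seq_len(a + b)],
       B = c(ids[seq_len(a)], ids[a + b + seq_len(c)]),
       universe = length(ids))
}

expect_setequal_chr <- function(x, y) {
  expect_true(setequal(x, y),
              info = sprintf("sets differ: %d vs %d members",
                             length(x), length(y)))
}
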