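# Reciprocal-best-hit orthology and cross-species response-overlap
# statistics.

#' Best hit per query in a directed similarity table
#'
#' The best hit is the record with the highest score; ties are broken by the
#' lower e-value, then by lexicographic subject id, so the result is
#' deterministic regardless of input order. Tables without e-values skip
#' straight to the lexicographic rule.
#'
#' @param tab Similarity table as returned by [read_similarity_table()].
#' @return Data frame with columns `query_id`, `subject_id`; one row per
#'   query.
#' @export
best_hits <- function(tab) {
  if (nrow(tab) == 0L) stopf("similarity table is empty")
  ev <- if (all(is.na(tab$e_value))) rep(0, nrow(tab)) else tab$e_value
  ord <- order(tab$query_id, -tab$score, ev, tab$subject_id)
  t2 <- tab[ord, , drop = FALSE]
  first <- !duplicated(t2$query_id)
  out <- t2[first, c("query_id", "subject_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is an ortholog pair when b is a's best hit in the A-to-B
#' table and a is b's best hit in the B-to-A table. Every gene occurs in at
#' most one pair, and swapping the two inputs yields the mirrored pair set.
#'
#' @param tab_ab Directed similarity table, species A queries vs species B
#'   subjects.
#' @param tab_ba The reverse direction.
#' @return Data frame with columns `gene_a`, `gene_b`, sorted by `gene_a`.
#' @export
reciprocal_best_hits <- function(tab_ab, tab_ba) {
  ab <- best_hits(tab_ab)
  ba <- best_hits(tab_ba)
  m <- merge(ab, ba, by.x = c("query_id", "subject_id"),
             by.y = c("subject_id", "query_id"))
  out <- data.frame(gene_a = m$query_id, gene_b = m$subject_id,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-species overlap of regulated ortholog pairs
#'
#' Counts ortholog pairs whose species-A side is in the species-A gene set
#' and whose species-B side is in the species-B response set, compares the
#' count with the independence expectation
#' `|setA in pairs| * |setB in pairs| / n_orthologs`, and reports the Fisher
#' two-tail p-value over the ortholog-pair universe.
#'
#' @param pairs Ortholog pair table from [reciprocal_best_hits()].
#' @param set_a Character vector of species-A gene ids.
#' @param set_b A [response_set()] (or gene-id vector) on species B.
#' @param n_orthologs Size of the ortholog universe (defaults to
#'   `nrow(pairs)`).
#' @param label Row label.
#' @return One-row data frame with columns `label`, `n_a`, `n_b`, `overlap`,
#'   `expected`, `fold`, `p_two_tail`.
#' @export
cross_species_overlap <- function(pairs, set_a, set_b,
                                  n_orthologs = nrow(pairs),
                                  label = "overlap") {
  if (n_orthologs == 0L) stopf("undefined for an empty ortholog universe")
  a_in <- pairs$gene_a %in% as_member_ids(set_a)
  b_in <- pairs$gene_b %in% as_member_ids(set_b)
  ov <- sum(a_in & b_in)
  n_a <- sum(a_in); n_b <- sum(b_in)
  expected <- n_a * n_b / n_orthologs
  counts <- matrix(c(ov, n_a - ov, n_b - ov,
                     n_orthologs - n_a - n_b + ov), 2L, byrow = TRUE)
  data.frame(label = label, n_a = n_a, n_b = n_b, overlap = ov,
             expected = expected,
             fold = if (expected > 0) ov / expected else NA_real_,
             p_two_tail = contingency_test(counts, "fisher_exact"),
             stringsAsFactors = FALSE)
}

#' Down/up ratio of cross-species overlap proportions
#'
#' The ratio of the down-regulated overlap proportion to the up-regulated
#' one, `(down_overlap / down_total) / (up_overlap / up_total)`, reported
#' rounded to one decimal, with a Fisher two-tail test of the two
#' proportions.
#'
#' @param up_overlap,up_total Overlapping and total counts for the
#'   up-regulated sets.
#' @param down_overlap,down_total Likewise for the down-regulated sets.
#' @return List with `ratio`, `ratio_rounded` and `result`
#'   (a [contingency_result()]).
#' @export
down_up_ratio <- function(up_overlap, up_total, down_overlap, down_total) {
  if (up_total <= 0L || down_total <= 0L) stopf("totals must be positive")
  counts <- matrix(c(up_overlap, up_total - up_overlap,
                     down_overlap, down_total - down_overlap),
                   nrow = 2L, byrow = TRUE)
  if (any(counts < 0)) stopf("overlap cannot exceed its total")
  ratio <- if (up_overlap == 0L) {
    warnf("down/up ratio undefined: no up-regulated overlap")
    NA_real_
  } else {
    (down_overlap / down_total) / (up_overlap / up_total)
  }
  res <- contingency_result(counts, fold = ratio %||% NA_real_,
                            p_two_tail = contingency_test(counts,
                                                          "fisher_exact"),
                            method = "fisher_exact",
                            fold_defined = !is.na(ratio))
  list(ratio = ratio,
       ratio_rounded = if (is.na(ratio)) NA_real_ else round(ratio, 1L),
       result = res)
}
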