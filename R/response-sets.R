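# Direction-specific differentially-expressed gene sets and all
# cross-condition overlap statistics.
#
# Threshold convention: the selection rule is strict on both scales,
# log2FC > min_abs_log2fc (up), log2FC < -min_abs_log2fc (down), and
# p < max_p. `min_abs_log2fc` is always on the log2 scale; callers working
# in raw fold change should pass log2(fc).

#' Construct a response set
#'
#' A labelled, direction-specific set of differentially expressed gene ids
#' with the thresholds that produced it.
#'
#' @param members Character vector of gene ids (de-duplicated).
#' @param label Set label (e.g. `"VsSf up"`).
#' @param direction `"up"` or `"down"`.
#' @param min_abs_log2fc,max_p Thresholds recorded for provenance.
#' @return An object of class `"response_set"`.
#' @export
response_set <- function(members, label, direction = c("up", "down"),
                         min_abs_log2fc = NA_real_, max_p = NA_real_) {
  direction <- match.arg(direction)
  structure(list(members = unique(as.character(members)),
                 label = label, direction = direction,
                 min_abs_log2fc = min_abs_log2fc, max_p = max_p),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("response_set '%s' (%s): %d genes [|log2FC| > %s, p < %s]\n",
              x$label, x$direction, length(x$members),
              format(x$min_abs_log2fc), format(x$max_p)))
  invisible(x)
}

#' @export
length.response_set <- function(x) length(x$members)

# accept a response_set or a plain character vector of ids
as_member_ids <- function(x) {
  if (inherits(x, "response_set")) x$members
  else if (is.character(x)) unique(x)
  else stopf("expected a response_set or a character vector of gene ids")
}

#' Build a response set from expression records
#'
#' Selection is strict: `log2fc > min_abs_log2fc` (up) or
#' `log2fc < -min_abs_log2fc` (down), and `p_value < max_p`. A gene with
#' log2FC exactly equal to the threshold is excluded. Up and down sets built
#' from the same table at the same thresholds are therefore disjoint.
#'
#' @param records Expression records (one row per gene) as returned by
#'   [read_expression_table()].
#' @param direction `"up"` or `"down"`.
#' @param min_abs_log2fc Log2 fold-change threshold (> 0; default 2).
#' @param max_p P-value threshold (default 0.01).
#' @param label Optional set label; defaults to `<condition> <direction>`.
#' @return A [response_set()].
#' @export
build_response_set <- function(records, direction = c("up", "down"),
                               min_abs_log2fc = 2, max_p = 0.01,
                               label = NULL) {
  direction <- match.arg(direction)
  if (min_abs_log2fc < 0) stopf("min_abs_log2fc must be >= 0")
  if (max_p < 0) stopf("max_p must be >= 0")
  if (anyDuplicated(records$gene_id))
    stopf("expression records must contain one row per gene (duplicate '%s')",
          records$gene_id[duplicated(records$gene_id)][1L])
  sel <- if (direction == "up") records$log2fc > min_abs_log2fc
         else records$log2fc < -min_abs_log2fc
  sel <- sel & records$p_value < max_p
  label <- label %||% paste(records$condition[1L] %||% "set", direction)
  response_set(records$gene_id[sel], label = label, direction = direction,
               min_abs_log2fc = min_abs_log2fc, max_p = max_p)
}

#' Pool two response sets of the same direction (union of members)
#'
#' Used to collapse the time points of one condition into the set of unique
#' regulated genes (e.g. VsSf = VsSf2h U VsSf6h). The label records the
#' provenance.
#'
#' @param set_a,set_b [response_set()]s with the same direction.
#' @param label Optional label for the pooled set.
#' @return A [response_set()].
#' @export
pool_conditions <- function(set_a, set_b, label = NULL) {
  if (!identical(set_a$direction, set_b$direction))
    stopf("cannot pool sets with mixed directions (%s vs %s)",
          set_a$direction, set_b$direction)
  response_set(union(set_a$members, set_b$members),
               label = label %||% paste(set_a$label, "+", set_b$label),
               direction = set_a$direction,
               min_abs_log2fc = min(set_a$min_abs_log2fc,
                                    set_b$min_abs_log2fc),
               max_p = max(set_a$max_p, set_b$max_p))
}

#' Pool the expression records of two time points of one condition
#'
#' For per-gene statistics on a pooled condition (magnitude bias, fold-change
#' concordance, threshold profiles) each gene keeps the record with the
#' largest absolute log2 fold change across time points, and the smaller of
#' the two p-values.
#'
#' @param rec_a,rec_b Expression record data frames.
#' @param condition Label for the pooled records.
#' @return An expression record data frame.
#' @export
pool_records <- function(rec_a, rec_b, condition = "pooled") {
  m <- merge(rec_a[, c("gene_id", "log2fc", "p_value")],
             rec_b[, c("gene_id", "log2fc", "p_value")],
             by = "gene_id", all = TRUE, suffixes = c("_a", "_b"))
  fa <- ifelse(is.na(m$log2fc_a), 0, m$log2fc_a)
  fb <- ifelse(is.na(m$log2fc_b), 0, m$log2fc_b)
  take_a <- abs(fa) >= abs(fb)
  data.frame(gene_id = m$gene_id, condition = condition,
             log2fc = ifelse(take_a, fa, fb),
             p_value = pmin(ifelse(is.na(m$p_value_a), 1, m$p_value_a),
                            ifelse(is.na(m$p_value_b), 1, m$p_value_b)),
             stringsAsFactors = FALSE)
}

#' Exhaustive Venn region counts for two or three response sets
#'
#' @param sets List of two or three [response_set()]s with the same
#'   direction.
#' @return Data frame with columns `region` (e.g. `"A&B"`, using the set
#'   labels) and `count`; regions are mutually exclusive and sum to the size
#'   of the union. The input set labels are kept in the `"labels"` attribute.
#' @export
venn <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 3L) stopf("venn() supports 2 or 3 sets, got %d", k)
  dirs <- vapply(sets, `[[`, character(1L), "direction")
  if (length(unique(dirs)) != 1L)
    stopf("all sets must share one direction")
  labels <- vapply(sets, `[[`, character(1L), "label")
  u <- unique(unlist(lapply(sets, `[[`, "members")))
  m <- vapply(sets, function(s) u %in% s$members, logical(length(u)))
  if (length(u) == 1L) m <- matrix(m, nrow = 1L)
  patterns <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k)))
  patterns <- patterns[-nrow(patterns), , drop = FALSE]  # drop all-FALSE
  region <- apply(patterns, 1L, function(p) {
    nm <- paste(labels[p], collapse = "&")
    if (sum(p) == 1L) nm <- paste(nm, "only")
    nm
  })
  count <- apply(patterns, 1L, function(p) {
    if (length(u) == 0L) return(0L)
    sum(apply(m, 1L, function(row) all(row == p)))
  })
  out <- data.frame(region = region, count = as.integer(count),
                    stringsAsFactors = FALSE)
  attr(out, "labels") <- labels
  out
}

#' Condition-specific fraction of a response set
#'
#' The percentage of A's members absent from B, `100 * |A \ B| / |A|`.
#' With A the VsSm down set (1,615 genes) and 153 genes outside VsSf this is
#' the study-style "9.5% of VsSm down genes are not in VsSf".
#'
#' @param set_a,set_b [response_set()]s (or character vectors) with the same
#'   direction.
#' @return A percentage in `[0, 100]`, or `NA` (with a warning) when A is
#'   empty.
#' @export
specific_fraction <- function(set_a, set_b) {
  if (inherits(set_a, "response_set") && inherits(set_b, "response_set") &&
      !identical(set_a$direction, set_b$direction))
    stopf("sets must share one direction")
  a <- as_member_ids(set_a)
  b <- as_member_ids(set_b)
  if (length(a) == 0L) {
    warnf("specific_fraction undefined: first set is empty")
    return(NA_real_)
  }
  100 * length(setdiff(a, b)) / length(a)
}

#' Test the overlap of two gene sets against independence
#'
#' Builds the 2x2 table `[in A & B, A only; B only, neither]` over an
#' explicit universe and reports the two-tail Fisher exact (default) or
#' chi-square p-value. Fold is observed overlap over the independence
#' expectation `|A| * |B| / universe`.
#'
#' @param set_a,set_b [response_set()]s or character vectors of gene ids.
#' @param universe_size Number of genes in the statistical universe; must be
#'   at least `|A U B|`. Always explicit, never defaulted.
#' @param method `"fisher_exact"` or `"chi_square"`.
#' @return A [contingency_result()].
#' @export
overlap_test <- function(set_a, set_b, universe_size,
                         method = c("fisher_exact", "chi_square")) {
  method <- match.arg(method)
  a <- as_member_ids(set_a)
  b <- as_member_ids(set_b)
  n_ab <- length(intersect(a, b))
  n_union <- length(a) + length(b) - n_ab
  if (universe_size < n_union)
    stopf("universe_size (%d) smaller than |A U B| (%d)",
          universe_size, n_union)
  counts <- matrix(c(n_ab, length(a) - n_ab,
                     length(b) - n_ab, universe_size - n_union),
                   nrow = 2L, byrow = TRUE)
  expected <- length(a) * length(b) / universe_size
  fold <- if (expected > 0) n_ab / expected else NA_real_
  contingency_result(counts, fold, contingency_test(counts, method), method)
}

#' Which condition regulates shared genes more strongly?
#'
#' For every shared gene the absolute log2 fold changes in the two conditions
#' are compared; ties are counted separately. The default test is a two-sided
#' binomial sign test of `n_greater_in_a` against `n_greater_in_b` (null:
#' 50/50); `test = "fisher"` instead runs a Fisher exact test of the observed
#' split against an even split of the same total.
#'
#' @param rec_a,rec_b Expression record data frames for the two conditions.
#' @param shared Gene ids present in both tables ([response_set()] or
#'   character vector).
#' @param test `"binomial"` (default) or `"fisher"`.
#' @return An object of class `"magnitude_bias"` with counts and the test
#'   result.
#' @export
magnitude_bias <- function(rec_a, rec_b, shared,
                           test = c("binomial", "fisher")) {
  test <- match.arg(test)
  ids <- as_member_ids(shared)
  if (length(ids) == 0L) stopf("magnitude_bias undefined for an empty set")
  a <- stats::setNames(rec_a$log2fc, rec_a$gene_id)[ids]
  b <- stats::setNames(rec_b$log2fc, rec_b$gene_id)[ids]
  if (anyNA(a) || anyNA(b))
    stopf("shared gene absent from an expression table: %s",
          ids[is.na(a) | is.na(b)][1L])
  ma <- abs(a); mb <- abs(b)
  n_a <- sum(ma > mb); n_b <- sum(mb > ma); n_t <- sum(ma == mb)
  n <- n_a + n_b
  if (test == "binomial") {
    p <- if (n == 0L) 1 else stats::binom.test(n_a, n, 0.5)$p.value
    res <- contingency_result(matrix(c(n_a, n_b, n - n_a, n - n_b), 2L),
                              fold = if (n_b > 0) n_a / n_b else NA_real_,
                              p_two_tail = p, method = "binomial")
  } else {
    e1 <- n %/% 2L; e2 <- n - e1
    counts <- matrix(c(n_a, n_b, e1, e2), nrow = 2L)
    res <- contingency_result(counts,
                              fold = if (n_b > 0) n_a / n_b else NA_real_,
                              p_two_tail = contingency_test(counts),
                              method = "fisher_exact")
  }
  structure(list(n_greater_in_a = n_a, n_greater_in_b = n_b, n_tied = n_t,
                 test = res),
            class = "magnitude_bias")
}

#' @export
print.magnitude_bias <- function(x, ...) {
  cat(sprintf(
    "magnitude bias: %d genes greater in A, %d in B, %d tied (%s p = %s)\n",
    x$n_greater_in_a, x$n_greater_in_b, x$n_tied, x$test$method,
    format_pvalue(x$test$p_two_tail)))
  invisible(x)
}

#' Fold-change concordance between two conditions on shared genes
#'
#' @param rec_a,rec_b Expression record data frames.
#' @param shared Gene ids present in both tables (>= 3).
#' @param method `"spearman"` (rank, default) or `"pearson"` (linear).
#' @return Correlation coefficient in `[-1, 1]`; `NA` with a warning when a
#'   side has zero variance.
#' @export
fc_concordance <- function(rec_a, rec_b, shared,
                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ids <- as_member_ids(shared)
  if (length(ids) < 3L) stopf("need at least 3 shared genes")
  a <- stats::setNames(rec_a$log2fc, rec_a$gene_id)[ids]
  b <- stats::setNames(rec_b$log2fc, rec_b$gene_id)[ids]
  if (anyNA(a) || anyNA(b))
    stopf("shared gene absent from an expression table")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warnf("fc_concordance undefined: zero variance")
    return(NA_real_)
  }
  stats::cor(a, b, method = method)
}

#' Overlap with a reference response across a fold-change threshold sweep
#'
#' For each threshold, direction and condition the response set is rebuilt at
#' that threshold and the percentage of its members also present in the
#' reference set (e.g. the vegetative-incompatibility response) is reported,
#' with a Fisher two-tail p-value against an explicit universe. Rows whose
#' rebuilt set is empty are flagged.
#'
#' @param tables Named list of expression record data frames, one per
#'   condition.
#' @param thresholds Ascending numeric vector of log2 fold-change thresholds.
#' @param reference List with elements `up` and `down`: the reference
#'   [response_set()]s (or gene-id vectors) per direction.
#' @param max_p P-value threshold used when rebuilding the sets.
#' @param universe_size Universe for the Fisher test (optional; p is `NA`
#'   when omitted).
#' @return Data frame with one row per threshold x condition x direction.
#' @export
threshold_profile_overlap <- function(tables, thresholds, reference,
                                      max_p = 0.01, universe_size = NULL) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stopf("thresholds must be strictly ascending")
  rows <- list()
  for (thr in thresholds) for (cond in names(tables))
    for (dir in c("up", "down")) {
      set <- build_response_set(tables[[cond]], dir, thr, max_p,
                                label = paste(cond, dir))
      ref <- as_member_ids(reference[[dir]])
      n <- length(set$members)
      ov <- length(intersect(set$members, ref))
      p <- NA_real_
      if (!is.null(universe_size) && n > 0L)
        p <- overlap_test(set, ref, universe_size)$p_two_tail
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = thr, condition = cond, direction = dir,
        n_set = n, n_overlap = ov,
        pct_overlap = if (n > 0L) 100 * ov / n else NA_real_,
        p_two_tail = p, empty = n == 0L, stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}
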