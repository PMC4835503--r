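# Categorical enrichment/depletion of annotations in response sets,
# fold-change threshold sweeps, secondary-metabolite cluster summaries,
# up/down bias tests and common-core annotation reporting.
#
# The universe size is always an explicit argument: enrichment folds depend
# on the denominator and no single constant is appropriate across analyses,
# so none is baked in.

#' Enrichment (or depletion) of a gene category in a response set
#'
#' Fisher exact two-tail test on the 2x2 table
#' `[in set & category, in set & not; not in set & category, neither]`.
#' Fold is `(observed / |set|) / (genome_count / universe)`; a fold below 1
#' marks depletion, which is reported with the same two-tail p-value.
#'
#' @param set A [response_set()] or character vector of gene ids.
#' @param category_members Character vector of gene ids carrying the
#'   annotation genome-wide.
#' @param universe_size Size of the gene universe (explicit, never
#'   defaulted).
#' @param label Category label for the output row.
#' @return One-row data frame with columns `category`, `genome_count`,
#'   `observed`, `set_size`, `fold`, `p_two_tail`, `direction`
#'   (`"enriched"` / `"depleted"`), `fold_defined`.
#' @export
category_enrichment <- function(set, category_members, universe_size,
                                label = "category") {
  s <- as_member_ids(set)
  cat_ids <- unique(as.character(category_members))
  n_set <- length(s); n_cat <- length(cat_ids)
  a <- length(intersect(s, cat_ids))
  if (universe_size < length(union(s, cat_ids)))
    stopf("universe_size smaller than |set U category|")
  counts <- matrix(c(a, n_set - a, n_cat - a,
                     universe_size - n_set - n_cat + a), 2L, byrow = TRUE)
  defined <- n_cat > 0L && n_set > 0L
  if (!defined) warnf("fold undefined for '%s': empty set or category", label)
  fold <- if (defined) (a / n_set) / (n_cat / universe_size) else NA_real_
  p <- contingency_test(counts, "fisher_exact")
  data.frame(category = label, genome_count = n_cat, observed = a,
             set_size = n_set, fold = fold, p_two_tail = p,
             direction = if (!defined || is.na(fold) || fold >= 1)
                         "enriched" else "depleted",
             fold_defined = defined, stringsAsFactors = FALSE)
}

#' Enrichment of several categories across several response sets
#'
#' Runs [category_enrichment()] for every set x category combination and
#' appends a Benjamini-Hochberg adjusted p-value per set alongside the raw
#' two-tail p.
#'
#' @param sets Named list of [response_set()]s.
#' @param categories Named list of character vectors of gene ids.
#' @param universe_size Size of the gene universe.
#' @return Data frame with one row per set x category, plus `set` and
#'   `p_adjusted` columns.
#' @export
enrichment_table <- function(sets, categories, universe_size) {
  rows <- list()
  for (set_name in names(sets)) {
    block <- do.call(rbind, lapply(names(categories), function(cat)
      category_enrichment(sets[[set_name]], categories[[cat]],
                          universe_size, label = cat)))
    block$set <- set_name
    block$p_adjusted <- stats::p.adjust(block$p_two_tail, "BH")
    rows[[set_name]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("set", setdiff(names(out), "set"))]
}

#' Category enrichment across a fold-change threshold sweep
#'
#' Rebuilds the response set at each threshold (strict `log2FC` cutoffs,
#' shared `max_p`) and reports the category's observed count, fold and
#' Fisher p at every threshold. Observed counts are non-increasing along
#' ascending thresholds because the sets are nested.
#'
#' @param records Expression records for one condition.
#' @param direction `"up"` or `"down"`.
#' @param category_members Genome-wide gene ids of the category.
#' @param thresholds Ascending log2 fold-change thresholds
#'   (e.g. `log2(c(2, 4, 6, 8))` for raw fold-change steps).
#' @param max_p P-value threshold (default 0.01).
#' @param universe_size Size of the gene universe.
#' @param label Category label.
#' @return Data frame with one row per threshold.
#' @export
sweep_thresholds <- function(records, direction, category_members,
                             thresholds, max_p = 0.01, universe_size,
                             label = "category") {
  if (is.unsorted(thresholds, strictly = TRUE))
    stopf("thresholds must be strictly ascending")
  out <- do.call(rbind, lapply(thresholds, function(thr) {
    set <- build_response_set(records, direction, thr, max_p)
    row <- category_enrichment(set, category_members, universe_size, label)
    cbind(data.frame(threshold = thr), row)
  }))
  rownames(out) <- NULL
  out
}

#' Secondary-metabolite cluster regulation summary
#'
#' Counts up-regulated genes per cluster and condition, summarises how many
#' clusters have at least one and at least three up-regulated genes, and
#' tests the pooled cluster gene set for enrichment in each up set.
#'
#' @param cluster_map Named character vector mapping gene id to cluster id
#'   (e.g. from [sm_cluster_map()]).
#' @param up_sets Named list of up-regulated [response_set()]s.
#' @param universe_size Size of the gene universe.
#' @return List with `per_cluster` (cluster x condition count table as a
#'   data frame) and `summary` (per condition: `n_genes_up`, `clusters_ge1`,
#'   `clusters_ge3`, `fold`, `p_two_tail`).
#' @export
sm_cluster_summary <- function(cluster_map, up_sets, universe_size) {
  clusters <- sort(unique(cluster_map))
  per <- data.frame(cluster = clusters, stringsAsFactors = FALSE)
  summ <- list()
  for (cond in names(up_sets)) {
    members <- as_member_ids(up_sets[[cond]])
    in_up <- names(cluster_map) %in% members
    counts <- table(factor(cluster_map[in_up], levels = clusters))
    per[[cond]] <- as.integer(counts)
    enr <- category_enrichment(up_sets[[cond]], names(cluster_map),
                               universe_size, label = "SM_clusters")
    summ[[cond]] <- data.frame(
      condition = cond, n_genes_up = sum(in_up),
      clusters_ge1 = sum(counts >= 1L), clusters_ge3 = sum(counts >= 3L),
      fold = enr$fold, p_two_tail = enr$p_two_tail,
      stringsAsFactors = FALSE)
  }
  list(per_cluster = per,
       summary = do.call(rbind, c(summ, list(make.row.names = FALSE))))
}

#' Up- versus down-regulation bias of a gene category
#'
#' Counts the category's genes in the up and the down set and tests the
#' split against 50/50 with a two-sided binomial test (default) or a Fisher
#' exact test of the observed split against an even split.
#'
#' @param category_genes Character vector of gene ids.
#' @param up_set,down_set Disjoint [response_set()]s (or gene-id vectors).
#' @param test `"binomial"` (default) or `"fisher"`.
#' @return List with `n_up`, `n_down`, `ratio` (`n_up / n_down`),
#'   `p_two_tail` and `test`.
#' @export
updown_bias <- function(category_genes, up_set, down_set,
                        test = c("binomial", "fisher")) {
  test <- match.arg(test)
  up <- as_member_ids(up_set); down <- as_member_ids(down_set)
  if (length(intersect(up, down)))
    stopf("up and down sets must be disjoint")
  ids <- unique(as.character(category_genes))
  n_up <- length(intersect(ids, up))
  n_down <- length(intersect(ids, down))
  n <- n_up + n_down
  if (n == 0L) {
    warnf("updown_bias undefined: no category gene is regulated")
    return(list(n_up = 0L, n_down = 0L, ratio = NA_real_,
                p_two_tail = NA_real_, test = test))
  }
  p <- if (test == "binomial") {
    stats::binom.test(n_up, n, 0.5)$p.value
  } else {
    e1 <- n %/% 2L
    contingency_test(matrix(c(n_up, n_down, e1, n - e1), 2L), "fisher_exact")
  }
  list(n_up = n_up, n_down = n_down,
       ratio = if (n_down > 0L) n_up / n_down else Inf,
       p_two_tail = p, test = test)
}

#' Annotation terms of the genes regulated in all conditions
#'
#' Intersects the up sets of all conditions (and likewise the down sets) and
#' counts annotation terms within each intersection; a term is reported when
#' it occurs at least `min_occurrence` times in either intersection.
#'
#' @param up_sets,down_sets Lists of three [response_set()]s (one per
#'   condition).
#' @param annotations Data frame with columns `gene_id`, `term` (e.g. from
#'   [gene_annotations()]).
#' @param min_occurrence Reporting cutoff (default 5, inclusive).
#' @return Data frame with columns `term`, `n_up_core`, `n_down_core`,
#'   sorted by decreasing total count.
#' @export
common_core_report <- function(up_sets, down_sets, annotations,
                               min_occurrence = 5L) {
  if (length(up_sets) != 3L || length(down_sets) != 3L)
    stopf("three conditions are required")
  core_up <- Reduce(intersect, lapply(up_sets, as_member_ids))
  core_down <- Reduce(intersect, lapply(down_sets, as_member_ids))
  count_terms <- function(ids) {
    tab <- table(annotations$term[annotations$gene_id %in% ids])
    stats::setNames(as.integer(tab), names(tab))
  }
  up_n <- count_terms(core_up)
  down_n <- count_terms(core_down)
  terms <- union(names(up_n), names(down_n))
  out <- data.frame(term = terms,
                    n_up_core = as.integer(up_n[terms]),
                    n_down_core = as.integer(down_n[terms]),
                    stringsAsFactors = FALSE)
  out$n_up_core[is.na(out$n_up_core)] <- 0L
  out$n_down_core[is.na(out$n_down_core)] <- 0L
  out <- out[out$n_up_core >= min_occurrence |
             out$n_down_core >= min_occurrence, , drop = FALSE]
  out <- out[order(-(out$n_up_core + out$n_down_core), out$term), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
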