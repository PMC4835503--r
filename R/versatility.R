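# Gene versatility: orphan / quantile-bin / core classification from
# genus-level homolog hit counts, and the 0..(n_bins + 1) versatility index.
#
# Versatility proxies how readily a gene is gained or lost across evolution:
# a single (self) hit marks an orphan, an ortholog in a distant ascomycete
# marks the conserved core genome, and the remaining genes are ranked into
# equal-occupancy bins by increasing hit count, bin 1 holding the
# lineage-specific end of the spectrum.

#' Partition genes into orphan, core and remaining classes
#'
#' A gene is an orphan when its product has exactly one (self) hit and it is
#' not in the core list. Core membership takes precedence over the hit count:
#' core status is defined by orthology, a stronger criterion, so a core gene
#' with a single hit is still classified core.
#'
#' @param hits Named integer vector of hit counts (>= 1, self hit included).
#' @param core_ids Character vector of core-genome gene ids; every id must be
#'   present in `hits`.
#' @return A list with character-vector elements `orphan`, `core`,
#'   `remaining`.
#' @export
classify_genes <- function(hits, core_ids) {
  if (is.null(names(hits)) || anyNA(names(hits)))
    stopf("hits must be a named vector")
  missing <- setdiff(core_ids, names(hits))
  if (length(missing))
    stopf("core gene absent from hit-count table: %s", missing[1L])
  ids <- names(hits)
  is_core <- ids %in% core_ids
  is_orphan <- !is_core & hits == 1L
  list(orphan = ids[is_orphan],
       core = ids[is_core],
       remaining = ids[!is_core & !is_orphan])
}

#' Rank the non-orphan, non-core genes into equal-occupancy versatility bins
#'
#' Genes are sorted by ascending hit count and sliced into `n_bins` bins of
#' near-equal occupancy (sizes differ by at most one, with the larger bins
#' first: 6,698 genes over 10 bins gives eight bins of 670 followed by two of
#' 669). Bin 1 holds the fewest-hit genes. Ties at a bin boundary are split
#' deterministically by a secondary lexicographic sort on the gene id; with
#' `keep_ties = TRUE` a tie group spanning a boundary is instead kept whole in
#' the bin holding the majority of its members (occupancies then only
#' approximate).
#'
#' @param hits Named integer vector of hit counts for the remaining genes.
#' @param n_bins Number of bins (>= 2; default 10).
#' @param keep_ties Keep equal hit counts together rather than balancing
#'   occupancy (default `FALSE`).
#' @return Named integer vector of bin numbers in `1..n_bins`.
#' @export
bin_remaining <- function(hits, n_bins = 10L, keep_ties = FALSE) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stopf("n_bins must be >= 2")
  n <- length(hits)
  if (n < n_bins)
    stopf("cannot split %d genes into %d bins", n, n_bins)
  ord <- order(hits, names(hits))
  base <- n %/% n_bins
  sizes <- rep(base, n_bins)
  extra <- n %% n_bins
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  bins <- rep.int(seq_len(n_bins), sizes)
  if (keep_ties) {
    # reassign each tie group to the bin holding most of its members
    h <- hits[ord]
    for (v in unique(h[duplicated(h)])) {
      idx <- which(h == v)
      tab <- table(bins[idx])
      bins[idx] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  out <- integer(n)
  out[ord] <- bins
  stats::setNames(out, names(hits))
}

#' Assign every gene a versatility category and index
#'
#' Combines [classify_genes()] and [bin_remaining()]: the index is 0 for
#' orphans, `n_bins + 1` for core-genome genes (11 with the default 10 bins)
#' and the bin number otherwise.
#'
#' @inheritParams classify_genes
#' @inheritParams bin_remaining
#' @return Data frame with columns `gene_id`, `n_hits`, `category`
#'   (`"orphan"`, `"bin1"`..`"bin<n>"`, `"core"`) and `index` (integer
#'   `0..n_bins + 1`), one row per gene in the order of `hits`.
#' @export
assign_versatility <- function(hits, core_ids, n_bins = 10L,
                               keep_ties = FALSE) {
  parts <- classify_genes(hits, core_ids)
  n_bins <- as.integer(n_bins)
  idx <- stats::setNames(rep(NA_integer_, length(hits)), names(hits))
  idx[parts$orphan] <- 0L
  idx[parts$core] <- n_bins + 1L
  if (length(parts$remaining)) {
    bins <- bin_remaining(hits[parts$remaining], n_bins, keep_ties)
    idx[names(bins)] <- bins
  }
  category <- ifelse(idx == 0L, "orphan",
              ifelse(idx == n_bins + 1L, "core", paste0("bin", idx)))
  structure(data.frame(gene_id = names(hits), n_hits = as.integer(hits),
                       category = category, index = unname(idx),
                       stringsAsFactors = FALSE, row.names = NULL),
            n_bins = n_bins)
}

#' Versatility index lookup
#'
#' @param assignment Result of [assign_versatility()].
#' @return Named integer vector mapping gene id to index.
#' @export
versatility_index <- function(assignment) {
  stats::setNames(assignment$index, assignment$gene_id)
}

# ordered category levels for an assignment: orphan, bin1..binN, core
versatility_levels <- function(assignment) {
  n_bins <- attr(assignment, "n_bins") %||%
    max(assignment$index[assignment$category != "core"], 1L)
  c("orphan", paste0("bin", seq_len(n_bins)), "core")
}

#' Count up- and down-regulated genes per versatility category
#'
#' @param assignment Result of [assign_versatility()].
#' @param up,down [response_set()]s (or character vectors of gene ids) built
#'   on the same genome.
#' @return Data frame with columns `category`, `index`, `n_up`, `n_down`;
#'   one row per category in index order. Column sums equal the number of set
#'   members present in the assignment.
#' @export
category_regulation_counts <- function(assignment, up, down) {
  lev <- versatility_levels(assignment)
  cat_f <- factor(assignment$category, levels = lev)
  up_ids <- as_member_ids(up)
  down_ids <- as_member_ids(down)
  n_up <- table(cat_f[assignment$gene_id %in% up_ids])
  n_down <- table(cat_f[assignment$gene_id %in% down_ids])
  data.frame(category = lev,
             index = seq_along(lev) - 1L,
             n_up = as.integer(n_up),
             n_down = as.integer(n_down),
             stringsAsFactors = FALSE)
}
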