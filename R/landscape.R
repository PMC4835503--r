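# Sliding-window landscapes of versatility and up-regulation density along
# chromosomes, and region calling.
#
# Naming note: regions dense in lineage-specific (low-index) genes are
# called "versatility troughs" here -- they are troughs of the numeric index
# even though such regions are often described as having a *high* density of
# versatile genes. Up-regulation hotspots mirror the rule with mean + sd.

#' Sliding-window profiles of versatility and up-regulation density
#'
#' Windows of `window` genes advance by `step` gene ordinals along each
#' chromosome. Each window reports the arithmetic mean versatility index and,
#' for every supplied up-regulated set, the fraction of window genes in the
#' set. Chromosomes shorter than the window are skipped with a warning.
#'
#' @param genes A validated gene table.
#' @param assignment Result of [assign_versatility()].
#' @param up_sets Named list of [response_set()]s (or gene-id vectors); one
#'   profile column per element.
#' @param window Window size in genes (>= 2; default 100).
#' @param step Step in gene ordinals (default 1).
#' @return Data frame with columns `chromosome`, `start`, `end` (closed,
#'   1-based gene ordinals), `mean_index`, then one fraction column per set.
#'   Set column names are kept in the `"set_labels"` attribute.
#' @export
window_profiles <- function(genes, assignment, up_sets = list(),
                            window = 100L, step = 1L) {
  window <- as.integer(window); step <- as.integer(step)
  if (window < 2L) stopf("window must be >= 2")
  if (step < 1L) stopf("step must be >= 1")
  vi <- versatility_index(assignment)
  if (anyNA(vi[genes$gene_id]))
    stopf("assignment does not cover every gene in the table")
  set_labels <- names(up_sets)
  if (length(up_sets) && (is.null(set_labels) || any(!nzchar(set_labels))))
    stopf("up_sets must be a named list")
  member_ids <- lapply(up_sets, as_member_ids)
  out <- list()
  for (chr in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chr, , drop = FALSE]
    g <- g[order(g$ordinal), , drop = FALSE]
    n <- nrow(g)
    if (n < window) {
      warnf("chromosome %s has %d genes (< window %d); skipped", chr, n,
            window)
      next
    }
    starts <- seq.int(1L, n - window + 1L, by = step)
    roll <- function(x) {
      cs <- cumsum(c(0, x))
      (cs[starts + window] - cs[starts]) / window
    }
    df <- data.frame(chromosome = chr, start = starts,
                     end = starts + window - 1L,
                     mean_index = roll(vi[g$gene_id]),
                     stringsAsFactors = FALSE)
    for (lab in set_labels)
      df[[lab]] <- roll(as.numeric(g$gene_id %in% member_ids[[lab]]))
    out[[chr]] <- df
  }
  if (!length(out)) stopf("no chromosome is at least %d genes long", window)
  prof <- do.call(rbind, out)
  rownames(prof) <- NULL
  attr(prof, "window") <- window
  attr(prof, "set_labels") <- set_labels
  prof
}

# union of closed integer intervals; overlapping or adjacent intervals merge.
# idempotent: merging already-merged output changes nothing.
merge_intervals <- function(start, end) {
  if (length(start) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# shared machinery: call maximal runs of consecutive units (windows or
# genes) whose value lies beyond the per-chromosome mean -/+ sd threshold,
# drop runs of fewer than min_run units, then merge overlapping or adjacent
# spans into regions. Counting the run in units suppresses single-window
# noise excursions, which in gene units would always span a whole window.
call_threshold_regions <- function(chroms, values, starts, ends, side,
                                   min_run, kind) {
  out <- list()
  for (chr in unique(chroms)) {
    sel <- chroms == chr
    v <- values[sel]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      warnf("chromosome %s: zero variance, no %s called", chr, kind)
      next
    }
    thr <- if (side == "low") mean(v) - s else mean(v) + s
    flag <- if (side == "low") v < thr else v > thr
    if (!any(flag)) next
    runs <- rle(flag)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1L
    keep <- runs$values & runs$lengths >= min_run
    if (!any(keep)) next
    reg <- merge_intervals(starts[sel][run_start[keep]],
                           ends[sel][run_end[keep]])
    if (!nrow(reg)) next
    out[[chr]] <- data.frame(chromosome = chr, start = reg$start,
                             end = reg$end,
                             n_genes = reg$end - reg$start + 1L,
                             kind = kind, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), n_genes = integer(0),
                      kind = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  reg <- do.call(rbind, out)
  reg <- reg[order(reg$chromosome, reg$start), , drop = FALSE]
  reg$label <- make_region_labels(nrow(reg))
  rownames(reg) <- NULL
  reg
}

#' Call low-versatility regions (versatility troughs)
#'
#' A trough is a maximal run of consecutive units whose versatility lies
#' strictly below the chromosome's mean minus one standard deviation, with
#' overlapping or adjacent flagged units merged into one region and regions
#' with runs of fewer than `min_run` consecutive units dropped. In `"window"` mode (the
#' default, matching landscape plots of window means) the unit is the
#' sliding window and the threshold is computed over the chromosome's window
#' means; in `"gene"` mode the unit is the single gene and the threshold is
#' computed over per-gene indices. Regions are labelled alphabetically
#' genome-wide by position.
#'
#' @param profiles Result of [window_profiles()] (window mode).
#' @param genes,assignment Gene table and [assign_versatility()] result
#'   (gene mode).
#' @param mode `"window"` (default) or `"gene"`.
#' @param min_run Minimum run length in consecutive units -- windows in
#'   window mode, genes in gene mode (default 5).
#' @return Region data frame with columns `chromosome`, `start`, `end`,
#'   `n_genes`, `kind = "versatility_trough"`, `label`.
#' @export
call_versatility_troughs <- function(profiles = NULL, genes = NULL,
                                     assignment = NULL,
                                     mode = c("window", "gene"),
                                     min_run = 5L) {
  mode <- match.arg(mode)
  if (mode == "window") {
    if (is.null(profiles)) stopf("window mode requires profiles")
    call_threshold_regions(profiles$chromosome, profiles$mean_index,
                           profiles$start, profiles$end, "low", min_run,
                           "versatility_trough")
  } else {
    if (is.null(genes) || is.null(assignment))
      stopf("gene mode requires genes and assignment")
    g <- genes[order(genes$chromosome, genes$ordinal), , drop = FALSE]
    vi <- versatility_index(assignment)[g$gene_id]
    call_threshold_regions(g$chromosome, as.numeric(vi), g$ordinal,
                           g$ordinal, "low", min_run, "versatility_trough")
  }
}

#' Call up-regulation hotspots for one condition
#'
#' Mirror image of [call_versatility_troughs()]: maximal runs of windows
#' whose up-regulated fraction exceeds the chromosome's mean plus one
#' standard deviation, merged, with the same minimum-run rule.
#'
#' @param profiles Result of [window_profiles()] containing a column for
#'   `condition`.
#' @param condition Name of the profile column to scan.
#' @param min_run Minimum run length in consecutive windows (default 5).
#' @return Region data frame (`kind = "expression_hotspot"`) with a
#'   `condition` column.
#' @export
call_expression_hotspots <- function(profiles, condition, min_run = 5L) {
  if (!condition %in% names(profiles))
    stopf("profiles have no column '%s'", condition)
  reg <- call_threshold_regions(profiles$chromosome, profiles[[condition]],
                                profiles$start, profiles$end, "high",
                                min_run, "expression_hotspot")
  if (nrow(reg)) reg$condition <- condition
  else reg$condition <- character(0)
  reg
}

#' Coincidence between versatility troughs and expression hotspots
#'
#' A trough coincides when it overlaps at least `min_overlap` genes of a
#' hotspot in at least one condition. Hotspots overlapping no hotspot of any
#' other condition are reported as condition-specific.
#'
#' @param troughs Region data frame from [call_versatility_troughs()].
#' @param hotspots Named list of region data frames (one per condition) from
#'   [call_expression_hotspots()].
#' @param min_overlap Minimum overlap in genes (default 1).
#' @return An object of class `"region_coincidence"`: list with `per_trough`
#'   (data frame: trough columns plus `conditions`, `coincident`),
#'   `n_troughs`, `n_coincident`, `fraction`, and `specific_hotspots`.
#' @export
region_coincidence <- function(troughs, hotspots, min_overlap = 1L) {
  overlap_len <- function(s1, e1, s2, e2) {
    pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
  }
  hits_any <- function(region, others) {
    if (is.null(others) || nrow(others) == 0L) return(FALSE)
    same <- others[others$chromosome == region$chromosome, , drop = FALSE]
    any(overlap_len(region$start, region$end, same$start, same$end) >=
          min_overlap)
  }
  conds <- character(nrow(troughs))
  for (i in seq_len(nrow(troughs))) {
    hit <- names(hotspots)[vapply(hotspots, function(h)
      hits_any(troughs[i, ], h), logical(1L))]
    conds[i] <- paste(hit, collapse = ";")
  }
  per_trough <- cbind(troughs,
                      data.frame(conditions = conds,
                                 coincident = nzchar(conds),
                                 stringsAsFactors = FALSE))
  specific <- list()
  for (cond in names(hotspots)) {
    h <- hotspots[[cond]]
    if (is.null(h) || nrow(h) == 0L) next
    others <- do.call(rbind, lapply(hotspots[setdiff(names(hotspots), cond)],
                                    function(x) x[, c("chromosome", "start",
                                                      "end")]))
    sp <- vapply(seq_len(nrow(h)), function(i)
      !hits_any(h[i, ], others), logical(1L))
    if (any(sp)) specific[[cond]] <- h[sp, , drop = FALSE]
  }
  specific_hotspots <- if (length(specific)) {
    do.call(rbind, c(specific, list(make.row.names = FALSE)))
  } else {
    data.frame(chromosome = character(0), start = integer(0),
               end = integer(0), condition = character(0))
  }
  structure(list(per_trough = per_trough,
                 n_troughs = nrow(troughs),
                 n_coincident = sum(per_trough$coincident),
                 fraction = if (nrow(troughs)) mean(per_trough$coincident)
                            else NA_real_,
                 specific_hotspots = specific_hotspots),
            class = "region_coincidence")
}

#' @export
print.region_coincidence <- function(x, ...) {
  cat(sprintf("%d of %d versatility troughs coincide with an up-regulation %s",
              x$n_coincident, x$n_troughs, "hotspot in >= 1 condition\n"))
  if (nrow(x$specific_hotspots))
    cat(sprintf("%d condition-specific hotspot(s)\n",
                nrow(x$specific_hotspots)))
  invisible(x)
}

#' Flag regions near a chromosome end as (sub)telomeric
#'
#' A region is flagged when it lies within `k` genes of either chromosome
#' end.
#'
#' @param regions Region data frame.
#' @param genes Gene table (supplies chromosome lengths in genes).
#' @param k Margin in genes (default 100).
#' @return `regions` with an added logical `telomeric` column.
#' @export
flag_telomeric <- function(regions, genes, k = 100L) {
  len <- tapply(genes$ordinal, genes$chromosome, max)
  L <- as.integer(len[regions$chromosome])
  regions$telomeric <- regions$start <= k | regions$end >= L - k + 1L
  regions
}

#' Plot versatility and up-regulation landscapes for one chromosome
#'
#' Draws the window-mean versatility track (left axis) and the up-regulated
#' fraction tracks (right axis), with called regions marked along the base
#' line.
#'
#' @param profiles Result of [window_profiles()].
#' @param chromosome Chromosome to draw.
#' @param troughs,hotspots Optional region data frames to mark.
#' @return Invisibly, `NULL`.
#' @export
plot_landscape <- function(profiles, chromosome, troughs = NULL,
                           hotspots = NULL) {
  p <- profiles[profiles$chromosome == chromosome, , drop = FALSE]
  if (!nrow(p)) stopf("no profile rows for chromosome %s", chromosome)
  labs <- attr(profiles, "set_labels") %||% character(0)
  mid <- (p$start + p$end) / 2
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  plot(mid, p$mean_index, type = "l", col = "blue", ylim = c(0, 11.5),
       xlab = sprintf("gene ordinal (chromosome %s)", chromosome),
       ylab = "mean versatility index",
       main = sprintf("chromosome %s", chromosome))
  if (length(labs)) {
    graphics::par(new = TRUE)
    cols <- grDevices::hcl.colors(max(2L, length(labs)), "Dark 2")
    plot(NA, xlim = range(mid), ylim = c(0, 1), axes = FALSE, xlab = "",
         ylab = "")
    for (i in seq_along(labs))
      graphics::lines(mid, p[[labs[i]]], col = cols[i])
    graphics::axis(4)
    graphics::mtext("fraction up-regulated", side = 4, line = 2.5)
    graphics::legend("topright", legend = labs, col = cols[seq_along(labs)],
                     lty = 1, bty = "n", cex = 0.8)
  }
  mark <- function(reg, y, col) {
    reg <- reg[reg$chromosome == chromosome, , drop = FALSE]
    if (nrow(reg))
      graphics::segments(reg$start, y, reg$end, y, col = col, lwd = 4)
  }
  if (!is.null(troughs)) mark(troughs, 0.02, "purple")
  if (!is.null(hotspots)) mark(hotspots, 0.00, "red")
  invisible(NULL)
}
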