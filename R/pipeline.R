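# End-to-end analysis entry points wiring the stages together, plus a
# formatting-only report. These functions are the programmatic equivalent of
# the command-line wrapper shipped in inst/cli/nonself.R (subcommands
# simulate / run-all / report).

#' Simulate a dataset from a run configuration
#'
#' Thin wrapper over [simulate_dataset()] taking a configuration list (see
#' [default_run_config()]); `config$seed` and `config$out_dir` are required.
#'
#' @param config Configuration list.
#' @return Invisibly, the [simulate_dataset()] result.
#' @export
cmd_simulate <- function(config) {
  config <- validate_run_config(utils::modifyList(default_run_config(),
                                                  config))
  if (is.null(config$seed))
    stopf("an explicit seed is required (set config$seed)")
  if (is.null(config$out_dir)) stopf("config$out_dir is required")
  simulate_dataset(config$out_dir, seed = config$seed,
                   genome_args = config$genome_args %||% list(),
                   expression_params = config$expression_params %||% list(),
                   similarity_args = config$similarity_args %||% list())
}

# expected input keys of config$inputs
pipeline_input_keys <- function(conditions) {
  c("genes", "hits", "core",
    paste0("expression_", conditions),
    "sim_ab", "sim_ba", "species_a_up", "species_a_down")
}

#' Run the full comparative analysis
#'
#' Executes every stage in dependency order on the input files named in
#' `config$inputs` (as written by [cmd_simulate()]): versatility assignment,
#' response-set construction with time-point pooling, overlap / Venn /
#' magnitude statistics, the chromosomal landscape with region calling and
#' coincidence, categorical enrichment with the SSP threshold sweep and
#' secondary-metabolite summary, and (when similarity tables are provided)
#' reciprocal-best-hit orthology with the cross-species overlap report.
#' All tables are written to `config$out_dir` together with a YAML manifest
#' (configuration echo, input checksums, stage timings, output list)
#' sufficient to re-run the analysis bit-identically. A failing stage stops
#' with a stage-named error, recorded in the manifest.
#'
#' @param config Configuration list (see [default_run_config()]); requires
#'   `inputs` and `out_dir`.
#' @return Invisibly, a list of all stage results (class `"nonself_run"`).
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(utils::modifyList(default_run_config(),
                                                  config))
  if (is.null(config$out_dir)) stopf("config$out_dir is required")
  inp <- config$inputs
  conditions <- unlist(config$pooling, use.names = FALSE)
  for (key in c("genes", "hits", "core", paste0("expression_", conditions)))
    if (is.null(inp[[key]]))
      stopf("missing input '%s' in config$inputs", key)

  timings <- list()
  results <- list(config = config)
  manifest_path <- file.path(config$out_dir, "manifest.yaml")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(code), error = function(e) {
      manifest <- list(config = config, failed_stage = name,
                       error = conditionMessage(e))
      yaml::write_yaml(manifest, manifest_path)
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  io <- stage("io", {
    genes <- read_gene_table(inp$genes)
    list(genes = genes,
         hits = read_hit_counts(inp$hits),
         core_ids = read_core_ids(inp$core),
         expr = stats::setNames(lapply(conditions, function(cond) {
           f <- inp[[paste0("expression_", cond)]]
           if (is.null(f) || !file.exists(f))
             stopf("missing expression file for condition %s", cond)
           read_expression_table(f, cond)
         }), conditions))
  })
  universe <- config$universe_size %||% nrow(io$genes)

  results$versatility <- stage("versatility", {
    assign_versatility(io$hits, io$core_ids, n_bins = config$n_bins)
  })

  results$sets <- stage("sets", {
    thr <- config$min_abs_log2fc; maxp <- config$max_p
    per_cond <- list()
    for (cond in conditions) for (dir in c("up", "down"))
      per_cond[[paste(cond, dir)]] <-
        build_response_set(io$expr[[cond]], dir, thr, maxp,
                           label = paste(cond, dir))
    pooled <- list(); pooled_rec <- list()
    for (grp in names(config$pooling)) {
      members <- config$pooling[[grp]]
      for (dir in c("up", "down")) {
        s <- per_cond[[paste(members[1L], dir)]]
        if (length(members) > 1L)
          for (m in members[-1L])
            s <- pool_conditions(s, per_cond[[paste(m, dir)]],
                                 label = paste(grp, dir))
        else s$label <- paste(grp, dir)
        pooled[[paste(grp, dir)]] <- s
      }
      rec <- io$expr[[members[1L]]]
      if (length(members) > 1L)
        for (m in members[-1L]) rec <- pool_records(rec, io$expr[[m]], grp)
      pooled_rec[[grp]] <- rec
    }
    list(per_condition = per_cond, pooled = pooled,
         pooled_records = pooled_rec)
  })

  results$overlap <- stage("overlap", {
    pooled <- results$sets$pooled
    rec <- results$sets$pooled_records
    grp <- names(config$pooling)        # e.g. VsSf, VsSm, VI
    sf <- grp[1L]; sm <- grp[2L]; vi <- grp[3L]
    venn2 <- list(); venn3 <- list(); tests <- list(); spec <- list()
    for (dir in c("up", "down")) {
      a <- pooled[[paste(sf, dir)]]; b <- pooled[[paste(sm, dir)]]
      v <- pooled[[paste(vi, dir)]]
      venn2[[dir]] <- venn(list(a, b))
      venn3[[dir]] <- venn(list(a, b, v))
      tests[[paste0("bacteria_", dir)]] <- overlap_test(a, b, universe)
      tests[[paste0("vi_", dir)]] <-
        overlap_test(pool_conditions(a, b, label = "bacteria"), v, universe,
                     method = "chi_square")
      spec[[paste0(sm, "_", dir)]] <- specific_fraction(b, a)
      spec[[paste0(sf, "_", dir)]] <- specific_fraction(a, b)
    }
    shared_up <- intersect(pooled[[paste(sf, "up")]]$members,
                           pooled[[paste(sm, "up")]]$members)
    shared_down <- intersect(pooled[[paste(sf, "down")]]$members,
                             pooled[[paste(sm, "down")]]$members)
    bias <- list(
      up = magnitude_bias(rec[[sf]], rec[[sm]], shared_up),
      down = magnitude_bias(rec[[sf]], rec[[sm]], shared_down))
    conc <- list(
      up = if (length(shared_up) >= 3L)
        fc_concordance(rec[[sf]], rec[[sm]], shared_up) else NA_real_,
      down = if (length(shared_down) >= 3L)
        fc_concordance(rec[[sf]], rec[[sm]], shared_down) else NA_real_)
    profile <- threshold_profile_overlap(
      rec[c(sf, sm)], config$sweep_thresholds,
      reference = list(up = pooled[[paste(vi, "up")]],
                       down = pooled[[paste(vi, "down")]]),
      max_p = config$max_p, universe_size = universe)
    list(venn2 = venn2, venn3 = venn3, tests = tests,
         specific_fractions = spec, magnitude_bias = bias,
         concordance = conc, threshold_profile = profile)
  })

  results$landscape <- stage("landscape", {
    pooled <- results$sets$pooled
    up_sets <- stats::setNames(
      lapply(names(config$pooling), function(g) pooled[[paste(g, "up")]]),
      names(config$pooling))
    prof <- window_profiles(io$genes, results$versatility, up_sets,
                            window = config$window, step = config$step)
    troughs <- call_versatility_troughs(prof, min_run = config$min_run)
    troughs <- flag_telomeric(troughs, io$genes, k = config$telomere_k)
    hot <- stats::setNames(lapply(names(up_sets), function(g)
      call_expression_hotspots(prof, g, min_run = config$min_run)),
      names(up_sets))
    coin <- region_coincidence(troughs, hot)
    list(profiles = prof, troughs = troughs, hotspots = hot,
         coincidence = coin)
  })

  results$enrichment <- stage("enrichment", {
    genes <- io$genes
    pooled <- results$sets$pooled
    grp <- names(config$pooling)
    cats <- list(TF = category_members(genes, "TF"),
                 NLR = category_members(genes, "NLR"),
                 HK = category_members(genes, "HK"),
                 autophagy = category_members(genes, "autophagy"),
                 SSP = ssp_genes(genes, config$ssp_max_length),
                 SM = names(sm_cluster_map(genes)))
    cats <- cats[lengths(cats) > 0L]
    tab <- enrichment_table(pooled, cats, universe)
    sweep <- do.call(rbind, lapply(grp, function(g) {
      s <- sweep_thresholds(results$sets$pooled_records[[g]], "up",
                            cats$SSP, config$sweep_thresholds,
                            config$max_p, universe, label = "SSP")
      s$condition <- g
      s
    }))
    smmap <- sm_cluster_map(genes)
    sm <- if (length(smmap))
      sm_cluster_summary(smmap,
                         stats::setNames(lapply(grp, function(g)
                           pooled[[paste(g, "up")]]), grp), universe)
      else NULL
    versatile <- results$versatility$gene_id[
      results$versatility$category != "core"]
    core <- results$versatility$gene_id[
      results$versatility$category == "core"]
    bias <- do.call(rbind, lapply(grp, function(g) {
      up <- pooled[[paste(g, "up")]]; down <- pooled[[paste(g, "down")]]
      v <- updown_bias(versatile, up, down)
      k <- updown_bias(core, up, down)
      data.frame(condition = g, group = c("versatile_or_orphan", "core"),
                 n_up = c(v$n_up, k$n_up), n_down = c(v$n_down, k$n_down),
                 p_two_tail = c(v$p_two_tail, k$p_two_tail),
                 stringsAsFactors = FALSE)
    }))
    common <- common_core_report(
      lapply(grp, function(g) pooled[[paste(g, "up")]]),
      lapply(grp, function(g) pooled[[paste(g, "down")]]),
      gene_annotations(genes))
    cat_counts <- do.call(rbind, lapply(grp, function(g)
      cbind(condition = g,
            category_regulation_counts(results$versatility,
                                       pooled[[paste(g, "up")]],
                                       pooled[[paste(g, "down")]]))))
    list(categories = cats, table = tab, ssp_sweep = sweep, sm = sm,
         updown_bias = bias, common_core = common,
         category_counts = cat_counts)
  })

  if (!is.null(inp$sim_ab) && !is.null(inp$sim_ba)) {
    results$orthology <- stage("orthology", {
      ab <- read_similarity_table(inp$sim_ab)
      ba <- read_similarity_table(inp$sim_ba)
      pairs <- reciprocal_best_hits(ab, ba)
      rows <- NULL
      if (!is.null(inp$species_a_up) && !is.null(inp$species_a_down)) {
        a_up <- read_core_ids(inp$species_a_up)
        a_down <- read_core_ids(inp$species_a_down)
        pooled <- results$sets$pooled
        grp <- names(config$pooling)
        rows <- do.call(rbind, lapply(grp, function(g) rbind(
          cross_species_overlap(pairs, a_up, pooled[[paste(g, "up")]],
                                label = paste("A_up vs", g, "up")),
          cross_species_overlap(pairs, a_down,
                                pooled[[paste(g, "down")]],
                                label = paste("A_down vs", g, "down")))))
        ratio <- down_up_ratio(
          up_overlap = rows$overlap[1L], up_total = length(a_up),
          down_overlap = rows$overlap[2L], down_total = length(a_down))
        rows <- list(table = rows, down_up = ratio)
      }
      c(list(pairs = pairs), rows)
    })
  }

  stage("write", {
    pooled <- results$sets$pooled
    sizes <- do.call(rbind, lapply(names(pooled), function(nm) {
      s <- pooled[[nm]]
      rec <- results$sets$pooled_records[[sub(" (up|down)$", "", nm)]]
      fc <- rec$log2fc[rec$gene_id %in% s$members]
      data.frame(set = nm, n = length(s$members),
                 max_abs_log2fc = if (length(fc)) round(max(abs(fc)), 2)
                                  else NA_real_, stringsAsFactors = FALSE)
    }))
    spec <- results$overlap$specific_fractions
    spec_df <- data.frame(comparison = names(spec),
                          pct_specific = round(unlist(spec), 2))
    tests <- results$overlap$tests
    tests_df <- do.call(rbind, lapply(names(tests), function(nm)
      data.frame(test = nm, fold = tests[[nm]]$fold,
                 p_two_tail = format_pvalue(tests[[nm]]$p_two_tail),
                 stringsAsFactors = FALSE)))
    tables <- list(
      versatility = results$versatility,
      set_sizes = sizes,
      venn_up = results$overlap$venn3$up,
      venn_down = results$overlap$venn3$down,
      specific_fractions = spec_df,
      overlap_tests = tests_df,
      threshold_profile = results$overlap$threshold_profile,
      window_profiles = results$landscape$profiles,
      enrichment = results$enrichment$table,
      ssp_sweep = results$enrichment$ssp_sweep,
      updown_bias = results$enrichment$updown_bias,
      category_counts = results$enrichment$category_counts,
      common_core = results$enrichment$common_core,
      coincidence = results$landscape$coincidence$per_trough)
    if (!is.null(results$enrichment$sm)) {
      tables$sm_summary <- results$enrichment$sm$summary
      tables$sm_per_cluster <- results$enrichment$sm$per_cluster
    }
    if (!is.null(results$orthology)) {
      tables$ortholog_pairs <- results$orthology$pairs
      if (!is.null(results$orthology$table))
        tables$cross_species <- results$orthology$table
    }
    regions <- list(troughs = results$landscape$troughs)
    for (g in names(results$landscape$hotspots))
      if (nrow(results$landscape$hotspots[[g]]))
        regions[[paste0("hotspots_", g)]] <-
          results$landscape$hotspots[[g]]
    write_results(tables, regions, config$out_dir, config)
  })

  manifest <- list(
    config = config,
    seed = config$seed,
    inputs = lapply(inp[!vapply(inp, is.null, logical(1L))], function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    stage_timings_s = timings,
    outputs = list.files(config$out_dir))
  yaml::write_yaml(manifest, manifest_path)
  class(results) <- "nonself_run"
  invisible(results)
}

#' @rdname run_pipeline
#' @export
cmd_run_all <- run_pipeline

#' @export
print.nonself_run <- function(x, ...) {
  cat("nonself pipeline run\n")
  cat(sprintf("  genes: %d, universe: %d\n",
              nrow(x$versatility),
              x$config$universe_size %||% nrow(x$versatility)))
  for (nm in names(x$sets$pooled))
    cat(sprintf("  %-12s %5d genes\n", nm,
                length(x$sets$pooled[[nm]]$members)))
  coin <- x$landscape$coincidence
  cat(sprintf("  troughs: %d (%d coincident with a hotspot)\n",
              coin$n_troughs, coin$n_coincident))
  invisible(x)
}

#' Render a consolidated report from a pipeline output directory
#'
#' Pure formatting: every number in the report is read from one of the
#' output TSVs written by [run_pipeline()]; nothing is recomputed. Missing
#' output files are listed in the error.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param path Output file (default `report.md` inside `out_dir`).
#' @return Invisibly, the report path.
#' @export
cmd_report <- function(out_dir, path = file.path(out_dir, "report.md")) {
  need <- c("set_sizes.tsv", "specific_fractions.tsv", "overlap_tests.tsv",
            "venn_up.tsv", "venn_down.tsv", "coincidence.tsv",
            "enrichment.tsv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing))
    stopf("incomplete outputs; missing: %s", paste(missing, collapse = ", "))
  rd <- function(f) read_tsv(file.path(out_dir, f))
  fmt_table <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) format(col, digits = 4) else col)
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      apply(df, 1L, function(r)
        paste("|", paste(r, collapse = " | "), "|")))
  }
  lines <- c("# Non-self response analysis report", "",
             "## Response set sizes", "", fmt_table(rd("set_sizes.tsv")), "",
             "## Condition-specific fractions (%)", "",
             fmt_table(rd("specific_fractions.tsv")), "",
             "## Overlap tests", "", fmt_table(rd("overlap_tests.tsv")), "",
             "## Venn regions (up)", "", fmt_table(rd("venn_up.tsv")), "",
             "## Venn regions (down)", "", fmt_table(rd("venn_down.tsv")),
             "", "## Versatility troughs and hotspot coincidence", "",
             fmt_table(rd("coincidence.tsv")), "",
             "## Category enrichment", "", fmt_table(rd("enrichment.tsv")))
  for (extra in c("sm_summary.tsv", "ssp_sweep.tsv", "cross_species.tsv")) {
    f <- file.path(out_dir, extra)
    if (file.exists(f))
      lines <- c(lines, "", paste0("## ", sub(".tsv", "", extra)), "",
                 fmt_table(rd(extra)))
  }
  writeLines(lines, path)
  invisible(path)
}
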