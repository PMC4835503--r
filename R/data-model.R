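# Domain tables, readers and writers shared by all pipeline stages.
#
# All tabular inputs are tab-delimited with a header line; lines starting
# with '#' are comments. Gene coordinates are gene ordinals (rank along the
# chromosome, 1-based), not base pairs: every downstream computation
# ("window of 100 genes") is in gene units. BED export maps closed ordinal
# intervals to 0-based half-open intervals.

read_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

write_tsv <- function(x, path) {
  ok <- tryCatch({
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stopf("%s: missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  invisible(df)
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Validate a gene table
#'
#' Enforces the gene-record invariants: unique gene ids, unique
#' (chromosome, ordinal) pairs, ordinals covering `1..n` without gaps on each
#' chromosome, and protein lengths of at least one residue. Returns the table
#' sorted by (chromosome, ordinal).
#'
#' @param genes Data frame with columns `gene_id`, `chromosome`, `ordinal`,
#'   `protein_length`, `is_secreted`, `categories`.
#' @return The validated, sorted gene table.
#' @export
validate_gene_table <- function(genes) {
  need <- c("gene_id", "chromosome", "ordinal", "protein_length",
            "is_secreted", "categories")
  require_columns(genes, need, "gene table")
  if (anyDuplicated(genes$gene_id))
    stopf("duplicated gene_id: %s",
          genes$gene_id[duplicated(genes$gene_id)][1L])
  key <- paste(genes$chromosome, genes$ordinal)
  if (anyDuplicated(key))
    stopf("duplicate (chromosome, ordinal): %s", key[duplicated(key)][1L])
  for (chr in unique(genes$chromosome)) {
    o <- sort(genes$ordinal[genes$chromosome == chr])
    if (!identical(as.integer(o), seq_along(o)))
      stopf("chromosome %s: ordinals must cover 1..%d with no gaps",
            chr, length(o))
  }
  bad_len <- !is.na(genes$protein_length) & genes$protein_length < 1
  if (any(bad_len))
    stopf("protein_length < 1 for gene %s", genes$gene_id[bad_len][1L])
  genes <- genes[order(genes$chromosome, genes$ordinal), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Read a gene table from TSV or GFF3
#'
#' The TSV dialect carries columns `gene_id`, `chromosome`, `ordinal`,
#' `protein_length`, `is_secreted` and an optional `categories` column of
#' `;`-separated labels (Pfam accessions, GO ids, class tags such as TF, NLR,
#' HK, autophagy, `SM:<k>` secondary-metabolite cluster ids). For GFF3 input
#' (requires the rtracklayer package), `gene` features are taken and ordinals
#' are assigned per chromosome by ascending start coordinate; protein length
#' and secretion status are taken from `protein_length` / `is_secreted`
#' attributes when present and are `NA` otherwise.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"gff3"`.
#' @return A validated gene table (see [validate_gene_table()]).
#' @export
read_gene_table <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv(path)
    require_columns(df, c("gene_id", "chromosome", "ordinal",
                          "protein_length", "is_secreted"), path)
    if (is.null(df$categories)) df$categories <- ""
    genes <- data.frame(
      gene_id = as.character(df$gene_id),
      chromosome = as.character(df$chromosome),
      ordinal = as.integer(df$ordinal),
      protein_length = as.integer(df$protein_length),
      is_secreted = parse_logical(df$is_secreted),
      categories = ifelse(is.na(df$categories), "",
                          as.character(df$categories)),
      stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stopf("reading GFF3 requires the 'rtracklayer' package")
    g <- as.data.frame(rtracklayer::readGFF(path))
    g <- g[g$type == "gene", , drop = FALSE]
    if (nrow(g) == 0L) stopf("%s: no 'gene' features found", path)
    id <- if (!is.null(g$ID) && !all(is.na(g$ID))) g$ID else g$Name
    genes <- data.frame(
      gene_id = as.character(id),
      chromosome = as.character(g$seqid),
      start = as.integer(g$start),
      protein_length =
        if (!is.null(g$protein_length)) as.integer(g$protein_length)
        else NA_integer_,
      is_secreted =
        if (!is.null(g$is_secreted)) parse_logical(g$is_secreted) else NA,
      categories =
        if (!is.null(g$categories)) as.character(g$categories) else "",
      stringsAsFactors = FALSE)
    genes <- genes[order(genes$chromosome, genes$start), , drop = FALSE]
    genes$ordinal <- as.integer(stats::ave(
      genes$start, genes$chromosome,
      FUN = function(x) rank(x, ties.method = "first")))
    genes$start <- NULL
  }
  validate_gene_table(genes)
}

#' @rdname read_gene_table
#' @param genes A validated gene table.
#' @export
write_gene_table <- function(genes, path) {
  write_tsv(genes, path)
}

#' Small-secreted-protein (SSP) gene ids
#'
#' SSP status is derived on the fly, never stored: a gene is an SSP when it is
#' secreted and its protein is shorter than `max_length` amino acids
#' (default 250).
#'
#' @param genes A gene table.
#' @param max_length Length cutoff in amino acids (exclusive).
#' @return Character vector of gene ids.
#' @export
ssp_genes <- function(genes, max_length = 250L) {
  genes$gene_id[genes$is_secreted %in% TRUE &
                !is.na(genes$protein_length) &
                genes$protein_length < max_length]
}

#' Genes annotated with a category label
#'
#' @param genes A gene table.
#' @param label A single category label (exact match against the
#'   `;`-separated `categories` field).
#' @return Character vector of gene ids.
#' @export
category_members <- function(genes, label) {
  cats <- strsplit(genes$categories, ";", fixed = TRUE)
  genes$gene_id[vapply(cats, function(x) label %in% x, logical(1L))]
}

#' Flatten the gene table's categories into a long annotation table
#'
#' @param genes A gene table.
#' @return Data frame with columns `gene_id`, `term` (one row per label).
#' @export
gene_annotations <- function(genes) {
  cats <- strsplit(genes$categories, ";", fixed = TRUE)
  n <- lengths(cats)
  keep <- n > 0L
  out <- data.frame(gene_id = rep(genes$gene_id[keep], n[keep]),
                    term = unlist(cats[keep]), stringsAsFactors = FALSE)
  out[nzchar(out$term), , drop = FALSE]
}

#' Secondary-metabolite cluster membership map
#'
#' @param genes A gene table.
#' @param prefix Label prefix marking cluster membership (default `"SM:"`).
#' @return Named character vector mapping gene id to cluster id.
#' @export
sm_cluster_map <- function(genes, prefix = "SM:") {
  ann <- gene_annotations(genes)
  ann <- ann[startsWith(ann$term, prefix), , drop = FALSE]
  stats::setNames(ann$term, ann$gene_id)
}

#' Read a homolog hit-count table
#'
#' Two columns: `gene_id` and `n_hits`, the number of genus-level homolog
#' hits including the self hit (so `n_hits >= 1` always).
#'
#' @param path Path to the TSV file.
#' @return Named integer vector mapping gene id to hit count.
#' @export
read_hit_counts <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("gene_id", "n_hits"), path)
  if (anyDuplicated(df$gene_id))
    stopf("%s: duplicated gene_id '%s'", path,
          df$gene_id[duplicated(df$gene_id)][1L])
  hits <- as.integer(df$n_hits)
  if (any(is.na(hits) | hits < 1L))
    stopf("%s: n_hits must be an integer >= 1 (self hit always present)", path)
  stats::setNames(hits, as.character(df$gene_id))
}

#' @rdname read_hit_counts
#' @param hits Named integer vector of hit counts.
#' @export
write_hit_counts <- function(hits, path) {
  write_tsv(data.frame(gene_id = names(hits), n_hits = as.integer(hits),
                       stringsAsFactors = FALSE), path)
}

#' Read / write a core-genome membership list
#'
#' One gene id per line (an optional `gene_id` header line is tolerated).
#'
#' @param path Path to the file.
#' @return Character vector of gene ids.
#' @export
read_core_ids <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) && x[1L] == "gene_id") x <- x[-1L]
  unique(x)
}

#' @rdname read_core_ids
#' @param ids Character vector of gene ids.
#' @export
write_core_ids <- function(ids, path) {
  writeLines(c("gene_id", ids), path)
  invisible(path)
}

#' Read a differential-expression table for one condition
#'
#' Columns `gene_id`, `log2fc` (log2 fold change versus control) and
#' `p_value` are required; one row per gene. Non-numeric values and p-values
#' outside `[0, 1]` are rejected with the offending line number.
#'
#' @param path Path to the TSV file.
#' @param condition Condition label attached to every record
#'   (e.g. `"VsSf2h"`).
#' @return Data frame with columns `gene_id`, `condition`, `log2fc`,
#'   `p_value`.
#' @export
read_expression_table <- function(path, condition) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*#", raw) & nzchar(trimws(raw)))
  if (length(keep) < 1L) stopf("%s: empty file", path)
  df <- utils::read.delim(text = paste(raw[keep], collapse = "\n"),
                          sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  require_columns(df, c("gene_id", "log2fc", "p_value"), path)
  line_of <- function(i) keep[i + 1L]  # data row i sits after the header line
  fc <- suppressWarnings(as.numeric(df$log2fc))
  if (anyNA(fc))
    stopf("%s: non-numeric log2fc at line %d", path,
          line_of(which(is.na(fc))[1L]))
  p <- suppressWarnings(as.numeric(df$p_value))
  bad <- is.na(p) | p < 0 | p > 1
  if (any(bad))
    stopf("%s: p_value outside [0, 1] at line %d", path,
          line_of(which(bad)[1L]))
  if (anyDuplicated(df$gene_id))
    stopf("%s: duplicated gene_id '%s'", path,
          df$gene_id[duplicated(df$gene_id)][1L])
  data.frame(gene_id = df$gene_id, condition = condition,
             log2fc = fc, p_value = p, stringsAsFactors = FALSE)
}

#' @rdname read_expression_table
#' @param records Expression record data frame.
#' @export
write_expression_table <- function(records, path) {
  write_tsv(records[, c("gene_id", "log2fc", "p_value")], path)
}

#' Read a directed pairwise similarity table
#'
#' BLAST outfmt-6-like TSV with columns `qseqid`, `sseqid`, `bitscore` and
#' optionally `evalue`. At most one record per (query, subject) pair.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `query_id`, `subject_id`, `score`,
#'   `e_value` (`NA` when absent from the input).
#' @export
read_similarity_table <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("qseqid", "sseqid", "bitscore"), path)
  score <- as.numeric(df$bitscore)
  if (anyNA(score) || any(score < 0))
    stopf("%s: bitscore must be numeric and >= 0", path)
  key <- paste(df$qseqid, df$sseqid)
  if (anyDuplicated(key))
    stopf("%s: duplicate (query, subject) record: %s", path,
          key[duplicated(key)][1L])
  data.frame(query_id = as.character(df$qseqid),
             subject_id = as.character(df$sseqid),
             score = score,
             e_value = if (!is.null(df$evalue)) as.numeric(df$evalue)
                       else NA_real_,
             stringsAsFactors = FALSE)
}

#' @rdname read_similarity_table
#' @param tab Similarity table data frame.
#' @export
write_similarity_table <- function(tab, path) {
  out <- data.frame(qseqid = tab$query_id, sseqid = tab$subject_id,
                    bitscore = tab$score, evalue = tab$e_value,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

# ---- regions ---------------------------------------------------------------

#' Convert called regions to BED on gene-ordinal coordinates
#'
#' Regions are closed 1-based ordinal intervals internally; BED output is
#' 0-based half-open, so a closed interval `[5, 9]` becomes `start 4, end 9`.
#'
#' @param regions Region data frame (columns `chromosome`, `start`, `end`,
#'   and optionally `label`, `kind`).
#' @return Data frame with BED columns `chrom`, `start`, `end`, `name`.
#' @export
regions_to_bed <- function(regions) {
  name <- if (!is.null(regions$label)) regions$label
          else if (!is.null(regions$kind)) regions$kind
          else rep(".", nrow(regions))
  data.frame(chrom = regions$chromosome,
             start = regions$start - 1L,
             end = regions$end,
             name = name, stringsAsFactors = FALSE)
}

#' @rdname regions_to_bed
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# gene-ordinal coordinates: 0-based, half-open",
                   "(ordinal k spans [k-1, k))"), con)
  if (nrow(regions)) {
    bed <- regions_to_bed(regions)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read / write a response set
#'
#' The TSV carries the set's thresholds and provenance as `# key=value`
#' comment lines followed by a one-column member list, so that a
#' write-then-read round trip is the identity on membership and metadata.
#'
#' @param set A [response_set()].
#' @param path File path.
#' @return `read_response_set()` returns a [response_set()].
#' @export
write_response_set <- function(set, path) {
  stopifnot(inherits(set, "response_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label=%s", set$label),
               sprintf("# direction=%s", set$direction),
               sprintf("# min_abs_log2fc=%.10g", set$min_abs_log2fc),
               sprintf("# max_p=%.10g", set$max_p),
               "gene_id",
               set$members), con)
  invisible(path)
}

#' @rdname write_response_set
#' @export
read_response_set <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readLines(path)
  meta_lines <- grep("^# *[a-z0-9_]+=", raw, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^# *", "", m)
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  body <- raw[!startsWith(raw, "#")]
  body <- body[nzchar(trimws(body))]
  if (length(body) && body[1L] == "gene_id") body <- body[-1L]
  response_set(members = body,
               label = meta$label %||% basename(path),
               direction = meta$direction %||% "up",
               min_abs_log2fc = as.numeric(meta$min_abs_log2fc %||% NA),
               max_p = as.numeric(meta$max_p %||% NA))
}

#' Write result tables, regions and a run log to an output directory
#'
#' @param tables Named list of data frames, written as `<name>.tsv`.
#' @param regions Named list of region data frames, each written as both
#'   `<name>.tsv` and `<name>.bed`.
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration list echoed into `run.log`.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(tables = list(), regions = list(), out_dir,
                          config = NULL) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory: %s", out_dir)
  written <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], f)
    written <- c(written, f)
  }
  for (nm in names(regions)) {
    ft <- file.path(out_dir, paste0(nm, ".tsv"))
    fb <- file.path(out_dir, paste0(nm, ".bed"))
    write_tsv(regions[[nm]], ft)
    write_regions_bed(regions[[nm]], fb)
    written <- c(written, ft, fb)
  }
  log <- file.path(out_dir, "run.log")
  writeLines(c(sprintf("# nonself %s | %s | %s",
                       as.character(utils::packageVersion("nonself")),
                       R.version.string, format(Sys.time())),
               if (!is.null(config)) c("# config:",
                                       strsplit(yaml::as.yaml(config),
                                                "\n")[[1L]])),
             log)
  invisible(c(written, log))
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' Central place for the analysis thresholds: `min_abs_log2fc` (default 2,
#' i.e. log2 fold change strictly above 2), `max_p` (default 0.01, strict),
#' the 100-gene sliding window with step 1, 10 versatility bins, the 5-gene
#' minimum region run, the 100-gene telomere margin, the 250-aa SSP cutoff
#' and the `c(2, 4, 6, 8)` fold-change sweep grid.
#'
#' @param seed Integer seed recorded in the configuration (required by the
#'   simulation entry points).
#' @return A named list.
#' @export
default_run_config <- function(seed = NULL) {
  list(
    seed = seed,
    min_abs_log2fc = 2,
    max_p = 0.01,
    window = 100L,
    step = 1L,
    n_bins = 10L,
    min_run = 5L,
    telomere_k = 100L,
    ssp_max_length = 250L,
    sweep_thresholds = c(2, 4, 6, 8),
    universe_size = NULL,
    pooling = list(VsSf = c("VsSf2h", "VsSf6h"),
                   VsSm = c("VsSm2h", "VsSm6h"),
                   VI = "VI"),
    inputs = list(),
    out_dir = NULL)
}

#' Read a YAML run configuration, merged over the defaults
#'
#' @param path Path to a YAML file; keys override [default_run_config()].
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(default_run_config(), yaml::read_yaml(path))
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A configuration list.
#' @export
validate_run_config <- function(config) {
  if (config$min_abs_log2fc <= 0 || config$max_p <= 0 ||
      any(config$sweep_thresholds <= 0))
    stopf("all thresholds must be > 0")
  if (config$window < 2L) stopf("window must be >= 2")
  if (config$n_bins < 2L) stopf("n_bins must be >= 2")
  config
}
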