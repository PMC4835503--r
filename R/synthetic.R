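# Seeded synthetic-data generator.
#
# Emulates the statistical structure of a bacterial-fungal interaction
# transcriptome study: a ~10,635-gene genome on 7 chromosomes with a 3,297
# gene conserved core, 640 orphans and 6,698 genes of intermediate
# versatility; 19 implanted low-versatility regions (8 telomeric), 13 of
# which are also up-regulation hotspots; two correlated bacterial response
# conditions with a magnitude bias; a partially overlapping vegetative-
# incompatibility (VI) response; category labels (TF, NLR, HK, autophagy,
# SSP via secretion + length, 35 secondary-metabolite clusters of 470 genes);
# and a second proteome with a known ortholog map for reciprocal-best-hit
# recovery. Every output is a deterministic function of the master seed;
# each table draws from its own labelled RNG stream (see [stream_seed()]).

#' Default chromosome sizes (in genes)
#'
#' @param n_genes Total gene count (default 10,635).
#' @param n_chrom Number of chromosomes (default 7).
#' @return Named integer vector of per-chromosome gene counts.
#' @export
default_chromosome_sizes <- function(n_genes = 10635L, n_chrom = 7L) {
  prop <- if (n_chrom == 7L) c(0.17, 0.16, 0.15, 0.14, 0.13, 0.13, 0.12)
          else rep(1 / n_chrom, n_chrom)
  sizes <- floor(prop / sum(prop) * n_genes)
  sizes[1L] <- sizes[1L] + (n_genes - sum(sizes))
  stats::setNames(as.integer(sizes), as.character(seq_len(n_chrom)))
}

#' Default implanted low-versatility region layout
#'
#' Nineteen regions of `region_len` genes spread over the chromosomes,
#' `n_telomeric` of them placed at chromosome ends and `n_hotspot` of them
#' designated as up-regulation hotspots. In the default layout the six
#' non-hotspot (cold) regions are telomeric and sit on chromosomes that also
#' carry at least two designated regions, so that both the trough and the
#' hotspot thresholds (per-chromosome mean -/+ sd) are anchored by real
#' signal; placement is deterministic given the sizes.
#'
#' @param chrom_sizes Named integer vector from
#'   [default_chromosome_sizes()].
#' @param n_regions Number of regions (default 19).
#' @param region_len Region length in genes (default 60).
#' @param n_telomeric How many regions sit at chromosome ends (default 8).
#' @param n_hotspot How many regions are up-regulation hotspots
#'   (default 13).
#' @return Data frame with columns `chromosome`, `start`, `end`,
#'   `telomeric`, `hotspot`.
#' @export
default_region_spec <- function(chrom_sizes = default_chromosome_sizes(),
                                n_regions = 19L, region_len = 60L,
                                n_telomeric = 8L, n_hotspot = 13L) {
  n_chrom <- length(chrom_sizes)
  row <- function(chr, s, telo, hot)
    data.frame(chromosome = chr, start = as.integer(s),
               end = as.integer(s + region_len - 1L), telomeric = telo,
               hotspot = hot, stringsAsFactors = FALSE)
  if (n_regions == 19L && n_telomeric == 8L && n_hotspot == 13L &&
      n_chrom >= 7L) {
    # study layout. Two anchoring requirements drive the placement: a
    # chromosome's trough threshold (mean - sd of window index means) needs
    # enough low-index window mass, which an interior region supplies about
    # three times better than a telomeric one; and a chromosome hosting a
    # non-hotspot (cold) region needs at least two designated regions so
    # its hotspot threshold (mean + sd of window up-fractions) is anchored
    # by real signal, not noise.
    nm <- names(chrom_sizes); L <- chrom_sizes
    rows <- list(
      row(nm[1L], 1L, TRUE, FALSE),                     # cold telomere
      row(nm[1L], round(L[1L] * 0.35), FALSE, TRUE),
      row(nm[1L], round(L[1L] * 0.68), FALSE, TRUE),
      row(nm[1L], L[1L] - region_len + 1L, TRUE, FALSE) # cold telomere
    )
    for (ci in 2:4) rows <- c(rows, list(
      row(nm[ci], 1L, TRUE, FALSE),
      row(nm[ci], round(L[ci] * 0.40), FALSE, TRUE),
      row(nm[ci], round(L[ci] * 0.72), FALSE, TRUE)))
    rows <- c(rows, list(
      row(nm[5L], 1L, TRUE, FALSE),
      row(nm[5L], round(L[5L] * 0.50), FALSE, TRUE),
      row(nm[5L], L[5L] - region_len + 1L, TRUE, TRUE),
      row(nm[6L], 1L, TRUE, TRUE),
      row(nm[6L], round(L[6L] * 0.55), FALSE, TRUE),
      row(nm[7L], round(L[7L] * 0.50), FALSE, TRUE)))
    spec <- do.call(rbind, rows)
    rownames(spec) <- NULL
    return(spec)
  }
  # generic fallback for non-default layouts: regions round-robin over
  # chromosomes, telomeric first-of-chromosome, hotspots interior-first
  counts <- tabulate(rep(seq_len(n_chrom), length.out = n_regions),
                     nbins = n_chrom)
  rows <- list()
  telo_left <- n_telomeric
  for (ci in seq_len(n_chrom)) {
    k <- counts[ci]
    L <- chrom_sizes[ci]
    chr <- names(chrom_sizes)[ci]
    for (j in seq_len(k)) {
      telo <- FALSE
      if (j == 1L && telo_left > 0L) {          # start telomere
        s <- 1L; telo <- TRUE; telo_left <- telo_left - 1L
      } else if (j == k && k > 1L && telo_left > n_chrom - ci) {
        s <- L - region_len + 1L                # end telomere
        telo <- TRUE; telo_left <- telo_left - 1L
      } else {
        s <- as.integer(round(L * j / (k + 1L)))
      }
      rows[[length(rows) + 1L]] <- row(chr, s, telo, FALSE)
    }
  }
  spec <- do.call(rbind, rows)
  prio <- c(which(!spec$telomeric), which(spec$telomeric))
  spec$hotspot[prio[seq_len(min(n_hotspot, nrow(spec)))]] <- TRUE
  rownames(spec) <- NULL
  spec
}

# logical vector over the gene table: inside any region of the spec?
genes_in_regions <- function(genes, regions) {
  inside <- rep(FALSE, nrow(genes))
  for (i in seq_len(NROW(regions))) {
    inside <- inside | (genes$chromosome == regions$chromosome[i] &
                        genes$ordinal >= regions$start[i] &
                        genes$ordinal <= regions$end[i])
  }
  inside
}

#' Generate a synthetic genome with hit counts and category labels
#'
#' Orphans receive a single (self) hit; core genes draw hit counts from a
#' high range (150-400); the remaining genes draw from a broad log-uniform
#' range (2-400), except inside the implanted regions where counts come from
#' the low tail (2-5), creating the low-versatility clusters. Core genes are
#' placed outside the implanted regions and about half the region genes are
#' orphans, so the regions are troughs of the versatility index. Category
#' labels (TF, NLR, HK, autophagy) are assigned at the requested counts;
#' secondary-metabolite clusters are contiguous blocks totalling
#' `n_sm_genes` genes; `n_secreted` genes are flagged secreted with shorter
#' length draws so that a realistic SSP complement (< 250 aa) emerges.
#'
#' @param n_genes,n_chrom,n_core,n_orphan Genome composition (defaults
#'   10,635 / 7 / 3,297 / 640, leaving 6,698 genes of intermediate
#'   versatility).
#' @param region_spec Data frame of implanted regions
#'   (default [default_region_spec()]); `NULL` for none.
#' @param category_counts Named list of label counts
#'   (default 216 TF, 77 NLR, 21 HK, 18 autophagy).
#' @param n_sm_clusters,n_sm_genes Secondary-metabolite layout (35 clusters,
#'   470 genes).
#' @param n_secreted Number of secreted proteins (default 801).
#' @param seed Integer master seed (required).
#' @return List with `genes` (gene table), `hits` (named integer vector),
#'   `core_ids`, and `truth` (generator parameters plus implanted structure;
#'   sufficient to recompute every expected summary).
#' @export
generate_genome <- function(n_genes = 10635L, n_chrom = 7L,
                            n_core = 3297L, n_orphan = 640L,
                            region_spec = NULL,
                            category_counts = list(TF = 216L, NLR = 77L,
                                                   HK = 21L,
                                                   autophagy = 18L),
                            n_sm_clusters = 35L, n_sm_genes = 470L,
                            n_secreted = 801L, seed) {
  if (missing(seed) || is.null(seed)) stopf("an explicit seed is required")
  if (n_core + n_orphan > n_genes)
    stopf("n_core + n_orphan exceeds n_genes")
  chrom_sizes <- default_chromosome_sizes(n_genes, n_chrom)
  if (is.null(region_spec) && n_genes >= 8000L && n_chrom == 7L)
    region_spec <- default_region_spec(chrom_sizes)
  if (!is.null(region_spec)) {
    bad <- region_spec$start < 1L |
      region_spec$end > chrom_sizes[region_spec$chromosome]
    if (any(bad)) stopf("region_spec does not fit on its chromosome")
    if (is.null(region_spec$hotspot)) region_spec$hotspot <- FALSE
    if (is.null(region_spec$telomeric)) region_spec$telomeric <- FALSE
  }
  with_seed(stream_seed(seed, "genome"), {
    chrom <- rep(names(chrom_sizes), chrom_sizes)
    ordinal <- unlist(lapply(chrom_sizes, seq_len), use.names = FALSE)
    gene_id <- sprintf("Pa_%s_%05d", chrom, ordinal)
    genes <- data.frame(gene_id = gene_id, chromosome = chrom,
                        ordinal = ordinal, stringsAsFactors = FALSE)
    in_region <- if (is.null(region_spec)) rep(FALSE, n_genes)
                 else genes_in_regions(genes, region_spec)

    # classes: core outside regions, orphans preferentially inside
    outside <- which(!in_region)
    if (length(outside) < n_core)
      stopf("not enough genes outside regions for %d core genes", n_core)
    core_idx <- sort(pick(outside, n_core))
    pool_in <- setdiff(which(in_region), core_idx)
    n_orph_in <- min(round(0.5 * length(pool_in)), n_orphan)
    orph_idx <- pick(pool_in, n_orph_in)
    pool_out <- setdiff(seq_len(n_genes), c(core_idx, orph_idx,
                                            which(in_region)))
    orph_idx <- sort(c(orph_idx, pick(pool_out, n_orphan - n_orph_in)))
    rem_idx <- setdiff(seq_len(n_genes), c(core_idx, orph_idx))

    hits <- integer(n_genes)
    hits[orph_idx] <- 1L
    hits[core_idx] <- sample(150:400, length(core_idx), replace = TRUE)
    rem_in <- intersect(rem_idx, which(in_region))
    rem_out <- setdiff(rem_idx, rem_in)
    hits[rem_in] <- sample(2:5, length(rem_in), replace = TRUE)
    hits[rem_out] <- pmax(2L, as.integer(round(exp(
      stats::runif(length(rem_out), log(2), log(400))))))

    # protein lengths and secretion; secreted proteins draw shorter lengths
    protein_length <- pmax(50L, as.integer(round(
      stats::rlnorm(n_genes, log(420), 0.45))))
    sec_idx <- pick(seq_len(n_genes), min(n_secreted, n_genes))
    protein_length[sec_idx] <- pmax(50L, as.integer(round(
      stats::rlnorm(length(sec_idx), log(300), 0.45))))
    is_secreted <- rep(FALSE, n_genes)
    is_secreted[sec_idx] <- TRUE

    # category labels at exact requested counts
    cats <- vector("list", n_genes)
    add_label <- function(idx, label) {
      for (i in idx) cats[[i]] <<- c(cats[[i]], label)
    }
    non_core <- setdiff(seq_len(n_genes), core_idx)
    for (lab in names(category_counts)) {
      k <- category_counts[[lab]]
      pool <- if (lab == "NLR") non_core else seq_len(n_genes)
      add_label(pick(pool, min(k, length(pool))), lab)
    }

    # contiguous secondary-metabolite clusters, avoiding each other and a
    # 200-gene margin around the implanted regions: clusters are up-biased
    # in the expression stage, so keeping them a window-plus-edge away from
    # the implanted layout leaves that layout identifiable in the landscape
    sm_sizes <- rep(n_sm_genes %/% n_sm_clusters, n_sm_clusters)
    extra <- n_sm_genes %% n_sm_clusters
    if (extra > 0L) sm_sizes[seq_len(extra)] <- sm_sizes[seq_len(extra)] + 1L
    taken <- if (is.null(region_spec)) in_region else {
      grown <- region_spec
      grown$start <- pmax(1L, grown$start - 200L)
      grown$end <- grown$end + 200L
      grown$end <- pmin(grown$end, chrom_sizes[grown$chromosome])
      genes_in_regions(genes, grown)
    }
    sm_regions <- list()
    for (ki in seq_len(n_sm_clusters)) {
      size <- sm_sizes[ki]
      placed <- FALSE
      for (try in 1:500) {
        chr <- sample(names(chrom_sizes), 1L)
        L <- chrom_sizes[[chr]]
        if (L < size + 2L) next
        s <- sample.int(L - size + 1L, 1L)
        idx <- which(genes$chromosome == chr & genes$ordinal >= s &
                     genes$ordinal <= s + size - 1L)
        if (any(taken[idx])) next
        taken[idx] <- TRUE
        add_label(idx, sprintf("SM:%02d", ki))
        sm_regions[[ki]] <- data.frame(cluster = sprintf("SM:%02d", ki),
                                       chromosome = chr, start = s,
                                       end = s + size - 1L,
                                       stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stopf("could not place secondary-metabolite cluster %d", ki)
    }

    genes$protein_length <- protein_length
    genes$is_secreted <- is_secreted
    genes$categories <- vapply(cats, function(x)
      paste(x, collapse = ";"), character(1L))
    genes <- validate_gene_table(genes)
    hits <- stats::setNames(hits, gene_id)[genes$gene_id]

    truth <- list(
      params = list(n_genes = n_genes, n_chrom = n_chrom, n_core = n_core,
                    n_orphan = n_orphan,
                    category_counts = category_counts,
                    n_sm_clusters = n_sm_clusters, n_sm_genes = n_sm_genes,
                    n_secreted = n_secreted, seed = seed),
      chrom_sizes = chrom_sizes,
      regions = region_spec,
      sm_regions = if (length(sm_regions)) do.call(rbind, sm_regions)
                   else NULL,
      core_ids = genes$gene_id[genes$gene_id %in% gene_id[core_idx]],
      orphan_ids = genes$gene_id[genes$gene_id %in% gene_id[orph_idx]])
    list(genes = genes, hits = hits, core_ids = truth$core_ids,
         truth = truth)
  })
}

#' Default expression-generator parameters
#'
#' The regulated-set sizes, specific fractions and time-point splits mirror
#' the study conditions: pooled bacterial up sets of about 17% of the genome
#' with 21% of the surviving-interaction (VsSf-like) up set specific to it,
#' a smaller second condition (VsSm-like) whose own specific genes amount to
#' ~11% of the first set, a VI response of similar size drawn preferentially
#' (odds 4) from the bacterial union with the preference decaying for
#' strongly regulated genes, a 1.3-fold magnitude bias of VsSf over VsSm on
#' shared genes, and regulated effect sizes of `2 + Gamma(4, 0.6)` on the
#' log2 scale capped at 11.5.
#'
#' @return Named list of parameters accepted by [generate_expression()].
#' @export
default_expression_params <- function() {
  list(
    base_up_rate = 1847 / 10635, base_down_rate = 1882 / 10635,
    sf_specific_up = 0.21, sf_specific_down = 0.22,
    sm_only_up_frac = 211 / 1847, sm_only_down_frac = 153 / 1882,
    vi_up_rate = NA_real_, vi_down_rate = NA_real_,  # NA: scale with base
    vi_overlap_odds = 4, vi_mag_decay = 0.25,
    vi_hotspot_rate = 0.85, n_vi_specific_regions = 2L,
    magnitude_ratio = 1.3, mag_sigma = 0.10, time_sigma = 0.15,
    effect_shape = 4, effect_scale = 0.6, max_abs_log2fc = 11.5,
    hotspot_up_rate = 0.85,
    time_split_sf = c(both = 710 / 1847, early = 522 / 1847,
                      late = 615 / 1847),
    time_split_sm = c(both = 712 / 1668, early = 379 / 1668,
                      late = 577 / 1668),
    up_weight_decay = 0.04, down_weight_growth = 0.12,
    vi_weight_decay = 0.04,
    category_up_odds = c(SSP = 1.3, SM = 2.2, HK = 2.5, autophagy = 2.5,
                         TF = 1.3, NLR = 0.4),
    category_vi_up_odds = c(NLR = 3, SM = 2.2, HK = 2.5, autophagy = 2.5),
    tf_down_odds = 0.4, ssp_mag_boost = 1.6,
    null_sd = 0.4, reg_p_max = 5e-3)
}

# continuous versatility proxy in [0, 11]: 0 orphans, 11 core, remaining
# genes spread by hit-count rank (avoids requiring >= n_bins genes)
versatility_proxy <- function(hits, core_ids) {
  parts <- classify_genes(hits, core_ids)
  v <- stats::setNames(numeric(length(hits)), names(hits))
  v[parts$core] <- 11
  r <- parts$remaining
  if (length(r))
    v[r] <- 0.5 + 10 * rank(hits[r], ties.method = "average") /
      (length(r) + 1L)
  v
}

#' Generate synthetic expression tables for the five conditions
#'
#' Regulated genes are drawn with up-selection probability increasing as the
#' versatility proxy decreases and down-selection enriched in core genes;
#' the second bacterial condition shares `1 - sf_specific_up` of the first
#' condition's regulated genes plus its own specific genes; the VI sets are
#' drawn with configurable odds in favour of bacterial-regulated genes,
#' decaying with the bacterial effect size (so the most strongly regulated
#' bacterial genes overlap VI least); genes inside the designated hotspot
#' regions are up-regulated at `hotspot_up_rate` in the bacterial
#' conditions. Regulated log2 fold changes are `direction * (2 + Gamma)`
#' (always beyond the |log2FC| = 2 threshold) capped at `max_abs_log2fc`,
#' with the VsSf magnitude scaled by `magnitude_ratio` over VsSm on shared
#' genes; regulated p-values are below `reg_p_max`, null p-values uniform,
#' null log2FC ~ N(0, `null_sd`). Each condition's pooled set is split over
#' the two time points by `time_split_*`.
#'
#' @param genome Result of [generate_genome()].
#' @param params Named list overriding [default_expression_params()].
#' @param seed Integer master seed (required).
#' @return List with `records` (named list of five expression record data
#'   frames: VsSf2h, VsSf6h, VsSm2h, VsSm6h, VI) and `truth` (the regulated
#'   gene sets per condition and direction, pooled and per time point, plus
#'   the parameters).
#' @export
generate_expression <- function(genome, params = list(), seed) {
  if (missing(seed) || is.null(seed)) stopf("an explicit seed is required")
  p <- utils::modifyList(default_expression_params(), params)
  # VI set sizes track the bacterial rates unless given explicitly
  if (is.na(p$vi_up_rate)) p$vi_up_rate <- p$base_up_rate * (1913 / 1847)
  if (is.na(p$vi_down_rate))
    p$vi_down_rate <- p$base_down_rate * (1923 / 1882)
  rates <- c(p$base_up_rate, p$base_down_rate, p$sf_specific_up,
             p$sf_specific_down, p$sm_only_up_frac, p$sm_only_down_frac,
             p$vi_up_rate, p$vi_down_rate, p$hotspot_up_rate)
  if (any(rates < 0 | rates > 1))
    stopf("rates and fractions must lie in [0, 1]")
  if (p$magnitude_ratio <= 0) stopf("magnitude_ratio must be > 0")
  genes <- genome$genes
  ids <- genes$gene_id
  n <- length(ids)
  v <- versatility_proxy(genome$hits, genome$core_ids)[ids]
  cat_list <- strsplit(genes$categories, ";", fixed = TRUE)
  has_cat <- function(lab) vapply(cat_list, function(x)
    any(startsWith(x, lab)), logical(1L))
  is_sm <- has_cat("SM:")
  is_ssp <- ids %in% ssp_genes(genes)
  odds_vec <- function(odds_table) {
    w <- rep(1, n)
    for (lab in names(odds_table)) {
      m <- switch(lab, SSP = is_ssp, SM = is_sm, has_cat(lab))
      w[m] <- w[m] * odds_table[[lab]]
    }
    w
  }
  hot <- if (!is.null(genome$truth$regions) &&
             any(genome$truth$regions$hotspot)) {
    genes_in_regions(genes,
                     genome$truth$regions[genome$truth$regions$hotspot, ,
                                          drop = FALSE])
  } else rep(FALSE, n)
  # non-designated implanted regions are expression-neutral by design:
  # their genes draw at the genome-average rate, so the designed coincidence
  # count (hotspot regions only) is the ground truth the pipeline recovers
  cold <- if (!is.null(genome$truth$regions) &&
              any(!genome$truth$regions$hotspot)) {
    genes_in_regions(genes,
                     genome$truth$regions[!genome$truth$regions$hotspot, ,
                                          drop = FALSE])
  } else rep(FALSE, n)

  sets <- with_seed(stream_seed(seed, "expression/sets"), {
    w_up <- exp(-p$up_weight_decay * v) * odds_vec(p$category_up_odds)
    if (any(cold)) w_up[cold] <- mean(w_up[!cold & !hot])
    w_down <- exp(p$down_weight_growth * v)
    w_down[has_cat("TF")] <- w_down[has_cat("TF")] * p$tf_down_odds

    n_up_sf <- round(p$base_up_rate * n)
    n_down_sf <- round(p$base_down_rate * n)

    # bacterial up (VsSf): forced hotspot genes + versatility-weighted rest
    forced <- which(hot & stats::runif(n) < p$hotspot_up_rate)
    forced <- forced[seq_len(min(length(forced), n_up_sf))]
    rest_pool <- setdiff(seq_len(n), forced)
    sf_up <- c(forced, pick(rest_pool, n_up_sf - length(forced),
                            prob = w_up[rest_pool]))
    pool <- setdiff(seq_len(n), sf_up)
    sf_down <- pick(pool, min(n_down_sf, length(pool)),
                    prob = w_down[pool])

    shared_up <- pick(sf_up, round((1 - p$sf_specific_up) * length(sf_up)))
    shared_down <- pick(sf_down,
                        round((1 - p$sf_specific_down) * length(sf_down)))
    pool <- setdiff(seq_len(n), c(sf_up, sf_down))
    sm_only_up <- pick(pool, min(round(p$sm_only_up_frac * length(sf_up)),
                                 length(pool)), prob = w_up[pool])
    pool <- setdiff(pool, sm_only_up)
    sm_only_down <- pick(pool,
                         min(round(p$sm_only_down_frac * length(sf_down)),
                             length(pool)), prob = w_down[pool])
    sm_up <- c(shared_up, sm_only_up)
    sm_down <- c(shared_down, sm_only_down)
    list(sf_up = sf_up, sf_down = sf_down, sm_up = sm_up, sm_down = sm_down,
         shared_up = shared_up, shared_down = shared_down)
  })

  mags <- with_seed(stream_seed(seed, "expression/magnitudes"), {
    gmag <- function(k) 2 + stats::rgamma(k, shape = p$effect_shape,
                                          scale = p$effect_scale)
    cap <- function(m) pmin(m, p$max_abs_log2fc)
    m_sm <- stats::setNames(rep(NA_real_, n), ids)
    m_sf <- m_sm
    sh <- sets$shared_up
    base <- gmag(length(sh))
    m_sm[sh] <- cap(base)
    m_sf[sh] <- cap(2 + (base - 2) * p$magnitude_ratio *
                      exp(stats::rnorm(length(sh), 0, p$mag_sigma)))
    shd <- sets$shared_down
    based <- gmag(length(shd))
    m_sm[shd] <- cap(based)
    m_sf[shd] <- cap(2 + (based - 2) * p$magnitude_ratio *
                       exp(stats::rnorm(length(shd), 0, p$mag_sigma)))
    only <- setdiff(c(sets$sf_up, sets$sf_down), c(sh, shd))
    m_sf[only] <- cap(gmag(length(only)))
    onlym <- setdiff(c(sets$sm_up, sets$sm_down), c(sh, shd))
    m_sm[onlym] <- cap(gmag(length(onlym)))
    # SSP effect sizes skew high so enrichment grows with the FC threshold
    boost <- which(is_ssp & !is.na(m_sf))
    m_sf[boost] <- cap(2 + (m_sf[boost] - 2) * p$ssp_mag_boost)
    boost <- which(is_ssp & !is.na(m_sm))
    m_sm[boost] <- cap(2 + (m_sm[boost] - 2) * p$ssp_mag_boost)
    list(sf = m_sf, sm = m_sm)
  })

  # VI's own spatial structure: the designated regions (dense in
  # bacterial-up genes that VI shares) plus VI-specific regions placed at a
  # fixed fraction of the first chromosomes, clear of the implanted troughs
  vi_specific_regions <- NULL
  if (!is.null(genome$truth$regions)) {
    cs <- genome$truth$chrom_sizes
    k <- min(p$n_vi_specific_regions, length(cs))
    if (k > 0L) {
      len <- 60L
      vi_specific_regions <- data.frame(
        chromosome = names(cs)[seq_len(k)],
        start = as.integer(round(0.30 * cs[seq_len(k)])),
        stringsAsFactors = FALSE)
      vi_specific_regions$end <- vi_specific_regions$start + len - 1L
    }
  }
  vi_hot <- hot
  if (!is.null(vi_specific_regions))
    vi_hot <- vi_hot | genes_in_regions(genes, vi_specific_regions)

  vi <- with_seed(stream_seed(seed, "expression/vi"), {
    w_vi_up <- exp(-p$vi_weight_decay * v) *
      odds_vec(p$category_vi_up_odds)
    if (any(cold)) w_vi_up[cold] <- mean(w_vi_up[!cold & !vi_hot])
    bact_up <- union(sets$sf_up, sets$sm_up)
    # overlap odds decay with the bacterial effect size: the most strongly
    # regulated bacterial genes are the least shared with VI
    msf <- mags$sf; msf[is.na(msf)] <- 2
    odds <- rep(1, n)
    odds[bact_up] <- p$vi_overlap_odds *
      exp(-p$vi_mag_decay * (msf[bact_up] - 2))
    n_vi_up <- round(p$vi_up_rate * n)
    forced <- which(vi_hot & stats::runif(n) < p$vi_hotspot_rate)
    forced <- forced[seq_len(min(length(forced), n_vi_up))]
    rest <- setdiff(seq_len(n), forced)
    vi_up <- c(forced, pick(rest, n_vi_up - length(forced),
                            prob = (w_vi_up * odds)[rest]))
    w_vi_down <- exp(p$down_weight_growth * v)
    bact_down <- union(sets$sf_down, sets$sm_down)
    oddsd <- rep(1, n)
    oddsd[bact_down] <- p$vi_overlap_odds
    pool <- setdiff(seq_len(n), vi_up)
    vi_down <- pick(pool, min(round(p$vi_down_rate * n), length(pool)),
                    prob = (w_vi_down * oddsd)[pool])
    m_vi <- stats::setNames(rep(NA_real_, n), ids)
    m_vi[c(vi_up, vi_down)] <- pmin(
      2 + stats::rgamma(length(vi_up) + length(vi_down),
                        shape = p$effect_shape, scale = p$effect_scale),
      p$max_abs_log2fc)
    list(up = vi_up, down = vi_down, mag = m_vi)
  })

  # split a pooled index set over two time points
  split_time <- function(idx, fr) {
    grp <- sample(c("both", "early", "late"), length(idx), replace = TRUE,
                  prob = fr)
    list(early = idx[grp != "late"], late = idx[grp != "early"])
  }
  one_table <- function(cond, up_idx, down_idx, mag) {
    log2fc <- stats::rnorm(n, 0, p$null_sd)
    pv <- stats::runif(n)
    reg <- c(up_idx, down_idx)
    tmag <- pmin(2 + (mag[reg] - 2) *
                   exp(stats::rnorm(length(reg), 0, p$time_sigma)),
                 p$max_abs_log2fc)
    sign <- rep(c(1, -1), c(length(up_idx), length(down_idx)))
    log2fc[reg] <- sign * tmag
    pv[reg] <- 10^stats::runif(length(reg), -12, log10(p$reg_p_max))
    data.frame(gene_id = ids, condition = cond, log2fc = log2fc,
               p_value = pv, stringsAsFactors = FALSE)
  }

  records <- list()
  tp <- with_seed(stream_seed(seed, "expression/timepoints"), {
    list(sf_up = split_time(sets$sf_up, p$time_split_sf),
         sf_down = split_time(sets$sf_down, p$time_split_sf),
         sm_up = split_time(sets$sm_up, p$time_split_sm),
         sm_down = split_time(sets$sm_down, p$time_split_sm))
  })
  records$VsSf2h <- with_seed(stream_seed(seed, "table/VsSf2h"),
    one_table("VsSf2h", tp$sf_up$early, tp$sf_down$early, mags$sf))
  records$VsSf6h <- with_seed(stream_seed(seed, "table/VsSf6h"),
    one_table("VsSf6h", tp$sf_up$late, tp$sf_down$late, mags$sf))
  records$VsSm2h <- with_seed(stream_seed(seed, "table/VsSm2h"),
    one_table("VsSm2h", tp$sm_up$early, tp$sm_down$early, mags$sm))
  records$VsSm6h <- with_seed(stream_seed(seed, "table/VsSm6h"),
    one_table("VsSm6h", tp$sm_up$late, tp$sm_down$late, mags$sm))
  records$VI <- with_seed(stream_seed(seed, "table/VI"), {
    log2fc <- stats::rnorm(n, 0, p$null_sd)
    pv <- stats::runif(n)
    reg <- c(vi$up, vi$down)
    sign <- rep(c(1, -1), c(length(vi$up), length(vi$down)))
    log2fc[reg] <- sign * vi$mag[reg]
    pv[reg] <- 10^stats::runif(length(reg), -12, log10(p$reg_p_max))
    data.frame(gene_id = ids, condition = "VI", log2fc = log2fc,
               p_value = pv, stringsAsFactors = FALSE)
  })

  truth <- list(
    params = p, seed = seed,
    up = list(VsSf = ids[sets$sf_up], VsSm = ids[sets$sm_up],
              VI = ids[vi$up]),
    down = list(VsSf = ids[sets$sf_down], VsSm = ids[sets$sm_down],
                VI = ids[vi$down]),
    sf_specific_up_pct = 100 * (1 - length(sets$shared_up) /
                                  max(1L, length(sets$sf_up))),
    sf_specific_down_pct = 100 * (1 - length(sets$shared_down) /
                                    max(1L, length(sets$sf_down))),
    hotspot_regions = if (!is.null(genome$truth$regions))
      genome$truth$regions[genome$truth$regions$hotspot, , drop = FALSE]
      else NULL,
    vi_specific_regions = vi_specific_regions)
  list(records = records, truth = truth)
}

#' Generate directed similarity tables with a known ortholog map
#'
#' `round(ortholog_frac * n_other)` true ortholog pairs link sampled genome
#' genes to a second proteome. Each true pair receives a mutually highest
#' score (250 before noise); near decoys (180-240) and background decoys
#' (50-180) are added per query, and Gaussian score noise of standard
#' deviation `noise` (default 10) is applied to every record. Decoy records are never
#' reciprocal by construction, so with `noise = 0` reciprocal-best-hit
#' search recovers the true map exactly, and with moderate noise recall
#' degrades only through true pairs losing their top rank.
#'
#' @param genome Result of [generate_genome()].
#' @param n_other Number of genes in the second proteome (default 3,228).
#' @param ortholog_frac Fraction of the second proteome with a true ortholog
#'   (default 0.22, i.e. ~712 pairs at the default size).
#' @param noise Standard deviation of the score noise (default 10).
#' @param seed Integer master seed (required).
#' @return List with `ab` and `ba` (similarity tables), `ortholog_map`
#'   (data frame `gene_a`, `gene_b` of true pairs; species A is the second
#'   proteome) and `truth`.
#' @export
generate_similarity <- function(genome, n_other = 3228L,
                                ortholog_frac = 0.22, noise = 10,
                                seed) {
  if (missing(seed) || is.null(seed)) stopf("an explicit seed is required")
  if (ortholog_frac < 0 || ortholog_frac > 1)
    stopf("ortholog_frac must lie in [0, 1]")
  with_seed(stream_seed(seed, "similarity"), {
    ids_b <- genome$genes$gene_id
    ids_a <- sprintf("Rs_%05d", seq_len(n_other))
    n_pairs <- round(ortholog_frac * n_other)
    n_pairs <- min(n_pairs, length(ids_b), n_other)
    pair_a <- pick(ids_a, n_pairs)
    pair_b <- pick(ids_b, n_pairs)
    map <- data.frame(gene_a = pair_a, gene_b = pair_b,
                      stringsAsFactors = FALSE)

    mk_decoys <- function(queries, subjects, lo, hi, k) {
      if (!length(queries)) return(NULL)
      q <- rep(queries, k)
      data.frame(query_id = q,
                 subject_id = sample(subjects, length(q), replace = TRUE),
                 score = stats::runif(length(q), lo, hi),
                 stringsAsFactors = FALSE)
    }
    true_df <- function(q, s) {
      if (!length(q)) return(NULL)
      data.frame(query_id = q, subject_id = s,
                 score = rep(250, length(q)), stringsAsFactors = FALSE)
    }
    # A -> B direction
    ab <- rbind(
      true_df(pair_a, pair_b),
      mk_decoys(pair_a, ids_b, 180, 240, 1L),
      mk_decoys(pair_a, ids_b, 50, 180, 2L),
      mk_decoys(pick(setdiff(ids_a, pair_a),
                     min(500L, n_other - n_pairs)),
                ids_b, 50, 180, 3L))
    ba <- rbind(
      true_df(pair_b, pair_a),
      mk_decoys(pair_b, ids_a, 180, 240, 1L),
      mk_decoys(pair_b, ids_a, 50, 180, 2L),
      mk_decoys(pick(setdiff(ids_b, pair_b),
                     min(500L, length(ids_b) - n_pairs)),
                ids_a, 50, 180, 3L))

    finish <- function(tab, true_q, true_s) {
      # drop decoys that duplicate a true record or mirror one (decoys are
      # never reciprocal), then de-duplicate (query, subject)
      true_key <- paste(true_q, true_s)
      is_true <- tab$score == 250
      key <- paste(tab$query_id, tab$subject_id)
      mirror <- paste(tab$subject_id, tab$query_id)
      drop <- !is_true & (key %in% true_key | mirror %in% true_key |
                          mirror %in% paste(true_s, true_q))
      tab <- tab[!drop, , drop = FALSE]
      key <- paste(tab$query_id, tab$subject_id)
      tab <- tab[order(-tab$score), , drop = FALSE]
      tab <- tab[!duplicated(paste(tab$query_id, tab$subject_id)), ,
                 drop = FALSE]
      if (noise > 0)
        tab$score <- pmax(1, tab$score +
                            stats::rnorm(nrow(tab), 0, noise))
      tab$e_value <- signif(10^(-tab$score / 25), 3)
      rownames(tab) <- NULL
      tab[order(tab$query_id, -tab$score), , drop = FALSE]
    }
    # remove cross-direction reciprocal decoys: a BA decoy (b, a) is dropped
    # whenever (a, b) exists in AB
    ab <- finish(ab, pair_a, pair_b)
    key_ab <- paste(ab$query_id, ab$subject_id)
    ba <- ba[ba$score == 250 |
             !(paste(ba$subject_id, ba$query_id) %in% key_ab), ,
             drop = FALSE]
    ba <- finish(ba, pair_b, pair_a)

    truth <- list(params = list(n_other = n_other,
                                ortholog_frac = ortholog_frac,
                                noise = noise, seed = seed),
                  ids_a = ids_a)
    list(ab = ab, ba = ba, ortholog_map = map, truth = truth)
  })
}

#' Generate species-A regulated gene sets linked to the synthetic responses
#'
#' Builds up- and down-regulated gene sets for the second proteome whose
#' overlap with the focal species' response, through the true ortholog map,
#' matches the configured fractions -- the input needed for cross-species
#' overlap reports.
#'
#' @param similarity Result of [generate_similarity()].
#' @param expression Result of [generate_expression()].
#' @param n_up,n_down Species-A set sizes (defaults 279 / 352).
#' @param overlap_up_frac,overlap_down_frac Fraction of each species-A set
#'   whose ortholog partner is regulated the same way in VsSf
#'   (defaults 78/279 and 178/352).
#' @param seed Integer master seed (required).
#' @return List with `up` and `down` character vectors of species-A gene
#'   ids.
#' @export
generate_species_a_sets <- function(similarity, expression,
                                    n_up = 279L, n_down = 352L,
                                    overlap_up_frac = 78 / 279,
                                    overlap_down_frac = 178 / 352,
                                    seed) {
  if (missing(seed) || is.null(seed)) stopf("an explicit seed is required")
  with_seed(stream_seed(seed, "species_a_sets"), {
    map <- similarity$ortholog_map
    ids_a <- similarity$truth$ids_a
    one <- function(b_set, n_set, frac, exclude = character(0)) {
      partners <- map$gene_a[map$gene_b %in% b_set]
      partners <- setdiff(partners, exclude)
      k <- min(round(frac * n_set), length(partners))
      chosen <- pick(partners, k)
      rest_pool <- setdiff(ids_a, c(chosen, exclude))
      c(chosen, pick(rest_pool, min(n_set - k, length(rest_pool))))
    }
    up <- one(expression$truth$up$VsSf, n_up, overlap_up_frac)
    down <- one(expression$truth$down$VsSf, n_down, overlap_down_frac,
                exclude = up)
    list(up = up, down = down)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Runs [generate_genome()], [generate_expression()],
#' [generate_similarity()] and [generate_species_a_sets()] under one master
#' seed and writes the tables the pipeline readers consume, together with a
#' YAML truth file that is sufficient to recompute every expected summary
#' without re-reading the generated tables. Identical seed and parameters
#' give byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed (required).
#' @param genome_args,expression_params,similarity_args Optional argument
#'   lists forwarded to the generators.
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_dataset <- function(out_dir, seed, genome_args = list(),
                             expression_params = list(),
                             similarity_args = list()) {
  if (missing(seed) || is.null(seed)) stopf("an explicit seed is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- do.call(generate_genome, c(genome_args, list(seed = seed)))
  expr <- generate_expression(genome, expression_params, seed = seed)
  sim <- do.call(generate_similarity,
                 c(list(genome = genome), similarity_args,
                   list(seed = seed)))
  a_sets <- generate_species_a_sets(sim, expr, seed = seed)

  files <- c(genes = file.path(out_dir, "genes.tsv"),
             hits = file.path(out_dir, "hit_counts.tsv"),
             core = file.path(out_dir, "core_genes.txt"),
             sim_ab = file.path(out_dir, "similarity_AB.tsv"),
             sim_ba = file.path(out_dir, "similarity_BA.tsv"),
             orthologs = file.path(out_dir, "orthologs_true.tsv"),
             species_a_up = file.path(out_dir, "species_a_up.txt"),
             species_a_down = file.path(out_dir, "species_a_down.txt"),
             truth = file.path(out_dir, "truth.yaml"))
  write_gene_table(genome$genes, files[["genes"]])
  write_hit_counts(genome$hits, files[["hits"]])
  write_core_ids(genome$core_ids, files[["core"]])
  for (cond in names(expr$records)) {
    f <- file.path(out_dir, sprintf("expression_%s.tsv", cond))
    write_expression_table(expr$records[[cond]], f)
    files[[paste0("expression_", cond)]] <- f
  }
  write_similarity_table(sim$ab, files[["sim_ab"]])
  write_similarity_table(sim$ba, files[["sim_ba"]])
  write_tsv(sim$ortholog_map, files[["orthologs"]])
  writeLines(c("gene_id", a_sets$up), files[["species_a_up"]])
  writeLines(c("gene_id", a_sets$down), files[["species_a_down"]])

  truth <- list(seed = seed,
                genome = genome$truth[c("params", "chrom_sizes")],
                regions = if (!is.null(genome$truth$regions))
                  as.list(genome$truth$regions) else NULL,
                core_ids = genome$core_ids,
                orphan_ids = genome$truth$orphan_ids,
                expression = list(
                  params = expr$truth$params,
                  up = expr$truth$up, down = expr$truth$down,
                  sf_specific_up_pct = expr$truth$sf_specific_up_pct,
                  sf_specific_down_pct = expr$truth$sf_specific_down_pct),
                ortholog_map = sim$ortholog_map,
                species_a = a_sets)
  yaml::write_yaml(truth, files[["truth"]])
  invisible(list(genome = genome, expression = expr, similarity = sim,
                 species_a = a_sets, files = files))
}
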