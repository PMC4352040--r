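#' Read / write pipeline TSV tables
#'
#' All pipeline tables are plain TSV with a header line, UTF-8, "." decimal
#' separator and "NA" for missing values, so round-trips are lossless and
#' diffs stay readable.
#'
#' @param path File path.
#' @return `read_pipeline_tsv()` returns a tibble.
#' @export
read_pipeline_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, na = "NA")
}

#' @rdname read_pipeline_tsv
#' @param x Data frame to write.
#' @export
write_pipeline_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Run the full synthetic screen + phosphoproteomics analysis
#'
#' End-to-end composition of every stage on generated data: simulate screen
#' plates -> score Z/ZDiff -> call primary hits and signature classes ->
#' per-gene ZDiffFinal and high-confidence calls -> complex enrichment; and
#' simulate TMT experiments -> quantify phosphosites -> fold-change set
#' classification -> k-means profiles. Returns a machine-readable summary
#' alongside every intermediate table.
#'
#' @param screen_cfg A [screen_sim_config()].
#' @param phospho_cfg A [phospho_sim_config()].
#' @param thresholds A [screen_thresholds()].
#' @param fold_threshold Linear fold-change threshold for set calling.
#' @param n_random Random gene sets per complex for enrichment.
#' @param k Profile cluster count.
#' @param seed Seed for enrichment resampling, complex library and k-means
#'   (the generators carry their own seeds in their configs).
#' @param out_dir Optional directory; when given, all tables are written
#'   there as TSV.
#' @return A list with `screen` (scores, hits, gene_summaries, truth),
#'   `enrichment`, `phospho` (sites, sets, profiles, truth) and `summary`
#'   (named list of headline counts).
#' @export
run_full_analysis <- function(screen_cfg = screen_sim_config(),
                              phospho_cfg = phospho_sim_config(),
                              thresholds = screen_thresholds(),
                              fold_threshold = 1.5,
                              n_random = 1000,
                              k = 10,
                              seed = 1,
                              out_dir = NULL) {
  ## --- screen branch -------------------------------------------------
  sim <- generate_screen_plates(screen_cfg)
  scores <- score_screen(sim$readings,
                         amplicon_map = sim$truth[, c("amplicon_id", "gene_id")])
  hits <- select_primary_hits(scores$merged, thresholds) |>
    classify_signatures(thresholds)
  gene_summaries <- compute_zdiff_final(scores$merged) |>
    select_high_confidence(thresholds)

  gene_scores <- gene_summaries |>
    dplyr::transmute(gene_id = .data$gene_id, score = .data$zdiff_final)
  lib <- generate_complex_library(gene_scores, seed = seed)
  enrichment <- complex_enrichment(lib$complexes, gene_scores,
                                   n_random = n_random, seed = seed)

  ## --- phospho branch ------------------------------------------------
  ## within-background (insulin, EcR) comparisons come from the two
  ## replicated six-plexes (one per receptor background); cross-background
  ## comparisons come from the single-run six-plex that carries all six
  ## states in one mixture, so every ratio is within-plex and
  ## peptide-matched
  phospho <- generate_phospho_experiment(phospho_cfg)
  is_exp3 <- phospho$psms$experiment == "exp3"
  quant <- quantify_phosphosites(phospho$psms[!is_exp3, ], phospho$design,
                                 phospho$impurity_matrix)
  quant3 <- quantify_phosphosites(phospho$psms[is_exp3, ], phospho$design,
                                  phospho$impurity_matrix)
  sites <- quant$sites
  sites3 <- quant3$sites
  inr_high <- define_inr_set(sites, "high_pvr", fold_threshold)
  inr_low <- define_inr_set(sites, "low_pvr", fold_threshold)
  ecr_high <- define_ecr_set(sites, "high_pvr", fold_threshold)
  ecr_low <- define_ecr_set(sites, "low_pvr", fold_threshold)
  pvr_set <- define_pvr_set(sites3, fold_threshold)
  common <- define_common_set(sites3, fold_threshold)
  receptor <- define_receptor_specific_sets(sites3, fold_threshold,
                                            common_sites = common$site_id)
  rescue <- tryCatch(
    rescue_fraction(sites3, pvr_set, fold_threshold),
    sensimod_undefined_rate = function(e) NA_real_
  )
  profiles <- kmeans_profiles(sites3, k = k, seed = seed)

  summary <- list(
    n_amplicons = nrow(scores$merged),
    n_primary_hits = nrow(hits),
    n_suppressors = sum(hits$class == "Suppressor"),
    n_enhancers = sum(hits$class == "Enhancer"),
    n_upstream = sum(hits$class == "Upstream"),
    n_high_conf_suppressors =
      sum(gene_summaries$confidence == "HighConfSuppressor"),
    n_high_conf_enhancers =
      sum(gene_summaries$confidence == "HighConfEnhancer"),
    n_enriched_complexes_05 = sum(enrichment$p_value <= 0.05),
    n_sites_quantified = nrow(sites),
    n_inr_up_high_pvr = sum(inr_high$direction == "up"),
    n_inr_down_high_pvr = sum(inr_high$direction == "down"),
    n_inr_up_low_pvr = sum(inr_low$direction == "up"),
    n_inr_down_low_pvr = sum(inr_low$direction == "down"),
    n_ecr_up_high_pvr = sum(ecr_high$direction == "up"),
    n_ecr_down_high_pvr = sum(ecr_high$direction == "down"),
    n_pvr_set = length(pvr_set),
    n_common_set = nrow(common),
    n_pvr_only = sum(receptor$label == "Pvr_only"),
    n_inr_only = sum(receptor$label == "InR_only"),
    rescue_fraction = rescue
  )

  result <- list(
    screen = list(scores = scores$merged, per_replicate = scores$per_replicate,
                  hits = hits, gene_summaries = gene_summaries,
                  truth = sim$truth),
    enrichment = enrichment,
    complex_truth = lib$truth,
    phospho = list(sites = sites, sites3 = sites3,
                   inr_high = inr_high, inr_low = inr_low,
                   ecr_high = ecr_high, ecr_low = ecr_low,
                   pvr_set = pvr_set, common = common, receptor = receptor,
                   profiles = profiles, truth = phospho$truth),
    summary = summary
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_tsv(scores$merged, file.path(out_dir, "amplicon_scores.tsv"))
    write_pipeline_tsv(hits, file.path(out_dir, "hits.tsv"))
    write_pipeline_tsv(gene_summaries,
                       file.path(out_dir, "gene_summaries.tsv"))
    write_pipeline_tsv(tidy(enrichment), file.path(out_dir, "enrichment.tsv"))
    write_pipeline_tsv(sites, file.path(out_dir, "phosphosites.tsv"))
    write_pipeline_tsv(tidy(profiles), file.path(out_dir, "clusters.tsv"))
    write_pipeline_tsv(
      tibble::tibble(metric = names(summary),
                     value = unlist(lapply(summary, as.numeric))),
      file.path(out_dir, "summary.tsv")
    )
  }
  result
}

#' Sensitivity and precision of planted-class recovery
#'
#' Compares called classes against planted truth, per class:
#' sensitivity = recovered planted / planted, precision = correctly called /
#' called.
#'
#' @param called Tibble with `amplicon_id` (or `site_id`) and `class`.
#' @param truth Tibble with the same key column and a `class` column of
#'   planted labels; label vocabularies must match.
#' @param key Join column (default `"amplicon_id"`).
#' @param classes Which classes to report.
#' @return Tibble `class`, `n_planted`, `n_called`, `n_correct`,
#'   `sensitivity`, `precision`.
#' @export
recovery_stats <- function(called, truth, key = "amplicon_id",
                           classes = c("Suppressor", "Enhancer", "Upstream")) {
  check_columns(called, c(key, "class"))
  check_columns(truth, c(key, "class"))
  joined <- dplyr::full_join(
    dplyr::select(truth, dplyr::all_of(key), planted = "class"),
    dplyr::select(called, dplyr::all_of(key), called = "class"),
    by = key
  )
  purrr::map_dfr(classes, function(cl) {
    planted <- !is.na(joined$planted) & joined$planted == cl
    called_cl <- !is.na(joined$called) & joined$called == cl
    tibble::tibble(
      class = cl,
      n_planted = sum(planted),
      n_called = sum(called_cl),
      n_correct = sum(planted & called_cl),
      sensitivity = ifelse(sum(planted) == 0, NA_real_,
                           sum(planted & called_cl) / sum(planted)),
      precision = ifelse(sum(called_cl) == 0, NA_real_,
                         sum(planted & called_cl) / sum(called_cl))
    )
  })
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a clustering and reference labels;
#' 1 = identical partitions, 0 = chance-level agreement.
#'
#' @param a,b Equal-length label vectors.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
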