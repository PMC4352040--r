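#' Select primary screen hits by ZDiff cutoffs
#'
#' An amplicon is a primary hit iff its merged ZDiff is at or above
#' `primary_up` or at or below `primary_down` (both bounds inclusive).
#'
#' @param scores Merged amplicon scores (columns `amplicon_id`, `zdiff`, and
#'   usually `z_sensitized`, `z_control`).
#' @param thresholds A threshold set from [screen_thresholds()].
#' @return The subset of `scores` passing either cutoff.
#' @export
select_primary_hits <- function(scores, thresholds = screen_thresholds()) {
  check_columns(scores, c("amplicon_id", "zdiff"))
  dplyr::filter(scores, .data$zdiff >= thresholds$primary_up |
                  .data$zdiff <= thresholds$primary_down)
}

#' Assign Suppressor / Enhancer / Upstream signatures to primary hits
#'
#' Rule-based three-class assignment on (Z sensitized, Z control, ZDiff)
#' signatures: hits with ZDiff at or below `primary_down` worsen the
#' sensitized phenotype (Enhancer); among positive hits, those that strongly
#' depress viability in the control background
#' (`z_control <= upstream_control_floor`) act upstream of the sensitizing
#' receptor (Upstream), the rest rescue the sensitized background
#' (Suppressor).
#'
#' @param hits Primary hits with columns `amplicon_id`, `z_control`, `zdiff`.
#' @inheritParams select_primary_hits
#' @return `hits` with a `class` factor column
#'   (`Suppressor`/`Enhancer`/`Upstream`).
#' @seealso [cluster_signatures()] for the unsupervised counterpart.
#' @export
classify_signatures <- function(hits, thresholds = screen_thresholds()) {
  check_columns(hits, c("amplicon_id", "z_control", "zdiff"))
  hits |>
    dplyr::mutate(class = factor(dplyr::case_when(
      .data$zdiff <= thresholds$primary_down ~ "Enhancer",
      .data$z_control <= thresholds$upstream_control_floor ~ "Upstream",
      TRUE ~ "Suppressor"
    ), levels = HIT_CLASSES))
}

#' Cluster hit signatures (centered correlation, complete linkage)
#'
#' Hierarchical clustering of the (z_sensitized, z_control, zdiff) signature
#' of each hit amplicon, using 1 - centered Pearson correlation as the
#' distance and complete linkage, cut into `k` flat clusters. Each cluster is
#' then mapped to a modifier class by applying the signature rules of
#' [classify_signatures()] to its centroid.
#'
#' @param hits Primary hits with columns `amplicon_id`, `z_sensitized`,
#'   `z_control`, `zdiff`.
#' @param k Number of flat clusters (default 3, the three signature classes).
#' @inheritParams select_primary_hits
#' @return A list with `assignments` (tibble `amplicon_id`, `cluster`,
#'   `class`), `tree` (the `hclust` object) and `excluded` (amplicons with a
#'   constant signature row, for which correlation distance is undefined).
#' @export
cluster_signatures <- function(hits, k = 3, thresholds = screen_thresholds()) {
  check_columns(hits, c("amplicon_id", "z_sensitized", "z_control", "zdiff"))
  x <- as.matrix(hits[, c("z_sensitized", "z_control", "zdiff")])
  rownames(x) <- hits$amplicon_id
  constant <- apply(x, 1, function(r) stats::sd(r) == 0)
  excluded <- rownames(x)[constant]
  x <- x[!constant, , drop = FALSE]
  if (nrow(x) < 2) {
    rlang::abort("need >= 2 non-constant hit signatures to cluster",
                 class = "sensimod_data_error")
  }
  # centered Pearson across the 3-score signature; cor() works on columns
  d <- stats::as.dist(1 - stats::cor(t(x)))
  tree <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(tree, k = min(k, nrow(x)))
  centroids <- rowsum(x, cl) / as.vector(table(cl))
  centroid_class <- classify_signatures(
    tibble::tibble(amplicon_id = rownames(centroids),
                   z_sensitized = centroids[, "z_sensitized"],
                   z_control = centroids[, "z_control"],
                   zdiff = centroids[, "zdiff"]),
    thresholds
  )$class
  assignments <- tibble::tibble(
    amplicon_id = rownames(x),
    cluster = unname(cl),
    class = centroid_class[cl]
  )
  list(assignments = assignments, tree = tree, excluded = excluded)
}

#' Per-gene ZDiffFinal: unweighted mean over all amplicons of a gene
#'
#' Pools every contributing amplicon ZDiff of a gene — primary and
#' verification (secondary) screen alike — and averages them equally.
#'
#' @param amplicon_scores Tibble with columns `gene_id` and `zdiff`; pass the
#'   row-bound primary and secondary scores.
#' @return Tibble `gene_id`, `zdiff_final`, `n_amplicons`.
#' @export
compute_zdiff_final <- function(amplicon_scores) {
  check_columns(amplicon_scores, c("gene_id", "zdiff"))
  scores <- dplyr::filter(amplicon_scores, !is.na(.data$gene_id))
  if (nrow(scores) == 0) {
    rlang::abort("no amplicons with a gene_id", class = "sensimod_data_error")
  }
  scores |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(zdiff_final = mean(.data$zdiff),
                     n_amplicons = dplyr::n(), .groups = "drop")
}

#' High-confidence modifier calls from ZDiffFinal
#'
#' A gene is a high-confidence Suppressor iff `zdiff_final >= final_sup` and
#' a high-confidence Enhancer iff `zdiff_final <= final_enh` (inclusive).
#'
#' @param gene_summaries Output of [compute_zdiff_final()].
#' @inheritParams select_primary_hits
#' @return `gene_summaries` plus a `confidence` factor
#'   (`HighConfSuppressor`/`HighConfEnhancer`/`None`).
#' @export
select_high_confidence <- function(gene_summaries,
                                   thresholds = screen_thresholds()) {
  check_columns(gene_summaries, c("gene_id", "zdiff_final"))
  gene_summaries |>
    dplyr::mutate(confidence = factor(dplyr::case_when(
      .data$zdiff_final >= thresholds$final_sup ~ "HighConfSuppressor",
      .data$zdiff_final <= thresholds$final_enh ~ "HighConfEnhancer",
      TRUE ~ "None"
    ), levels = c("HighConfSuppressor", "HighConfEnhancer", "None")))
}

#' Screen error-rate estimation from reference gene lists
#'
#' False-positive rate: the fraction of genes known not to be expressed in
#' the assayed cells that nevertheless score in the primary screen. False-
#' negative rate: among all library amplicons targeting the high-confidence
#' modifier genes, the fraction that failed to score in the primary screen.
#'
#' @param primary_hit_genes Character vector of gene ids scoring in the
#'   primary screen.
#' @param nonexpressed_genes Character vector of genes not expressed in the
#'   assay cells (false-positive reference).
#' @param high_confidence_genes Character vector of high-confidence modifier
#'   genes (false-negative reference).
#' @param library_amplicons Data frame `amplicon_id`, `gene_id` describing the
#'   full screened library.
#' @param primary_hit_amplicons Character vector of amplicon ids scoring in
#'   the primary screen.
#' @return Tibble with one row: `fp_rate`, `fp_n`, `fn_rate`, `fn_scored`,
#'   `fn_total`.
#' @export
#' @examples
#' # 355 non-expressed genes of which one scores -> FP < 1%
#' lib <- tibble::tibble(amplicon_id = as.character(1:80),
#'                       gene_id = rep(sprintf("hc%02d", 1:38), length.out = 80))
#' estimate_screen_error_rates(
#'   primary_hit_genes = "ne001",
#'   nonexpressed_genes = sprintf("ne%03d", 1:355),
#'   high_confidence_genes = sprintf("hc%02d", 1:38),
#'   library_amplicons = lib,
#'   primary_hit_amplicons = as.character(1:41)
#' )
estimate_screen_error_rates <- function(primary_hit_genes,
                                        nonexpressed_genes,
                                        high_confidence_genes,
                                        library_amplicons,
                                        primary_hit_amplicons) {
  if (length(nonexpressed_genes) == 0 || length(high_confidence_genes) == 0) {
    rlang::abort("reference gene lists must be nonempty",
                 class = "sensimod_undefined_rate")
  }
  check_columns(library_amplicons, c("amplicon_id", "gene_id"))
  fp_n <- sum(unique(nonexpressed_genes) %in% primary_hit_genes)
  fp_rate <- fp_n / length(unique(nonexpressed_genes))

  hc_amplicons <- library_amplicons |>
    dplyr::filter(.data$gene_id %in% high_confidence_genes) |>
    dplyr::distinct(.data$amplicon_id)
  if (nrow(hc_amplicons) == 0) {
    rlang::abort("no library amplicons map to the high-confidence genes",
                 class = "sensimod_undefined_rate")
  }
  fn_scored <- sum(hc_amplicons$amplicon_id %in% primary_hit_amplicons)
  fn_total <- nrow(hc_amplicons)
  tibble::tibble(
    fp_rate = fp_rate, fp_n = fp_n,
    fn_rate = (fn_total - fn_scored) / fn_total,
    fn_scored = fn_scored, fn_total = fn_total
  )
}
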