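#' Phenotype score of a protein complex
#'
#' Aggregates gene-level modifier strength over the members of each complex:
#' the mean absolute gene score (|ZDiffFinal|) over members detected in the
#' screen. Members absent from the scored universe are ignored; complexes
#' with no detected member are dropped.
#'
#' @param complexes Data frame `complex_id`, `gene_id` (long membership
#'   table; >= 2 unique members per complex).
#' @param gene_scores Data frame `gene_id`, `score` (typically `zdiff_final`).
#' @return Tibble `complex_id`, `n_members`, `n_detected`, `score`.
#' @export
complex_scores <- function(complexes, gene_scores) {
  check_columns(complexes, c("complex_id", "gene_id"))
  check_columns(gene_scores, c("gene_id", "score"))
  gene_scores <- dplyr::distinct(gene_scores, .data$gene_id, .keep_all = TRUE)
  complexes |>
    dplyr::distinct(.data$complex_id, .data$gene_id) |>
    dplyr::left_join(gene_scores, by = "gene_id") |>
    dplyr::group_by(.data$complex_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_detected = sum(!is.na(.data$score)),
      score = mean(abs(.data$score[!is.na(.data$score)])),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_detected > 0)
}

#' Complex over-representation by gene-set resampling
#'
#' For each complex, compares its observed phenotype score (mean |score| of
#' detected members) with scores of `n_random` random gene sets of the same
#' size drawn uniformly without replacement from the scored universe. The
#' permutation p-value uses the plus-one correction
#' p = (1 + #\{random >= observed\}) / (n_random + 1), so p is never zero and
#' never below 1/(n_random + 1).
#'
#' @inheritParams complex_scores
#' @param n_random Number of random gene sets per complex (default 1000).
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return A `complex_enrichment` tibble: `complex_id`, `n_members`,
#'   `n_detected`, `score`, `p_value`, with attributes `n_random` and `seed`.
#' @export
#' @examples
#' genes <- tibble::tibble(gene_id = letters[1:10], score = 1:10 / 2)
#' cx <- tibble::tibble(complex_id = "top3", gene_id = c("h", "i", "j"))
#' complex_enrichment(cx, genes, n_random = 200, seed = 1)
complex_enrichment <- function(complexes, gene_scores, n_random = 1000,
                               seed = 1) {
  scored <- complex_scores(complexes, gene_scores)
  gene_scores <- dplyr::distinct(gene_scores, .data$gene_id, .keep_all = TRUE) |>
    dplyr::filter(!is.na(.data$score))
  universe <- abs(gene_scores$score)
  if (any(scored$n_detected > length(universe))) {
    rlang::abort("complex larger than the scored universe",
                 class = "sensimod_config_error")
  }
  set.seed(seed)
  p <- purrr::map2_dbl(scored$score, scored$n_detected, function(obs, m) {
    rand <- replicate(n_random, mean(sample(universe, m)))
    (1 + sum(rand >= obs)) / (n_random + 1)
  })
  out <- dplyr::mutate(scored, p_value = p)
  structure(out, class = c("complex_enrichment", class(out)),
            n_random = n_random, seed = seed)
}

#' @export
tidy.complex_enrichment <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x) %in%
    c("complex_id", "n_members", "n_detected", "score", "p_value")])
}

#' @export
glance.complex_enrichment <- function(x, ...) {
  tibble::tibble(
    n_complexes = nrow(x),
    n_random = attr(x, "n_random"),
    seed = attr(x, "seed"),
    n_significant_05 = sum(x$p_value <= 0.05),
    min_p = min(x$p_value)
  )
}

#' @export
autoplot.complex_enrichment <- function(object, ...) {
  df <- tidy.complex_enrichment(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   y = -log10(.data$p_value),
                                   size = .data$n_detected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "complex phenotype score (mean |ZDiffFinal|)",
                  y = expression(-log[10]~p),
                  size = "members\ndetected",
                  title = "Complex over-representation") +
    ggplot2::theme_minimal()
}
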