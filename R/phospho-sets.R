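#' Fold-change calls between two signaling conditions
#'
#' Computes per-site ratios of replicate-averaged intensities,
#' `ratio = intensity[numerator] / intensity[denominator]`, and calls each
#' site `up` if the ratio strictly exceeds `threshold`, `down` if it is
#' strictly below `1/threshold`, else `unchanged`. Sites lacking a positive
#' intensity in either condition are `not_callable` and excluded from set
#' counts.
#'
#' @param sites Wide site table from [quantify_phosphosites()] (`site_id`
#'   plus one intensity column per condition).
#' @param numerator,denominator Condition column names to compare.
#' @param threshold Linear fold-change threshold (default 1.5, strict).
#' @return Tibble `site_id`, `ratio`, `direction`
#'   (`up`/`down`/`unchanged`/`not_callable`).
#' @export
fold_change_call <- function(sites, numerator, denominator, threshold = 1.5) {
  check_columns(sites, c("site_id", numerator, denominator))
  a <- sites[[numerator]]
  b <- sites[[denominator]]
  callable <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  ratio <- ifelse(callable, a / b, NA_real_)
  tibble::tibble(
    site_id = sites$site_id,
    ratio = ratio,
    direction = factor(dplyr::case_when(
      !callable ~ "not_callable",
      ratio > threshold ~ "up",
      ratio < 1 / threshold ~ "down",
      TRUE ~ "unchanged"
    ), levels = c("up", "down", "unchanged", "not_callable"))
  )
}

#' Insulin-responsive (InR) phosphosite sets within one receptor background
#'
#' Partitions callable sites into up/down/unchanged under insulin stimulation
#' (high InR vs low InR) within the stated Pvr background. In the
#' unperturbed ("high Pvr") background this yields the InR-specific set.
#'
#' @inheritParams fold_change_call
#' @param background `"high_pvr"` or `"low_pvr"`.
#' @return Tibble of fold calls (as [fold_change_call()]) for the
#'   high-vs-low InR comparison in that background.
#' @export
define_inr_set <- function(sites, background = c("high_pvr", "low_pvr"),
                           threshold = 1.5) {
  background <- match.arg(background)
  fold_change_call(sites,
                   numerator = paste0(background, "_high_inr"),
                   denominator = paste0(background, "_low_inr"),
                   threshold = threshold)
}

#' EcR-responsive phosphosite sets within one receptor background
#'
#' Same fold machinery as [define_inr_set()] for ecdysone-receptor
#' knockdown: low EcR vs the low-InR control within the given Pvr
#' background.
#'
#' @inheritParams define_inr_set
#' @export
define_ecr_set <- function(sites, background = c("high_pvr", "low_pvr"),
                           threshold = 1.5) {
  background <- match.arg(background)
  fold_change_call(sites,
                   numerator = paste0(background, "_low_ecr"),
                   denominator = paste0(background, "_low_inr"),
                   threshold = threshold)
}

#' Pvr-dependent phosphosite set
#'
#' Sites downregulated more than `threshold`-fold when the receptor is
#' silenced: a `down` call comparing `low_pvr_low_inr` against
#' `high_pvr_low_inr`.
#'
#' @inheritParams fold_change_call
#' @return Character vector of site ids in the Pvr set.
#' @export
define_pvr_set <- function(sites, threshold = 1.5) {
  calls <- fold_change_call(sites, "low_pvr_low_inr", "high_pvr_low_inr",
                            threshold)
  calls$site_id[calls$direction == "down"]
}

#' Common Pvr and InR phosphorylation targets
#'
#' Sites regulated by both receptors, inferred from the reciprocal effects of
#' receptor knockdown and insulin stimulation. In the default `"reciprocal"`
#' mode a site qualifies when it is down under Pvr loss AND restored (up) by
#' insulin in the low-Pvr background — or the mirrored pairing (up under Pvr
#' loss AND down under insulin). In `"shared"` mode a site qualifies when the
#' low-vs-high Pvr and insulin comparisons both produce a call, in matched
#' (restoring) directions, without requiring membership checks beyond
#' direction.
#'
#' @inheritParams fold_change_call
#' @param mode `"reciprocal"` (default) or `"shared"`.
#' @return Tibble `site_id`, `pvr_direction`, `inr_direction`.
#' @export
define_common_set <- function(sites, threshold = 1.5,
                              mode = c("reciprocal", "shared")) {
  mode <- match.arg(mode)
  pvr_calls <- fold_change_call(sites, "low_pvr_low_inr", "high_pvr_low_inr",
                                threshold)
  inr_calls <- define_inr_set(sites, "low_pvr", threshold)
  joined <- dplyr::inner_join(
    dplyr::rename(pvr_calls, pvr_direction = "direction", pvr_ratio = "ratio"),
    dplyr::rename(inr_calls, inr_direction = "direction", inr_ratio = "ratio"),
    by = "site_id"
  )
  common <- dplyr::filter(
    joined,
    (.data$pvr_direction == "down" & .data$inr_direction == "up") |
      (.data$pvr_direction == "up" & .data$inr_direction == "down")
  )
  if (mode == "shared") {
    # shared directionality of regulation: both perturbations move the site,
    # in either reciprocal pairing or the same direction
    common <- dplyr::filter(
      joined,
      .data$pvr_direction %in% c("up", "down") &
        .data$inr_direction %in% c("up", "down")
    )
  }
  dplyr::select(common, "site_id", "pvr_direction", "inr_direction")
}

#' Receptor-specific phosphosite sets
#'
#' Compares the two single-receptor-active states, `high_pvr_low_inr` vs
#' `low_pvr_high_inr`. Pvr-only sites are more than `threshold`-fold higher
#' when only Pvr is active; InR-only sites are higher when only InR is
#' active; sites in the common set are excluded from both. The labels are
#' mutually exclusive by construction.
#'
#' @inheritParams fold_change_call
#' @param common_sites Character vector of common-set site ids to exclude
#'   (defaults to [define_common_set()] on `sites`).
#' @return Tibble `site_id`, `label` (`Pvr_only`/`InR_only`).
#' @export
define_receptor_specific_sets <- function(sites, threshold = 1.5,
                                          common_sites = NULL) {
  if (is.null(common_sites)) {
    common_sites <- define_common_set(sites, threshold)$site_id
  }
  calls <- fold_change_call(sites, "high_pvr_low_inr", "low_pvr_high_inr",
                            threshold)
  calls |>
    dplyr::filter(.data$direction %in% c("up", "down"),
                  !.data$site_id %in% common_sites) |>
    dplyr::mutate(label = ifelse(.data$direction == "up",
                                 "Pvr_only", "InR_only")) |>
    dplyr::select("site_id", "label")
}

#' Fraction of Pvr-dependent sites restored by insulin
#'
#' Among sites downregulated under Pvr loss, the fraction whose low-Pvr
#' insulin comparison calls `up` — i.e. whose phosphorylation insulin
#' stimulation restores.
#'
#' @inheritParams fold_change_call
#' @param pvr_set Character vector of Pvr-set site ids (defaults to
#'   [define_pvr_set()] on `sites`).
#' @return A single fraction in \[0, 1\].
#' @export
rescue_fraction <- function(sites, pvr_set = NULL, threshold = 1.5) {
  if (is.null(pvr_set)) pvr_set <- define_pvr_set(sites, threshold)
  if (length(pvr_set) == 0) {
    rlang::abort("the Pvr set is empty; rescue fraction undefined",
                 class = "sensimod_undefined_rate")
  }
  inr_calls <- define_inr_set(sites, "low_pvr", threshold)
  restored <- inr_calls$site_id[inr_calls$direction == "up"]
  mean(pvr_set %in% restored)
}

#' K-means clustering of phosphosite condition profiles
#'
#' Each site's intensity profile across conditions is divided by its row
#' median, then clustered by k-means with Euclidean distance, keeping the
#' best of `nstart` restarts (lowest total within-cluster sum of squares).
#' Initial centers are drawn by D-squared (kmeans++) sampling, which covers
#' well-separated groups far more reliably than uniform point sampling when
#' k is large. Deterministic for a fixed `seed`.
#'
#' @param sites Wide site table (`site_id` plus condition columns); rows with
#'   missing values or a non-positive median are dropped.
#' @param k Number of clusters (default 10).
#' @param seed Integer seed.
#' @param nstart Number of random restarts (default 25).
#' @return A `phospho_profiles` object: list with `clusters` (tibble
#'   `site_id`, `cluster`), `centers`, `tot_withinss`, `k`.
#' @export
kmeans_profiles <- function(sites, k = 10, seed = 1, nstart = 25) {
  check_columns(sites, "site_id")
  cond_cols <- setdiff(names(sites),
                       c("site_id", "protein", "residue", "position"))
  x <- as.matrix(sites[, cond_cols])
  rownames(x) <- sites$site_id
  keep <- apply(x, 1, function(r) all(is.finite(r)) && median(r) > 0)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < k) {
    rlang::abort("fewer complete profiles than clusters requested",
                 class = "sensimod_config_error")
  }
  xn <- x / apply(x, 1, stats::median)
  set.seed(seed)
  fit <- NULL
  for (i in seq_len(nstart)) {
    centers <- kmeanspp_centers(xn, k)
    cand <- suppressWarnings(
      stats::kmeans(xn, centers = centers, iter.max = 100))
    if (is.null(fit) || cand$tot.withinss < fit$tot.withinss) fit <- cand
  }
  structure(
    list(
      clusters = tibble::tibble(site_id = rownames(xn),
                                cluster = unname(fit$cluster)),
      centers = fit$centers,
      tot_withinss = fit$tot.withinss,
      k = k, seed = seed
    ),
    class = "phospho_profiles"
  )
}

# D-squared sampling of k initial centers (kmeans++)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    pick <- sample.int(n, 1, prob = pmax(d2, .Machine$double.xmin))
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' @export
tidy.phospho_profiles <- function(x, ...) x$clusters

#' @export
glance.phospho_profiles <- function(x, ...) {
  tibble::tibble(k = x$k, n_sites = nrow(x$clusters),
                 tot_withinss = x$tot_withinss, seed = x$seed)
}

#' @export
autoplot.phospho_profiles <- function(object, ...) {
  centers <- tibble::as_tibble(object$centers) |>
    dplyr::mutate(cluster = factor(seq_len(nrow(object$centers)))) |>
    tidyr::pivot_longer(-"cluster", names_to = "condition",
                        values_to = "intensity")
  ggplot2::ggplot(centers,
                  ggplot2::aes(x = .data$condition, y = .data$intensity,
                               group = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "median-normalized intensity",
                  title = "Phosphosite profile clusters") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
print.phospho_profiles <- function(x, ...) {
  cat("K-means phosphosite profiles: k =", x$k, ",",
      nrow(x$clusters), "sites, total within-SS =",
      signif(x$tot_withinss, 4), "\n")
  invisible(x)
}
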