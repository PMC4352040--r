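#' Filter PSMs on phosphosite localization and precursor purity
#'
#' Keeps peptide-spectrum matches whose phosphosite localization score
#' (AScore) exceeds `ascore_min` (strictly; AScore > 13 corresponds to
#' p < 0.05 for correct localization) and whose isolation specificity — the
#' fraction of precursor-window signal attributable to the selected peptide —
#' strictly exceeds `isolation_min`. Records with a missing AScore are
#' rejected and counted in the `n_missing_ascore` attribute.
#'
#' @param psms PSM-level tibble with columns `ascore` and
#'   `isolation_specificity`.
#' @param ascore_min Strict lower bound on AScore (default 13).
#' @param isolation_min Strict lower bound on isolation specificity
#'   (default 0.75).
#' @return The retained rows, with attribute `n_missing_ascore`.
#' @export
apply_psm_filters <- function(psms, ascore_min = 13, isolation_min = 0.75) {
  check_columns(psms, c("ascore", "isolation_specificity"))
  n_missing <- sum(is.na(psms$ascore))
  if (n_missing > 0) {
    rlang::warn(sprintf("%d PSM(s) dropped for missing AScore", n_missing))
  }
  out <- dplyr::filter(psms, !is.na(.data$ascore),
                       .data$ascore > ascore_min,
                       .data$isolation_specificity > isolation_min)
  attr(out, "n_missing_ascore") <- n_missing
  out
}

#' Target-decoy FDR thresholding of PSM search scores
#'
#' Scans candidate score cutoffs from the highest score down and keeps the
#' largest accepted set whose decoy-to-target ratio does not exceed `fdr`.
#' Decoy matches (reversed-database hits) estimate the number of incorrect
#' target matches at each cutoff. Decoys are removed from the returned set.
#'
#' @param psms Tibble with columns `search_score` and `is_decoy` (logical).
#' @param fdr Target false discovery rate (default 0.01).
#' @return List with `cutoff` (lowest accepted score, `Inf` when nothing can
#'   be accepted) and `accepted` (target rows with
#'   `search_score >= cutoff`).
#' @export
fdr_threshold <- function(psms, fdr = 0.01) {
  check_columns(psms, c("search_score", "is_decoy"))
  if (sum(!psms$is_decoy) == 0) {
    return(list(cutoff = Inf, accepted = psms[0, ]))
  }
  ord <- psms[order(psms$search_score, decreasing = TRUE), ]
  cum_decoy <- cumsum(ord$is_decoy)
  cum_target <- cumsum(!ord$is_decoy)
  ratio <- ifelse(cum_target == 0, Inf, cum_decoy / cum_target)
  # a cutoff must sit at a distinct score boundary: take each score's last row
  boundary <- c(ord$search_score[-1] != ord$search_score[-nrow(ord)], TRUE)
  ok <- which(boundary & ratio <= fdr)
  if (length(ok) == 0) {
    rlang::warn("no score cutoff achieves the requested FDR; empty accept set")
    return(list(cutoff = Inf, accepted = psms[0, ]))
  }
  cutoff <- ord$search_score[max(ok)]
  accepted <- dplyr::filter(psms, !.data$is_decoy,
                            .data$search_score >= cutoff)
  list(cutoff = cutoff, accepted = accepted)
}

#' Correct TMT reporter intensities for channel impurities
#'
#' Isobaric labels leak a known fraction of their signal into neighbouring
#' channels (isotopic impurities). With `observed = M %*% true`, where
#' `M[i, j]` is the fraction of channel `j`'s signal appearing in channel
#' `i`, the correction solves the linear system for the true intensities and
#' clamps small negative solutions to zero.
#'
#' @param intensities A numeric matrix (rows = peptides, 6 columns = channels
#'   126..131) or a length-6 vector.
#' @param impurity_matrix 6 x 6 invertible mixing matrix.
#' @return Corrected intensities, same shape as the input.
#' @export
correct_impurities <- function(intensities, impurity_matrix) {
  vec <- is.null(dim(intensities))
  x <- if (vec) matrix(intensities, nrow = 1) else as.matrix(intensities)
  m <- as.matrix(impurity_matrix)
  if (ncol(x) != nrow(m) || nrow(m) != ncol(m)) {
    rlang::abort("impurity matrix must be square and match channel count",
                 class = "sensimod_config_error")
  }
  if (abs(det(m)) < .Machine$double.eps * nrow(m)) {
    rlang::abort("impurity matrix is singular", class = "sensimod_config_error")
  }
  corrected <- t(solve(m, t(x)))
  # clamp negatives and sub-tolerance solver residue: a channel whose true
  # signal is zero must come back exactly zero, or downstream detection
  # calls (> 0) would count numerical noise as signal
  tol <- 1e-9 * apply(abs(corrected), 1, max)
  corrected[corrected < tol[row(corrected)]] <- 0
  if (vec) as.vector(corrected) else {
    dimnames(corrected) <- dimnames(x)
    corrected
  }
}

#' Normalize reporter intensities to equal channel totals
#'
#' Divides each value by its channel's summed intensity, then rescales by the
#' mean of the channel totals so magnitudes stay on the original scale. After
#' normalization all channel (column) totals are equal, removing per-label
#' loading differences.
#'
#' @param intensities Numeric matrix, rows = peptides, columns = channels.
#' @return Normalized matrix of the same shape.
#' @export
normalize_channels <- function(intensities) {
  x <- as.matrix(intensities)
  totals <- colSums(x)
  if (any(totals <= 0)) {
    rlang::abort("every channel must have a positive total intensity",
                 class = "sensimod_degenerate_channel")
  }
  sweep(x, 2, totals, "/") * mean(totals)
}

#' Replicate-average peptide channel intensities per condition
#'
#' Joins the long peptide x channel table to the TMT design, marks a
#' (peptide, condition, replicate) as detected iff its corrected intensity is
#' positive, excludes peptides detected in only one replicate (for replicated
#' designs), and averages detected intensities per condition. For replicated
#' designs a per-condition average is reported only when at least two
#' replicates of that condition were detected; single-run designs pass
#' through unchanged.
#'
#' @param quant Long tibble with columns `peptide_key`, `condition`,
#'   `replicate`, `intensity` (plus any id columns, carried through).
#' @return List with `averaged` (tibble `peptide_key`, `condition`,
#'   `intensity`, `n_replicates_detected`) and `excluded` (peptide keys
#'   dropped by the single-replicate rule).
#' @export
aggregate_replicates <- function(quant) {
  check_columns(quant, c("peptide_key", "condition", "replicate", "intensity"))
  n_design_reps <- length(unique(quant$replicate))
  detected <- dplyr::mutate(quant, detected = .data$intensity > 0)
  rep_counts <- detected |>
    dplyr::group_by(.data$peptide_key) |>
    dplyr::summarise(
      n_reps_detected = length(unique(.data$replicate[.data$detected])),
      .groups = "drop"
    )
  excluded <- rep_counts$peptide_key[
    n_design_reps > 1 & rep_counts$n_reps_detected == 1]
  averaged <- detected |>
    dplyr::filter(!.data$peptide_key %in% excluded) |>
    dplyr::group_by(.data$peptide_key, .data$condition) |>
    dplyr::summarise(
      n_replicates_detected = sum(.data$detected),
      intensity = ifelse(sum(.data$detected) == 0, NA_real_,
                         mean(.data$intensity[.data$detected])),
      .groups = "drop"
    )
  if (n_design_reps > 1) {
    averaged <- dplyr::mutate(averaged, intensity = ifelse(
      .data$n_replicates_detected >= 2, .data$intensity, NA_real_))
  }
  list(averaged = averaged, excluded = excluded)
}

#' Collapse peptide quantifications to unique phosphosites
#'
#' A phosphosite is keyed by (protein, residue, position). Intensities of all
#' peptides covering the same site are summed per condition; a
#' multiply-phosphorylated peptide contributes to each of its constituent
#' sites.
#'
#' @param peptide_quant Tibble with columns `protein`, `site_positions`
#'   (";"-separated `residue|position` tokens, e.g. `"S25;T40"`), `condition`,
#'   `intensity`.
#' @return Tibble `site_id`, `protein`, `residue`, `position`, `condition`,
#'   `intensity`, `n_peptides`.
#' @export
collapse_to_phosphosites <- function(peptide_quant) {
  check_columns(peptide_quant,
                c("protein", "site_positions", "condition", "intensity"))
  expanded <- peptide_quant |>
    dplyr::mutate(.site = strsplit(as.character(.data$site_positions), ";")) |>
    tidyr::unnest(".site")
  bad <- !grepl("^[A-Z][0-9]+$", expanded$.site)
  if (any(bad)) {
    rlang::warn(sprintf("%d record(s) dropped for unparseable site positions",
                        sum(bad)))
    expanded <- expanded[!bad, ]
  }
  expanded |>
    dplyr::mutate(
      residue = substr(.data$.site, 1, 1),
      position = as.integer(sub("^[A-Z]", "", .data$.site)),
      site_id = paste0(.data$protein, ":", .data$.site)
    ) |>
    dplyr::group_by(.data$site_id, .data$protein, .data$residue,
                    .data$position, .data$condition) |>
    dplyr::summarise(
      n_peptides = sum(!is.na(.data$intensity)),
      intensity = ifelse(all(is.na(.data$intensity)), NA_real_,
                         sum(.data$intensity, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$protein, .data$position, .data$condition)
}

#' Full phosphosite quantification pipeline
#'
#' Composes the quantification stages in order: PSM quality filters
#' (AScore, isolation specificity) -> target-decoy FDR thresholding ->
#' TMT impurity correction -> per-channel normalization -> replicate
#' averaging with single-replicate exclusion -> collapsing to unique
#' phosphosites. Experiments are processed independently (each six-plex is
#' its own mixture) and site tables are combined at the end; conditions
#' quantified in several experiments are averaged across them.
#'
#' @param psms PSM tibble with columns `peptide`, `protein`,
#'   `site_positions`, `ascore`, `isolation_specificity`, `search_score`,
#'   `is_decoy`, `experiment`, and intensity columns `i126`..`i131`.
#' @param design TMT design tibble: `experiment`, `channel` (`"i126"`..),
#'   `condition`, `replicate`.
#' @param impurity_matrix 6 x 6 channel mixing matrix (see
#'   [correct_impurities()]).
#' @param fdr,ascore_min,isolation_min Filter parameters.
#' @return List with `sites` (wide tibble: `site_id`, `protein`, `residue`,
#'   `position`, one intensity column per condition), `sites_long`,
#'   `fdr_cutoffs` (per experiment) and `excluded_peptides`.
#' @export
quantify_phosphosites <- function(psms, design, impurity_matrix,
                                  fdr = 0.01, ascore_min = 13,
                                  isolation_min = 0.75) {
  check_columns(psms, c("peptide", "protein", "site_positions", "ascore",
                        "isolation_specificity", "search_score", "is_decoy",
                        "experiment", TMT_CHANNELS))
  check_columns(design, c("experiment", "channel", "condition", "replicate"))
  filtered <- apply_psm_filters(psms, ascore_min, isolation_min)

  per_exp <- lapply(split(filtered, filtered$experiment), function(df) {
    exp_id <- df$experiment[[1]]
    thr <- fdr_threshold(df, fdr = fdr)
    accepted <- thr$accepted
    if (nrow(accepted) == 0) {
      return(list(sites = NULL, cutoff = thr$cutoff, excluded = character()))
    }
    x <- as.matrix(accepted[, TMT_CHANNELS])
    x <- correct_impurities(x, impurity_matrix)
    x <- normalize_channels(x)
    accepted[, TMT_CHANNELS] <- x
    des <- dplyr::filter(design, .data$experiment == exp_id)
    long <- accepted |>
      dplyr::mutate(peptide_key = paste0(.data$protein, "::", .data$peptide,
                                         "::", .data$site_positions)) |>
      dplyr::select("peptide_key", "protein", "site_positions",
                    dplyr::all_of(TMT_CHANNELS)) |>
      tidyr::pivot_longer(dplyr::all_of(TMT_CHANNELS), names_to = "channel",
                          values_to = "intensity") |>
      dplyr::group_by(.data$peptide_key, .data$protein, .data$site_positions,
                      .data$channel) |>
      dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
      dplyr::inner_join(des, by = "channel")
    agg <- aggregate_replicates(long)
    keys <- dplyr::distinct(long, .data$peptide_key, .data$protein,
                            .data$site_positions)
    sites <- agg$averaged |>
      dplyr::inner_join(keys, by = "peptide_key") |>
      dplyr::select("protein", "site_positions", "condition", "intensity") |>
      collapse_to_phosphosites()
    list(sites = sites, cutoff = thr$cutoff, excluded = agg$excluded)
  })

  sites_long <- dplyr::bind_rows(lapply(per_exp, `[[`, "sites")) |>
    dplyr::group_by(.data$site_id, .data$protein, .data$residue,
                    .data$position, .data$condition) |>
    dplyr::summarise(
      intensity = ifelse(all(is.na(.data$intensity)), NA_real_,
                         mean(.data$intensity, na.rm = TRUE)),
      n_peptides = sum(.data$n_peptides), .groups = "drop"
    )
  sites <- sites_long |>
    dplyr::select(-"n_peptides") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "intensity")
  list(
    sites = sites,
    sites_long = sites_long,
    fdr_cutoffs = tibble::tibble(
      experiment = names(per_exp),
      cutoff = vapply(per_exp, `[[`, numeric(1), "cutoff")
    ),
    excluded_peptides = unlist(lapply(per_exp, `[[`, "excluded"),
                               use.names = FALSE)
  )
}
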