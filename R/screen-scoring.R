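#' Per-well Z scores against in-plate controls
#'
#' Computes z = (reading - mu) / sigma for every well of every
#' plate x condition x replicate, where mu and sigma are the mean and sample
#' standard deviation of the control wells of that same plate, condition and
#' replicate. Scoring against in-plate controls removes plate-to-plate and
#' run-to-run luminescence drift, the standard normalization for arrayed
#' viability screens.
#'
#' @param readings A data frame of plate readings with columns `plate_id`,
#'   `well`, `condition`, `replicate`, `amplicon_id`, `is_control` (logical)
#'   and `reading` (positive luminescence counts).
#' @return A tibble: the input plus `mu`, `sigma` and `z` columns.
#' @details Control wells themselves are scored too; by construction their z
#'   values have mean exactly 0 and sample standard deviation exactly 1 within
#'   each plate x condition x replicate.
#' @export
#' @examples
#' plates <- tibble::tibble(
#'   plate_id = 1, well = c("A1", "A2", "A3", "B1"),
#'   condition = "sensitized", replicate = 1L,
#'   amplicon_id = c(NA, NA, NA, "amp1"),
#'   is_control = c(TRUE, TRUE, TRUE, FALSE),
#'   reading = c(90, 100, 110, 120)
#' )
#' plate_zscores(plates)$z
plate_zscores <- function(readings) {
  check_columns(readings, c("plate_id", "well", "condition", "replicate",
                            "is_control", "reading"))
  scored <- readings |>
    dplyr::group_by(.data$plate_id, .data$condition, .data$replicate) |>
    dplyr::mutate(
      mu = mean(.data$reading[.data$is_control]),
      sigma = stats::sd(.data$reading[.data$is_control])
    ) |>
    dplyr::ungroup()
  n_ctrl <- readings |>
    dplyr::group_by(.data$plate_id, .data$condition, .data$replicate) |>
    dplyr::summarise(n = sum(.data$is_control), .groups = "drop")
  if (any(n_ctrl$n < 2)) {
    rlang::abort("every plate x condition x replicate needs >= 2 control wells",
                 class = "sensimod_missing_controls")
  }
  if (any(!is.finite(scored$sigma)) || any(scored$sigma <= 0)) {
    rlang::abort("control wells have zero spread on at least one plate",
                 class = "sensimod_degenerate_plate")
  }
  scored |>
    dplyr::mutate(z = (.data$reading - .data$mu) / .data$sigma) |>
    tibble::as_tibble()
}

#' Differential Z score between sensitized and control backgrounds
#'
#' ZDiff = Z(sensitized) - Z(control) for each amplicon, the statistic of a
#' differential (sensitized) modifier screen: amplicons acting equally in both
#' backgrounds cancel out, modifiers of the sensitizing perturbation do not.
#'
#' @param z_sensitized,z_control Numeric vectors of paired Z scores
#'   (same amplicon and replicate pairing, element-wise).
#' @return `z_sensitized - z_control`.
#' @export
compute_zdiff <- function(z_sensitized, z_control) {
  if (length(z_sensitized) != length(z_control)) {
    rlang::abort("z_sensitized and z_control must pair element-wise",
                 class = "sensimod_pairing_error")
  }
  z_sensitized - z_control
}

#' Score a sensitized screen: per-amplicon Z, ZDiff, merged over replicates
#'
#' Runs [plate_zscores()] on every plate, pairs each amplicon's sensitized and
#' control background scores within replicates, and merges across replicates
#' by averaging Z per background (ZDiff is then recomputed from the merged
#' means; with equal replicate counts this equals the mean of per-replicate
#' ZDiffs).
#'
#' @inheritParams plate_zscores
#' @param sensitized,control The `condition` labels of the sensitized and
#'   control backgrounds (defaults `"sensitized"` and `"control"`).
#' @param amplicon_map Optional data frame with columns `amplicon_id`,
#'   `gene_id` used to attach gene identifiers.
#' @return A list with
#'   \describe{
#'     \item{per_replicate}{tibble `amplicon_id`, `gene_id`, `replicate`,
#'       `z_sensitized`, `z_control`, `zdiff`}
#'     \item{merged}{tibble `amplicon_id`, `gene_id`, `z_sensitized`,
#'       `z_control`, `zdiff`, `n_replicates`}
#'     \item{incomplete}{amplicons lacking one background entirely, excluded
#'       from `merged`}
#'   }
#' @export
score_screen <- function(readings, sensitized = "sensitized",
                         control = "control", amplicon_map = NULL) {
  scored <- plate_zscores(readings)
  candidates <- scored |>
    dplyr::filter(!.data$is_control, !is.na(.data$amplicon_id))
  bad <- setdiff(unique(candidates$condition), c(sensitized, control))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown condition label(s): ",
                        paste(bad, collapse = ", ")),
                 class = "sensimod_config_error")
  }
  per_rep <- candidates |>
    dplyr::mutate(background = ifelse(.data$condition == sensitized,
                                      "z_sensitized", "z_control")) |>
    dplyr::select("amplicon_id", "replicate", "background", "z") |>
    tidyr::pivot_wider(names_from = "background", values_from = "z",
                       values_fn = mean) |>
    dplyr::filter(!is.na(.data$z_sensitized), !is.na(.data$z_control)) |>
    dplyr::mutate(zdiff = compute_zdiff(.data$z_sensitized, .data$z_control)) |>
    dplyr::arrange(.data$amplicon_id, .data$replicate)

  merged <- merge_replicates(per_rep)
  by_bg <- candidates |>
    dplyr::distinct(.data$amplicon_id, .data$condition) |>
    dplyr::count(.data$amplicon_id)
  incomplete <- by_bg$amplicon_id[by_bg$n < 2]

  if (!is.null(amplicon_map)) {
    check_columns(amplicon_map, c("amplicon_id", "gene_id"))
    map <- dplyr::distinct(amplicon_map, .data$amplicon_id, .data$gene_id)
    per_rep <- dplyr::left_join(per_rep, map, by = "amplicon_id") |>
      dplyr::relocate("gene_id", .after = "amplicon_id")
    merged <- dplyr::left_join(merged, map, by = "amplicon_id") |>
      dplyr::relocate("gene_id", .after = "amplicon_id")
  }
  list(per_replicate = per_rep, merged = merged, incomplete = incomplete)
}

#' Merge per-replicate amplicon scores
#'
#' Averages `z_sensitized` and `z_control` (unweighted) across replicates and
#' recomputes `zdiff` from the merged means.
#'
#' @param per_replicate A tibble with columns `amplicon_id`, `replicate`,
#'   `z_sensitized`, `z_control` (and optionally `zdiff`).
#' @return One row per amplicon with merged scores and `n_replicates`.
#' @export
merge_replicates <- function(per_replicate) {
  check_columns(per_replicate,
                c("amplicon_id", "replicate", "z_sensitized", "z_control"))
  per_replicate |>
    dplyr::group_by(.data$amplicon_id) |>
    dplyr::summarise(
      z_sensitized = mean(.data$z_sensitized),
      z_control = mean(.data$z_control),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(zdiff = compute_zdiff(.data$z_sensitized, .data$z_control)) |>
    dplyr::relocate("zdiff", .after = "z_control")
}

check_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
                 class = "sensimod_data_error")
  }
  invisible(df)
}
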