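#' Configuration for the synthetic sensitized-screen generator
#'
#' Defaults emulate a candidate-enriched (verification-style) differential
#' viability screen: duplicate 384-well plates read under a sensitized and a
#' control background, with control wells in fixed columns and planted
#' modifier classes whose multiplicative effects act per background.
#'
#' @param n_plates Number of distinct plate layouts.
#' @param wells_per_plate Wells per plate (default 384).
#' @param n_control_wells Control wells per plate (default 32, >= 2).
#' @param n_replicates Replicates per condition (default 2, screens run in
#'   duplicate).
#' @param baseline_mean Baseline luminescence of an unaffected well.
#' @param baseline_cv Coefficient of variation of the log-normal well noise.
#' @param effect_sizes Named list of per-class multiplicative effects on the
#'   reading, each `c(sensitized = , control = )`. A Suppressor raises
#'   viability in the sensitized background only; an Enhancer lowers it
#'   there; an Upstream gene lowers viability in the control background
#'   only; null amplicons are neutral.
#' @param class_fractions Named simplex weights over
#'   `suppressor`/`enhancer`/`upstream`/`null`.
#' @param seed Integer seed.
#' @return A validated `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_plates = 2,
                              wells_per_plate = 384,
                              n_control_wells = 32,
                              n_replicates = 2,
                              baseline_mean = 1e5,
                              baseline_cv = 0.1,
                              effect_sizes = list(
                                suppressor = c(sensitized = 1.8, control = 1.0),
                                enhancer   = c(sensitized = 0.5, control = 1.0),
                                upstream   = c(sensitized = 1.0, control = 0.5),
                                null       = c(sensitized = 1.0, control = 1.0)
                              ),
                              class_fractions = c(suppressor = 0.25,
                                                  enhancer = 0.22,
                                                  upstream = 0.13,
                                                  null = 0.40),
                              seed = 1) {
  if (abs(sum(class_fractions) - 1) > 1e-8 || any(class_fractions < 0)) {
    rlang::abort("class_fractions must be non-negative and sum to 1",
                 class = "sensimod_config_error")
  }
  if (baseline_cv <= 0 || n_control_wells < 2 || n_plates < 1 ||
      wells_per_plate <= n_control_wells) {
    rlang::abort("invalid screen simulation dimensions",
                 class = "sensimod_config_error")
  }
  if (!setequal(names(class_fractions),
                c("suppressor", "enhancer", "upstream", "null"))) {
    rlang::abort("class_fractions must name suppressor/enhancer/upstream/null",
                 class = "sensimod_config_error")
  }
  structure(list(
    n_plates = n_plates, wells_per_plate = wells_per_plate,
    n_control_wells = n_control_wells, n_replicates = n_replicates,
    baseline_mean = baseline_mean, baseline_cv = baseline_cv,
    effect_sizes = effect_sizes, class_fractions = class_fractions,
    seed = seed
  ), class = "screen_sim_config")
}

# log-normal multiplicative noise with expectation 1 and the requested CV;
# luminescence counts are strictly positive so additive Gaussian noise is
# inappropriate
rlnorm_cv <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate synthetic screen plates with planted modifier classes
#'
#' Produces one reading per well for every plate x condition x replicate.
#' Control wells (no candidate dsRNA) occupy the first
#' `n_control_wells` wells of each plate; every amplicon appears at the same
#' well of its plate in both backgrounds and all replicates. Readings are
#' `baseline_mean * effect(class, background) * noise`, with log-normal
#' noise of coefficient of variation `baseline_cv`. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [screen_sim_config()].
#' @return List with `readings` (tibble `plate_id`, `well`, `condition`,
#'   `replicate`, `amplicon_id`, `gene_id`, `is_control`, `reading`) and
#'   `truth` (tibble `amplicon_id`, `gene_id`, `class`). Amplicons of the
#'   same gene share a planted class (two amplicons per gene).
#' @export
generate_screen_plates <- function(cfg = screen_sim_config()) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  set.seed(cfg$seed)
  n_cand <- cfg$wells_per_plate - cfg$n_control_wells
  n_amplicons <- n_cand * cfg$n_plates
  amp_ids <- sprintf("amp%05d", seq_len(n_amplicons))
  # two amplicons per gene, so genes span plates and ZDiffFinal averages >1
  gene_ids <- sprintf("gene%05d", rep(seq_len(ceiling(n_amplicons / 2)),
                                      each = 2)[seq_len(n_amplicons)])
  classes <- c("suppressor", "enhancer", "upstream", "null")
  gene_class <- sample(classes, ceiling(n_amplicons / 2), replace = TRUE,
                       prob = cfg$class_fractions[classes])
  amp_class <- gene_class[rep(seq_along(gene_class),
                              each = 2)[seq_len(n_amplicons)]]
  truth <- tibble::tibble(amplicon_id = amp_ids, gene_id = gene_ids,
                          class = amp_class)

  layout <- tibble::tibble(
    plate_id = rep(seq_len(cfg$n_plates), each = cfg$wells_per_plate),
    well_index = rep(seq_len(cfg$wells_per_plate), cfg$n_plates)
  ) |>
    dplyr::mutate(
      well = sprintf("%s%02d", LETTERS[(.data$well_index - 1) %/% 24 + 1],
                     (.data$well_index - 1) %% 24 + 1),
      is_control = .data$well_index <= cfg$n_control_wells
    )
  layout$amplicon_id <- NA_character_
  layout$amplicon_id[!layout$is_control] <- amp_ids
  layout <- dplyr::left_join(layout, truth, by = "amplicon_id")
  layout$class[layout$is_control] <- "null"

  grid <- tidyr::expand_grid(
    condition = c("sensitized", "control"),
    replicate = seq_len(cfg$n_replicates)
  )
  readings <- tidyr::crossing(layout, grid) |>
    dplyr::arrange(.data$plate_id, .data$condition, .data$replicate,
                   .data$well_index)
  e_sens <- vapply(cfg$effect_sizes, `[[`, numeric(1), "sensitized")
  e_ctrl <- vapply(cfg$effect_sizes, `[[`, numeric(1), "control")
  effects <- ifelse(readings$condition == "sensitized",
                    e_sens[readings$class], e_ctrl[readings$class])
  readings$reading <- cfg$baseline_mean * effects *
    rlnorm_cv(nrow(readings), cfg$baseline_cv)
  readings <- readings |>
    dplyr::select("plate_id", "well", "condition", "replicate",
                  "amplicon_id", "gene_id", "is_control", "reading")
  list(readings = readings, truth = truth)
}
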