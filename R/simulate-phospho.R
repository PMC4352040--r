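#' Configuration for the synthetic TMT phosphoproteomics generator
#'
#' Defaults emulate two six-plex TMT experiments covering the six signaling
#' states in biological duplicate — experiment 1 carries the unperturbed
#' ("high Pvr") background (channels 126/127 low InR, 128/129 high InR,
#' 130/131 low EcR), experiment 2 the receptor-silenced ("low Pvr")
#' background with the same channel layout — plus planted responsive
#' phosphosite classes, isotopic channel cross-leakage, log-normal intensity
#' noise and per-replicate dropout.
#'
#' @param n_phosphosites Number of unique phosphosites.
#' @param peptides_per_site Mean of the (1 + Poisson) number of peptides
#'   covering each site.
#' @param planted_set_fractions Named fractions of sites planted as
#'   `inr` (insulin-responsive, split evenly between up- and down-regulated
#'   on InR stimulation), `pvr` (receptor-dependent, down on receptor loss),
#'   `common` (down on receptor loss, restored by insulin) and `ecr`
#'   (EcR-knockdown-responsive, split evenly up/down); the remainder is
#'   null. Planting both directions mirrors real phosphoproteomes and keeps
#'   channel totals comparable, which the total-intensity normalization
#'   assumes.
#' @param effect_fold True fold change of planted effects (> 1).
#' @param intensity_cv Coefficient of variation of log-normal intensity
#'   noise.
#' @param dropout_rate Probability a peptide is undetected in one biological
#'   replicate (zeroes that replicate's channels).
#' @param decoy_fraction Fraction of additional decoy PSMs.
#' @param impurity_matrix 6 x 6 channel mixing matrix; the default leaks 2%
#'   to each adjacent channel.
#' @param seed Integer seed.
#' @return A validated `phospho_sim_config` list.
#' @export
phospho_sim_config <- function(n_phosphosites = 400,
                               peptides_per_site = 2,
                               planted_set_fractions = c(inr = 0.10,
                                                         pvr = 0.10,
                                                         common = 0.05,
                                                         ecr = 0.01),
                               effect_fold = 2.5,
                               intensity_cv = 0.10,
                               dropout_rate = 0.05,
                               decoy_fraction = 0.10,
                               impurity_matrix = default_impurity_matrix(),
                               seed = 1) {
  if (effect_fold <= 1) {
    rlang::abort("effect_fold must exceed 1", class = "sensimod_config_error")
  }
  if (sum(planted_set_fractions) > 1 || any(planted_set_fractions < 0)) {
    rlang::abort("planted_set_fractions must be non-negative, summing to <= 1",
                 class = "sensimod_config_error")
  }
  m <- as.matrix(impurity_matrix)
  if (nrow(m) != 6 || ncol(m) != 6) {
    rlang::abort("impurity_matrix must be 6 x 6",
                 class = "sensimod_config_error")
  }
  if (any(m < 0) || any(colSums(m) > 1 + 1e-8)) {
    rlang::abort("impurity_matrix entries must be non-negative with column sums <= 1",
                 class = "sensimod_config_error")
  }
  structure(list(
    n_phosphosites = n_phosphosites, peptides_per_site = peptides_per_site,
    planted_set_fractions = planted_set_fractions, effect_fold = effect_fold,
    intensity_cv = intensity_cv, dropout_rate = dropout_rate,
    decoy_fraction = decoy_fraction, impurity_matrix = m, seed = seed
  ), class = "phospho_sim_config")
}

#' Default TMT impurity matrix (2% adjacent-channel leakage)
#'
#' Column j holds the mixing fractions of label j's true signal across the
#' observed channels: 2% leaks to each adjacent channel, the diagonal keeps
#' the rest.
#'
#' @param leak Fraction leaked to each neighbouring channel.
#' @return A 6 x 6 matrix with `observed = M %*% true`.
#' @export
default_impurity_matrix <- function(leak = 0.02) {
  m <- diag(6)
  for (j in 1:6) {
    if (j > 1) m[j - 1, j] <- leak
    if (j < 6) m[j + 1, j] <- leak
    m[j, j] <- 1 - leak * ((j > 1) + (j < 6))
  }
  dimnames(m) <- list(TMT_CHANNELS, TMT_CHANNELS)
  m
}

#' Standard six-plex channel design for the duplicate experiments
#'
#' @param experiments Which experiments to include: `"exp1"` (high-Pvr
#'   background, duplicate), `"exp2"` (low-Pvr background, duplicate),
#'   `"exp3"` (all six states, single run).
#' @return Tibble `experiment`, `channel`, `condition`, `replicate`.
#' @export
tmt_design <- function(experiments = c("exp1", "exp2")) {
  designs <- list(
    exp1 = tibble::tibble(
      experiment = "exp1", channel = TMT_CHANNELS,
      condition = rep(c("high_pvr_low_inr", "high_pvr_high_inr",
                        "high_pvr_low_ecr"), each = 2),
      replicate = rep(1:2, 3)
    ),
    exp2 = tibble::tibble(
      experiment = "exp2", channel = TMT_CHANNELS,
      condition = rep(c("low_pvr_low_inr", "low_pvr_high_inr",
                        "low_pvr_low_ecr"), each = 2),
      replicate = rep(1:2, 3)
    ),
    exp3 = tibble::tibble(
      experiment = "exp3", channel = TMT_CHANNELS,
      condition = c("low_pvr_low_inr", "low_pvr_high_inr", "low_pvr_low_ecr",
                    "high_pvr_low_inr", "high_pvr_high_inr",
                    "high_pvr_low_ecr"),
      replicate = 1L
    )
  )
  dplyr::bind_rows(designs[experiments])
}

# expected true intensity multiplier of a planted class in one condition
planted_effect <- function(class, condition, fold) {
  low_pvr <- grepl("^low_pvr", condition)
  high_inr <- grepl("high_inr$", condition)
  low_ecr <- grepl("low_ecr$", condition)
  switch(class,
    null = 1,
    # insulin-responsive: moved by InR stimulation in either background
    inr_up = if (high_inr) fold else 1,
    inr_down = if (high_inr) 1 / fold else 1,
    # receptor-dependent: lost in every low-Pvr state, insulin or not
    pvr = if (low_pvr) 1 / fold else 1,
    # common target: lost on receptor silencing, restored by insulin
    common = if (low_pvr && !high_inr) 1 / fold else 1,
    # ecdysone-receptor-responsive: moved by EcR knockdown
    ecr_up = if (low_ecr) fold else 1,
    ecr_down = if (low_ecr) 1 / fold else 1
  )
}

#' Expected differential-set membership implied by the planted classes
#'
#' Derives, in closed form from the noise-free effect model, which planted
#' sites each differential-set operation should return. This is the oracle
#' against which pipeline recovery is measured: it applies the same ratio
#' logic as the set operations but to the exact planted effect multipliers.
#'
#' @param truth Truth tibble from [generate_phospho_experiment()].
#' @param fold The planted `effect_fold`.
#' @param threshold The fold-change calling threshold.
#' @return `truth` with logical columns `inr_up_high_pvr`,
#'   `inr_down_high_pvr`, `inr_up_low_pvr`, `ecr_up_high_pvr`,
#'   `ecr_down_high_pvr`, `pvr_set`, `common_set`, `pvr_only`, `inr_only`.
#' @export
planted_set_truth <- function(truth, fold = 2.5, threshold = 1.5) {
  eff <- function(cond) {
    vapply(truth$class, planted_effect, numeric(1),
           condition = cond, fold = fold)
  }
  e <- lapply(setNames(CONDITIONS, CONDITIONS), eff)
  up <- function(num, den) e[[num]] / e[[den]] > threshold
  down <- function(num, den) e[[num]] / e[[den]] < 1 / threshold
  pvr_set <- down("low_pvr_low_inr", "high_pvr_low_inr")
  common <- (pvr_set & up("low_pvr_high_inr", "low_pvr_low_inr")) |
    (up("low_pvr_low_inr", "high_pvr_low_inr") &
       down("low_pvr_high_inr", "low_pvr_low_inr"))
  dplyr::mutate(
    truth,
    inr_up_high_pvr = up("high_pvr_high_inr", "high_pvr_low_inr"),
    inr_down_high_pvr = down("high_pvr_high_inr", "high_pvr_low_inr"),
    inr_up_low_pvr = up("low_pvr_high_inr", "low_pvr_low_inr"),
    ecr_up_high_pvr = up("high_pvr_low_ecr", "high_pvr_low_inr"),
    ecr_down_high_pvr = down("high_pvr_low_ecr", "high_pvr_low_inr"),
    pvr_set = pvr_set,
    common_set = common,
    pvr_only = up("high_pvr_low_inr", "low_pvr_high_inr") & !common,
    inr_only = down("high_pvr_low_inr", "low_pvr_high_inr") & !common
  )
}

#' Generate a synthetic TMT phosphoproteomics experiment
#'
#' Simulates PSM-level reporter tables for the requested experiments with
#' planted responsive site classes. True per-channel intensities are the
#' site's baseline times its class effect in the channel's condition; the
#' observed channels are the true intensities forward-mixed through the
#' impurity matrix, scaled by log-normal noise, with whole biological
#' replicates of a peptide dropped out at `dropout_rate` (their channels set
#' to zero). Decoy PSMs carry search scores from a distribution shifted well
#' below the target distribution so a 1% FDR cutoff exists.
#'
#' @param cfg A [phospho_sim_config()].
#' @param experiments Passed to [tmt_design()].
#' @return List with `psms` (PSM tibble as consumed by
#'   [quantify_phosphosites()]), `design`, `impurity_matrix` and `truth`
#'   (tibble `site_id`, `protein`, `class`).
#' @export
generate_phospho_experiment <- function(cfg = phospho_sim_config(),
                                        experiments = c("exp1", "exp2",
                                                        "exp3")) {
  stopifnot(inherits(cfg, "phospho_sim_config"))
  set.seed(cfg$seed)
  design <- tmt_design(experiments)
  n <- cfg$n_phosphosites
  fr <- cfg$planted_set_fractions
  # inr and ecr fractions split evenly between up- and down-regulated sites
  split_fr <- c(inr_up = unname(fr["inr"]) / 2,
                inr_down = unname(fr["inr"]) / 2,
                pvr = unname(fr["pvr"]),
                common = unname(fr["common"]),
                ecr_up = unname(fr["ecr"]) / 2,
                ecr_down = unname(fr["ecr"]) / 2)
  n_planted <- round(split_fr * n)
  classes <- sample(c(rep(names(n_planted), n_planted),
                      rep("null", n - sum(n_planted))))
  proteins <- sprintf("P%04d", seq_len(n))
  positions <- sample(20:800, n, replace = TRUE)
  residues <- sample(c("S", "T", "Y"), n, replace = TRUE,
                     prob = c(0.75, 0.2, 0.05))
  site_tok <- paste0(residues, positions)
  truth <- tibble::tibble(
    site_id = paste0(proteins, ":", site_tok),
    protein = proteins, class = classes
  )
  baseline <- rlnorm_cv(n, 0.8) * 1e6
  # the peptide roster covering each site is a property of the protein, so
  # it is drawn once and shared by every experiment
  n_pep <- 1 + stats::rpois(n, cfg$peptides_per_site - 1)
  idx <- rep(seq_len(n), n_pep)

  psm_rows <- list()
  for (exp_id in unique(design$experiment)) {
    des <- design[design$experiment == exp_id, ]
    n_psm <- length(idx)
    # true signal per channel: baseline x class effect in that condition
    eff <- matrix(1, n, 6)
    for (ch in 1:6) {
      eff[, ch] <- vapply(classes, planted_effect, numeric(1),
                          condition = des$condition[ch],
                          fold = cfg$effect_fold)
    }
    true_int <- baseline[idx] * eff[idx, , drop = FALSE] *
      matrix(rlnorm_cv(n_psm * 6, cfg$intensity_cv), n_psm, 6)
    # whole-replicate dropout per peptide
    for (r in unique(des$replicate)) {
      drop <- stats::runif(n_psm) < cfg$dropout_rate
      true_int[drop, which(des$replicate == r)] <- 0
    }
    observed <- t(cfg$impurity_matrix %*% t(true_int))
    colnames(observed) <- TMT_CHANNELS
    targets <- tibble::tibble(
      peptide = sprintf("PEP_%s_%d", proteins[idx],
                        stats::ave(idx, idx, FUN = seq_along)),
      protein = proteins[idx],
      site_positions = site_tok[idx],
      ascore = 13 + stats::rexp(n_psm, 1 / 10),
      isolation_specificity = 0.76 + 0.24 * stats::runif(n_psm),
      search_score = stats::rnorm(n_psm, mean = 4, sd = 1),
      is_decoy = FALSE,
      experiment = exp_id
    )
    targets <- dplyr::bind_cols(targets, tibble::as_tibble(observed))
    n_decoy <- round(cfg$decoy_fraction * n_psm)
    if (n_decoy > 0) {
      decoys <- tibble::tibble(
        peptide = sprintf("DECOY_%05d", seq_len(n_decoy)),
        protein = sprintf("rev_P%04d", seq_len(n_decoy)),
        site_positions = "S1",
        ascore = 13 + stats::rexp(n_decoy, 1 / 10),
        isolation_specificity = 0.76 + 0.24 * stats::runif(n_decoy),
        search_score = stats::rnorm(n_decoy, mean = 0, sd = 1),
        is_decoy = TRUE,
        experiment = exp_id
      )
      dmat <- matrix(rlnorm_cv(n_decoy * 6, cfg$intensity_cv) * 1e4,
                     n_decoy, 6, dimnames = list(NULL, TMT_CHANNELS))
      decoys <- dplyr::bind_cols(decoys, tibble::as_tibble(dmat))
      targets <- dplyr::bind_rows(targets, decoys)
    }
    psm_rows[[exp_id]] <- targets
  }
  list(
    psms = dplyr::bind_rows(psm_rows),
    design = design,
    impurity_matrix = cfg$impurity_matrix,
    truth = truth
  )
}

#' Generate a synthetic protein-complex library
#'
#' Draws `n_complexes` complexes from a gene universe. A `planted_fraction`
#' of complexes is enriched: their members are sampled preferentially from
#' the genes with the largest absolute scores; the rest are uniform draws.
#'
#' @param gene_scores Tibble `gene_id`, `score` defining the universe.
#' @param n_complexes Number of complexes.
#' @param size_range Integer range of complex sizes (inclusive).
#' @param planted_fraction Fraction of complexes planted as enriched.
#' @param seed Integer seed.
#' @return List with `complexes` (tibble `complex_id`, `gene_id`) and
#'   `truth` (tibble `complex_id`, `planted` logical).
#' @export
generate_complex_library <- function(gene_scores, n_complexes = 50,
                                     size_range = c(3, 8),
                                     planted_fraction = 0.2, seed = 1) {
  check_columns(gene_scores, c("gene_id", "score"))
  universe <- gene_scores$gene_id
  if (length(universe) == 0 || max(size_range) > length(universe)) {
    rlang::abort("size_range exceeds the gene universe",
                 class = "sensimod_config_error")
  }
  set.seed(seed)
  planted <- stats::runif(n_complexes) < planted_fraction
  # planted complexes oversample strong phenotypes
  w <- abs(gene_scores$score)
  w_planted <- (w + 1e-9)^3
  members <- lapply(seq_len(n_complexes), function(i) {
    size <- sample(seq(size_range[1], size_range[2]), 1)
    if (planted[i]) {
      sample(universe, size, prob = w_planted)
    } else {
      sample(universe, size)
    }
  })
  complexes <- tibble::tibble(
    complex_id = rep(sprintf("cpx%03d", seq_len(n_complexes)),
                     lengths(members)),
    gene_id = unlist(members)
  )
  list(complexes = complexes,
       truth = tibble::tibble(complex_id = sprintf("cpx%03d",
                                                   seq_len(n_complexes)),
                              planted = planted))
}
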