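# shared fixture builders; all fixtures are generated in code

# one plate x one condition x one replicate with explicit control readings
tiny_plate <- function(controls = c(90, 100, 110), candidates = c(120),
                       condition = "sensitized", replicate = 1L,
                       plate_id = 1L) {
  n_c <- length(controls)
  n_a <- length(candidates)
  tibble::tibble(
    plate_id = plate_id,
    well = sprintf("W%02d", seq_len(n_c + n_a)),
    condition = condition,
    replicate = replicate,
    amplicon_id = c(rep(NA_character_, n_c), sprintf("amp%02d", seq_len(n_a))),
    is_control = c(rep(TRUE, n_c), rep(FALSE, n_a)),
    reading = c(controls, candidates)
  )
}

# paired-background readings for the same plate layout
tiny_screen <- function(controls = c(90, 100, 110),
                        sensitized = c(120, 80),
                        control_bg = c(100, 100)) {
  dplyr::bind_rows(
    tiny_plate(controls, sensitized, condition = "sensitized"),
    tiny_plate(controls, control_bg, condition = "control")
  )
}

# minimal PSM table for one experiment; intensities given as a matrix
tiny_psms <- function(intensities, peptide = NULL, protein = "P1",
                      site_positions = "S10", ascore = 20,
                      isolation = 0.9, score = 5, is_decoy = FALSE,
                      experiment = "exp1") {
  m <- matrix(intensities, ncol = 6)
  n <- nrow(m)
  colnames(m) <- paste0("i", 126:131)
  if (is.null(peptide)) peptide <- sprintf("PEP%02d", seq_len(n))
  dplyr::bind_cols(
    tibble::tibble(
      peptide = peptide,
      protein = rep_len(protein, n),
      site_positions = rep_len(site_positions, n),
      ascore = rep_len(ascore, n),
      isolation_specificity = rep_len(isolation, n),
      search_score = rep_len(score, n),
      is_decoy = rep_len(is_decoy, n),
      experiment = rep_len(experiment, n)
    ),
    tibble::as_tibble(m)
  )
}

# site x condition table with named condition columns
tiny_sites <- function(...) {
  vals <- list(...)
  n <- length(vals[[1]])
  tibble::tibble(site_id = sprintf("P%02d:S%d", seq_len(n), seq_len(n)), !!!vals)
}

# map generator class labels onto the hit-calling vocabulary
screen_truth_classes <- function(truth) {
  truth$class <- c(suppressor = "Suppressor", enhancer = "Enhancer",
                   upstream = "Upstream", null = "NotHit")[truth$class]
  truth
}

# ten well-separated planted profile groups over the six conditions: every
# pattern holds two induced (2x), two repressed (0.5x) and two unchanged
# conditions, so each row median is ~1 and cluster scatter is comparable
planted_profiles <- function(n_per_cluster = 30, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  patterns <- matrix(c(
    2, 2, 1, 1, 0.5, 0.5,
    1, 1, 2, 2, 0.5, 0.5,
    0.5, 0.5, 2, 2, 1, 1,
    0.5, 0.5, 1, 1, 2, 2,
    1, 1, 0.5, 0.5, 2, 2,
    2, 2, 0.5, 0.5, 1, 1,
    2, 0.5, 2, 0.5, 1, 1,
    0.5, 2, 1, 2, 0.5, 1,
    1, 2, 0.5, 1, 2, 0.5,
    2, 1, 1, 0.5, 0.5, 2
  ), nrow = 10, byrow = TRUE)
  n <- 10 * n_per_cluster
  cl <- rep(seq_len(10), each = n_per_cluster)
  x <- patterns[cl, ] + matrix(rnorm(n * 6, 0, noise_sd), n, 6)
  x[x <= 0] <- 1e-3
  sites <- tibble::as_tibble(x, .name_repair = ~sensimod:::CONDITIONS)
  sites <- dplyr::bind_cols(
    tibble::tibble(site_id = sprintf("prof%03d", seq_len(n))), sites)
  list(sites = sites, cluster = cl)
}

# three well-separated signature groups on the (z_sensitized, z_control,
# zdiff) plane, one per modifier class prototype
planted_signatures <- function(n_per_class = 40, noise_sd = 0.4, seed = 1) {
  set.seed(seed)
  proto <- rbind(
    Suppressor = c(10, 0),
    Enhancer = c(-10, 0),
    Upstream = c(0, -10)
  )
  cls <- rep(rownames(proto), each = n_per_class)
  z <- proto[cls, ] + matrix(rnorm(3 * n_per_class * 2, 0, noise_sd),
                             ncol = 2)
  tibble::tibble(
    amplicon_id = sprintf("sig%03d", seq_along(cls)),
    truth = cls,
    z_sensitized = z[, 1],
    z_control = z[, 2],
    zdiff = z[, 1] - z[, 2]
  )
}
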