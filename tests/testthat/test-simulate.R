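test_that("generators are deterministic under a fixed seed", {
  cfg <- screen_sim_config(n_plates = 1, seed = 12)
  expect_identical(generate_screen_plates(cfg), generate_screen_plates(cfg))
  pcfg <- phospho_sim_config(n_phosphosites = 40, seed = 12)
  expect_identical(generate_phospho_experiment(pcfg),
                   generate_phospho_experiment(pcfg))
  genes <- tibble::tibble(gene_id = letters[1:20], score = 1:20)
  expect_identical(generate_complex_library(genes, n_complexes = 5, seed = 3),
                   generate_complex_library(genes, n_complexes = 5, seed = 3))
})

test_that("screen layout invariants hold", {
  cfg <- screen_sim_config(n_plates = 2, seed = 5)
  sim <- generate_screen_plates(cfg)
  counts <- sim$readings |>
    dplyr::group_by(plate_id, condition, replicate) |>
    dplyr::summarise(n_ctrl = sum(is_control), n = dplyr::n(),
                     .groups = "drop")
  expect_true(all(counts$n_ctrl == cfg$n_control_wells))
  expect_true(all(counts$n == cfg$wells_per_plate))
  expect_true(all(sim$readings$reading > 0))
  # every amplicon appears once per condition x replicate
  per_amp <- sim$readings |>
    dplyr::filter(!is.na(amplicon_id)) |>
    dplyr::count(amplicon_id, condition, replicate)
  expect_true(all(per_amp$n == 1))
})

test_that("an all-null screen has centered zdiff and calibrated tails", {
  cfg <- screen_sim_config(
    n_plates = 2,
    class_fractions = c(suppressor = 0, enhancer = 0, upstream = 0, null = 1),
    seed = 31
  )
  merged <- score_screen(generate_screen_plates(cfg)$readings)$merged
  # candidate z's on a plate share the control mean/sd estimate, so the
  # plate-mean zdiff carries a common shift of sd ~ sqrt(2/n_controls)
  expect_lt(abs(mean(merged$zdiff)), 0.4)
  # two-sided tail mass beyond the hit cutoffs stays within binomial error
  # of the empirical null rate (~6% for duplicate plates, see scoring model)
  frac_hits <- mean(abs(merged$zdiff) >= 2)
  expect_lt(frac_hits, 0.12)
})

test_that("invalid configurations are rejected", {
  expect_error(screen_sim_config(class_fractions = c(suppressor = 0.5,
                                                     enhancer = 0.5,
                                                     upstream = 0.5,
                                                     null = -0.5)),
               class = "sensimod_config_error")
  expect_error(screen_sim_config(n_control_wells = 1),
               class = "sensimod_config_error")
  expect_error(phospho_sim_config(effect_fold = 0.9),
               class = "sensimod_config_error")
  expect_error(phospho_sim_config(impurity_matrix = diag(5)),
               class = "sensimod_config_error")
  genes <- tibble::tibble(gene_id = letters[1:4], score = 1:4)
  expect_error(generate_complex_library(genes, size_range = c(2, 10)),
               class = "sensimod_config_error")
})

test_that("identity impurities and zero noise give observed = true intensities", {
  cfg <- phospho_sim_config(n_phosphosites = 30, intensity_cv = 1e-12,
                            dropout_rate = 0, decoy_fraction = 0,
                            impurity_matrix = diag(6), seed = 3)
  ph <- generate_phospho_experiment(cfg, experiments = "exp1")
  v <- as.matrix(ph$psms[, paste0("i", 126:131)])
  # true intensity = site baseline x class effect; replicate channels of the
  # same condition must be identical with zero noise
  expect_equal(v[, 1], v[, 2], tolerance = 1e-6)
  expect_equal(v[, 3], v[, 4], tolerance = 1e-6)
})

test_that("unmixing generated intensities recovers truth under zero noise", {
  cfg <- phospho_sim_config(n_phosphosites = 25, intensity_cv = 1e-12,
                            dropout_rate = 0, decoy_fraction = 0, seed = 4)
  ph <- generate_phospho_experiment(cfg, experiments = "exp2")
  observed <- as.matrix(ph$psms[, paste0("i", 126:131)])
  unmixed <- correct_impurities(observed, ph$impurity_matrix)
  # forward model consistency: replicate channels equal after unmixing and
  # the planted fold shows up exactly between conditions
  expect_equal(unmixed[, 1] / unmixed[, 2], rep(1, nrow(unmixed)),
               tolerance = 1e-6)
  tt <- ph$truth
  null_rows <- ph$psms$protein %in% tt$protein[tt$class == "null"]
  expect_equal(unmixed[null_rows, 3] / unmixed[null_rows, 1],
               rep(1, sum(null_rows)), tolerance = 1e-6)
})

test_that("zero dropout leaves no peptide excluded downstream", {
  cfg <- phospho_sim_config(n_phosphosites = 40, dropout_rate = 0, seed = 6)
  ph <- generate_phospho_experiment(cfg, experiments = c("exp1", "exp2"))
  q <- quantify_phosphosites(ph$psms, ph$design, ph$impurity_matrix)
  expect_length(q$excluded_peptides, 0)
})

test_that("decoy scores sit below target scores so a 1% FDR cutoff exists", {
  ph <- generate_phospho_experiment(
    phospho_sim_config(n_phosphosites = 150, seed = 7), experiments = "exp1")
  res <- fdr_threshold(apply_psm_filters(ph$psms), fdr = 0.01)
  expect_true(is.finite(res$cutoff))
  expect_gt(nrow(res$accepted), 0.5 * sum(!ph$psms$is_decoy))
})

test_that("a complex spanning the whole universe is never enriched", {
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:12),
                          score = rnorm(12))
  cx <- tibble::tibble(complex_id = "all", gene_id = genes$gene_id)
  res <- complex_enrichment(cx, genes, n_random = 50, seed = 2)
  expect_equal(res$p_value, 1)
})

test_that("planted complexes oversample strong-phenotype genes", {
  set.seed(8)
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                          score = c(rep(5, 10), rep(0.1, 90)))
  lib <- generate_complex_library(genes, n_complexes = 60,
                                  planted_fraction = 0.5, seed = 8)
  sc <- complex_scores(lib$complexes, genes) |>
    dplyr::inner_join(lib$truth, by = "complex_id")
  expect_gt(mean(sc$score[sc$planted]), mean(sc$score[!sc$planted]))
})
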