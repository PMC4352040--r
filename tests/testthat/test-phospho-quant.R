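test_that("PSM quality filters are strict at their boundaries", {
  psms <- tiny_psms(matrix(1, 4, 6))
  psms$ascore <- c(13, 14, 20, NA)
  psms$isolation_specificity <- c(0.9, 0.75, 0.76, 0.9)
  expect_warning(kept <- apply_psm_filters(psms), "missing AScore")
  # ascore exactly 13 and isolation exactly 0.75 are both excluded
  expect_equal(kept$peptide, "PEP03")
  expect_equal(attr(kept, "n_missing_ascore"), 1L)
})

test_that("FDR cutoff equals the exhaustive scan oracle on 1000 PSMs", {
  set.seed(31)
  n_t <- 900
  n_d <- 100
  psms <- tibble::tibble(
    search_score = c(rnorm(n_t, 3.5, 1.2), rnorm(n_d, 0, 1)),
    is_decoy = rep(c(FALSE, TRUE), c(n_t, n_d))
  )
  res <- fdr_threshold(psms, fdr = 0.01)
  # oracle: brute-force scan over every distinct score as candidate cutoff
  cuts <- sort(unique(psms$search_score))
  ok <- vapply(cuts, function(ct) {
    acc <- psms[psms$search_score >= ct, ]
    sum(acc$is_decoy) / max(sum(!acc$is_decoy), 1) <= 0.01 &
      sum(!acc$is_decoy) > 0
  }, logical(1))
  oracle_cutoff <- min(cuts[ok])
  expect_equal(res$cutoff, oracle_cutoff)
  expect_equal(nrow(res$accepted),
               sum(!psms$is_decoy & psms$search_score >= oracle_cutoff))
  expect_false(any(res$accepted$is_decoy))
})

test_that("FDR edge cases: no decoys accepts all, all decoys accepts none", {
  targets <- tibble::tibble(search_score = rnorm(10), is_decoy = FALSE)
  expect_equal(nrow(fdr_threshold(targets)$accepted), 10)
  decoys <- tibble::tibble(search_score = rnorm(10), is_decoy = TRUE)
  expect_equal(nrow(fdr_threshold(decoys)$accepted), 0)
})

test_that("impurity correction solves the mixing system", {
  expect_equal(correct_impurities(c(1, 2, 3, 4, 5, 6), diag(6)),
               c(1, 2, 3, 4, 5, 6))
  # 5% one-way leak from channel 1 into channel 2
  m <- diag(6)
  m[2, 1] <- 0.05
  m[1, 1] <- 0.95
  observed <- c(95, 5, 0, 0, 0, 0)
  expect_equal(correct_impurities(observed, m), c(100, 0, 0, 0, 0, 0),
               tolerance = 1e-9)
  expect_error(correct_impurities(rep(1, 6), matrix(1, 6, 6)),
               class = "sensimod_config_error")
})

test_that("forward-mix then correct round-trips random non-negative vectors", {
  set.seed(17)
  m <- default_impurity_matrix(0.03)
  for (i in 1:20) {
    true <- runif(6) * 10^runif(6, 2, 6)
    observed <- as.vector(m %*% true)
    back <- correct_impurities(observed, m)
    expect_equal(back, true, tolerance = 1e-9)
  }
})

test_that("channel normalization equalizes totals and is idempotent", {
  set.seed(23)
  x <- matrix(rexp(60, 1e-4), 10, 6)
  n1 <- normalize_channels(x)
  expect_equal(unname(colSums(n1)), rep(mean(colSums(x)), 6),
               tolerance = 1e-9)
  expect_equal(normalize_channels(n1), n1, tolerance = 1e-12)
  # already-balanced tables pass through unchanged
  bal <- matrix(1, 3, 6)
  expect_equal(normalize_channels(bal), bal, tolerance = 1e-12)
  expect_error(normalize_channels(cbind(matrix(1, 3, 5), 0)),
               class = "sensimod_degenerate_channel")
})

test_that("single-replicate peptides are excluded and averages computed", {
  quant <- tibble::tibble(
    peptide_key = c("both", "both", "both", "both", "solo", "solo"),
    condition = c("A", "A", "B", "B", "A", "B"),
    replicate = c(1L, 2L, 1L, 2L, 1L, 1L),
    intensity = c(2, 4, 10, 20, 7, 9)
  )
  res <- aggregate_replicates(quant)
  expect_equal(res$excluded, "solo")
  a <- res$averaged
  expect_equal(a$intensity[a$peptide_key == "both" & a$condition == "A"], 3)
  expect_equal(a$intensity[a$peptide_key == "both" & a$condition == "B"], 15)
})

test_that("single-run designs pass through unchanged", {
  quant <- tibble::tibble(
    peptide_key = rep("p", 3),
    condition = c("A", "B", "C"),
    replicate = 1L,
    intensity = c(5, 6, 7)
  )
  res <- aggregate_replicates(quant)
  expect_equal(res$excluded, character(0))
  expect_equal(res$averaged$intensity, c(5, 6, 7))
})

test_that("site collapsing sums covering peptides and splits multi-site peptides", {
  pep <- tibble::tibble(
    protein = c("P1", "P1", "P2"),
    site_positions = c("S10", "S10", "S5;T9"),
    condition = "A",
    intensity = c(3, 4, 10)
  )
  sites <- collapse_to_phosphosites(pep)
  expect_equal(sites$intensity[sites$site_id == "P1:S10"], 7)
  expect_setequal(sites$site_id[sites$protein == "P2"], c("P2:S5", "P2:T9"))
  expect_equal(sites$intensity[sites$site_id == "P2:S5"], 10)
  expect_warning(
    collapse_to_phosphosites(
      tibble::tibble(protein = "P", site_positions = "bad",
                     condition = "A", intensity = 1)),
    "unparseable")
})

test_that("quantification is invariant to PSM row order", {
  ph <- generate_phospho_experiment(
    phospho_sim_config(n_phosphosites = 60, seed = 8), experiments = "exp1")
  q1 <- quantify_phosphosites(ph$psms, ph$design, ph$impurity_matrix)
  set.seed(1)
  shuffled <- ph$psms[sample(nrow(ph$psms)), ]
  q2 <- quantify_phosphosites(shuffled, ph$design, ph$impurity_matrix)
  s1 <- dplyr::arrange(q1$sites_long, site_id, condition)
  s2 <- dplyr::arrange(q2$sites_long, site_id, condition)
  expect_equal(s1, s2)
})

test_that("sites detected in both replicates are exactly those reported", {
  cfg <- phospho_sim_config(n_phosphosites = 80, dropout_rate = 0.3, seed = 5)
  ph <- generate_phospho_experiment(cfg, experiments = "exp1")
  q <- quantify_phosphosites(ph$psms, ph$design, ph$impurity_matrix)
  long <- q$sites_long
  reported <- unique(long$site_id[!is.na(long$intensity)])
  # every reported intensity must rest on >= 2 detected replicates:
  # reconstruct detection from the raw generator output
  raw <- ph$psms[!ph$psms$is_decoy, ]
  raw$site_id <- paste0(raw$protein, ":", raw$site_positions)
  chans <- as.matrix(raw[, paste0("i", 126:131)])
  # undo the channel mixing independently; dropped channels return to ~0
  unmixed <- t(solve(ph$impurity_matrix, t(chans)))
  des <- ph$design
  rep_detected <- sapply(unique(des$replicate), function(r) {
    idx <- which(des$replicate == r)
    rowSums(unmixed[, idx, drop = FALSE] > 1e-3) > 0
  })
  # peptide detected in both replicates (generator drops whole replicates)
  ok_pep <- rowSums(rep_detected) >= 2
  oracle_sites <- unique(raw$site_id[ok_pep])
  expect_true(all(reported %in% oracle_sites))
})

test_that("with no dropout every planted site is quantified in all conditions", {
  cfg <- phospho_sim_config(n_phosphosites = 50, dropout_rate = 0, seed = 2)
  ph <- generate_phospho_experiment(cfg, experiments = c("exp1", "exp2"))
  q <- quantify_phosphosites(ph$psms, ph$design, ph$impurity_matrix)
  expect_equal(nrow(q$sites), 50)
  expect_false(any(is.na(as.matrix(q$sites[, sensimod:::CONDITIONS]))))
  expect_equal(length(q$excluded_peptides), 0)
})
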