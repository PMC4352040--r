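test_that("fold-change calls are strict at the 1.5 boundary", {
  sites <- tiny_sites(a = c(3.2, 3.0, 2.0, 2.0, NA),
                      b = c(2.0, 2.0, 3.2, 2.0, 1.0))
  calls <- fold_change_call(sites, "a", "b")
  expect_equal(as.character(calls$direction),
               c("up", "unchanged", "down", "unchanged", "not_callable"))
  expect_equal(calls$ratio[1], 1.6)
  # ratio exactly 1.5 (and exactly 1/1.5) is unchanged
  edge <- tiny_sites(a = c(1.5, 1), b = c(1, 1.5))
  expect_equal(as.character(fold_change_call(edge, "a", "b")$direction),
               c("unchanged", "unchanged"))
})

test_that("call categories partition every site for any comparison", {
  set.seed(3)
  sites <- tiny_sites(a = c(runif(50, 0.5, 5), NA, 0),
                      b = c(runif(51, 0.5, 5), 2))
  calls <- fold_change_call(sites, "a", "b")
  expect_equal(sum(table(calls$direction)), nrow(sites))
})

test_that("raising the fold threshold never enlarges the up or down sets", {
  set.seed(4)
  sites <- tiny_sites(a = runif(200, 0.5, 5), b = runif(200, 0.5, 5))
  c15 <- fold_change_call(sites, "a", "b", threshold = 1.5)
  c20 <- fold_change_call(sites, "a", "b", threshold = 2.0)
  expect_lte(sum(c20$direction == "up"), sum(c15$direction == "up"))
  expect_lte(sum(c20$direction == "down"), sum(c15$direction == "down"))
  expect_true(all(c20$site_id[c20$direction == "up"] %in%
                    c15$site_id[c15$direction == "up"]))
})

test_that("differential sets obey their set algebra", {
  ph <- generate_phospho_experiment(
    phospho_sim_config(n_phosphosites = 200, seed = 6), experiments = "exp3")
  sites <- quantify_phosphosites(ph$psms, ph$design,
                                 ph$impurity_matrix)$sites
  pvr <- define_pvr_set(sites)
  common <- define_common_set(sites)
  receptor <- define_receptor_specific_sets(sites,
                                            common_sites = common$site_id)
  # every down-restored common site is Pvr-dependent by construction
  down_common <- common$site_id[common$pvr_direction == "down"]
  expect_true(all(down_common %in% pvr))
  # receptor-specific labels exclude the common set and each other
  expect_length(intersect(receptor$site_id, common$site_id), 0)
  expect_length(intersect(receptor$site_id[receptor$label == "Pvr_only"],
                          receptor$site_id[receptor$label == "InR_only"]), 0)
  # the insulin-up and insulin-down sets are disjoint
  inr <- define_inr_set(sites, "low_pvr")
  expect_length(intersect(inr$site_id[inr$direction == "up"],
                          inr$site_id[inr$direction == "down"]), 0)
})

test_that("shared mode relaxes reciprocal common-set membership", {
  ph <- generate_phospho_experiment(
    phospho_sim_config(n_phosphosites = 150, seed = 9), experiments = "exp3")
  sites <- quantify_phosphosites(ph$psms, ph$design,
                                 ph$impurity_matrix)$sites
  recip <- define_common_set(sites, mode = "reciprocal")
  shared <- define_common_set(sites, mode = "shared")
  expect_true(all(recip$site_id %in% shared$site_id))
})

test_that("rescue fraction counts insulin-restored receptor-dependent sites", {
  sites <- tiny_sites(
    low_pvr_low_inr = c(1, 1, 1),
    high_pvr_low_inr = c(2, 2, 2),     # all three in the Pvr set (ratio 0.5)
    low_pvr_high_inr = c(2, 2, 1)      # two restored by insulin
  )
  expect_equal(rescue_fraction(sites), 2 / 3)
  none <- tiny_sites(low_pvr_low_inr = c(2), high_pvr_low_inr = c(2),
                     low_pvr_high_inr = c(2))
  expect_error(rescue_fraction(none), class = "sensimod_undefined_rate")
})

test_that("k-means trivia: k = 1 pools everything, duplicates share labels", {
  prof <- planted_profiles(n_per_cluster = 3, noise_sd = 0.01, seed = 2)
  one <- kmeans_profiles(prof$sites, k = 1, seed = 1, nstart = 2)
  expect_equal(unique(one$clusters$cluster), 1)
  dup <- prof$sites[rep(1, 5), ]
  dup$site_id <- sprintf("dup%d", 1:5)
  both <- dplyr::bind_rows(prof$sites, dup)
  fit <- kmeans_profiles(both, k = 3, seed = 1, nstart = 5)
  labs <- fit$clusters$cluster[grepl("^dup", fit$clusters$site_id)]
  expect_equal(length(unique(labs)), 1)
  expect_error(kmeans_profiles(prof$sites[1:4, ], k = 10),
               class = "sensimod_config_error")
})

test_that("k-means recovers planted well-separated profile groups", {
  aris <- vapply(1:3, function(s) {
    prof <- planted_profiles(n_per_cluster = 25, noise_sd = 0.05, seed = s)
    fit <- kmeans_profiles(prof$sites, k = 10, seed = s)
    labels <- fit$clusters$cluster[match(prof$sites$site_id,
                                         fit$clusters$site_id)]
    adjusted_rand_index(labels, prof$cluster)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("k-means is deterministic under a fixed seed, and tidiers work", {
  prof <- planted_profiles(n_per_cluster = 5, seed = 4)
  f1 <- kmeans_profiles(prof$sites, k = 4, seed = 9, nstart = 5)
  f2 <- kmeans_profiles(prof$sites, k = 4, seed = 9, nstart = 5)
  expect_equal(tidy(f1), tidy(f2))
  expect_equal(glance(f1)$k, 4)
  expect_s3_class(autoplot(f1), "ggplot")
})
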