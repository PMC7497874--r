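test_that("generation is deterministic under a fixed seed", {
  spec <- cohort_spec(n_egos = 5, seed = 91)
  a <- generate_ego(spec, seed = 42)
  b <- generate_ego(spec, seed = 42)
  expect_identical(a, b)

  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("file", f))
  }
  # a different seed changes the draw
  expect_false(identical(generate_ego(spec, seed = 43), a))
})

test_that("a degenerate roster-size distribution pins every roster at the cap", {
  spec <- cohort_spec(n_egos = 8, seed = 5,
                      roster_size_distribution = c(0, 0, 0, 0, 0, 1))
  cohort <- generate_cohort(spec)
  sizes <- vapply(cohort$ya_surveys, function(s) nrow(s$alters), integer(1))
  expect_true(all(sizes == 5))
  expect_equal(cohort$manifest$total_alters, 40)
})

test_that("generated surveys are valid and respect the cap", {
  spec <- cohort_spec(n_egos = 10, seed = 17)
  cohort <- generate_cohort(spec)
  for (s in c(cohort$ya_surveys, cohort$pa_surveys)) {
    expect_s3_class(validate_ego_survey(s), "ego_survey")
    expect_lte(nrow(s$alters), spec$roster_cap)
  }
})

test_that("role composition recovers the generating probabilities", {
  spec <- cohort_spec(n_egos = 250, seed = 1234, pair_fraction = 0)
  cohort <- generate_cohort(spec)
  nets <- lapply(cohort$ya_surveys, as_ego_network)
  cs <- cohort_summary(nets)
  n_alters <- cohort$manifest$total_alters
  for (cl in role_classes()) {
    p <- spec$role_probs[[cl]]
    se <- sqrt(p * (1 - p) / n_alters)
    # per-ego percentages average close to the multinomial expectation;
    # the alter-count SE bounds the deviation generously (3 SE)
    expect_lt(abs(cs$mean_role_pct[[cl]] / 100 - p), 3 * se + 0.02)
  }
})

test_that("support prevalence recovers a flat generating probability", {
  flat <- matrix(0.5, 3, 6, dimnames = list(role_classes(), support_types()))
  spec <- cohort_spec(n_egos = 220, seed = 99, pair_fraction = 0,
                      support_probs = flat)
  cohort <- generate_cohort(spec)
  cs <- cohort_summary(lapply(cohort$ya_surveys, as_ego_network))
  n <- cohort$manifest$total_alters
  se <- sqrt(0.5 * 0.5 / n)
  for (s in support_types()) {
    expect_lt(abs(cs$mean_support_pct[[s]] / 100 - 0.5), 3 * se + 0.02)
  }
})

test_that("mean density recovers a uniform tie probability", {
  p <- 0.3
  flat_ties <- matrix(p, 3, 3, dimnames = list(role_classes(),
                                               role_classes()))
  spec <- cohort_spec(n_egos = 220, seed = 2718, pair_fraction = 0,
                      tie_probs = flat_ties)
  cohort <- generate_cohort(spec)
  dens <- vapply(cohort$ya_surveys, function(s)
    network_density(as_ego_network(s)), numeric(1))
  n_pairs <- sum(vapply(cohort$ya_surveys, function(s)
    choose(nrow(s$alters), 2), numeric(1)))
  se <- sqrt(p * (1 - p) / n_pairs)
  expect_lt(abs(mean(dens, na.rm = TRUE) - p), 3 * se + 0.02)
})

test_that("full overlap with a smaller parent roster yields the subset motif", {
  spec <- cohort_spec(seed = 31, overlap_prob = 1,
                      roster_size_distribution = c(0, 0, 0, 0, 0, 1),
                      parent_named_prob = 0)
  for (rep in 1:10) {
    mp <- generate_matched_pair(spec, pair_id = paste0("S", rep))
    duo <- merge_duocentric(mp$ya, mp$pa)
    ou <- overlap_and_unique(duo)
    expect_equal(ou$unique_pa, 0)
    expect_equal(characteristics(duo)[["parent_network_is_subset"]], "yes")
  }
})

test_that("discrepancy rate over shared reported pairs matches the dial", {
  # discrepancy_prob = 0: clean duplication, empty logs
  spec0 <- cohort_spec(seed = 61, discrepancy_prob = 0, overlap_prob = 0.8,
                       roster_size_distribution = c(0, 0, 0, 0, 0, 1))
  for (rep in 1:10) {
    mp <- generate_matched_pair(spec0, pair_id = paste0("D", rep))
    expect_equal(nrow(merge_duocentric(mp$ya, mp$pa)$discrepancies), 0)
  }

  # discrepancy_prob = 0.5: every flip produces a conflict, so the observed
  # conflict rate over doubly-observed pairs estimates 0.5
  spec5 <- cohort_spec(seed = 62, discrepancy_prob = 0.5, overlap_prob = 0.9,
                       roster_size_distribution = c(0, 0, 0, 0, 0, 1),
                       parent_roster_distribution = c(0, 0, 0, 0, 1, 0))
  n_disc <- 0; n_shared <- 0
  for (rep in 1:80) {
    mp <- generate_matched_pair(spec5, pair_id = paste0("E", rep))
    duo <- merge_duocentric(mp$ya, mp$pa)
    both_seen <- nrow(duo$nodes[!is.na(duo$nodes$ya_rank) &
                                  !is.na(duo$nodes$pa_rank), ])
    n_shared_pairs <- choose(both_seen, 2)
    n_shared <- n_shared + n_shared_pairs
    n_disc <- n_disc + nrow(duo$discrepancies)
  }
  se <- sqrt(0.25 / n_shared)
  expect_gt(n_shared, 100)
  expect_lt(abs(n_disc / n_shared - 0.5), 3 * se)
})

test_that("matched pairs exercise exact-string matching and the parent link", {
  spec <- cohort_spec(seed = 8, overlap_prob = 0.6, parent_named_prob = 1,
                      roster_size_distribution = c(0, 0, 0, 0, 0, 1))
  mp <- generate_matched_pair(spec)
  expect_true(mp$parent_named)
  expect_true(mp$parent_name %in% mp$ya$alters$label)
  expect_false(mp$parent_name %in% mp$pa$alters$label)
  duo <- merge_duocentric(mp$ya, mp$pa)
  expect_false(is.na(duo$parent_node))
  expect_equal(sum(duo$nodes$provenance == "both"), mp$n_shared)

  # name-noise mode perturbs copied labels without breaking normalization
  specn <- cohort_spec(seed = 9, overlap_prob = 1, name_noise_prob = 1,
                       roster_size_distribution = c(0, 0, 0, 0, 0, 1),
                       parent_named_prob = 0)
  mpn <- generate_matched_pair(specn)
  duon <- merge_duocentric(mpn$ya, mpn$pa)
  expect_equal(overlap_and_unique(duon)$unique_pa, 0)
})
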