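test_that("name normalization folds case, whitespace, and punctuation only", {
  expect_equal(normalize_name("Aunt  Sue "), "aunt sue")
  expect_equal(normalize_name("J. Smith"), normalize_name("J Smith"))
  expect_equal(normalize_name("o'brien, Pat"), "obrien pat")
  expect_false(normalize_name("Sue") == normalize_name("Susan"))
  expect_error(normalize_name(""), "empty")
  expect_error(normalize_name(c("A B", NA)), "empty")
})

test_that("alter matching partitions both rosters by provenance", {
  ya <- make_survey(paste("Person", 1:5), ego_id = "YA")
  pa <- make_survey(c("Person 1", "Person 9", "Person 8", "Person 7"),
                    ego_id = "PA", kind = "parent")
  m <- match_alters(ya, pa)
  expect_equal(sum(m$provenance == "both"), 1)
  expect_equal(sum(m$provenance == "ya_only"), 4)
  expect_equal(sum(m$provenance == "pa_only"), 3)
  expect_equal(nrow(m), 5 + 4 - 1)
  # every roster member appears exactly once
  expect_setequal(m$ya_rank[!is.na(m$ya_rank)], 1:5)
  expect_setequal(m$pa_rank[!is.na(m$pa_rank)], 1:4)

  # parent roster a subset of the young adult's
  sub <- study_pair_3()
  m3 <- match_alters(sub$ya, sub$pa)
  expect_equal(sum(m3$provenance == "both"), 2)
  expect_equal(sum(m3$provenance == "pa_only"), 0)

  # disjoint rosters
  dis <- match_alters(make_survey(c("A One", "B Two")),
                      make_survey(c("C Three", "D Four"), kind = "parent"))
  expect_equal(sum(dis$provenance == "both"), 0)
})

test_that("matching is exact on the normalized key, role only breaks ties", {
  ya <- make_survey(c("J. Smith", "Ann Poe"))
  pa <- make_survey(c("j smith"), kind = "parent")
  m <- match_alters(ya, pa)
  expect_equal(sum(m$provenance == "both"), 1)
  expect_equal(m$match_basis[m$provenance == "both"], "name_exact")

  # same key twice in one survey: role class disambiguates
  ya2 <- make_survey(c("Sam Gray", "Sam Gray"),
                     roles = c("family", "professional"))
  pa2 <- make_survey("Sam Gray", roles = "professional", kind = "parent")
  m2 <- match_alters(ya2, pa2)
  hit <- m2[m2$provenance == "both", ]
  expect_equal(hit$match_basis, "name_plus_role")
  expect_equal(hit$ya_rank, 2L)

  # no role separation: ambiguity error, or review flags when asked
  ya3 <- make_survey(c("Sam Gray", "Sam Gray"),
                     roles = c("family", "family"))
  expect_error(match_alters(ya3, pa2), "ambiguous")
  flagged <- match_alters(ya3, pa2, on_ambiguity = "flag")
  expect_true(any(flagged$needs_review))
  expect_equal(sum(flagged$provenance == "both"), 0)
})

test_that("conflicting reports resolve to the maximum and are logged", {
  # both respondents see the same two alters; YA says untied, parent tied
  ya <- make_survey(c("A One", "B Two"), ego_id = "YA")
  pa <- make_survey(c("A One", "B Two"), tie_pairs = list(c(1, 2)),
                    freq = 2L, ego_id = "PA", kind = "parent")
  duo <- merge_duocentric(ya, pa)
  expect_equal(nrow(duo$edges), 1)
  expect_equal(duo$edges$weight, 2L)
  expect_equal(nrow(duo$discrepancies), 1)
  expect_equal(duo$discrepancies$resolved_value, 2L)

  # swapped direction of the conflict: same merged network
  duo_sw <- merge_duocentric(
    make_survey(c("A One", "B Two"), tie_pairs = list(c(1, 2)), freq = 2L,
                ego_id = "YA"),
    make_survey(c("A One", "B Two"), ego_id = "PA", kind = "parent")
  )
  expect_equal(duo_sw$edges$weight, duo$edges$weight)
  expect_equal(duo_sw$discrepancies$resolved_value,
               duo$discrepancies$resolved_value)

  # both report untied: no edge, no discrepancy
  duo0 <- merge_duocentric(ya, make_survey(c("A One", "B Two"), ego_id = "PA",
                                           kind = "parent"))
  expect_equal(nrow(duo0$edges), 0)
  expect_equal(nrow(duo0$discrepancies), 0)

  # ordinal frequencies 2 vs 3 merge to 3
  duo23 <- merge_duocentric(
    make_survey(c("A One", "B Two"), tie_pairs = list(c(1, 2)), freq = 2L),
    make_survey(c("A One", "B Two"), tie_pairs = list(c(1, 2)), freq = 3L,
                kind = "parent")
  )
  expect_equal(duo23$edges$weight, 3L)
  expect_equal(nrow(duo23$discrepancies), 1)
})

test_that("the three study-style pairs yield exactly one discrepant tie", {
  duos <- lapply(list(study_pair_1(), study_pair_2(), study_pair_3()),
                 function(p) merge_duocentric(p$ya, p$pa))
  n_disc <- vapply(duos, function(d) nrow(d$discrepancies), integer(1))
  expect_equal(sum(n_disc), 1)
  # the discrepant pair is YA3's: parent unreported, young adult tied
  d3 <- duos[[3]]$discrepancies
  expect_equal(nrow(d3), 1)
  expect_equal(d3$pa_value, 0L)
  expect_gt(d3$ya_value, 0)
  expect_equal(d3$resolved_value, max(d3$ya_value, d3$pa_value))
})

test_that("pairs observable by neither respondent are flagged, not edges", {
  p <- study_pair_1()
  duo <- merge_duocentric(p$ya, p$pa)
  # ya-only vs pa-only alters have no possible report
  ya_only <- duo$nodes$unified_id[duo$nodes$provenance == "ya_only" &
                                    !duo$nodes$is_parent]
  pa_only <- duo$nodes$unified_id[duo$nodes$provenance == "pa_only"]
  expect_equal(nrow(duo$unobserved), length(ya_only) * length(pa_only))
  expect_true(all(duo$unobserved$reason == "unobservable"))
})

test_that("merged node count follows set arithmetic on random pairs", {
  set.seed(303)
  spec <- cohort_spec(seed = 303)
  for (rep in 1:40) {
    mp <- generate_matched_pair(spec, pair_id = paste0("P", rep))
    duo <- merge_duocentric(mp$ya, mp$pa)
    n_ya <- nrow(mp$ya$alters)
    n_pa <- nrow(mp$pa$alters)
    n_both <- length(intersect(normalize_name(mp$ya$alters$label),
                               normalize_name(mp$pa$alters$label)))
    expect_equal(nrow(duo$nodes), n_ya + n_pa - n_both)
    d <- duo$discrepancies
    if (nrow(d) > 0) {
      expect_equal(d$resolved_value, pmax(d$ya_value, d$pa_value))
    }
  }
})

test_that("merging the resolved projections reproduces the merged network", {
  set.seed(404)
  spec <- cohort_spec(seed = 404, discrepancy_prob = 0.5)
  for (rep in 1:20) {
    mp <- generate_matched_pair(spec, pair_id = paste0("P", rep))
    duo <- merge_duocentric(mp$ya, mp$pa)
    duo2 <- merge_duocentric(project_duo(duo, "ya"), project_duo(duo, "pa"),
                             parent_label = mp$pa$ego_attributes$name)
    expect_equal(resolved_edge_key(duo2), resolved_edge_key(duo))
    expect_equal(nrow(duo2$discrepancies), 0)
  }
})

test_that("the parent node exists only when the young adult named the parent", {
  p1 <- study_pair_1()
  duo1 <- merge_duocentric(p1$ya, p1$pa)
  expect_false(is.na(duo1$parent_node))
  expect_equal(duo1$nodes$label[duo1$nodes$is_parent], "Mona Reyes")
  # implied ties: parent to each parent-roster alter not already tied.
  # The shared alter is already really tied to the parent in the young
  # adult's reports, so only the three parent-only alters gain implied ties.
  implied <- duo1$edges[duo1$edges$implied, ]
  expect_equal(nrow(implied), 3)
  expect_true(all(implied$node_a == duo1$parent_node |
                    implied$node_b == duo1$parent_node))

  p3 <- study_pair_3()
  duo3 <- merge_duocentric(p3$ya, p3$pa)
  expect_true(is.na(duo3$parent_node))
  expect_false(any(duo3$edges$implied))
})
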