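# Seeded synthetic survey cohorts. The generator emulates the study design:
# a name-generator roster capped at five alters ranked by importance, roles
# drawn from {family, community, professional}, six Bernoulli support flags
# per alter conditioned on role, role-block-structured alter-alter ties
# (family ties dense, reproducing family closure), and matched young-adult /
# parent pairs with partially overlapping rosters, occasional discrepant
# shared tie reports, and a parent sometimes named by the young adult.

first_names <- c(
  "Ada", "Amir", "Ana", "Ben", "Bea", "Carl", "Cora", "Dan", "Dina", "Eli",
  "Emma", "Finn", "Gina", "Hank", "Ida", "Ivan", "Jade", "Joel", "Kara",
  "Kofi", "Lena", "Luis", "Mara", "Mateo", "Nina", "Noor", "Omar", "Opal",
  "Pia", "Quinn", "Rosa", "Sam", "Sana", "Theo", "Tess", "Umar", "Vera",
  "Wade", "Xena", "Yara", "Zane", "Zoe"
)
last_names <- c(
  "Abbott", "Baker", "Chen", "Diaz", "Ellis", "Fischer", "Garcia", "Hale",
  "Ito", "Jones", "Khan", "Lopez", "Mori", "Nunez", "Okafor", "Park",
  "Quist", "Reyes", "Silva", "Tran", "Usman", "Vance", "Webb", "Young"
)

name_pool <- function() {
  as.vector(outer(first_names, last_names, paste))
}

role_vocab <- list(
  family = c("mother", "father", "brother", "sister", "aunt", "uncle",
             "grandmother", "grandfather", "cousin"),
  community = c("friend", "neighbor", "coworker", "mentor", "roommate",
                "coach"),
  professional = c("therapist", "counselor", "job coach", "teacher",
                   "social worker")
)

default_support_probs <- function() {
  m <- rbind(
    family       = c(0.55, 0.85, 0.75, 0.50, 0.40, 0.20),
    community    = c(0.95, 0.65, 0.65, 0.10, 0.15, 0.25),
    professional = c(0.20, 0.60, 0.90, 0.05, 0.30, 0.50)
  )
  colnames(m) <- support_types()
  m
}

default_tie_probs <- function() {
  m <- matrix(c(
    0.95, 0.50, 0.40,
    0.50, 0.30, 0.20,
    0.40, 0.20, 0.20
  ), nrow = 3, byrow = TRUE,
  dimnames = list(role_classes(), role_classes()))
  m
}

#' Specification for a synthetic survey cohort
#'
#' Parameters of the generator, defaulting to the study conditions: 17 egos,
#' a five-person roster cap with mean roster size 4.88 (median 5), role mix
#' about 60/36/4 family/community/professional, role-conditioned support
#' probabilities yielding overall support prevalences near the reported
#' cohort values, role-block tie probabilities with dense family-family ties
#' (family closure), three matched parent pairs per 17 egos, and parent
#' rosters of two to four alters.
#'
#' @param n_egos Number of young-adult respondents.
#' @param roster_cap Maximum roster size (default 5).
#' @param roster_size_distribution Probabilities over roster sizes
#'   `0..roster_cap` (normalized internally).
#' @param parent_roster_distribution Same, for parent rosters.
#' @param role_probs Probabilities over [role_classes()] (normalized).
#' @param support_probs `3 x 6` matrix of Bernoulli probabilities, role
#'   class by support type.
#' @param tie_probs Symmetric `3 x 3` matrix of alter-alter tie
#'   probabilities by role-class block.
#' @param freq_probs Probabilities over ordinal frequencies `1..freq_cap`
#'   given a tie.
#' @param freq_cap Top of the ordinal frequency scale (default 3).
#' @param pair_fraction Fraction of egos with a matched parent survey.
#' @param overlap_prob Probability a parent-roster slot copies a young-adult
#'   alter (exact same name) rather than introducing a new one.
#' @param parent_named_prob Probability the young adult names the parent as
#'   an alter.
#' @param discrepancy_prob Probability a shared alter pair's parent report
#'   conflicts with the young adult's.
#' @param name_noise_prob Probability a copied (matched) alter name is
#'   perturbed with case/punctuation noise that [normalize_name()] removes;
#'   0 by default (exact strings).
#' @param seed Integer seed used by [generate_cohort()].
#' @return Validated list of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_egos = 4, seed = 11)
#' cohort <- generate_cohort(spec)
#' cohort$manifest$total_alters
cohort_spec <- function(n_egos = 17L,
                        roster_cap = 5L,
                        roster_size_distribution = c(0, 0, 0, 0, 0.12, 0.88),
                        parent_roster_distribution = c(0, 0, 1, 1, 1, 0) / 3,
                        role_probs = c(family = 61, community = 36,
                                       professional = 4) / 101,
                        support_probs = default_support_probs(),
                        tie_probs = default_tie_probs(),
                        freq_probs = c(0.25, 0.35, 0.40),
                        freq_cap = 3L,
                        pair_fraction = 3 / 17,
                        overlap_prob = 0.5,
                        parent_named_prob = 2 / 3,
                        discrepancy_prob = 0.1,
                        name_noise_prob = 0,
                        seed = 1L) {
  norm1 <- function(p) {
    stopifnot(all(p >= 0), sum(p) > 0)
    p / sum(p)
  }
  stopifnot(n_egos >= 1, roster_cap >= 1,
            length(roster_size_distribution) == roster_cap + 1,
            length(parent_roster_distribution) == roster_cap + 1,
            length(role_probs) == 3,
            identical(dim(support_probs), c(3L, 6L)),
            identical(dim(tie_probs), c(3L, 3L)),
            isTRUE(all.equal(tie_probs, t(tie_probs))),
            all(support_probs >= 0 & support_probs <= 1),
            all(tie_probs >= 0 & tie_probs <= 1),
            length(freq_probs) == freq_cap,
            pair_fraction >= 0, pair_fraction <= 1,
            overlap_prob >= 0, overlap_prob <= 1,
            parent_named_prob >= 0, parent_named_prob <= 1,
            discrepancy_prob >= 0, discrepancy_prob <= 1,
            name_noise_prob >= 0, name_noise_prob <= 1)
  rownames(support_probs) <- role_classes()
  colnames(support_probs) <- support_types()
  dimnames(tie_probs) <- list(role_classes(), role_classes())
  structure(
    list(
      n_egos = as.integer(n_egos),
      roster_cap = as.integer(roster_cap),
      roster_size_distribution = norm1(roster_size_distribution),
      parent_roster_distribution = norm1(parent_roster_distribution),
      role_probs = setNames(norm1(role_probs), role_classes()),
      support_probs = support_probs,
      tie_probs = tie_probs,
      freq_probs = norm1(freq_probs),
      freq_cap = as.integer(freq_cap),
      pair_fraction = pair_fraction,
      overlap_prob = overlap_prob,
      parent_named_prob = parent_named_prob,
      discrepancy_prob = discrepancy_prob,
      name_noise_prob = name_noise_prob,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

draw_size <- function(probs) {
  sample(seq_along(probs) - 1L, 1, prob = probs)
}

draw_freq <- function(spec) {
  sample(seq_len(spec$freq_cap), 1, prob = spec$freq_probs)
}

draw_supports <- function(spec, role_class) {
  p <- spec$support_probs[role_class, ]
  setNames(as.list(stats::runif(length(p)) < p), support_types())
}

draw_alter_row <- function(spec, label, rank, role_class = NULL) {
  role_class <- role_class %||% sample(role_classes(), 1,
                                       prob = spec$role_probs)
  tibble::tibble(
    label = label, rank = as.integer(rank),
    role_raw = sample(role_vocab[[role_class]], 1),
    role_class = role_class,
    !!!draw_supports(spec, role_class)
  )
}

draw_ties <- function(spec, alters) {
  n <- nrow(alters)
  if (n < 2) return(empty_ties())
  idx <- utils::combn(sort(alters$rank), 2)
  freq <- vapply(seq_len(ncol(idx)), function(k) {
    ra <- alters$role_class[match(idx[1, k], alters$rank)]
    rb <- alters$role_class[match(idx[2, k], alters$rank)]
    if (stats::runif(1) < spec$tie_probs[ra, rb]) draw_freq(spec) else 0L
  }, integer(1))
  tibble::tibble(a = idx[1, ], b = idx[2, ], frequency = as.integer(freq))
}

draw_ego_attributes <- function(spec, name) {
  list(
    name = name,
    gender = sample(c("man", "woman", "gender_nonconforming"), 1,
                    prob = c(0.59, 0.29, 0.12)),
    age = as.integer(min(29, max(18, round(stats::rnorm(1, 23.25, 3.6))))),
    dating = stats::runif(1) < 0.18,
    employed = stats::runif(1) < 0.29,
    college = stats::runif(1) < 0.82,
    independent_living = stats::runif(1) < 0.35
  )
}

#' Generate one synthetic egocentric survey
#'
#' Draws roster size, alter names, roles, support flags, and the full
#' tie-report matrix from a [cohort_spec()]. With `seed` given the output is
#' reproducible on its own; otherwise the current RNG stream is used (as by
#' [generate_cohort()]).
#'
#' @param spec A [cohort_spec()].
#' @param ego_id Identifier for the respondent.
#' @param reporter_kind `"young_adult"` (default) or `"parent"`.
#' @param seed Optional integer seed.
#' @return An [ego_survey()].
#' @export
generate_ego <- function(spec, ego_id = "YA1",
                         reporter_kind = "young_adult", seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  pool <- name_pool()
  picks <- sample(pool, spec$roster_cap + 1)
  n <- draw_size(spec$roster_size_distribution)
  alters <- if (n > 0) {
    dplyr::bind_rows(lapply(seq_len(n), function(i)
      draw_alter_row(spec, picks[i], i)))
  } else empty_alters()
  ego_survey(
    ego_id = ego_id, reporter_kind = reporter_kind,
    alters = alters, tie_reports = draw_ties(spec, alters),
    ego_attributes = draw_ego_attributes(spec, picks[spec$roster_cap + 1]),
    roster_cap = spec$roster_cap, freq_cap = spec$freq_cap
  )
}

perturb_name <- function(label) {
  # case/punctuation noise that normalize_name() undoes
  choice <- sample(3, 1)
  if (choice == 1) toupper(label)
  else if (choice == 2) paste0(" ", gsub(" ", "  ", label), " ")
  else sub(" ", ". ", label, fixed = TRUE)
}

#' Generate a matched young-adult / parent survey pair
#'
#' The young adult's survey is drawn first; with probability
#' `parent_named_prob` one roster slot becomes the parent (a family alter
#' carrying the parent's name). The parent roster then copies young-adult
#' alters (never the parent themself) with probability `overlap_prob` per
#' slot — exact name strings, optionally perturbed with case/punctuation
#' noise — and introduces fresh alters otherwise. Parent tie reports for
#' shared alter pairs duplicate the young adult's report and are flipped
#' with probability `discrepancy_prob`; all other parent pairs are drawn
#' fresh from the role-block tie model.
#'
#' @param spec A [cohort_spec()].
#' @param pair_id Identifier for the dyad.
#' @param seed Optional integer seed.
#' @return List: `ya` and `pa` ([ego_survey()]s), `pair_id`, `parent_name`,
#'   `parent_named` (whether the young adult's roster includes the parent),
#'   `n_shared` (alters copied into the parent roster).
#' @export
generate_matched_pair <- function(spec, pair_id = "P1", seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  ya <- generate_ego(spec, ego_id = paste0("YA-", pair_id))
  pool <- setdiff(name_pool(), ya$alters$label)
  parent_name <- sample(pool, 1)
  pool <- setdiff(pool, parent_name)

  parent_named <- nrow(ya$alters) > 0 &&
    stats::runif(1) < spec$parent_named_prob
  if (parent_named) {
    slot <- sample(nrow(ya$alters), 1)
    ya$alters$label[slot] <- parent_name
    ya$alters$role_raw[slot] <- sample(c("mother", "father"), 1)
    if (ya$alters$role_class[slot] != "family") {
      ya$alters$role_class[slot] <- "family"
      sup <- draw_supports(spec, "family")
      for (s in support_types()) ya$alters[[s]][slot] <- sup[[s]]
    }
  }

  n_pa <- draw_size(spec$parent_roster_distribution)
  candidates <- ya$alters[ya$alters$label != parent_name, , drop = FALSE]
  rows <- list()
  shared_src <- integer() # ya rank copied into each pa slot (NA if fresh)
  for (i in seq_len(n_pa)) {
    take_overlap <- nrow(candidates) > 0 &&
      stats::runif(1) < spec$overlap_prob
    if (take_overlap) {
      k <- sample(nrow(candidates), 1)
      src <- candidates[k, ]
      candidates <- candidates[-k, , drop = FALSE]
      lab <- src$label
      if (stats::runif(1) < spec$name_noise_prob) lab <- perturb_name(lab)
      row <- draw_alter_row(spec, lab, i, role_class = src$role_class)
      row$role_raw <- src$role_raw
      rows[[i]] <- row
      shared_src[i] <- src$rank
    } else {
      lab <- sample(pool, 1)
      pool <- setdiff(pool, lab)
      rows[[i]] <- draw_alter_row(spec, lab, i)
      shared_src[i] <- NA_integer_
    }
  }
  pa_alters <- if (n_pa > 0) dplyr::bind_rows(rows) else empty_alters()

  ties <- empty_ties()
  if (n_pa >= 2) {
    idx <- utils::combn(n_pa, 2)
    freq <- vapply(seq_len(ncol(idx)), function(k) {
      sa <- shared_src[idx[1, k]]; sb <- shared_src[idx[2, k]]
      if (!is.na(sa) && !is.na(sb)) {
        base <- freq_lookup(ya, sa, sb)
        if (stats::runif(1) < spec$discrepancy_prob) {
          if (base > 0) 0L else draw_freq(spec)
        } else base
      } else {
        ra <- pa_alters$role_class[idx[1, k]]
        rb <- pa_alters$role_class[idx[2, k]]
        if (stats::runif(1) < spec$tie_probs[ra, rb]) draw_freq(spec) else 0L
      }
    }, integer(1))
    ties <- tibble::tibble(a = idx[1, ], b = idx[2, ],
                           frequency = as.integer(freq))
  }
  pa <- ego_survey(
    ego_id = paste0("PA-", pair_id), reporter_kind = "parent",
    alters = pa_alters, tie_reports = ties,
    ego_attributes = c(list(name = parent_name),
                       draw_ego_attributes(spec, parent_name)["gender"]),
    roster_cap = spec$roster_cap, freq_cap = spec$freq_cap
  )
  list(ya = ya, pa = pa, pair_id = pair_id, parent_name = parent_name,
       parent_named = parent_named, n_shared = sum(!is.na(shared_src)))
}

#' Generate a full synthetic cohort
#'
#' Seeds the RNG from `spec$seed` and draws `n_egos` young-adult surveys, a
#' `pair_fraction` of which come with a matched parent survey. The manifest
#' records the generating parameters and bookkeeping counts (total alters,
#' pair identifiers) for use as test oracles.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `cohort`: `ya_surveys`, `pa_surveys` (named by
#'   pair id), `pairs` (tibble of ya/pa ids), `manifest`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_pairs <- round(spec$pair_fraction * spec$n_egos)
  ya_surveys <- list(); pa_surveys <- list(); pair_rows <- list()
  for (i in seq_len(spec$n_egos)) {
    if (i <= n_pairs) {
      mp <- generate_matched_pair(spec, pair_id = paste0("P", i))
      mp$ya$ego_id <- paste0("YA", i)
      mp$pa$ego_id <- paste0("PA", i)
      ya_surveys[[i]] <- mp$ya
      pa_surveys[[length(pa_surveys) + 1]] <- mp$pa
      pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
        pair_id = mp$pair_id, ya_id = paste0("YA", i),
        pa_id = paste0("PA", i), parent_named = mp$parent_named,
        n_shared = mp$n_shared
      )
    } else {
      ya_surveys[[i]] <- generate_ego(spec, ego_id = paste0("YA", i))
    }
  }
  pairs <- if (length(pair_rows)) dplyr::bind_rows(pair_rows) else
    tibble::tibble(pair_id = character(), ya_id = character(),
                   pa_id = character(), parent_named = logical(),
                   n_shared = integer())
  structure(
    list(
      ya_surveys = ya_surveys,
      pa_surveys = pa_surveys,
      pairs = pairs,
      manifest = list(
        seed = spec$seed,
        n_egos = spec$n_egos,
        n_pairs = nrow(pairs),
        total_alters = sum(vapply(ya_surveys, function(s)
          nrow(s$alters), integer(1))),
        role_probs = as.list(spec$role_probs),
        tie_probs = spec$tie_probs,
        overlap_prob = spec$overlap_prob,
        discrepancy_prob = spec$discrepancy_prob,
        parent_named_prob = spec$parent_named_prob
      )
    ),
    class = "cohort"
  )
}

#' Write a synthetic cohort to disk
#'
#' Emits `young_adults.csv` (and `parents.csv` when matched pairs exist) in
#' the wide survey dialect, plus `manifest.json` with the ground-truth
#' generating parameters. Output is byte-identical for a given spec and
#' seed.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_survey(cohort$ya_surveys, file.path(dir, "young_adults.csv"))
  if (length(cohort$pa_surveys) > 0) {
    write_survey(cohort$pa_surveys, file.path(dir, "parents.csv"))
  }
  manifest <- cohort$manifest
  manifest$pairs <- cohort$pairs
  manifest$tie_probs <- as.data.frame(manifest$tie_probs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
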