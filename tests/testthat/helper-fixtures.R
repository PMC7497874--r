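# Fixture builders and independent brute-force oracles.

sup_defaults <- function(n, flagged = list()) {
  out <- lapply(support_types(), function(s) {
    v <- rep(FALSE, n)
    if (!is.null(flagged[[s]])) v[flagged[[s]]] <- TRUE
    v
  })
  names(out) <- support_types()
  out
}

make_alters <- function(labels, roles = rep("community", length(labels)),
                        supports = list()) {
  n <- length(labels)
  raw <- vapply(roles, function(r) switch(r, family = "mother",
                                          community = "friend",
                                          professional = "therapist"),
                character(1))
  tibble::tibble(
    label = labels, rank = seq_len(n), role_raw = unname(raw),
    role_class = roles, !!!sup_defaults(n, supports)
  )
}

# tie_pairs: list of c(i, j) rank pairs that interact; freq: frequency for
# those pairs (recycled). All other pairs get frequency 0.
make_survey <- function(labels, roles = rep("community", length(labels)),
                        tie_pairs = list(), freq = 1L, ego_id = "E1",
                        kind = "young_adult", supports = list(),
                        attrs = list()) {
  n <- length(labels)
  ties <- if (n >= 2) {
    idx <- utils::combn(n, 2)
    freq <- rep_len(as.integer(freq), length(tie_pairs))
    f <- vapply(seq_len(ncol(idx)), function(k) {
      hit <- which(vapply(tie_pairs, function(p)
        min(p) == idx[1, k] && max(p) == idx[2, k], logical(1)))
      if (length(hit) >= 1) freq[hit[1]] else 0L
    }, integer(1))
    tibble::tibble(a = idx[1, ], b = idx[2, ], frequency = f)
  } else {
    tibble::tibble(a = integer(), b = integer(), frequency = integer())
  }
  ego_survey(ego_id, kind, make_alters(labels, roles, supports), ties,
             ego_attributes = attrs)
}

make_net <- function(n, tie_pairs = list(), roles = rep("community", n),
                     supports = list(), ego_id = "E1") {
  labels <- paste("Alter", seq_len(n))
  edges <- if (length(tie_pairs) > 0) {
    tibble::tibble(
      a = vapply(tie_pairs, min, numeric(1)),
      b = vapply(tie_pairs, max, numeric(1)),
      weight = 1L
    )
  } else {
    tibble::tibble(a = integer(), b = integer(), weight = integer())
  }
  ego_network(ego_id, make_alters(labels, roles, supports), edges)
}

complete_pairs <- function(ranks) {
  if (length(ranks) < 2) return(list())
  idx <- utils::combn(ranks, 2)
  lapply(seq_len(ncol(idx)), function(k) idx[, k])
}

random_survey <- function(n_max = 5, ego_id = "R1", p_tie = 0.5) {
  n <- sample(0:n_max, 1)
  labels <- paste("Person", sample(1000, n))
  roles <- sample(role_classes(), n, replace = TRUE)
  supports <- lapply(setNames(support_types(), support_types()),
                     function(s) which(stats::runif(n) < 0.5))
  tie_pairs <- list()
  freq <- integer()
  if (n >= 2) {
    idx <- utils::combn(n, 2)
    for (k in seq_len(ncol(idx))) {
      if (stats::runif(1) < p_tie) {
        tie_pairs[[length(tie_pairs) + 1]] <- idx[, k]
        freq <- c(freq, sample(3, 1))
      }
    }
  }
  make_survey(labels, roles, tie_pairs,
              freq = if (length(freq)) freq else 1L,
              ego_id = ego_id, supports = supports)
}

# Brute-force oracles, independent of the measure implementations.
density_oracle <- function(net) {
  n <- nrow(net$alters)
  if (n < 2) return(NA_real_)
  ranks <- net$alters$rank
  ties <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- min(ranks[i], ranks[j]); b <- max(ranks[i], ranks[j])
      if (any(net$edges$a == a & net$edges$b == b)) ties <- ties + 1L
    }
  }
  ties / (n * (n - 1) / 2)
}

degree_oracle <- function(net, rank) {
  sum(net$edges$a == rank) + sum(net$edges$b == rank)
}

# Study-style matched-pair fixtures reproducing the three published dyads.
# Pair 1: YA names the parent + 4 others; parent + 3 others fully tied, one
# isolate; parent roster of 4 shares one alter and holds a single tie.
study_pair_1 <- function() {
  ya <- make_survey(
    labels = c("Mona Reyes", "Alex Chen", "Bea Ortiz", "Cal Webb",
               "Dev Silva"),
    roles = c("family", "community", "family", "community", "community"),
    tie_pairs = complete_pairs(1:4),
    ego_id = "YA1"
  )
  pa <- make_survey(
    labels = c("Alex Chen", "Elle Khan", "Fay Tran", "Gus Park"),
    roles = c("community", "family", "community", "community"),
    tie_pairs = list(c(1, 2)),
    ego_id = "PA1", kind = "parent",
    attrs = list(name = "Mona Reyes")
  )
  list(ya = ya, pa = pa)
}

# Pair 2: parent tied to every other alter; parent roster of 3, one shared.
study_pair_2 <- function() {
  ya <- make_survey(
    labels = c("Mona Vance", "Ana Diaz", "Ben Ito", "Cy Lopez", "Dot Hale"),
    roles = c("family", "professional", "community", "professional",
              "professional"),
    tie_pairs = c(complete_pairs(c(1, 2)), complete_pairs(c(1, 3)),
                  complete_pairs(c(1, 4)), complete_pairs(c(1, 5)),
                  list(c(2, 3), c(3, 4), c(4, 5))),
    ego_id = "YA2"
  )
  pa <- make_survey(
    labels = c("Ana Diaz", "Eve Mori", "Flo Quist"),
    roles = c("professional", "family", "community"),
    tie_pairs = list(c(1, 2), c(2, 3)),
    ego_id = "PA2", kind = "parent",
    attrs = list(name = "Mona Vance")
  )
  list(ya = ya, pa = pa)
}

# Pair 3: parent not named; parent roster is a 2-alter subset with no tie,
# while the YA reports that same pair as tied (the one discrepancy).
study_pair_3 <- function() {
  ya <- make_survey(
    labels = c("Ana Okafor", "Bo Usman", "Cleo Jones", "Dara Webb",
               "Eli Baker"),
    roles = c("family", "family", "family", "community", "community"),
    tie_pairs = list(c(1, 2), c(1, 3), c(2, 3), c(1, 4), c(2, 4), c(3, 4),
                     c(1, 5)),
    ego_id = "YA3"
  )
  pa <- make_survey(
    labels = c("Ana Okafor", "Bo Usman"),
    roles = c("family", "family"),
    tie_pairs = list(),
    ego_id = "PA3", kind = "parent",
    attrs = list(name = "Rae Ellis")
  )
  list(ya = ya, pa = pa)
}

# Rebuild one respondent's survey with tie reports replaced by the merged
# resolved values (the duo network's projection onto that roster).
project_duo <- function(duo, side) {
  net <- if (side == "ya") duo$ya_net else duo$pa_net
  rank_col <- paste0(side, "_rank")
  ids <- duo$nodes$unified_id[match(net$alters$rank, duo$nodes[[rank_col]])]
  look <- function(i, j) {
    lo <- min(ids[i], ids[j]); hi <- max(ids[i], ids[j])
    k <- which(duo$edges$node_a == lo & duo$edges$node_b == hi &
                 !duo$edges$implied)
    if (length(k) == 1) duo$edges$weight[k] else 0L
  }
  n <- nrow(net$alters)
  ties <- if (n >= 2) {
    idx <- utils::combn(n, 2)
    tibble::tibble(
      a = net$alters$rank[idx[1, ]], b = net$alters$rank[idx[2, ]],
      frequency = vapply(seq_len(ncol(idx)), function(k)
        look(idx[1, k], idx[2, k]), integer(1))
    )
  } else tibble::tibble(a = integer(), b = integer(), frequency = integer())
  parent_lab <- duo$nodes$label[duo$nodes$is_parent]
  ego_survey(net$ego_id, if (side == "ya") "young_adult" else "parent",
             net$alters, ties,
             ego_attributes = if (side == "pa" && length(parent_lab) == 1)
               list(name = parent_lab) else list())
}

# Exchange the two respondents' reports on every doubly-observed alter pair.
swap_shared_reports <- function(ya, pa) {
  ya_key <- normalize_name(ya$alters$label)
  pa_key <- normalize_name(pa$alters$label)
  shared <- intersect(ya_key, pa_key)
  if (length(shared) >= 2) {
    combos <- utils::combn(shared, 2)
    for (k in seq_len(ncol(combos))) {
      ra <- ya$alters$rank[match(combos[, k], ya_key)]
      rb <- pa$alters$rank[match(combos[, k], pa_key)]
      yi <- which(ya$tie_reports$a == min(ra) & ya$tie_reports$b == max(ra))
      pi <- which(pa$tie_reports$a == min(rb) & pa$tie_reports$b == max(rb))
      f_ya <- ya$tie_reports$frequency[yi]
      ya$tie_reports$frequency[yi] <- pa$tie_reports$frequency[pi]
      pa$tie_reports$frequency[pi] <- f_ya
    }
    ya$tie_reports$interacts <- ya$tie_reports$frequency > 0
    pa$tie_reports$interacts <- pa$tie_reports$frequency > 0
  }
  list(ya = validate_ego_survey(ya), pa = validate_ego_survey(pa))
}

# Label-keyed resolved (non-implied) edge set of a duo network, for
# comparisons that must not depend on unified id assignment.
resolved_edge_key <- function(duo) {
  e <- duo$edges[!duo$edges$implied, , drop = FALSE]
  lab <- stats::setNames(duo$nodes$label, duo$nodes$unified_id)
  sort(paste(pmin(lab[e$node_a], lab[e$node_b]),
             pmax(lab[e$node_a], lab[e$node_b]), e$weight))
}
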