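# Core S3 containers: ego_survey (raw name-generator answers) and
# ego_network (the alter-only undirected graph derived from one survey).

#' Support universe and role classes
#'
#' The six binary support types elicited per alter, and the three role
#' classes alters are coded into.
#'
#' @return A character vector.
#' @export
#' @examples
#' support_types()
#' role_classes()
support_types <- function() {
  c("friendship", "emotional", "advice", "financial", "logistical", "job")
}

#' @rdname support_types
#' @export
role_classes <- function() {
  c("family", "community", "professional")
}

#' Construct an egocentric survey record
#'
#' One respondent's answers to the name generator: an ordered roster of up to
#' `roster_cap` alters (rank 1 = most important), each with a free-text role,
#' a role class, and six binary support flags, plus one tie report per
#' unordered alter pair ("Does A interact with B? (If yes) How often?") on an
#' ordinal 0..`freq_cap` frequency scale (0 = no interaction).
#'
#' @param ego_id Respondent identifier.
#' @param reporter_kind `"young_adult"` or `"parent"`. Parent surveys use the
#'   parent name generator (people who help support the young adult).
#' @param alters Tibble with columns `label`, `rank`, `role_raw`,
#'   `role_class`, and one logical column per [support_types()].
#' @param tie_reports Tibble with columns `a`, `b` (alter ranks, `a < b`) and
#'   `frequency` (integer 0..`freq_cap`). A logical `interacts` column is
#'   derived as `frequency > 0`.
#' @param ego_attributes Named list of respondent attributes (e.g. `gender`,
#'   `age`, `dating`, `employed`, `college`, `independent_living`, `name`).
#' @param roster_cap Maximum roster size (default 5).
#' @param freq_cap Top of the ordinal frequency scale (default 3:
#'   never / rarely / monthly / weekly or more).
#'
#' @return An object of class `ego_survey`.
#' @export
#' @examples
#' alters <- tibble::tibble(
#'   label = c("Ana Reyes", "Ben Ortiz"), rank = 1:2,
#'   role_raw = c("mother", "friend"),
#'   role_class = c("family", "community"),
#'   friendship = c(TRUE, TRUE), emotional = c(TRUE, FALSE),
#'   advice = c(TRUE, FALSE), financial = c(FALSE, FALSE),
#'   logistical = c(FALSE, FALSE), job = c(FALSE, FALSE)
#' )
#' ties <- tibble::tibble(a = 1L, b = 2L, frequency = 2L)
#' ego_survey("YA1", "young_adult", alters, ties)
ego_survey <- function(ego_id, reporter_kind, alters, tie_reports,
                       ego_attributes = list(), roster_cap = 5L,
                       freq_cap = 3L) {
  alters <- tibble::as_tibble(alters)
  tie_reports <- tibble::as_tibble(tie_reports)
  if (nrow(tie_reports) > 0 && !"interacts" %in% names(tie_reports)) {
    tie_reports$interacts <- tie_reports$frequency > 0
  } else if (nrow(tie_reports) == 0) {
    tie_reports <- tibble::tibble(
      a = integer(), b = integer(), frequency = integer(),
      interacts = logical()
    )
  }
  out <- structure(
    list(
      ego_id = as.character(ego_id),
      reporter_kind = match.arg(reporter_kind, c("young_adult", "parent")),
      ego_attributes = ego_attributes,
      alters = alters,
      tie_reports = tie_reports,
      roster_cap = as.integer(roster_cap),
      freq_cap = as.integer(freq_cap)
    ),
    class = "ego_survey"
  )
  validate_ego_survey(out)
}

#' Validate an egocentric survey record
#'
#' Checks the structural invariants: ranks are unique positive integers with
#' roster size at most `roster_cap`; role classes are one of
#' [role_classes()]; support flags are logical; tie reports cover every
#' unordered alter pair exactly once with frequencies in 0..`freq_cap` and
#' `interacts == (frequency > 0)`.
#'
#' @param x An `ego_survey`.
#' @return `x`, invisibly-checked (returned unchanged); errors otherwise.
#' @export
validate_ego_survey <- function(x) {
  stopifnot(inherits(x, "ego_survey"))
  al <- x$alters
  need <- c("label", "rank", "role_raw", "role_class", support_types())
  missing_cols <- setdiff(need, names(al))
  if (length(missing_cols) > 0) {
    stop("alters table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(al)
  if (n > x$roster_cap) {
    stop("survey ", x$ego_id, ": ", n, " alters exceed roster cap of ",
         x$roster_cap, call. = FALSE)
  }
  if (n > 0) {
    if (anyDuplicated(al$rank) > 0) {
      stop("survey ", x$ego_id, ": duplicate alter rank(s): ",
           paste(unique(al$rank[duplicated(al$rank)]), collapse = ", "),
           call. = FALSE)
    }
    if (any(al$rank < 1) || any(al$rank != as.integer(al$rank))) {
      stop("alter ranks must be positive integers", call. = FALSE)
    }
    bad_class <- setdiff(unique(al$role_class), role_classes())
    if (length(bad_class) > 0) {
      stop("unknown role class(es): ", paste(bad_class, collapse = ", "),
           call. = FALSE)
    }
    for (s in support_types()) {
      if (!is.logical(al[[s]]) || anyNA(al[[s]])) {
        stop("support column '", s, "' must be logical with no NA",
             call. = FALSE)
      }
    }
  }
  tr <- x$tie_reports
  expected_pairs <- if (n >= 2) utils::combn(sort(al$rank), 2) else
    matrix(integer(), nrow = 2)
  if (nrow(tr) != ncol(expected_pairs)) {
    have <- if (nrow(tr) > 0) paste(tr$a, tr$b, sep = "-") else character()
    want <- if (ncol(expected_pairs) > 0)
      paste(expected_pairs[1, ], expected_pairs[2, ], sep = "-") else character()
    miss <- setdiff(want, have)
    stop("survey ", x$ego_id, ": tie report(s) missing for pair(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(tr) > 0) {
    if (any(tr$a >= tr$b)) {
      stop("tie reports must have a < b (canonical unordered pairs)",
           call. = FALSE)
    }
    key <- paste(tr$a, tr$b, sep = "-")
    if (anyDuplicated(key) > 0) {
      stop("duplicate tie report for pair(s): ",
           paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
    }
    want <- paste(expected_pairs[1, ], expected_pairs[2, ], sep = "-")
    miss <- setdiff(want, key)
    if (length(miss) > 0) {
      stop("survey ", x$ego_id, ": tie report(s) missing for pair(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (any(tr$frequency < 0) || any(tr$frequency > x$freq_cap) ||
        anyNA(tr$frequency)) {
      stop("tie frequencies must lie in 0..", x$freq_cap, call. = FALSE)
    }
    if (any(tr$interacts != (tr$frequency > 0))) {
      stop("interacts flag inconsistent with frequency (> 0)", call. = FALSE)
    }
  }
  x
}

#' @export
print.ego_survey <- function(x, ...) {
  n <- nrow(x$alters)
  cat("<ego_survey> ", x$ego_id, " (", x$reporter_kind, "): ",
      n, " alter", if (n == 1) "" else "s", ", ",
      nrow(x$tie_reports), " tie report",
      if (nrow(x$tie_reports) == 1) "" else "s", "\n", sep = "")
  if (n > 0) {
    cat("  roster:", paste0(x$alters$label, " [", x$alters$role_class, "]",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct an egocentric alter network
#'
#' The alter-only undirected graph of one survey: nodes are the named alters,
#' edges are the binarized alter-alter ties (reported frequency >= 1). The
#' ego is not a node; by construction of the name generator the ego is tied
#' to every alter, so ego ties carry no information and are excluded from all
#' density computations.
#'
#' @param ego_id Respondent identifier.
#' @param alters Alter tibble as in [ego_survey()].
#' @param edges Tibble with columns `a`, `b` (alter ranks, `a < b`) and
#'   `weight` (ordinal frequency, >= 1).
#' @return An object of class `ego_network`.
#' @export
ego_network <- function(ego_id, alters, edges) {
  alters <- tibble::as_tibble(alters)
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(a = integer(), b = integer(), weight = integer())
  }
  if (nrow(edges) > 0) {
    stopifnot(all(edges$a < edges$b), all(edges$weight >= 1))
    if (!all(c(edges$a, edges$b) %in% alters$rank)) {
      stop("edge endpoints must be alter ranks present in the roster",
           call. = FALSE)
    }
  }
  structure(
    list(ego_id = as.character(ego_id), alters = alters, edges = edges),
    class = "ego_network"
  )
}

#' Derive the alter network from a survey
#'
#' Binarizes tie reports at frequency >= 1 and keeps the ordinal frequency as
#' the edge weight.
#'
#' @param survey A validated [ego_survey()].
#' @return An [ego_network()].
#' @export
#' @examples
#' spec <- cohort_spec(n_egos = 1, seed = 7)
#' net <- as_ego_network(generate_ego(spec, ego_id = "YA1"))
#' network_density(net)
as_ego_network <- function(survey) {
  stopifnot(inherits(survey, "ego_survey"))
  tr <- survey$tie_reports
  tied <- tr[tr$frequency > 0, , drop = FALSE]
  ego_network(
    ego_id = survey$ego_id,
    alters = survey$alters,
    edges = tibble::tibble(a = tied$a, b = tied$b,
                           weight = as.integer(tied$frequency))
  )
}

#' @export
print.ego_network <- function(x, ...) {
  cat("<ego_network> ", x$ego_id, ": ", nrow(x$alters), " alters, ",
      nrow(x$edges), " ties", sep = "")
  d <- network_density(x)
  if (!is.na(d)) cat(" (density ", format(round(d, 2), nsmall = 2), ")",
                     sep = "")
  cat("\n")
  invisible(x)
}
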