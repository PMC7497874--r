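# Survey import/export. The wide CSV dialect mirrors a flattened online-survey
# export: one row per respondent with positional alter columns and one tie
# column per unordered roster pair.
#
# Columns:
#   ego_id, reporter_kind,
#   <ego attribute columns: any other non-alter, non-tie column>,
#   alter{N}_name, alter{N}_role, alter{N}_class,
#   alter{N}_friendship ... alter{N}_job        (N = 1..roster_cap),
#   tie_{i}_{j}                                 (1 <= i < j <= roster_cap)
# Alter rank is positional (N). Tie cells hold the ordinal frequency
# (0 = no interaction); cells for absent alters are blank.
# The JSON form is a faithful nested serialization of the same records.

#' Default role-classification map
#'
#' Maps the study's free-text role vocabulary onto the three role classes.
#' Kinship terms are family; friends, neighbors, and other informal community
#' ties are community; service providers are professional.
#'
#' @return Named character vector: role term -> role class.
#' @export
default_role_map <- function() {
  fam <- c("mother", "father", "mom", "dad", "parent", "stepmother",
           "stepfather", "brother", "sister", "sibling", "grandmother",
           "grandfather", "grandparent", "aunt", "uncle", "cousin",
           "husband", "wife", "spouse", "son", "daughter")
  com <- c("friend", "best friend", "neighbor", "roommate", "boyfriend",
           "girlfriend", "partner", "coworker", "colleague", "classmate",
           "mentor", "coach", "pastor")
  pro <- c("therapist", "doctor", "psychiatrist", "psychologist",
           "counselor", "social worker", "case manager", "job coach",
           "teacher", "professor", "aide", "nurse", "service provider")
  stats::setNames(
    c(rep("family", length(fam)), rep("community", length(com)),
      rep("professional", length(pro))),
    c(fam, com, pro)
  )
}

#' Classify a free-text alter role into a role class
#'
#' Matches the lower-cased, trimmed role term against a mapping table. Terms
#' not in the map are routed to a configurable fallback class (default
#' `"community"`, the residual informal category) with a warning.
#'
#' @param role_raw Character vector of free-text roles.
#' @param mapping Named character vector, term -> class
#'   (default [default_role_map()]).
#' @param unmapped Fallback class for unmapped terms, or `"error"` to fail.
#' @return Character vector of role classes (see [role_classes()]).
#' @export
#' @examples
#' classify_role(c("mother", "therapist", "neighbor"))
classify_role <- function(role_raw, mapping = default_role_map(),
                          unmapped = "community") {
  if (length(role_raw) == 0) return(character())
  key <- tolower(trimws(role_raw))
  if (any(!nzchar(key) | is.na(key))) {
    stop("empty role string cannot be classified", call. = FALSE)
  }
  out <- unname(mapping[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    if (identical(unmapped, "error")) {
      stop("unmapped role term(s): ",
           paste(unique(role_raw[unknown]), collapse = ", "), call. = FALSE)
    }
    unmapped <- match.arg(unmapped, role_classes())
    warning("unmapped role term(s) routed to '", unmapped, "': ",
            paste(unique(role_raw[unknown]), collapse = ", "), call. = FALSE)
    out[unknown] <- unmapped
  }
  out
}

pair_cols <- function(cap) {
  if (cap < 2) return(character())
  idx <- utils::combn(cap, 2)
  paste0("tie_", idx[1, ], "_", idx[2, ])
}

as_flag <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  tolower(trimws(as.character(x))) %in% c("true", "t", "yes", "y", "1")
}

#' Read survey exports
#'
#' Reads one or more respondent records from the documented wide CSV dialect
#' or its JSON equivalent, validates them, and returns a list of
#' [ego_survey()] objects.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @param role_map Mapping used when a CSV lacks explicit `alterN_class`
#'   columns; see [classify_role()].
#' @param roster_cap,freq_cap Caps applied to CSV records (JSON records carry
#'   their own).
#' @return List of `ego_survey` objects.
#' @export
read_survey <- function(path, format = c("guess", "csv", "json"),
                        role_map = default_role_map(), roster_cap = 5L,
                        freq_cap = 3L) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "json") read_survey_json(path) else
    read_survey_csv(path, role_map, roster_cap, freq_cap)
}

read_survey_csv <- function(path, role_map, roster_cap, freq_cap) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("ego_id", "reporter_kind")) {
    if (!col %in% names(df)) {
      stop("malformed survey header: missing required column '", col, "'",
           call. = FALSE)
    }
  }
  name_cols <- grep("^alter[0-9]+_name$", names(df), value = TRUE)
  if (length(name_cols) == 0) {
    stop("malformed survey header: no 'alterN_name' columns found",
         call. = FALSE)
  }
  cap <- max(as.integer(sub("^alter([0-9]+)_name$", "\\1", name_cols)))
  cap <- max(cap, roster_cap)
  alter_cols <- unlist(lapply(seq_len(cap), function(n) {
    paste0("alter", n, "_", c("name", "role", "class", support_types()))
  }))
  tie_cols <- pair_cols(cap)
  attr_cols <- setdiff(names(df), c("ego_id", "reporter_kind",
                                    alter_cols, tie_cols))

  lapply(seq_len(nrow(df)), function(r) {
    row <- df[r, , drop = FALSE]
    present <- integer()
    recs <- list()
    for (n in seq_len(cap)) {
      nm <- row[[paste0("alter", n, "_name")]]
      if (is.null(nm) || is.na(nm) || !nzchar(trimws(nm))) next
      present <- c(present, n)
      role_raw <- as.character(row[[paste0("alter", n, "_role")]])
      cls_col <- paste0("alter", n, "_class")
      cls <- if (cls_col %in% names(df) && !is.na(row[[cls_col]]) &&
                 nzchar(row[[cls_col]])) {
        as.character(row[[cls_col]])
      } else {
        classify_role(role_raw, mapping = role_map)
      }
      sup <- lapply(support_types(), function(s) {
        as_flag(row[[paste0("alter", n, "_", s)]])
      })
      names(sup) <- support_types()
      recs[[length(recs) + 1]] <- tibble::tibble(
        label = as.character(nm), rank = as.integer(n),
        role_raw = role_raw, role_class = cls, !!!sup
      )
    }
    alters <- if (length(recs) > 0) dplyr::bind_rows(recs) else
      empty_alters()
    ties <- empty_ties()
    if (length(present) >= 2) {
      idx <- utils::combn(present, 2)
      freq <- vapply(seq_len(ncol(idx)), function(k) {
        col <- paste0("tie_", idx[1, k], "_", idx[2, k])
        v <- if (col %in% names(df)) row[[col]] else NA
        if (is.null(v) || is.na(v) || (is.character(v) && !nzchar(trimws(v)))) {
          stop("survey ", row$ego_id, ": missing tie report for pair ",
               idx[1, k], "-", idx[2, k], call. = FALSE)
        }
        as.integer(v)
      }, integer(1))
      ties <- tibble::tibble(a = idx[1, ], b = idx[2, ], frequency = freq)
    }
    attrs <- as.list(row[attr_cols])
    attrs <- attrs[!vapply(attrs, function(v) is.na(v) ||
                             (is.character(v) && !nzchar(v)), logical(1))]
    ego_survey(
      ego_id = row$ego_id, reporter_kind = row$reporter_kind,
      alters = alters, tie_reports = ties, ego_attributes = attrs,
      roster_cap = cap, freq_cap = freq_cap
    )
  })
}

read_survey_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    alters <- if (length(s$alters) > 0) {
      dplyr::bind_rows(lapply(s$alters, function(a) {
        sup <- stats::setNames(
          lapply(support_types(), function(t) isTRUE(a$supports[[t]])),
          support_types()
        )
        tibble::tibble(label = a$label, rank = as.integer(a$rank),
                       role_raw = a$role_raw, role_class = a$role_class,
                       !!!sup)
      }))
    } else empty_alters()
    if (nrow(alters) > 0 && anyDuplicated(alters$rank) > 0) {
      stop("survey ", s$ego_id, ": duplicate alter rank(s): ",
           paste(unique(alters$rank[duplicated(alters$rank)]),
                 collapse = ", "), call. = FALSE)
    }
    ties <- if (length(s$tie_reports) > 0) {
      dplyr::bind_rows(lapply(s$tie_reports, function(t) {
        tibble::tibble(a = as.integer(t$a), b = as.integer(t$b),
                       frequency = as.integer(t$frequency))
      }))
    } else empty_ties()
    ego_survey(
      ego_id = s$ego_id, reporter_kind = s$reporter_kind,
      alters = alters, tie_reports = ties,
      ego_attributes = lapply(s$ego_attributes, function(v) {
        if (is.list(v)) unlist(v) else v
      }),
      roster_cap = as.integer(s$roster_cap %||% 5L),
      freq_cap = as.integer(s$freq_cap %||% 3L)
    )
  })
}

empty_alters <- function() {
  sup <- stats::setNames(rep(list(logical()), length(support_types())),
                         support_types())
  tibble::tibble(label = character(), rank = integer(),
                 role_raw = character(), role_class = character(), !!!sup)
}

empty_ties <- function() {
  tibble::tibble(a = integer(), b = integer(), frequency = integer())
}

#' Write surveys to disk
#'
#' Writes one or more [ego_survey()] objects in the wide CSV dialect or the
#' JSON form read back by [read_survey()]. Write-then-read is the identity on
#' every field.
#'
#' @param surveys An `ego_survey` or a list of them.
#' @param path Output file.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_survey <- function(surveys, path, format = c("guess", "csv", "json")) {
  if (inherits(surveys, "ego_survey")) surveys <- list(surveys)
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") write_survey_json(surveys, path) else
    write_survey_csv(surveys, path)
  invisible(path)
}

write_survey_csv <- function(surveys, path) {
  cap <- max(vapply(surveys, function(s) s$roster_cap, integer(1)))
  attr_names <- unique(unlist(lapply(surveys, function(s)
    names(s$ego_attributes))))
  rows <- lapply(surveys, function(s) {
    row <- list(ego_id = s$ego_id, reporter_kind = s$reporter_kind)
    for (a in attr_names) row[[a]] <- s$ego_attributes[[a]] %||% NA
    al <- s$alters
    for (n in seq_len(cap)) {
      i <- match(n, al$rank)
      row[[paste0("alter", n, "_name")]] <-
        if (is.na(i)) NA_character_ else al$label[i]
      row[[paste0("alter", n, "_role")]] <-
        if (is.na(i)) NA_character_ else al$role_raw[i]
      row[[paste0("alter", n, "_class")]] <-
        if (is.na(i)) NA_character_ else al$role_class[i]
      for (sup in support_types()) {
        row[[paste0("alter", n, "_", sup)]] <-
          if (is.na(i)) NA else al[[sup]][i]
      }
    }
    tr <- s$tie_reports
    for (col in pair_cols(cap)) {
      ij <- as.integer(strsplit(sub("^tie_", "", col), "_")[[1]])
      k <- which(tr$a == ij[1] & tr$b == ij[2])
      row[[col]] <- if (length(k) == 1) tr$frequency[k] else NA_integer_
    }
    tibble::as_tibble(row)
  })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

write_survey_json <- function(surveys, path) {
  payload <- lapply(surveys, function(s) {
    list(
      ego_id = s$ego_id,
      reporter_kind = s$reporter_kind,
      ego_attributes = s$ego_attributes,
      roster_cap = s$roster_cap,
      freq_cap = s$freq_cap,
      alters = lapply(seq_len(nrow(s$alters)), function(i) {
        a <- s$alters[i, ]
        list(label = a$label, rank = a$rank, role_raw = a$role_raw,
             role_class = a$role_class,
             supports = as.list(a[support_types()]))
      }),
      tie_reports = lapply(seq_len(nrow(s$tie_reports)), function(i) {
        t <- s$tie_reports[i, ]
        list(a = t$a, b = t$b, frequency = t$frequency)
      })
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Reshape a survey into a network edge list
#'
#' One row per reported interacting alter pair (frequency >= 1), with
#' canonical node ordering (lower rank first). Isolated alters and
#' non-interacting pairs produce no rows.
#'
#' @param survey A validated [ego_survey()].
#' @return Tibble with columns `ego_id`, `node_a`, `node_b`, `weight`.
#' @export
#' @examples
#' spec <- cohort_spec(n_egos = 1, seed = 3)
#' to_edge_list(generate_ego(spec, ego_id = "YA1"))
to_edge_list <- function(survey) {
  stopifnot(inherits(survey, "ego_survey"))
  tr <- survey$tie_reports
  tied <- tr[tr$frequency > 0, , drop = FALSE]
  lab <- stats::setNames(survey$alters$label, survey$alters$rank)
  tibble::tibble(
    ego_id = rep(survey$ego_id, nrow(tied)),
    node_a = unname(lab[as.character(tied$a)]),
    node_b = unname(lab[as.character(tied$b)]),
    weight = as.integer(tied$frequency)
  )
}
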