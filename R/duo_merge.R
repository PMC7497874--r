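# Duocentric merging: match alters across a young-adult and a parent survey
# by exact normalized name (role class used only to break ties among same-key
# candidates), then combine the two tie-report sets under the maximum-value
# rule, logging every conflicting shared report as a discrepancy.

#' Normalize an alter name for matching
#'
#' Case-folds, strips punctuation, and collapses internal whitespace, so that
#' "J. Smith", "j  smith", and "J Smith" share one key. No fuzzy or phonetic
#' matching: "Sue" and "Susan" remain distinct.
#'
#' @param label Character vector of names.
#' @return Character vector of canonical keys.
#' @export
#' @examples
#' normalize_name(c("Aunt  Sue ", "J. Smith", "j smith"))
normalize_name <- function(label) {
  if (length(label) == 0) return(character())
  if (any(is.na(label)) || any(!nzchar(trimws(label)))) {
    stop("cannot normalize an empty name", call. = FALSE)
  }
  key <- tolower(label)
  key <- gsub("[^[:alnum:][:space:]]", "", key)
  key <- gsub("[[:space:]]+", " ", key)
  trimws(key)
}

#' Match alters across a young-adult and a parent survey
#'
#' Every alter of either survey lands in exactly one match row. Alters
#' sharing a normalized name key are candidate matches; when one survey
#' holds several alters under the same key, role-class agreement is used to
#' pair them, and candidates that still cannot be paired uniquely raise an
#' ambiguity error (or, with `on_ambiguity = "flag"`, are left unmatched
#' with `needs_review = TRUE` for a manual-review export).
#'
#' @param ya Young-adult [ego_survey()].
#' @param pa Parent [ego_survey()].
#' @param on_ambiguity `"error"` (default) or `"flag"`.
#' @return Tibble with columns `unified_id`, `label`, `ya_rank`, `pa_rank`,
#'   `provenance` (`"both"`, `"ya_only"`, `"pa_only"`), `match_basis`
#'   (`"name_exact"`, `"name_plus_role"`, `"manual"`), `needs_review`.
#' @export
match_alters <- function(ya, pa, on_ambiguity = c("error", "flag")) {
  stopifnot(inherits(ya, "ego_survey"), inherits(pa, "ego_survey"))
  on_ambiguity <- match.arg(on_ambiguity)
  ya_tab <- ya$alters
  pa_tab <- pa$alters
  ya_key <- if (nrow(ya_tab)) normalize_name(ya_tab$label) else character()
  pa_key <- if (nrow(pa_tab)) normalize_name(pa_tab$label) else character()

  # resolve key by key: a key carried by at most one alter per survey is an
  # exact name match; a duplicated key needs role-class agreement, and keys
  # whose candidates still cannot be paired uniquely are ambiguous
  pair_rows <- list(); single_rows <- list(); ambiguous <- character()
  for (key in unique(c(ya_key, pa_key))) {
    yi <- which(ya_key == key)
    pj <- which(pa_key == key)
    emit_single <- function(side, idx, review = FALSE) {
      tab <- if (side == "ya") ya_tab else pa_tab
      tibble::tibble(
        label = tab$label[idx],
        ya_rank = if (side == "ya") tab$rank[idx] else NA_integer_,
        pa_rank = if (side == "pa") tab$rank[idx] else NA_integer_,
        provenance = paste0(side, "_only"),
        match_basis = if (review) "manual" else "name_exact",
        needs_review = review
      )
    }
    if (length(yi) <= 1 && length(pj) <= 1) {
      if (length(yi) == 1 && length(pj) == 1) {
        pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
          label = ya_tab$label[yi], ya_rank = ya_tab$rank[yi],
          pa_rank = pa_tab$rank[pj], provenance = "both",
          match_basis = "name_exact", needs_review = FALSE
        )
      } else if (length(yi) == 1) {
        single_rows[[length(single_rows) + 1]] <- emit_single("ya", yi)
      } else if (length(pj) == 1) {
        single_rows[[length(single_rows) + 1]] <- emit_single("pa", pj)
      }
      next
    }
    if (length(yi) == 0 || length(pj) == 0) {
      # duplicates confined to one survey never cross-match; they stay
      # distinct unmatched alters
      for (i in yi) single_rows[[length(single_rows) + 1]] <-
          emit_single("ya", i)
      for (j in pj) single_rows[[length(single_rows) + 1]] <-
          emit_single("pa", j)
      next
    }
    # duplicated key present in both surveys: pair by role-class agreement
    used_ya <- rep(FALSE, length(yi)); used_pa <- rep(FALSE, length(pj))
    key_pairs <- list(); key_ambiguous <- FALSE
    for (b in seq_along(pj)) {
      hits <- which(!used_ya &
                      ya_tab$role_class[yi] == pa_tab$role_class[pj[b]])
      if (length(hits) == 1) {
        used_ya[hits] <- TRUE; used_pa[b] <- TRUE
        key_pairs[[length(key_pairs) + 1]] <- c(yi[hits], pj[b])
      } else {
        key_ambiguous <- TRUE
      }
    }
    if (key_ambiguous) {
      ambiguous <- c(ambiguous, ya_tab$label[yi[1]])
      for (i in yi) single_rows[[length(single_rows) + 1]] <-
          emit_single("ya", i, review = TRUE)
      for (j in pj) single_rows[[length(single_rows) + 1]] <-
          emit_single("pa", j, review = TRUE)
    } else {
      for (kp in key_pairs) {
        pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
          label = ya_tab$label[kp[1]], ya_rank = ya_tab$rank[kp[1]],
          pa_rank = pa_tab$rank[kp[2]], provenance = "both",
          match_basis = "name_plus_role", needs_review = FALSE
        )
      }
      for (i in yi[!used_ya]) single_rows[[length(single_rows) + 1]] <-
          emit_single("ya", i)
    }
  }
  if (length(ambiguous) > 0 && on_ambiguity == "error") {
    stop("ambiguous alter match (same normalized name, role does not ",
         "disambiguate): ", paste(unique(ambiguous), collapse = ", "),
         "; rerun with on_ambiguity = \"flag\" to export for manual review",
         call. = FALSE)
  }
  out <- dplyr::bind_rows(c(pair_rows, single_rows))
  # stable roster order: young-adult roster first, then parent-only alters
  out <- out[order(is.na(out$ya_rank), out$ya_rank, out$pa_rank), ]
  out$unified_id <- sprintf("N%02d", seq_len(nrow(out)))
  out[, c("unified_id", "label", "ya_rank", "pa_rank", "provenance",
          "match_basis", "needs_review")]
}

freq_lookup <- function(survey, rank_a, rank_b) {
  if (is.na(rank_a) || is.na(rank_b)) return(NA_integer_)
  lo <- min(rank_a, rank_b); hi <- max(rank_a, rank_b)
  tr <- survey$tie_reports
  k <- which(tr$a == lo & tr$b == hi)
  if (length(k) != 1) return(NA_integer_)
  as.integer(tr$frequency[k])
}

#' Merge a matched pair of surveys into a duocentric network
#'
#' The node set is the union of the two alter rosters after matching. For
#' each unordered node pair, the two respondents' tie reports are combined
#' with the maximum-value rule: where both reported, the merged ordinal
#' frequency is the larger of the two and a discrepancy is logged whenever
#' they differ; where only one respondent knows both endpoints, that report
#' stands; pairs neither respondent could observe (a ya-only alter against a
#' pa-only alter) carry no report and are returned in `unobserved`.
#'
#' The parent respondent appears as a node only when the young adult named
#' the parent as an alter (matched via `parent_label`, defaulting to the
#' parent survey's `ego_attributes$name`). When present, the parent node
#' gains generator-implied ties (`implied = TRUE`, no ordinal weight) to
#' every alter on the parent's own roster; implied ties are excluded from
#' density and disconnection counts but available to the merged-frame parent
#' centrality.
#'
#' @param ya Young-adult [ego_survey()].
#' @param pa Parent [ego_survey()].
#' @param matches Match table from [match_alters()] (computed if `NULL`).
#' @param pair_id Identifier for the dyad (default `"<ya>-<pa>"`).
#' @param parent_label Name identifying the parent respondent among the
#'   young adult's alters.
#' @return Object of class `duo_network`: `pair_id`, `nodes`, `parent_node`
#'   (unified id or `NA`), `edges` (resolved ties with `weight`, `source`,
#'   `implied`), `discrepancies`, `unobserved`, plus the two component
#'   [ego_network()]s (`ya_net`, `pa_net`).
#' @export
merge_duocentric <- function(ya, pa, matches = NULL, pair_id = NULL,
                             parent_label = NULL) {
  stopifnot(inherits(ya, "ego_survey"), inherits(pa, "ego_survey"))
  if (is.null(matches)) matches <- match_alters(ya, pa)
  pair_id <- pair_id %||% paste0(ya$ego_id, "-", pa$ego_id)
  parent_label <- parent_label %||% pa$ego_attributes$name

  got_ya <- sort(matches$ya_rank[!is.na(matches$ya_rank)])
  got_pa <- sort(matches$pa_rank[!is.na(matches$pa_rank)])
  if (!identical(got_ya, sort(ya$alters$rank)) ||
      !identical(got_pa, sort(pa$alters$rank)) ||
      anyDuplicated(got_ya) > 0 || anyDuplicated(got_pa) > 0) {
    stop("match table does not cover the two rosters exactly once each",
         call. = FALSE)
  }

  nodes <- matches
  nodes$role_class <- vapply(seq_len(nrow(nodes)), function(i) {
    if (!is.na(nodes$ya_rank[i])) {
      ya$alters$role_class[match(nodes$ya_rank[i], ya$alters$rank)]
    } else {
      pa$alters$role_class[match(nodes$pa_rank[i], pa$alters$rank)]
    }
  }, character(1))
  parent_node <- NA_character_
  if (!is.null(parent_label) && !is.na(parent_label) &&
      nzchar(trimws(parent_label))) {
    pk <- normalize_name(parent_label)
    hit <- which(normalize_name(nodes$label) == pk & !is.na(nodes$ya_rank))
    if (length(hit) >= 1) parent_node <- nodes$unified_id[hit[1]]
  }
  nodes$is_parent <- nodes$unified_id %in% parent_node

  edge_rows <- list(); disc_rows <- list(); unobs_rows <- list()
  nn <- nrow(nodes)
  if (nn >= 2) {
    for (i in seq_len(nn - 1)) {
      for (j in seq(i + 1, nn)) {
        ya_v <- freq_lookup(ya, nodes$ya_rank[i], nodes$ya_rank[j])
        pa_v <- freq_lookup(pa, nodes$pa_rank[i], nodes$pa_rank[j])
        if (is.na(ya_v) && is.na(pa_v)) {
          # a parent-to-own-roster pair is generator-implied, not
          # unobservable; every other doubly-unseen pair is flagged
          implied_pair <- !is.na(parent_node) &&
            ((nodes$unified_id[i] == parent_node && !is.na(nodes$pa_rank[j])) ||
               (nodes$unified_id[j] == parent_node && !is.na(nodes$pa_rank[i])))
          if (!implied_pair) {
            unobs_rows[[length(unobs_rows) + 1]] <- tibble::tibble(
              node_a = nodes$unified_id[i], node_b = nodes$unified_id[j],
              reason = "unobservable"
            )
          }
          next
        }
        resolved <- max(ya_v, pa_v, na.rm = TRUE)
        if (!is.na(ya_v) && !is.na(pa_v) && ya_v != pa_v) {
          disc_rows[[length(disc_rows) + 1]] <- tibble::tibble(
            node_a = nodes$unified_id[i], node_b = nodes$unified_id[j],
            ya_value = ya_v, pa_value = pa_v, resolved_value = resolved
          )
        }
        if (resolved >= 1) {
          src <- if (!is.na(ya_v) && !is.na(pa_v)) "both"
          else if (!is.na(ya_v)) "ya" else "pa"
          edge_rows[[length(edge_rows) + 1]] <- tibble::tibble(
            node_a = nodes$unified_id[i], node_b = nodes$unified_id[j],
            weight = as.integer(resolved), source = src, implied = FALSE
          )
        }
      }
    }
  }
  edges <- if (length(edge_rows)) dplyr::bind_rows(edge_rows) else
    tibble::tibble(node_a = character(), node_b = character(),
                   weight = integer(), source = character(),
                   implied = logical())
  if (!is.na(parent_node)) {
    pa_nodes <- nodes$unified_id[!is.na(nodes$pa_rank) &
                                   nodes$unified_id != parent_node]
    for (x in pa_nodes) {
      lo <- min(parent_node, x); hi <- max(parent_node, x)
      already <- any(edges$node_a == lo & edges$node_b == hi)
      if (!already) {
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          node_a = lo, node_b = hi, weight = NA_integer_,
          source = "generator", implied = TRUE
        ))
      }
    }
  }
  structure(
    list(
      pair_id = pair_id,
      nodes = nodes[, c("unified_id", "label", "role_class", "provenance",
                        "ya_rank", "pa_rank", "match_basis", "needs_review",
                        "is_parent")],
      parent_node = parent_node,
      edges = edges,
      discrepancies = if (length(disc_rows)) dplyr::bind_rows(disc_rows) else
        tibble::tibble(node_a = character(), node_b = character(),
                       ya_value = integer(), pa_value = integer(),
                       resolved_value = integer()),
      unobserved = if (length(unobs_rows)) dplyr::bind_rows(unobs_rows) else
        tibble::tibble(node_a = character(), node_b = character(),
                       reason = character()),
      ya_net = as_ego_network(ya),
      pa_net = as_ego_network(pa),
      ya_id = ya$ego_id,
      pa_id = pa$ego_id
    ),
    class = "duo_network"
  )
}

#' @export
print.duo_network <- function(x, ...) {
  tab <- table(factor(x$nodes$provenance,
                      levels = c("both", "ya_only", "pa_only")))
  cat("<duo_network> ", x$pair_id, ": ", nrow(x$nodes), " alters (",
      tab[["both"]], " overlap, ", tab[["ya_only"]], " YA-only, ",
      tab[["pa_only"]], " parent-only), ",
      sum(!x$edges$implied), " resolved ties, ",
      nrow(x$discrepancies), " discrepanc",
      if (nrow(x$discrepancies) == 1) "y" else "ies", "\n", sep = "")
  if (!is.na(x$parent_node)) {
    cat("  parent node:", x$parent_node, "(named by the young adult)\n")
  } else {
    cat("  parent not named by the young adult\n")
  }
  invisible(x)
}
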