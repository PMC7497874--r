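# Duocentric measures: the six overall measures, the five 75%-rule
# characteristics, and the social-capital configuration with ADD accounting
# over parent-unique alters.

#' Overlap and unique member counts
#'
#' Overlap members are alters named by both respondents; unique members are
#' named by only one. The parent respondent, when named by the young adult
#' and therefore present as a node, is counted in neither bucket: the parent
#' belongs to both networks by construction (as the ego of one of them), so
#' the counts run over non-respondent alters only.
#'
#' @param duo A [merge_duocentric()] network.
#' @return List: `overlap`, `unique_ya`, `unique_pa`.
#' @export
overlap_and_unique <- function(duo) {
  stopifnot(inherits(duo, "duo_network"))
  p <- duo$nodes$provenance[!duo$nodes$is_parent]
  list(
    overlap = sum(p == "both"),
    unique_ya = sum(p == "ya_only"),
    unique_pa = sum(p == "pa_only")
  )
}

#' Parent centrality
#'
#' The number of alters tied to the parent divided by the total number of
#' alters minus the parent. In the default `"ya"` frame this is computed on
#' the young adult's own alter network: the parent must have been named by
#' the young adult (otherwise `NA`), the denominator is the young adult's
#' roster size minus one, and ties are the young adult's reported
#' alter-alter ties to the parent. The `"merged"` frame instead uses all
#' merged alters and all resolved ties including the generator-implied
#' parent ties; it has no counterpart in per-respondent reporting and is
#' labeled accordingly.
#'
#' @param duo A [merge_duocentric()] network.
#' @param frame `"ya"` (default) or `"merged"`.
#' @return Fraction in `[0, 1]`, or `NA` when the parent was not named by
#'   the young adult (or the frame has no other alters).
#' @export
parent_centrality <- function(duo, frame = c("ya", "merged")) {
  stopifnot(inherits(duo, "duo_network"))
  frame <- match.arg(frame)
  if (is.na(duo$parent_node)) return(NA_real_)
  if (frame == "ya") {
    prank <- duo$nodes$ya_rank[duo$nodes$unified_id == duo$parent_node]
    if (is.na(prank)) return(NA_real_)
    net <- duo$ya_net
    n <- nrow(net$alters)
    if (n < 2) return(NA_real_)
    deg <- sum(net$edges$a == prank | net$edges$b == prank)
    return(deg / (n - 1))
  }
  n <- nrow(duo$nodes)
  if (n < 2) return(NA_real_)
  deg <- sum(duo$edges$node_a == duo$parent_node |
               duo$edges$node_b == duo$parent_node)
  deg / (n - 1)
}

tie_fraction <- function(duo, node) {
  e <- duo$edges[!duo$edges$implied, , drop = FALSE]
  others <- setdiff(duo$nodes$unified_id, node)
  if (length(others) == 0) return(NA_real_)
  deg <- sum(e$node_a == node | e$node_b == node)
  deg / length(others)
}

#' The five duocentric network characteristics
#'
#' Yes/no codes for a matched pair: whether the young adult named alters the
#' parent did not (`youth_only_alters`), whether the parent named alters the
#' young adult did not (`parent_only_alters`), whether the parent's roster
#' is a subset of the young adult's (`parent_network_is_subset`), whether
#' every overlap alter is tied to most other merged alters
#' (`overlap_alters_high_tie`), and whether the parent is tied to most other
#' alters (`parent_high_centrality`). "Most" means a tie fraction at or
#' above `threshold` (default 0.75, i.e. 75% or more). A pair whose parent
#' was never named by the young adult codes `parent_high_centrality` as
#' `"no"`; a pair with no overlap alters codes `overlap_alters_high_tie` as
#' `"no"`.
#'
#' @param duo A [merge_duocentric()] network.
#' @param threshold High-tie fraction cutoff (default 0.75).
#' @return Named character vector of `"yes"`/`"no"` codes.
#' @export
characteristics <- function(duo, threshold = 0.75) {
  stopifnot(inherits(duo, "duo_network"))
  ou <- overlap_and_unique(duo)
  overlap_nodes <- duo$nodes$unified_id[duo$nodes$provenance == "both"]
  overlap_high <- length(overlap_nodes) > 0 &&
    all(vapply(overlap_nodes, function(nd) {
      f <- tie_fraction(duo, nd)
      !is.na(f) && f >= threshold
    }, logical(1)))
  pc <- parent_centrality(duo, frame = "ya")
  yn <- function(x) if (isTRUE(x)) "yes" else "no"
  c(
    parent_only_alters = yn(ou$unique_pa > 0),
    youth_only_alters = yn(ou$unique_ya > 0),
    parent_network_is_subset = yn(ou$unique_pa == 0),
    overlap_alters_high_tie = yn(overlap_high),
    parent_high_centrality = yn(!is.na(pc) && pc >= threshold)
  )
}

#' Six overall duocentric measures for a matched pair
#'
#' Mirrors the per-pair report structure: per-respondent alter network size,
#' density, and disconnected counts, overlap and unique member counts, and
#' parent centrality (young-adult frame, as a fraction).
#'
#' @param duo A [merge_duocentric()] network.
#' @return One-row tibble.
#' @export
duo_measures <- function(duo) {
  stopifnot(inherits(duo, "duo_network"))
  ou <- overlap_and_unique(duo)
  tibble::tibble(
    pair_id = duo$pair_id,
    ya_size = network_size(duo$ya_net),
    pa_size = network_size(duo$pa_net),
    ya_density = network_density(duo$ya_net),
    pa_density = network_density(duo$pa_net),
    overlap = ou$overlap,
    unique_ya = ou$unique_ya,
    unique_pa = ou$unique_pa,
    disconnected_ya = disconnected_count(duo$ya_net),
    disconnected_pa = disconnected_count(duo$pa_net),
    parent_centrality = parent_centrality(duo),
    n_discrepancies = nrow(duo$discrepancies)
  )
}

#' Social-capital configuration with ADD accounting
#'
#' Per-respondent role and support percentages (via the egocentric measure
#' suite), plus the ADD counts: for each role class and support type, the
#' number of parent-unique alters (named only by the parent) carrying it —
#' the additional roles and resources the parent's network contributes
#' beyond the young adult's own. A parent roster that is a subset of the
#' young adult's therefore adds nothing (all ADD counts 0).
#'
#' @param duo A [merge_duocentric()] network.
#' @return List of class `social_capital_config`: `ya` and `pa` (named
#'   vectors of percentages over roles, supports, and family friendship) and
#'   `add_counts` (named integer vector over the same keys).
#' @export
social_capital_config <- function(duo) {
  stopifnot(inherits(duo, "duo_network"))
  pct_vec <- function(net) {
    rc <- role_composition(net)
    sp <- support_prevalence(net)
    c(rc, family_friendship = family_friendship_pct(net), sp)
  }
  pa_only_ranks <- duo$nodes$pa_rank[duo$nodes$provenance == "pa_only"]
  pa_al <- duo$pa_net$alters
  uniq <- pa_al[pa_al$rank %in% pa_only_ranks, , drop = FALSE]
  add <- c(
    vapply(role_classes(), function(cl)
      sum(uniq$role_class == cl), integer(1)),
    family_friendship = sum(uniq$role_class == "family" & uniq$friendship),
    vapply(support_types(), function(s) sum(uniq[[s]]), integer(1))
  )
  structure(
    list(ya = pct_vec(duo$ya_net), pa = pct_vec(duo$pa_net),
         add_counts = add, n_pa_only = nrow(uniq)),
    class = "social_capital_config"
  )
}

#' @export
print.social_capital_config <- function(x, ...) {
  keys <- names(x$ya)
  cat("<social_capital_config>\n")
  cat(sprintf("  %-18s %8s %8s %5s\n", "", "YA %", "PA %", "ADD"))
  for (k in keys) {
    cat(sprintf("  %-18s %8.0f %8.0f %5d\n", k, x$ya[[k]], x$pa[[k]],
                x$add_counts[[k]]))
  }
  invisible(x)
}

#' Per-pair report combining measures, characteristics, and social capital
#'
#' @param duo A [merge_duocentric()] network.
#' @return List: `measures` (tibble), `characteristics` (named codes),
#'   `social_capital` (a [social_capital_config()]).
#' @export
duo_report <- function(duo) {
  list(
    measures = duo_measures(duo),
    characteristics = characteristics(duo),
    social_capital = social_capital_config(duo)
  )
}
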