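# Egocentric measures. All structural measures are alter-alter only: the ego
# is tied to every named alter by construction of the name generator, so ego
# ties carry no information and are never counted.

#' Network size
#'
#' Number of alters named; the ego is not counted.
#'
#' @param net An [ego_network()].
#' @return Integer count.
#' @export
network_size <- function(net) {
  stopifnot(inherits(net, "ego_network"))
  nrow(net$alters)
}

#' Alter-alter network density
#'
#' Number of reported alter-alter ties divided by the number of possible
#' alter pairs, `choose(n, 2)`. Undefined (`NA`) for networks with fewer than
#' two alters, where there are no possible pairs. A two-alter network with no
#' tie has density 0 (one possible pair, zero ties).
#'
#' @param net An [ego_network()].
#' @return Fraction in `[0, 1]`, or `NA` when `network_size(net) < 2`.
#' @export
#' @examples
#' # 5 alters, one isolate, the remaining 4 fully tied: 6/10 = 0.6
#' al <- tibble::tibble(
#'   label = paste("Alter", 1:5), rank = 1:5,
#'   role_raw = "friend", role_class = "community",
#'   friendship = TRUE, emotional = FALSE, advice = FALSE,
#'   financial = FALSE, logistical = FALSE, job = FALSE
#' )
#' idx <- utils::combn(4, 2)
#' net <- ego_network("YA1", al,
#'   tibble::tibble(a = idx[1, ], b = idx[2, ], weight = 1L))
#' network_density(net)
network_density <- function(net) {
  n <- network_size(net)
  if (n < 2) return(NA_real_)
  nrow(net$edges) / choose(n, 2)
}

#' Role composition
#'
#' Percentage of alters in each role class. Sums to 100 up to rounding; the
#' raw (unrounded) percentages are returned.
#'
#' @param net An [ego_network()].
#' @return Named numeric vector over [role_classes()], or all-`NA` for an
#'   empty network.
#' @export
role_composition <- function(net) {
  n <- network_size(net)
  if (n == 0) {
    return(setNames(rep(NA_real_, 3), role_classes()))
  }
  counts <- vapply(role_classes(), function(cl)
    sum(net$alters$role_class == cl), numeric(1))
  100 * counts / n
}

#' Support prevalence
#'
#' For each support type, the percentage of named alters who provide it:
#' 100 * (# alters flagged) / network size.
#'
#' @param net An [ego_network()].
#' @return Named numeric vector over [support_types()], or all-`NA` for an
#'   empty network.
#' @export
support_prevalence <- function(net) {
  n <- network_size(net)
  if (n == 0) {
    return(setNames(rep(NA_real_, length(support_types())), support_types()))
  }
  vapply(support_types(), function(s)
    100 * sum(net$alters[[s]]) / n, numeric(1))
}

#' Family friendship percentage
#'
#' Percentage of *family* alters who provide friendship (the denominator is
#' the family alters only, not the whole roster). `NA` when the network has
#' no family alters; cohort means coerce that `NA` to 0 (see
#' [cohort_summary()]).
#'
#' @param net An [ego_network()].
#' @return Percent in `[0, 100]` or `NA`.
#' @export
family_friendship_pct <- function(net) {
  stopifnot(inherits(net, "ego_network"))
  fam <- net$alters[net$alters$role_class == "family", , drop = FALSE]
  if (nrow(fam) == 0) return(NA_real_)
  100 * sum(fam$friendship) / nrow(fam)
}

#' Disconnected network members
#'
#' Number of alters with no ties to any other alter (the implicit ego tie is
#' ignored).
#'
#' @param net An [ego_network()].
#' @return Integer count.
#' @export
disconnected_count <- function(net) {
  stopifnot(inherits(net, "ego_network"))
  touched <- unique(c(net$edges$a, net$edges$b))
  sum(!net$alters$rank %in% touched)
}

#' Per-ego measure row
#'
#' All egocentric measures for one network as a one-row tibble.
#'
#' @param net An [ego_network()].
#' @return One-row tibble with size, density, role and support percentages,
#'   family friendship, and disconnected count.
#' @export
ego_measures <- function(net) {
  rc <- role_composition(net)
  sp <- support_prevalence(net)
  tibble::tibble(
    ego_id = net$ego_id,
    network_size = network_size(net),
    density = network_density(net),
    pct_family = rc[["family"]],
    pct_community = rc[["community"]],
    pct_professional = rc[["professional"]],
    pct_friendship = sp[["friendship"]],
    pct_family_friendship = family_friendship_pct(net),
    pct_emotional = sp[["emotional"]],
    pct_advice = sp[["advice"]],
    pct_financial = sp[["financial"]],
    pct_logistical = sp[["logistical"]],
    pct_job = sp[["job"]],
    disconnected = disconnected_count(net)
  )
}

#' Cohort-level summary of egocentric measures
#'
#' Unweighted means over egos of each per-ego measure, plus the median
#' network size. Density is averaged over the egos for which it is defined
#' (networks with >= 2 alters). Per-ego family-friendship values that are
#' `NA` because the network contains no family alters enter the mean as 0,
#' so a subgroup naming no family reports a 0% family-friendship mean rather
#' than a missing one.
#'
#' @param nets Nonempty list of [ego_network()] objects (an [ego_survey()]
#'   list is converted automatically).
#' @return List of class `cohort_summary`: `n_egos`, `per_ego` (tibble of
#'   [ego_measures()] rows), `mean_network_size`, `median_network_size`,
#'   `mean_density`, `mean_role_pct`, `mean_support_pct`,
#'   `mean_family_friendship_pct`, `mean_disconnected`.
#' @export
cohort_summary <- function(nets) {
  if (length(nets) == 0) stop("empty cohort", call. = FALSE)
  nets <- lapply(nets, function(x) {
    if (inherits(x, "ego_survey")) as_ego_network(x) else x
  })
  per <- dplyr::bind_rows(lapply(nets, ego_measures))
  ff <- ifelse(is.na(per$pct_family_friendship), 0,
               per$pct_family_friendship)
  structure(
    list(
      n_egos = length(nets),
      per_ego = per,
      mean_network_size = mean(per$network_size),
      median_network_size = stats::median(per$network_size),
      mean_density = mean(per$density, na.rm = TRUE),
      mean_role_pct = c(
        family = mean(per$pct_family, na.rm = TRUE),
        community = mean(per$pct_community, na.rm = TRUE),
        professional = mean(per$pct_professional, na.rm = TRUE)
      ),
      mean_support_pct = c(
        friendship = mean(per$pct_friendship, na.rm = TRUE),
        emotional = mean(per$pct_emotional, na.rm = TRUE),
        advice = mean(per$pct_advice, na.rm = TRUE),
        financial = mean(per$pct_financial, na.rm = TRUE),
        logistical = mean(per$pct_logistical, na.rm = TRUE),
        job = mean(per$pct_job, na.rm = TRUE)
      ),
      mean_family_friendship_pct = mean(ff),
      mean_disconnected = mean(per$disconnected)
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> N =", x$n_egos, "egos\n")
  cat(sprintf("  network size: mean %.2f, median %g\n",
              x$mean_network_size, x$median_network_size))
  cat(sprintf("  density (defined networks): %.2f\n", x$mean_density))
  cat(sprintf("  roles %%: family %.0f / community %.0f / professional %.0f\n",
              x$mean_role_pct[["family"]], x$mean_role_pct[["community"]],
              x$mean_role_pct[["professional"]]))
  cat(sprintf(
    "  support %%: friendship %.0f, emotional %.0f, advice %.0f, financial %.0f, logistical %.0f, job %.0f\n",
    x$mean_support_pct[["friendship"]], x$mean_support_pct[["emotional"]],
    x$mean_support_pct[["advice"]], x$mean_support_pct[["financial"]],
    x$mean_support_pct[["logistical"]], x$mean_support_pct[["job"]]))
  cat(sprintf("  family friendship %%: %.0f\n",
              x$mean_family_friendship_pct))
  invisible(x)
}
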