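# Peer-exposure predictors: average responses of a focal pupil's nominated
# friends, school class (excluding self) and school year group (excluding
# self), at each wave; percent-susceptible analogues for binary outcomes.

.peer_ids <- function(i, nominations, wave) {
  ed <- nominations
  if ("wave" %in% names(ed)) ed <- ed[ed$wave == wave, , drop = FALSE]
  ed$nominee_id[ed$nominator_id == i]
}

.exposure_of <- function(values, is_binary) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0) return(list(exposure = NA_real_, n_peers = 0L))
  v <- if (is_binary) 100 * mean(values[ok]) else mean(values[ok])
  list(exposure = v, n_peers = n)
}

.is_binary_outcome <- function(cohort, outcome) {
  v <- cohort[[outcome_col(outcome, 0)]]
  all(v %in% c(0, 1, NA))
}

.outcome_values <- function(cohort, outcome, wave) {
  cl <- outcome_col(outcome, wave)
  if (!cl %in% names(cohort)) pm_stop("unknown outcome column '%s'", cl)
  cohort[[cl]]
}

#' Mean outcome of a pupil's nominated friends
#'
#' Averages the outcome values of pupil `i`'s directed out-neighbours
#' (the friends `i` nominated) at the given wave; nominated friends with
#' missing values are excluded, and zero contributing peers yields a missing
#' exposure.
#'
#' @param i Focal pupil id.
#' @param outcome Outcome name.
#' @param wave Wave of peer measurement (0 or 1); the nomination wave
#'   matches the measurement wave.
#' @param nominations Nomination edge list (`nominator_id`, `nominee_id`,
#'   `wave`).
#' @param cohort Cohort data frame.
#' @return List with `exposure` and `n_peers`.
#' @export
friend_mean <- function(i, outcome, wave, nominations, cohort) {
  vals <- .outcome_values(cohort, outcome, wave)
  peers <- .peer_ids(i, nominations, wave)
  .exposure_of(vals[match(peers, cohort$pupil_id)],
               .is_binary_outcome(cohort, outcome))
}

.group_mean_excluding_self <- function(i, outcome, wave, cohort, group_col) {
  vals <- .outcome_values(cohort, outcome, wave)
  row <- match(i, cohort$pupil_id)
  if (is.na(row)) pm_stop("pupil '%s' not on roster", i)
  members <- which(cohort[[group_col]] == cohort[[group_col]][row])
  members <- setdiff(members, row)
  if (length(members) == 0) {
    pm_warn("SINGLETON_GROUP", "pupil %s is alone in its %s", i, group_col)
    return(list(exposure = NA_real_, n_peers = 0L))
  }
  .exposure_of(vals[members], .is_binary_outcome(cohort, outcome))
}

#' Mean outcome of a pupil's classmates, excluding the pupil
#'
#' @inheritParams friend_mean
#' @return List with `exposure` and `n_peers`.
#' @export
class_mean_excluding_self <- function(i, outcome, wave, cohort) {
  .group_mean_excluding_self(i, outcome, wave, cohort, "class_id")
}

#' Mean outcome of a pupil's school-year group, excluding the pupil
#'
#' The year group is the school roster (one year group per school).
#'
#' @inheritParams friend_mean
#' @return List with `exposure` and `n_peers`.
#' @export
year_mean_excluding_self <- function(i, outcome, wave, cohort) {
  .group_mean_excluding_self(i, outcome, wave, cohort, "school_id")
}

#' Percentage of peers positive on a binary outcome
#'
#' @inheritParams friend_mean
#' @param peer_group `"friends"`, `"class"` or `"year"`.
#' @return List with `exposure` (0-100) and `n_peers`.
#' @export
peer_percentage <- function(i, outcome, peer_group, wave, nominations,
                            cohort) {
  if (!.is_binary_outcome(cohort, outcome)) {
    pm_stop("peer_percentage(): outcome '%s' is not binary", outcome)
  }
  switch(peer_group,
         friends = friend_mean(i, outcome, wave, nominations, cohort),
         class = class_mean_excluding_self(i, outcome, wave, cohort),
         year = year_mean_excluding_self(i, outcome, wave, cohort),
         pm_stop("unknown peer group '%s'", peer_group))
}

# vectorised group means excluding self: (group sum - own) / (group n - own)
.group_exposures <- function(cohort, vals, group_col, is_binary) {
  g <- cohort[[group_col]]
  ok <- !is.na(vals)
  s <- tapply(ifelse(ok, vals, 0), g, sum)
  k <- tapply(ok, g, sum)
  si <- s[as.character(g)] - ifelse(ok, vals, 0)
  ki <- k[as.character(g)] - ok
  exposure <- ifelse(ki > 0, si / ki, NA_real_)
  if (is_binary) exposure <- 100 * exposure
  list(exposure = unname(exposure), n_peers = as.integer(unname(ki)))
}

.friend_exposures <- function(cohort, vals, nominations, wave, is_binary) {
  ed <- nominations
  if ("wave" %in% names(ed)) ed <- ed[ed$wave == wave, , drop = FALSE]
  v <- vals[match(ed$nominee_id, cohort$pupil_id)]
  ok <- !is.na(v)
  exposure <- rep(NA_real_, nrow(cohort))
  npeer <- rep(0L, nrow(cohort))
  if (any(ok)) {
    s <- rowsum(v[ok], ed$nominator_id[ok])
    k <- rowsum(rep(1L, sum(ok)), ed$nominator_id[ok])
    idx <- match(rownames(s), as.character(cohort$pupil_id))
    exposure[idx] <- s / k
    npeer[idx] <- k
  }
  if (is_binary) exposure <- 100 * exposure
  list(exposure = exposure, n_peers = npeer)
}

#' Build the full peer-exposure table
#'
#' One row per pupil x outcome x peer group x wave holding the mean (or, for
#' binary outcomes, the percentage) of contributing peers' values and the
#' number of contributing peers. Exposure is missing iff no peer
#' contributes.
#'
#' @param cohort Cohort data frame.
#' @param nominations Nomination edge list with a `wave` column.
#' @param outcomes Character vector of outcome names (default: all outcomes
#'   present as `<name>_w0` columns is not inferred; pass explicitly).
#' @param peer_groups Subset of `c("friends", "class", "year")`.
#' @param waves Waves of peer measurement (default `c(0, 1)`).
#' @return Data frame with columns `pupil_id`, `outcome`, `peer_group`,
#'   `wave`, `exposure`, `n_peers`.
#' @export
build_exposure_table <- function(cohort, nominations, outcomes,
                                 peer_groups = c("friends", "class", "year"),
                                 waves = c(0L, 1L)) {
  out <- list()
  for (o in outcomes) {
    bin <- .is_binary_outcome(cohort, o)
    for (w in waves) {
      vals <- .outcome_values(cohort, o, w)
      for (pg in peer_groups) {
        e <- switch(pg,
          friends = .friend_exposures(cohort, vals, nominations, w, bin),
          class = .group_exposures(cohort, vals, "class_id", bin),
          year = .group_exposures(cohort, vals, "school_id", bin),
          pm_stop("unknown peer group '%s'", pg))
        out[[length(out) + 1L]] <- data.frame(
          pupil_id = cohort$pupil_id, outcome = o, peer_group = pg,
          wave = w, exposure = e$exposure, n_peers = e$n_peers,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
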