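#' Study list descriptor
#'
#' A study list is the ordered set of to-be-remembered items (story details or
#' words). Study positions are the integers `1..n_items`.
#'
#' @param unit_id Identifier of the story or wordlist.
#' @param n_items Number of studied items (must be at least 2).
#' @param labels Optional character vector of item labels, length `n_items`.
#'
#' @return An object of class `study_list`.
#' @export
#' @examples
#' study_list("story1", 10)
study_list <- function(unit_id, n_items, labels = NULL) {
  n_items <- as.integer(n_items)
  stopifnot(length(unit_id) == 1L, length(n_items) == 1L, !is.na(n_items))
  if (n_items < 2L) {
    stop("`n_items` must be at least 2, got ", n_items, call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != n_items) {
    stop("`labels` must have length `n_items`", call. = FALSE)
  }
  structure(
    list(unit_id = unit_id, n_items = n_items, labels = labels),
    class = "study_list"
  )
}

#' @export
print.study_list <- function(x, ...) {
  cat("<study_list> unit", format(x$unit_id), "with", x$n_items, "items\n")
  invisible(x)
}

#' Clean a raw recall ordering
#'
#' Prepares a raw recall ordering for transition analysis: out-of-list
#' intrusions (coded `NA`) are dropped, and repetitions of an already-recalled
#' study position are ignored, keeping only the first occurrence. With the
#' default `repeat_policy = "bridge"`, transitions are later formed between the
#' remaining successive recalls, bridging across the removed entries; with
#' `"break"`, no transition is formed across a removed repetition (the
#' chain restarts after the repeat).
#'
#' @param raw_positions Integer vector of recalled study positions in output
#'   order. Intrusions (recalls not on the study list) are coded `NA`.
#' @param study A [study_list()].
#' @param repeat_policy Either `"bridge"` (default) or `"break"`; see above.
#'
#' @return An integer vector of distinct study positions in recall order.
#'   Under `repeat_policy = "break"` the vector carries an attribute
#'   `"no_transition_into"`: a logical vector marking elements that a
#'   repetition immediately preceded, into which no transition is scored.
#' @export
#' @examples
#' clean_recall(c(2, 4, 4, 3), study_list("s", 10))  # -> 2 4 3
clean_recall <- function(raw_positions, study,
                         repeat_policy = c("bridge", "break")) {
  repeat_policy <- match.arg(repeat_policy)
  stopifnot(inherits(study, "study_list"))
  pos <- as.integer(raw_positions)
  if (length(pos) == 0L) {
    stop("`raw_positions` must be nonempty", call. = FALSE)
  }
  in_list <- !is.na(pos)
  if (any(pos[in_list] < 1L | pos[in_list] > study$n_items)) {
    bad <- pos[in_list][pos[in_list] < 1L | pos[in_list] > study$n_items][1L]
    stop("study position ", bad, " outside 1..", study$n_items, call. = FALSE)
  }
  pos <- pos[in_list]
  keep <- !duplicated(pos)
  out <- pos[keep]
  if (repeat_policy == "break" && length(out) > 0L) {
    # an element is unreachable by a transition if the raw entry just before
    # its first occurrence was a repetition of something already recalled
    dropped_repeat <- !keep
    no_into <- logical(length(out))
    j <- 0L
    for (i in seq_along(pos)) {
      if (keep[i]) {
        j <- j + 1L
        if (i > 1L && dropped_repeat[i - 1L]) no_into[j] <- TRUE
      }
    }
    attr(out, "no_transition_into") <- no_into
  }
  out
}

#' Study positions still available for recall
#'
#' @param study A [study_list()].
#' @param recalled_so_far Integer vector of positions already recalled.
#' @return Integer vector of not-yet-recalled study positions.
#' @export
available_positions <- function(study, recalled_so_far) {
  stopifnot(inherits(study, "study_list"))
  recalled_so_far <- as.integer(recalled_so_far)
  if (length(recalled_so_far) &&
      any(recalled_so_far < 1L | recalled_so_far > study$n_items)) {
    stop("recalled positions outside 1..", study$n_items, call. = FALSE)
  }
  setdiff(seq_len(study$n_items), recalled_so_far)
}

#' Percentile score of a single recall transition
#'
#' The temporal distance of the actual transition is compared with the
#' distances to every item still available for recall. Distances are
#' reverse-ranked so that the smallest distance receives the largest rank,
#' with tied distances sharing the mean of their ranks; the percentile score
#' is (R - 1) / (N - 1), where R is the rank of the actual distance and N the
#' number of available items. A score of 1 means the closest possible item
#' was recalled next; 0 means the farthest.
#'
#' @param from_pos Study position of the just-recalled item (not in
#'   `available`).
#' @param to_pos Study position of the next recalled item (must be in
#'   `available`).
#' @param available Integer vector of study positions still available.
#'
#' @return A percentile in `[0, 1]`, or `NA` when only one item was available
#'   (the transition is forced and carries no information).
#' @export
#' @examples
#' transition_percentile(2, 1, c(1, 3:10))  # 0.9375
transition_percentile <- function(from_pos, to_pos, available) {
  available <- as.integer(available)
  if (!(to_pos %in% available)) {
    stop("transition to position ", to_pos,
         " which is not available for recall", call. = FALSE)
  }
  if (from_pos %in% available) {
    stop("`from_pos` must already have been recalled", call. = FALSE)
  }
  n <- length(available)
  if (n == 1L) return(NA_real_)
  d <- abs(available - from_pos)
  # reverse rank: smallest distance -> largest rank; ties share the mean rank
  r <- rank(-d, ties.method = "average")
  actual <- r[match(to_pos, available)]
  (actual - 1) / (n - 1)
}

# Internal fast path: percentiles for every transition of a cleaned sequence.
# Returns a numeric vector, NA for forced (N = 1) transitions and, under the
# break policy, for transitions into elements flagged by clean_recall().
transition_percentiles <- function(positions, n_items) {
  k <- length(positions)
  if (k < 2L) return(numeric(0))
  no_into <- attr(positions, "no_transition_into")
  avail <- rep(TRUE, n_items)
  avail[positions[1L]] <- FALSE
  out <- numeric(k - 1L)
  idx <- seq_len(n_items)
  for (j in 2:k) {
    from <- positions[j - 1L]
    to <- positions[j]
    if (!is.null(no_into) && no_into[j]) {
      out[j - 1L] <- NA_real_
    } else {
      av <- idx[avail]
      n <- length(av)
      if (n == 1L) {
        out[j - 1L] <- NA_real_
      } else {
        r <- rank(-abs(av - from), ties.method = "average")
        out[j - 1L] <- (r[match(to, av)] - 1) / (n - 1)
      }
    }
    avail[to] <- FALSE
  }
  out
}

#' Temporal organization score of a recall sequence
#'
#' The mean of the per-transition percentile scores (see
#' [transition_percentile()]) over all successive pairs of a cleaned recall
#' sequence. 1.0 reflects perfect temporal clustering (only +1 lag
#' transitions); 0.5 is the chance level under uniformly random recall order.
#'
#' @param positions Cleaned recall sequence (distinct study positions in
#'   recall order), e.g. from [clean_recall()].
#' @param study A [study_list()] (or a bare item count).
#'
#' @return A single score in `[0, 1]`, or `NA` when no transition has a
#'   defined percentile (fewer than two recalls, or only forced transitions).
#' @export
#' @examples
#' s10 <- study_list("s", 10)
#' temporal_organization_score(c(2, 1, 4), s10)  # 0.897... prints as .90
#' temporal_organization_score(c(1, 5, 9), s10)  # 0.383... prints as .38
temporal_organization_score <- function(positions, study) {
  n_items <- if (inherits(study, "study_list")) study$n_items else
    as.integer(study)
  positions <- check_sequence(positions, n_items)
  p <- transition_percentiles(positions, n_items)
  p <- p[!is.na(p)]
  if (length(p) == 0L) return(NA_real_)
  mean(p)
}

check_sequence <- function(positions, n_items) {
  no_into <- attr(positions, "no_transition_into")
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) {
    stop("recall sequence contains repetitions; run clean_recall() first",
         call. = FALSE)
  }
  if (length(positions) && any(positions < 1L | positions > n_items)) {
    stop("recall positions outside 1..", n_items, call. = FALSE)
  }
  attr(positions, "no_transition_into") <- no_into
  positions
}

#' Lag-conditional response probability table for one sequence
#'
#' For each signed lag in `-max_lag..-1, +1..+max_lag`, counts how often that
#' lag transition occurred and how often it could possibly have occurred,
#' given the list length and the items already recalled. The CRP is
#' occurred / possible. Denominator windows open only at steps where an
#' actual transition was made; an actual lag beyond `max_lag` contributes to
#' the possibility counts at its step but to no occurrence bin.
#'
#' @inheritParams temporal_organization_score
#' @param max_lag Truncation window for lags (default 5).
#'
#' @return A tibble with one row per signed lag: `lag`, `occurred`,
#'   `possible`, `crp` (`NA` where `possible` is 0).
#' @export
#' @examples
#' lag_crp(c(1, 2, 3), study_list("s", 10))
lag_crp <- function(positions, study, max_lag = 5L) {
  n_items <- if (inherits(study, "study_list")) study$n_items else
    as.integer(study)
  max_lag <- as.integer(max_lag)
  stopifnot(max_lag >= 1L)
  positions <- check_sequence(positions, n_items)
  cnt <- crp_counts(positions, n_items, max_lag)
  lags <- c(-max_lag:-1L, 1L:max_lag)
  tibble::tibble(
    lag = lags,
    occurred = cnt$occurred,
    possible = cnt$possible,
    crp = ifelse(cnt$possible > 0L, cnt$occurred / cnt$possible, NA_real_)
  )
}

# Internal: occurrence/possibility counts as plain integer vectors ordered
# like c(-max_lag:-1, 1:max_lag).
crp_counts <- function(positions, n_items, max_lag) {
  lags <- c(-max_lag:-1L, 1L:max_lag)
  occurred <- integer(2L * max_lag)
  possible <- integer(2L * max_lag)
  k <- length(positions)
  if (k >= 2L) {
    no_into <- attr(positions, "no_transition_into")
    avail <- rep(TRUE, n_items)
    avail[positions[1L]] <- FALSE
    for (j in 2:k) {
      from <- positions[j - 1L]
      to <- positions[j]
      if (is.null(no_into) || !no_into[j]) {
        targets <- from + lags
        ok <- targets >= 1L & targets <= n_items
        ok[ok] <- avail[targets[ok]]
        possible <- possible + ok
        lag <- to - from
        if (abs(lag) <= max_lag) {
          occurred[match(lag, lags)] <- occurred[match(lag, lags)] + 1L
        }
      }
      avail[to] <- FALSE
    }
  }
  list(occurred = occurred, possible = possible)
}

#' Pool lag-CRP tables across sequences
#'
#' Sums occurrence and possibility counts within groups and recomputes the
#' pooled CRP as the ratio of summed counts. Also reports the mean of the
#' per-sequence CRP values (`mean_crp`), the variant usually plotted.
#'
#' @param crp_table A tibble of per-sequence lag-CRP rows, e.g. from
#'   [crp_sequences()]: must contain `lag`, `occurred`, `possible`, `crp`.
#' @param by Character vector of grouping columns (may be empty for a single
#'   pooled curve).
#'
#' @return A tibble with one row per group x lag: summed `occurred` and
#'   `possible`, pooled `crp`, and `mean_crp`.
#' @export
aggregate_crp <- function(crp_table, by = character()) {
  stopifnot(all(c("lag", "occurred", "possible", "crp") %in% names(crp_table)))
  lag_sets <- dplyr::distinct(
    dplyr::summarise(
      dplyr::group_by(crp_table,
        dplyr::across(dplyr::any_of(c("participant_id", "unit_id", "timepoint", "task")))),
      .lags = paste(sort(.data$lag), collapse = ","), .groups = "drop"
    ), .data$.lags)
  if (nrow(lag_sets) > 1L) {
    stop("lag-CRP tables have mixed lag windows (different max_lag); ",
         "recompute with a common `max_lag`", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(crp_table, dplyr::across(dplyr::all_of(c(by, "lag")))),
    occurred = sum(.data$occurred),
    possible = sum(.data$possible),
    mean_crp = if (all(is.na(.data$crp))) NA_real_ else
      mean(.data$crp, na.rm = TRUE),
    .groups = "drop"
  )
  out$crp <- ifelse(out$possible > 0, out$occurred / out$possible, NA_real_)
  dplyr::relocate(out, "crp", .after = "possible")
}

#' Score every recall sequence in a dataset
#'
#' Computes the temporal organization score, transition counts, and percent
#' recall for each participant x unit x timepoint sequence.
#'
#' @param data A `recall_data` object ([read_recall_csv()] or
#'   [simulate_cohort()]).
#' @return A tibble with one row per sequence: identifying keys, `n_items`,
#'   `n_recalled`, `percent_recall`, `n_transitions` (transitions with a
#'   defined percentile), and `score` (`NA` when undefined).
#' @export
score_sequences <- function(data) {
  stopifnot(inherits(data, "recall_data"))
  seqs <- data$sequences
  res <- purrr::map2(seqs$positions, seqs$n_items, function(pos, n) {
    p <- transition_percentiles(pos, n)
    p <- p[!is.na(p)]
    c(n_transitions = length(p),
      score = if (length(p)) mean(p) else NA_real_)
  })
  m <- do.call(rbind, res)
  out <- seqs[setdiff(names(seqs), "positions")]
  out$n_recalled <- lengths(seqs$positions)
  out$percent_recall <- out$n_recalled / out$n_items
  out$n_transitions <- as.integer(m[, "n_transitions"])
  out$score <- m[, "score"]
  out
}

#' Lag-CRP rows for every recall sequence in a dataset
#'
#' @inheritParams score_sequences
#' @param max_lag Truncation window for lags (default 5).
#' @return A tibble with one row per sequence x signed lag: identifying keys
#'   plus `lag`, `occurred`, `possible`, `crp`.
#' @export
crp_sequences <- function(data, max_lag = 5L) {
  stopifnot(inherits(data, "recall_data"))
  max_lag <- as.integer(max_lag)
  seqs <- data$sequences
  lags <- c(-max_lag:-1L, 1L:max_lag)
  nl <- length(lags)
  counts <- purrr::map2(seqs$positions, seqs$n_items, function(pos, n) {
    crp_counts(check_sequence(pos, n), n, max_lag)
  })
  keys <- seqs[setdiff(names(seqs), "positions")]
  out <- keys[rep(seq_len(nrow(keys)), each = nl), ]
  out$lag <- rep(lags, nrow(keys))
  out$occurred <- unlist(purrr::map(counts, "occurred"), use.names = FALSE)
  out$possible <- unlist(purrr::map(counts, "possible"), use.names = FALSE)
  out$crp <- ifelse(out$possible > 0L, out$occurred / out$possible, NA_real_)
  tibble::as_tibble(out)
}
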