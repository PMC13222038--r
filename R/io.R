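#' Container for a validated recall dataset
#'
#' Bundles cleaned recall sequences with their study-list manifest. Most
#' users obtain one from [read_recall_csv()] or [simulate_cohort()] rather
#' than calling this constructor directly.
#'
#' @param sequences Tibble with columns `participant_id`, `group`, `task`,
#'   `unit_id`, `timepoint`, `n_items`, and a list-column `positions` of
#'   cleaned recall orders.
#' @param lists Tibble manifest with columns `unit_id`, `n_items`.
#' @param log Optional named list of validation counts.
#' @return An object of class `recall_data`.
#' @export
recall_data <- function(sequences, lists, log = list()) {
  needed <- c("participant_id", "group", "task", "unit_id", "timepoint",
              "n_items", "positions")
  missing <- setdiff(needed, names(sequences))
  if (length(missing)) {
    stop("`sequences` is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(c("unit_id", "n_items") %in% names(lists)))
  ok <- mapply(function(pos, n) {
    length(pos) >= 1L && !anyDuplicated(pos) && all(pos >= 1L & pos <= n)
  }, sequences$positions, sequences$n_items)
  if (!all(ok)) {
    stop("sequence ", which(!ok)[1L],
         " fails validation against its study list", call. = FALSE)
  }
  structure(
    list(sequences = tibble::as_tibble(sequences),
         lists = tibble::as_tibble(lists),
         log = log),
    class = "recall_data"
  )
}

#' @export
print.recall_data <- function(x, ...) {
  s <- x$sequences
  cat("<recall_data> ", nrow(s), " sequences, ",
      dplyr::n_distinct(s$participant_id), " participants, tasks: ",
      paste(unique(s$task), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read long-format recall data from CSV
#'
#' The recall CSV has one row per recalled item, columns `participant_id`,
#' `group`, `task`, `unit_id`, `timepoint`, `output_position`,
#' `study_position`, `is_intrusion`; the manifest CSV maps `unit_id` to
#' `n_items`. Rows are grouped into sequences by participant x unit x
#' timepoint, ordered by `output_position`, and passed through
#' [clean_recall()] (intrusions dropped, repetitions ignored).
#'
#' @param path Path to the recall CSV.
#' @param manifest_path Path to the study-list manifest CSV.
#' @param repeat_policy Passed to [clean_recall()].
#' @return A [recall_data()] object; its `$log` reports how many intrusion
#'   and repetition rows were dropped.
#' @export
read_recall_csv <- function(path, manifest_path,
                            repeat_policy = c("bridge", "break")) {
  repeat_policy <- match.arg(repeat_policy)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  need <- c("participant_id", "group", "task", "unit_id", "timepoint",
            "output_position", "study_position", "is_intrusion")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("recall CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("unit_id", "n_items") %in% names(manifest))) {
    stop("manifest CSV must have columns unit_id, n_items", call. = FALSE)
  }
  raw$.row <- seq_len(nrow(raw))
  raw <- dplyr::left_join(raw, manifest[c("unit_id", "n_items")],
                          by = "unit_id")
  if (anyNA(raw$n_items)) {
    bad <- raw$.row[is.na(raw$n_items)][1L]
    stop("row ", bad, ": unit_id not present in the manifest", call. = FALSE)
  }
  intr <- as.logical(raw$is_intrusion)
  oob <- !intr & (raw$study_position < 1L | raw$study_position > raw$n_items)
  if (any(oob)) {
    stop("row ", raw$.row[oob][1L], ": study_position ",
         raw$study_position[oob][1L], " exceeds list length ",
         raw$n_items[oob][1L], call. = FALSE)
  }
  dup <- duplicated(raw[c("participant_id", "unit_id", "timepoint",
                          "output_position")])
  if (any(dup)) {
    stop("row ", raw$.row[dup][1L],
         ": duplicate (participant, unit, timepoint, output_position)",
         call. = FALSE)
  }
  raw <- dplyr::arrange(raw, .data$participant_id, .data$task, .data$unit_id,
                        .data$timepoint, .data$output_position)
  grouped <- dplyr::group_by(raw, .data$participant_id, .data$group,
                             .data$task, .data$unit_id, .data$timepoint,
                             .data$n_items)
  n_intrusion <- 0L
  n_repeat <- 0L
  seqs <- dplyr::summarise(grouped, positions = {
    p <- .data$study_position
    p[as.logical(.data$is_intrusion)] <- NA_integer_
    list(p)
  }, .groups = "drop")
  cleaned <- purrr::map2(seqs$positions, seqs$n_items, function(p, n) {
    out <- clean_recall(p, study_list("x", n), repeat_policy = repeat_policy)
    n_intrusion <<- n_intrusion + sum(is.na(p))
    n_repeat <<- n_repeat + (sum(!is.na(p)) - length(out))
    out
  })
  seqs$positions <- cleaned
  seqs <- seqs[lengths(seqs$positions) > 0L, ]
  recall_data(
    seqs, manifest,
    log = list(n_rows = nrow(raw), n_sequences = nrow(seqs),
               dropped_intrusions = n_intrusion,
               dropped_repetitions = n_repeat)
  )
}

#' Write a recall dataset back to long-format CSV
#'
#' Inverse of [read_recall_csv()] for cleaned data: one row per recalled
#' item with `is_intrusion = FALSE` throughout.
#'
#' @param data A [recall_data()] object.
#' @param path Output path for the recall CSV.
#' @param manifest_path Output path for the manifest CSV.
#' @return Invisibly, the paths written.
#' @export
write_recall_csv <- function(data, path, manifest_path) {
  stopifnot(inherits(data, "recall_data"))
  seqs <- data$sequences
  long <- tidyr::unnest(
    dplyr::mutate(seqs,
      positions = purrr::map(.data$positions, function(p) {
        tibble::tibble(output_position = seq_along(p),
                       study_position = as.integer(p))
      })),
    "positions")
  long$is_intrusion <- FALSE
  long <- long[c("participant_id", "group", "task", "unit_id", "timepoint",
                 "output_position", "study_position", "is_intrusion")]
  readr::write_csv(long, path, progress = FALSE)
  readr::write_csv(data$lists[c("unit_id", "n_items")], manifest_path,
                   progress = FALSE)
  invisible(c(path, manifest_path))
}

#' Expand a recall dataset to per-item binary outcomes
#'
#' For each sequence and each study position of its list, emits whether the
#' item was recalled (1) or not (0). This is the response for the
#' recall-accuracy model.
#'
#' @inheritParams score_sequences
#' @return A tibble with the sequence keys plus `item` and `recalled`.
#' @export
recall_outcomes <- function(data) {
  stopifnot(inherits(data, "recall_data"))
  seqs <- data$sequences
  keys <- seqs[setdiff(names(seqs), "positions")]
  reps <- rep(seq_len(nrow(seqs)), seqs$n_items)
  out <- keys[reps, ]
  out$item <- unlist(lapply(seqs$n_items, seq_len), use.names = FALSE)
  rec <- unlist(purrr::map2(seqs$positions, seqs$n_items, function(p, n) {
    v <- integer(n); v[p] <- 1L; v
  }), use.names = FALSE)
  out$recalled <- rec
  tibble::as_tibble(out)
}
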