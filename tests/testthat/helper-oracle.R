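# Independent brute-force reference for scores and lag-CRP tables.
# It literally materializes, for every transition, the list of all possible
# lag transitions to not-yet-recalled items, sorts their absolute values,
# and hands out reverse ranks by explicit enumeration - sharing nothing
# with the package's incremental implementation.

brute_transitions <- function(positions, n_items) {
  lapply(seq_along(positions)[-1], function(j) {
    prev <- positions[j - 1L]
    not_recalled <- setdiff(seq_len(n_items), positions[seq_len(j - 1L)])
    list(actual_lag = positions[j] - prev,
         possible_lags = not_recalled - prev)
  })
}

brute_score <- function(positions, n_items) {
  trans <- brute_transitions(positions, n_items)
  percs <- vapply(trans, function(tr) {
    n <- length(tr$possible_lags)
    if (n < 2L) return(NA_real_)
    dists <- abs(tr$possible_lags)
    sorted_desc <- sort(dists, decreasing = TRUE)
    rank_of <- function(v) mean(which(sorted_desc == v))
    (rank_of(abs(tr$actual_lag)) - 1) / (n - 1)
  }, numeric(1))
  percs <- percs[!is.na(percs)]
  if (length(percs) == 0L) NA_real_ else mean(percs)
}

brute_crp <- function(positions, n_items, max_lag = 5L) {
  trans <- brute_transitions(positions, n_items)
  lags <- c(-max_lag:-1L, 1L:max_lag)
  occurred <- vapply(lags, function(l) {
    sum(vapply(trans, function(tr) tr$actual_lag == l, logical(1)))
  }, integer(1))
  possible <- vapply(lags, function(l) {
    sum(vapply(trans, function(tr) l %in% tr$possible_lags, logical(1)))
  }, integer(1))
  data.frame(lag = lags, occurred = occurred, possible = possible,
             crp = ifelse(possible > 0, occurred / possible, NA_real_))
}

# all ordered selections of `len` distinct elements of 1..n
all_recall_orders <- function(n, len) {
  if (len == 1L) return(as.list(seq_len(n)))
  shorter <- all_recall_orders(n, len - 1L)
  out <- list()
  for (s in shorter) {
    for (nxt in setdiff(seq_len(n), s)) {
      out[[length(out) + 1L]] <- c(s, nxt)
    }
  }
  out
}

random_sequence <- function(n_items, k) {
  sample(seq_len(n_items), k)
}
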