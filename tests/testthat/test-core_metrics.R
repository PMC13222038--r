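s10 <- study_list("s", 10)

test_that("clean_recall drops intrusions and keeps first occurrence of repeats", {
  expect_equal(clean_recall(c(2, 4, 4, 3), s10), c(2L, 4L, 3L))
  expect_equal(clean_recall(5, s10), 5L)
  expect_equal(clean_recall(c(1, NA, 3), s10), c(1L, 3L))
  expect_equal(clean_recall(c(NA, NA), s10), integer(0))
  expect_error(clean_recall(integer(0), s10), "nonempty")
  expect_error(clean_recall(c(2, 11), s10), "outside")
})

test_that("break policy withholds the transition that crosses a repetition", {
  out <- clean_recall(c(2, 4, 4, 3), s10, repeat_policy = "break")
  expect_equal(as.integer(out), c(2L, 4L, 3L))
  expect_equal(attr(out, "no_transition_into"), c(FALSE, FALSE, TRUE))
  # only the 2 -> 4 transition is scored: percentile of distance 2 among
  # the 9 items available after recalling item 2
  expect_equal(temporal_organization_score(out, s10),
               transition_percentile(2, 4, c(1, 3:10)))
  # bridging scores both transitions
  bridged <- clean_recall(c(2, 4, 4, 3), s10)
  expect_equal(temporal_organization_score(bridged, s10),
               mean(c(transition_percentile(2, 4, c(1, 3:10)),
                      transition_percentile(4, 3, c(1, 3, 5:10)))))
})

test_that("available_positions is the set difference with recalled items", {
  expect_equal(available_positions(s10, 2L), c(1L, 3:10))
  expect_equal(available_positions(s10, c(2L, 1L)), 3:10)
  expect_equal(available_positions(study_list("s", 3), 1:3), integer(0))
})

test_that("transition percentile matches hand-computed reverse-rank values", {
  expect_equal(transition_percentile(2, 1, c(1, 3:10)), 0.9375)
  expect_equal(transition_percentile(1, 4, 3:10), 6 / 7)
  expect_equal(transition_percentile(1, 10, 2:10), 0)
  expect_true(is.na(transition_percentile(2, 3, 3)))
  expect_error(transition_percentile(2, 5, c(1, 3)), "not available")
  expect_error(transition_percentile(2, 1, c(1, 2, 3)), "already")
})

test_that("percentile is 1 only at the strict minimum distance and 0 only at the strict maximum", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:15, 1)
    recalled <- sample(seq_len(n), sample(seq_len(n - 2), 1))
    from <- recalled[length(recalled)]
    avail <- setdiff(seq_len(n), recalled)
    to <- sample(avail, 1)
    p <- transition_percentile(from, to, avail)
    expect_gte(p, 0)
    expect_lte(p, 1)
    d <- abs(avail - from)
    d_act <- abs(to - from)
    if (p == 1) expect_true(sum(d == min(d)) == 1 && d_act == min(d))
    if (p == 0) expect_true(sum(d == max(d)) == 1 && d_act == max(d))
    if (d_act == min(d) && sum(d == min(d)) == 1) expect_equal(p, 1)
    if (d_act == max(d) && sum(d == max(d)) == 1) expect_equal(p, 0)
  }
})

test_that("temporal organization score reproduces the published worked examples", {
  expect_equal(round(temporal_organization_score(c(2, 1, 4), s10), 2), 0.90)
  expect_equal(round(temporal_organization_score(c(1, 5, 9), s10), 2), 0.38)
  expect_identical(temporal_organization_score(1:10, s10), 1)
  expect_true(is.na(temporal_organization_score(5L, s10)))
  expect_error(temporal_organization_score(c(2, 2, 3), s10), "repetitions")
})

test_that("+1 chains from the list start score exactly 1 at any length", {
  for (n in c(5L, 10L, 15L)) {
    s <- study_list("s", n)
    for (k in c(2L, 3L, n)) {
      expect_identical(temporal_organization_score(seq_len(k), s), 1)
    }
  }
  # a +1 chain starting mid-list leaves the backward neighbour available:
  # the distance-1 tie shares the mean rank, so each percentile dips just
  # below 1 while remaining the best untied value
  sc <- temporal_organization_score(4:6, study_list("s", 10))
  expect_lt(sc, 1)
  expect_gt(sc, 0.9)
})

test_that("lag_crp counts occurrences and possibilities per signed lag", {
  tab <- lag_crp(c(1, 2, 3), s10)
  get <- function(t, l, col) t[[col]][t$lag == l]
  expect_equal(get(tab, 1, "crp"), 1)
  expect_equal(get(tab, 1, "possible"), 2L)
  expect_equal(get(tab, 2, "crp"), 0)
  expect_equal(get(tab, 2, "possible"), 2L)
  # at the second transition position 1 is already recalled, so a -1 lag
  # was never possible in this series
  expect_equal(get(tab, -1, "possible"), 0L)
  expect_true(is.na(get(tab, -1, "crp")))

  tab2 <- lag_crp(c(2, 4), s10)
  expect_equal(get(tab2, 2, "crp"), 1)
  expect_equal(get(tab2, 1, "crp"), 0)
  expect_equal(get(tab2, -1, "crp"), 0)
  expect_equal(get(tab2, -1, "possible"), 1L)

  # actual lag +7 is outside the window: counts possibilities, no occurrence
  tab3 <- lag_crp(c(1, 8), s10)
  expect_equal(sum(tab3$occurred), 0L)
  expect_equal(tab3$possible[tab3$lag > 0], rep(1L, 5))
  expect_equal(tab3$possible[tab3$lag < 0], rep(0L, 5))
})

test_that("occurrence counts conserve the number of in-window transitions", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(6:15, 1)
    k <- sample(2:n, 1)
    pos <- random_sequence(n, k)
    tab <- lag_crp(pos, study_list("s", n))
    in_window <- sum(abs(diff(pos)) <= 5)
    expect_identical(sum(tab$occurred), in_window)
    expect_true(all(tab$occurred <= tab$possible))
  }
})

test_that("score and lag-CRP agree with the brute-force oracle on random sequences", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(8:15, 1)
    k <- sample(2:n, 1)
    pos <- random_sequence(n, k)
    s <- study_list("s", n)
    expect_equal(temporal_organization_score(pos, s), brute_score(pos, n))
    got <- lag_crp(pos, s)
    want <- brute_crp(pos, n)
    expect_equal(got$occurred, want$occurred)
    expect_equal(got$possible, want$possible)
  }
})

test_that("aggregate_crp pools counts, not per-sequence probabilities", {
  tabs <- dplyr::bind_rows(
    dplyr::mutate(lag_crp(c(1, 2), s10), participant_id = "a"),
    dplyr::mutate(lag_crp(c(3, 5, 4), s10), participant_id = "b")
  )
  pooled <- aggregate_crp(tabs)
  get <- function(t, l, col) t[[col]][t$lag == l]
  expect_equal(get(pooled, 1, "occurred"),
               get(tabs[tabs$participant_id == "a", ], 1, "occurred") +
                 get(tabs[tabs$participant_id == "b", ], 1, "occurred"))
  expect_equal(get(pooled, 1, "crp"),
               get(pooled, 1, "occurred") / get(pooled, 1, "possible"))
  # a single table pools to itself
  one <- dplyr::mutate(lag_crp(c(2, 4, 1), s10), participant_id = "a")
  same <- aggregate_crp(one)
  expect_equal(same$crp, one$crp)
  expect_equal(same$occurred, one$occurred)
  # empty denominators stay undefined
  expect_true(is.na(get(pooled, -5, "crp")))
  # mixed windows are refused
  mixed <- dplyr::bind_rows(
    dplyr::mutate(lag_crp(c(1, 2), s10), participant_id = "a"),
    dplyr::mutate(lag_crp(c(1, 2), s10, max_lag = 3), participant_id = "b"))
  expect_error(aggregate_crp(mixed), "mixed lag windows")
})

test_that("dataset-level scoring matches sequence-level calls", {
  cfg <- simulation_config(
    n_per_group = 3, wordlist = NULL,
    narrative = list(items_per_unit = c(10L, 12L),
                     timepoints = c("No Delay", "Long Delay")),
    seed = 9)
  d <- simulate_cohort(cfg)
  sc <- score_sequences(d)
  cr <- crp_sequences(d)
  i <- 5L
  pos <- d$sequences$positions[[i]]
  n <- d$sequences$n_items[i]
  expect_equal(sc$score[i], temporal_organization_score(pos, study_list("u", n)))
  expect_equal(sc$n_recalled[i], length(pos))
  expect_equal(sc$percent_recall[i], length(pos) / n)
  sub <- cr[cr$participant_id == d$sequences$participant_id[i] &
              cr$unit_id == d$sequences$unit_id[i] &
              cr$timepoint == d$sequences$timepoint[i], ]
  expect_equal(sub$crp, lag_crp(pos, study_list("u", n))$crp)
})
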