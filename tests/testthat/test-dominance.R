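test_that("displacements and peaceful SBTs credit the dominant member", {
  ev <- make_events(actor = c("a", "b"), recipient = c("b", "a"),
                    behaviour = c("displacement", "peaceful_sbt"))
  w <- build_winloss(ev, "baseline", c("a", "b", "c"))
  expect_equal(w$direct["a", "b"], 2)  # one win per event type
  expect_equal(w$direct["b", "a"], 0)
  expect_equal(diag(w$direct), setNames(rep(0, 3), c("a", "b", "c")))
  ## aggression events are not status signals and never enter the matrix
  ag <- make_events("a", "b", behaviour = "aggression", severity = "mild",
                    submissive_response = TRUE)
  expect_equal(sum(build_winloss(ag, "baseline", c("a", "b"))$direct), 0)
})

test_that("win-loss matrices match an event-scan oracle on simulated data", {
  s <- small_study(seed = 41)
  elig <- phase_presence_filter(s$roster)
  for (ph in phases()) {
    w <- build_winloss(s$events, ph, elig)
    expect_equal(w$direct, oracle_winloss(s$events, ph, elig))
  }
})

test_that("a two-step chain imputes the product of win proportions", {
  ## a beats b 1-0, b beats c 1-0, no a-c data: imputed a-over-c = 1 * 1 = 1
  ev <- make_events(actor = c("a", "b"), recipient = c("b", "c"),
                    behaviour = "displacement")
  m <- impute_path_wins(build_winloss(ev, "baseline", c("a", "b", "c")))
  expect_equal(m$imputed["a", "c"], 1)
  expect_equal(m$imputed["c", "a"], 0)
  expect_equal(m$imputed["a", "b"], 1)  # direct count kept

  ## mixed dyad: a beats b 2-1 -> step proportion 2/3
  ev2 <- make_events(actor = c("a", "a", "b", "b"),
                     recipient = c("b", "b", "a", "c"),
                     behaviour = "displacement")
  m2 <- impute_path_wins(build_winloss(ev2, "baseline", c("a", "b", "c")))
  expect_equal(m2$imputed["a", "c"], 2 / 3)
})

test_that("imputation is the identity without length-2 paths or at path length 1", {
  ev <- make_events(actor = c("a", "c"), recipient = c("b", "d"),
                    behaviour = "displacement")
  m <- build_winloss(ev, "baseline", letters[1:4])
  expect_equal(impute_path_wins(m)$imputed, m$direct)
  s <- small_study(seed = 43, n = 8)
  ms <- build_winloss(s$events, "baseline", phase_presence_filter(s$roster))
  expect_equal(impute_path_wins(ms, max_path_len = 1)$imputed, ms$direct)
})

test_that("imputation agrees with exhaustive path enumeration", {
  set.seed(47)
  for (rep in 1:5) {
    n <- 5
    ids <- letters[1:n]
    W <- matrix(rpois(n * n, 1.2), n, n, dimnames = list(ids, ids))
    diag(W) <- 0
    m <- structure(list(ids = ids, direct = W, imputed = NULL,
                        max_path_len = NULL, phase = "baseline"),
                   class = "winloss_matrix")
    for (L in 2:3)
      expect_equal(impute_path_wins(m, max_path_len = L)$imputed,
                   oracle_impute(W, L), label = paste("rep", rep, "L", L))
  }
  ## larger matrix, default length
  s <- small_study(seed = 53)
  ms <- build_winloss(s$events, "experimental", phase_presence_filter(s$roster))
  expect_equal(impute_path_wins(ms)$imputed, oracle_impute(ms$direct, 2))
})

test_that("adding a direct win never decreases the imputed score", {
  set.seed(59)
  ids <- letters[1:6]
  W <- matrix(rpois(36, 0.8), 6, 6, dimnames = list(ids, ids))
  diag(W) <- 0
  m <- structure(list(ids = ids, direct = W, imputed = NULL,
                      max_path_len = NULL, phase = "baseline"),
                 class = "winloss_matrix")
  base_imp <- impute_path_wins(m, 3)$imputed
  for (k in 1:5) {
    i <- sample(6, 1); j <- sample(setdiff(1:6, i), 1)
    m2 <- m
    m2$direct[i, j] <- m2$direct[i, j] + 1
    expect_gte(impute_path_wins(m2, 3)$imputed[i, j], base_imp[i, j])
  }
})

test_that("dominance probabilities are complementary and default to 1/2", {
  ev <- make_events("a", "b", behaviour = "displacement")
  d <- dominance_probs(build_winloss(ev, "baseline", c("a", "b", "c")))
  p <- d$dominance_prob
  expect_equal(p["a", "b"], 1)
  expect_equal(p["b", "a"], 0)
  expect_equal(p["a", "c"], 0.5)  # no information at all
  off <- !diag(3)
  expect_equal((p + t(p))[off], rep(1, 6))
})

test_that("a complete linear tournament is ranked in its true order", {
  ids <- c("w", "x", "y", "z")
  pairs <- t(combn(ids, 2))
  ev <- make_events(actor = pairs[, 1], recipient = pairs[, 2],
                    behaviour = "displacement")
  d <- dominance_probs(build_winloss(ev, "baseline", ids))
  expect_equal(d$ordinal_rank, setNames(1:4, ids))
})

test_that("fully observed transitive tournaments recover the topological order", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 8
    ids <- sprintf("t%02d", 1:n)
    true_order <- sample(ids)
    pos <- setNames(seq_len(n), true_order)
    pairs <- t(combn(ids, 2))
    winner <- ifelse(pos[pairs[, 1]] < pos[pairs[, 2]],
                     pairs[, 1], pairs[, 2])
    loser <- ifelse(winner == pairs[, 1], pairs[, 2], pairs[, 1])
    ev <- make_events(actor = winner, recipient = loser,
                      behaviour = "displacement")
    d <- dominance_probs(build_winloss(ev, "baseline", ids),
                         phase = "baseline")
    expect_equal(d$ordinal_rank[true_order], setNames(seq_len(n), true_order))
  }
})

test_that("rank correlation is 1 for identical and -1 for reversed orders", {
  ids <- letters[1:5]
  mk <- function(rk) structure(list(
    dominance_prob = NULL, ordinal_rank = setNames(rk, ids),
    mean_prob = NULL, phase = "baseline"), class = "dominance_result")
  expect_equal(rank_correlation(mk(1:5), mk(1:5)), 1)
  expect_equal(rank_correlation(mk(1:5), mk(5:1)), -1)
  expect_error(rank_correlation(mk(1:5), structure(list(
    ordinal_rank = setNames(1:4, letters[2:5])), class = "dominance_result")),
    "different individual")
})

test_that("higher-ranked percentage counts events or unique actors", {
  ranks <- setNames(1:5, c("hi", "h2", "f", "lo", "l2"))
  ev <- make_events(actor = c("hi", "hi", "h2", "lo"),
                    recipient = rep("f", 4),
                    behaviour = "aggression", severity = "mild",
                    submissive_response = TRUE)
  out <- pct_from_higher_ranked(ev, "aggression", "baseline", "f", ranks)
  expect_equal(out$focal, 75)
  expect_equal(out$by_id$n[out$by_id$id == "f"], 4L)
  ## unique-actor mode: hi counted once -> 2 of 3 actors outrank
  outu <- pct_from_higher_ranked(ev, "aggression", "baseline", "f", ranks,
                                 mode = "actors")
  expect_equal(outu$focal, 100 * 2 / 3)
  ## no received events -> missing
  expect_true(is.na(pct_from_higher_ranked(ev, "displacement", "baseline",
                                           "f", ranks)$focal))
  ## giving role: aggression directed at higher-ranked individuals
  outg <- pct_from_higher_ranked(ev, "aggression", "baseline", "lo", ranks,
                                 role = "actor")
  expect_equal(outg$focal, 100)
})

test_that("higher-ranked percentages match a filter-and-count oracle", {
  s <- small_study(seed = 61)
  elig <- phase_presence_filter(s$roster)
  d <- rank_phase(s$events, "baseline", elig)
  out <- pct_from_higher_ranked(s$events, "aggression", "baseline",
                                s$roster$focal_id, d$ordinal_rank)
  for (id in sample(elig, 8)) {
    expect_equal(out$by_id$pct_higher[out$by_id$id == id],
                 oracle_pct_higher(s$events, "aggression", "baseline", id,
                                   d$ordinal_rank), label = id)
  }
})
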