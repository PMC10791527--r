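test_that("degree and strength follow their definitions on a star", {
  ev <- make_events(actor = c("a", "a", "b", "b", "c", "c"),
                    recipient = rep("z", 6))
  net <- build_network(ev, "grooming", "baseline", c("a", "b", "c", "z", "q"))
  ct <- node_centralities(net)
  z <- ct[ct$id == "z", ]
  expect_equal(z$degree_in, 3L)
  expect_equal(z$strength_in, 6)
  expect_equal(z$degree_out, 0L)
  q <- ct[ct$id == "q", ]  # isolate
  expect_equal(unlist(q[c("degree_in", "degree_out", "degree_total",
                          "strength_in", "strength_out", "strength_total")]),
               setNames(rep(0, 6), c("degree_in", "degree_out", "degree_total",
                                     "strength_in", "strength_out",
                                     "strength_total")))
})

test_that("undirected layers populate only total columns", {
  ev <- make_events(c("a", "a"), c("b", "c"), behaviour = "proximity")
  ct <- node_centralities(build_network(ev, "proximity", "baseline",
                                        c("a", "b", "c")))
  expect_true(all(is.na(ct$degree_in)))
  expect_equal(ct$degree_total[ct$id == "a"], 2L)
  expect_equal(ct$strength_total[ct$id == "a"], 2)
})

test_that("centralities match a per-node scan oracle on simulated networks", {
  s <- small_study(seed = 29)
  elig <- phase_presence_filter(s$roster)
  for (beh in c("aggression", "grooming", "huddling")) {
    net <- build_network(filter_events(s$events, beh, "experimental"),
                         beh, "experimental", elig)
    ct <- node_centralities(net)
    for (id in sample(elig, 6)) {
      o <- oracle_centrality(net, id)
      row <- ct[ct$id == id, ]
      for (f in names(o))
        expect_equal(row[[f]], o[[f]], label = paste(beh, id, f))
    }
  }
})

test_that("change scores subtract baseline from experimental per individual", {
  s <- small_study(seed = 31)
  elig <- phase_presence_filter(s$roster)
  nb <- node_centralities(build_network(
    filter_events(s$events, "grooming", "baseline"), "grooming",
    "baseline", elig))
  ne <- node_centralities(build_network(
    filter_events(s$events, "grooming", "experimental"), "grooming",
    "experimental", elig))
  ch <- change_scores(nb, ne, "strength_in")
  expect_equal(unname(ch[nb$id[3]]),
               ne$strength_in[3] - nb$strength_in[3])
  expect_equal(change_scores(nb, nb, "strength_in"),
               setNames(rep(0, nrow(nb)), sort(nb$id)))
  expect_error(change_scores(nb, ne[-1, ], "strength_in"),
               "different individuals")
  expect_error(change_scores(nb, ne, "betweenness"), "unknown metric")
})

test_that("a 10-to-36 strength change scores +26", {
  bl <- data.frame(id = c("f", "g", "h"), strength_in = c(10, 2, 4),
                   degree_in = 1, degree_out = 1, degree_total = 1,
                   strength_out = 0, strength_total = 0)
  ex <- transform(bl, strength_in = c(36, 3, 1))
  ch <- change_scores(bl, ex, "strength_in")
  expect_equal(unname(ch["f"]), 26)
})

test_that("focal_z centres and scales against the group, focal included", {
  ch <- setNames(c(5, 1, 0, 2), c("f", "x", "y", "z"))
  st <- focal_z(ch, "f")
  expect_equal(st$z, (5 - mean(ch)) / sd(ch))
  expect_equal(st$n, 4L)
  ## focal equal to the mean gives z = 0 and p = 1
  ch0 <- setNames(c(2, 1, 3), c("f", "x", "y"))
  expect_equal(focal_z(ch0, "f")$z, 0)
  expect_equal(focal_z(ch0, "f")$p_two_tailed, 1)
  ## location/scale equivariance
  for (k in c(0.5, 3)) for (c0 in c(-4, 7)) {
    expect_equal(focal_z(ch * k + c0, "f")$z, st$z)
  }
  expect_error(focal_z(setNames(rep(1, 5), letters[1:5]), "a"), "degenerate")
  expect_error(focal_z(setNames(1:2, c("a", "b")), "a"), "at least 3")
  expect_error(focal_z(ch, "nope"), "not found")
})

test_that("normal tail probabilities behave and relate as expected", {
  expect_equal(two_tailed_p(0), 1)
  expect_equal(one_tailed_p(0), 0.5)
  zs <- c(-2.5, -0.35, 0.1, 1.66, 3)
  for (z in zs)
    expect_equal(two_tailed_p(z), 2 * one_tailed_p(abs(z)))
  ## strictly decreasing in |z| / z
  expect_true(all(diff(sapply(abs(zs), two_tailed_p)[order(abs(zs))]) < 0))
  expect_true(all(diff(sapply(sort(zs), one_tailed_p)) < 0))
  expect_lt(one_tailed_p(20), 1e-15)
})

test_that("exact permutation p is the share of group members as extreme", {
  ch <- setNames(c(9, 1, 0, 2, -1, 1), c("f", letters[1:5]))
  pp <- permutation_p(ch, "f")
  zs <- abs((ch - mean(ch)) / sd(ch))
  expect_equal(pp$p, mean(zs >= zs[["f"]]))
  set.seed(1)
  pp2 <- permutation_p(ch, "f", n_perm = 500)
  expect_gt(pp2$p, 0)
  expect_lte(abs(pp2$p - pp$p), 0.05)
})

test_that("grooming balance is received minus given and sums to zero", {
  ev <- make_events(actor = c(rep("x", 4), rep("f", 4), rep("y", 18)),
                    recipient = c(rep("f", 4), rep("y", 4), rep("f", 18)))
  net <- build_network(ev, "grooming", "baseline", c("f", "x", "y"))
  gb <- grooming_balances(net, "f")
  fb <- gb$balances[gb$balances$id == "f", ]
  expect_equal(fb$received, 22)
  expect_equal(fb$given, 4)
  expect_equal(fb$balance, 18)
  expect_equal(sum(gb$balances$balance), 0)

  ## perfectly reciprocal network: every balance 0
  rec <- make_events(c("a", "b", "b", "c"), c("b", "a", "c", "b"))
  gb0 <- grooming_balances(build_network(rec, "grooming", "baseline",
                                         c("a", "b", "c")), "a")
  expect_equal(gb0$balances$balance, rep(0, 3))
})

test_that("balances match the strength-difference oracle on simulated data", {
  s <- small_study(seed = 37)
  elig <- phase_presence_filter(s$roster)
  net <- build_network(filter_events(s$events, "grooming", "baseline"),
                       "grooming", "baseline", elig)
  gb <- grooming_balances(net, s$roster$focal_id)
  for (id in sample(elig, 8))
    expect_equal(gb$balances$balance[gb$balances$id == id],
                 oracle_balance(s$events, "baseline", id), label = id)
  expect_equal(sum(gb$balances$balance), 0)
})
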