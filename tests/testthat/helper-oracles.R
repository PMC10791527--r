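# Independent brute-force implementations used as oracles. These scan
# events row by row (or enumerate paths exhaustively) and share no code
# with the package internals they check.

# Dyadic weight map as a named vector "from|to" -> count.
oracle_weights <- function(events, behaviour, phase, eligible, directed) {
  w <- c()
  for (i in seq_len(nrow(events))) {
    row <- events[i, ]
    if (row$behaviour != behaviour || row$phase != phase) next
    if (behaviour == "aggression" &&
        (is.na(row$submissive_response) || !row$submissive_response)) next
    if (!(row$actor %in% eligible) || !(row$recipient %in% eligible)) next
    a <- row$actor; b <- row$recipient
    if (!directed && a > b) { tmp <- a; a <- b; b <- tmp }
    key <- paste(a, b, sep = "|")
    w[key] <- (if (key %in% names(w)) w[[key]] else 0) + 1
  }
  w
}

net_weights <- function(net) {
  if (nrow(net$edges) == 0) return(c())
  stats::setNames(net$edges$weight, paste(net$edges$from, net$edges$to,
                                          sep = "|"))
}

# Per-node centrality scan.
oracle_centrality <- function(net, id) {
  e <- net$edges
  if (net$directed) {
    din <- length(unique(e$from[e$to == id]))
    dout <- length(unique(e$to[e$from == id]))
    sin <- sum(e$weight[e$to == id])
    sout <- sum(e$weight[e$from == id])
    partners <- unique(c(e$from[e$to == id], e$to[e$from == id]))
    list(degree_in = din, degree_out = dout, degree_total = length(partners),
         strength_in = sin, strength_out = sout,
         strength_total = sin + sout)
  } else {
    inc <- e$from == id | e$to == id
    partners <- setdiff(unique(c(e$from[inc], e$to[inc])), id)
    list(degree_total = length(partners), strength_total = sum(e$weight[inc]))
  }
}

# Win-loss scan: displacements (actor wins) + peaceful SBTs (recipient wins).
oracle_winloss <- function(events, phase, ids) {
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(events))) {
    row <- events[i, ]
    if (row$phase != phase) next
    if (row$behaviour == "displacement") {
      win <- row$actor; lose <- row$recipient
    } else if (row$behaviour == "peaceful_sbt") {
      win <- row$recipient; lose <- row$actor
    } else next
    if (win %in% ids && lose %in% ids) W[win, lose] <- W[win, lose] + 1
  }
  W
}

# Exhaustive simple-path imputation: enumerates every ordered tuple of
# distinct intermediate nodes per path length via expand.grid.
oracle_impute <- function(direct, max_path_len) {
  n <- nrow(direct)
  tot <- direct + t(direct)
  P <- ifelse(tot > 0, direct / tot, 0)
  diag(P) <- 0
  imp <- direct + 0
  for (len in seq(2, max_path_len)) {
    if (len > max_path_len || n < len + 1) next
    n_mid <- len - 1
    grids <- expand.grid(rep(list(seq_len(n)), n_mid))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      for (g in seq_len(nrow(grids))) {
        mid <- as.integer(grids[g, ])
        nodes <- c(i, mid, j)
        if (anyDuplicated(nodes)) next
        wt <- 1
        for (s in seq_len(len)) wt <- wt * P[nodes[s], nodes[s + 1]]
        imp[i, j] <- imp[i, j] + wt
      }
    }
  }
  imp
}

# Grooming balance scan.
oracle_balance <- function(events, phase, id) {
  rec <- sum(events$behaviour == "grooming" & events$phase == phase &
               events$recipient == id)
  giv <- sum(events$behaviour == "grooming" & events$phase == phase &
               events$actor == id)
  rec - giv
}

# Percentage of received events whose actor outranks the receiver.
oracle_pct_higher <- function(events, behaviour, phase, id, ranks) {
  cnt <- 0; hi <- 0
  for (i in seq_len(nrow(events))) {
    row <- events[i, ]
    if (row$behaviour != behaviour || row$phase != phase) next
    if (behaviour == "aggression" &&
        (is.na(row$submissive_response) || !row$submissive_response)) next
    if (row$recipient != id) next
    if (!row$actor %in% names(ranks)) next
    cnt <- cnt + 1
    if (ranks[[row$actor]] < ranks[[id]]) hi <- hi + 1
  }
  if (cnt == 0) NA_real_ else 100 * hi / cnt
}
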