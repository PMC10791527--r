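#' Build a win-loss matrix from status-signalling events
#'
#' Dominance information comes from status signalling only: a displacement
#' credits the actor with a win over the recipient, and a peaceful SBT
#' (silent bared-teeth display, given by the signaller = event actor)
#' credits the **recipient** with a win over the signaller, since the
#' signal marks the signaller as the subordinate. Aggression events are
#' deliberately not used for ranking.
#'
#' @param events validated `interaction_events`.
#' @param phase phase label.
#' @param eligible_ids individuals to rank (rows/columns of the matrix).
#' @return An object of class `"winloss_matrix"`: list with `ids` (sorted),
#'   `direct` (square count matrix, `direct[i, j]` = events where i
#'   dominated j, zero diagonal), `imputed` (`NULL` until
#'   [impute_path_wins()]) and `max_path_len`.
#' @examples
#' ev <- interaction_events(data.frame(
#'   date = "2019-03-04", phase = "baseline",
#'   behaviour = c("displacement", "peaceful_sbt"),
#'   actor = c("a", "b"), recipient = c("b", "a"),
#'   severity = NA, submissive_response = NA))
#' w <- build_winloss(ev, "baseline", c("a", "b", "c"))
#' w$direct["a", "b"]  # 2: one displacement by a, one SBT signalled by b
#' @export
build_winloss <- function(events, phase, eligible_ids) {
  .check_phase(phase)
  ids <- sort(unique(as.character(eligible_ids)))
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  disp <- filter_events(events, "displacement", phase)
  sbt <- filter_events(events, "peaceful_sbt", phase)
  winner <- c(disp$actor, sbt$recipient)
  loser <- c(disp$recipient, sbt$actor)
  ok <- winner %in% ids & loser %in% ids
  winner <- winner[ok]; loser <- loser[ok]
  if (length(winner)) {
    idx <- cbind(match(winner, ids), match(loser, ids))
    for (k in seq_len(nrow(idx)))
      W[idx[k, 1], idx[k, 2]] <- W[idx[k, 1], idx[k, 2]] + 1
  }
  structure(list(ids = ids, direct = W, imputed = NULL,
                 max_path_len = NULL, phase = phase),
            class = "winloss_matrix")
}

#' @export
print.winloss_matrix <- function(x, ...) {
  cat(sprintf("<winloss_matrix> %d ids, %g direct wins%s\n",
              length(x$ids), sum(x$direct),
              if (is.null(x$imputed)) ""
              else sprintf(", imputed (max path length %d)", x$max_path_len)))
  invisible(x)
}

#' Complete a win-loss matrix with transitive network pathways
#'
#' Many dyads are never observed interacting directly; their relationship
#' can still be inferred through chains of decided relationships (A
#' dominant to B and B dominant to C implies A dominant to C). For every
#' ordered pair the imputed win score adds, to the direct count, the sum
#' over all simple directed paths of length 2..`max_path_len` of the
#' product of per-step win *proportions* `w[a,b] / (w[a,b] + w[b,a])`
#' (direct counts only). Using proportions rather than raw counts keeps any
#' single chain's contribution at most 1, so indirect evidence cannot swamp
#' direct observation. Steps with no direct data contribute nothing.
#'
#' @param m a `"winloss_matrix"`.
#' @param max_path_len longest chain considered (default 2; 1 returns the
#'   direct counts unchanged).
#' @return `m` with `imputed` and `max_path_len` filled in.
#' @export
impute_path_wins <- function(m, max_path_len = 2L) {
  stopifnot(inherits(m, "winloss_matrix"))
  if (max_path_len < 1L) stop("max_path_len must be >= 1")
  W <- m$direct
  n <- nrow(W)
  tot <- W + t(W)
  P <- matrix(0, n, n, dimnames = dimnames(W))
  nz <- tot > 0
  P[nz] <- W[nz] / tot[nz]
  diag(P) <- 0
  imp <- W + 0  # numeric copy
  if (max_path_len >= 2L && n >= 3L) {
    if (max_path_len == 2L) {
      ## length-2 chains: the zero diagonal of P already rules out repeats
      C2 <- P %*% P
      diag(C2) <- 0
      imp <- imp + C2
    } else {
      adj <- lapply(seq_len(n), function(i) which(P[i, ] > 0))
      acc <- matrix(0, n, n)
      walk <- function(start, node, depth, wprod, visited) {
        for (k in adj[[node]]) {
          if (visited[k]) next
          w2 <- wprod * P[node, k]
          if (depth + 1L >= 2L)
            acc[start, k] <<- acc[start, k] + w2
          if (depth + 1L < max_path_len) {
            visited[k] <- TRUE
            walk(start, k, depth + 1L, w2, visited)
            visited[k] <- FALSE
          }
        }
      }
      for (i in seq_len(n)) {
        visited <- rep(FALSE, n)
        visited[i] <- TRUE
        walk(i, i, 0L, 1, visited)
      }
      imp <- imp + acc
    }
  }
  m$imputed <- imp
  m$max_path_len <- as.integer(max_path_len)
  m
}

#' Dominance probabilities and ordinal ranks
#'
#' Converts a (pathway-completed) win-loss matrix into dyadic dominance
#' probabilities `d[i, j] = imputed[i, j] / (imputed[i, j] + imputed[j, i])`
#' (0.5 for dyads with no direct or imputed information) and an ordinal
#' rank (1 = most dominant) by descending mean dominance probability over
#' all partners; ties are broken by descending total direct wins, then by
#' id.
#'
#' @param m a `"winloss_matrix"`; if not yet imputed,
#'   [impute_path_wins()] is applied with its default path length.
#' @param phase optional phase label carried into the result (defaults to
#'   the matrix's own).
#' @return An object of class `"dominance_result"`: list with
#'   `dominance_prob` (square matrix, `NA` diagonal), `ordinal_rank`
#'   (named integer vector, a permutation of 1..n), `mean_prob` (named) and
#'   `phase`.
#' @export
dominance_probs <- function(m, phase = m$phase) {
  stopifnot(inherits(m, "winloss_matrix"))
  if (is.null(m$imputed)) m <- impute_path_wins(m)
  imp <- m$imputed
  tot <- imp + t(imp)
  d <- matrix(0.5, nrow(imp), ncol(imp), dimnames = dimnames(imp))
  nz <- tot > 0
  d[nz] <- imp[nz] / tot[nz]
  diag(d) <- NA
  mean_prob <- rowMeans(d, na.rm = TRUE)
  direct_tot <- rowSums(m$direct)
  ord <- order(-mean_prob, -direct_tot, m$ids)
  ranks <- integer(length(ord))
  ranks[ord] <- seq_along(ord)
  names(ranks) <- m$ids
  structure(list(dominance_prob = d,
                 ordinal_rank = ranks,
                 mean_prob = mean_prob,
                 phase = phase),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  top <- names(sort(x$ordinal_rank))[1:min(3, length(x$ordinal_rank))]
  cat(sprintf("<dominance_result> %s: %d ranked ids (top: %s)\n",
              x$phase %||% "?", length(x$ordinal_rank),
              paste(top, collapse = " > ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation of ordinal ranks across phases
#'
#' @param bl,exp `"dominance_result"` objects for the two phases, covering
#'   the same individuals.
#' @return Pearson correlation coefficient of the two rank vectors.
#' @export
rank_correlation <- function(bl, exp) {
  stopifnot(inherits(bl, "dominance_result"),
            inherits(exp, "dominance_result"))
  ids <- names(bl$ordinal_rank)
  if (!setequal(ids, names(exp$ordinal_rank)))
    stop("phases rank different individual sets")
  if (length(ids) < 3L) stop("need at least 3 individuals")
  stats::cor(bl$ordinal_rank[ids], exp$ordinal_rank[ids])
}

#' Percentage of interactions involving a higher-ranked partner
#'
#' For every individual, among the events of one behaviour in one phase in
#' which it took the given role (`"recipient"`: events received, the
#' default; `"actor"`: events given), the percentage whose *other*
#' participant outranks it. Counting is per event by default; `mode =
#' "actors"` counts each distinct partner once.
#'
#' @param events validated `interaction_events`.
#' @param behaviour,phase layer selection (aggression events are filtered
#'   to those with a submissive response, as in the network build).
#' @param focal_id id whose value is highlighted in the result.
#' @param ranks named vector of ordinal ranks (1 = highest), e.g.
#'   `ordinal_rank` from [dominance_probs()].
#' @param role `"recipient"` or `"actor"`.
#' @param mode `"events"` (default) or `"actors"` (distinct partners).
#' @return List with `focal` (the focal's percentage, `NA` if it had no
#'   such events) and `by_id` (data.frame `id`, `n`, `pct_higher`;
#'   `pct_higher` is `NA` for individuals with no events).
#' @export
pct_from_higher_ranked <- function(events, behaviour, phase, focal_id,
                                   ranks, role = c("recipient", "actor"),
                                   mode = c("events", "actors")) {
  role <- match.arg(role)
  mode <- match.arg(mode)
  ev <- filter_events(events, behaviour, phase)
  ids <- names(ranks)
  ev <- ev[ev$actor %in% ids & ev$recipient %in% ids, , drop = FALSE]
  self <- if (role == "recipient") ev$recipient else ev$actor
  other <- if (role == "recipient") ev$actor else ev$recipient
  if (mode == "actors" && nrow(ev)) {
    keep <- !duplicated(paste(self, other, sep = "\r"))
    self <- self[keep]; other <- other[keep]
  }
  higher <- ranks[other] < ranks[self]
  by_id <- data.frame(id = ids, n = 0L, pct_higher = NA_real_,
                      stringsAsFactors = FALSE)
  if (length(self)) {
    tab_n <- table(factor(self, levels = ids))
    tab_h <- tapply(higher, factor(self, levels = ids), sum)
    by_id$n <- as.integer(tab_n)
    has <- by_id$n > 0
    by_id$pct_higher[has] <- 100 * as.numeric(tab_h[has]) / by_id$n[has]
  }
  focal <- by_id$pct_higher[by_id$id == focal_id]
  if (!length(focal)) focal <- NA_real_
  list(focal = focal, by_id = by_id)
}

#' Dominance ranking for one phase, end to end
#'
#' Convenience wrapper: [build_winloss()] then [impute_path_wins()] then
#' [dominance_probs()].
#'
#' @inheritParams build_winloss
#' @inheritParams impute_path_wins
#' @return A `"dominance_result"`.
#' @export
rank_phase <- function(events, phase, eligible_ids, max_path_len = 2L) {
  m <- build_winloss(events, phase, eligible_ids)
  m <- impute_path_wins(m, max_path_len = max_path_len)
  dominance_probs(m)
}
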