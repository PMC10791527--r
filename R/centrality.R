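#' Node centralities of a behavioural network
#'
#' Degree is the number of distinct partners (adjacent edges); strength is
#' the total number of interactions (sum of incident edge weights). For
#' directed networks both are split into in/out components and a total
#' (distinct partners in either direction; in- plus out-strength); for
#' undirected networks only the `_total` columns are populated.
#'
#' @param network a `"behaviour_network"` from [build_network()].
#' @return data.frame with one row per node: `id`, `behaviour`, `phase`,
#'   `degree_in`, `degree_out`, `degree_total`, `strength_in`,
#'   `strength_out`, `strength_total` (in/out are `NA` for undirected
#'   layers). Isolates have zeros.
#' @export
node_centralities <- function(network) {
  stopifnot(inherits(network, "behaviour_network"))
  nodes <- network$nodes
  n <- length(nodes)
  e <- network$edges
  fi <- match(e$from, nodes); ti <- match(e$to, nodes)
  if (network$directed) {
    strength_out <- as.numeric(tabulate_w(fi, e$weight, n))
    strength_in  <- as.numeric(tabulate_w(ti, e$weight, n))
    degree_out <- tabulate(fi, n)
    degree_in  <- tabulate(ti, n)
    ## distinct partners in either direction
    pk <- unique(data.frame(i = c(fi, ti), j = c(ti, fi)))
    degree_total <- tabulate(pk$i, n)
    out <- data.frame(id = nodes,
                      behaviour = network$behaviour, phase = network$phase,
                      degree_in = degree_in, degree_out = degree_out,
                      degree_total = degree_total,
                      strength_in = strength_in, strength_out = strength_out,
                      strength_total = strength_in + strength_out,
                      stringsAsFactors = FALSE)
  } else {
    inc_i <- c(fi, ti)
    strength_total <- as.numeric(tabulate_w(inc_i, c(e$weight, e$weight), n))
    degree_total <- tabulate(inc_i, n)  # pairs are unique keys already
    out <- data.frame(id = nodes,
                      behaviour = network$behaviour, phase = network$phase,
                      degree_in = NA_integer_, degree_out = NA_integer_,
                      degree_total = degree_total,
                      strength_in = NA_real_, strength_out = NA_real_,
                      strength_total = strength_total,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

## weighted tabulate: sum w over bins 1..n
tabulate_w <- function(bin, w, n) {
  out <- numeric(n)
  if (!length(bin)) return(out)
  agg <- rowsum(as.numeric(w), bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Centrality table for a set of networks
#'
#' @param networks list of `"behaviour_network"` objects (e.g. from
#'   [build_phase_networks()]).
#' @return Row-bound [node_centralities()] output.
#' @export
centrality_table <- function(networks) {
  do.call(rbind, lapply(networks, node_centralities))
}

#' Per-individual change in a centrality metric
#'
#' Change is experimental minus baseline for one metric of one behavioural
#' layer. Both phases must cover the same individuals (the eligible set).
#'
#' @param bl,exp [node_centralities()] data.frames for the baseline and
#'   experimental networks of the same behaviour.
#' @param metric one of `degree_in`, `degree_out`, `degree_total`,
#'   `strength_in`, `strength_out`, `strength_total`.
#' @return Named numeric vector of changes, one per individual.
#' @export
change_scores <- function(bl, exp, metric) {
  ok <- c("degree_in", "degree_out", "degree_total",
          "strength_in", "strength_out", "strength_total")
  if (!metric %in% ok) stop("unknown metric: ", metric)
  if (!setequal(bl$id, exp$id))
    stop("baseline and experimental phases cover different individuals")
  ids <- sort(bl$id)
  v_bl <- bl[[metric]][match(ids, bl$id)]
  v_ex <- exp[[metric]][match(ids, exp$id)]
  if (all(is.na(v_bl)) || all(is.na(v_ex)))
    stop("metric '", metric, "' is not defined for this layer")
  stats::setNames(as.numeric(v_ex) - as.numeric(v_bl), ids)
}

#' z-statistic of a focal value against a group distribution
#'
#' `change_stat()` is the bare computation: given a group mean and standard
#' deviation and the focal's value, it returns
#' `z = (focal - mean) / sd` with the corresponding normal-tail p-values.
#' `focal_z()` computes the mean and sd from the per-individual values
#' themselves, with the focal **included** in the group distribution and
#' the sample (n-1) standard deviation — the convention under which the
#' reference tables this package reproduces are internally consistent.
#'
#' @param mean_change group mean of the values.
#' @param sd_change group standard deviation (must be > 0).
#' @param focal_change the focal's value.
#' @return A list of class `"change_stat"` with fields `mean_change`,
#'   `sd_change`, `focal_change`, `z`, `p_two_tailed`, `p_one_tailed` and
#'   (for `focal_z`) `n`.
#' @examples
#' s <- change_stat(1.30, 5.28, 16)
#' round(s$z, 2)            # 2.78
#' round(s$p_two_tailed, 2) # 0.01
#' @export
change_stat <- function(mean_change, sd_change, focal_change) {
  if (!is.finite(sd_change) || sd_change <= 0)
    stop("degenerate change distribution: sd must be positive")
  z <- (focal_change - mean_change) / sd_change
  structure(list(mean_change = mean_change, sd_change = sd_change,
                 focal_change = focal_change, z = z,
                 p_two_tailed = two_tailed_p(z),
                 p_one_tailed = one_tailed_p(z)),
            class = "change_stat")
}

#' @rdname change_stat
#' @param changes named numeric vector of per-individual values (e.g. from
#'   [change_scores()]).
#' @param focal_id id of the focal individual; must be a name of `changes`.
#' @param include_focal include the focal in the group mean/sd (default
#'   `TRUE`); set `FALSE` to compare the focal against the others only.
#' @export
focal_z <- function(changes, focal_id, include_focal = TRUE) {
  if (!focal_id %in% names(changes))
    stop("focal id '", focal_id, "' not found among the changes")
  if (length(changes) < 3L)
    stop("need at least 3 individuals for a group distribution")
  grp <- if (include_focal) changes else changes[names(changes) != focal_id]
  st <- change_stat(mean(grp), stats::sd(grp), changes[[focal_id]])
  st$n <- length(grp)
  st
}

#' @export
print.change_stat <- function(x, ...) {
  cat(sprintf("mean %.3f, sd %.3f, focal %.3f -> z = %.2f (p2 = %.3f, p1 = %.3f)\n",
              x$mean_change, x$sd_change, x$focal_change, x$z,
              x$p_two_tailed, x$p_one_tailed))
  invisible(x)
}

#' Normal-tail p-values for a z-statistic
#'
#' `two_tailed_p(z)` is `2 * (1 - pnorm(|z|))`, the two-sided tail
#' probability under a standard normal reference; `one_tailed_p(z)` is the
#' upper tail `1 - pnorm(z)`.
#'
#' @param z finite z-statistic.
#' @return Probability in (0, 1].
#' @examples
#' round(two_tailed_p(-0.35), 2)  # 0.73
#' round(one_tailed_p(1.66), 3)   # 0.048
#' @export
two_tailed_p <- function(z) {
  stopifnot(is.finite(z))
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' @rdname two_tailed_p
#' @export
one_tailed_p <- function(z) {
  stopifnot(is.finite(z))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Permutation p-value for the focal's z
#'
#' Instead of the normal reference, resamples which eligible individual is
#' labelled "focal" and recomputes the z-statistic. With `n_perm = NULL`
#' (default) the permutation distribution is enumerated exactly — every
#' individual takes a turn as focal — which is feasible at group sizes of a
#' few hundred; otherwise `n_perm` labels are drawn with replacement.
#'
#' @inheritParams focal_z
#' @param n_perm number of resampled labels, or `NULL` for exact
#'   enumeration.
#' @param two_tailed compare `|z|` (default) rather than `z`.
#' @return List with `p`, the observed `z`, and `n_perm` used.
#' @export
permutation_p <- function(changes, focal_id, n_perm = NULL,
                          two_tailed = TRUE) {
  obs <- focal_z(changes, focal_id)$z
  m <- mean(changes); s <- stats::sd(changes)
  if (s <= 0) stop("degenerate change distribution: sd must be positive")
  zs <- (changes - m) / s
  if (is.null(n_perm)) {
    stat <- if (two_tailed) abs(zs) else zs
    ref <- if (two_tailed) abs(obs) else obs
    p <- mean(stat >= ref)
    n_used <- length(zs)
  } else {
    pick <- sample(seq_along(zs), n_perm, replace = TRUE)
    stat <- if (two_tailed) abs(zs[pick]) else zs[pick]
    ref <- if (two_tailed) abs(obs) else obs
    p <- (sum(stat >= ref) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  list(p = p, z = obs, n_perm = n_used)
}

#' Grooming balance per individual
#'
#' Grooming balance is grooming received minus grooming given (in-strength
#' minus out-strength in the directed grooming network of one phase); a
#' positive balance means net receipt. The focal's balance is compared with
#' the group distribution via [focal_z()], both with the focal included in
#' the group mean/sd (the package-wide convention) and with it excluded,
#' since the two variants can differ noticeably when the focal is an
#' outlier; the report shows both.
#'
#' @param network the directed grooming `"behaviour_network"` of one phase.
#' @param focal_id focal individual id.
#' @return A list of class `"grooming_balance"`: `balances` (data.frame
#'   `id`, `phase`, `received`, `given`, `balance`), `stat` (focal
#'   included) and `stat_excl` (focal excluded).
#' @export
grooming_balances <- function(network, focal_id) {
  stopifnot(inherits(network, "behaviour_network"))
  if (!network$directed || network$behaviour != "grooming")
    stop("grooming_balances() needs the directed grooming network")
  ct <- node_centralities(network)
  balances <- data.frame(id = ct$id, phase = network$phase,
                         received = ct$strength_in, given = ct$strength_out,
                         balance = ct$strength_in - ct$strength_out,
                         stringsAsFactors = FALSE)
  vals <- stats::setNames(balances$balance, balances$id)
  ## a fully reciprocal (or empty) network has a degenerate balance
  ## distribution: report the balances with no z rather than failing
  safe_z <- function(...) tryCatch(focal_z(...), error = function(e) NULL)
  structure(list(balances = balances,
                 stat = safe_z(vals, focal_id),
                 stat_excl = safe_z(vals, focal_id, include_focal = FALSE)),
            class = "grooming_balance")
}

#' @export
print.grooming_balance <- function(x, ...) {
  if (is.null(x$stat)) {
    cat(sprintf("<grooming_balance> %s: degenerate balance distribution\n",
                x$balances$phase[1]))
  } else {
    cat(sprintf("<grooming_balance> %s: focal balance %g, z = %.2f (incl.) / %.2f (excl.)\n",
                x$balances$phase[1], x$stat$focal_change, x$stat$z,
                x$stat_excl$z))
  }
  invisible(x)
}
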