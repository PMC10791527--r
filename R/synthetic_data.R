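#' Simulation parameters for a synthetic provisioning study
#'
#' Defines the generative law of a synthetic two-phase study: a group of
#' adults in matrilines with a latent strict dominance order, and
#' independent Poisson event counts per dyad, phase and behaviour layer.
#' Agonistic events (aggression, displacement) flow from the higher- to the
#' lower-ranked member of a dyad with probability
#' `plogis(rank_steepness * rank gap)`; peaceful SBTs are signalled by the
#' lower-ranked member with the same law. Affiliative layers (grooming,
#' huddling, proximity) are rank-blind but kin-biased: within-matriline
#' dyads have their rates multiplied by `kin_multiplier`.
#'
#' Default rates are calibrated so that per-individual strengths are tens
#' of events per 4-week phase, the order of magnitude reported for a
#' macaque group of 83 adults (e.g. roughly 10 aggressive events and 12
#' grooming bouts received, and near 50 huddling/proximity associations,
#' for a mid-ranked female at baseline).
#'
#' @param n_adults number of adults (>= 4); default 83.
#' @param n_matrilines number of matrilines; individuals are assigned
#'   round-robin so matriline sizes are balanced within one.
#' @param phase_days days of observation per phase (default 28, two 4-week
#'   phases).
#' @param base_rate named numeric vector of expected events per dyad per
#'   phase for each of the six behaviours (see [behaviours()]). For
#'   directed affiliative grooming the rate is the dyad total, split evenly
#'   between the two directions.
#' @param rank_steepness non-negative slope of the logistic law giving the
#'   probability that agonism flows down-rank (per unit of ordinal rank
#'   gap). 0 makes direction a coin flip; large values make the hierarchy
#'   strict.
#' @param kin_multiplier multiplicative (>= 1) boost of affiliative rates
#'   within matrilines.
#' @param p_submission probability that an aggression event is met with a
#'   clear submissive response (such events are the ones retained in the
#'   aggression network); default 1.
#' @param start_date first day of the baseline phase (ISO string or Date).
#' @param seed integer master seed; phase-level seeds are derived from it
#'   deterministically so each phase is independently reproducible.
#' @return An object of class `"simulation_params"` (a validated list).
#' @export
simulation_params <- function(n_adults = 83,
                              n_matrilines = 7,
                              phase_days = 28,
                              base_rate = c(aggression = 0.25,
                                            displacement = 0.25,
                                            peaceful_sbt = 0.07,
                                            grooming = 0.22,
                                            huddling = 0.45,
                                            proximity = 0.45),
                              rank_steepness = 0.15,
                              kin_multiplier = 5,
                              p_submission = 1,
                              start_date = "2019-03-04",
                              seed = 42L) {
  if (n_adults < 4) stop("n_adults must be at least 4")
  if (n_matrilines < 1 || n_matrilines > n_adults)
    stop("n_matrilines must be in [1, n_adults]")
  if (is.null(names(base_rate)))
    names(base_rate) <- .BEHAVIOURS
  miss <- setdiff(.BEHAVIOURS, names(base_rate))
  if (length(miss))
    stop("base_rate must be named for all six behaviours; missing: ",
         paste(miss, collapse = ", "))
  base_rate <- base_rate[.BEHAVIOURS]
  if (any(base_rate < 0)) stop("base rates must be non-negative")
  if (rank_steepness < 0) stop("rank_steepness must be non-negative")
  if (kin_multiplier < 1) stop("kin_multiplier must be >= 1")
  if (p_submission < 0 || p_submission > 1)
    stop("p_submission must be a probability")
  structure(list(n_adults = as.integer(n_adults),
                 n_matrilines = as.integer(n_matrilines),
                 phase_days = as.integer(phase_days),
                 base_rate = base_rate,
                 rank_steepness = rank_steepness,
                 kin_multiplier = kin_multiplier,
                 p_submission = p_submission,
                 start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Perturbation effects on the focal's dyadic rates
#'
#' Multiplicative effects applied, in the experimental phase only, to the
#' Poisson rates of dyads involving the focal in the stated role. A value
#' of 1 means no effect; values above 1 increase and below 1 decrease the
#' corresponding rate. `aggression_in_mult` scales aggression events
#' directed at the focal, `sbt_in_mult` the peaceful SBTs she receives,
#' `grooming_in_mult`/`grooming_out_mult` grooming received/given, and
#' `huddling_mult`/`proximity_mult` her undirected association rates.
#'
#' @param aggression_in_mult,sbt_in_mult,grooming_in_mult,grooming_out_mult,huddling_mult,proximity_mult
#'   non-negative multipliers (default 1 = no effect).
#' @param focal_id optional focal id; if `NULL`, the roster's focal is used.
#' @return An object of class `"effect_spec"`.
#' @export
effect_spec <- function(aggression_in_mult = 1, sbt_in_mult = 1,
                        grooming_in_mult = 1, grooming_out_mult = 1,
                        huddling_mult = 1, proximity_mult = 1,
                        focal_id = NULL) {
  m <- c(aggression_in_mult = aggression_in_mult,
         sbt_in_mult = sbt_in_mult,
         grooming_in_mult = grooming_in_mult,
         grooming_out_mult = grooming_out_mult,
         huddling_mult = huddling_mult,
         proximity_mult = proximity_mult)
  if (any(m < 0)) stop("effect multipliers must be non-negative")
  structure(c(as.list(m), list(focal_id = focal_id)), class = "effect_spec")
}

## deterministic per-phase seed derived from the master seed, so baseline
## and experimental phases are independently reproducible
.phase_seed <- function(seed, phase) {
  offset <- match(phase, .PHASES)  # 1 = baseline, 2 = experimental
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

#' Simulate a group roster
#'
#' Creates `n_adults` adult individuals assigned round-robin to matrilines
#' (sizes balanced within one), draws a latent strict dominance order
#' (stored in the `true_rank` column, 1 = highest) and places the focal
#' "provider" female exactly mid-hierarchy (`true_rank = ceiling(n/2)`), a
#' mid-ranked animal as in the experimental design the generator emulates.
#' Sexes are drawn female-biased (72:11, the adult sex ratio of the study
#' group the generator mirrors) and all individuals are present in both
#' phases.
#'
#' @param params a [simulation_params()] object.
#' @return A [roster()] whose `individuals` carry a `true_rank` column.
#' @export
simulate_roster <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_adults
  ids <- sprintf("id%0*d", nchar(n), seq_len(n))
  individuals <- data.frame(
    id = ids,
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(72, 11)),
    age_years = sample(3:24, n, replace = TRUE),
    matriline_id = sprintf("mat%d", rep_len(seq_len(params$n_matrilines), n)),
    present_baseline = TRUE,
    present_experimental = TRUE,
    true_rank = sample(n),
    stringsAsFactors = FALSE
  )
  focal_rank <- ceiling(n / 2)
  focal_id <- individuals$id[individuals$true_rank == focal_rank]
  individuals$sex[individuals$id == focal_id] <- "F"
  roster(individuals, focal_id = focal_id)
}

## Per-dyad Poisson rate table for one phase. Returns ordered-pair rates
## for directed behaviours and unordered-pair rates for huddling/proximity.
.dyad_rates <- function(params, ind, behaviour, effects, focal_id) {
  n <- nrow(ind)
  ut <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  a <- ind$id[ut[, 1]]; b <- ind$id[ut[, 2]]
  ra <- ind$true_rank[ut[, 1]]; rb <- ind$true_rank[ut[, 2]]
  kin <- ind$matriline_id[ut[, 1]] == ind$matriline_id[ut[, 2]]
  base <- params$base_rate[[behaviour]]
  kmul <- ifelse(behaviour %in% .AFFILIATIVE & kin, params$kin_multiplier, 1)
  s <- params$rank_steepness
  emul <- function(name) if (is.null(effects)) 1 else effects[[name]]
  if (behaviour %in% .UNDIRECTED) {
    lambda <- base * kmul
    if (!is.null(effects)) {
      mult <- emul(paste0(behaviour, "_mult"))
      lambda[a == focal_id | b == focal_id] <-
        lambda[a == focal_id | b == focal_id] * mult
    }
    return(data.frame(actor = a, recipient = b, lambda = lambda,
                      stringsAsFactors = FALSE))
  }
  ## directed: stack both orientations of every dyad
  if (behaviour %in% c("aggression", "displacement")) {
    ## probability that the first-listed member acts: logistic in the rank
    ## gap, > 1/2 when it outranks (smaller true_rank) the other
    p_ab <- stats::plogis(s * (rb - ra))
  } else if (behaviour == "peaceful_sbt") {
    ## the signaller (actor) is the lower-ranked member
    p_ab <- stats::plogis(s * (ra - rb))
  } else {  # grooming: direction rank-blind
    p_ab <- rep(0.5, length(a))
  }
  out <- data.frame(actor = c(a, b), recipient = c(b, a),
                    lambda = c(base * kmul * p_ab, base * kmul * (1 - p_ab)),
                    stringsAsFactors = FALSE)
  if (!is.null(effects)) {
    inm <- switch(behaviour,
                  aggression = emul("aggression_in_mult"),
                  peaceful_sbt = emul("sbt_in_mult"),
                  grooming = emul("grooming_in_mult"),
                  1)
    out$lambda[out$recipient == focal_id] <-
      out$lambda[out$recipient == focal_id] * inm
    if (behaviour == "grooming")
      out$lambda[out$actor == focal_id] <-
        out$lambda[out$actor == focal_id] * emul("grooming_out_mult")
  }
  out
}

#' Simulate one phase of interaction events
#'
#' Draws dyadic event counts for every behaviour layer from independent
#' Poisson laws (see [simulation_params()] for the rate structure) and
#' expands them into an event log. Effects, if supplied, modify the focal's
#' dyadic rates and are intended for the experimental phase; they are
#' applied whenever non-`NULL`.
#'
#' The phase RNG seed is derived deterministically from the master seed, so
#' the same `(params, phase)` pair always yields the same events and the
#' two phases are independent.
#'
#' @param params a [simulation_params()].
#' @param roster a roster from [simulate_roster()] (needs `true_rank`).
#' @param phase `"baseline"` or `"experimental"`.
#' @param effects an [effect_spec()] or `NULL` for no perturbation.
#' @return A validated `interaction_events` data.frame.
#' @export
simulate_phase <- function(params, roster, phase, effects = NULL) {
  stopifnot(inherits(params, "simulation_params"), inherits(roster, "roster"))
  .check_phase(phase)
  ind <- roster$individuals
  if (is.null(ind$true_rank))
    stop("roster lacks a true_rank column; use simulate_roster()")
  present <- ind[ind$is_adult & ind[[paste0("present_", phase)]], ]
  focal_id <- roster$focal_id
  if (!is.null(effects)) {
    stopifnot(inherits(effects, "effect_spec"))
    if (!is.null(effects$focal_id)) {
      if (!effects$focal_id %in% ind$id)
        stop("effects name a focal not in the roster: ", effects$focal_id)
      focal_id <- effects$focal_id
    }
  }
  set.seed(.phase_seed(params$seed, phase))
  day0 <- params$start_date +
    (match(phase, .PHASES) - 1L) * params$phase_days
  pieces <- lapply(.BEHAVIOURS, function(beh) {
    rates <- .dyad_rates(params, present, beh, effects, focal_id)
    counts <- stats::rpois(nrow(rates), rates$lambda)
    keep <- counts > 0
    if (!any(keep)) return(NULL)
    idx <- rep(which(keep), counts[keep])
    ne <- length(idx)
    data.frame(
      date = day0 + sample(0:(params$phase_days - 1L), ne, replace = TRUE),
      phase = phase,
      behaviour = beh,
      actor = rates$actor[idx],
      recipient = rates$recipient[idx],
      severity = if (beh == "aggression")
        sample(.SEVERITIES, ne, replace = TRUE, prob = c(0.6, 0.3, 0.1))
      else NA_character_,
      submissive_response = if (beh == "aggression")
        stats::runif(ne) < params$p_submission
      else NA,
      stringsAsFactors = FALSE
    )
  })
  ev <- do.call(rbind, pieces)
  if (is.null(ev))
    ev <- data.frame(date = as.Date(character()), phase = character(),
                     behaviour = character(), actor = character(),
                     recipient = character(), severity = character(),
                     submissive_response = logical())
  ev <- ev[order(ev$date, ev$behaviour, ev$actor, ev$recipient), ]
  interaction_events(ev)
}

#' Simulate a complete two-phase study
#'
#' Generates a roster, a baseline phase with no perturbation and an
#' experimental phase with the supplied effects. Phase seeds are split
#' deterministically from the master seed, so each phase can be regenerated
#' independently with [simulate_phase()].
#'
#' @inheritParams simulate_phase
#' @param effects an [effect_spec()]; all-1 multipliers give a null study.
#' @return A list with elements `roster` and `events` (both phases,
#'   row-bound).
#' @examples
#' p <- simulation_params(n_adults = 12, n_matrilines = 3, seed = 1)
#' s <- generate_study(p, effect_spec(aggression_in_mult = 3))
#' table(s$events$phase, s$events$behaviour)[, 1:3]
#' @export
generate_study <- function(params, effects = effect_spec()) {
  stopifnot(inherits(params, "simulation_params"))
  ros <- simulate_roster(params)
  bl <- simulate_phase(params, ros, "baseline", effects = NULL)
  ex <- simulate_phase(params, ros, "experimental", effects = effects)
  ev <- interaction_events(rbind(as.data.frame(bl), as.data.frame(ex)))
  list(roster = ros, events = ev)
}

#' Write a simulated study to disk
#'
#' Writes `roster.csv`, `events.csv` and `params.json` (which round-trips
#' the [simulation_params()] and [effect_spec()]) into a directory.
#'
#' @param params a [simulation_params()].
#' @param effects an [effect_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list returned by [generate_study()].
#' @export
write_simulation <- function(params, effects = effect_spec(), dir) {
  study <- generate_study(params, effects)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_roster(study$roster, file.path(dir, "roster.csv"))
  write_events(study$events, file.path(dir, "events.csv"))
  pj <- unclass(params)
  pj$start_date <- format(pj$start_date)
  jsonlite::write_json(list(simulation = pj, effects = unclass(effects)),
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(study)
}

#' Read simulation parameters back from params.json
#'
#' @param path path to a `params.json` written by [write_simulation()].
#' @return A list with elements `params` ([simulation_params()]) and
#'   `effects` ([effect_spec()]).
#' @export
read_simulation_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- j$simulation
  params <- simulation_params(n_adults = p$n_adults,
                              n_matrilines = p$n_matrilines,
                              phase_days = p$phase_days,
                              base_rate = unlist(p$base_rate),
                              rank_steepness = p$rank_steepness,
                              kin_multiplier = p$kin_multiplier,
                              p_submission = p$p_submission,
                              start_date = p$start_date,
                              seed = p$seed)
  e <- j$effects
  effects <- effect_spec(aggression_in_mult = e$aggression_in_mult,
                         sbt_in_mult = e$sbt_in_mult,
                         grooming_in_mult = e$grooming_in_mult,
                         grooming_out_mult = e$grooming_out_mult,
                         huddling_mult = e$huddling_mult,
                         proximity_mult = e$proximity_mult,
                         focal_id = e$focal_id)
  list(params = params, effects = effects)
}
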