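#' Kinship test
#'
#' Two individuals are kin when they belong to the same matriline (maternal
#' kin group). The roster carries no pedigree, so matriline-label equality
#' is the operational definition.
#'
#' @param a,b individual ids.
#' @param roster a [roster()].
#' @return Logical.
#' @export
are_kin <- function(a, b, roster) {
  stopifnot(inherits(roster, "roster"))
  ind <- roster$individuals
  ia <- match(a, ind$id); ib <- match(b, ind$id)
  if (anyNA(ia) || anyNA(ib))
    stop("unknown id(s): ",
         paste(unique(c(a[is.na(ia)], b[is.na(ib)])), collapse = ", "))
  ind$matriline_id[ia] == ind$matriline_id[ib]
}

#' Kin composition of the focal's interactions and partners
#'
#' Summarises, for one behaviour and phase, how much of the focal's social
#' activity involved kin: the count of her events (as either participant),
#' the percentage of those events with a kin partner, the number of
#' distinct partners, and the percentage of partners that are kin.
#' Percentages are rounded half-up to 2 decimal places, the precision of
#' the summary tables this mirrors. Aggression events are filtered to
#' those with a submissive response, as in the network build.
#'
#' @param events validated `interaction_events`.
#' @param behaviour,phase layer selection.
#' @param focal_id the focal's id.
#' @param roster a [roster()] (for matriline lookup).
#' @return One-row data.frame of class `"kin_summary"`: `phase`,
#'   `behaviour`, `total_interactions`, `pct_kin_interactions`,
#'   `unique_partners`, `pct_kin_partners`. Percentages are `NA` when the
#'   focal had no events.
#' @examples
#' # 4 huddles, 1 with a kin partner
#' ind <- data.frame(id = c("f", "k", "x", "y"), sex = "F", age_years = 6,
#'                   matriline_id = c("m1", "m1", "m2", "m3"),
#'                   present_baseline = TRUE, present_experimental = TRUE)
#' r <- roster(ind, "f")
#' ev <- interaction_events(data.frame(
#'   date = "2019-03-04", phase = "baseline", behaviour = "huddling",
#'   actor = c("f", "f", "x", "f"), recipient = c("k", "x", "f", "y"),
#'   severity = NA, submissive_response = NA))
#' kin_summary(ev, "huddling", "baseline", "f", r)
#' @export
kin_summary <- function(events, behaviour, phase, focal_id, roster) {
  stopifnot(inherits(roster, "roster"))
  ev <- filter_events(events, behaviour, phase)
  ev <- ev[ev$actor == focal_id | ev$recipient == focal_id, , drop = FALSE]
  partner <- ifelse(ev$actor == focal_id, ev$recipient, ev$actor)
  total <- length(partner)
  if (total == 0L) {
    out <- data.frame(phase = phase, behaviour = behaviour,
                      total_interactions = 0L,
                      pct_kin_interactions = NA_real_,
                      unique_partners = 0L,
                      pct_kin_partners = NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    kin <- are_kin(rep(focal_id, total), partner, roster)
    up <- unique(partner)
    upkin <- are_kin(rep(focal_id, length(up)), up, roster)
    out <- data.frame(
      phase = phase, behaviour = behaviour,
      total_interactions = total,
      pct_kin_interactions = .round_half_up(100 * sum(kin) / total, 2),
      unique_partners = length(up),
      pct_kin_partners = .round_half_up(100 * sum(upkin) / length(up), 2),
      stringsAsFactors = FALSE)
  }
  class(out) <- c("kin_summary", class(out))
  out
}

#' Kin-composition table across phases and socio-spatial behaviours
#'
#' One [kin_summary()] row per phase for each requested behaviour
#' (defaults to the socio-spatial layers, huddling and proximity).
#'
#' @inheritParams kin_summary
#' @param behaviours_used behaviours to tabulate.
#' @return Row-bound `kin_summary` data.frame.
#' @export
kin_table <- function(events, focal_id, roster,
                      behaviours_used = c("huddling", "proximity")) {
  rows <- list()
  for (ph in .PHASES)
    for (beh in behaviours_used)
      rows[[paste(ph, beh)]] <-
        kin_summary(events, beh, ph, focal_id, roster)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
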