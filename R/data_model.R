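#' Construct a group roster
#'
#' A roster holds one row per individual (id, sex, age, matriline, per-phase
#' presence) together with the identity of the focal ("provider") animal.
#' Adults are individuals aged 3 years or more at study start; only adults
#' enter the behavioural networks.
#'
#' @param individuals data.frame with columns `id`, `sex` (`"F"`/`"M"`),
#'   `age_years`, `matriline_id`, `present_baseline`, `present_experimental`
#'   (logical). An optional `true_rank` column (1 = highest) carries the
#'   latent dominance order of simulated rosters.
#' @param focal_id id of the provider female; must be present in both phases.
#' @return An object of class `"roster"`: a list with elements
#'   `individuals` (the validated data.frame, with a derived logical
#'   `is_adult` column) and `focal_id`.
#' @examples
#' ind <- data.frame(id = c("a", "b", "c"), sex = "F", age_years = 5,
#'                   matriline_id = "m1", present_baseline = TRUE,
#'                   present_experimental = TRUE)
#' r <- roster(ind, focal_id = "b")
#' r$focal_id
#' @export
roster <- function(individuals, focal_id) {
  req <- c("id", "sex", "age_years", "matriline_id",
           "present_baseline", "present_experimental")
  miss <- setdiff(req, names(individuals))
  if (length(miss))
    stop("roster is missing column(s): ", paste(miss, collapse = ", "))
  individuals$id <- as.character(individuals$id)
  if (anyDuplicated(individuals$id))
    stop("duplicate individual id(s): ",
         paste(unique(individuals$id[duplicated(individuals$id)]),
               collapse = ", "))
  if (any(!individuals$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'")
  if (any(is.na(individuals$age_years)) || any(individuals$age_years < 0))
    stop("age_years must be non-negative")
  for (cl in c("present_baseline", "present_experimental"))
    individuals[[cl]] <- as.logical(individuals[[cl]])
  if (any(!individuals$present_baseline & !individuals$present_experimental))
    stop("every individual must be present in at least one phase")
  individuals$is_adult <- individuals$age_years >= 3
  focal_id <- as.character(focal_id)
  if (length(focal_id) != 1L || !focal_id %in% individuals$id)
    stop("focal_id must name exactly one roster member")
  frow <- individuals[individuals$id == focal_id, ]
  if (!frow$present_baseline || !frow$present_experimental)
    stop("the focal individual must be present in both phases")
  rownames(individuals) <- NULL
  structure(list(individuals = individuals, focal_id = focal_id),
            class = "roster")
}

#' @export
print.roster <- function(x, ...) {
  n <- nrow(x$individuals)
  cat(sprintf("<roster> %d individuals (%d adults), focal = %s\n",
              n, sum(x$individuals$is_adult), x$focal_id))
  invisible(x)
}

#' Read or write a roster CSV
#'
#' The roster file has one row per individual with columns `id`, `sex`,
#' `age_years`, `matriline_id`, `present_baseline`, `present_experimental`
#' and `is_focal`; exactly one row must have `is_focal = TRUE`. A
#' `true_rank` column, if present, is kept (simulated rosters carry the
#' latent dominance order there).
#'
#' @param path path to a CSV file.
#' @return `read_roster()` returns a [roster()] object; `write_roster()`
#'   invisibly returns `path`.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "sex", "age_years", "matriline_id",
           "present_baseline", "present_experimental", "is_focal")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("roster file is missing column(s): ", paste(miss, collapse = ", "))
  df$is_focal <- as.logical(df$is_focal)
  nf <- sum(df$is_focal, na.rm = TRUE)
  if (nf != 1L)
    stop("roster must flag exactly one focal individual (found ", nf, ")")
  focal_id <- df$id[which(df$is_focal)]
  df$is_focal <- NULL
  roster(df, focal_id = focal_id)
}

#' @rdname read_roster
#' @param x a [roster()] object.
#' @export
write_roster <- function(x, path) {
  stopifnot(inherits(x, "roster"))
  df <- x$individuals
  df$is_adult <- NULL
  df$is_focal <- df$id == x$focal_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Validate a data.frame of interaction events
#'
#' One row per observed dyadic event. Columns: `date` (ISO-8601), `phase`
#' (`baseline`/`experimental`), `behaviour` (one of [behaviours()]),
#' `actor`, `recipient`, `severity` (`mild`/`moderate`/`severe`, aggression
#' only, otherwise `NA`) and `submissive_response` (logical, aggression
#' only). A derived logical column `directed` is added. Huddling and
#' proximity events keep the recorded (initiator, recipient) pair but the
#' direction is ignored downstream.
#'
#' @param df data.frame of raw events.
#' @return The validated data.frame with class `c("interaction_events",
#'   "data.frame")`.
#' @export
interaction_events <- function(df) {
  req <- c("date", "phase", "behaviour", "actor", "recipient",
           "severity", "submissive_response")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("events are missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(df)
  if (n == 0L) {
    df$directed <- logical(0)
    class(df) <- c("interaction_events", "data.frame")
    return(df)
  }
  if (!inherits(df$date, "Date")) {
    parsed <- as.Date(as.character(df$date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(df$date) & df$date != "")
    if (length(bad))
      stop("malformed date in event row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    df$date <- parsed
  }
  if (any(is.na(df$date))) stop("missing date in event row(s): ",
                                paste(which(is.na(df$date)), collapse = ", "))
  badb <- which(!df$behaviour %in% .BEHAVIOURS)
  if (length(badb))
    stop("unknown behaviour token in event row(s): ",
         paste(utils::head(badb, 5), collapse = ", "))
  badp <- which(!df$phase %in% .PHASES)
  if (length(badp))
    stop("unknown phase token in event row(s): ",
         paste(utils::head(badp, 5), collapse = ", "))
  df$actor <- as.character(df$actor)
  df$recipient <- as.character(df$recipient)
  self <- which(df$actor == df$recipient)
  if (length(self))
    stop("actor equals recipient in event row(s): ",
         paste(utils::head(self, 5), collapse = ", "))
  df$severity <- as.character(df$severity)
  df$severity[!is.na(df$severity) & df$severity == ""] <- NA_character_
  bads <- which(!is.na(df$severity) &
                  (!df$severity %in% .SEVERITIES | df$behaviour != "aggression"))
  if (length(bads))
    stop("invalid severity (must be mild/moderate/severe, aggression only) ",
         "in event row(s): ", paste(utils::head(bads, 5), collapse = ", "))
  df$submissive_response <- as.logical(df$submissive_response)
  df$submissive_response[df$behaviour != "aggression"] <- NA
  df$directed <- df$behaviour %in% .DIRECTED
  rownames(df) <- NULL
  class(df) <- unique(c("interaction_events", class(df)))
  df
}

#' Read or write an interaction-event CSV
#'
#' `read_events()` parses and validates an event log (see
#' [interaction_events()] for the schema). Rows whose actor or recipient is
#' not a roster member are rejected rather than failing the whole read: they
#' are dropped with a message and returned in the `"rejected"` attribute of
#' the result. Malformed dates, unknown behaviour tokens and self-loops are
#' hard errors naming the offending row.
#'
#' @param path path to a CSV file with header `date, phase, behaviour,
#'   actor, recipient, severity, submissive_response`.
#' @param roster a [roster()]; used to screen event participants.
#' @return A validated `interaction_events` data.frame; rejected rows (if
#'   any) in `attr(, "rejected")`.
#' @export
read_events <- function(path, roster) {
  stopifnot(inherits(roster, "roster"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(date = "character",
                                          severity = "character"))
  req <- c("date", "phase", "behaviour", "actor", "recipient",
           "severity", "submissive_response")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("event file is missing column(s): ", paste(miss, collapse = ", "))
  known <- roster$individuals$id
  unknown <- !(df$actor %in% known) | !(df$recipient %in% known)
  rejected <- df[unknown, , drop = FALSE]
  if (nrow(rejected))
    message(nrow(rejected), " event row(s) rejected: participant not in roster")
  ev <- interaction_events(df[!unknown, , drop = FALSE])
  attr(ev, "rejected") <- rejected
  ev
}

#' @rdname read_events
#' @param events a validated `interaction_events` data.frame.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  df$directed <- NULL
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Individuals eligible for group-level summaries
#'
#' Individuals absent for part of the study appear in few or no experimental
#' networks, so group-level change means are restricted to adults present in
#' both phases. The focal is always retained (it must be present in both
#' phases by construction).
#'
#' @param roster a [roster()].
#' @return Character vector of eligible ids, sorted.
#' @examples
#' ind <- data.frame(id = c("a", "b", "c"), sex = "F",
#'                   age_years = c(5, 8, 2), matriline_id = "m1",
#'                   present_baseline = TRUE,
#'                   present_experimental = c(TRUE, TRUE, TRUE))
#' phase_presence_filter(roster(ind, "a"))  # "c" is a juvenile -> excluded
#' @export
phase_presence_filter <- function(roster) {
  stopifnot(inherits(roster, "roster"))
  ind <- roster$individuals
  keep <- ind$is_adult & ind$present_baseline & ind$present_experimental
  ids <- sort(unique(c(ind$id[keep], roster$focal_id)))
  ids
}
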