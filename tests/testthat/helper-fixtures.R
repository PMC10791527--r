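# Small programmatic fixtures shared across test files.

make_individuals <- function(ids, matrilines = "m1", ages = 6,
                             present_bl = TRUE, present_ex = TRUE) {
  data.frame(id = ids, sex = "F",
             age_years = rep_len(ages, length(ids)),
             matriline_id = rep_len(matrilines, length(ids)),
             present_baseline = rep_len(present_bl, length(ids)),
             present_experimental = rep_len(present_ex, length(ids)),
             stringsAsFactors = FALSE)
}

make_roster <- function(n = 4, focal = NULL, ...) {
  ids <- letters[seq_len(n)]
  roster(make_individuals(ids, ...), focal_id = focal %||% ids[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Event-log builder: one row per (actor, recipient) pair given.
make_events <- function(actor, recipient, behaviour = "grooming",
                        phase = "baseline", date = "2019-03-04",
                        severity = NA_character_,
                        submissive_response = NA) {
  interaction_events(data.frame(
    date = date, phase = phase, behaviour = behaviour,
    actor = actor, recipient = recipient,
    severity = severity, submissive_response = submissive_response,
    stringsAsFactors = FALSE))
}

# Expand a focal-centred partner/count table into events (for kin tables):
# counts is a named integer vector, partner id -> number of events.
events_with_partners <- function(focal, counts, behaviour, phase) {
  partners <- rep(names(counts), counts)
  make_events(actor = rep(focal, length(partners)), recipient = partners,
              behaviour = behaviour, phase = phase)
}

# A small simulated study shared by oracle-equivalence tests.
small_study <- function(seed = 20, n = 20, effects = effect_spec()) {
  p <- simulation_params(n_adults = n, n_matrilines = 4, seed = seed)
  generate_study(p, effects)
}
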