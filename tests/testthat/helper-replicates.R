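# Replicated simulated studies for the calibration / recovery checks.
# Returns the focal z for each of the ten network x direction combinations
# (undirected layers on *_total, directed layers in and out).

table1_combos <- list(c("huddling", "total"), c("proximity", "total"),
                      c("aggression", "in"), c("displacement", "in"),
                      c("grooming", "in"), c("peaceful_sbt", "in"),
                      c("aggression", "out"), c("displacement", "out"),
                      c("grooming", "out"), c("peaceful_sbt", "out"))

combo_names <- vapply(table1_combos, paste, "", collapse = "_")

focal_change_zs <- function(seed, effects = effect_spec(),
                            metric = "degree", params = NULL) {
  p <- params %||% simulation_params(seed = seed)
  p$seed <- as.integer(seed)
  ros <- simulate_roster(p)
  elig <- phase_presence_filter(ros)
  nb <- build_phase_networks(simulate_phase(p, ros, "baseline"),
                             "baseline", elig)
  ne <- build_phase_networks(simulate_phase(p, ros, "experimental",
                                            effects = effects),
                             "experimental", elig)
  z <- vapply(table1_combos, function(cm) {
    ch <- change_scores(node_centralities(nb[[cm[1]]]),
                        node_centralities(ne[[cm[1]]]),
                        paste0(metric, "_", cm[2]))
    focal_z(ch, ros$focal_id)$z
  }, numeric(1))
  names(z) <- combo_names
  z
}
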