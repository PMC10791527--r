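## the 10 network x direction combinations of the main change table:
## two undirected layers (degree), four directed layers in and out
.TABLE1_ROWS <- data.frame(
  network_type = c("undirected", "undirected",
                   rep("directed_in", 4), rep("directed_out", 4)),
  behaviour = c("huddling", "proximity",
                rep(c("aggression", "displacement", "grooming",
                      "peaceful_sbt"), 2)),
  stringsAsFactors = FALSE
)
.TABLE1_ROWS$metric_degree <- ifelse(
  .TABLE1_ROWS$network_type == "undirected", "degree_total",
  ifelse(.TABLE1_ROWS$network_type == "directed_in", "degree_in",
         "degree_out"))
.TABLE1_ROWS$metric_strength <- sub("degree", "strength",
                                    .TABLE1_ROWS$metric_degree)

#' Configuration for an end-to-end study run
#'
#' Exactly one input source must be given: either paths to `events.csv` and
#' `roster.csv`, or a simulation block ([simulation_params()] plus
#' [effect_spec()]).
#'
#' @param events_path,roster_path CSV inputs (see [read_events()],
#'   [read_roster()]).
#' @param sim_params,sim_effects simulation block.
#' @param focal_id optional override of the roster's focal.
#' @param max_path_len longest pathway used to complete the win-loss
#'   matrix (default 2).
#' @param p_mode `"normal"` (normal-tail p-values, the default) or
#'   `"permutation"` (relabel which eligible individual is focal).
#' @param n_permutations resampled labels when `p_mode = "permutation"`
#'   (>= 100), or `NULL` for exact enumeration.
#' @param seed integer seed for any randomness (simulation, permutation).
#' @param out_dir optional output directory; when given, [run_study()]
#'   writes all CSV outputs plus `report.json` there.
#' @param write_plots also write density plots of the change distributions
#'   (PNG) under `out_dir`.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(events_path = NULL, roster_path = NULL,
                       sim_params = NULL, sim_effects = effect_spec(),
                       focal_id = NULL, max_path_len = 2L,
                       p_mode = c("normal", "permutation"),
                       n_permutations = NULL, seed = 1L,
                       out_dir = NULL, write_plots = FALSE) {
  p_mode <- match.arg(p_mode)
  have_files <- !is.null(events_path) || !is.null(roster_path)
  have_sim <- !is.null(sim_params)
  if (have_files == have_sim)
    stop("give exactly one input source: file paths or a simulation block")
  if (have_files && (is.null(events_path) || is.null(roster_path)))
    stop("both events_path and roster_path are required")
  if (have_sim) stopifnot(inherits(sim_params, "simulation_params"))
  if (p_mode == "permutation" && !is.null(n_permutations) &&
      n_permutations < 100)
    stop("n_permutations must be >= 100")
  structure(list(events_path = events_path, roster_path = roster_path,
                 sim_params = sim_params, sim_effects = sim_effects,
                 focal_id = focal_id, max_path_len = as.integer(max_path_len),
                 p_mode = p_mode, n_permutations = n_permutations,
                 seed = as.integer(seed), out_dir = out_dir,
                 write_plots = isTRUE(write_plots)),
            class = "run_config")
}

.stat_row <- function(stat, behaviour, network_type, metric) {
  data.frame(network_type = network_type, behaviour = behaviour,
             metric = metric,
             mean_change = stat$mean_change, sd_change = stat$sd_change,
             focal_change = stat$focal_change, z = stat$z,
             p_two_tailed = stat$p_two_tailed,
             p_one_tailed = stat$p_one_tailed,
             stringsAsFactors = FALSE)
}

#' Run the full perturbation analysis
#'
#' Orchestrates the whole pipeline: load or simulate the data, build the
#' six behavioural networks per phase over the eligible individuals,
#' compute centralities and their baseline-to-experimental changes, the
#' focal z-statistic for every network/direction (degree, as in the main
#' change table, and strength), grooming balances per phase, dominance
#' ranks per phase with their cross-phase correlation, higher-ranked
#' partner percentages for agonistic layers, and the focal's kin
#' composition for the socio-spatial layers. Deterministic given the
#' configuration seed.
#'
#' @param config a [run_config()].
#' @return A list of class `"study_report"` with elements `table1`
#'   (degree-change stats, 10 rows), `strength_stats` (same rows on
#'   strength), `centrality` (full per-node table), `balances` (grooming
#'   balance per phase), `ranks` (per-phase `"dominance_result"` plus
#'   `rank_correlation`), `higher_ranked`, `table2` (kin summaries),
#'   `focal_id`, `eligible_ids`, `exclusions` (dropped animals/events) and
#'   `config` echoes. If `config$out_dir` is set, CSV outputs and
#'   `report.json` are written there.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  ## --- data_model stage -------------------------------------------------
  if (!is.null(config$sim_params)) {
    study <- generate_study(config$sim_params, config$sim_effects)
    ros <- study$roster
    events <- study$events
  } else {
    ros <- tryCatch(read_roster(config$roster_path),
                    error = function(e) stop("data_model stage (roster): ",
                                             conditionMessage(e)))
    events <- tryCatch(read_events(config$events_path, ros),
                       error = function(e) stop("data_model stage (events): ",
                                                conditionMessage(e)))
  }
  focal_id <- config$focal_id %||% ros$focal_id
  if (!focal_id %in% ros$individuals$id)
    stop("data_model stage: focal '", focal_id, "' not in roster")
  eligible <- phase_presence_filter(ros)
  n_excluded <- sum(ros$individuals$is_adult) -
    sum(eligible %in% ros$individuals$id[ros$individuals$is_adult])
  ## --- network_build stage ----------------------------------------------
  nets <- lapply(stats::setNames(.PHASES, .PHASES), function(ph)
    build_phase_networks(events, ph, eligible))
  dropped_events <- sum(vapply(unlist(nets, recursive = FALSE),
                               function(nw) attr(nw, "dropped"), 0L))
  ## --- centrality_change stage -------------------------------------------
  cent <- lapply(nets, centrality_table)
  all_cent <- rbind(cent$baseline, cent$experimental)
  stat_rows <- function(metric_col) {
    rows <- lapply(seq_len(nrow(.TABLE1_ROWS)), function(i) {
      beh <- .TABLE1_ROWS$behaviour[i]
      metric <- .TABLE1_ROWS[[metric_col]][i]
      ch <- change_scores(cent$baseline[cent$baseline$behaviour == beh, ],
                          cent$experimental[cent$experimental$behaviour == beh, ],
                          metric)
      st <- focal_z(ch, focal_id)
      if (config$p_mode == "permutation") {
        pp <- permutation_p(ch, focal_id, n_perm = config$n_permutations)
        st$p_two_tailed <- pp$p
      }
      .stat_row(st, beh, .TABLE1_ROWS$network_type[i], metric)
    })
    do.call(rbind, rows)
  }
  table1 <- stat_rows("metric_degree")
  strength_stats <- stat_rows("metric_strength")
  balances <- lapply(stats::setNames(.PHASES, .PHASES), function(ph)
    grooming_balances(nets[[ph]]$grooming, focal_id))
  ## --- dominance stage ----------------------------------------------------
  dom <- lapply(stats::setNames(.PHASES, .PHASES), function(ph)
    rank_phase(events, ph, eligible, max_path_len = config$max_path_len))
  rc <- rank_correlation(dom$baseline, dom$experimental)
  higher_ranked <- list()
  for (beh in c("aggression", "displacement")) {
    for (ph in .PHASES) {
      hr_in <- pct_from_higher_ranked(events, beh, ph, focal_id,
                                      dom[[ph]]$ordinal_rank,
                                      role = "recipient")
      hr_out <- pct_from_higher_ranked(events, beh, ph, focal_id,
                                       dom[[ph]]$ordinal_rank,
                                       role = "actor")
      higher_ranked[[paste(beh, ph, sep = ".")]] <-
        list(received = hr_in, given = hr_out)
    }
  }
  ## group mean change in % received from higher-ranked, per agonistic layer
  hr_change <- lapply(stats::setNames(c("aggression", "displacement"),
                                      c("aggression", "displacement")),
                      function(beh) {
    bl <- higher_ranked[[paste(beh, "baseline", sep = ".")]]$received$by_id
    ex <- higher_ranked[[paste(beh, "experimental", sep = ".")]]$received$by_id
    both <- !is.na(bl$pct_higher) & !is.na(ex$pct_higher)
    delta <- ex$pct_higher[both] - bl$pct_higher[both]
    fb <- bl$pct_higher[bl$id == focal_id]
    fe <- ex$pct_higher[ex$id == focal_id]
    list(group_mean_change = if (length(delta)) mean(delta) else NA_real_,
         focal_change = if (!is.na(fb) && !is.na(fe)) fe - fb else NA_real_,
         focal_baseline = fb, focal_experimental = fe)
  })
  ## --- partner_composition stage ------------------------------------------
  table2 <- kin_table(events, focal_id, ros)
  report <- structure(list(
    table1 = table1,
    strength_stats = strength_stats,
    centrality = all_cent,
    balances = balances,
    ranks = list(baseline = dom$baseline, experimental = dom$experimental,
                 rank_correlation = rc),
    higher_ranked = higher_ranked,
    higher_ranked_change = hr_change,
    table2 = table2,
    focal_id = focal_id,
    eligible_ids = eligible,
    exclusions = list(animals_excluded = n_excluded,
                      events_dropped = dropped_events,
                      events_rejected = nrow(attr(events, "rejected") %||%
                                               data.frame())),
    networks = nets,
    seed = config$seed,
    p_mode = config$p_mode,
    max_path_len = config$max_path_len
  ), class = "study_report")
  if (!is.null(config$out_dir))
    write_report(report, config$out_dir, write_plots = config$write_plots)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> focal %s, %d eligible individuals\n",
              x$focal_id, length(x$eligible_ids)))
  cat("\nChange in degree centrality (experimental - baseline):\n")
  print(render_table1(x), row.names = FALSE)
  cat(sprintf("\nGrooming balance z (focal incl.): baseline %.2f, experimental %.2f\n",
              x$balances$baseline$stat$z, x$balances$experimental$stat$z))
  cat(sprintf("Rank correlation baseline vs experimental: %.2f\n",
              x$ranks$rank_correlation))
  invisible(x)
}

#' Render the main change table
#'
#' Formats the degree-centrality change statistics in the layout of the
#' study's main table: network type, network, mean change, s.d., provider's
#' change, Z-score, two-tailed p-value, all rounded to 2 decimal places.
#'
#' @param report a `"study_report"` (or any data.frame shaped like its
#'   `table1` element).
#' @return data.frame with character/numeric columns ready for printing or
#'   `write.csv`.
#' @export
render_table1 <- function(report) {
  t1 <- if (inherits(report, "study_report")) report$table1 else report
  pretty_type <- c(undirected = "undirected", directed_in = "directed (in)",
                   directed_out = "directed (out)")
  pretty_net <- c(aggression = "aggression", displacement = "displacement",
                  grooming = "grooming", peaceful_sbt = "SBT",
                  huddling = "huddling", proximity = "proximity")
  data.frame(network_type = pretty_type[t1$network_type],
             network = pretty_net[t1$behaviour],
             mean_change = .round_half_up(t1$mean_change, 2),
             sd = .round_half_up(t1$sd_change, 2),
             provider_change = t1$focal_change,
             z = .round_half_up(t1$z, 2),
             p = .round_half_up(t1$p_two_tailed, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write all study outputs to a directory
#'
#' Writes `centrality.csv`, `change_stats.csv` (degree and strength rows),
#' `table1.csv` (rendered), `balances.csv`, `ranks.csv`, per-phase
#' dominance-probability matrices, `partners.csv`, per-network edge lists
#' and GraphML files, and a machine-readable `report.json`.
#'
#' @param report a `"study_report"`.
#' @param dir output directory (created if needed).
#' @param write_plots also write change-distribution density plots (PNG).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir, write_plots = FALSE) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$centrality, file.path(dir, "centrality.csv"),
                   row.names = FALSE)
  chg <- rbind(report$table1, report$strength_stats)
  utils::write.csv(chg, file.path(dir, "change_stats.csv"), row.names = FALSE)
  utils::write.csv(render_table1(report), file.path(dir, "table1.csv"),
                   row.names = FALSE)
  bal <- do.call(rbind, lapply(report$balances, function(b) b$balances))
  utils::write.csv(bal, file.path(dir, "balances.csv"), row.names = FALSE)
  rk <- do.call(rbind, lapply(.PHASES, function(ph) {
    d <- report$ranks[[ph]]
    data.frame(id = names(d$ordinal_rank), phase = ph,
               ordinal_rank = as.integer(d$ordinal_rank),
               mean_dominance_prob = as.numeric(d$mean_prob),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rk, file.path(dir, "ranks.csv"), row.names = FALSE)
  for (ph in .PHASES)
    utils::write.csv(report$ranks[[ph]]$dominance_prob,
                     file.path(dir, paste0("dominance_prob_", ph, ".csv")))
  utils::write.csv(report$table2, file.path(dir, "partners.csv"),
                   row.names = FALSE)
  netdir <- file.path(dir, "networks")
  dir.create(netdir, showWarnings = FALSE)
  for (ph in .PHASES)
    for (beh in .BEHAVIOURS) {
      nw <- report$networks[[ph]][[beh]]
      write_edgelist(nw, file.path(netdir, sprintf("%s_%s.csv", beh, ph)))
      write_graphml(nw, file.path(netdir, sprintf("%s_%s.graphml", beh, ph)))
    }
  if (write_plots) {
    pdir <- file.path(dir, "figures")
    dir.create(pdir, showWarnings = FALSE)
    cent <- report$centrality
    for (i in seq_len(nrow(.TABLE1_ROWS))) {
      beh <- .TABLE1_ROWS$behaviour[i]
      metric <- .TABLE1_ROWS$metric_degree[i]
      ch <- change_scores(cent[cent$behaviour == beh &
                                 cent$phase == "baseline", ],
                          cent[cent$behaviour == beh &
                                 cent$phase == "experimental", ], metric)
      f <- file.path(pdir, sprintf("change_%s_%s.png", beh, metric))
      grDevices::png(f, width = 600, height = 450)
      plot_change_density(ch, ch[[report$focal_id]],
                          main = sprintf("%s (%s)", beh, metric))
      grDevices::dev.off()
    }
  }
  ## machine-readable summary (CSV-sized pieces only; networks live in files)
  j <- list(
    focal_id = report$focal_id,
    n_eligible = length(report$eligible_ids),
    exclusions = report$exclusions,
    table1 = report$table1,
    strength_stats = report$strength_stats,
    grooming_balance = lapply(report$balances, function(b)
      list(focal_balance = b$stat$focal_change,
           group_mean = b$stat$mean_change, group_sd = b$stat$sd_change,
           z_focal_included = b$stat$z, z_focal_excluded = b$stat_excl$z,
           p_one_tailed_included = b$stat$p_one_tailed,
           p_one_tailed_excluded = b$stat_excl$p_one_tailed)),
    rank_correlation = report$ranks$rank_correlation,
    focal_rank = lapply(report$ranks[.PHASES], function(d)
      as.integer(d$ordinal_rank[[report$focal_id]])),
    higher_ranked_change = report$higher_ranked_change,
    table2 = report$table2,
    seed = report$seed,
    p_mode = report$p_mode,
    max_path_len = report$max_path_len
  )
  jsonlite::write_json(j, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows",
                       pretty = TRUE, null = "null")
  invisible(dir)
}
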