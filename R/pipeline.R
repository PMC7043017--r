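# Study pipeline: from one configuration file, score every recording,
# compute hypnogram metrics at the study timepoints, classify coping
# phenotype from defeat latencies, and run the group statistics.

TIMEPOINTS <- c("baseline", "day1", "day4", "day7", "twoweeks")

#' Load and validate a study configuration
#'
#' The configuration is a YAML file listing, per animal, its group
#' (`control` or `defeated`) and one recording file per timepoint
#' (`baseline` may list several files, which are averaged), plus the
#' analysis windows, scoring-threshold overrides, classifier and
#' statistics settings, and an optional defeat-latency CSV. Relative
#' paths are resolved against the configuration file's directory. Every
#' referenced file must exist.
#'
#' @param path Path to the YAML configuration.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  cfg$config_path <- normalizePath(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$lights_on <- cfg$lights_on %||% "07:00"
  cfg$lights_off <- cfg$lights_off %||% "19:00"
  w <- cfg$windows %||% list()
  cfg$windows <- list(light = unlist(w$light) %||% c("10:00", "19:00"),
                      dark = unlist(w$dark) %||% c("19:00", "06:00"),
                      event = unlist(w$event) %||% c("10:00", "16:00"))
  for (win in cfg$windows) {
    parse_tod(win)
    if (length(win) != 2) stop("each window needs a start and an end")
  }
  cfg$classifier <- utils::modifyList(list(n_boot = 1000,
                                           band = c(0.1, 0.9)),
                                      cfg$classifier %||% list())
  cfg$stats <- utils::modifyList(list(gg_correction = TRUE),
                                 cfg$stats %||% list())
  cfg$thresholds <- cfg$thresholds %||% list()
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  if (!is.null(cfg$latencies)) {
    cfg$latencies <- resolve(cfg$latencies)
    if (!file.exists(cfg$latencies))
      stop("latency file not found: ", cfg$latencies)
  }
  if (is.null(cfg$animals) || !length(cfg$animals))
    stop("config must list at least one animal")
  for (i in seq_along(cfg$animals)) {
    a <- cfg$animals[[i]]
    if (is.null(a$id) || is.null(a$group) ||
        !a$group %in% c("control", "defeated"))
      stop("each animal needs an id and a group (control/defeated)")
    if (!all(names(a$recordings) %in% TIMEPOINTS))
      stop("animal ", a$id, ": timepoints must be among ",
           paste(TIMEPOINTS, collapse = ", "))
    for (tp in names(a$recordings)) {
      files <- resolve(unlist(a$recordings[[tp]]))
      missing <- files[!file.exists(files)]
      if (length(missing))
        stop("animal ", a$id, " ", tp, ": file not found: ", missing[1])
      cfg$animals[[i]]$recordings[[tp]] <- files
    }
  }
  structure(cfg, class = "study_config")
}

# Metrics for one scored recording: state percentages in the light and
# dark windows, awakenings + exaggerated responses and REM episodes in
# the event window.
.animal_day_metrics <- function(rec, hyp, windows) {
  pct <- lapply(windows[c("light", "dark")], function(w)
    state_percentages(hyp, w))
  ev <- detect_awakenings(hyp, windows$event)
  ev <- classify_exaggerated(ev, rec)
  epi <- segment_rem_episodes(hyp, windows$event)
  list(pct = pct, events = ev, episodes = epi,
       awakening_counts = c(total = nrow(ev),
                            exaggerated = sum(ev$exaggerated),
                            exaggerated_from_sws =
                              sum(ev$exaggerated & ev$prior_stage == "S"),
                            exaggerated_from_rem =
                              sum(ev$exaggerated & ev$prior_stage == "P")),
       sin_seq = count_sin_seq(epi))
}

#' Run the full study pipeline
#'
#' For every animal and timepoint: reads the recording, calibrates the
#' staging thresholds, scores the hypnogram, and computes state-time
#' percentages (light and dark windows), awakenings with exaggerated
#' motor responses (event window) and REM-episode counts (event
#' window). Baseline metrics are averaged over the baseline recordings
#' and subtracted to give change-from-baseline values. Defeated animals
#' are classified into active/passive copers from the latency table
#' when at least four defeated animals have latencies. Group statistics
#' (mixed ANOVA plus Tukey HSD) are run per outcome when every group
#' retains at least two animals.
#'
#' Output TSVs are written atomically at the end of the run, so a
#' failing stage (reported with the offending animal and timepoint)
#' leaves no partial outputs. Reruns with the same configuration and
#' seed are byte-identical.
#'
#' @param config Path to a YAML configuration, or a `study_config`.
#' @param outdir Output directory (default: `output_dir` from the
#'   configuration, resolved against its directory).
#' @return Invisibly, the list of output file paths.
#' @export
run_study <- function(config, outdir = NULL) {
  cfg <- if (inherits(config, "study_config")) config
         else study_config(config)
  outdir <- outdir %||%
    file.path(dirname(cfg$config_path), cfg$output_dir %||% "somnotype_out")
  ids <- vapply(cfg$animals, `[[`, "", "id")
  groups <- vapply(cfg$animals, `[[`, "", "group")

  # --- coping classification -------------------------------------------
  coping <- data.frame(animal_id = character(), mean_latency_s = numeric(),
                       active_probability = numeric(), label = character())
  final_group <- stats::setNames(groups, ids)
  if (!is.null(cfg$latencies)) {
    lat <- read_latency_table(cfg$latencies)
    defeated <- ids[groups == "defeated"]
    lat <- lat[lat$animal_id %in% defeated, ]
    if (length(unique(lat$animal_id)) >= 4) {
      means <- mean_latencies(lat)
      coping <- bootstrap_classify(means, n_boot = cfg$classifier$n_boot,
                                   seed = cfg$seed,
                                   band = cfg$classifier$band)
      final_group[coping$animal_id] <- coping$label
    } else {
      message("fewer than 4 defeated animals with latencies; ",
              "coping classification skipped")
    }
  }

  # --- per-animal per-timepoint metrics --------------------------------
  state_rows <- list(); event_rows <- list(); episode_rows <- list()
  count_rows <- list()
  for (i in seq_along(cfg$animals)) {
    a <- cfg$animals[[i]]
    per_tp <- list()
    for (tp in names(a$recordings)) {
      files <- a$recordings[[tp]]
      reps <- lapply(seq_along(files), function(k) {
        tryCatch({
          rec <- read_recording(files[k], animal_id = a$id,
                                lights_on = cfg$lights_on,
                                lights_off = cfg$lights_off)
          th <- calibrate_thresholds(rec, overrides = cfg$thresholds)
          hyp <- score_recording(rec, th)
          m <- .animal_day_metrics(rec, hyp, cfg$windows)
          m$recording_id <- paste0(tp, if (length(files) > 1) k else "")
          m
        }, error = function(e)
          stop("animal ", a$id, " ", tp, ": ", conditionMessage(e),
               call. = FALSE))
      })
      per_tp[[tp]] <- reps
      for (m in reps) {
        if (nrow(m$events)) {
          ev <- m$events
          ev$animal_id <- a$id; ev$timepoint <- tp
          ev$recording_id <- m$recording_id
          ev$transition_clock <- format_clock(ev$transition_clock)
          event_rows[[length(event_rows) + 1]] <- ev
        }
        if (nrow(m$episodes)) {
          ep <- m$episodes
          ep$animal_id <- a$id; ep$timepoint <- tp
          ep$recording_id <- m$recording_id
          ep$start_clock <- format_clock(ep$start_clock)
          ep$end_clock <- format_clock(ep$end_clock)
          episode_rows[[length(episode_rows) + 1]] <- ep
        }
      }
    }
    if (!"baseline" %in% names(per_tp))
      stop("animal ", a$id, ": baseline recordings are required")
    avg_tp <- function(reps, what)
      Reduce(`+`, lapply(reps, `[[`, what)) / length(reps)
    base_pct <- list(
      light = rowMeans(sapply(per_tp$baseline, function(m) m$pct$light)),
      dark = rowMeans(sapply(per_tp$baseline, function(m) m$pct$dark)))
    for (tp in names(per_tp)) {
      reps <- per_tp[[tp]]
      for (period in c("light", "dark")) {
        pct <- rowMeans(sapply(reps, function(m) m$pct[[period]]))
        state_rows[[length(state_rows) + 1]] <- data.frame(
          animal_id = a$id, group = unname(final_group[a$id]),
          timepoint = tp, period = period,
          pct_wake = pct["pct_wake"], pct_sws = pct["pct_sws"],
          pct_rem = pct["pct_rem"],
          d_wake = change_from_baseline(pct["pct_wake"],
                                        base_pct[[period]]["pct_wake"]),
          d_sws = change_from_baseline(pct["pct_sws"],
                                       base_pct[[period]]["pct_sws"]),
          d_rem = change_from_baseline(pct["pct_rem"],
                                       base_pct[[period]]["pct_rem"]),
          row.names = NULL)
      }
      cnt <- avg_tp(reps, "awakening_counts")
      ss <- avg_tp(reps, "sin_seq")
      count_rows[[length(count_rows) + 1]] <- data.frame(
        animal_id = a$id, group = unname(final_group[a$id]),
        timepoint = tp, t(cnt), t(ss), row.names = NULL)
    }
  }
  state_time <- do.call(rbind, state_rows)
  counts <- do.call(rbind, count_rows)
  awakenings <- if (length(event_rows)) do.call(rbind, event_rows) else
    data.frame()
  rem_episodes <- if (length(episode_rows)) do.call(rbind, episode_rows)
    else data.frame()

  # --- group statistics ------------------------------------------------
  keep <- state_time$group %in% c("control", "passive", "active",
                                  "defeated") &
    state_time$timepoint != "baseline"
  anova_rows <- list(); tukey_rows <- list()
  outcomes <- list(
    d_wake_light = function() subset(state_time, keep &
                                       state_time$period == "light",
                                     c(animal_id, group, timepoint, d_wake)),
    d_sws_light = function() subset(state_time, keep &
                                      state_time$period == "light",
                                    c(animal_id, group, timepoint, d_sws)),
    d_rem_light = function() subset(state_time, keep &
                                      state_time$period == "light",
                                    c(animal_id, group, timepoint, d_rem)),
    total_awakenings = function()
      counts[counts$timepoint != "baseline",
             c("animal_id", "group", "timepoint", "total")],
    exaggerated = function()
      counts[counts$timepoint != "baseline",
             c("animal_id", "group", "timepoint", "exaggerated")],
    n_sin = function() counts[counts$timepoint != "baseline",
                              c("animal_id", "group", "timepoint", "n_sin")],
    n_seq = function() counts[counts$timepoint != "baseline",
                              c("animal_id", "group", "timepoint", "n_seq")])
  for (oc in names(outcomes)) {
    d <- outcomes[[oc]]()
    names(d)[4] <- "value"
    d <- d[d$group != "excluded", ]
    gsz <- table(unique(d[c("animal_id", "group")])$group)
    if (length(gsz) >= 2 && all(gsz >= 2) &&
        length(unique(d$timepoint)) >= 2) {
      an <- mixed_anova(d, gg = isTRUE(cfg$stats$gg_correction))
      at <- an$table; at$outcome <- oc
      anova_rows[[length(anova_rows) + 1]] <- at
      for (tp in unique(d$timepoint)) {
        dd <- d[d$timepoint == tp, ]
        tk <- tukey_hsd(dd$value, dd$group)
        tk$outcome <- oc; tk$timepoint <- tp
        tukey_rows[[length(tukey_rows) + 1]] <- tk
      }
    }
  }
  anova_tab <- if (length(anova_rows)) do.call(rbind, anova_rows) else
    data.frame(effect = character(), ss = numeric(), df_num = numeric(),
               df_den = numeric(), F = numeric(), epsilon = numeric(),
               p = numeric(), outcome = character())
  tukey_tab <- if (length(tukey_rows)) do.call(rbind, tukey_rows) else
    data.frame(group1 = character(), group2 = character(),
               diff = numeric(), q = numeric(), p_adj = numeric(),
               outcome = character(), timepoint = character())

  # --- write outputs (atomically, at the end) --------------------------
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  out <- c(
    state_time = wt(state_time, "state_time.tsv"),
    awakenings = wt(awakenings, "awakenings.tsv"),
    awakening_counts = wt(counts, "awakening_counts.tsv"),
    rem_episodes = wt(rem_episodes, "rem_episodes.tsv"),
    coping = wt(coping, "coping.tsv"),
    anova = wt(anova_tab, "anova.tsv"),
    tukey = wt(tukey_tab, "tukey.tsv"))
  manifest <- data.frame(
    key = c("config_hash", "seed", "n_animals", "somnotype_version"),
    value = c(unname(tools::md5sum(cfg$config_path)), cfg$seed,
              length(cfg$animals),
              as.character(utils::packageVersion("somnotype"))))
  out <- c(out, manifest = wt(manifest, "manifest.tsv"))
  invisible(out)
}

#' Write a synthetic study to disk
#'
#' Generates a complete synthetic study - per-animal EDF recordings for
#' every timepoint, a bimodal defeat-latency CSV for the defeated
#' animals, and a pipeline configuration YAML - so the full pipeline
#' can be exercised end to end with known ground truth.
#'
#' @param dir Directory to create the study in.
#' @param n_control,n_passive,n_active Animals per generating group
#'   (defeated = passive + active).
#' @param duration_h Hours per recording.
#' @param fs Sampling rate for EEG and EMG in Hz.
#' @param start_clock Clock time at which each recording starts.
#' @param windows Named list of `light`, `dark`, `event` analysis
#'   windows, matched to the recording span.
#' @param seed Integer seed.
#' @return Path to the written configuration YAML.
#' @export
write_synthetic_study <- function(dir, n_control = 1, n_passive = 3,
                                  n_active = 2, duration_h = 3,
                                  fs = 100,
                                  start_clock = "2024-03-01 17:00:00",
                                  windows = list(light = c("17:00", "19:00"),
                                                 dark = c("19:00", "20:00"),
                                                 event = c("17:00", "20:00")),
                                  seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_def <- n_passive + n_active
  ids <- sprintf("rat%02d", seq_len(n_control + n_def))
  groups <- rep(c("control", "defeated"), c(n_control, n_def))
  tps <- c("baseline", "day1", "day4", "day7", "twoweeks")
  animals <- list()
  k <- 0L
  for (i in seq_along(ids)) {
    recs <- list()
    for (tp in tps) {
      k <- k + 1L
      cfg_i <- sim_config(seed = seed * 1000L + k, duration_h = duration_h,
                          fs_eeg = fs, fs_emg = fs,
                          start_clock = start_clock, animal_id = ids[i])
      sim <- simulate_recording(cfg_i)
      f <- sprintf("%s_%s.edf", ids[i], tp)
      write_recording(sim$recording, file.path(dir, f))
      recs[[tp]] <- f
    }
    animals[[i]] <- list(id = ids[i], group = groups[i],
                         recordings = recs)
  }
  lat <- simulate_latencies(n_passive = n_passive, n_active = n_active,
                            seed = seed)
  lat$animal_id <- rep(ids[groups == "defeated"], each = 7)
  utils::write.csv(lat[c("animal_id", "day", "latency_s")],
                   file.path(dir, "latencies.csv"), row.names = FALSE)
  cfg <- list(seed = seed, output_dir = "out",
              windows = lapply(windows, as.list),
              classifier = list(n_boot = 500),
              latencies = "latencies.csv",
              animals = animals)
  cfg_path <- file.path(dir, "study.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
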