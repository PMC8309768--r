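#' Fish-level behavioral endpoint table for a set of group recordings
#'
#' Applies the tracking-accuracy gate, then computes the three social and
#' four activity endpoints for every fish of every passing tank.
#'
#' @param groups List of [group_recording()] objects.
#' @param prox_cfg A [proximity_config()].
#' @param act_cfg An [activity_config()].
#' @param qc_threshold Minimum per-fish detection fraction (default 0.80);
#'   tanks failing the gate are dropped with a message.
#' @return A fish-level [endpoint_table()]; the ids of excluded tanks are in
#'   attribute `"excluded_tanks"`.
#' @export
behavior_endpoints <- function(groups, prox_cfg = proximity_config(),
                               act_cfg = activity_config(),
                               qc_threshold = 0.80) {
  excluded <- character(0)
  rows <- list()
  for (g in groups) {
    qc <- qc_tracking_accuracy(g, qc_threshold)
    if (!qc$tank_pass) {
      message(sprintf("behavior_endpoints: tank %s excluded by QC (fish: %s)",
                      as.character(g$tank_id),
                      paste(qc$failing_fish, collapse = ", ")))
      excluded <- c(excluded, as.character(g$tank_id))
      next
    }
    iid <- interindividual_distance(g)
    tip <- time_in_proximity(g, prox_cfg)
    nnd <- nearest_neighbor_distance(g)
    act <- lapply(g$trajectories, function(tr) {
      ex <- exploration_area(tr, g$calibration, act_cfg)
      c(dist = distance_traveled(tr, g$calibration),
        speed = swim_speed(tr, g$calibration),
        motion = time_in_motion(tr, g$calibration, act_cfg),
        expl_mm2 = ex$area_mm2, expl_pct = ex$percent)
    })
    act <- do.call(rbind, act)
    rows[[length(rows) + 1L]] <- data.frame(
      site = as.character(g$site), tank_id = as.character(g$tank_id),
      fish_id = names(g$trajectories),
      interindividual_distance_mm = unname(iid),
      time_in_proximity_s = as.numeric(tip),
      proximity_fraction_ratio = attr(tip, "fraction"),
      nearest_neighbor_distance_mm = unname(nnd),
      distance_traveled_mm = unname(act[, "dist"]),
      swim_speed_mm_s = unname(act[, "speed"]),
      time_in_motion_s = unname(act[, "motion"]),
      exploration_mm2 = unname(act[, "expl_mm2"]),
      exploration_pct = unname(act[, "expl_pct"]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("behavior_endpoints: no tank passed QC", call. = FALSE)
  out <- endpoint_table(do.call(rbind, rows), level = "fish")
  attr(out, "excluded_tanks") <- excluded
  out
}

#' The seven behavioral endpoints compared between sites
#' @noRd
behavioral_endpoint_names <- function() {
  c("interindividual_distance_mm", "time_in_proximity_s",
    "nearest_neighbor_distance_mm", "distance_traveled_mm",
    "swim_speed_mm_s", "time_in_motion_s", "exploration_pct")
}

#' Welch tests of tank-mean endpoints between two sites
#'
#' @param tank_table A tank-level [endpoint_table()] with exactly two sites.
#' @param endpoints Endpoint columns to test (default: the seven behavioral
#'   endpoints).
#' @return Data frame: endpoint, per-site means/SEMs/n, t, Welch df, p,
#'   direction.
#' @export
site_welch_tests <- function(tank_table,
                             endpoints = behavioral_endpoint_names()) {
  stopifnot(inherits(tank_table, "endpoint_table"))
  sites <- sort(unique(tank_table$site))
  if (length(sites) != 2L) {
    stop("site_welch_tests: exactly two sites required", call. = FALSE)
  }
  a <- tank_table[tank_table$site == sites[1L], , drop = FALSE]
  b <- tank_table[tank_table$site == sites[2L], , drop = FALSE]
  rows <- lapply(endpoints, function(ep) {
    res <- welch_t(a[[ep]], b[[ep]], sites[1L], sites[2L])
    sem <- function(v) sd(v) / sqrt(length(v))
    data.frame(endpoint = ep,
               mean_site1 = mean(a[[ep]]), sem_site1 = sem(a[[ep]]),
               mean_site2 = mean(b[[ep]]), sem_site2 = sem(b[[ep]]),
               n_site1 = nrow(a), n_site2 = nrow(b),
               t = res$statistic, df_welch = res$df, p = res$p_value,
               direction = res$effect_direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Morphometric endpoint table
#'
#' Standard length, region areas, and their ratio per specimen, on the
#' original mm-scale landmarks.
#'
#' @param sets List of [landmark_set()] objects.
#' @return Data frame with one row per specimen.
#' @export
morphometric_endpoints <- function(sets) {
  rows <- lapply(sets, function(s) {
    ra <- region_areas(s)
    data.frame(fish_id = as.character(s$fish_id),
               site = as.character(s$site), sex = s$sex,
               standard_length_mm = standard_length(s),
               anterior_mm2 = ra$anterior_mm2,
               posterior_mm2 = ra$posterior_mm2,
               area_ratio = ra$ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run configuration
#'
#' Validates and normalizes the configuration of a pipeline run before any
#' computation happens.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param preset For synthetic mode: `"reference"`, `"identical_sites"`, or
#'   a `study_preset` object.
#' @param trajectory_files,tps_file,tps_metadata For real mode: paths to the
#'   per-tank trajectory tables (named `site:tank`), the TPS landmark file,
#'   and its sidecar metadata table.
#' @param dialect Trajectory dialect for real mode.
#' @param calibration A [calibration_info()] (real mode).
#' @param prox_cfg,act_cfg Metric configurations.
#' @param qc_threshold Tracking-accuracy gate (default 0.80).
#' @param manova_min_variance Shape variance retained in the MANOVA response
#'   (default 0.99).
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   writing.
#' @param seed Integer seed.
#' @param make_plots Write composite figures (default `FALSE`).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"), preset = "reference",
                       trajectory_files = NULL, tps_file = NULL,
                       tps_metadata = NULL, dialect = "generic-csv",
                       calibration = NULL,
                       prox_cfg = proximity_config(),
                       act_cfg = activity_config(), qc_threshold = 0.80,
                       manova_min_variance = 0.99,
                       out_dir = NULL, seed = 1L, make_plots = FALSE) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    if (is.character(preset)) {
      preset <- switch(preset,
        reference = reference_study_preset(),
        identical_sites = identical_sites_preset(),
        stop("run_config: unknown preset '", preset, "'", call. = FALSE))
    }
    if (!inherits(preset, "study_preset")) {
      stop("run_config: preset must be a study_preset or a known preset name",
           call. = FALSE)
    }
  } else {
    if (is.null(trajectory_files) && is.null(tps_file)) {
      stop("run_config: real mode needs trajectory_files and/or tps_file",
           call. = FALSE)
    }
    missing_files <- c(trajectory_files, tps_file)
    missing_files <- missing_files[!file.exists(missing_files)]
    if (length(missing_files)) {
      stop("run_config: missing input file(s): ",
           paste(missing_files, collapse = ", "), call. = FALSE)
    }
    if (!is.null(trajectory_files) && is.null(calibration)) {
      stop("run_config: real trajectories need a calibration_info",
           call. = FALSE)
    }
    if (!is.null(tps_file) && is.null(tps_metadata)) {
      stop("run_config: TPS input needs a sidecar metadata table ",
           "(id, site, sex); the TPS format carries neither", call. = FALSE)
    }
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("run_config: seed must be a single integer", call. = FALSE)
  }
  structure(list(mode = mode, preset = preset,
                 trajectory_files = trajectory_files, tps_file = tps_file,
                 tps_metadata = tps_metadata, dialect = dialect,
                 calibration = calibration, prox_cfg = prox_cfg,
                 act_cfg = act_cfg, qc_threshold = qc_threshold,
                 manova_min_variance = manova_min_variance,
                 out_dir = out_dir, seed = as.integer(seed),
                 make_plots = make_plots),
            class = "run_config")
}

#' Read a run configuration from a YAML document
#'
#' A thin front end to [run_config()]: top-level keys mirror its arguments;
#' `proximity` and `activity` sub-maps are passed to [proximity_config()]
#' and [activity_config()]; `calibration` to [calibration_info()].
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("mode", "preset", "trajectory_files", "tps_file",
                        "tps_metadata", "dialect", "qc_threshold",
                        "manova_min_variance", "out_dir", "seed",
                        "make_plots"))]
  if (!is.null(y$proximity)) args$prox_cfg <- do.call(proximity_config, y$proximity)
  if (!is.null(y$activity)) args$act_cfg <- do.call(activity_config, y$activity)
  if (!is.null(y$calibration)) args$calibration <- do.call(calibration_info, y$calibration)
  do.call(run_config, args)
}

config_hash <- function(config) {
  # the hash covers everything that determines the numbers; the output
  # location does not
  hashed <- config
  hashed$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(serialize_config(hashed), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

serialize_config <- function(x) {
  if (is.list(x)) {
    out <- lapply(unclass(x), serialize_config)
    if (!is.null(class(x)) && class(x)[1L] != "list") {
      out <- c(list(.class = class(x)[1L]), out)
    }
    out
  } else if (is.matrix(x)) {
    apply(x, 1L, as.numeric, simplify = FALSE)
  } else x
}

load_study_inputs <- function(config) {
  if (config$mode == "synthetic") {
    study <- simulate_study(config$preset, config$seed)
    list(groups = study$groups, landmarks = study$landmarks,
         truth = study$truth)
  } else {
    groups <- NULL
    if (!is.null(config$trajectory_files)) {
      groups <- lapply(seq_along(config$trajectory_files), function(i) {
        nm <- names(config$trajectory_files)[i]
        parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
        read_trajectory_table(config$trajectory_files[[i]], config$dialect,
                              config$calibration,
                              site = parts[1L],
                              tank_id = parts[min(2L, length(parts))])
      })
    }
    landmarks <- NULL
    if (!is.null(config$tps_file)) {
      landmarks <- read_tps(config$tps_file, metadata = config$tps_metadata)
    }
    list(groups = groups, landmarks = landmarks, truth = NULL)
  }
}

out_path <- function(config, name) {
  if (is.null(config$out_dir)) return(NULL)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$out_dir, name)
}

#' Run the behavioral branch of the pipeline
#'
#' Simulates or reads the group recordings, computes fish-level endpoints,
#' collapses them to tank means, and runs the Welch site comparisons on the
#' seven behavioral endpoints. Tables and a JSON report are written when the
#' configuration names an output directory.
#'
#' @param config A [run_config()].
#' @return List with `fish_table`, `tank_table`, `tests`, `excluded_tanks`,
#'   and `provenance`.
#' @export
run_behavior <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_study_inputs(config)
  if (is.null(inputs$groups)) {
    stop("run_behavior: no trajectory inputs in this configuration",
         call. = FALSE)
  }
  fish <- behavior_endpoints(inputs$groups, config$prox_cfg, config$act_cfg,
                             config$qc_threshold)
  tanks <- collapse_to_tank_means(fish)
  tests <- site_welch_tests(tanks)
  prov <- provenance(config)
  if (!is.null(config$out_dir)) {
    write_endpoint_table(fish, out_path(config, "endpoints_fish.tsv"))
    write_endpoint_table(tanks, out_path(config, "endpoints_tank.tsv"))
    write.table(tests, out_path(config, "behavior_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report <- list(provenance = prov, excluded_tanks = attr(fish, "excluded_tanks"),
                   tests = tests)
    jsonlite::write_json(report, out_path(config, "behavior_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (config$make_plots) plot_behavior(tanks, out_path(config, "behavior_boxplots.png"))
  }
  list(fish_table = fish, tank_table = tanks, tests = tests,
       excluded_tanks = attr(fish, "excluded_tanks"), provenance = prov)
}

#' Run the morphometric branch of the pipeline
#'
#' GPA and shape PCA over all specimens, per-group consensus shapes, the
#' specimen-level size endpoints, and the four morphometric tests: MANOVA on
#' retained shape PCs, two-way ANOVA + Tukey on the area ratio, paired
#' Wilcoxon of posterior vs anterior area, and Kruskal-Wallis on standard
#' length across the site x sex groups.
#'
#' @param config A [run_config()].
#' @return List with `shape` (a `shape_analysis`), `consensus_by_group`,
#'   `endpoints` (specimen table), `manova`, `anova_tukey`, `wilcoxon`,
#'   `kruskal`, and `provenance`.
#' @export
run_morphometrics <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_study_inputs(config)
  if (is.null(inputs$landmarks)) {
    stop("run_morphometrics: no landmark inputs in this configuration",
         call. = FALSE)
  }
  sets <- inputs$landmarks
  if (length(sets) < 3L) {
    stop("run_morphometrics: need at least 3 specimens", call. = FALSE)
  }
  shape <- shape_pca(gpa_align(sets))
  cons <- consensus_by_group(shape)
  endpoints <- morphometric_endpoints(sets)
  scores <- manova_scores(shape, config$manova_min_variance)
  man <- shape_manova(scores, shape$info$site, shape$info$sex)
  at <- ratio_anova_tukey(endpoints$area_ratio, endpoints$site, endpoints$sex)
  wil <- paired_wilcoxon(endpoints$posterior_mm2, endpoints$anterior_mm2)
  kw <- kruskal_wallis(endpoints$standard_length_mm,
                       paste(endpoints$site, endpoints$sex, sep = ":"))
  prov <- provenance(config)
  if (!is.null(config$out_dir)) {
    write.table(endpoints, out_path(config, "morpho_endpoints.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    n <- dim(shape$aligned)[1L]
    aligned_flat <- data.frame(fish_id = shape$info$fish_id,
                               matrix(shape$aligned, nrow = n))
    write.table(aligned_flat, out_path(config, "aligned_coordinates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(fish_id = shape$info$fish_id, shape$pc_scores),
                out_path(config, "pc_scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (g in names(cons)) {
      write.table(data.frame(landmark = rownames(cons[[g]]), cons[[g]]),
                  out_path(config, paste0("consensus_",
                                          gsub("[^a-z0-9]", "_", g), ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report <- list(
      provenance = prov,
      variance_explained = shape$variance_explained,
      pc12_variance_pct = 100 * sum(shape$variance_explained[1:2]),
      manova = lapply(man, unclass),
      anova = lapply(at$anova, unclass), tukey = at$tukey,
      wilcoxon = unclass(wil), kruskal = unclass(kw))
    jsonlite::write_json(report, out_path(config, "morpho_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (config$make_plots) {
      plot_consensus_overlay(cons, out_path(config, "consensus_overlay.png"))
      plot_ratio_boxplot(endpoints, out_path(config, "ratio_boxplot.png"))
    }
  }
  list(shape = shape, consensus_by_group = cons, endpoints = endpoints,
       manova = man, anova_tukey = at, wilcoxon = wil, kruskal = kw,
       provenance = prov)
}

#' Run the full pipeline
#'
#' Both branches plus one combined JSON report carrying provenance (config
#' hash, seed, package version) and every test result.
#'
#' @param config A [run_config()].
#' @return List with `behavior`, `morphometrics`, and `provenance`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  behavior <- run_behavior(config)
  morpho <- run_morphometrics(config)
  prov <- provenance(config)
  if (!is.null(config$out_dir)) {
    report <- list(
      provenance = prov,
      behavior_tests = behavior$tests,
      excluded_tanks = behavior$excluded_tanks,
      morphometrics = list(
        pc12_variance_pct = 100 * sum(morpho$shape$variance_explained[1:2]),
        manova = lapply(morpho$manova, unclass),
        anova = lapply(morpho$anova_tukey$anova, unclass),
        tukey = morpho$anova_tukey$tukey,
        wilcoxon = unclass(morpho$wilcoxon),
        kruskal = unclass(morpho$kruskal)))
    jsonlite::write_json(report, out_path(config, "study_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(behavior = behavior, morphometrics = morpho, provenance = prov)
}

provenance <- function(config) {
  list(package = "shoalmorph",
       version = as.character(utils::packageVersion("shoalmorph")),
       config_hash = config_hash(config),
       seed = config$seed,
       mode = config$mode,
       qc_threshold = config$qc_threshold,
       proximity_threshold_px = if (config$prox_cfg$use_mm) NA else
         config$prox_cfg$threshold_px,
       proximity_threshold_mm = if (config$prox_cfg$use_mm)
         config$prox_cfg$threshold_mm else NA,
       motion_speed_threshold_mm_s = config$act_cfg$motion_speed_threshold_mm_s,
       exploration_cell_mm = config$act_cfg$exploration_cell_mm,
       manova_min_variance = config$manova_min_variance,
       anova_ss_type = "II",
       gap_rule = "linear interpolation for gaps <= 5 frames; longer gaps excluded")
}
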