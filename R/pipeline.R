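# Config-driven end-to-end orchestration: load/simulate -> preprocess ->
# averages -> markers/windows -> topographic statistics -> microstates,
# with TSV/JSON outputs, figures and a reproducibility manifest.

#' Demo pipeline configuration
#'
#' A small, fully synthetic configuration (5 subjects, 2 frequencies,
#' 20-channel montage) that exercises every pipeline stage in well under a
#' minute; the natural starting point for adapting a config to real data.
#'
#' @return A nested configuration list (YAML-serializable).
#' @export
demo_config <- function() {
  list(
    input = list(simulate = list(
      montage = "10-20-20", n_subjects = 5,
      frequencies = c("0.5 Hz", "1.1 Hz"), trials = 12,
      sampling_rate = 125, noise_sd = 1
    )),
    preprocess = list(
      reference = "average",
      virtual_channels = FALSE,
      reject = list(threshold_uv = 100),
      baseline = list(window_ms = c(-53, -3))
    ),
    markers = list(
      enable = TRUE, channel_pair = c("Cz", "Fz"), r_min = 0.5,
      search_windows = list(P1 = c(40, 90), N1 = c(80, 170), P2 = c(185, 380))
    ),
    windows = list(enable = TRUE),
    topostats = list(enable = TRUE, n_perm = 499, tests = c("tanova", "gfp", "tct")),
    microstates = list(
      enable = TRUE, k_grid = 2:6, n_repeats = 5, n_perm = 199,
      window_ms = c(20, 600)
    ),
    figures = list(enable = FALSE, step_ms = 15, range_ms = c(-85, 380))
  )
}

.validate_config <- function(config) {
  if (is.null(config$input)) abort("config: missing `input` block")
  sources <- intersect(names(config$input), c("brainvision", "fixtures", "simulate"))
  if (length(sources) != 1) {
    abort(sprintf(
      "config: exactly one input source required (found %s)",
      if (length(sources)) paste(sources, collapse = " + ") else "none"
    ))
  }
  sources
}

.stage_msg <- function(log_level, ...) {
  if (identical(log_level, "quiet")) return(invisible())
  inform(paste0("[erptopo] ", sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes the configured workflow and writes all result tables (TSV),
#' summaries (JSON), optional figures (PNG) and a reproducibility manifest
#' into `out_dir`. The run is fully deterministic given `(config, seed)`:
#' rerunning yields byte-identical tables and summaries.
#'
#' @param config Configuration list or path to a YAML file (see
#'   [demo_config()] for the schema).
#' @param out_dir Output directory, created if needed.
#' @param seed Integer seed driving every random element; mandatory when any
#'   randomization stage is enabled.
#' @param log_level `"info"` or `"quiet"`.
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, log_level = "info") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  source <- .validate_config(config)
  needs_seed <- isTRUE(config$topostats$enable) ||
    isTRUE(config$microstates$enable) || source == "simulate"
  if (needs_seed && is.null(seed)) {
    abort("`seed` is mandatory when simulation or randomization stages are enabled")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config_hash = rlang::hash(config), seed = seed,
    package_version = as.character(utils::packageVersion("erptopo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    status = "running", failed_stage = NULL
  )
  results <- list()
  stage <- "input"
  res <- tryCatch(
    {
      # ---- input -----------------------------------------------------------
      dataset <- switch(source,
        simulate = {
          sb <- config$input$simulate
          mnt <- if (is.character(sb$montage %||% "10-10-64")) {
            standard_montage(sb$montage %||% "10-10-64")
          } else {
            sb$montage
          }
          cfg <- generator_config(
            montage = mnt,
            n_subjects = unlist(sb$n_subjects %||% 5),
            frequencies = unlist(sb$frequencies %||% c("0.5 Hz", "1.1 Hz", "1.6 Hz")),
            trials = sb$trials %||% 60,
            sampling_rate = sb$sampling_rate %||% 250,
            noise_sd = sb$noise_sd %||% 1
          )
          .stage_msg(log_level, "simulating %d subject(s) x %d condition(s)",
            sum(cfg$n_subjects), length(cfg$frequencies))
          simulate_sep(cfg, seed = seed)
        },
        fixtures = {
          paths <- unlist(config$input$fixtures)
          .stage_msg(log_level, "reading %d epoch fixture(s)", length(paths))
          eps <- lapply(paths, read_epochs)
          names(eps) <- vapply(eps, function(e) {
            paste0(e$subject_id, "|", e$condition[["frequency"]])
          }, "")
          subjects <- unique(vapply(eps, function(e) e$subject_id, ""))
          groups <- vapply(subjects, function(s) {
            e <- eps[[which(startsWith(names(eps), paste0(s, "|")))[1]]]
            e$condition[["location"]] %||% "G1"
          }, "")
          freqs <- unique(vapply(eps, function(e) e$condition[["frequency"]], ""))
          list(
            epochs = eps,
            subjects = tibble(subject = subjects, group = unname(groups)),
            config = list(frequencies = freqs, montage = eps[[1]]$montage)
          )
        },
        brainvision = {
          bb <- config$input$brainvision
          .stage_msg(log_level, "reading BrainVision recording %s", bb$header)
          rec <- read_brainvision(bb$header)
          fspec <- filter_spec(
            band = unlist(config$preprocess$filter$band %||% c(0.5, 70)),
            notch_hz = config$preprocess$filter$notch_hz %||% 50
          )
          rec <- bandpass_notch(rec, fspec)
          ep <- segment_epochs(rec,
            event_codes = bb$event_codes %||% NULL,
            t_min_ms = (config$preprocess$epoch$window_ms %||% c(-100, 600))[1],
            t_max_ms = (config$preprocess$epoch$window_ms %||% c(-100, 600))[2],
            subject_id = bb$subject_id %||% "S001",
            condition = c(
              frequency = bb$frequency %||% "cond1",
              location = bb$location %||% "G1"
            )
          )
          list(
            epochs = stats::setNames(
              list(ep),
              paste0(ep$subject_id, "|", ep$condition[["frequency"]])
            ),
            subjects = tibble(
              subject = ep$subject_id,
              group = ep$condition[["location"]]
            ),
            config = list(
              frequencies = ep$condition[["frequency"]],
              montage = ep$montage
            )
          )
        }
      )

      # ---- preprocess ------------------------------------------------------
      stage <- "preprocess"
      pp <- config$preprocess %||% list()
      thr <- pp$reject$threshold_uv %||% 100
      blw <- unlist(pp$baseline$window_ms %||% c(-53, -3))
      .stage_msg(log_level, "preprocessing %d epoch stack(s)", length(dataset$epochs))
      dataset$epochs <- lapply(dataset$epochs, function(e) {
        if (identical(pp$reference %||% "average", "average")) {
          e <- to_average_reference(e)
        }
        if (isTRUE(pp$virtual_channels)) e <- add_virtual_channels(e)
        e <- reject_artifacts(e, threshold_uv = thr)
        baseline_correct(e, window_ms = blw)
      })
      kept <- vapply(dataset$epochs, function(e) sum(e$kept), 0L)
      total <- vapply(dataset$epochs, function(e) length(e$kept), 0L)
      .stage_msg(log_level, "kept %d / %d trials", sum(kept), sum(total))

      # ---- averages and markers -------------------------------------------
      stage <- "markers"
      marker_tbl <- NULL
      if (isTRUE(config$markers$enable %||% TRUE)) {
        mk <- config$markers %||% list()
        pair <- unlist(mk$channel_pair %||% c("Cz", "Fz"))
        wins <- lapply(
          mk$search_windows %||% marker_windows_default(),
          unlist
        )
        rows <- lapply(names(dataset$epochs), function(nm) {
          e <- dataset$epochs[[nm]]
          ev <- average_epochs(e)
          sh <- split_half_averages(e)
          tr <- difference_channel(ev, pair[1], pair[2])
          st <- stability(
            difference_channel(sh$odd, pair[1], pair[2]),
            difference_channel(sh$even, pair[1], pair[2]),
            r_min = mk$r_min %||% 0.5
          )
          ms <- detect_markers(tr,
            search_windows = wins,
            channel_pair = paste(pair, collapse = "-")
          )
          dplyr::mutate(tidy(ms),
            subject = e$subject_id,
            frequency = e$condition[["frequency"]],
            channel_pair = paste(pair, collapse = "-"),
            stability_r = st$r, stable = st$stable
          )
        })
        marker_tbl <- dplyr::bind_rows(rows)
        readr::write_tsv(marker_tbl, file.path(out_dir, "markers.tsv"))
        jsonlite::write_json(
          list(
            responder_rate = responder_rate(
              dplyr::distinct(marker_tbl, .data$subject, .data$frequency,
                .keep_all = TRUE
              )
            ),
            n_recordings = nrow(dplyr::distinct(
              marker_tbl, .data$subject, .data$frequency
            ))
          ),
          file.path(out_dir, "responder_rate.json"),
          digits = NA, auto_unbox = TRUE
        )
        results$markers <- marker_tbl
      }

      # ---- grand average + windows ----------------------------------------
      stage <- "windows"
      ga <- grand_average(dataset, average_reference = TRUE)
      if (isTRUE(config$windows$enable %||% TRUE)) {
        gc_tbl <- gfp_curve(ga)
        win_rows <- list()
        for (mode in c("minima", "inflection")) {
          w <- tryCatch(
            windows_from_gfp(gc_tbl, mode = mode),
            error = function(e) NULL
          )
          if (!is.null(w)) win_rows <- c(win_rows, list(w))
        }
        if (!is.null(marker_tbl)) {
          dt <- time_step(ga$time)
          m2 <- marker_tbl |>
            dplyr::group_by(.data$component) |>
            dplyr::summarise(
              start_ms = windows_mean2sd(.data$latency_ms, dt_ms = dt)[1],
              end_ms = windows_mean2sd(.data$latency_ms, dt_ms = dt)[2]
            ) |>
            dplyr::mutate(peak_ms = NA_real_, method = "mean2sd")
          win_rows <- c(win_rows, list(m2))
        }
        windows_tbl <- dplyr::bind_rows(win_rows)
        readr::write_tsv(windows_tbl, file.path(out_dir, "windows.tsv"))
        results$windows <- windows_tbl
      }

      # ---- topographic statistics -----------------------------------------
      stage <- "topostats"
      if (isTRUE(config$topostats$enable %||% TRUE)) {
        ts <- config$topostats %||% list()
        np <- ts$n_perm %||% 5000
        stk <- evoked_stack(dataset, average_reference = TRUE, baseline = FALSE)
        .stage_msg(log_level, "randomization statistics: %d runs", np)
        if ("tanova" %in% (ts$tests %||% "tanova") &&
          length(dataset$config$frequencies) > 1) {
          rt <- tanova(stk$maps, stk$design,
            n_perm = np, seed = seed,
            time = stk$time
          )
          readr::write_tsv(tidy(rt), file.path(out_dir, "tanova.tsv"))
          results$tanova <- rt
        }
        if ("gfp" %in% (ts$tests %||% character()) &&
          length(dataset$config$frequencies) > 1) {
          rg <- gfp_test(stk$maps, stk$design,
            n_perm = np, seed = seed,
            time = stk$time
          )
          readr::write_tsv(tidy(rg), file.path(out_dir, "gfp_test.tsv"))
          results$gfp_test <- rg
        }
        if ("tct" %in% (ts$tests %||% character()) && dim(stk$maps)[1] >= 2) {
          pooled <- apply(stk$maps, c(1, 3, 4), mean)
          rc <- tct(pooled, n_perm = np, seed = seed, time = stk$time)
          readr::write_tsv(tidy(rc), file.path(out_dir, "tct.tsv"))
          results$tct <- rc
        }
        sig <- dplyr::bind_rows(lapply(
          results[intersect(names(results), c("tanova", "gfp_test", "tct"))],
          significant_intervals
        ), .id = "test")
        jsonlite::write_json(sig, file.path(out_dir, "significant_intervals.json"),
          digits = NA
        )
      }

      # ---- microstates -----------------------------------------------------
      stage <- "microstates"
      if (isTRUE(config$microstates$enable %||% TRUE) &&
        nrow(dataset$subjects) >= 4) {
        msc <- config$microstates %||% list()
        stk <- evoked_stack(dataset, average_reference = TRUE, baseline = FALSE)
        win <- unlist(msc$window_ms %||% c(20, 600))
        widx <- which(stk$time >= win[1] & stk$time <= win[2])
        # per-subject series: condition averages concatenated over time
        subj_series <- lapply(seq_len(dim(stk$maps)[1]), function(s) {
          do.call(rbind, lapply(seq_len(dim(stk$maps)[2]), function(cc) {
            t(stk$maps[s, cc, , widx])
          }))
        })
        cv <- cross_validate_k(subj_series,
          k_grid = unlist(msc$k_grid %||% 3:20),
          n_repeats = msc$n_repeats %||% 50, seed = seed
        )
        readr::write_tsv(tidy(cv), file.path(out_dir, "cv_curve.tsv"))
        k <- attr(cv, "chosen_k")
        .stage_msg(log_level, "microstates: chosen k = %d", k)
        train <- Reduce(`+`, subj_series) / length(subj_series)
        model <- aahc(train, k_target = k)
        write_microstates_json(model, file.path(out_dir, "microstates_model.json"))
        ac <- assign_and_compare(model, stk$maps, stk$time,
          window_ms = win,
          design = stk$design, n_perm = msc$n_perm %||% 5000, seed = seed
        )
        readr::write_tsv(ac$parameters, file.path(out_dir, "microstate_parameters.tsv"))
        readr::write_tsv(tidy(ac$tests), file.path(out_dir, "microstate_tests.tsv"))
        results$microstates <- list(cv = cv, model = model, comparison = ac)
      }

      # ---- figures ---------------------------------------------------------
      stage <- "figures"
      if (isTRUE(config$figures$enable)) {
        rng <- unlist(config$figures$range_ms %||% c(-85, 380))
        rng[1] <- max(rng[1], min(ga$time))
        rng[2] <- min(rng[2], max(ga$time))
        plot_map_series(ga, rng[1], rng[2],
          step_ms = config$figures$step_ms %||% 15,
          out_dir = file.path(out_dir, "figures")
        )
      }
      results$grand_average <- ga
      manifest$status <- "ok"
      results
    },
    error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- stage
      manifest$error <<- conditionMessage(e)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
        digits = NA, auto_unbox = TRUE, null = "null"
      )
      abort(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)))
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    digits = NA, auto_unbox = TRUE, null = "null"
  )
  .stage_msg(log_level, "done; outputs in %s", out_dir)
  invisible(list(results = res, manifest = manifest))
}
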