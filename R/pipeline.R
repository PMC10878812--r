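# End-to-end orchestration: simulate -> score -> fit -> report, with
# per-stage seeds, cached outputs and a hash manifest.

#' Pipeline configuration
#'
#' Builds the single configuration object consumed by [run_pipeline()]:
#' per-stage parameter lists, one master seed from which every stage seed
#' is derived deterministically, and the output directory. The object
#' round-trips through YAML unchanged ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param out_dir run directory.
#' @param seed master integer seed.
#' @param stages stages to execute, in dependency order.
#' @param behaviour,motion,fnirs,mcmc per-stage settings; any omitted entry
#'   keeps its default.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "dyadsync-run", seed = 1L,
                            stages = c("schedule", "behaviour", "motion",
                                       "fnirs", "report"),
                            behaviour = list(), motion = list(),
                            fnirs = list(), mcmc = list()) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    behaviour = utils::modifyList(
      list(n_per_group = 12L, n_blocks = 12L), behaviour),
    motion = utils::modifyList(
      list(n_dyads = 2L, duration_s = 40), motion),
    fnirs = utils::modifyList(
      list(n_per_group = 4L, n_blocks = 8L, long_per_roi = 2L,
           n_short = 4L), fnirs),
    mcmc = utils::modifyList(
      list(n_chains = 2L, n_adapt = 400L, n_burn = 400L, n_iter = 800L),
      mcmc)
  )
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

file_hash <- function(path) unname(tools::md5sum(path))

hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  yaml::write_yaml(x, tf)
  file_hash(tf)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the configured stages in dependency order, writing every stage
#' output as CSV into the run directory together with a JSON manifest
#' recording package version, per-stage seeds, parameter hashes and output
#' file hashes. On re-runs a stage is skipped when its parameters, its
#' upstream inputs and its own outputs all match the manifest; a modified
#' (corrupted) upstream file makes the downstream stage refuse with a
#' hash-mismatch error.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list(package = "dyadsync",
              version = as.character(utils::packageVersion("dyadsync")),
              seed = config$seed, stages = list())
  manifest$stages <- manifest$stages %||% list()

  out <- function(name) file.path(config$out_dir, name)

  check_inputs <- function(inputs) {
    for (f in inputs) {
      rec <- manifest$files[[basename(f)]]
      if (!file.exists(f)) stop("missing upstream output: ", f)
      if (!is.null(rec) && file_hash(f) != rec) {
        stop(sprintf("hash mismatch for '%s': upstream output was modified",
                     basename(f)))
      }
    }
  }

  stage_done <- function(name, params, inputs, outputs) {
    rec <- manifest$stages[[name]]
    if (is.null(rec)) return(FALSE)
    if (!identical(rec$param_hash, hash_object(params))) return(FALSE)
    if (!all(file.exists(outputs))) return(FALSE)
    ok <- vapply(outputs, function(f) {
      identical(unname(manifest$files[[basename(f)]]), file_hash(f))
    }, logical(1))
    if (!all(ok)) {
      stop(sprintf(
        "hash mismatch for '%s': stage output was modified outside the pipeline",
        basename(outputs[!ok][1])), call. = FALSE)
    }
    TRUE
  }

  record_stage <- function(name, params, outputs) {
    manifest$stages[[name]] <<- list(
      param_hash = hash_object(params),
      seed = derive_seed(config$seed, match(name, config$stages)),
      outputs = basename(outputs)
    )
    for (f in outputs) manifest$files[[basename(f)]] <<- file_hash(f)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  run_stage <- function(name, params, inputs, outputs, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    check_inputs(inputs)
    if (stage_done(name, params, inputs, outputs)) {
      message(sprintf("[%s] cached, skipping", name))
      return(invisible(NULL))
    }
    message(sprintf("[%s] running", name))
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    record_stage(name, params, outputs)
  }

  seed_of <- function(name) derive_seed(config$seed, match(name, config$stages))
  mc <- config$mcmc

  # --- schedule ---------------------------------------------------------
  run_stage(
    "schedule", config["behaviour"], character(0), out("schedule.csv"),
    function() {
      sched <- simulate_task_schedule(seed_of("schedule"),
                                      n_blocks = config$behaviour$n_blocks)
      readr::write_csv(sched, out("schedule.csv"))
    })

  # --- behaviour --------------------------------------------------------
  run_stage(
    "behaviour", config[c("behaviour", "mcmc")], out("schedule.csv"),
    c(out("trials.csv"), out("behaviour_descriptives.csv"),
      out("behaviour_effects.csv")),
    function() {
      sched <- readr::read_csv(out("schedule.csv"), show_col_types = FALSE)
      bp <- behaviour_params(n_per_group = config$behaviour$n_per_group,
                             seed = seed_of("behaviour"))
      trials <- simulate_behaviour(bp, sched)
      readr::write_csv(trials, out("trials.csv"))
      readr::write_csv(descriptive_stats(trials),
                       out("behaviour_descriptives.csv"))
      fits <- list(
        rt = fit_rt_model(trials, n_chains = mc$n_chains,
                          n_adapt = mc$n_adapt, n_burn = mc$n_burn,
                          n_iter = mc$n_iter, seed = seed_of("behaviour")),
        ce = fit_ce_model(trials, n_chains = mc$n_chains,
                          n_adapt = mc$n_adapt, n_burn = mc$n_burn,
                          n_iter = mc$n_iter, seed = seed_of("behaviour")),
        rtce = fit_rt_ce_model(trials, n_chains = mc$n_chains,
                               n_adapt = mc$n_adapt, n_burn = mc$n_burn,
                               n_iter = mc$n_iter, seed = seed_of("behaviour"))
      )
      eff <- dplyr::bind_rows(lapply(names(fits), function(nm) {
        dplyr::mutate(tidy(fits[[nm]]), model = nm, .before = 1)
      }))
      readr::write_csv(eff, out("behaviour_effects.csv"))
    })

  # --- motion + similarity ---------------------------------------------
  run_stage(
    "motion", config["motion"], character(0), out("similarity.csv"),
    function() {
      rows <- list()
      for (regime in c("synchronized", "control")) {
        for (d in seq_len(config$motion$n_dyads)) {
          mp <- motion_params(regime = regime,
                              duration_s = config$motion$duration_s,
                              seed = derive_seed(seed_of("motion"),
                                                 d + 100 * (regime == "control")))
          tr <- simulate_dyad_motion(mp)
          g <- glance(dyad_similarity(tr$participant, tr$confederate))
          rows[[length(rows) + 1]] <-
            dplyr::mutate(g, regime = regime, dyad = d, .before = 1)
        }
      }
      readr::write_csv(dplyr::bind_rows(rows), out("similarity.csv"))
    })

  # --- fNIRS ------------------------------------------------------------
  run_stage(
    "fnirs", config[c("fnirs", "mcmc")], character(0),
    c(out("roi_estimates.csv"), out("fnirs_contrasts.csv")),
    function() {
      lpr <- config$fnirs$long_per_roi
      montage <- default_montage(
        long_per_roi = setNames(rep(lpr, 5),
                                c("LIFG", "LPFC", "MPFC", "RPFC", "RIFG")),
        n_short = config$fnirs$n_short)
      sched <- simulate_task_schedule(seed_of("fnirs"),
                                      n_blocks = config$fnirs$n_blocks)
      ev <- schedule_events(sched)
      n <- config$fnirs$n_per_group
      groups <- rep(c("Control", "Synchronized"), each = n)
      est <- purrr::imap_dfr(groups, function(g, i) {
        fp <- fnirs_params(seed = derive_seed(seed_of("fnirs"), i))
        raw <- simulate_fnirs(fp, ev, montage)
        fnirs_first_level(raw)$roi_estimates |>
          dplyr::mutate(participant_id = sprintf("F%03d", i), group = g)
      })
      readr::write_csv(est, out("roi_estimates.csv"))
      mv <- fit_multivariate_model(est, n_chains = mc$n_chains,
                                   n_adapt = mc$n_adapt, n_burn = mc$n_burn,
                                   n_iter = mc$n_iter,
                                   seed = seed_of("fnirs"))
      contrasts <- dplyr::bind_rows(
        dplyr::mutate(contrast_marginal(mv, "block"), contrast = "block"),
        dplyr::mutate(contrast_marginal(mv, "group"), contrast = "group")
      )
      diffs <- hbo_hbr_difference(est)
      dm <- fit_difference_model(diffs, "negative_only",
                                 n_chains = mc$n_chains,
                                 n_adapt = mc$n_adapt, n_burn = mc$n_burn,
                                 n_iter = mc$n_iter, seed = seed_of("fnirs"))
      contrasts <- dplyr::bind_rows(
        contrasts,
        dplyr::mutate(contrast_marginal(dm, "block"), contrast = "block"),
        dplyr::mutate(contrast_marginal(dm, "group"), contrast = "group")
      )
      readr::write_csv(contrasts, out("fnirs_contrasts.csv"))
    })

  # --- report -----------------------------------------------------------
  if ("report" %in% config$stages) {
    report_run(config$out_dir)
    record_stage("report", list(), out("report.md"))
  }
  invisible(manifest)
}

md_table <- function(df, digits = 3) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = digits, format = "fg") else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Render a run-directory summary report
#'
#' Writes `report.md` summarising whatever stage outputs are present:
#' behavioural descriptives and model effects, the movement-similarity
#' summary and the fNIRS contrast tables. Missing stages are noted and
#' their sections omitted.
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @return Invisibly, the report path.
#' @export
report_run <- function(run_dir) {
  if (!dir.exists(run_dir) || !length(list.files(run_dir))) {
    stop("report_run(): empty or missing run directory: ", run_dir)
  }
  parts <- c("# dyadsync run report", "")
  section <- function(file, title) {
    p <- file.path(run_dir, file)
    if (file.exists(p)) {
      df <- readr::read_csv(p, show_col_types = FALSE)
      c(paste("##", title), "", md_table(df), "")
    } else {
      c(paste("##", title), "", sprintf("_%s not available (stage not run)._", file), "")
    }
  }
  parts <- c(parts,
             section("behaviour_descriptives.csv",
                     "Go/NoGo descriptive statistics"),
             section("behaviour_effects.csv", "Behavioural model effects"),
             section("similarity.csv", "Movement similarity"),
             section("fnirs_contrasts.csv", "fNIRS second-level contrasts"))
  path <- file.path(run_dir, "report.md")
  writeLines(parts, path)
  invisible(path)
}
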