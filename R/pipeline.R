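#' Pipeline configuration
#'
#' Bundles every stage's parameters with the defaults used throughout:
#' spectral multitaper T = 2 s, 1.9 s overlap, TW = 2, K = 3; coherence
#' TW = 3, K = 5, T = 2 s, non-overlapping; 2000 bootstrap replicates at a
#' 95% CI; 10 end-tidal concentration bins. Constructors validate
#' physical consistency (K <= 2TW - 1, overlap < T, ci_level in (0, 100)),
#' so an inconsistent configuration fails before any stage runs.
#'
#' @param cohort A [cohort_spec()] (synthetic input) — its `master_seed`
#'   seeds every stage.
#' @param out_dir Output directory for stage outputs and the manifest.
#' @param multitaper Spectral [multitaper_params()].
#' @param coherence Coherence [coherence_params()].
#' @param bootstrap A [bootstrap_config()]; its seed defaults to a value
#'   derived from the cohort master seed.
#' @param stages Stages to run (subset of cohort, preproc, spectral,
#'   coherence, stats, emergence; dependencies are run as needed).
#' @param artifact_threshold_uv Artifact amplitude threshold.
#' @param fmax Upper frequency bound of reported grids, Hz.
#' @param spectrogram_electrodes Electrodes whose full group-median
#'   spectrograms are written (band topography always covers all).
#' @param write_edf Write each subject's raw recording as EDF (off by
#'   default; recordings are large).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            out_dir = file.path(tempdir(), "sevoeeg_run"),
                            multitaper = multitaper_params(),
                            coherence = coherence_params(),
                            bootstrap = NULL,
                            stages = c("cohort", "preproc", "spectral",
                                       "coherence", "stats", "emergence"),
                            artifact_threshold_uv = 200,
                            fmax = 30,
                            spectrogram_electrodes = c("F7", "F8"),
                            write_edf = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(multitaper, "multitaper_params"),
            inherits(coherence, "multitaper_params"))
  if (is.null(bootstrap)) {
    bootstrap <- bootstrap_config(seed = derive_seed(cohort$master_seed, 999))
  }
  stopifnot(inherits(bootstrap, "bootstrap_config"))
  bad <- setdiff(stages, c("cohort", "preproc", "spectral", "coherence",
                           "stats", "emergence"))
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(cohort = cohort, out_dir = out_dir,
                 multitaper = multitaper, coherence = coherence,
                 bootstrap = bootstrap, stages = stages,
                 artifact_threshold_uv = artifact_threshold_uv,
                 fmax = fmax,
                 spectrogram_electrodes = spectrogram_electrodes,
                 write_edf = isTRUE(write_edf)),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' Recognized top-level keys: `seed`, `n_young`, `n_old`, `fs`, `out_dir`,
#' `stages`, `artifact_threshold_uv`, `fmax`, `write_edf`, and blocks
#' `multitaper` (window_T, overlap, TW, K), `coherence` (same fields) and
#' `bootstrap` (n_replicates, ci_level, seed). Unknown keys are an error so
#' typos never silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "n_young", "n_old", "fs", "out_dir", "stages",
             "artifact_threshold_uv", "fmax", "write_edf", "multitaper",
             "coherence", "bootstrap")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) stop("unknown config key(s): ",
                            paste(bad, collapse = ", "))
  co_args <- list(master_seed = y$seed %||% 1)
  if (!is.null(y$n_young)) co_args$n_young <- y$n_young
  if (!is.null(y$n_old)) co_args$n_old <- y$n_old
  if (!is.null(y$fs)) co_args$fs <- y$fs
  mt <- do.call(multitaper_params, y$multitaper %||% list())
  ch <- do.call(coherence_params, y$coherence %||% list())
  bs <- if (is.null(y$bootstrap)) NULL else
    do.call(bootstrap_config, y$bootstrap)
  args <- list(cohort = do.call(cohort_spec, co_args),
               multitaper = mt, coherence = ch, bootstrap = bs)
  for (k in c("out_dir", "stages", "artifact_threshold_uv", "fmax",
              "write_edf")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

write_tsv_ <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes generate -> preprocess -> spectral -> coherence -> bootstrap ->
#' emergence on a synthetic cohort, writing TSV/JSON outputs per stage and
#' a run manifest (seeds, package version, per-file MD5 hashes, exclusion
#' log). Two runs with the same configuration produce bit-identical
#' outputs. Any stage failure aborts with the stage name (and subject id
#' where applicable).
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logs <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    logs <<- c(logs, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  want <- function(s) s %in% config$stages
  completed <- character(0)
  files <- character(0)
  add_files <- function(...) files <<- c(files, unlist(list(...)))

  ## ---- cohort + preproc (streamed subject by subject; a raw default
  ## recording is ~370 MB, so it is generated, preprocessed, epoched and
  ## discarded before the next subject) ------------------------------------
  cs <- config$cohort
  n_subj <- cs$n_young + cs$n_old
  weights <- build_laplacian_weights(cs$montage)
  cdir <- file.path(out, "cohort")
  if (want("cohort")) dir.create(cdir, showWarnings = FALSE)
  movements <- vector("list", n_subj)
  pp <- list()
  need_pp <- any(c("preproc", "spectral", "coherence", "stats",
                   "emergence") %in% config$stages)
  for (i in seq_len(n_subj)) {
    s <- stage("cohort", generate_cohort_subject(cs, i))
    id <- s$spec$subject_id
    movements[[i]] <- s$movement
    if (want("cohort")) {
      stage("cohort", {
        add_files(write_tsv_(s$sevo, file.path(
          cdir, paste0("sevo_", id, ".tsv"))))
        if (config$write_edf) {
          add_files(write_edf(s$recording, file.path(
            cdir, paste0(id, ".edf"))))
        }
      })
    }
    if (need_pp) stage("preproc", {
      rec <- tryCatch({
        antialias_downsample(apply_laplacian(s$recording, weights))
      }, error = function(e) {
        stop("subject ", id, ": ", conditionMessage(e))
      })
      withCallingHandlers({
        mossa <- extract_state_epochs(rec, s$sevo, state = "MOSSA",
          artifact_threshold_uv = config$artifact_threshold_uv)
        awake <- extract_state_epochs(rec, s$sevo, state = "awake",
          artifact_threshold_uv = config$artifact_threshold_uv)
        fm <- extract_state_epochs(rec, s$sevo, s$movement,
          state = "first_movement",
          artifact_threshold_uv = config$artifact_threshold_uv)
        emer <- bin_emergence_epochs(rec, s$sevo,
          artifact_threshold_uv = config$artifact_threshold_uv)
      }, message = function(m) {
        logs <<- c(logs, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
      fm_states <- vapply(fm, function(e) e$state, "")
      pp[[id]] <- list(
        id = id, age_group = s$spec$age_group,
        mossa = if (length(mossa) > 0) mossa[[1]] else NULL,
        awake = if (length(awake) > 0) awake[[1]] else NULL,
        fm_pair = list(
          mossa = if (any(fm_states == "MOSSA"))
            fm[[which(fm_states == "MOSSA")[1]]] else NULL,
          movement = if (any(fm_states == "first_movement"))
            fm[[which(fm_states == "first_movement")[1]]] else NULL),
        emergence = emer)
      if (length(mossa) == 0) note("subject ", id, ": no MOSSA epoch")
    })
    rm(s)
  }
  movements <- dplyr::bind_rows(movements)
  if (want("cohort")) {
    stage("cohort", {
      add_files(write_tsv_(movements,
                           file.path(cdir, "movement_annotations.tsv")))
      man <- purrr::map_dfr(seq_len(n_subj), function(i) {
        sp <- cohort_subject_spec(cs, i)
        tibble::tibble(subject_id = sp$subject_id,
                       age_group = sp$age_group,
                       fs = sp$fs, seed = sp$seed)
      })
      yaml::write_yaml(man, file.path(cdir, "cohort_manifest.yaml"))
      add_files(file.path(cdir, "cohort_manifest.yaml"))
    })
  }
  completed <- c(completed, "cohort", if (need_pp) "preproc")
  groups <- vapply(pp, function(x) x$age_group, "")
  ids <- names(pp)
  labs <- montage_channels(config$cohort$montage)

  need_spectral <- want("spectral") || want("stats")
  f7_spectra <- list()
  if (need_spectral) {
    stage("spectral", {
      sdir <- file.path(out, "spectral")
      dir.create(sdir, showWarnings = FALSE)
      have <- ids[!vapply(pp, function(x) is.null(x$mossa), logical(1))]
      topo <- list("0-3mo" = list(), "4-6mo" = list())
      for (lab in labs) {
        ests <- lapply(have, function(id) {
          multitaper_spectrogram(pp[[id]]$mossa, config$multitaper,
                                 channel = lab, fmax = config$fmax)
        })
        names(ests) <- have
        for (g in unique(groups[have])) {
          gm <- group_median_spectrogram(ests[groups[have] == g])
          topo[[g]][[lab]] <- gm
          if (want("spectral") && lab %in% config$spectrogram_electrodes) {
            df <- tidy(gm)
            add_files(write_tsv_(df, file.path(sdir, paste0(
              "spectrogram_median_", lab, "_", gsub("-", "", g), ".tsv"))))
          }
        }
        if (lab == "F7") {
          f7_spectra <- lapply(ests, subject_mean_spectrum)
          if (want("spectral")) {
            for (g in unique(groups[have])) {
              ps <- group_spectrum(ests[groups[have] == g], group = g)
              add_files(write_tsv_(ps, file.path(sdir, paste0(
                "group_spectrum_F7_", gsub("-", "", g), ".tsv"))))
            }
          }
        }
      }
      if (want("spectral")) {
        for (g in names(topo)) {
          if (length(topo[[g]]) == 0) next
          tp <- band_power_topography(topo[[g]])
          add_files(write_tsv_(tp, file.path(sdir, paste0(
            "band_topography_", gsub("-", "", g), ".tsv"))))
        }
      }
      completed <- c(completed, "spectral")
    })
  }

  if (want("coherence")) {
    stage("coherence", {
      kdir <- file.path(out, "coherence")
      dir.create(kdir, showWarnings = FALSE)
      have <- ids[!vapply(pp, function(x) is.null(x$mossa), logical(1))]
      cohs <- lapply(have, function(id) {
        pairwise_coherogram(pp[[id]]$mossa, "F7", "F8", config$coherence,
                            fmax = config$fmax)
      })
      names(cohs) <- have
      gcs <- lapply(have, function(id) {
        global_coherence(cross_spectral_matrix(pp[[id]]$mossa,
                                               config$coherence,
                                               fmax = config$fmax))
      })
      names(gcs) <- have
      for (g in unique(groups[have])) {
        sel <- have[groups[have] == g]
        gm <- group_median_coherogram(cohs[sel])
        add_files(write_tsv_(tidy(gm), file.path(kdir, paste0(
          "coherogram_median_F7F8_", gsub("-", "", g), ".tsv"))))
        cg <- vapply(gcs[sel], function(x) x$c_global,
                     numeric(length(gcs[[1]]$freqs)))
        cg_med <- tibble::tibble(freq = gcs[[1]]$freqs,
                                 c_global_median =
                                   matrixStats::rowMedians(cg))
        add_files(write_tsv_(cg_med, file.path(kdir, paste0(
          "global_coherence_", gsub("-", "", g), ".tsv"))))
        maps <- lapply(gcs[sel], spatial_coherence_map)
        med_map <- maps[[1]]
        for (b in band_scheme()$band) {
          M <- vapply(maps, function(m) m[[b]], numeric(nrow(med_map)))
          med_map[[b]] <- matrixStats::rowMedians(M)
        }
        add_files(write_tsv_(med_map, file.path(kdir, paste0(
          "spatial_coherence_", gsub("-", "", g), ".tsv"))))
      }
      completed <- c(completed, "coherence")
    })
  }

  if (want("stats")) {
    stage("stats", {
      bdir <- file.path(out, "stats")
      dir.create(bdir, showWarnings = FALSE)
      old <- f7_spectra[groups[names(f7_spectra)] == "4-6mo"]
      young <- f7_spectra[groups[names(f7_spectra)] == "0-3mo"]
      if (length(old) >= 2 && length(young) >= 2) {
        bt <- bootstrap_group_difference(old, young, config$bootstrap)
        add_files(write_tsv_(bt, file.path(bdir,
                                           "group_difference_F7.tsv")))
        add_files(write_tsv_(band_significance(bt), file.path(
          bdir, "group_difference_F7_bands.tsv")))
      } else {
        note("stats: not enough subjects per group for the unpaired ",
             "comparison")
      }
      for (g in unique(groups)) {
        pairs <- purrr::map(pp[groups == g], "fm_pair")
        ok <- withCallingHandlers({
          tryCatch(mossa_vs_movement_difference(
            pairs, config$bootstrap, config$multitaper,
            fmax = config$fmax), error = function(e) NULL)
        }, message = function(m) {
          logs <<- c(logs, trimws(conditionMessage(m)))
          invokeRestart("muffleMessage")
        })
        if (!is.null(ok)) {
          add_files(write_tsv_(ok, file.path(bdir, paste0(
            "mossa_vs_movement_", gsub("-", "", g), ".tsv"))))
        } else {
          note("stats: no MOSSA/movement pairs in group ", g)
        }
      }
      completed <- c(completed, "stats")
    })
  }

  if (want("emergence")) {
    stage("emergence", {
      edir <- file.path(out, "emergence")
      dir.create(edir, showWarnings = FALSE)
      for (g in unique(groups)) {
        eps <- purrr::flatten(purrr::map(pp[groups == g], "emergence"))
        if (length(eps) == 0) {
          note("emergence: no binned epochs in group ", g)
          next
        }
        idx <- purrr::map_dfr(eps, function(e) {
          tibble::tibble(subject_id = e$subject_id, bin = e$etsevo_bin)
        })
        bp <- band_power_by_bin(eps, params = config$multitaper)
        add_files(write_tsv_(bp$group_median, file.path(edir, paste0(
          "band_power_by_bin_", gsub("-", "", g), ".tsv"))))
        mf <- movement_fraction_by_bin(movements[movements$age_group == g, ], idx)
        add_files(write_tsv_(mf, file.path(edir, paste0(
          "movement_fraction_", gsub("-", "", g), ".tsv"))))
      }
      completed <- c(completed, "emergence")
    })
  }

  manifest <- list(
    package = "sevoeeg",
    version = as.character(utils::packageVersion("sevoeeg")),
    master_seed = config$cohort$master_seed,
    bootstrap_seed = config$bootstrap$seed,
    stages_completed = unique(completed),
    n_subjects = n_subj,
    files = as.list(stats::setNames(
      unname(tools::md5sum(sort(unique(files)))),
      sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", out), "/?"),
          "", sort(unique(files))))),
    log = logs)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
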