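#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Values
#' mirror the study defaults: 2-20 Hz band (1-40 Hz as the usual
#' alternative), k = 4 microstates, up to 10000 GFP peaks, 2 s window,
#' TR = 2 s, motion-RMS censor threshold 0.2, and the mTDNN grids.
#'
#' @param band Length-2 Hz band for segmentation.
#' @param k Number of microstate classes.
#' @param max_peaks Maximum GFP peaks clustered per subject.
#' @param window_s Activity/transition window (s).
#' @param tr Repetition time (s).
#' @param n_tr Number of volumes per subject.
#' @param sfreq EEG sampling rate (Hz).
#' @param n_channels Number of EEG channels.
#' @param n_subjects Number of synthetic subjects.
#' @param n_rois Number of BOLD ROIs.
#' @param coupling Named list of planted couplings (regressor -> per-ROI
#'   coefficients), passed to the generator.
#' @param censor_threshold Motion RMS censoring threshold.
#' @param n_perm Permutations for cluster correction.
#' @param glm_regressor Regressor analysed in the GLM stage.
#' @param mtdnn Named list: `neuron_grid`, `delay_grid`, `initial`,
#'   `epochs`, `reg`.
#' @param seed Master seed; per-stage seeds derive from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(band = c(2, 20), k = 4, max_peaks = 10000,
                            window_s = 2, tr = 2, n_tr = 244, sfreq = 250,
                            n_channels = 32, n_subjects = 5, n_rois = 70,
                            coupling = list(AT_A = c(rep(-0.5, 10), rep(0, 60))),
                            censor_threshold = 0.2, n_perm = 1000,
                            glm_regressor = "AT_A",
                            mtdnn = list(neuron_grid = c(5, 10),
                                         delay_grid = 1:2, initial = 31,
                                         epochs = 60, reg = 1e-2),
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$band) == 2, cfg$band[1] < cfg$band[2],
            cfg$k >= 1, cfg$window_s > 0, cfg$tr > 0, cfg$n_tr > 3,
            cfg$n_subjects >= 1, cfg$n_perm >= 100)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$coupling)) {
    vals$coupling <- lapply(vals$coupling, as.numeric)
  }
  do.call(pipeline_config, vals)
}

write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full synthetic EEG-BOLD pipeline
#'
#' Orchestrates simulate -> segment -> regressors -> glm -> mtdnn with
#' fixed per-stage seeds, writing delimited artifacts and a manifest to
#' `out_dir`. Rerunning with the same configuration reproduces all
#' deterministic artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results
#'   (`group_templates`, `regressors`, `group_stat`, `clusters`,
#'   `overlap`, `cv`) and the manifest path.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("msbold_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  log_line <- function(...) cat(sprintf(...), "\n", sep = "")

  # -- simulate ------------------------------------------------------------
  log_line("[simulate] %d subject(s), %d TRs, seed %d",
           config$n_subjects, config$n_tr, config$seed)
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    simulate_subject(n_channels = config$n_channels, k = config$k,
                     sfreq = config$sfreq, tr = config$tr, n_tr = config$n_tr,
                     n_rois = config$n_rois, coupling = config$coupling,
                     window_s = config$window_s,
                     seed = config$seed * 1000L + s)
  })
  stages <- c(stages, "simulate")

  # -- segment -------------------------------------------------------------
  log_line("[segment] band %g-%g Hz, k = %d", config$band[1], config$band[2],
           config$k)
  subj_templates <- lapply(seq_along(subjects), function(s) {
    extract_templates(subjects[[s]]$eeg, band = config$band, k = config$k,
                      max_peaks = config$max_peaks,
                      seed = config$seed * 1000L + s)
  })
  group_templates <- align_and_average_templates(subj_templates)
  tpl_tab <- as.data.frame(t(group_templates$templates))
  names(tpl_tab) <- group_templates$labels
  write_table(tpl_tab, file.path(out_dir, "group_templates.tsv"))
  stages <- c(stages, "segment")

  # -- regressors ----------------------------------------------------------
  log_line("[regressors] window %g s, TR %g s", config$window_s, config$tr)
  reg_sets <- lapply(subjects, function(sub) {
    filt <- bandpass_filter(average_reference(sub$eeg),
                            config$band[1], config$band[2])
    bf <- backfit(filt, group_templates)
    regressor_set(bf$labels, eeg = filt, templates = group_templates,
                  sfreq = config$sfreq, window_s = config$window_s,
                  tr = config$tr, n_tr = config$n_tr, k = config$k)
  })
  write_table(reg_sets[[1]]$tr_rate, file.path(out_dir, "regressors_subject1.tsv"))
  stages <- c(stages, "regressors")

  # -- glm -----------------------------------------------------------------
  log_line("[glm] regressor %s, %d permutations", config$glm_regressor,
           config$n_perm)
  betas <- t(vapply(seq_along(subjects), function(s) {
    design <- build_design_matrix(reg_sets[[s]]$tr_rate[[config$glm_regressor]])
    fit_subject_glm(subjects[[s]]$bold, design)$beta
  }, numeric(config$n_rois)))
  gstat <- group_ttest(betas)
  clusters <- permutation_cluster_correction(
    betas, n_perm = config$n_perm, seed = config$seed + 7L)
  overlap <- network_overlap(clusters, subjects[[1]]$bold$parcellation)
  write_table(as.data.frame(gstat), file.path(out_dir, "group_stats.tsv"))
  write_table(as.data.frame(dplyr::select(clusters, -"units")),
              file.path(out_dir, "clusters.tsv"))
  write_table(overlap, file.path(out_dir, "network_overlap.tsv"))
  stages <- c(stages, "glm")

  # -- mtdnn ---------------------------------------------------------------
  log_line("[mtdnn] initial %d TRs, epochs %d", config$mtdnn$initial,
           config$mtdnn$epochs)
  sub1 <- subjects[[1]]
  regs1 <- reg_sets[[1]]$tr_rate
  letters_k <- LETTERS[seq_len(config$k)]
  dt_cols <- paste0("DT_", letters_k)
  dyn_cols <- setdiff(names(regs1), dt_cols)
  bold7 <- network_bold(sub1$bold)
  cv <- run_four_experiments(
    as.matrix(regs1[dt_cols]), as.matrix(regs1[dyn_cols]), bold7,
    initial = config$mtdnn$initial, epochs = config$mtdnn$epochs,
    reg = config$mtdnn$reg, n_hidden = config$mtdnn$neuron_grid[1],
    max_delay = config$mtdnn$delay_grid[1], seed = config$seed + 11L)
  write_table(cv, file.path(out_dir, "mtdnn_cv.tsv"))
  stages <- c(stages, "mtdnn")

  # -- manifest ------------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  cfg_plain <- unclass(config)
  yaml::write_yaml(cfg_plain, cfg_path)
  manifest <- c(
    sprintf("package: msbold %s", as.character(utils::packageVersion("msbold"))),
    sprintf("stages: %s", paste(stages, collapse = ", ")),
    sprintf("n_stages: %d", length(stages)),
    sprintf("seed: %d", config$seed),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_path)))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(list(group_templates = group_templates, regressors = reg_sets,
                 group_stat = gstat, clusters = clusters, overlap = overlap,
                 cv = cv, manifest = file.path(out_dir, "manifest.txt"),
                 out_dir = out_dir))
}

#' Average BOLD units into network signals
#'
#' Averages the unit-level BOLD series within each nonzero network of the
#' parcellation, yielding one series per network (the 7-network reduction
#' used by the prediction experiments).
#'
#' @param bold A [bold_dataset()] with a parcellation.
#' @return Numeric matrix n_TR x n_networks, columns `net<k>`.
#' @export
network_bold <- function(bold) {
  if (is.null(bold$parcellation)) abort("BOLD dataset has no parcellation.")
  nets <- sort(unique(bold$parcellation[bold$parcellation != 0]))
  out <- vapply(nets, function(nw) {
    colMeans(bold$data[bold$parcellation == nw, , drop = FALSE])
  }, numeric(ncol(bold$data)))
  colnames(out) <- paste0("net", nets)
  out
}
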