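# Pipeline orchestration, configuration and file I/O --------------------------

#' Build a validated pipeline configuration
#'
#' Defaults reproduce the package's stated analysis parameters (42 Hz
#' analysis rate, QI >= 0.4 filter, lasso unmixing, BIC-selected Gaussian
#' mixtures). Stage toggles control which stages [run_pipeline()] executes;
#' later stages depend on earlier ones.
#'
#' @param seed master RNG seed.
#' @param outdir output directory.
#' @param n_rois,noise_sd,n_repeats synthetic population parameters
#'   (see [make_population()]).
#' @param qi_min ROI quality threshold (inclusive keep), default 0.4.
#' @param n_pc PCA components considered, capped at the trace/sample count.
#' @param k_range candidate cluster counts.
#' @param n_init EM restarts per k.
#' @param lasso_lambda penalty for [fit_cone_weights()] (number or "cv").
#' @param band_hz band for [power_explained()].
#' @param stages character vector of stages to run, subset of
#'   `c("simulate", "preprocess", "cluster", "decompose", "analyze")`.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, outdir = tempfile("spectramap_run_"),
                            n_rois = 200, noise_sd = 0.08, n_repeats = 7,
                            qi_min = 0.4, n_pc = 48, k_range = 1:10,
                            n_init = 5, lasso_lambda = "cv",
                            band_hz = c(0.16, 2),
                            stages = c("simulate", "preprocess", "cluster",
                                       "decompose", "analyze")) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(seed == round(seed), n_rois >= 1, qi_min >= 0,
            length(band_hz) == 2)
  structure(list(seed = as.integer(seed), outdir = outdir, n_rois = n_rois,
                 noise_sd = noise_sd, n_repeats = n_repeats, qi_min = qi_min,
                 n_pc = n_pc, k_range = k_range, n_init = n_init,
                 lasso_lambda = lasso_lambda, band_hz = band_hz,
                 stages = stages), class = "pipeline_config")
}

write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> preprocess -> cluster -> decompose -> analyze as
#' toggled in the config, writing every stage product as CSV/JSON under
#' `config$outdir`, and emits a run manifest (config hash, package version,
#' per-file checksums, wall times). Fully reproducible from (config, seed).
#'
#' @param config a `pipeline_config`.
#' @return The manifest (invisibly), a list also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  need <- function(stage, dep, file) {
    if (!(dep %in% st) && !file.exists(file.path(config$outdir, file)))
      stop("stage-dependency error: '", stage, "' needs output of '", dep,
           "'")
  }
  times <- c(); files <- c()
  tic <- function() proc.time()[["elapsed"]]
  protocol <- make_stimulus_protocol()
  cones <- make_cone_tunings()
  basis <- make_temporal_basis(protocol)

  if ("simulate" %in% st) {
    t0 <- tic()
    pop <- make_population(n_rois = config$n_rois,
                           noise_sd = config$noise_sd,
                           n_repeats = config$n_repeats, seed = config$seed)
    records <- simulate_roi_traces(pop, protocol, cones, basis)
    truth <- cbind(data.frame(id = seq_len(pop$n_rois),
                              archetype = as.character(pop$archetype),
                              ipl_depth = pop$ipl_depth,
                              region = as.character(pop$region)),
                   weights_to_table(pop$weights))
    utils::write.csv(truth, file.path(config$outdir, "population.csv"),
                     row.names = FALSE)
    times["simulate"] <- tic() - t0
    files <- c(files, "population.csv")
  } else records <- NULL

  if ("preprocess" %in% st) {
    t0 <- tic()
    if (is.null(records)) stop("stage-dependency error: 'preprocess' needs ",
                               "'simulate' outputs in memory")
    records <- lapply(records, preprocess_record)
    kept <- filter_rois(records, config$qi_min)
    roi_tab <- data.frame(
      id = vapply(kept, `[[`, numeric(1), "id"),
      qi = vapply(kept, `[[`, numeric(1), "qi"),
      ipl_depth = vapply(kept, `[[`, numeric(1), "ipl_depth"),
      region = vapply(kept, `[[`, character(1), "region"),
      archetype = vapply(kept, function(r) r$truth$archetype, character(1)))
    utils::write.csv(roi_tab, file.path(config$outdir, "rois.csv"),
                     row.names = FALSE)
    trace_means <- t(vapply(kept, `[[`,
                            numeric(length(kept[[1]]$trace_mean)),
                            "trace_mean"))
    write_matrix_csv(trace_means, file.path(config$outdir,
                                            "trace_means.csv"))
    times["preprocess"] <- tic() - t0
    files <- c(files, "rois.csv", "trace_means.csv")
  } else {
    kept <- NULL; roi_tab <- NULL; trace_means <- NULL
  }

  if ("cluster" %in% st) {
    t0 <- tic()
    if (is.null(trace_means))
      stop("stage-dependency error: 'cluster' needs 'preprocess'")
    n_pc <- min(config$n_pc, nrow(trace_means) - 1, ncol(trace_means))
    red <- pca_reduce(trace_means, n_pc = n_pc,
                      rate = protocol$resample_rate_hz)
    model <- fit_gmm_bic(red$scores,
                         k_range = config$k_range[config$k_range <=
                                                    nrow(trace_means)],
                         n_init = config$n_init, seed = config$seed)
    summ <- summarize_clusters(model$labels, trace_means, roi_tab$ipl_depth,
                               factor(roi_tab$region,
                                      c("AZ", "D", "N", "V")))
    utils::write.csv(data.frame(id = roi_tab$id, cluster = summ$labels),
                     file.path(config$outdir, "clusters.csv"),
                     row.names = FALSE)
    write_matrix_csv(summ$cluster_means,
                     file.path(config$outdir, "cluster_means.csv"))
    utils::write.csv(data.frame(k = as.integer(names(model$bic_curve)),
                                bic = as.numeric(model$bic_curve)),
                     file.path(config$outdir, "bic.csv"), row.names = FALSE)
    times["cluster"] <- tic() - t0
    files <- c(files, "clusters.csv", "cluster_means.csv", "bic.csv")
  } else summ <- NULL

  if ("decompose" %in% st) {
    t0 <- tic()
    if (is.null(summ)) {
      cmf <- file.path(config$outdir, "cluster_means.csv")
      if (!file.exists(cmf))
        stop("stage-dependency error: 'decompose' needs 'cluster'")
      summ <- list(cluster_means = as.matrix(utils::read.csv(cmf)))
      summ$n_clusters <- nrow(summ$cluster_means)
    }
    # factorize across all light responses and the cluster means: the ROI
    # traces supply the temporal diversity that identifies the basis
    nmf_input <- if (!is.null(trace_means))
      rbind(trace_means, summ$cluster_means) else summ$cluster_means
    basis_hat <- extract_temporal_basis_nmf(nmf_input, protocol,
                                            seed = config$seed)
    fits <- lapply(seq_len(summ$n_clusters), function(j)
      decompose_to_weights(summ$cluster_means[j, ], basis_hat, protocol,
                           cones, lasso_lambda = config$lasso_lambda))
    wt <- weights_to_table(lapply(fits, `[[`, "w"))
    wt_norm <- weights_to_table(lapply(fits, `[[`, "w_norm"))
    names(wt_norm) <- paste0(names(wt_norm), "_norm")
    utils::write.csv(cbind(cluster = seq_len(summ$n_clusters), wt, wt_norm),
                     file.path(config$outdir, "weights.csv"),
                     row.names = FALSE)
    write_matrix_csv(basis_hat$kernels, file.path(config$outdir,
                                                  "basis.csv"))
    recons <- t(vapply(fits, function(f)
      reconstruct(f, cones, basis_hat, protocol)$full,
      numeric(samples_per_flash(protocol) *
                length(protocol$central_led_indices))))
    write_matrix_csv(recons, file.path(config$outdir,
                                       "reconstructions.csv"))
    times["decompose"] <- tic() - t0
    files <- c(files, "weights.csv", "basis.csv", "reconstructions.csv")
  } else fits <- NULL

  if ("analyze" %in% st) {
    t0 <- tic()
    if (is.null(fits))
      stop("stage-dependency error: 'analyze' needs 'decompose'")
    wl <- cones$wavelength_nm
    curves <- lapply(fits, function(f) bulk_tuning(f$w_norm, cones))
    groups <- vapply(curves, assign_spectral_group, character(1),
                     cone_set = cones)
    crossings <- lapply(curves, find_zero_crossings, wavelengths = wl)
    n_rois <- if (!is.null(summ$n_rois)) summ$n_rois
    else rep(1, length(curves))
    zch <- zero_crossing_histogram(curves, n_rois, wl)
    tun_mat <- do.call(cbind, curves)
    colnames(tun_mat) <- paste0("cluster_", seq_along(curves))
    utils::write.csv(cbind(wavelength_nm = wl, as.data.frame(tun_mat)),
                     file.path(config$outdir, "tunings.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(cluster = seq_along(curves), group = groups,
                 crossings = vapply(crossings, function(cr)
                   paste(round(cr, 1), collapse = ";"), character(1))),
      file.path(config$outdir, "groups.csv"), row.names = FALSE)
    # reconstruction quality over the central flash window
    cm <- summ$cluster_means
    idx <- protocol$central_led_indices
    P <- samples_per_flash(protocol)
    win <- as.vector(vapply(idx, function(f)
      ((f - 1) * P + 1):(f * P), integer(P)))
    recons <- as.matrix(utils::read.csv(file.path(config$outdir,
                                                  "reconstructions.csv")))
    ve <- variance_explained(cm[, win, drop = FALSE], recons)
    pe <- power_explained(cm[, win, drop = FALSE], recons,
                          rate = protocol$resample_rate_hz,
                          band = config$band_hz)
    metrics <- list(
      variance_explained_pct = ve$variance_explained_pct,
      residual_variance_pct = ve$residual_variance_pct,
      power_explained_pct = pe$power_explained_pct,
      residual_power_pct = pe$residual_power_pct,
      crossing_histogram = list(mids = zch$mids, counts = zch$counts),
      trimodality = trimodality_score(zch))
    if (length(curves) >= 4) {
      wt <- weights_to_table(lapply(fits, function(f) f$w_norm))
      metrics$correlations <- weight_correlations(wt)
      metrics$weight_stats <- weight_statistics(wt)[c("cone_stats",
                                                      "component_stats")]
    }
    jsonlite::write_json(metrics, file.path(config$outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    times["analyze"] <- tic() - t0
    files <- c(files, "tunings.csv", "groups.csv", "metrics.json")
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- file.path(config$outdir, "config.json")
  writeLines(cfg_json, cfg_file)
  paths <- file.path(config$outdir, files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("spectramap")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    stages = st,
    wall_times_s = as.list(times),
    checksums = as.list(stats::setNames(unname(tools::md5sum(paths)), files))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Deposit adapter ---------------------------------------------------------------

#' Default column mapping for the deposited per-ROI data layout
#'
#' Maps deposit column names onto internal field names; adjust when the
#' on-disk schema differs. The adapter never coerces silently: missing
#' columns raise a field-mapping error.
#' @return Named list `internal_name = deposit_column`.
#' @export
dryad_mapping <- function() {
  list(id = "id", region = "region", ipl_depth = "ipl_depth", qi = "qi",
       area_um2 = "area_um2")
}

#' Load a downloaded per-ROI deposit (trial-averaged responses + 16 weights)
#'
#' Reads `rois.csv` (metadata + trial-averaged trace columns `t1..tN`) and
#' `weights.csv` (16 `w_<cone>_<component>` columns) from `path`, maps the
#' columns onto the package's internal types and reports row counts per
#' region. No download is performed; the files must already be on disk.
#'
#' @param path directory containing `rois.csv` and `weights.csv`.
#' @param mapping column mapping, see [dryad_mapping()].
#' @return List with `rois` (data.frame), `traces` (matrix, one row per
#'   ROI), `weights` (data.frame, 16 columns), `report` (ROI counts per
#'   region and total).
#' @export
load_dryad_deposit <- function(path, mapping = dryad_mapping()) {
  f_rois <- file.path(path, "rois.csv")
  f_w <- file.path(path, "weights.csv")
  for (f in c(f_rois, f_w)) if (!file.exists(f))
    stop("field-mapping error: missing deposit file ", basename(f))
  rois <- utils::read.csv(f_rois)
  wt <- utils::read.csv(f_w)
  missing_cols <- setdiff(unlist(mapping), names(rois))
  if (length(missing_cols))
    stop("field-mapping error: deposit lacks columns ",
         paste(missing_cols, collapse = ", "))
  missing_w <- setdiff(weight_colnames(), names(wt))
  if (length(missing_w))
    stop("field-mapping error: weight table lacks ",
         paste(missing_w, collapse = ", "))
  if (nrow(wt) != nrow(rois))
    stop("field-mapping error: ROI and weight row counts differ")
  tr_cols <- grep("^t[0-9]+$", names(rois), value = TRUE)
  if (!length(tr_cols))
    stop("field-mapping error: no trace columns (t1..tN) found")
  meta <- stats::setNames(rois[, unlist(mapping), drop = FALSE],
                          names(mapping))
  report <- list(n_rois = nrow(rois),
                 per_region = as.list(table(meta$region)))
  list(rois = meta, traces = as.matrix(rois[, tr_cols]),
       weights = wt[, weight_colnames()], report = report)
}

#' Write ROI tables in the deposit layout (round-trip helper)
#'
#' @param rois data.frame with the internal metadata fields.
#' @param traces matrix of trial-averaged traces (rows aligned with
#'   `rois`).
#' @param weights data.frame with the 16 weight columns.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_deposit <- function(rois, traces, weights, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tr <- as.data.frame(traces)
  names(tr) <- paste0("t", seq_len(ncol(tr)))
  utils::write.csv(cbind(rois, tr), file.path(path, "rois.csv"),
                   row.names = FALSE)
  utils::write.csv(weights, file.path(path, "weights.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Thin CLI over [run_pipeline()]: `spectramap_cli(c("all", "--seed", "3",
#' "--outdir", "out"))`. Subcommands: `all` or any subset of stage names
#' joined by commas. Flags mirror config keys (`--seed`, `--outdir`,
#' `--n-rois`, `--qi-min`, `--lasso-lambda`).
#'
#' @param args character vector (default: `commandArgs(trailingOnly=TRUE)`).
#' @return The run manifest, invisibly.
#' @export
spectramap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: spectramap <all|stage[,stage...]> [flags]")
  sub <- args[1]
  stages <- if (identical(sub, "all"))
    c("simulate", "preprocess", "cluster", "decompose", "analyze")
  else strsplit(sub, ",")[[1]]
  flag <- function(name, default, cast = as.numeric) {
    i <- which(args == name)
    if (length(i) && i < length(args)) cast(args[i + 1]) else default
  }
  cfg <- pipeline_config(
    seed = flag("--seed", 1, as.integer),
    outdir = flag("--outdir", "spectramap_out", as.character),
    n_rois = flag("--n-rois", 200, as.integer),
    qi_min = flag("--qi-min", 0.4),
    lasso_lambda = {
      ll <- flag("--lasso-lambda", 1e-6, as.character)
      if (identical(ll, "cv")) "cv" else as.numeric(ll)
    },
    stages = stages)
  message("spectramap: running ", paste(stages, collapse = ", "),
          " -> ", cfg$outdir)
  run_pipeline(cfg)
}
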