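#' Write / read a parcel time-series scan
#'
#' A scan is stored as a delimited matrix (parcels x samples, tab-separated
#' by default, full double precision) plus a JSON sidecar
#' (`<basename>.json`) holding `fs`, `parcel_labels`, `scan_id` and `group`.
#'
#' @param ts a `"parcel_ts"` object.
#' @param path path of the matrix file (`.tsv` or `.csv`).
#' @param sep field separator; defaults to tab for `.tsv` and comma for
#'   `.csv`.
#' @return `write_scan` returns `path` invisibly; `read_scan` returns a
#'   `"parcel_ts"`.
#' @export
write_scan <- function(ts, path, sep = NULL) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(format(ts$data, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(fs = ts$fs, parcel_labels = ts$parcel_labels,
                            scan_id = ts$scan_id, group = ts$group),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".json")

#' @rdname write_scan
#' @param path path of the matrix file written by [write_scan()].
#' @export
read_scan <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("missing sidecar header: ", side)
  hdr <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(hdr$fs)) stop("sidecar header lacks required field 'fs'")
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  mat <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                     colClasses = "numeric"))
  dimnames(mat) <- NULL
  if (!is.null(hdr$parcel_labels) &&
      nrow(mat) != length(hdr$parcel_labels))
    stop("shape mismatch: matrix has ", nrow(mat), " rows but header lists ",
         length(hdr$parcel_labels), " parcels")
  parcel_ts(mat, fs = hdr$fs, parcel_labels = hdr$parcel_labels,
            scan_id = hdr$scan_id %||% basename(path),
            group = if (is.null(hdr$group)) NA else hdr$group)
}

#' Configuration for an end-to-end pipeline run
#'
#' Collects the stage parameters of the whole analysis.  Stage seeds are
#' derived deterministically from `seed`, so each stage is independently
#' reproducible.
#'
#' @param cohort a `"cohort_spec"` (scans are simulated) or a directory of
#'   scans written by [write_scan()] with a `manifest.json`.
#' @param band `c(lo, hi)` broadband filter applied before clustering.
#' @param n_peaks GFP peaks sampled per scan.
#' @param k fixed model order, or `NULL` for kneedle selection over
#'   `k_range`.
#' @param k_range candidate model orders.
#' @param restarts k-means restarts per k.
#' @param window_s connectivity window length (seconds).
#' @param bands connectivity bands (names from [eeg_bands()]), or `NULL` to
#'   skip the connectivity stage.
#' @param n_perm MVPA permutations (per band).
#' @param alpha significance level for group comparisons.
#' @param seed master seed.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(cohort, band = c(1, 30), n_peaks = 5000, k = NULL,
                       k_range = 2:20, restarts = 20, window_s = 5,
                       bands = names(eeg_bands()), n_perm = 100,
                       alpha = 0.05, seed = 1L) {
  structure(list(cohort = cohort, band = band, n_peaks = n_peaks, k = k,
                 k_range = k_range, restarts = restarts,
                 window_s = window_s, bands = bands, n_perm = n_perm,
                 alpha = alpha, seed = seed),
            class = "run_config")
}

log_stage <- function(log_path, stage, t0, extra = list()) {
  rec <- c(list(stage = stage,
                wall_s = round(as.numeric(Sys.time()) - t0, 3)), extra)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE)
}

#' Run the full microstate pipeline
#'
#' Executes simulate (or load) -> bandpass + GFP-peak extraction -> pooled
#' clustering with model-order selection -> backfitting -> sequence
#' statistics -> (optionally) state-segmented wPLI connectivity with MVPA ->
#' two-group comparison, writing per-stage artifacts, a line-delimited JSON
#' log, and a Markdown summary report.  Re-running with an identical config
#' reproduces identical numeric outputs.
#'
#' @param config a [run_config()] object.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the fitted `model`, per-scan `sequences`,
#'   `stats_table`, `syntax`, `mvpa` (per band, or `NULL`), `comparison`, and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  seeds <- derive_seeds(config$seed, 5L)   # simulate/peaks/cluster/mvpa/spare

  # --- stage 1: simulate or load ------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (inherits(config$cohort, "cohort_spec")) {
    spec <- config$cohort
    spec$seed <- seeds[[1]]
    cohort <- generate_cohort(spec)
    scans <- cohort$scans
    manifest <- cohort$manifest
  } else {
    man_path <- file.path(config$cohort, "manifest.json")
    if (!file.exists(man_path)) stop("no manifest.json in ", config$cohort)
    manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    scans <- lapply(manifest$scan_id, function(id)
      read_scan(file.path(config$cohort, paste0(id, ".tsv"))))
    cohort <- NULL
  }
  n <- length(scans)
  log_stage(log_path, "simulate", t0, list(n_scans = n))

  # --- stage 2: preprocessing + peak pooling ------------------------------
  t0 <- as.numeric(Sys.time())
  peak_seeds <- derive_seeds(seeds[[2]], n)
  prep <- vector("list", n)
  for (i in seq_len(n)) {
    filt <- bandpass(scans[[i]], config$band[1], config$band[2])
    prep[[i]] <- c(peak_maps(filt, n_peaks = config$n_peaks,
                             seed = peak_seeds[[i]]),
                   list(ts = filt))
  }
  pooled <- do.call(rbind, lapply(prep, `[[`, "maps"))
  pooled_gfp <- unlist(lapply(prep, `[[`, "gfp"))
  log_stage(log_path, "prep", t0, list(pooled_peaks = nrow(pooled)))

  # --- stage 3: clustering + model-order selection ------------------------
  t0 <- as.numeric(Sys.time())
  model <- microstates(pooled, k = config$k, k_range = config$k_range,
                       gfp = pooled_gfp, restarts = config$restarts,
                       seed = seeds[[3]])
  utils::write.csv(data.frame(state = seq_len(model$k), model$maps),
                   file.path(out_dir, "microstate_maps.csv"),
                   row.names = FALSE)
  if (!is.null(model$gev_curve))
    utils::write.csv(data.frame(k = model$gev_curve$k,
                                gev = model$gev_curve$gev),
                     file.path(out_dir, "gev_curve.csv"), row.names = FALSE)
  log_stage(log_path, "cluster", t0, list(k = model$k,
                                          gev = round(model$gev, 4)))

  # --- stage 4: backfit + sequence statistics -----------------------------
  t0 <- as.numeric(Sys.time())
  sequences <- lapply(seq_len(n), function(i)
    backfit(prep[[i]]$ts, model, gfp = prep[[i]]$gfp_trace))
  stats_table <- cohort_stats_table(sequences, manifest$group,
                                    manifest$scan_id)
  syntax <- lapply(sequences, transition_matrix)
  hurst <- vapply(sequences, hurst_exponent, 0)
  global_tab <- data.frame(scan_id = manifest$scan_id,
                           group = manifest$group,
                           mean_duration_ms = vapply(sequences, function(s)
                             class_stats(s)$global_mean_duration_ms, 0),
                           hurst = hurst)
  utils::write.csv(stats_table, file.path(out_dir, "class_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(global_tab, file.path(out_dir, "global_stats.csv"),
                   row.names = FALSE)
  log_stage(log_path, "stats", t0, list())

  # --- stage 5: connectivity + MVPA (pooled windows across scans) ---------
  mvpa <- NULL
  if (!is.null(config$bands)) {
    t0 <- as.numeric(Sys.time())
    feats <- list()
    labs <- list()
    for (i in seq_len(n)) {
      sc <- state_connectivity(prep[[i]]$ts, sequences[[i]],
                               bands = config$bands,
                               window_s = config$window_s)
      for (bn in names(sc$bands)) {
        feats[[bn]] <- rbind(feats[[bn]], sc$bands[[bn]]$features)
        labs[[bn]] <- c(labs[[bn]], sc$bands[[bn]]$window_state)
      }
    }
    mvpa_seeds <- derive_seeds(seeds[[4]], length(feats))
    mvpa <- list()
    for (bi in seq_along(feats)) {
      bn <- names(feats)[bi]
      mvpa[[bn]] <- permutation_test(feats[[bn]], labs[[bn]],
                                     n_perm = config$n_perm,
                                     seed = mvpa_seeds[[bi]])
    }
    mvpa_tab <- data.frame(band = names(mvpa),
                           accuracy = vapply(mvpa, `[[`, 0, "accuracy"),
                           p_value = vapply(mvpa, `[[`, 0, "p_value"))
    utils::write.csv(mvpa_tab, file.path(out_dir, "mvpa.csv"),
                     row.names = FALSE)
    log_stage(log_path, "connect", t0, list(bands = names(mvpa)))
  }

  # --- stage 6: group comparison ------------------------------------------
  t0 <- as.numeric(Sys.time())
  comparison <- compare_cohorts(stats_table, syntax = syntax,
                                syntax_group = manifest$group,
                                alpha = config$alpha)
  utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  log_stage(log_path, "compare", t0, list())

  write_report(out_dir, model, stats_table, mvpa, comparison)
  invisible(list(model = model, sequences = sequences,
                 stats_table = stats_table, syntax = syntax,
                 hurst = hurst, mvpa = mvpa, comparison = comparison,
                 cohort = cohort, out_dir = out_dir))
}

write_report <- function(out_dir, model, stats_table, mvpa, comparison) {
  path <- file.path(out_dir, "report.md")
  lines <- c("# Microstate pipeline report", "",
             sprintf("- model order k = %d, GEV = %.4f", model$k,
                     model$gev))
  if (!is.null(model$gev_curve))
    lines <- c(lines, sprintf("- kneedle-selected over k = %d..%d",
                              min(model$gev_curve$k),
                              max(model$gev_curve$k)))
  if (!is.null(mvpa)) {
    lines <- c(lines, "", "## MVPA decoding", "",
               "| Band | Accuracy | p-value |", "|---|---|---|",
               vapply(names(mvpa), function(bn)
                 sprintf("| %s | %.4f | %.4g |", bn, mvpa[[bn]]$accuracy,
                         mvpa[[bn]]$p_value), ""))
  }
  n_sig <- sum(comparison$flag_fdr, na.rm = TRUE)
  lines <- c(lines, "", "## Group comparison", "",
             sprintf("- %d of %d tests significant after FDR", n_sig,
                     nrow(comparison)),
             "- full table in comparison.csv")
  writeLines(lines, path)
  invisible(path)
}
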