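#' Run configuration for pipeline orchestration
#'
#' Bundles paths and parameters for end-to-end runs. Structure/ensemble
#' entries may be paths (read with the package readers) or in-memory
#' objects. Referenced paths are checked at run time.
#'
#' @param receptor path to a receptor PDB or a [structure3d].
#' @param ensemble_a,ensemble_b paths to pose files or [pose_ensemble]s
#'   (A = the peptide being selected, B = the comparison peptide).
#' @param consensus a [consensus_params].
#' @param grid a [grid_spec].
#' @param criteria an [interaction_criteria].
#' @param landmarks landmark residue sets for pocket naming (named list or a
#'   JSON path; `NULL` keeps numeric cavity labels).
#' @param out_dir output directory for TSV/JSON reports (`NULL`: no files).
#' @param seed seed forwarded to any randomized stage.
#' @param orientation_filter apply the N-terminus orientation criterion.
#' @param window_b energy-window the B ensemble too.
#' @return list of class `run_config`.
#' @export
run_config <- function(receptor = NULL, ensemble_a = NULL, ensemble_b = NULL,
                       consensus = consensus_params(), grid = grid_spec(),
                       criteria = interaction_criteria(), landmarks = NULL,
                       out_dir = NULL, seed = 1, orientation_filter = TRUE,
                       window_b = FALSE) {
  structure(list(receptor = receptor, ensemble_a = ensemble_a,
                 ensemble_b = ensemble_b, consensus = consensus,
                 grid = grid, criteria = criteria, landmarks = landmarks,
                 out_dir = out_dir, seed = seed,
                 orientation_filter = orientation_filter,
                 window_b = window_b),
            class = "run_config")
}

resolve_structure <- function(x, what) {
  if (inherits(x, "structure3d")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config ", what, " path does not exist: ", x)
    return(read_structure(x))
  }
  stop("config is missing ", what)
}

resolve_ensemble <- function(x, what, peptide) {
  if (inherits(x, "pose_ensemble")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config ", what, " path does not exist: ", x)
    return(read_pose_ensemble(x, peptide))
  }
  stop("config is missing ", what)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full binding-site mapping pipeline
#'
#' Executes energy-window filtering, cross-peptide consensus matching,
#' cavity detection, pose-to-pocket assignment, the N-terminus orientation
#' filter and interaction fingerprinting, and returns (optionally writes) a
#' report of selected poses per pocket with their interactions. Stage errors
#' are propagated with the stage name; when `out_dir` is set, outputs
#' produced before a failure are flushed along with a `FAILED` marker file.
#'
#' @param config a [run_config] with receptor and both ensembles.
#' @return list of class `site_mapping_report`: `matches` (consensus table
#'   with `pocket_label` and `orientation_ok`), `selected` (the rows passing
#'   all filters), `cavities`, `fingerprints` (per selected pose).
#' @export
run_site_mapping <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    config$out_dir
  } else NULL
  flush_failure <- function(e) {
    if (!is.null(out))
      writeLines(conditionMessage(e), file.path(out, "FAILED"))
    stop(e)
  }
  tryCatch({
    receptor <- stage("read_receptor",
                      resolve_structure(config$receptor, "receptor"))
    ens_a <- stage("read_ensemble_a",
                   resolve_ensemble(config$ensemble_a, "ensemble_a", "FRRFa"))
    ens_b <- stage("read_ensemble_b",
                   resolve_ensemble(config$ensemble_b, "ensemble_b",
                                    "KNFLRFa"))
    matches <- stage("match_consensus",
                     match_consensus(ens_a, ens_b, config$consensus,
                                     window_b = config$window_b))
    cavities <- stage("cavity_detection",
                      probe_accessible_cavities(receptor, config$grid,
                                                landmarks = config$landmarks))
    poses_a <- setNames(ens_a$poses,
                        vapply(ens_a$poses, `[[`, character(1), "pose_id"))
    matches$pocket_label <- NA_character_
    matches$orientation_ok <- NA
    for (k in seq_len(nrow(matches))) {
      p <- poses_a[[matches$pose_a[k]]]
      lab <- stage("pocket_assignment",
                   if (nrow(cavities)) assign_pose_pocket(p, cavities)
                   else NA_character_)
      matches$pocket_label[k] <- lab
      if (config$orientation_filter && !is.na(lab))
        matches$orientation_ok[k] <-
          stage("orientation_filter", nterm_orientation_ok(p, cavities))
    }
    sel <- matches[!is.na(matches$pocket_label) &
                     (!config$orientation_filter |
                        matches$orientation_ok %in% TRUE), , drop = FALSE]
    fps <- stage("fingerprints",
                 lapply(sel$pose_a, function(id)
                   detect_interactions(poses_a[[id]], receptor,
                                       config$criteria)))
    names(fps) <- sel$pose_a
    report <- structure(list(matches = matches, selected = sel,
                             cavities = cavities, fingerprints = fps),
                        class = "site_mapping_report")
    if (!is.null(out)) {
      write_matches_tsv(matches, file.path(out, "consensus_matches.tsv"))
      write_cavities_tsv(cavities, file.path(out, "cavities.tsv"))
      write_fingerprints_tsv(fps, file.path(out, "fingerprints.tsv"))
      jsonlite::write_json(
        list(n_matches = nrow(matches), n_selected = nrow(sel),
             pockets = as.list(table(sel$pocket_label))),
        file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
    }
    report
  }, error = flush_failure)
}

#' Run the electrophysiology analysis pipeline
#'
#' Computes per-cell trace metrics from trace CSVs (when given), fits SSD /
#' dose-response / kinetic series per genotype (when given), and classifies
#' each mutant against wild type. Any subset of inputs may be supplied; the
#' comparison section requires `replicates` with a `"WT"` entry and at least
#' one mutant.
#'
#' @param replicates named list of per-cell replicate tables (see
#'   [compare_modulation]); the entry named `"WT"` is the reference.
#' @param trace_files optional data.frame with columns `csv`, `protocol`
#'   (file paths) and optionally `genotype`.
#' @param ssd_series optional named list (per genotype) of data.frames with
#'   columns `pH`, `I` for [fit_ssd].
#' @param dose_series optional named list of data.frames with columns
#'   `conc`, `ratio` for [fit_dose_response].
#' @param alpha significance level for the comparison symbols.
#' @param out_dir optional output directory for TSV/JSON reports.
#' @return list of class `ephys_report` with elements `metrics`,
#'   `ssd_fits`, `dose_fits`, `comparison` (those that apply).
#' @export
run_ephys <- function(replicates = NULL, trace_files = NULL,
                      ssd_series = NULL, dose_series = NULL, alpha = 0.05,
                      out_dir = NULL) {
  report <- list()
  if (!is.null(trace_files)) {
    report$metrics <- stage("trace_metrics", {
      rows <- lapply(seq_len(nrow(trace_files)), function(k) {
        tr <- read_trace_csv(trace_files$csv[k], trace_files$protocol[k])
        m <- trace_metrics(tr)
        data.frame(file = basename(trace_files$csv[k]),
                   genotype = if (!is.null(trace_files$genotype))
                     trace_files$genotype[k] else NA_character_,
                   i_peak = m$i_peak, i_sust = m$i_sust, ratio = m$ratio,
                   usable = m$usable, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
  }
  if (!is.null(ssd_series))
    report$ssd_fits <- stage("ssd_fits",
                             lapply(ssd_series, function(d)
                               fit_ssd(d$pH, d$I)))
  if (!is.null(dose_series))
    report$dose_fits <- stage("dose_response_fits",
                              lapply(dose_series, function(d)
                                fit_dose_response(d$conc, d$ratio)))
  if (!is.null(replicates)) {
    if (!"WT" %in% names(replicates))
      stop("[stage comparison] replicates must contain a 'WT' entry")
    muts <- replicates[setdiff(names(replicates), "WT")]
    if (length(muts) > 0L)
      report$comparison <- stage("comparison",
                                 compare_modulation(replicates$WT, muts,
                                                    alpha = alpha))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$metrics))
      write.table(report$metrics, file.path(out_dir, "trace_metrics.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$comparison))
      write.table(report$comparison, file.path(out_dir, "comparison.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    fitjson <- list()
    if (!is.null(report$ssd_fits))
      fitjson$ssd <- lapply(report$ssd_fits, function(f)
        list(pHD50 = f$pHD50, nH = f$nH, Imax = f$Imax))
    if (!is.null(report$dose_fits))
      fitjson$dose_response <- lapply(report$dose_fits, function(f)
        list(EC50 = f$EC50, hill = f$hill, r_max = f$r_max, r_0 = f$r_0))
    if (length(fitjson))
      jsonlite::write_json(fitjson, file.path(out_dir, "fits.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  class(report) <- "ephys_report"
  report
}
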