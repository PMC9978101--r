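#' Pipeline run configuration
#'
#' All defaults are the analysis's reference values: discard 10 initial
#' volumes; scrub at FD > 0.2 mm; exclude below 3 min surviving scan time
#' or above 2 mm translation / 2 degrees rotation; bandpass 0.01-0.08 Hz;
#' sparsity sweep 0.05-0.40 in steps of 0.01 with reporting sparsity
#' 0.30; alpha 0.05 with age, sex, education and mean FD as covariates.
#'
#' @param ts_dir,rp_dir,phenotype_file input locations (may be NULL when
#'   the pipeline runs on an in-memory cohort).
#' @param out_dir output directory.
#' @param n_discard,fd_threshold,min_minutes,trans_limit_mm,rot_limit_deg
#'   preprocessing parameters.
#' @param low_hz,high_hz bandpass edges.
#' @param s_min,s_max,s_step sparsity sweep.
#' @param report_sparsity reporting threshold.
#' @param alpha significance level.
#' @param covariates covariate names for the adjusted group tests.
#' @param seed integer seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(ts_dir = NULL, rp_dir = NULL, phenotype_file = NULL,
                       out_dir = "dcnet-out", n_discard = 10L,
                       fd_threshold = 0.2, min_minutes = 3,
                       trans_limit_mm = 2, rot_limit_deg = 2,
                       low_hz = 0.01, high_hz = 0.08,
                       s_min = 0.05, s_max = 0.40, s_step = 0.01,
                       report_sparsity = 0.30, alpha = 0.05,
                       covariates = c("age", "sex", "education", "mean_fd"),
                       seed = 1L) {
  cfg <- list(ts_dir = ts_dir, rp_dir = rp_dir,
              phenotype_file = phenotype_file, out_dir = out_dir,
              n_discard = as.integer(n_discard),
              fd_threshold = fd_threshold, min_minutes = min_minutes,
              trans_limit_mm = trans_limit_mm,
              rot_limit_deg = rot_limit_deg, low_hz = low_hz,
              high_hz = high_hz, s_min = s_min, s_max = s_max,
              s_step = s_step, report_sparsity = report_sparsity,
              alpha = alpha, covariates = covariates,
              seed = as.integer(seed))
  stopifnot(cfg$fd_threshold > 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$s_min > 0, cfg$s_max < 1, cfg$s_min <= cfg$s_max,
            cfg$low_hz < cfg$high_hz)
  structure(cfg, class = "run_config")
}

#' Write a synthetic cohort to disk
#'
#' One tab-separated time-series file per subject (T rows x g columns, no
#' header), one SPM-dialect realignment file per subject (6 whitespace-
#' separated columns: x y z in mm, then pitch roll yaw in radians), a
#' phenotype CSV (subject_id, group, age, sex, education, bdi, hamd) and
#' a ground-truth JSON sidecar for test harnesses.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    # full double precision so a write -> read round trip is exact
    utils::write.table(
      matrix(formatC(s$series, digits = 17, format = "g"),
             nrow(s$series)),
      file.path(dir, paste0(s$subject_id, "_ts.tsv")),
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(
      matrix(formatC(s$realignment, digits = 17, format = "g"),
             nrow(s$realignment)),
      file.path(dir, paste0(s$subject_id, "_rp.txt")),
      sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  utils::write.csv(cohort_phenotype(cohort),
                   file.path(dir, "phenotype.csv"), row.names = FALSE)
  truth <- list(
    affected_nodes = cohort$truth$affected_nodes,
    effects = lapply(cohort$truth$effects, function(e)
      list(group = e$group, hub_node = e$hub_node,
           partner_count = e$partner_count, delta_r = e$delta_r)))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a ROI time-series file
#'
#' @param path tab-separated file, T rows x g columns, no header.
#' @param g expected column count (optional cross-check).
#' @return numeric matrix.
#' @export
read_series <- function(path, g = NULL) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  if (!is.numeric(m))
    stop("non-numeric cells in time-series file: ", path)
  if (!is.null(g) && ncol(m) != g)
    stop(sprintf("%s: expected %d columns, found %d", path, g, ncol(m)))
  dimnames(m) <- NULL
  m
}

#' Read an SPM-dialect realignment-parameter file
#'
#' @param path whitespace-separated file with exactly 6 columns
#'   (x y z translations in mm, then pitch roll yaw rotations in radians).
#' @return T x 6 numeric matrix.
#' @export
read_rp <- function(path) {
  if (!file.exists(path)) stop("realignment file not found: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop(sprintf("%s: realignment files use the 6-column rp dialect, found %d columns",
                 path, ncol(m)))
  if (!is.numeric(m)) stop("non-numeric cells in realignment file: ", path)
  dimnames(m) <- NULL
  m
}

#' Read a phenotype table
#'
#' @param path CSV with header subject_id, group, age, sex, education and
#'   optionally bdi, hamd.
#' @param subject_ids optional ids that must all be present.
#' @return data.frame.
#' @export
read_phenotype <- function(path, subject_ids = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex", "education")
  missing_cols <- setdiff(required, names(ph))
  if (length(missing_cols))
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(subject_ids)) {
    absent <- setdiff(subject_ids, ph$subject_id)
    if (length(absent))
      stop("phenotype table lacks subject(s): ",
           paste(absent, collapse = ", "))
  }
  ph
}

#' Read a cohort from disk
#'
#' Counterpart of [write_cohort()]: loads every subject listed in the
#' phenotype table from `<id>_ts.tsv` and `<id>_rp.txt`.
#'
#' @param dir directory written by [write_cohort()] (or following the
#'   same layout).
#' @param tr_seconds repetition time of the data.
#' @param g expected node count (optional check).
#' @return a `cohort`-like list (subjects, spec with tr_seconds, truth if
#'   the ground-truth sidecar exists).
#' @export
read_cohort <- function(dir, tr_seconds = 2.5, g = NULL) {
  ph <- read_phenotype(file.path(dir, "phenotype.csv"))
  subjects <- lapply(seq_len(nrow(ph)), function(i) {
    id <- ph$subject_id[i]
    series <- read_series(file.path(dir, paste0(id, "_ts.tsv")), g)
    rp <- read_rp(file.path(dir, paste0(id, "_rp.txt")))
    if (nrow(rp) != nrow(series))
      stop(id, ": realignment rows do not match series rows")
    structure(list(subject_id = id, group = ph$group[i], age = ph$age[i],
                   sex = ph$sex[i], education = ph$education[i],
                   bdi = if ("bdi" %in% names(ph)) ph$bdi[i] else NA_real_,
                   hamd = if ("hamd" %in% names(ph)) ph$hamd[i] else NA_real_,
                   series = series, realignment = rp),
              class = "subject_record")
  })
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(subjects = subjects, truth = truth,
                 spec = list(tr_seconds = tr_seconds,
                             g = ncol(subjects[[1]]$series),
                             n_volumes = nrow(subjects[[1]]$series))),
            class = "cohort")
}

#' Run the full analysis pipeline
#'
#' Preprocessing, degree-centrality tables, node-wise group inference,
#' post-hoc pairwise comparisons, and ROC discrimination, on either an
#' in-memory cohort or the files named in the config. Writes the
#' motion-QC table, the DC table, node statistics, per-comparison ROC
#' reports and a JSON manifest into `config$out_dir`. Re-running with
#' identical inputs and config reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @param cohort optional in-memory `cohort`; when NULL the cohort is
#'   read from the configured paths.
#' @return invisibly, a list: qc, dc, pheno, anova, posthoc, roc,
#'   demographics, manifest.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    if (is.null(config$ts_dir))
      stop("run_pipeline needs either a cohort or configured input paths")
    cohort <- read_cohort(config$ts_dir)
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  prep <- prep_cohort(cohort,
                      n_discard = config$n_discard,
                      fd_threshold = config$fd_threshold,
                      min_minutes = config$min_minutes,
                      trans_limit_mm = config$trans_limit_mm,
                      rot_limit_deg = config$rot_limit_deg,
                      low_hz = config$low_hz, high_hz = config$high_hz)
  utils::write.csv(prep$qc, file.path(out, "motion_qc.csv"),
                   row.names = FALSE)
  if (length(prep$clean) == 0L)
    stop("prep stage: every subject was excluded; nothing to analyse")

  dc <- build_dc_table(prep$clean, sparsity = config$report_sparsity)
  utils::write.table(dc, file.path(out, "dc_table.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)

  pheno <- cohort_phenotype(cohort)
  pheno <- pheno[match(rownames(dc), pheno$subject_id), , drop = FALSE]
  pheno$mean_fd <- prep$qc$mean_fd[match(rownames(dc), prep$qc$subject_id)]

  demo <- demographic_tests(pheno)
  utils::write.csv(demo, file.path(out, "demographics.csv"),
                   row.names = FALSE)

  anova_res <- nodewise_anova(dc, pheno, alpha = config$alpha,
                              covariates = config$covariates)
  utils::write.table(anova_res, file.path(out, "nodewise_anova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig_nodes <- anova_res$node[anova_res$significant]

  pairs <- list(c("MDD", "HC"), c("SD", "HC"), c("MDD", "SD"))
  posthoc <- list()
  rocs <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "_vs_")
    ph_res <- posthoc_pairwise(dc, pheno, pr, sig_nodes,
                               alpha = config$alpha,
                               covariates = config$covariates)
    posthoc[[key]] <- ph_res
    utils::write.table(ph_res, file.path(out, paste0("posthoc_", key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    flagged <- ph_res$node[ph_res$significant]
    if (length(flagged) >= 1L) {
      rr <- roc_report(dc, pheno, pr, flagged)
      rocs[[key]] <- rr
      utils::write.csv(rr$table, file.path(out, paste0("roc_", key, ".csv")),
                       row.names = FALSE)
    }
  }

  manifest <- list(
    seed = config$seed,
    parameters = unclass(config)[c(
      "n_discard", "fd_threshold", "min_minutes", "trans_limit_mm",
      "rot_limit_deg", "low_hz", "high_hz", "s_min", "s_max", "s_step",
      "report_sparsity", "alpha", "covariates")],
    counts = list(
      subjects_in = length(cohort$subjects),
      subjects_retained = nrow(dc),
      excluded = sum(prep$qc$excluded),
      nodes = ncol(dc),
      anova_significant = length(sig_nodes),
      posthoc_significant = lapply(posthoc, function(x) sum(x$significant)),
      auc = lapply(rocs, function(x)
        stats::setNames(x$table$auc, x$table$index))),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(qc = prep$qc, dc = dc, pheno = pheno, anova = anova_res,
                 posthoc = posthoc, roc = rocs, demographics = demo,
                 manifest = manifest))
}
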