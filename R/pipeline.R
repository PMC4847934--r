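# Stage orchestration: localizer -> pattern extraction -> decoding ->
# group inference -> report.

#' Group functional localizer over a cohort
#'
#' Per subject: spatial smoothing, first-level GLM (task-condition epochs
#' convolved with the canonical HRF, six motion regressors, intercept;
#' fixation implicit), contrast of encoding > baseline. The per-subject
#' contrast maps enter a second-level one-sample t-test, thresholded
#' voxelwise at the familywise-error-corrected level with a cluster extent
#' filter, and each surviving cluster peak is wrapped in a 15-mm sphere ROI.
#'
#' @param subjects List of `synthetic_subject`s (full 4D images).
#' @param fwhm_mm Smoothing kernel FWHM (localizer path only; the MVPA path
#'   consumes unsmoothed data).
#' @param alpha_fwe,k_min,connectivity Cluster thresholding parameters (see
#'   [threshold_clusters()]).
#' @param radius_mm Sphere ROI radius.
#' @return List with `statmap`, `clusters`, `cluster_table`, and `rois`
#'   (named `roi_mask` list, `"roi_1"` at the strongest peak).
#' @export
localize_cohort <- function(subjects, fwhm_mm = 8, alpha_fwe = 0.05,
                            k_min = 20L, connectivity = 26L,
                            radius_mm = 15) {
  acq <- subjects[[1]]$truth$acquisition
  maps <- lapply(subjects, function(s) {
    sm <- smooth_gaussian(s$image, fwhm_mm, acq$voxel_mm)
    des <- make_design(s$events, acq, s$motion)
    fit <- fit_glm(sm, des, contrast_vector(des, "encoding"))
    fit$beta_contrast
  })
  statmap <- group_ttest(maps)
  clusters <- threshold_clusters(statmap, alpha_fwe, k_min, connectivity)
  rois <- lapply(clusters, function(cl)
    sphere_roi(cl$peak_voxel, radius_mm, acq$voxel_mm, acq$grid_dims))
  names(rois) <- if (length(rois)) paste0("roi_", seq_along(rois)) else
    character(0)
  list(statmap = statmap, clusters = clusters,
       cluster_table = cluster_table(clusters), rois = rois)
}

#' MVPA of one subject in one ROI
#'
#' Extracts the vocabulary and encoding block patterns (with hemodynamic-lag
#' exclusion) and computes the within-vocabulary d-prime and the
#' cross-decoded reactivation proportion.
#'
#' @param image 4D array or ROI matrix (see [extract_block_patterns()]).
#' @param events Events table.
#' @param roi A `roi_mask`.
#' @param acquisition An [acq_params()].
#' @param lag_exclude_s Lag exclusion in seconds (applied to vocabulary and
#'   encoding blocks alike).
#' @param cost_C SVM cost.
#' @param encoding_scope `"all"` uses every paired-associates encoding epoch
#'   (both distractor-task conditions and immediate recall);
#'   `"distractor_only"` restricts to the distractor-task conditions.
#' @param threshold Cross-decoding threshold mode (see [cross_decode()]).
#' @return List with `dprime` (from [subject_dprime()]) and `decoding`
#'   (a `subject_decoding`).
#' @export
analyze_subject_roi <- function(image, events, roi,
                                acquisition = acq_params(),
                                lag_exclude_s = 10, cost_C = 1,
                                encoding_scope = c("all", "distractor_only"),
                                threshold = "baseline") {
  encoding_scope <- match.arg(encoding_scope)
  vocab <- extract_block_patterns(image, events, roi,
                                  c("vocab_distractor", "vocab_independent"),
                                  lag_exclude_s, acquisition)
  enc_events <- events[events$trial_type == "encoding", , drop = FALSE]
  if (encoding_scope == "distractor_only")
    enc_events <- enc_events[grepl("^distractor", enc_events$condition_tag), ,
                             drop = FALSE]
  enc <- extract_block_patterns(image, enc_events, roi, "encoding",
                                lag_exclude_s, acquisition)
  list(dprime = subject_dprime(vocab, cost_C),
       decoding = cross_decode(vocab, enc, cost_C, threshold))
}

#' Fast replicate study of the reactivation analysis
#'
#' Simulates a cohort restricted to the planted pattern sphere (identical in
#' law to the full 4D simulation in that ROI), runs the MVPA per subject,
#' and performs the two group tests: one-tailed Wilcoxon signed-rank on
#' d-prime (> 0) and on the cross-decoding proportion (> 0.5). This is the
#' path used for calibration and power studies, where the localizer stage
#' (validated separately) would only re-derive the same sphere.
#'
#' @param config A [sim_config()].
#' @param lag_exclude_s,cost_C,threshold Analysis parameters.
#' @param compute_dprime If `FALSE`, skip the within-vocabulary d-prime
#'   folds and compute only the cross-decoding proportions (used by large
#'   replicate studies of the reactivation test alone).
#' @return List with `dprimes` (or `NULL`), `proportions` (per subject),
#'   `wilcoxon_dprime` (or `NULL`), `wilcoxon_reactivation` (both
#'   `group_result`), `decodings` (per-subject `subject_decoding`s).
#' @export
reactivation_study <- function(config, lag_exclude_s = 10, cost_C = 1,
                               threshold = "baseline",
                               compute_dprime = TRUE) {
  roi <- pattern_roi(config)
  sessions <- simulate_cohort(config, roi_only = TRUE)
  if (compute_dprime) {
    res <- lapply(sessions, function(s)
      analyze_subject_roi(s$mat, s$events, roi, config$acquisition,
                          lag_exclude_s, cost_C, threshold = threshold))
    dprimes <- vapply(res, function(r) r$dprime$dprime_mean, numeric(1))
    decodings <- lapply(res, `[[`, "decoding")
  } else {
    decodings <- lapply(sessions, function(s) {
      vocab <- extract_block_patterns(
        s$mat, s$events, roi, c("vocab_distractor", "vocab_independent"),
        lag_exclude_s, config$acquisition)
      enc <- extract_block_patterns(s$mat, s$events, roi, "encoding",
                                    lag_exclude_s, config$acquisition)
      cross_decode(vocab, enc, cost_C, threshold)
    })
    dprimes <- NULL
  }
  props <- vapply(decodings, `[[`, numeric(1),
                  "encoding_distractor_proportion")
  list(dprimes = dprimes, proportions = props,
       wilcoxon_dprime = if (compute_dprime)
         wilcoxon_signed_rank(dprimes, 0, "greater"),
       wilcoxon_reactivation = wilcoxon_signed_rank(props, 0.5, "greater"),
       decodings = decodings)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' simulate -> localize -> extract -> decode -> infer. Subjects are
#' simulated as full 4D volumes; the group localizer defines sphere ROIs;
#' every ROI is analysed with the within-vocabulary d-prime MVPA; ROIs with
#' above-chance discrimination (one-tailed Wilcoxon on d-prime at `alpha`)
#' are gated into the second analysis, the cross-decoding reactivation test
#' against the 50% chance level, and the temporal-proximity control.
#' Behavioural comparisons are always included.
#'
#' @param config A [sim_config()].
#' @param fwhm_mm,alpha_fwe,k_min Localizer parameters.
#' @param lag_exclude_s,cost_C,encoding_scope,threshold MVPA parameters.
#' @param alpha Gating level for the first multivariate analysis.
#' @param radius_mm Sphere radius for the localizer-peak ROIs.
#' @param extra_rois Named list of additional `roi_mask`s analysed alongside
#'   the localizer ROIs (e.g. anatomically defined masks loaded with
#'   [load_mask()], mirroring post-hoc anatomical ROI analyses).
#' @return A `group_report` list (see [write_report()]).
#' @export
run_experiment <- function(config, fwhm_mm = 8, alpha_fwe = 0.05,
                           k_min = 20L, lag_exclude_s = 10, cost_C = 1,
                           encoding_scope = "all", threshold = "baseline",
                           alpha = 0.05, radius_mm = 15,
                           extra_rois = list()) {
  subjects <- simulate_cohort(config)
  loc <- localize_cohort(subjects, fwhm_mm, alpha_fwe, k_min,
                         radius_mm = radius_mm)
  all_rois <- c(loc$rois, extra_rois)
  if (!length(all_rois)) stop("localizer found no clusters: no ROIs to analyse")

  roi_results <- lapply(names(all_rois), function(rn) {
    roi <- all_rois[[rn]]
    res <- lapply(subjects, function(s)
      analyze_subject_roi(s$image, s$events, roi, config$acquisition,
                          lag_exclude_s, cost_C, encoding_scope, threshold))
    dprimes <- vapply(res, function(r) r$dprime$dprime_mean, numeric(1))
    wd <- wilcoxon_signed_rank(dprimes, 0, "greater")
    list(roi_name = rn, roi = roi, dprimes = dprimes,
         wilcoxon_dprime = wd,
         decodings = lapply(res, `[[`, "decoding"))
  })
  names(roi_results) <- names(all_rois)

  # gate: only ROIs with above-chance discrimination enter the second
  # (reactivation) analysis
  gated <- Filter(function(rr) rr$wilcoxon_dprime$p_value <= alpha,
                  roi_results)
  for (rn in names(roi_results)) {
    rr <- roi_results[[rn]]
    rr$gated <- rn %in% names(gated)
    if (rr$gated) {
      props <- vapply(rr$decodings, `[[`, numeric(1),
                      "encoding_distractor_proportion")
      rr$proportions <- props
      rr$wilcoxon_reactivation <- wilcoxon_signed_rank(props, 0.5, "greater")
      ps <- proximity_series(rr$decodings)
      # a saturated (constant) series carries no temporal gradient to test
      rr$proximity_pooled <- tryCatch(
        proximity_test(ps$volume_index, ps$proportion),
        error = function(e) NULL)
      rr$proximity_by_subject <- tryCatch(
        proximity_subject_test(
          subject_volume_series(rr$decodings),
          sort(unique(rr$decodings[[1]]$volume_index))),
        error = function(e) NULL)
    }
    roi_results[[rn]] <- rr
  }

  behavior <- do.call(rbind, lapply(subjects, `[[`, "behavior"))
  group_report(roi_results, behavioral_compare(behavior), loc, config,
               params = list(fwhm_mm = fwhm_mm, alpha_fwe = alpha_fwe,
                             k_min = k_min, lag_exclude_s = lag_exclude_s,
                             cost_C = cost_C,
                             encoding_scope = encoding_scope,
                             threshold = threshold, alpha = alpha))
}

#' Assemble the final group report
#'
#' @param roi_results Per-ROI analysis results (see [run_experiment()]).
#' @param behavioral Output of [behavioral_compare()].
#' @param localizer Output of [localize_cohort()] (or `NULL`).
#' @param config The `sim_config` used (echoed for provenance).
#' @param params Analysis parameter list (echoed).
#' @return A `group_report` list.
#' @export
group_report <- function(roi_results, behavioral, localizer = NULL,
                         config = NULL, params = list()) {
  if (!length(roi_results)) stop("no ROIs analysed")
  roi_rows <- do.call(rbind, lapply(roi_results, function(rr) {
    data.frame(
      roi = rr$roi_name,
      dprime_mean = mean(rr$dprimes),
      dprime_z = rr$wilcoxon_dprime$statistic_z,
      dprime_p = rr$wilcoxon_dprime$p_value,
      gated = isTRUE(rr$gated),
      proportion_mean = if (isTRUE(rr$gated)) mean(rr$proportions) else NA,
      reactivation_z = if (isTRUE(rr$gated))
        rr$wilcoxon_reactivation$statistic_z else NA,
      reactivation_p = if (isTRUE(rr$gated))
        rr$wilcoxon_reactivation$p_value else NA,
      proximity_r_pooled = if (isTRUE(rr$gated) &&
                                 !is.null(rr$proximity_pooled))
        rr$proximity_pooled$r else NA,
      proximity_p_pooled = if (isTRUE(rr$gated) &&
                                 !is.null(rr$proximity_pooled))
        rr$proximity_pooled$p_one_tailed_positive else NA)
  }))
  rownames(roi_rows) <- NULL
  structure(list(
    roi_table = roi_rows,
    roi_results = roi_results,
    behavioral = behavioral,
    cluster_table = if (!is.null(localizer)) localizer$cluster_table,
    config_echo = if (!is.null(config)) config_echo(config),
    params = params,
    seed = if (!is.null(config)) config$seed), class = "group_report")
}

# compact, JSON-serialisable echo of a sim_config
config_echo <- function(config) {
  list(tr_s = config$acquisition$tr_s,
       n_volumes = config$acquisition$n_volumes,
       voxel_mm = config$acquisition$voxel_mm,
       grid_dims = config$acquisition$grid_dims,
       order_id = config$order_id, baseline = config$baseline,
       beta_enc = config$beta_enc, a_voc = config$a_voc, rho = config$rho,
       noise_sd = config$noise_sd, ar1_phi = config$ar1_phi,
       drift_slope = config$drift_slope, seed = config$seed,
       n_subjects = config$n_subjects,
       p_distractor = config$p_distractor,
       p_immediate = config$p_immediate, p_vocab = config$p_vocab)
}

#' Write a group report to disk
#'
#' Emits `report.json` (machine readable, with config echo and seed),
#' `report.tsv` (per-ROI rows) and `behavioral.tsv`.
#'
#' @param report A `group_report`.
#' @param out_dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(out_dir, "report.json")
  payload <- list(
    seed = report$seed,
    config = report$config_echo,
    params = report$params,
    rois = report$roi_table,
    clusters = report$cluster_table,
    behavioral = report$behavioral$rows,
    chance_pairs = report$behavioral$chance_pairs)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  tsv_path <- file.path(out_dir, "report.tsv")
  write_tsv(report$roi_table, tsv_path)
  beh_path <- file.path(out_dir, "behavioral.tsv")
  write_tsv(report$behavioral$rows, beh_path)
  invisible(c(json = json_path, tsv = tsv_path, behavioral = beh_path))
}
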