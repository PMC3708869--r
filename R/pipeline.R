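#' TF regulatory-score feature sets from signal tracks
#'
#' Computes, for each track, the characteristic binding profile over the
#' training TSSs and the TIP regulatory scores of every TSS in `score_tss`
#' (default: the profile TSSs themselves).
#'
#' @param tracks named list of [signal_track()] objects.
#' @param tss TSS data.frame used to build the profiles.
#' @param score_tss TSS data.frame to score (default `tss`).
#' @param h TIP half-width in bp.
#' @return named list of named numeric score vectors, one per track.
#' @export
tip_feature_sets <- function(tracks, tss, score_tss = tss, h = 5000) {
  lapply(tracks, function(tr) {
    prof <- characteristic_profile(tr, tss, h = h)
    regulatory_scores(prof, tr, score_tss)
  })
}

#' Average-signal feature sets from signal tracks
#'
#' The unweighted 2 kb-window comparator to [tip_feature_sets()].
#'
#' @inheritParams tip_feature_sets
#' @param half_width window half-width in bp (default 1000).
#' @return named list of named numeric score vectors.
#' @export
avg_signal_feature_sets <- function(tracks, tss, half_width = 1000) {
  lapply(tracks, function(tr) average_signals(tr, tss, half_width))
}

#' Run the full pipeline on a config
#'
#' Orchestrates simulate (optional) -> TIP scoring -> motif scanning ->
#' feature assembly -> cross-validated Random Forest -> genome-wide TSS
#' prediction with artificial-TSS empirical FDR, writing TSV/JSON artifacts
#' and a manifest into `out_dir`. Deterministic given the seeds in `config`.
#'
#' @param config list with elements (all optional unless noted): `sim` (a
#'   [sim_config()] or its argument list; required for now — the pipeline runs
#'   on simulated data), `h` (TIP half-width, default 1000 at simulation
#'   scale), `upstream` (promoter bp, default 1000), `k` (CV folds, 10),
#'   `ntree` (trees, 200), `threshold` (prediction threshold, 0.7), `n_random`
#'   (artificial TSS count, 2000), `seed` (master seed, 1).
#' @param out_dir artifact directory (created).
#' @return invisible list with the main results: `cv` (per-model `cv_result`),
#'   `fdr` (threshold summary), `category` (per-category table), paths of
#'   written artifacts.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("cyclescan_run")) {
  cfg <- modifyList(list(h = 1000, upstream = 1000, k = 10, ntree = 200,
                         threshold = 0.7, n_random = 2000, seed = 1),
                    config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_line <- function(...) message("[cyclescan] ", ...)

  sim <- cfg$sim
  if (is.null(sim)) sim <- sim_config(seed = cfg$seed)
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  log_line("simulating bundle (seed ", sim$seed, ")")
  bundle <- simulate_cycle_data(sim)

  log_line("TIP scoring ", length(bundle$tracks), " tracks at h = ", cfg$h)
  reg_sets <- tip_feature_sets(bundle$tracks, bundle$tss, h = cfg$h)

  log_line("scanning promoters with ", length(bundle$pfms), " matrices")
  proms <- promoter_sequences(bundle$genome, bundle$tss,
                              upstream = cfg$upstream)
  names(proms) <- bundle$tss$gene_id
  B <- motif_score_matrix(proms, bundle$pfms)

  labels <- setNames(as.integer(bundle$tss$label == "cell_cycle"),
                     bundle$tss$gene_id)
  tables <- list(
    tf = build_feature_table(reg_sets, NULL, labels, "tf"),
    motif = build_feature_table(NULL, B, labels, "motif"),
    both = build_feature_table(reg_sets, B, labels, "both"))

  cv <- lapply(names(tables), function(m) {
    log_line("cross-validating ", m, " model")
    cross_validate(tables[[m]], k = cfg$k, seed = cfg$seed, ntree = cfg$ntree)
  })
  names(cv) <- names(tables)
  metrics <- data.frame(model = names(cv),
                        auc = vapply(cv, function(x) x$auc, 0),
                        auc_rank = vapply(cv, function(x) x$auc_rank, 0))
  write.table(metrics, file.path(out_dir, "cv_metrics.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  log_line("training final model and scoring random TSS controls")
  fit <- cycle_forest(tables$both, ntree = cfg$ntree, nperm = 0,
                      seed = cfg$seed)
  rand <- random_tss(bundle$chrom_lengths, n = cfg$n_random,
                     seed = cfg$seed + 7)
  rand_reg <- lapply(names(bundle$tracks), function(id) {
    prof <- characteristic_profile(bundle$tracks[[id]], bundle$tss, h = cfg$h)
    regulatory_scores(prof, bundle$tracks[[id]], rand)
  })
  names(rand_reg) <- names(bundle$tracks)
  rand_proms <- promoter_sequences(bundle$genome, rand,
                                   upstream = cfg$upstream)
  names(rand_proms) <- rand$gene_id
  rand_B <- motif_score_matrix(rand_proms, bundle$pfms)
  rand_tab <- build_feature_table(rand_reg, rand_B,
                                  setNames(rep(0L, nrow(rand)), rand$gene_id))
  real_pred <- predict_tss(fit, tables$both$X, bundle$tss)
  rand_pred <- predict_tss(fit, rand_tab$X, rand)

  fdr <- empirical_fdr(real_pred$prob, rand_pred$prob, cfg$threshold)
  curve <- fdr_curve(real_pred$prob, rand_pred$prob)
  catsum <- category_summary(real_pred, cfg$threshold)
  write.table(curve, file.path(out_dir, "fdr_curve.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(catsum, file.path(out_dir, "category_summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  imp <- importance(fit)
  write.table(imp, file.path(out_dir, "importance.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cyclescan")),
    seed = cfg$seed, sim_seed = sim$seed, h = cfg$h, k = cfg$k,
    ntree = cfg$ntree, threshold = cfg$threshold, n_random = cfg$n_random,
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    metrics = metrics, fdr = fdr[c("threshold", "f_real", "f_rand", "fdr")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done in ", round(manifest$wall_time_sec, 1), " s -> ", out_dir)
  invisible(list(bundle = bundle, tables = tables, cv = cv, fit = fit,
                 fdr = fdr, fdr_curve = curve, category = catsum,
                 importance = imp, out_dir = out_dir))
}
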