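## End-to-end orchestration: QC -> sex split -> per-sex ranking, sweep,
## smoothed ROC, leave-one-out CV -> overlap replication between the two
## sexes' top lists. All artifacts land in a write-once run directory
## together with a JSON manifest (package version, configuration, seeds,
## output checksums).

#' Pipeline run configuration
#'
#' @param input Input: a [genotype_dataset()], a PLINK prefix, or a path
#'   to the text genotype dialect.
#' @param out_dir Output directory; must not already contain files.
#' @param max_missing_rate,min_maf,hwe_alpha,window,step,vif_threshold
#'   QC parameters (defaults 0.10, 0.01, 1e-3, 50, 5, 2.0).
#' @param percentile Control-score percentile (default 95).
#' @param grid Variant-count grid for the sweep (clipped to availability).
#' @param loocv_n_variants Variants per LOO fold (clipped; default 50).
#' @param replic2_k Top-list size for the between-sex overlap test
#'   (clipped; default 50).
#' @param replic2_reps Monte-Carlo replicates (default 100000).
#' @param seed Integer seed for stochastic stages; recorded in the
#'   manifest.
#' @param prune Run LD pruning during QC (default TRUE).
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir, max_missing_rate = 0.10,
                       min_maf = 0.01, hwe_alpha = 1e-3, window = 50,
                       step = 5, vif_threshold = 2.0, percentile = 95,
                       grid = default_variant_grid(),
                       loocv_n_variants = 50, replic2_k = 50,
                       replic2_reps = 100000, seed = 1, prune = TRUE) {
  structure(list(input = input, out_dir = out_dir,
                 max_missing_rate = max_missing_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, window = window, step = step,
                 vif_threshold = vif_threshold, percentile = percentile,
                 grid = grid, loocv_n_variants = loocv_n_variants,
                 replic2_k = replic2_k, replic2_reps = replic2_reps,
                 seed = seed, prune = prune),
            class = "run_config")
}

load_dataset_input <- function(input) {
  if (inherits(input, "genotype_dataset")) return(input)
  if (file.exists(paste0(input, ".bed"))) return(read_plink(input))
  if (file.exists(input)) return(read_geno_text(input))
  stop("input not found: ", input)
}

#' Run the full sex-stratified PRS pipeline
#'
#' Stages: variant QC on the combined cohort; split into male and female
#' datasets; per sex, odds-ratio ranking, the variant-count sweep with
#' smoothed ROC and AUC, and leave-one-out cross-validation; finally the
#' Monte-Carlo overlap replication test between the two sexes' top-k
#' variant lists. Each stage's tables are written as TSV (JSON for the
#' overlap test) under `config$out_dir`, plus `manifest.json`.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (a list).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (dir.exists(out) && length(list.files(out)) > 0) {
    stop("output directory is not empty (runs are write-once): ", out)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  msg <- function(...) message("[prspredict] ", ...)

  ds <- load_dataset_input(config$input)
  msg("loaded ", n_samples(ds), " samples x ", n_variants(ds), " variants")

  qc <- run_qc(ds, max_missing_rate = config$max_missing_rate,
               min_maf = config$min_maf, hwe_alpha = config$hwe_alpha,
               window = config$window, step = config$step,
               vif_threshold = config$vif_threshold, prune = config$prune)
  write_qc_report(qc$report, file.path(out, "combined"))
  msg("QC retained ", qc$report$n_retained, " of ", qc$report$n_input,
      " variants")

  halves <- split_by_sex(qc$dataset)
  rankings <- list()
  for (sx in c("male", "female")) {
    d <- halves[[sx]]
    if (n_samples(d) == 0L) {
      msg("skipping empty ", sx, " dataset")
      next
    }
    rk <- rank_variants(d)
    rankings[[sx]] <- rk
    write_variant_stats(rk, file.path(out, paste0(sx, ".variant_stats.tsv")))

    grid <- unique(pmin(config$grid, nrow(rk)))
    sw <- suppressWarnings(sweep_grid(d, rk, grid = grid,
                                      percentile = config$percentile))
    sw <- tryCatch(smooth_roc(sw), error = function(e) {
      msg("ROC smoothing for ", sx, " did not converge: ", conditionMessage(e))
      sw
    })
    write_sweep_table(sw, file.path(out, paste0(sx, ".sweep.tsv")))
    write_roc_series(sw, file.path(out, paste0(sx, ".roc.tsv")))
    if (!is.null(sw$auc)) msg(sx, " AUC ", round(sw$auc, 4))

    n_loo <- min(config$loocv_n_variants, nrow(rk))
    loo <- loo_predict_all(d, loocv_config(n_variants = n_loo,
                                           percentile = config$percentile))
    write_loo_predictions(loo, file.path(out, paste0(sx, ".loocv.tsv")))
    msg(sx, " LOO accuracy ", round(loo$table$acc, 4))
  }

  overlap <- NULL
  if (!is.null(rankings$male) && !is.null(rankings$female)) {
    k <- min(config$replic2_k, nrow(rankings$male))
    top_m <- utils::head(rankings$male$variant_id, k)
    top_f <- utils::head(rankings$female$variant_id, k)
    obs <- overlap_count(top_m, top_f)
    overlap <- replic2(nrow(rankings$male), k, k, obs,
                       n_reps = config$replic2_reps, seed = config$seed)
    jsonlite::write_json(unclass(overlap), file.path(out, "replic2.json"),
                         auto_unbox = TRUE, digits = NA)
    shared <- shared_top_variants(rankings$male, rankings$female, k,
                                  min_or = 1.0, variants = qc$dataset$variants)
    names(shared)[names(shared) == "or_a"] <- "or_male"
    names(shared)[names(shared) == "or_b"] <- "or_female"
    utils::write.table(shared, file.path(out, "shared_top_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    msg("top-", k, " overlap ", obs, ", empirical p ",
        format(overlap$empirical_p, digits = 4))
  }

  cfg_out <- config
  cfg_out$input <- if (inherits(config$input, "genotype_dataset")) {
    "<in-memory dataset>"
  } else {
    as.character(config$input)
  }
  files <- setdiff(list.files(out), "manifest.json")
  manifest <- list(
    package = "prspredict",
    version = as.character(utils::packageVersion("prspredict")),
    config = unclass(cfg_out),
    seed = config$seed,
    outputs = as.list(tools::md5sum(file.path(out, files)))
  )
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
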