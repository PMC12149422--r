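#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis with the study
#' defaults: K scanned 2..10, 25 gray levels, ICC threshold 0.75, Spearman
#' threshold 0.9, 5-fold LASSO CV, 7:3 split, minimum module size 100.
#'
#' @param out_dir output directory of the run.
#' @param spec a [cohort_spec()] describing the synthetic cohort.
#' @param stages character vector of stages to run, in pipeline order.
#' @param k_range candidate habitat counts.
#' @param n_gray_levels gray levels for discretization.
#' @param icc_threshold reproducibility threshold on both ICCs.
#' @param icc_n_patients size of the re-delineated subset (default 20).
#' @param spearman_threshold redundancy threshold.
#' @param cv_folds LASSO cross-validation folds.
#' @param split_ratio training fraction of the 7:3 split.
#' @param radscore_region region whose candidate features form the radscore.
#' @param min_module_size minimum coexpression module size.
#' @param beta_grid candidate soft-threshold powers.
#' @param write_images also write NIfTI volumes (off by default).
#' @param seed master seed, fanned out into per-stage sub-seeds.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            spec = cohort_spec(),
                            stages = c("simulate", "habitats", "extract", "icc",
                                       "select", "models", "survival",
                                       "coexpression"),
                            k_range = 2:10,
                            n_gray_levels = 25L,
                            icc_threshold = 0.75,
                            icc_n_patients = 20L,
                            spearman_threshold = 0.9,
                            cv_folds = 5L,
                            split_ratio = 0.7,
                            radscore_region = "VOI1",
                            min_module_size = 100L,
                            beta_grid = 1:20,
                            write_images = FALSE,
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(icc_threshold > 0, icc_threshold < 1,
            spearman_threshold > 0, spearman_threshold <= 1,
            split_ratio > 0, split_ratio < 1, cv_folds >= 2,
            min_module_size >= 1)
  structure(list(out_dir = out_dir, spec = spec, stages = stages,
                 k_range = k_range, n_gray_levels = as.integer(n_gray_levels),
                 icc_threshold = icc_threshold,
                 icc_n_patients = as.integer(icc_n_patients),
                 spearman_threshold = spearman_threshold,
                 cv_folds = as.integer(cv_folds), split_ratio = split_ratio,
                 radscore_region = radscore_region,
                 min_module_size = as.integer(min_module_size),
                 beta_grid = beta_grid, write_images = write_images,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the habitat-radiomics pipeline end to end
#'
#' Executes simulate, habitats, extract, icc, select, models, survival and
#' coexpression in order (subject to the config's stage toggles), writing each
#' stage's outputs as CSV/TSV/JSON under `out_dir` and a `manifest.json`
#' recording the seed, a config checksum and the MD5 of every output file.
#' Re-running with an identical config reproduces identical checksums. A stage
#' failure halts the run with the failing stage named; earlier outputs are
#' preserved.
#'
#' @param config a [pipeline_config()].
#' @return object of class `habitomics_run`: list of in-memory stage results
#'   plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- fan_seeds(config$seed, 8L)
  names(seeds) <- c("simulate", "habitats", "extract", "icc", "select",
                    "models", "survival", "coexpression")
  res <- list(config = config)
  files <- character(0)
  need <- function(x, what)
    if (is.null(x)) stop("no ", what, " available; run the earlier stages", call. = FALSE)
  t_start <- Sys.time()
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    message(sprintf("[%s] stage %-12s ...", format(Sys.time(), "%H:%M:%S"), name))
    out <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] stage %-12s done (%.1fs)",
                    format(Sys.time(), "%H:%M:%S"), name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  # -- simulate ---------------------------------------------------------------
  res$cohort <- run_stage("simulate", function() {
    spec <- config$spec
    spec$seed <- seeds[["simulate"]]
    cohort <- generate_cohort(spec)
    files <<- c(files, .write_csv(cohort$clinical,
                                  file.path(config$out_dir, "clinical.csv")))
    if (config$write_images) {
      img_dir <- file.path(config$out_dir, "images")
      for (v in cohort$volumes) write_volume_nifti(v, img_dir)
    }
    cohort
  })

  # -- habitats ---------------------------------------------------------------
  res$habitats <- run_stage("habitats", function() {
    need(res$cohort, "cohort")
    vols <- res$cohort$volumes
    sseeds <- fan_seeds(seeds[["habitats"]], length(vols))
    habitats <- lapply(seq_along(vols), function(i)
      segment_habitats(vols[[i]], k_range = config$k_range, seed = sseeds[i]))
    names(habitats) <- names(vols)
    ksel <- data.frame(patient_id = names(habitats),
                       k_selected = vapply(habitats, function(h) h$k_selected, 1L))
    bic <- do.call(rbind, lapply(names(habitats), function(pid)
      data.frame(patient_id = pid,
                 k = as.integer(names(habitats[[pid]]$bic_by_k)),
                 bic = unname(habitats[[pid]]$bic_by_k))))
    files <<- c(files,
                .write_csv(ksel, file.path(config$out_dir, "k_selected.csv")),
                .write_csv(bic, file.path(config$out_dir, "bic_by_k.csv")))
    habitats
  })

  # -- extract ----------------------------------------------------------------
  res$features <- run_stage("extract", function() {
    need(res$cohort, "cohort"); need(res$habitats, "habitat maps")
    vols <- res$cohort$volumes
    pspec <- preprocess_spec(n_gray_levels = config$n_gray_levels)
    long <- do.call(rbind, lapply(seq_along(vols), function(i)
      extract_features(vols[[i]], res$habitats[[i]], pspec)))
    files <<- c(files, .write_csv(long, file.path(config$out_dir, "features.csv")))
    # repeat-delineation extraction on the ICC subset
    n_icc <- min(config$icc_n_patients, length(vols))
    sseeds <- fan_seeds(seeds[["extract"]], 2L * n_icc)
    rep_tabs <- list(intra = NULL, inter = NULL)
    for (j in seq_len(n_icc)) {
      v <- vols[[j]]
      for (w in c("intra", "inter")) {
        m <- v$repeat_masks[[w]]
        sd_idx <- if (w == "intra") j else n_icc + j
        hb <- segment_habitats(list(image = v$image, mask = m),
                               k_range = config$k_range, seed = sseeds[sd_idx])
        tab <- extract_features(v, hb, pspec, mask = m)
        rep_tabs[[w]] <- rbind(rep_tabs[[w]], tab)
      }
    }
    files <<- c(files,
                .write_csv(rep_tabs$intra, file.path(config$out_dir, "features_intra.csv")),
                .write_csv(rep_tabs$inter, file.path(config$out_dir, "features_inter.csv")))
    list(primary = long, intra = rep_tabs$intra, inter = rep_tabs$inter)
  })

  # -- icc --------------------------------------------------------------------
  res$icc <- run_stage("icc", function() {
    need(res$features, "feature tables")
    sub_ids <- unique(res$features$intra$patient_id)
    prim <- pivot_features(
      res$features$primary[res$features$primary$patient_id %in% sub_ids, ])
    flt <- filter_features_icc(prim,
                               pivot_features(res$features$intra),
                               pivot_features(res$features$inter),
                               threshold = config$icc_threshold)
    files <<- c(files, .write_csv(flt$report,
                                  file.path(config$out_dir, "icc_report.csv")))
    flt
  })

  # -- select -----------------------------------------------------------------
  res$selection <- run_stage("select", function() {
    need(res$features, "feature tables"); need(res$cohort, "cohort")
    wide <- pivot_features(res$features$primary)
    clin <- res$cohort$clinical[match(wide$patient_id,
                                      res$cohort$clinical$patient_id), ]
    sp <- split_cohort(clin$grade, ratio = config$split_ratio,
                       seed = seeds[["select"]])
    retained <- if (!is.null(res$icc)) res$icc$retained
      else setdiff(names(wide), "patient_id")
    regions <- unique(res$features$primary$region)
    models <- list()
    for (rg in regions) {
      cols <- intersect(retained, names(wide))
      cols <- cols[startsWith(cols, paste0(rg, "_"))]
      cols <- cols[vapply(wide[cols], function(v) all(is.finite(v)), logical(1))]
      if (length(cols) < 2) next
      models[[rg]] <- build_radscore_model(
        wide[sp$train, cols], clin$grade[sp$train],
        r_threshold = config$spearman_threshold,
        nfolds = config$cv_folds, seed = seeds[["select"]])
    }
    rsm <- models[[config$radscore_region]]
    if (is.null(rsm)) stop("no radscore model for region ", config$radscore_region)
    split_lab <- ifelse(seq_len(nrow(wide)) %in% sp$train, "train", "internal_test")
    scores <- data.frame(patient_id = wide$patient_id,
                         split = split_lab,
                         radscore = predict(rsm, wide),
                         risk_group = predict(rsm, wide, type = "risk"),
                         stringsAsFactors = FALSE)
    model_json <- list(region = config$radscore_region,
                       selected_features = rsm$selected_features,
                       coefficients = as.list(rsm$coefficients),
                       intercept = rsm$intercept, lambda = rsm$lambda,
                       bounds = rsm$bounds, cutoff = rsm$cutoff)
    jf <- file.path(config$out_dir, "radscore_model.json")
    jsonlite::write_json(model_json, jf, auto_unbox = TRUE, digits = NA)
    files <<- c(files, jf,
                .write_csv(scores, file.path(config$out_dir, "scores.csv")))
    list(models = models, radscore_model = rsm, scores = scores,
         split = sp, wide = wide, clinical = clin)
  })

  # -- models -----------------------------------------------------------------
  res$metrics <- run_stage("models", function() {
    need(res$selection, "selection results")
    sel <- res$selection
    rows <- list()
    for (rg in names(sel$models)) {
      feats <- sel$models[[rg]]$selected_features
      if (length(feats) == 0) next
      xs <- sel$wide[feats]
      y <- sel$clinical$grade
      tab <- evaluate_models(
        xs[sel$split$train, , drop = FALSE], y[sel$split$train],
        splits = list(train = list(x = xs[sel$split$train, , drop = FALSE],
                                   y = y[sel$split$train]),
                      internal_test = list(x = xs[sel$split$test, , drop = FALSE],
                                           y = y[sel$split$test])),
        seed = seeds[["models"]])
      rows[[rg]] <- cbind(region = rg, tab)
    }
    metrics <- do.call(rbind, rows)
    rownames(metrics) <- NULL
    files <<- c(files, .write_csv(metrics, file.path(config$out_dir, "metrics.csv")))
    metrics
  })

  # -- survival ---------------------------------------------------------------
  res$survival <- run_stage("survival", function() {
    need(res$selection, "selection results")
    sel <- res$selection
    out <- list()
    km_rows <- list(); test_rows <- list()
    for (spl in unique(sel$scores$split)) {
      idx <- sel$scores$split == spl
      rs <- risk_group_survival(sel$scores$radscore[idx],
                                sel$radscore_model$cutoff,
                                sel$clinical$os_time[idx],
                                sel$clinical$os_event[idx])
      out[[spl]] <- rs
      if ("group" %in% names(rs$km))
        km_rows[[spl]] <- cbind(split = spl, rs$km)
      test_rows[[spl]] <- data.frame(split = spl, test = "logrank",
                                     variable = "risk_group",
                                     statistic = rs$logrank$chisq,
                                     p = rs$logrank$p)
    }
    for (v in c("age", "sex", "laterality", "tnm")) {
      cg <- compare_groups(sel$clinical[[v]], sel$clinical$grade)
      test_rows[[v]] <- data.frame(split = "all", test = cg$test, variable = v,
                                   statistic = cg$statistic %||% NA_real_, p = cg$p)
    }
    files <<- c(files,
                .write_csv(do.call(rbind, km_rows),
                           file.path(config$out_dir, "km_curves.csv")),
                .write_csv(do.call(rbind, test_rows),
                           file.path(config$out_dir, "tests.csv")))
    out
  })

  # -- coexpression -----------------------------------------------------------
  res$coexpression <- run_stage("coexpression", function() {
    need(res$selection, "selection results")
    sel <- res$selection
    set.seed(seeds[["coexpression"]])
    spec <- config$spec
    ge <- generate_expression(spec, sel$scores$radscore,
                              sample_ids = sel$scores$patient_id)
    ann <- generate_annotation(ge$module_truth)
    traits <- data.frame(radscore = sel$scores$radscore)
    for (f in sel$radscore_model$selected_features)
      traits[[f]] <- sel$wide[[f]]
    ma <- coexpression_analysis(ge$expr, traits,
                                min_module_size = config$min_module_size,
                                powers = config$beta_grid)
    sel_genes <- names(ma$modules)[ma$modules == ma$selected_module]
    enr <- hypergeom_enrichment(sel_genes, ann, rownames(ge$expr))
    files <<- c(files,
                .write_csv(data.frame(gene = names(ma$modules),
                                      module = unname(ma$modules)),
                           file.path(config$out_dir, "modules.csv")),
                .write_csv(ma$module_trait,
                           file.path(config$out_dir, "module_trait.csv")),
                .write_csv(enr$table,
                           file.path(config$out_dir, "enrichment.csv")))
    hf <- file.path(config$out_dir, "hubs.txt")
    writeLines(ma$hubs, hf)
    files <<- c(files, hf)
    list(assignment = ma, enrichment = enr, expression = ge)
  })

  # -- manifest ---------------------------------------------------------------
  cfg_txt <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                              auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(
                     {tf <- tempfile(); writeLines(cfg_txt, tf); tf})),
                   stages = config$stages,
                   elapsed_sec = as.numeric(difftime(Sys.time(), t_start,
                                                     units = "secs")),
                   checksums = as.list(stats::setNames(
                     unname(tools::md5sum(sort(files))),
                     basename(sort(files)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  class(res) <- "habitomics_run"
  res
}

#' @export
print.habitomics_run <- function(x, ...) {
  cat("habitomics pipeline run:", length(x$manifest$checksums),
      "output files in", x$config$out_dir, "\n")
  cat("  stages:", paste(x$config$stages, collapse = " -> "), "\n")
  invisible(x)
}
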