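## End-to-end pipeline driver: simulate -> featured -> mlselect ->
## coexpress -> integrate, one root seed, TSV/JSON outputs and a
## machine-readable run manifest with file digests.

#' Annotate modules by their trait associations
#'
#' Derives the per-module habitat annotations the triage rules need from the
#' module-trait table: a module is saltwater-associated if it has a
#' significant positive correlation with stress severity (salinity),
#' focal-specific if it correlates significantly positively with the
#' focal-species indicator, and freshwater-associated if it correlates
#' significantly negatively with it. Grey stays unannotated (all FALSE).
#'
#' @param labels module labels per orthogroup.
#' @param trait_table output of [module_trait()].
#' @return data frame (orthogroup_id, module, fresh_associated,
#'   salt_associated, focal_specific).
#' @export
annotate_modules <- function(labels, trait_table) {
  sig <- trait_table[trait_table$significant, ]
  per_module <- function(m, trait, positive) {
    rows <- sig[sig$module == m & sig$trait == trait, ]
    if (!nrow(rows)) return(FALSE)
    if (positive) any(rows$r > 0) else any(rows$r < 0)
  }
  mods <- unique(labels)
  ann <- data.frame(
    module = mods,
    fresh_associated = vapply(mods, function(m)
      m != "grey" && per_module(m, "mem25_specific", FALSE), logical(1)),
    salt_associated = vapply(mods, function(m)
      m != "grey" && per_module(m, "severity", TRUE), logical(1)),
    focal_specific = vapply(mods, function(m)
      m != "grey" && per_module(m, "mem25_specific", TRUE), logical(1)))
  data.frame(orthogroup_id = names(labels),
             ann[match(labels, ann$module), ], row.names = NULL)
}

#' Summarize metagene expression for the triage rules
#'
#' @param mm a `metagene_matrix`.
#' @param traits sample traits aligned with the metagene samples.
#' @param focal_species focal species id (sample membership from
#'   `mem25_specific`).
#' @return data frame (orthogroup_id, expr_focal, expr_fresh,
#'   expr_focal_high, expr_focal_low).
#' @export
expression_summary <- function(mm, traits, focal_species = "MEM25") {
  idx <- match(colnames(mm$values), traits$sample_id)
  if (anyNA(idx)) stop("metagene samples missing from trait table")
  tr <- traits[idx, ]
  foc <- tr$mem25_specific == 1
  sev <- tr$severity
  hi <- foc & sev > stats::median(sev)
  lo <- foc & sev <= stats::median(sev)
  data.frame(
    orthogroup_id = rownames(mm$values),
    expr_focal = rowMeans(mm$values[, foc, drop = FALSE]),
    expr_fresh = rowMeans(mm$values[, !foc, drop = FALSE]),
    expr_focal_high = rowMeans(mm$values[, hi, drop = FALSE]),
    expr_focal_low = rowMeans(mm$values[, lo, drop = FALSE]),
    row.names = NULL)
}

#' A compact default registry for pipeline runs
#'
#' Random-forest and lasso selectors crossed with elastic-net (0.6) and
#' linear-SVM classifiers, plus a classifier-only elastic-net entry. The
#' full sweep is available via [build_registry()].
#' @return a registry list.
#' @export
default_pipeline_registry <- function() {
  sels <- list(model_spec("random_forest"), model_spec("lasso"))
  cls <- list(model_spec("elastic_net", 0.6), model_spec("svm_linear"))
  reg <- list()
  for (s in sels) for (cl in cls)
    reg[[length(reg) + 1L]] <- list(selector = s, classifier = cl)
  reg[[length(reg) + 1L]] <- list(selector = NULL,
                                  classifier = model_spec("elastic_net", 0.6))
  reg
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> featured -> mlselect -> coexpress -> integrate,
#' writing every stage's tables under `outdir` and a run manifest with MD5
#' digests, so identical config + seed yields identical digests.
#'
#' @param outdir output directory.
#' @param config an [analysis_config()]; `config$seed` drives every stage.
#' @param skip character vector of stage names to skip.
#' @param registry model registry for the ML stage.
#' @param sim list of overrides for the three generators, with optional
#'   elements `pam`, `expression`, `metabolites` (argument lists).
#' @return the manifest (invisibly also written to `outdir/manifest.json`).
#' @export
run_pipeline <- function(outdir, config = analysis_config(),
                         skip = character(0),
                         registry = default_pipeline_registry(),
                         sim = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- c("simulate", "featured", "mlselect", "coexpress", "integrate")
  manifest <- list(version = as.character(packageVersion("saltadapt")),
                   seed = config$seed,
                   config = unclass(config),
                   stages = list())
  t_all <- Sys.time()
  state <- new.env(parent = emptyenv())
  outputs <- character(0)

  run_stage <- function(name, fun) {
    if (name %in% skip) {
      manifest$stages[[name]] <<- list(status = "skipped")
      sa_log("stage ", name, ": skipped")
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    files <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = as.list(unname(tools::md5sum(files))))
    names(manifest$stages[[name]]$outputs) <<- basename(files)
    outputs <<- c(outputs, files)
    sa_log("stage ", name, ": done (",
           round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1),
           " s)")
  }

  run_stage("simulate", function() {
    pam_args <- sim$pam %||% list()
    pam_args$seed <- pam_args$seed %||% config$seed
    state$pam_sim <- do.call(simulate_presence_absence, pam_args)
    ex_args <- sim$expression %||% list()
    ex_args$seed <- ex_args$seed %||% config$seed
    state$ex_sim <- do.call(simulate_expression, ex_args)
    mb_args <- sim$metabolites %||% list()
    mb_args$seed <- mb_args$seed %||% config$seed
    state$mb_sim <- do.call(simulate_metabolites, mb_args)
    f <- character(0)
    f[1] <- write_orthogroup_counts(state$pam_sim$counts,
                                    file.path(outdir, "orthogroup_counts.tsv"))
    f[2] <- write_species_metadata(state$pam_sim$meta,
                                   file.path(outdir, "species_metadata.tsv"))
    for (sp in names(state$ex_sim$exprs))
      f[length(f) + 1] <- write_expression(
        state$ex_sim$exprs[[sp]],
        file.path(outdir, paste0("expression_", sp, ".tsv")))
    f[length(f) + 1] <- write_gene_map(state$ex_sim$gmap,
                                       file.path(outdir, "gene_map.tsv"))
    f[length(f) + 1] <- write_traits(state$ex_sim$traits,
                                     file.path(outdir, "sample_traits.tsv"))
    f[length(f) + 1] <- write_metabolites(
      state$mb_sim$mm, file.path(outdir, "metabolites.tsv"),
      file.path(outdir, "metabolite_conditions.tsv"))
    f[length(f) + 1] <- file.path(outdir, "metabolite_conditions.tsv")
    truth_path <- file.path(outdir, "planted_truth.json")
    jsonlite::write_json(list(pam = state$pam_sim$truth,
                              expression = state$ex_sim$truth,
                              metabolites = state$mb_sim$truth),
                         truth_path, auto_unbox = TRUE, digits = NA)
    f[length(f) + 1] <- truth_path
    unique(f)
  })

  run_stage("featured", function() {
    pam <- to_presence_absence(state$pam_sim$counts)
    fr <- habitat_fractions(pam, state$pam_sim$meta)
    feat <- classify_featured(fr, config$cutoff)
    state$featured <- feat
    assoc <- association_test(pam, state$pam_sim$meta, feat,
                              bootstrap_reps = config$bootstrap_reps,
                              seed = config$seed)
    state$assoc <- assoc
    fam_class <- ifelse(fr$family_id %in% feat$salt_featured, "saltwater",
                        ifelse(fr$family_id %in% feat$fresh_featured,
                               "freshwater", "none"))
    f1 <- write_tsv(cbind(fr, class = fam_class),
                    file.path(outdir, "featured_families.tsv"))
    f2 <- file.path(outdir, "association.json")
    jsonlite::write_json(list(chi2 = assoc$chi2, df = assoc$df,
                              p_value = assoc$p_value,
                              cramers_v = assoc$cramers_v,
                              v_ci95 = assoc$v_ci95,
                              table = assoc$table),
                         f2, auto_unbox = TRUE, digits = NA)
    featured_ids <- c(feat$salt_featured, feat$fresh_featured)
    ord <- pca_species(presence_absence_matrix(
      pam$values[, featured_ids, drop = FALSE]), n_components = 2L)
    f3 <- write_tsv(data.frame(species_id = rownames(ord$scores),
                               ord$scores, check.names = FALSE),
                    file.path(outdir, "ordination.tsv"))
    c(f1, f2, f3)
  })

  run_stage("mlselect", function() {
    pam <- to_presence_absence(state$pam_sim$counts)
    res <- run_combination_search(pam, state$pam_sim$meta, registry, config)
    state$ml <- res
    f1 <- write_tsv(res$leaderboard, file.path(outdir, "leaderboard.tsv"))
    best <- res$best
    groups <- if (isTRUE(best$weights_signed))
      categorize_by_weight(best) else list(salt_group = character(0),
                                           fresh_group = character(0))
    sel <- data.frame(family_id = best$selected_families,
                      weight = unname(best$weights[best$selected_families]),
                      group = ifelse(best$selected_families %in%
                                       groups$salt_group, "saltwater",
                                     ifelse(best$selected_families %in%
                                              groups$fresh_group,
                                            "freshwater", "unsigned")))
    f2 <- write_tsv(sel, file.path(outdir, "selected_families.tsv"))
    f3 <- file.path(outdir, "ml_manifest.json")
    jsonlite::write_json(list(seed = config$seed, folds = config$cv_folds,
                              batch_size = config$batch_size,
                              n_combinations = length(registry),
                              best = list(selector = spec_label(best$selector),
                                          classifier = spec_label(best$classifier),
                                          cv_accuracy = best$cv_accuracy,
                                          n_features = best$n_features_used)),
                         f3, auto_unbox = TRUE, digits = NA)
    c(f1, f2, f3)
  })

  run_stage("coexpress", function() {
    ms <- coexpression_modules(state$ex_sim$exprs, state$ex_sim$gmap,
                               state$ex_sim$traits, config)
    state$modules <- ms
    f1 <- write_tsv(data.frame(orthogroup_id = names(ms$labels),
                               module = unname(ms$labels)),
                    file.path(outdir, "modules.tsv"))
    f2 <- write_tsv(data.frame(module = rownames(ms$eigengenes),
                               ms$eigengenes, check.names = FALSE),
                    file.path(outdir, "eigengenes.tsv"))
    f3 <- write_tsv(ms$trait_table, file.path(outdir, "module_trait.tsv"))
    f4 <- write_tsv(ms$fit_table, file.path(outdir, "soft_threshold_fit.tsv"))
    c(f1, f2, f3, f4)
  })

  run_stage("integrate", function() {
    da <- metabolite_da(state$mb_sim$mm, config = config)
    f1 <- write_tsv(da, file.path(outdir, "metabolite_da.tsv"))
    ms <- state$modules
    fs <- NULL
    if (!is.null(ms)) {
      ann <- annotate_modules(ms$labels, ms$trait_table)
      es <- expression_summary(ms$mm, state$ex_sim$traits)
      # the synthetic counts table and the expression study share orthogroup
      # ids by construction; the focal column is the first saltwater species
      focal <- state$pam_sim$meta$species_id[
        state$pam_sim$meta$habitat == "saltwater"][1L]
      shared <- intersect(es$orthogroup_id,
                          rownames(state$pam_sim$counts$counts))
      tri <- triage_candidates(es[es$orthogroup_id %in% shared, ],
                               ann[ann$orthogroup_id %in% shared, ],
                               state$pam_sim$counts, state$pam_sim$meta,
                               focal_species = focal)
      state$triage <- tri
      fs <- write_tsv(tri, file.path(outdir, "triage.tsv"))
    } else {
      sa_log("integrate: no module set available, triage skipped")
    }
    c(f1, fs)
  })

  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all,
                                                units = "secs"))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a plain-text summary of a pipeline run
#'
#' @param outdir directory of a completed [run_pipeline()] run.
#' @return the report lines, invisibly; also printed.
#' @export
pipeline_report <- function(outdir) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, paste0(...))
  man <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  add("saltadapt run report (seed ", man$seed, ")")
  ff <- file.path(outdir, "featured_families.tsv")
  if (file.exists(ff)) {
    d <- read.delim(ff)
    add("featured families: ", sum(d$class != "none"),
        " (saltwater ", sum(d$class == "saltwater"),
        ", freshwater ", sum(d$class == "freshwater"), ")")
  }
  lb <- file.path(outdir, "leaderboard.tsv")
  if (file.exists(lb)) {
    d <- read.delim(lb)
    add("best combination: ", d$selector[1], " + ", d$classifier[1],
        " | CV accuracy ", sprintf("%.3f", d$cv_accuracy[1]),
        " | ", d$n_features[1], " families")
  }
  mt <- file.path(outdir, "module_trait.tsv")
  if (file.exists(mt)) {
    d <- read.delim(mt)
    add("modules: ", length(unique(d$module)), " with ",
        sum(d$significant), " significant module-trait pairs")
  }
  tri <- file.path(outdir, "triage.tsv")
  if (file.exists(tri)) {
    d <- read.delim(tri)
    add("triage candidates: ", nrow(d), " (strategy counts: ",
        paste(names(table(d$strategy)), table(d$strategy),
              sep = "=", collapse = ", "), ")")
  }
  da <- file.path(outdir, "metabolite_da.tsv")
  if (file.exists(da)) {
    d <- read.delim(da)
    add("differentially abundant metabolites: ", sum(d$significant),
        " of ", nrow(d))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
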