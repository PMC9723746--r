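pipeline_defaults <- list(
  depth = 20000,
  mantel_permutations = 999,
  rc_randomizations = 1000,
  niche_randomizations = 999,
  ci_level = 0.95,
  alpha = 0.05,
  seed = 1,
  out_dir = NULL,
  groups = NULL,      # named list: list(table = path, taxonomy = path or NULL)
  metadata = NULL,    # path to metadata TSV
  orientation = "taxa-as-rows",
  scenario = NULL)    # scenario_config (or TRUE for the default mixed run)

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML path or a list; fills defaults (depth 20,000; Mantel 999
#' permutations; Raup-Crick 1,000 randomizations; niche 999 randomizations;
#' 95% prediction band; alpha 0.05) and rejects unknown keys and
#' out-of-range values.
#'
#' @param config Path to a YAML file or a named list.
#' @return A normalized list of class `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  unknown <- setdiff(names(config), names(pipeline_defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(pipeline_defaults, config)
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1)
    stop("ci_level must lie in (0, 1)", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (cfg$depth < 1) stop("depth must be positive", call. = FALSE)
  if (cfg$mantel_permutations < 99)
    stop("mantel_permutations must be at least 99", call. = FALSE)
  if (cfg$rc_randomizations < 99)
    stop("rc_randomizations must be at least 99", call. = FALSE)
  if (cfg$niche_randomizations < 99)
    stop("niche_randomizations must be at least 99", call. = FALSE)
  if (is.null(cfg$scenario)) {
    if (is.null(cfg$groups) || !length(cfg$groups))
      stop("config needs either group table paths or a scenario",
           call. = FALSE)
    if (is.null(names(cfg$groups)) || any(names(cfg$groups) == ""))
      stop("groups must be named", call. = FALSE)
    dup <- unique(names(cfg$groups)[duplicated(names(cfg$groups))])
    if (length(dup))
      stop("duplicate group name(s): ", paste(dup, collapse = ", "),
           call. = FALSE)
    if (is.null(cfg$metadata))
      stop("config needs a metadata path when using input tables",
           call. = FALSE)
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

pipeline_log <- function(lines, msg) {
  c(lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
}

# One group's full analysis chain. `cache` is a directory for stage RDS
# artifacts; with resume = TRUE a stage whose artifact exists is reloaded
# instead of recomputed (downstream stages then reuse it).
run_group <- function(gname, table, meta, cfg, cache, resume) {
  stage <- function(name, expr) {
    path <- file.path(cache, paste0(gname, "_", name, ".rds"))
    if (resume && file.exists(path)) return(readRDS(path))
    val <- force(expr)
    saveRDS(val, path)
    val
  }
  seed_for <- function(stage_name) derive_seed(cfg$seed, gname, stage_name)

  rar <- stage("rarefy", suppressWarnings(
    rarefy_table(table, depth = cfg$depth, seed = seed_for("rarefy"))))
  meta_g <- meta[meta$sample_id %in% rownames(rar$counts), , drop = FALSE]
  meta_g <- sample_metadata(meta_g)

  sim <- stage("bray", bray_curtis(rar, as = "similarity"))
  jac <- stage("jaccard", jaccard(rar))
  geo <- stage("geo", geographic_distance(meta_g))
  env <- stage("env", environment_distance(meta_g))

  decay <- stage("decay", distance_decay(
    sim, geo, n_permutations = cfg$mantel_permutations,
    seed = seed_for("decay")))
  mantel_env <- stage("mantel_env", mantel_test(
    jac, env, n_permutations = cfg$mantel_permutations,
    seed = seed_for("mantel_env")))

  ncm <- stage("ncm", {
    st <- suppressWarnings(occurrence_stats(rar))
    ncm_fit(st, ci_level = cfg$ci_level)
  })
  rc <- stage("rc", raup_crick_matrix(
    rar, n_randomizations = cfg$rc_randomizations, seed = seed_for("rc")))
  niche <- stage("niche", suppressWarnings(classify_specialists(
    rar, n_randomizations = cfg$niche_randomizations,
    seed = seed_for("niche"), alpha = cfg$alpha)))
  adapted <- stage("adapted", {
    ids <- intersect_filters(ncm, niche)
    assign_ecosystem(ids, rar, meta_g, ncm = ncm, niche = niche)
  })

  part <- ncm_partition_summary(ncm)
  labels <- niche$per_taxon$label
  report <- data.frame(
    group = gname,
    n_samples = nrow(rar$counts),
    n_taxa = sum(colSums(rar$counts) > 0),
    decay_slope = decay$slope,
    mantel_r_geography = decay$r,
    mantel_p_geography = decay$p_value,
    mantel_r_environment = mantel_env$r,
    mantel_p_environment = mantel_env$p_value,
    ncm_m = ncm$m, ncm_Nm = ncm$Nm, ncm_r_squared = ncm$r_squared,
    ncm_below = part["below"], ncm_neutral = part["neutral"],
    ncm_above = part["above"],
    rc_mean = rc$mean_value, rc_process = rc$process,
    specialist_pct = 100 * mean(labels == "specialist"),
    generalist_pct = 100 * mean(labels == "generalist"),
    bcom_mean = mean(niche$per_sample_bcom, na.rm = TRUE),
    locally_adapted = nrow(adapted$taxa),
    row.names = NULL, stringsAsFactors = FALSE)

  list(report = report, rarefied = rar, ncm = ncm, rc = rc, niche = niche,
       adapted = adapted, decay = decay, mantel_env = mantel_env)
}

#' Run the full community-assembly pipeline
#'
#' For each taxonomic group: rarefaction, Bray-Curtis / Jaccard matrices,
#' geographic and environmental distances, distance-decay and Mantel tests,
#' the Sloan neutral model, the Raup-Crick null deviation, niche-breadth
#' classification, and the locally-adapted intersection; then a combined
#' cross-group summary. All stage seeds derive deterministically from the
#' master seed and the group/stage names, so identical configs reproduce all
#' numeric outputs exactly and adding a group does not perturb the others.
#'
#' @param config A [validate_pipeline_config()] input (list or YAML path).
#' @param resume Reuse stage artifacts already present in the output
#'   directory's cache (default FALSE).
#' @return list(reports = per-group data.frame, groups = per-group result
#'   objects, combined = list(locally_adapted_pct, counts_regression),
#'   failed = named character vector of per-group errors, log, out_dir).
#'   A group whose stage errors is skipped and reported in `failed`.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  cfg <- validate_pipeline_config(config)
  out_dir <- cfg$out_dir %||% tempfile("commassembly_run_")
  cache <- file.path(out_dir, "cache")
  dir.create(cache, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_lines <- pipeline_log(log_lines, "pipeline start")

  if (!is.null(cfg$scenario)) {
    scen <- if (inherits(cfg$scenario, "scenario_config")) cfg$scenario
            else scenario_config(regime = "mixed", n_taxa = 600,
                                 depth = cfg$depth, seed = cfg$seed)
    sim <- mixed_scenario(scen)
    tables <- sim$tables
    meta <- sim$meta
    truth <- sim$truth
  } else {
    meta <- read_sample_metadata(cfg$metadata)
    tables <- lapply(cfg$groups, function(g) {
      path <- if (is.list(g)) g$table else g
      tab <- read_community_table(path, orientation = cfg$orientation)
      if (is.list(g) && !is.null(g$taxonomy))
        tab$taxonomy <- read_taxonomy(g$taxonomy)
      tab
    })
    truth <- NULL
  }

  results <- list()
  failed <- character(0)
  for (gname in names(tables)) {
    log_lines <- pipeline_log(log_lines, paste("group", gname, "start"))
    res <- tryCatch(
      run_group(gname, tables[[gname]], meta, cfg, cache, resume),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[gname] <- conditionMessage(res)
      log_lines <- pipeline_log(log_lines, paste0("group ", gname,
                                                  " FAILED: ", failed[gname]))
      next
    }
    results[[gname]] <- res
    log_lines <- pipeline_log(log_lines, paste("group", gname, "done"))
  }
  if (!length(results))
    stop("all groups failed: ",
         paste(names(failed), failed, sep = ": ", collapse = "; "),
         call. = FALSE)

  reports <- do.call(rbind, lapply(results, `[[`, "report"))
  rownames(reports) <- NULL
  combined <- list(
    locally_adapted_total = sum(reports$locally_adapted),
    pool_total = sum(vapply(results, function(r) r$ncm$per_taxon |> nrow(),
                            numeric(1))),
    counts_regression = if (length(results) >= 3)
      counts_regression(lapply(results, `[[`, "ncm"),
                        lapply(results, `[[`, "niche")) else NULL)
  combined$locally_adapted_pct <-
    100 * combined$locally_adapted_total / combined$pool_total

  write.table(reports, file.path(out_dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = cfg[setdiff(names(cfg), "scenario")],
         combined = combined[c("locally_adapted_total", "pool_total",
                               "locally_adapted_pct")],
         failed = as.list(failed)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, null = "null",
    force = TRUE)
  for (gname in names(results)) {
    r <- results[[gname]]
    write.table(r$ncm$per_taxon,
                file.path(out_dir, paste0(gname, "_ncm_taxa.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(r$niche$per_taxon,
                file.path(out_dir, paste0(gname, "_niche_taxa.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(r$adapted$taxa,
                file.path(out_dir, paste0(gname, "_locally_adapted.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_dist_matrix(r$rc |> (\(x) dist_matrix(
      ifelse(is.na(x$values), 0, x$values), "raup_crick",
      "dissimilarity"))(),
      file.path(out_dir, paste0(gname, "_raup_crick.tsv")))
  }
  log_lines <- pipeline_log(log_lines, "pipeline done")
  writeLines(log_lines, file.path(out_dir, "run.log"))

  out <- list(reports = reports, groups = results, combined = combined,
              truth = truth, failed = failed, log = log_lines,
              out_dir = out_dir)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline run: %d group(s), %d failed; outputs in %s\n",
              nrow(x$reports), length(x$failed), x$out_dir))
  print(x$reports[, c("group", "n_samples", "n_taxa", "ncm_Nm",
                      "ncm_r_squared", "rc_mean", "specialist_pct",
                      "bcom_mean", "locally_adapted")])
  cat(sprintf("combined locally-adapted: %d taxa (%.2f%% of pool)\n",
              x$combined$locally_adapted_total,
              x$combined$locally_adapted_pct))
  invisible(x)
}
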