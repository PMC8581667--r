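# End-to-end orchestration: simulate -> segment -> quantify -> gate ->
# region stats -> cohort statistics, with a manifest that makes runs
# auditable and reproducible.

#' Pipeline run configuration
#'
#' Exactly one image source (a simulation spec or an input stack file) may
#' be present; likewise for the cohort (simulation spec or CSV). Either
#' section may be omitted to run only the other half.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; specimen i uses `seed + i`.
#' @param image_sim An `image_sim_spec` for simulated slides, or NULL.
#' @param n_specimens Number of simulated specimens (image stage).
#' @param image_stack_tiff Path to a multi-page TIFF written by
#'   [write_stack_tiff()], or NULL.
#' @param pixel_size_um Pixel size for file inputs.
#' @param cohort_sim A `cohort_sim_spec`, or NULL.
#' @param cohort_csv Path to a cohort CSV, or NULL.
#' @param gating_variant Panel variant for gating.
#' @param tissue_params,nest_params `morph_params` for segmentation.
#' @param index_feature Density feature dichotomized for survival
#'   analysis.
#' @param cutoff_rules Named list of `cutoff_rule`s applied to the index
#'   feature (one KM/log-rank analysis each).
#' @param cox_covariates Covariates entering the Cox model jointly
#'   (`"group_high"` is the dichotomized index feature).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       image_sim = NULL, n_specimens = 1L,
                       image_stack_tiff = NULL, pixel_size_um = NULL,
                       cohort_sim = NULL, cohort_csv = NULL,
                       gating_variant = "discovery",
                       tissue_params = morph_params(),
                       nest_params = morph_params(),
                       index_feature = "pd1_helper_nest",
                       cutoff_rules = list(mean = cutoff_rule("mean")),
                       cox_covariates = c("group_high", "hpv_negative",
                                          "male", "smoking_history",
                                          "stage_3_4")) {
  if (!is.null(image_sim) && !is.null(image_stack_tiff))
    stop("config must name exactly one image source")
  if (!is.null(cohort_sim) && !is.null(cohort_csv))
    stop("config must name exactly one cohort source")
  if (!is.null(image_stack_tiff)) {
    if (!file.exists(image_stack_tiff))
      stop("missing input file: ", image_stack_tiff)
    if (is.null(pixel_size_um))
      stop("pixel_size_um is required for file inputs")
  }
  if (!is.null(cohort_csv) && !file.exists(cohort_csv))
    stop("missing input file: ", cohort_csv)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 image_sim = image_sim, n_specimens = as.integer(n_specimens),
                 image_stack_tiff = image_stack_tiff,
                 pixel_size_um = pixel_size_um,
                 cohort_sim = cohort_sim, cohort_csv = cohort_csv,
                 gating_variant = gating_variant,
                 tissue_params = tissue_params, nest_params = nest_params,
                 index_feature = index_feature,
                 cutoff_rules = cutoff_rules,
                 cox_covariates = cox_covariates),
            class = "run_config")
}

# serializable view of a config (for the YAML audit copy and its hash)
config_as_list <- function(config) {
  rapply(unclass(config), unclass, how = "replace")
}

run_one_specimen <- function(stack, truth, config, tag, out_dir) {
  seg <- segment_slide(stack, tissue_params = config$tissue_params,
                       nest_params = config$nest_params)
  hema <- gray_image(stack$channels$hematoxylin, stack$pixel_size_um)
  cells <- detect_cells(hema, seg$roi)
  tab <- quantify_markers(cells, stack)
  tab <- classify_cells(tab, gating_config(config$gating_variant))
  tab <- assign_region(tab, seg)
  stats <- compute_region_stats(tab, seg)
  files <- c(
    nest_mask = write_mask_png(seg$nest, file.path(out_dir, paste0(tag, "_nest.png"))),
    stroma_mask = write_mask_png(seg$stroma, file.path(out_dir, paste0(tag, "_stroma.png"))),
    cells = write_cell_csv(tab, file.path(out_dir, paste0(tag, "_cells.csv"))),
    stats = write_report_json(
      list(nest_threshold = seg$nest_threshold,
           tissue_threshold = seg$tissue_threshold,
           areas_mm2 = as.list(stats$areas_mm2),
           by_lineage = stats$by_lineage, pd1 = stats$pd1),
      file.path(out_dir, paste0(tag, "_region_stats.json"))))
  t_lineages <- c("cd8_t", "treg", helper_lineages)
  summary <- data.frame(
    specimen = tag,
    nest_area_mm2 = stats$areas_mm2[["nest"]],
    stroma_area_mm2 = stats$areas_mm2[["stroma"]],
    t_density_nest = region_density(stats, "nest", t_lineages),
    t_density_stroma = region_density(stats, "stroma", t_lineages),
    pd1_helper_nest = stats$pd1$density[stats$pd1$region == "nest" &
                                          stats$pd1$subset == "helper_t"],
    tam_cd163pos_nest = region_density(stats, "nest", "tam_cd163pos"))
  list(files = files, summary = summary, stats = stats)
}

run_cohort_stage <- function(cohort, config, out_dir) {
  feature <- config$index_feature
  if (!feature %in% names(cohort))
    stop("cohort lacks index feature: ", feature)
  files <- c(cohort = write_cell_csv(cohort, file.path(out_dir, "cohort.csv")))
  analyses <- list()
  for (rule_name in names(config$cutoff_rules)) {
    rule <- config$cutoff_rules[[rule_name]]
    d <- dichotomize(cohort[[feature]], rule, events = cohort$event)
    lr <- logrank_test(cohort$time_months, cohort$event, d$high)
    km_hi <- km_estimate(cohort$time_months[d$high], cohort$event[d$high])
    km_lo <- km_estimate(cohort$time_months[!d$high], cohort$event[!d$high])
    files[paste0("km_high_", rule_name)] <- write_km_csv(
      km_hi, file.path(out_dir, paste0("km_high_", rule_name, ".csv")))
    files[paste0("km_low_", rule_name)] <- write_km_csv(
      km_lo, file.path(out_dir, paste0("km_low_", rule_name, ".csv")))
    analyses[[rule_name]] <- list(rule = rule$kind, cutoff = d$cutoff,
                                  n_high = sum(d$high), n_low = sum(!d$high),
                                  logrank_statistic = lr$statistic,
                                  logrank_p = lr$p)
  }
  rule1 <- config$cutoff_rules[[1L]]
  d <- dichotomize(cohort[[feature]], rule1, events = cohort$event)
  cohort$group_high <- d$high
  covs <- intersect(config$cox_covariates, names(cohort))
  covs <- covs[vapply(covs, function(cv) length(unique(cohort[[cv]])) > 1L,
                      logical(1))]
  cox <- cox_fit(cohort, covs)
  files["cox"] <- write_report_json(
    list(covariates = as.data.frame(cox), converged = attr(cox, "converged"),
         ties = attr(cox, "ties")),
    file.path(out_dir, "cox.json"))
  files["analysis"] <- write_report_json(
    list(index_feature = feature, cutoffs = analyses),
    file.path(out_dir, "cohort_analysis.json"))
  list(files = files, analyses = analyses, cox = cox)
}

#' Run the full pipeline
#'
#' Executes the configured stages in order -- simulate (or load), segment
#' into nest/stroma, detect and quantify cells, gate lineages, assign
#' regions, compute region statistics, then the cohort survival analyses --
#' writing every artifact plus a run manifest into the output directory.
#' Reruns with the same config and seed reproduce numerically identical
#' outputs. A stage failure aborts with the stage name; partial outputs
#' are retained and the manifest marks the failure point.
#'
#' @param config A `run_config`.
#' @return An object of class `run_manifest` (invisibly written to
#'   `manifest.json`): config copy + hash, per-stage parameters, seeds and
#'   output files, timestamps.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_spec_yaml(config_as_list(config), cfg_path)
  manifest <- list(package_version = as.character(utils::packageVersion("nestseg")),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list(), files = c(config = cfg_path),
                   status = "running")
  fail <- function(stage, err) {
    manifest$status <<- paste0("failed:", stage)
    out <- manifest
    out$files <- as.list(manifest$files)
    write_report_json(out, file.path(config$out_dir, "manifest.json"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(err)), call. = FALSE)
  }
  summaries <- NULL
  if (!is.null(config$image_sim) || !is.null(config$image_stack_tiff)) {
    res <- tryCatch({
      if (!is.null(config$image_sim)) {
        lapply(seq_len(config$n_specimens), function(i) {
          spec <- config$image_sim
          spec$seed <- config$seed + i
          sim <- generate_image_stack(spec)
          run_one_specimen(sim$stack, sim$truth, config,
                           sprintf("specimen%02d", i), config$out_dir)
        })
      } else {
        stack <- read_stack_tiff(config$image_stack_tiff, config$pixel_size_um)
        list(run_one_specimen(stack, NULL, config, "specimen01",
                              config$out_dir))
      }
    }, error = function(e) fail("image", e))
    summaries <- do.call(rbind, lapply(res, `[[`, "summary"))
    sm_path <- file.path(config$out_dir, "specimen_summaries.csv")
    write.csv(summaries, sm_path, row.names = FALSE)
    manifest$files <- c(manifest$files,
                        unlist(lapply(res, `[[`, "files")),
                        specimen_summaries = sm_path)
    manifest$stages$image <- list(
      n_specimens = length(res),
      seeds = config$seed + seq_along(res),
      gating_variant = config$gating_variant,
      tissue_params = unclass(config$tissue_params),
      nest_params = unclass(config$nest_params))
  }
  if (!is.null(config$cohort_sim) || !is.null(config$cohort_csv)) {
    res <- tryCatch({
      cohort <- if (!is.null(config$cohort_sim)) {
        spec <- config$cohort_sim
        spec$seed <- config$seed
        generate_cohort(spec)
      } else {
        tab <- read.csv(config$cohort_csv)
        tab$event <- as.logical(tab$event)
        tab
      }
      run_cohort_stage(cohort, config, config$out_dir)
    }, error = function(e) fail("cohort", e))
    manifest$files <- c(manifest$files, res$files)
    manifest$stages$cohort <- list(
      seed = config$seed, index_feature = config$index_feature,
      cutoff_rules = lapply(config$cutoff_rules, unclass),
      cox_covariates = config$cox_covariates,
      analyses = res$analyses)
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$status <- "ok"
  mpath <- file.path(config$out_dir, "manifest.json")
  out <- manifest
  out$files <- as.list(manifest$files)  # keep names through JSON
  write_report_json(out, mpath)
  manifest$files <- c(manifest$files, manifest = mpath)
  class(manifest) <- "run_manifest"
  manifest
}

#' Render a static Markdown report from a completed run
#'
#' Writes `report.md` plus figure PNGs into the run directory: per-region
#' lineage composition bars and a log-log nest-versus-stroma T cell
#' density scatter when the image stage ran, and one KM plot per
#' configured cutoff rule when the cohort stage ran (omitted with a
#' notice otherwise). Every statistic in the report is read back from the
#' files listed in the manifest.
#'
#' @param manifest A `run_manifest` (or the path of a run directory
#'   containing `manifest.json`).
#' @return Path of the report file.
#' @export
make_report <- function(manifest) {
  if (is.character(manifest)) {
    mpath <- file.path(manifest, "manifest.json")
    if (!file.exists(mpath)) stop("incomplete run: manifest.json missing")
    manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    manifest$files <- unlist(manifest$files)
  }
  out_dir <- dirname(manifest$files[["config"]])
  lines <- c("# nestseg run report", "",
             sprintf("- config hash: `%s`", manifest$config_hash),
             sprintf("- seed: %d", manifest$seed),
             sprintf("- status: %s", manifest$status), "")
  sm_path <- file.path(out_dir, "specimen_summaries.csv")
  if (file.exists(sm_path)) {
    sm <- read.csv(sm_path)
    lines <- c(lines, "## Tissue segmentation and image cytometry", "",
               sprintf("%d specimen(s); mean nest area %.3f mm2, mean stroma area %.3f mm2 (`specimen_summaries.csv`).",
                       nrow(sm), mean(sm$nest_area_mm2),
                       mean(sm$stroma_area_mm2)), "")
    pol_png <- file.path(out_dir, "fig_polarization.png")
    df <- sm[sm$t_density_nest > 0 & sm$t_density_stroma > 0, ]
    if (nrow(df) > 0) {
      p <- ggplot2::ggplot(df, ggplot2::aes(x = t_density_stroma,
                                            y = t_density_nest)) +
        ggplot2::geom_point() +
        ggplot2::geom_abline(slope = 1, intercept = log10(2),
                             linetype = "dashed") +
        ggplot2::geom_abline(slope = 1, intercept = log10(0.5),
                             linetype = "dashed") +
        ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
        ggplot2::labs(x = "T cell density, stroma (cells/mm2)",
                      y = "T cell density, nest (cells/mm2)",
                      title = "Nest/stroma polarization of T cells")
      ggplot2::ggsave(pol_png, p, width = 4.5, height = 4.5, dpi = 120)
      lines <- c(lines, "![polarization](fig_polarization.png)", "")
    }
    stats1 <- list.files(out_dir, pattern = "_region_stats\\.json$",
                         full.names = TRUE)
    if (length(stats1)) {
      bl <- do.call(rbind, lapply(stats1, function(f)
        jsonlite::read_json(f, simplifyVector = TRUE)$by_lineage))
      bl <- bl[bl$lineage != "other", ]
      comp <- stats::aggregate(pct_of_cd45 ~ region + lineage, bl, mean)
      p <- ggplot2::ggplot(comp, ggplot2::aes(x = lineage, y = pct_of_cd45,
                                              fill = region)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::coord_flip() +
        ggplot2::labs(y = "% of CD45+ cells", x = NULL,
                      title = "Leukocyte composition by region")
      comp_png <- file.path(out_dir, "fig_composition.png")
      ggplot2::ggsave(comp_png, p, width = 5.5, height = 4, dpi = 120)
      lines <- c(lines, "![composition](fig_composition.png)", "")
    }
  }
  an_path <- file.path(out_dir, "cohort_analysis.json")
  if (file.exists(an_path)) {
    an <- jsonlite::read_json(an_path, simplifyVector = TRUE)
    lines <- c(lines, "## Survival analyses", "",
               sprintf("Index feature: `%s` (`cohort_analysis.json`).",
                       an$index_feature), "")
    for (rule_name in names(an$cutoffs)) {
      a <- an$cutoffs[[rule_name]]
      hi <- read.csv(file.path(out_dir, paste0("km_high_", rule_name, ".csv")))
      lo <- read.csv(file.path(out_dir, paste0("km_low_", rule_name, ".csv")))
      km <- rbind(cbind(hi, group = "high"), cbind(lo, group = "low"))
      km0 <- data.frame(time = 0, n_risk = NA, n_event = NA, survival = 1,
                        group = c("high", "low"))
      p <- ggplot2::ggplot(rbind(km0, km[, names(km0)]),
                           ggplot2::aes(x = time, y = survival,
                                        color = group)) +
        ggplot2::geom_step() + ggplot2::ylim(0, 1) +
        ggplot2::labs(x = "Months", y = "Overall survival",
                      title = sprintf("KM by %s cutoff (%.3g); log-rank p = %.3g",
                                      a$rule, a$cutoff, a$logrank_p))
      km_png <- file.path(out_dir, paste0("fig_km_", rule_name, ".png"))
      ggplot2::ggsave(km_png, p, width = 5, height = 4, dpi = 120)
      lines <- c(lines,
                 sprintf("### Cutoff rule: %s", rule_name),
                 sprintf("cutoff = %.4g; n high/low = %d/%d; log-rank chi-square = %.4g, p = %.4g",
                         a$cutoff, a$n_high, a$n_low, a$logrank_statistic,
                         a$logrank_p),
                 sprintf("![km_%s](fig_km_%s.png)", rule_name, rule_name), "")
    }
    cox <- jsonlite::read_json(file.path(out_dir, "cox.json"),
                               simplifyVector = TRUE)
    lines <- c(lines, "### Cox proportional hazards (`cox.json`)", "",
               "| covariate | HR | 95% CI | p |", "|---|---|---|---|",
               sprintf("| %s | %.2f | (%.2f-%.2f) | %.3g |",
                       cox$covariates$covariate, cox$covariates$hr,
                       cox$covariates$ci_low, cox$covariates$ci_high,
                       cox$covariates$p), "")
  } else {
    lines <- c(lines, "## Survival analyses", "",
               "No cohort stage in this run; survival panels omitted.", "")
  }
  report <- file.path(out_dir, "report.md")
  writeLines(lines, report)
  report
}
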