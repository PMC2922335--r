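# End-to-end study orchestration: simulate -> fit -> evaluate -> project ->
# quantify -> richness -> stats, with deterministic seeded stages and a
# manifest of every artifact written.

#' Study configuration
#'
#' A config fully determines every output: each stochastic stage has its own
#' seed derived from `base_seed`. The defaults mirror the design of the
#' museum-record study the pipeline reconstructs: a pooled target-group
#' background capped at 4215 points, null sizes 50/205/405/695 with 1000
#' replicates, strict (cumulative 10) and liberal (minimum training
#' presence) thresholds, a 10 km dispersal buffer, 250 richness comparison
#' points, and a 2 GCM x 2 CO2 x 3 year scenario ensemble. Tests and demos
#' override the sizes downward.
#'
#' @param landscape A [landscape_spec()].
#' @param n_species Number of virtual species units.
#' @param occurrences_per_species Presence records per species (scalar or
#'   vector; each must exceed 30 for modelling).
#' @param bias `"uniform"` or `"collection"` (museum-style foci bias).
#' @param pool_size Target-group background pool cap.
#' @param null_sizes,null_replicates Null-model sample sizes and replicate
#'   count (sizes larger than the realized pool are skipped with a message).
#' @param gcms,co2_levels,years Scenario grid labels/horizons.
#' @param buffer_km Dispersal buffer distance (km).
#' @param known_range_coarsening County-like block size (cells) of the
#'   synthetic known ranges.
#' @param comparison_points Richness comparison points.
#' @param cumulative_cutoff Strict-threshold cumulative cutoff.
#' @param beta_multiplier Global regularization multiplier.
#' @param n_hinge_knots,n_threshold_knots Feature knot counts.
#' @param run_glm Fit the factorial GLM per year (needs enough units).
#' @param write_rasters Also write current binary ranges and richness maps as
#'   ASCII grids.
#' @param base_seed Integer; per-stage seeds are small fixed offsets of it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(landscape, n_species = 35,
                         occurrences_per_species = 200,
                         bias = c("uniform", "collection"),
                         pool_size = 4215,
                         null_sizes = c(50, 205, 405, 695),
                         null_replicates = 1000,
                         gcms = c(CGCM3 = 1.0, HADCM3 = 0.8),
                         co2_levels = c(high = 1.3, low = 0.9),
                         years = c(2020, 2050, 2080),
                         buffer_km = 10, known_range_coarsening = 5,
                         comparison_points = 250, cumulative_cutoff = 10,
                         beta_multiplier = 1, n_hinge_knots = 4,
                         n_threshold_knots = 4, run_glm = TRUE,
                         write_rasters = FALSE, base_seed = 1L) {
  bias <- match.arg(bias)
  stopifnot(inherits(landscape, "landscape_spec"), n_species >= 1,
            all(occurrences_per_species > 30), null_replicates >= 1,
            buffer_km >= 0, comparison_points >= 2)
  structure(list(landscape = landscape, n_species = n_species,
                 occurrences_per_species =
                   rep_len(occurrences_per_species, n_species),
                 bias = bias, pool_size = pool_size,
                 null_sizes = null_sizes, null_replicates = null_replicates,
                 gcms = gcms, co2_levels = co2_levels, years = years,
                 buffer_km = buffer_km,
                 known_range_coarsening = known_range_coarsening,
                 comparison_points = comparison_points,
                 cumulative_cutoff = cumulative_cutoff,
                 beta_multiplier = beta_multiplier,
                 n_hinge_knots = n_hinge_knots,
                 n_threshold_knots = n_threshold_knots,
                 run_glm = run_glm, write_rasters = write_rasters,
                 base_seed = as.integer(base_seed)),
            class = "study_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run a full synthetic study
#'
#' Executes simulate -> fit -> evaluate -> project -> quantify -> richness ->
#' stats under one [study_config()], writes CSV outputs plus a JSON manifest
#' (artifact, stage, md5) to `out_dir`, and returns the in-memory results.
#' Re-running with the same config reproduces byte-identical CSVs.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created; default: none, nothing written).
#' @return List with the stack, species, occurrence/background sets, fitted
#'   models, AUC/null-test table, change records, loss table, per-year ANOVA
#'   tables, richness maps and comparisons, and the manifest.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  seeds <- list(species = config$base_seed * 1000L,
                occurrences = config$base_seed * 1000L + 100L,
                background = config$base_seed * 1000L + 200L,
                nulls = config$base_seed * 1000L + 300L,
                points = config$base_seed * 1000L + 400L)

  stack <- stage("simulate", generate_climate_stack(config$landscape))
  species <- stage("simulate", lapply(seq_len(config$n_species), function(i) {
    random_virtual_species(stack, seed = seeds$species + i,
                           name = sprintf("vsp_%02d", i))
  }))
  bias <- if (config$bias == "collection") {
    collection_bias_surface(stack, seed = seeds$occurrences)
  } else NULL
  occ <- stage("simulate", lapply(seq_len(config$n_species), function(i) {
    sample_occurrences(species[[i]], stack, config$occurrences_per_species[i],
                       bias = bias, seed = seeds$occurrences + i,
                       for_modelling = TRUE)
  }))
  bg <- stage("simulate",
              build_target_group_background(occ, pool_size = config$pool_size,
                                            seed = seeds$background))

  null_cfg <- list(beta_multiplier = config$beta_multiplier,
                   n_hinge_knots = config$n_hinge_knots,
                   n_threshold_knots = config$n_threshold_knots)
  usable_sizes <- config$null_sizes[config$null_sizes <= bg$n]
  if (length(usable_sizes) < length(config$null_sizes)) {
    message("skipping null sizes larger than the background pool (",
            bg$n, " points)")
  }
  nulls <- stage("evaluate", lapply(seq_along(usable_sizes), function(k) {
    build_null_distribution(bg, stack, usable_sizes[k],
                            config$null_replicates, config = null_cfg,
                            seed = seeds$nulls + k)
  }))
  names(nulls) <- as.character(usable_sizes)

  strict <- threshold_rule("strict", config$cumulative_cutoff)
  liberal <- threshold_rule("liberal")
  deltas <- default_scenario_deltas(stack$layer_roles, years = config$years,
                                    gcm_warming = config$gcms,
                                    co2_multiplier = config$co2_levels)

  models <- vector("list", config$n_species)
  auc_rows <- list(); change_records <- list(); overlap_rows <- list()
  current_ranges <- list(strict = list(), liberal = list())
  scenario_ranges <- list()
  known_masks <- list()

  for (i in seq_len(config$n_species)) {
    sp <- species[[i]]
    fit <- stage("fit", fit_maxent(occ[[i]], bg, stack,
                                   beta_multiplier = config$beta_multiplier))
    models[[i]] <- fit
    surf <- stage("fit", to_cumulative(predict_raw(fit, stack)))
    auc <- stage("evaluate", compute_auc(surf, occ[[i]], bg))
    msize <- match_null_size(fit$sample_size, usable_sizes)
    sig <- test_significance(auc, nulls[[as.character(msize)]])
    auc_rows[[i]] <- data.frame(species = sp$name, n_records = occ[[i]]$n,
                                n_cells = fit$sample_size, auc = auc,
                                matched_size = msize,
                                percentile_95 = sig$percentile_95,
                                significant = sig$significant)

    known <- stage("project", generate_known_range(sp, stack,
                                                   config$known_range_coarsening))
    mask <- stage("project", buffer_mask(known, config$buffer_km))
    known_masks[[sp$name]] <- list(known = known, mask = mask)

    cur_clip <- list()
    for (rule in list(strict, liberal)) {
      cur <- binarize(surf, rule, fit$training_presence_raw,
                      provenance = list(species = sp$name, scenario = "current"))
      overlap_rows[[length(overlap_rows) + 1L]] <-
        data.frame(species = sp$name, threshold = rule$kind,
                   percent_overlap = percent_overlap(cur, known))
      cur_clip[[rule$kind]] <- clip_range(cur, mask)
      current_ranges[[rule$kind]][[sp$name]] <- cur_clip[[rule$kind]]
    }
    for (d in deltas) {
      fut_surf <- to_cumulative(predict_raw(fit, apply_scenario(stack, d)))
      for (rule in list(strict, liberal)) {
        fut <- clip_range(
          binarize(fut_surf, rule, fit$training_presence_raw,
                   provenance = list(species = sp$name,
                                     scenario = sprintf("%s_%s_%s", d$gcm,
                                                        d$co2, d$year))),
          mask)
        scen_key <- sprintf("%s_%s_%s_%s", d$gcm, d$co2, d$year, rule$kind)
        scenario_ranges[[scen_key]][[sp$name]] <- fut
        cc <- cur_clip[[rule$kind]]
        if (range_area(cc) > 0) {
          rec <- percent_change(cc, fut, species = sp$name)
          rec$gcm <- d$gcm; rec$co2 <- d$co2; rec$year <- d$year
          rec$centroid_latitude <- range_centroid_latitude(cc)
          change_records[[length(change_records) + 1L]] <- rec
        }
      }
    }
  }

  loss_table <- stage("quantify", {
    recs <- change_records
    if (length(recs)) {
      build_loss_table(recs,
                       year = vapply(recs, `[[`, numeric(1), "year"),
                       centroid_latitude = vapply(recs, `[[`, numeric(1),
                                                  "centroid_latitude"),
                       gcm = vapply(recs, `[[`, character(1), "gcm"),
                       co2 = vapply(recs, `[[`, character(1), "co2"))
    } else NULL
  })

  anova_tables <- list()
  if (config$run_glm && !is.null(loss_table)) {
    for (y in config$years) {
      d <- loss_table[loss_table$year == y, ]
      # the 26-parameter model needs spare df
      if (nrow(d) > 30 && length(unique(d$species)) >= 5) {
        anova_tables[[as.character(y)]] <-
          stage("stats", fit_factorial_glm(loss_table, y))
      }
    }
  }

  richness <- stage("richness", {
    known_stack <- stack_richness(lapply(known_masks, `[[`, "known"),
                                  provenance = list(scenario = "known"))
    cur_strict <- stack_richness(current_ranges$strict,
                                 provenance = list(scenario = "current",
                                                   threshold = "strict"))
    cur_liberal <- stack_richness(current_ranges$liberal,
                                  provenance = list(scenario = "current",
                                                    threshold = "liberal"))
    scen_maps <- lapply(scenario_ranges, stack_richness)
    comparisons <- list(
      strict_vs_liberal = compare_richness_at_points(
        cur_strict, cur_liberal, config$comparison_points, seed = seeds$points),
      known_vs_strict = compare_richness_at_points(
        known_stack, cur_strict, config$comparison_points, seed = seeds$points),
      known_vs_liberal = compare_richness_at_points(
        known_stack, cur_liberal, config$comparison_points, seed = seeds$points))
    list(known = known_stack, current_strict = cur_strict,
         current_liberal = cur_liberal, scenarios = scen_maps,
         comparisons = comparisons)
  })

  out <- list(config = config, stack = stack, species = species,
              occurrences = occ, background = bg, nulls = nulls,
              models = models, auc_table = do.call(rbind, auc_rows),
              overlap_table = do.call(rbind, overlap_rows),
              change_records = change_records, loss_table = loss_table,
              anova_tables = anova_tables, richness = richness,
              known_masks = known_masks)
  if (!is.null(out_dir)) out$manifest <- write_study_outputs(out, out_dir)
  out
}

# CSV + manifest writer; every artifact row records stage and md5
write_study_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  put <- function(obj, file, stage, writer = function(o, f) {
    write.csv(o, f, row.names = FALSE)
  }) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    artifacts[[length(artifacts) + 1L]] <<-
      list(file = file, stage = stage,
           md5 = unname(tools::md5sum(path)))
  }
  for (i in seq_along(res$occurrences)) {
    put(res$occurrences[[i]],
        sprintf("occurrences_%s.csv", res$occurrences[[i]]$species),
        "simulate", write_occurrences)
  }
  put(res$background, "background.csv", "simulate", write_occurrences)
  null_df <- do.call(rbind, lapply(res$nulls, function(nd) {
    data.frame(sample_size = nd$sample_size,
               replicate = seq_len(nd$n_replicates), auc = nd$auc_values)
  }))
  put(null_df, "null_distributions.csv", "evaluate")
  put(res$auc_table, "auc_results.csv", "evaluate")
  put(res$overlap_table, "overlap.csv", "quantify")
  if (!is.null(res$loss_table)) {
    put(res$loss_table, "loss_table.csv", "quantify")
  }
  for (y in names(res$anova_tables)) {
    put(as.data.frame(res$anova_tables[[y]]), sprintf("anova_%s.csv", y),
        "stats")
  }
  comp <- do.call(rbind, lapply(names(res$richness$comparisons), function(nm) {
    cc <- res$richness$comparisons[[nm]]
    data.frame(comparison = nm, t = cc$t, p = cc$p, df = cc$df,
               mean_diff = cc$mean_diff, degenerate = cc$degenerate)
  }))
  put(comp, "richness_comparisons.csv", "richness")
  if (isTRUE(res$config$write_rasters)) {
    put(res$richness$current_strict, "richness_current_strict.asc",
        "richness", write_range)
    put(res$richness$current_liberal, "richness_current_liberal.asc",
        "richness", write_range)
    put(res$richness$known, "richness_known.asc", "richness", write_range)
  }
  manifest <- list(created_by = "nichecast::run_study",
                   base_seed = res$config$base_seed,
                   artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
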