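#' Run the inferential layer on prepared condition tables
#'
#' Mirrors the analysis structure of a perspective-taking pain-empathy EMG
#' study: one mixed repeated-measures ANOVA per muscle (between factor:
#' participant gender; within factors: perspective, actor gender,
#' attractiveness, scene), a GRS ANOVA without the scene factor, contrasts of
#' each scene against the neutral-face scene for the corrugator, Sidak simple
#' effects of actor gender per scene, paired t / Cohen's d for the GRS
#' gender x attractiveness cells, and the trait-empathy correlation screen.
#'
#' @param condition_table condition table covering one or both muscles.
#' @param grs_table GRS condition table, or NULL to skip.
#' @param traits trait table with a `participant` column, or NULL to skip.
#' @return a named list of result tibbles.
#' @export
analyze_tables <- function(condition_table, grs_table = NULL, traits = NULL) {
  within <- c("perspective", "actor_gender", "attractiveness", "scene")
  res <- list()
  for (muscle in unique(condition_table$muscle)) {
    tab <- condition_table[condition_table$muscle == muscle, ]
    res[[paste0("anova_", tolower(muscle))]] <- mixed_rm_anova(
      tab, dv = "mean_rel", subject = "participant",
      within = within, between = "participant_gender")
    res[[paste0("scene_contrasts_", tolower(muscle))]] <- scene_contrasts(
      tab, dv = "mean_rel")
    res[[paste0("actor_gender_by_scene_", tolower(muscle))]] <-
      sidak_simple_effects(tab, dv = "mean_rel", effect = "actor_gender",
                           sliced_by = "scene")
  }
  if (!is.null(grs_table)) {
    res$anova_grs <- mixed_rm_anova(
      grs_table, dv = "grs", subject = "participant",
      within = c("perspective", "actor_gender", "attractiveness"),
      between = "participant_gender")
    cells <- collapse_cell_means(grs_table, "grs", "participant",
                                 c("actor_gender", "attractiveness"))
    pick <- function(g, a) {
      x <- cells[cells$actor_gender == g & cells$attractiveness == a, ]
      x$.value[match(sort(unique(cells$participant)), x$participant)]
    }
    comps <- list(
      c("F low vs M low", "F", "low", "M", "low"),
      c("F high vs M high", "F", "high", "M", "high"),
      c("F high vs F low", "F", "high", "F", "low"),
      c("M high vs M low", "M", "high", "M", "low"))
    res$grs_effect_sizes <- dplyr::bind_rows(lapply(comps, function(cm) {
      out <- paired_t_and_d(pick(cm[2], cm[3]), pick(cm[4], cm[5]))
      out$comparison <- cm[1]
      out
    }))
  }
  if (!is.null(traits)) {
    res$correlations <- correlation_screen(traits, condition_table)
  }
  res
}

#' Simulate, preprocess, aggregate and analyse a full experiment
#'
#' End-to-end driver: builds the randomized design, synthesizes and
#' preprocesses each participant's recording one at a time (recordings are
#' not kept in memory), generates ratings and trait scores, aggregates
#' condition tables, runs the inferential layer, and optionally writes every
#' intermediate table plus a provenance sidecar and a text report to
#' `out_dir`. Fully deterministic given `seed`.
#'
#' @param n_participants,n_female design size.
#' @param seed master seed; all stage substreams derive from it.
#' @param modulation,nuisance generative specifications.
#' @param filter conditioning-chain specification.
#' @param artifact_k artifact threshold multiplier.
#' @param grs_cell_means,grs_sd rating generator settings.
#' @param trait_coupling_r target EC / corrugator-responsiveness correlation.
#' @param out_dir output directory (created if needed), or NULL to skip
#'   writing.
#' @param verbose print stage progress.
#' @param ... further design arguments passed to [build_design()].
#' @return list with `design`, `trial_scene`, `condition_table`,
#'   `grs_table`, `ratings`, `traits`, `responsiveness`, `exclusions`, and
#'   `results` (the [analyze_tables()] output).
#' @export
run_pipeline <- function(n_participants = 51, n_female = 27, seed = 1L,
                         modulation = modulation_spec(),
                         nuisance = nuisance_spec(),
                         filter = filter_spec(),
                         artifact_k = 8,
                         grs_cell_means = default_grs_cell_means(),
                         grs_sd = 1,
                         trait_coupling_r = 0.42,
                         out_dir = NULL, verbose = TRUE, ...) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  design <- build_design(n_participants, n_female, seed = seed, ...)
  pids <- unique(design$events$participant)
  say("simulate+preprocess: %d participants, %d trials each",
      length(pids), design$trials_per_participant)

  trial_scene <- vector("list", length(pids))
  resp <- matrix(NA_real_, length(pids), 2, dimnames = list(pids, design$muscles))
  for (i in seq_along(pids)) {
    rec <- synthesize_recording(design, modulation, nuisance, pids[i])
    resp[i, ] <- rec$responsiveness[design$muscles]
    trial_scene[[i]] <- preprocess_recording(rec, design, spec = filter,
                                             artifact_k = artifact_k)
  }
  trial_scene <- dplyr::bind_rows(trial_scene)
  exclusions <- trial_scene |>
    dplyr::filter(.data$excluded, .data$scene == 1L) |>
    dplyr::count(.data$muscle, .data$reason)
  say("excluded trials: %s",
      if (nrow(exclusions)) paste(exclusions$muscle, exclusions$reason,
                                  exclusions$n, collapse = "; ") else "none")

  ratings <- generate_ratings(design, grs_cell_means, grs_sd)
  traits <- generate_traits(length(pids), trait_coupling_r, resp[, "CS"],
                            seed = participant_seed(seed, 0L, stream = 3L))
  traits$participant <- pids[traits$participant_index]

  condition_table <- build_condition_table(trial_scene, design$events,
                                           quiet = !verbose)
  grs_table <- build_grs_table(ratings, design$events)
  say("analyze: ANOVA per muscle + GRS, post hocs, correlation screen")
  results <- analyze_tables(condition_table, grs_table, traits)

  out <- list(design = design, trial_scene = trial_scene,
              condition_table = condition_table, grs_table = grs_table,
              ratings = ratings, traits = traits,
              responsiveness = tibble::tibble(participant = pids,
                                              CS = resp[, "CS"],
                                              OO = resp[, "OO"]),
              exclusions = exclusions, results = results)
  if (!is.null(out_dir)) write_pipeline_bundle(out, out_dir, seed = seed,
                                               artifact_k = artifact_k)
  invisible(out)
}

write_pipeline_bundle <- function(out, out_dir, seed, artifact_k) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) write_tsv_table(x, file.path(out_dir, name))
  w(out$design$events, "events.tsv")
  w(out$trial_scene, "trial_scene.tsv")
  w(out$condition_table, "condition_table.tsv")
  w(out$grs_table, "grs_table.tsv")
  w(out$ratings, "ratings.tsv")
  w(out$traits, "traits.tsv")
  w(out$responsiveness, "responsiveness.tsv")
  for (nm in names(out$results)) {
    w(tibble::as_tibble(out$results[[nm]]), paste0(nm, ".tsv"))
  }
  jsonlite::write_json(
    list(package = "facemg",
         version = as.character(utils::packageVersion("facemg")),
         seed = seed,
         artifact_k = artifact_k,
         n_participants = out$design$n_participants,
         n_female = out$design$n_female,
         sampling_rate = out$design$sampling_rate,
         scene_ms = out$design$scene_ms,
         excluded = if (nrow(out$exclusions)) out$exclusions else NULL,
         dropped = {
           d <- attr(out$condition_table, "dropped")
           if (!is.null(d) && nrow(d)) d else NULL
         }),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  writeLines(render_report(out), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

format_anova_lines <- function(tab, label) {
  c(sprintf("== %s ==", label),
    sprintf("  %-55s F(%d, %d) = %7.3f, p = %.4g, pes = %.3f",
            tab$effect, tab$df1, tab$df2, tab$f, tab$p, tab$pes))
}

render_report <- function(out) {
  lines <- c("facemg pipeline report", "")
  res <- out$results
  if (!is.null(res$anova_grs)) {
    lines <- c(lines, format_anova_lines(res$anova_grs, "Pain intensity (GRS)"))
    if (!is.null(res$grs_effect_sizes)) {
      es <- res$grs_effect_sizes
      lines <- c(lines, "  paired comparisons (gender x attractiveness):",
                 sprintf("    %-18s t(%d) = %7.3f, p = %.4g, d = %.2f (%s)",
                         es$comparison, es$df, es$t, es$p, es$d, es$label))
    }
    lines <- c(lines, "")
  }
  for (muscle in c("cs", "oo")) {
    key <- paste0("anova_", muscle)
    if (is.null(res[[key]])) next
    lines <- c(lines, format_anova_lines(res[[key]],
                                         sprintf("EMG %s muscle", toupper(muscle))))
    sc <- res[[paste0("scene_contrasts_", muscle)]]
    lines <- c(lines,
               "  scene contrasts vs scene 1 (Sidak):",
               sprintf("    %-20s diff = %+.4f, t(%d) = %6.2f, p_adj = %.4g",
                       sc$comparison, sc$mean_diff, sc$df, sc$t, sc$p_sidak),
               "")
  }
  if (!is.null(res$correlations)) {
    sig <- res$correlations[res$correlations$p_fdr < 0.05, ]
    lines <- c(lines, "== Trait-empathy correlation screen (BH-FDR) ==",
               sprintf("  %d correlations tested; %d significant at q < 0.05",
                       nrow(res$correlations), nrow(sig)))
    if (nrow(sig)) {
      lines <- c(lines,
                 sprintf("    %s x %s/%s/scene %s: r(%d) = %.2f, p_fdr = %.3f",
                         sig$subscale, sig$muscle, sig$perspective, sig$scene,
                         sig$df, sig$r, sig$p_fdr))
    }
  }
  lines
}

#' Read a pipeline configuration file
#'
#' YAML configuration with optional top-level keys `n_participants`,
#' `n_female`, `seed`, `grs_sd`, `trait_coupling_r`, `artifact_k`, and
#' nested `modulation`, `nuisance`, `filter` blocks whose entries are passed
#' to [modulation_spec()], [nuisance_spec()] and [filter_spec()].
#'
#' @param path path to the YAML file.
#' @return a named list of [run_pipeline()] arguments.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[setdiff(names(cfg), c("modulation", "nuisance", "filter"))]
  if (!is.null(cfg$modulation)) {
    args$modulation <- do.call(modulation_spec, cfg$modulation)
  }
  if (!is.null(cfg$nuisance)) args$nuisance <- do.call(nuisance_spec, cfg$nuisance)
  if (!is.null(cfg$filter)) args$filter <- do.call(filter_spec, cfg$filter)
  args
}
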