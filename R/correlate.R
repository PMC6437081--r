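#' FDR-screened trait-empathy correlations
#'
#' Pearson correlations between each IRI subscale (EC, PD, PT) and the
#' per-participant baseline-relative EMG response for every muscle x scene x
#' perspective combination (collapsed over the actor factors), with
#' Benjamini-Hochberg step-up false-discovery-rate adjustment. The FDR family
#' defaults to all correlations of a muscle (one screen per muscle, the scope
#' is configurable and recorded in the output).
#'
#' @param traits tibble with a `participant` column and subscale score
#'   columns.
#' @param condition_table condition table from [build_condition_table()].
#' @param subscales subscale columns to screen.
#' @param fdr_scope `"per_muscle"` (adjust within each muscle's set of
#'   correlations) or `"all"` (one family over the full screen).
#' @return tibble with one row per (subscale, muscle, perspective, scene):
#'   `r`, `df`, `n`, `p`, `p_fdr`, `fdr_scope`. Pairs with zero variance are
#'   skipped with a warning.
#' @export
correlation_screen <- function(traits, condition_table,
                               subscales = c("EC", "PD", "PT"),
                               fdr_scope = c("per_muscle", "all")) {
  fdr_scope <- match.arg(fdr_scope)
  if (!"participant" %in% names(traits)) {
    stopf("`traits` must contain a 'participant' column")
  }
  missing_sub <- setdiff(subscales, names(traits))
  if (length(missing_sub)) {
    stopf("subscale column(s) not found in `traits`: %s",
          paste(missing_sub, collapse = ", "))
  }
  responses <- condition_table |>
    dplyr::group_by(.data$participant, .data$muscle, .data$perspective,
                    .data$scene) |>
    dplyr::summarise(response = mean(.data$mean_rel), .groups = "drop")

  merged <- dplyr::inner_join(responses, traits, by = "participant")
  if (length(unique(merged$participant)) < 4L) {
    stopf("need at least 4 matched participants for correlations")
  }
  combos <- unique(merged[c("muscle", "perspective", "scene")])

  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- dplyr::inner_join(merged, combos[i, ],
                             by = c("muscle", "perspective", "scene"))
    n <- nrow(sub)
    if (n < 4L) stopf("need at least 4 matched participants for correlations")
    for (sc in subscales) {
      xs <- sub[[sc]]
      ys <- sub$response
      if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
        warnf("zero variance for %s x %s/%s/scene %s; pair skipped",
              sc, combos$muscle[i], combos$perspective[i], combos$scene[i])
        next
      }
      ct <- stats::cor.test(xs, ys, method = "pearson")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subscale = sc,
        muscle = combos$muscle[i],
        perspective = combos$perspective[i],
        scene = combos$scene[i],
        r = unname(ct$estimate), df = n - 2L, n = n, p = ct$p.value)
    }
  }
  if (!length(rows)) stopf("no valid correlation pairs (all skipped)")
  out <- dplyr::bind_rows(rows)
  if (fdr_scope == "per_muscle") {
    out <- out |>
      dplyr::group_by(.data$muscle) |>
      dplyr::mutate(p_fdr = stats::p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup()
  } else {
    out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  }
  out$fdr_scope <- fdr_scope
  out
}
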