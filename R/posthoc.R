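#' Sidak family-wise adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for a family of `m` comparisons; always at least
#' the raw p-value and capped at 1.
#'
#' @param p raw p-value(s).
#' @param m family size (default: `length(p)`).
#' @return adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (m < 1) stopf("family size must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  # pmax guards the adjusted >= raw invariant against floating-point round-off
  pmin(1, pmax(p, 1 - (1 - p)^m))
}

#' Paired t-test with Cohen's d
#'
#' The paired effect size is `d = mean(diff) / sd(diff)`, which equals
#' `t / sqrt(n)`. The qualitative label follows conventional cutpoints
#' (0.2 small, 0.5 medium, 0.8 large, 1.3 very large).
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return tibble with `t`, `df`, `n`, `p`, `d`, `label`, `mean_diff`.
#' @export
paired_t_and_d <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2) stopf("need at least 2 pairs")
  d_i <- x - y
  sdd <- stats::sd(d_i)
  if (!is.finite(sdd) || sdd == 0) {
    stopf("zero variance of the paired differences; t and d are undefined")
  }
  md <- mean(d_i)
  t <- md / (sdd / sqrt(n))
  d <- md / sdd
  lab <- cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, 1.3, Inf),
             labels = c("negligible", "small", "medium", "large", "very large"),
             right = FALSE)
  tibble::tibble(t = t, df = n - 1L, n = n,
                 p = 2 * stats::pt(-abs(t), n - 1L),
                 d = d, label = as.character(lab), mean_diff = md)
}

#' Paired Cohen's d recovered from a t statistic
#'
#' For a paired design, `d = t / sqrt(n)` with `n` the number of pairs;
#' useful for recomputing published effect sizes from printed t values.
#'
#' @param t paired t statistic(s).
#' @param n number of pairs (>= 2).
#' @return Cohen's d, same length as `t`.
#' @examples
#' paired_d_from_t(10.203, 51)  # 1.43
#' @export
paired_d_from_t <- function(t, n) {
  if (any(n < 2)) stopf("`n` must be at least 2")
  t / sqrt(n)
}

# per-subject cell means over the named factors, averaging everything else
collapse_cell_means <- function(data, dv, subject, keep) {
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(subject, keep)))) |>
    dplyr::summarise(.value = mean(.data[[dv]]), .groups = "drop")
}

#' Sidak-corrected simple main effects
#'
#' For each level of the slicing factor(s), compares the levels of `effect`
#' pairwise with a paired t-test on per-participant cell means (collapsed
#' over all remaining factors). The Sidak family is the full set of
#' comparisons produced by one call (one family per simple-effects analysis).
#'
#' @param data long data frame of cell means (e.g. a condition table).
#' @param dv response column name.
#' @param effect factor whose levels are compared.
#' @param sliced_by character vector of slicing factor(s).
#' @param subject subject identifier column.
#' @return tibble with one row per comparison per slice: slice columns,
#'   `comparison`, `mean_diff`, `t`, `df`, `p`, `p_sidak`, `m`.
#' @export
sidak_simple_effects <- function(data, dv, effect, sliced_by,
                                 subject = "participant") {
  data <- as.data.frame(data)
  levs <- unique(as.character(data[[effect]]))
  if (length(levs) < 2L) stopf("factor '%s' has fewer than 2 levels", effect)
  cells <- collapse_cell_means(data, dv, subject, c(sliced_by, effect))
  slices <- unique(cells[sliced_by])
  pairs <- utils::combn(levs, 2, simplify = FALSE)

  rows <- list()
  for (i in seq_len(nrow(slices))) {
    sl <- slices[i, , drop = FALSE]
    sub <- dplyr::inner_join(cells, sl, by = sliced_by)
    for (pr in pairs) {
      a <- sub[sub[[effect]] == pr[1], ]
      b <- sub[sub[[effect]] == pr[2], ]
      b <- b[match(a[[subject]], b[[subject]]), ]
      tt <- paired_t_and_d(a$.value, b$.value)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        sl,
        tibble::tibble(comparison = paste(pr[1], "-", pr[2]),
                       mean_diff = tt$mean_diff, t = tt$t, df = tt$df,
                       p = tt$p))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$m <- nrow(out)
  out$p_sidak <- sidak_adjust(out$p, m = nrow(out))
  out
}

#' Scene contrasts against a reference scene
#'
#' Compares every other scene with the reference scene (the neutral-face
#' scene by default) using paired t-tests on per-participant scene means
#' collapsed over the remaining within factors, Sidak-corrected for the
#' three comparisons.
#'
#' @param data long data frame of cell means with a scene column.
#' @param dv response column name.
#' @param subject subject identifier column.
#' @param scene scene column name.
#' @param reference reference scene level.
#' @return tibble with one row per contrast: `comparison`, `mean_diff`,
#'   `t`, `df`, `d`, `p`, `p_sidak`, `m`.
#' @export
scene_contrasts <- function(data, dv, subject = "participant",
                            scene = "scene", reference = 1) {
  data <- as.data.frame(data)
  levs <- unique(as.character(data[[scene]]))
  reference <- as.character(reference)
  if (!reference %in% levs) stopf("reference scene '%s' absent from data", reference)
  others <- setdiff(levs, reference)
  if (length(others) == 0L) stopf("no non-reference scenes to compare")
  cells <- collapse_cell_means(data, dv, subject, scene)
  ref <- cells[cells[[scene]] == reference, ]

  rows <- lapply(others, function(s) {
    b <- cells[cells[[scene]] == s, ]
    b <- b[match(ref[[subject]], b[[subject]]), ]
    tt <- paired_t_and_d(b$.value, ref$.value)
    tibble::tibble(comparison = paste("scene", s, "- scene", reference),
                   mean_diff = tt$mean_diff, t = tt$t, df = tt$df,
                   d = tt$d, p = tt$p)
  })
  out <- dplyr::bind_rows(rows)
  out$m <- nrow(out)
  out$p_sidak <- sidak_adjust(out$p, m = nrow(out))
  out
}
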