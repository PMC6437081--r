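#' Partial eta squared from an F statistic
#'
#' For any ANOVA effect, partial eta squared equals
#' `SS_effect / (SS_effect + SS_error)`, which is recoverable from the F
#' statistic and its degrees of freedom as `F * df1 / (F * df1 + df2)`.
#'
#' @param f F statistic(s), nonnegative.
#' @param df1,df2 numerator and denominator degrees of freedom (>= 1).
#' @return partial eta squared, same length as `f`.
#' @examples
#' partial_eta_squared(7.867, 1, 49)   # 0.138
#' partial_eta_squared(11.267, 3, 135) # 0.200
#' @export
partial_eta_squared <- function(f, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) stopf("degrees of freedom must be >= 1")
  if (any(f < 0)) stopf("F statistics must be nonnegative")
  f * df1 / (f * df1 + df2)
}

# Orthonormal effect contrasts for a factor with L levels (columns orthogonal
# to the unit vector, unit length).
orthonormal_contrasts <- function(L) {
  cc <- stats::contr.helmert(L)
  sweep(cc, 2, sqrt(colSums(cc^2)), "/")
}

#' Mixed-design repeated-measures ANOVA on cell means
#'
#' Univariate sums-of-squares decomposition for a balanced design with one
#' optional between-subjects factor and fully crossed within-subjects
#' factors, computed on per-participant condition cell means (the two-stage
#' approach: trials are averaged into cells first). Each purely-within effect
#' and its interaction with the between factor is tested against its own
#' interaction-with-subjects mean square; the between effect is tested
#' against subjects-within-groups. Computation applies orthonormal
#' within-subject contrasts per effect and general-linear-hypothesis sums of
#' squares on the between design (with sum-to-zero coding), which reproduces
#' the classical mixed-model ANOVA table and remains correct for unequal
#' group sizes (unweighted-means hypotheses).
#'
#' @param data long data frame of cell means.
#' @param dv name of the response column.
#' @param subject name of the subject identifier column.
#' @param within character vector of within-subject factor columns.
#' @param between optional name of the between-subjects factor column.
#' @param sphericity `"none"` (default; uncorrected univariate tests) or
#'   `"greenhouse-geisser"` to add epsilon-corrected p-values.
#' @return a tibble of class `femg_anova` with one row per effect: `effect`,
#'   `ss`, `df1`, `error_term`, `error_ss`, `df2`, `f`, `p`, `pes` (partial
#'   eta squared), and if requested `gg_epsilon`, `p_gg`.
#' @export
mixed_rm_anova <- function(data, dv, subject = "participant", within,
                           between = NULL,
                           sphericity = c("none", "greenhouse-geisser")) {
  sphericity <- match.arg(sphericity)
  data <- as.data.frame(data)
  for (v in c(dv, subject, within, between)) {
    if (!v %in% names(data)) stopf("column '%s' not found in `data`", v)
  }
  y <- data[[dv]]
  if (!is.numeric(y) || anyNA(y)) stopf("response must be numeric without NAs")

  subj <- factor(data[[subject]])
  wf <- lapply(data[within], function(x) if (is.factor(x)) droplevels(x) else factor(x))
  lv <- lapply(wf, levels)
  nlev <- lengths(lv)
  if (any(nlev < 2L)) stopf("every within factor needs at least 2 levels")
  m <- prod(nlev)

  # cell index with the first within factor varying fastest
  mult <- cumprod(c(1L, utils::head(nlev, -1L)))
  idx <- mapply(function(col, l) match(col, l), wf, lv)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = length(within))
  cell <- 1L + as.integer((idx - 1L) %*% mult)

  tab <- table(subj, cell)
  if (any(tab == 0L) || length(unique(c(tab))) != 1L) {
    stopf(paste("design is not balanced: every subject must contribute each",
                "within-subject cell equally often; aggregate trials to cell",
                "means (see build_condition_table) first"))
  }
  subjects <- levels(subj)
  n <- length(subjects)
  # equal replicate counts per cell (e.g. extra crossed factors present in
  # the data) are averaged into cell means
  reps <- c(tab)[1]
  idx <- match(subj, subjects) + n * (cell - 1L)
  acc <- rowsum(y, idx)
  Y <- matrix(0, n, m)
  Y[as.integer(rownames(acc))] <- acc[, 1] / reps

  # between design
  if (!is.null(between)) {
    gmap <- unique(data.frame(s = as.character(subj), g = as.character(data[[between]])))
    if (anyDuplicated(gmap$s)) stopf("subjects must each have a single '%s' level", between)
    g <- factor(gmap$g[match(subjects, gmap$s)])
    if (nlevels(g) < 2L) stopf("between factor needs at least 2 levels")
    if (any(table(g) < 2L)) stopf("need at least 2 subjects per between-factor level")
    X <- stats::model.matrix(~g, data = data.frame(g = g),
                             contrasts.arg = list(g = "contr.sum"))
  } else {
    X <- matrix(1, n, 1)
  }
  p <- ncol(X)
  XtXi <- solve(crossprod(X))

  effect_contrast <- function(in_effect) {
    Ms <- lapply(seq_along(nlev), function(j) {
      if (in_effect[j]) orthonormal_contrasts(nlev[j])
      else matrix(1 / sqrt(nlev[j]), nlev[j], 1)
    })
    Reduce(kronecker, rev(Ms))
  }

  rows <- list()
  add_row <- function(...) rows[[length(rows) + 1L]] <<- tibble::tibble(...)

  glh <- function(Z) {
    Bh <- XtXi %*% crossprod(X, Z)
    resid <- Z - X %*% Bh
    sse <- sum(resid^2)
    ss_mean <- sum(Bh[1, ]^2) / XtXi[1, 1]
    ss_grp <- if (p > 1) {
      M <- Bh[-1, , drop = FALSE]
      V <- XtXi[-1, -1, drop = FALSE]
      sum(M * solve(V, M))
    } else NA_real_
    list(ss_mean = ss_mean, ss_grp = ss_grp, sse = sse, resid = resid)
  }

  # between-subjects stratum
  if (!is.null(between)) {
    z0 <- Y %*% matrix(1 / sqrt(m), m, 1)
    fit0 <- glh(z0)
    if (fit0$sse <= 0) stopf("zero between-subjects error variance; F undefined")
    df2_b <- n - p
    f_b <- (fit0$ss_grp / (p - 1)) / (fit0$sse / df2_b)
    add_row(effect = between, ss = fit0$ss_grp, df1 = as.integer(p - 1),
            error_term = "subjects", error_ss = fit0$sse,
            df2 = as.integer(df2_b), f = f_b,
            p = stats::pf(f_b, p - 1, df2_b, lower.tail = FALSE),
            pes = fit0$ss_grp / (fit0$ss_grp + fit0$sse),
            gg_epsilon = NA_real_, p_gg = NA_real_)
  }

  # within strata: every non-empty subset of the within factors
  k <- length(within)
  for (mask in seq_len(2^k - 1L)) {
    in_effect <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    C <- effect_contrast(in_effect)
    q <- ncol(C)
    Z <- Y %*% C
    fit <- glh(Z)
    if (fit$sse <= 0) stopf("zero within-subjects error variance; F undefined")
    wname <- paste(within[in_effect], collapse = ":")
    err_label <- paste0(wname, ":subjects")
    df2 <- q * (n - p)

    gg_eps <- NA_real_
    if (sphericity == "greenhouse-geisser" && q > 1) {
      S <- crossprod(fit$resid) / (n - p)
      gg_eps <- max(1 / q, sum(diag(S))^2 / (q * sum(S^2)))
    } else if (sphericity == "greenhouse-geisser") {
      gg_eps <- 1
    }

    f_w <- (fit$ss_mean / q) / (fit$sse / df2)
    add_row(effect = wname, ss = fit$ss_mean, df1 = as.integer(q),
            error_term = err_label, error_ss = fit$sse, df2 = as.integer(df2),
            f = f_w, p = stats::pf(f_w, q, df2, lower.tail = FALSE),
            pes = fit$ss_mean / (fit$ss_mean + fit$sse),
            gg_epsilon = gg_eps,
            p_gg = if (!is.na(gg_eps)) {
              stats::pf(f_w, q * gg_eps, df2 * gg_eps, lower.tail = FALSE)
            } else NA_real_)

    if (!is.null(between)) {
      df1_i <- q * (p - 1)
      f_i <- (fit$ss_grp / df1_i) / (fit$sse / df2)
      add_row(effect = paste(between, wname, sep = ":"),
              ss = fit$ss_grp, df1 = as.integer(df1_i),
              error_term = err_label, error_ss = fit$sse,
              df2 = as.integer(df2), f = f_i,
              p = stats::pf(f_i, df1_i, df2, lower.tail = FALSE),
              pes = fit$ss_grp / (fit$ss_grp + fit$sse),
              gg_epsilon = gg_eps,
              p_gg = if (!is.na(gg_eps)) {
                stats::pf(f_i, df1_i * gg_eps, df2 * gg_eps, lower.tail = FALSE)
              } else NA_real_)
    }
  }

  out <- dplyr::bind_rows(rows)
  if (sphericity == "none") out$gg_epsilon <- out$p_gg <- NULL
  class(out) <- c("femg_anova", class(out))
  attr(out, "n_subjects") <- n
  attr(out, "between") <- between
  attr(out, "within") <- within
  out
}

#' @export
print.femg_anova <- function(x, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA (%d subjects)\n",
              attr(x, "n_subjects")))
  df <- as.data.frame(x)
  for (v in intersect(c("ss", "error_ss"), names(df))) df[[v]] <- signif(df[[v]], 5)
  for (v in intersect(c("f", "pes"), names(df))) df[[v]] <- round(df[[v]], 3)
  if ("p" %in% names(df)) df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
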