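#' Normality gate for choosing parametric versus rank analyses
#'
#' Shapiro-Wilk at alpha = 0.05. A constant sample has no defined test
#' and is treated as non-normal.
#'
#' @param values Numeric vector, `NA`s removed internally; at least 3
#'   finite values required.
#' @return `TRUE` when the sample is compatible with normality
#'   (Shapiro-Wilk p >= 0.05).
#' @export
shapiro_gate <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    stop("shapiro_gate needs at least 3 finite values", call. = FALSE)
  }
  if (sd(values) == 0) return(FALSE)
  shapiro.test(values)$p.value >= 0.05
}

.midrank <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  out[ok] <- rank(x[ok], ties.method = "average")
  out
}

#' One-covariate ANCOVA group comparison
#'
#' Fits `dv ~ group + covariate` (no interaction) and tests the group
#' term with the covariate partialled out (Type III sum of squares;
#' with a single two-level factor and one covariate this is the
#' drop-term F). Reports partial eta squared
#' `SS_group / (SS_group + SS_residual)` and Levene's test
#' (mean-centred) for homogeneity of variances. With `rank = TRUE` the
#' dependent variable and the covariate are first replaced by their
#' pooled midranks (rank ANCOVA in the Conover-Iman sense); a
#' completely tied dependent variable yields F = 0 by convention.
#'
#' @param data A data frame.
#' @param dv Name of the dependent-variable column (string).
#' @param group Name of the two-level group column.
#' @param covariate Name of the covariate column.
#' @param rank Fit on midranks of dv and covariate.
#' @return An object of class `ja_ancova`; see [tidy.ja_ancova()].
#' @export
ja_ancova <- function(data, dv, group = "group", covariate = "covariate",
                      rank = FALSE) {
  d <- tibble::tibble(
    dv = data[[dv]],
    group = as.character(data[[group]]),
    covariate = data[[covariate]]
  )
  d <- d[is.finite(d$dv) & is.finite(d$covariate) & !is.na(d$group), ]
  counts <- table(d$group)
  if (length(counts) < 2 || any(counts < 2)) {
    stop(sprintf("analysis error for '%s': need >= 2 observations per group after removing missing values", dv),
         call. = FALSE)
  }
  group_stats <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$dv), sd = sd(.data$dv),
                     n = dplyr::n(), .groups = "drop")
  ydat <- d
  if (rank) {
    ydat$dv <- .midrank(ydat$dv)
    ydat$covariate <- .midrank(ydat$covariate)
  }
  g <- factor(ydat$group)
  fit_full <- lm(dv ~ g + covariate, data = ydat)
  fit_null <- lm(dv ~ covariate, data = ydat)
  rss_full <- sum(resid(fit_full)^2)
  rss_null <- sum(resid(fit_null)^2)
  ss_group <- max(rss_null - rss_full, 0)
  df1 <- nlevels(g) - 1
  df2 <- nrow(ydat) - nlevels(g) - 1
  # a dv with zero variance (e.g. all-tied ranks) carries no information
  tot_ss <- sum((ydat$dv - mean(ydat$dv))^2)
  if (tot_ss <= 1e-12 * max(1, mean(ydat$dv)^2)) ss_group <- 0
  if (ss_group <= 0 || df2 <= 0) {
    f_val <- 0; p_val <- 1; eta2 <- 0
  } else if (rss_full <= 0) {
    f_val <- Inf; p_val <- 0; eta2 <- 1
  } else {
    f_val <- (ss_group / df1) / (rss_full / df2)
    p_val <- pf(f_val, df1, df2, lower.tail = FALSE)
    eta2 <- ss_group / (ss_group + rss_full)
  }
  lev <- tryCatch(
    suppressWarnings(car::leveneTest(ydat$dv, g, center = mean)$`Pr(>F)`[1]),
    error = function(e) NA_real_
  )
  structure(
    list(
      variable = dv, group_stats = group_stats,
      F = f_val, df1 = df1, df2 = df2, p = p_val,
      eta2_partial = eta2, ranked = rank, levene_p = lev,
      n = nrow(ydat), fit = fit_full
    ),
    class = "ja_ancova"
  )
}

#' @rdname ja_ancova
#' @export
ja_rank_ancova <- function(data, dv, group = "group", covariate = "covariate") {
  ja_ancova(data, dv, group = group, covariate = covariate, rank = TRUE)
}

#' @export
print.ja_ancova <- function(x, ...) {
  cat(sprintf("<ja_ancova%s> %s: F(%d, %d) = %.3f, p = %.4g, partial eta2 = %.3f\n",
              if (x$ranked) " on ranks" else "", x$variable,
              x$df1, x$df2, x$F, x$p, x$eta2_partial))
  invisible(x)
}

#' Tidy an ANCOVA group comparison
#'
#' @param x A [ja_ancova()] object.
#' @param ... Unused.
#' @return A one-row tibble with the test statistics and, spread wide,
#'   the per-group means/sds.
#' @export
tidy.ja_ancova <- function(x, ...) {
  gs <- x$group_stats
  wide <- stats::setNames(
    as.list(c(gs$mean, gs$sd)),
    c(paste0("mean_", gs$group), paste0("sd_", gs$group))
  )
  dplyr::bind_cols(
    tibble::tibble(variable = x$variable),
    tibble::as_tibble(wide),
    tibble::tibble(
      F = x$F, df1 = x$df1, df2 = x$df2, p = x$p,
      eta2_partial = x$eta2_partial, ranked = x$ranked,
      levene_p = x$levene_p
    )
  )
}

#' @rdname tidy.ja_ancova
#' @export
glance.ja_ancova <- function(x, ...) {
  tibble::tibble(n = x$n, df1 = x$df1, df2 = x$df2,
                 F = x$F, p = x$p, eta2_partial = x$eta2_partial,
                 ranked = x$ranked)
}

#' Benjamini-Hochberg false-discovery-rate decisions
#'
#' Step-up procedure at level `q`: sort the p-values, find the largest k
#' with `p_(k) <= k q / m`, reject hypotheses 1..k.
#'
#' @param pvalues Numeric vector in `[0, 1]` (`NA` allowed; an `NA`
#'   p-value is never rejected).
#' @param q FDR level.
#' @return Logical rejection flags, same order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all rejected at q = 0.05
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(FALSE, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH") <= q
  out
}

#' Distribution-gated correlation
#'
#' Pearson when both variables pass the normality gate
#' ([shapiro_gate()]), Spearman otherwise — the usual rule when some
#' eye-tracking measures are heavily skewed.
#'
#' @param data A data frame.
#' @param x,y Column names (strings).
#' @return One-row tibble `var_x, var_y, method, r, p, n`; `r` is `NA`
#'   (with `method = "undefined"`) when either variable is constant.
#' @export
correlate_auto <- function(data, x, y) {
  xv <- data[[x]]; yv <- data[[y]]
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 4) {
    stop("correlate_auto needs at least 4 complete pairs", call. = FALSE)
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    return(tibble::tibble(var_x = x, var_y = y, method = "undefined",
                          r = NA_real_, p = NA_real_, n = length(xv)))
  }
  method <- if (shapiro_gate(xv) && shapiro_gate(yv)) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(xv, yv, method = method, exact = FALSE))
  tibble::tibble(var_x = x, var_y = y, method = method,
                 r = unname(ct$estimate), p = ct$p.value, n = length(xv))
}

#' Repeated-measures ANOVA on usable-trial counts
#'
#' Two-way mixed ANOVA with task as the within-subject factor and group
#' as the between-subject factor, used to check that trial attrition is
#' even across tasks and groups. Fitted with an `aov` error stratum per
#' participant; requires a complete (balanced) participant x task table
#' and at least two participants per group.
#'
#' @param data Data frame with columns `participant_id, group, task` and
#'   the count column `n_usable`.
#' @param dv Name of the count column.
#' @return Tibble `term, df1, df2, F, p` for the task and group:task
#'   effects (and the between-subject group effect).
#' @export
usable_trials_anova <- function(data, dv = "n_usable") {
  d <- tibble::tibble(
    y = data[[dv]],
    participant_id = factor(data$participant_id),
    group = factor(data$group),
    task = factor(data$task)
  )
  tab <- table(d$participant_id, d$task)
  if (any(tab != 1)) {
    stop("analysis error: each participant needs exactly one count per task",
         call. = FALSE)
  }
  if (nlevels(d$participant_id) < 4 || any(table(unique(d[c("participant_id", "group")])$group) < 2)) {
    stop("analysis error: at least two participants per group required",
         call. = FALSE)
  }
  fit <- aov(y ~ group * task + Error(participant_id), data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    st <- stratum[[1]]
    terms <- trimws(rownames(st))
    resid_row <- terms == "Residuals"
    df2 <- st$Df[resid_row]
    for (i in which(!resid_row)) {
      f <- st$`F value`[i]
      # effect sums of squares at numerical zero (constant counts) are a
      # null effect, not a 0/0 artefact
      if (is.na(f) || st$`Sum Sq`[i] < 1e-10 * max(1, sum(st$`Sum Sq`))) {
        f <- 0; p <- 1
      } else {
        p <- st$`Pr(>F)`[i]
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        term = terms[i], df1 = st$Df[i], df2 = df2, F = f, p = p
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Compare groups on a set of participant measures
#'
#' For each variable: the Shapiro-Wilk gate is applied per group; when
#' both groups look normal a parametric ANCOVA is used, otherwise the
#' rank ANCOVA. FDR correction (Benjamini-Hochberg, `q`) is applied
#' within each family; by default the family is the set of variables
#' tested within one task.
#'
#' @param measures Per-participant measures (see
#'   [participant_measures()]) for one task, or with a `task` column.
#' @param vars Character vector of measure columns to test.
#' @param group,covariate Column names.
#' @param q FDR level.
#' @param family `"task"` (default) corrects within task; `"global"`
#'   corrects across everything tested in this call.
#' @return A tibble with one row per variable (and task): group means
#'   and sds, F, p, partial eta squared, rank flag, Levene p and the FDR
#'   decision.
#' @export
compare_groups <- function(measures, vars, group = "group",
                           covariate = "covariate", q = 0.05,
                           family = c("task", "global")) {
  family <- match.arg(family)
  has_task <- "task" %in% names(measures)
  tasks <- if (has_task) unique(measures$task) else NA_character_
  rows <- list()
  for (tk in tasks) {
    d <- if (has_task) measures[measures$task == tk, , drop = FALSE] else measures
    for (v in vars) {
      vals <- d[[v]]
      ok <- is.finite(vals)
      by_group <- split(vals[ok], d[[group]][ok])
      normal <- length(by_group) == 2 && all(lengths(by_group) >= 3) &&
        all(vapply(by_group, shapiro_gate, logical(1)))
      cmp <- tryCatch(
        ja_ancova(d, v, group = group, covariate = covariate, rank = !normal),
        error = function(e) NULL
      )
      if (is.null(cmp)) next
      row <- tidy(cmp)
      row <- dplyr::bind_cols(tibble::tibble(task = tk), row)
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  if (family == "task" && has_task) {
    out <- out |>
      dplyr::group_by(.data$task) |>
      dplyr::mutate(fdr_significant = bh_fdr(.data$p, q)) |>
      dplyr::ungroup()
  } else {
    out$fdr_significant <- bh_fdr(out$p, q)
  }
  class(out) <- c("ja_comparisons", class(out))
  out
}
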