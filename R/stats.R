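#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA computed directly from sums of
#' squares: F = MS_between / MS_within with (k - 1, N - k) degrees of
#' freedom, p from the F distribution.
#'
#' @param groups Named list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values).
#' @return Object of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `ms_within`, `group_means`, `group_n`, `degenerate` (TRUE when the
#'   within-group variance is zero with unequal means, in which case p = 0).
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values")
  n <- lengths(groups)
  means <- vapply(groups, mean, 0)
  N <- sum(n); k <- length(groups)
  gm <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - gm)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- k - 1L; df_w <- N - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  degenerate <- FALSE
  if (ms_w == 0) {
    if (ss_between == 0) { Fv <- 0; p <- 1 } else {
      Fv <- Inf; p <- 0; degenerate <- TRUE
      warning("zero within-group variance with unequal means; p set to 0")
    }
  } else {
    Fv <- ms_b / ms_w
    p <- stats::pf(Fv, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(F = Fv, df_between = df_b, df_within = df_w, p = p,
                 ms_within = ms_w, group_means = means, group_n = n,
                 degenerate = degenerate),
            class = "anova_result")
}

#' Student-Newman-Keuls post-hoc test
#'
#' Stepwise studentized-range procedure following a one-way ANOVA. Group
#' means are ordered; the range of each contiguous span of p means is
#' compared against q(1 - alpha; p, df_within) * sqrt(MS_within / n_h)
#' (n_h the harmonic mean group size), stepping down from the full span.
#' A pair nested inside a span already declared homogeneous is never tested
#' significant. Quantiles come from the studentized-range distribution
#' ([stats::qtukey()]).
#'
#' @param groups Named list of numeric vectors (as for [one_way_anova()]).
#' @param alpha Significance level. Default 0.05.
#' @return Object of class `snk_result`: data.frame `pairs` with columns
#'   `group1`, `group2`, `mean_diff`, `span`, `q_observed`, `q_critical`,
#'   `critical_range`, `significant`; plus `alpha`, `n_harmonic`,
#'   `anova` (the underlying [one_way_anova()] result).
#' @export
snk_test <- function(groups, alpha = 0.05) {
  aov_res <- suppressWarnings(one_way_anova(groups))
  k <- length(groups)
  n <- lengths(groups)
  n_h <- k / sum(1 / n)
  unequal <- length(unique(n)) > 1L
  if (unequal) {
    message(sprintf("unequal group sizes; using harmonic mean n = %.3f", n_h))
  }
  se <- sqrt(aov_res$ms_within / n_h)
  means <- sort(aov_res$group_means)
  labs <- names(means)
  df_w <- aov_res$df_within

  # significant[i, j]: verdict for the pair spanning sorted positions i..j
  sig <- matrix(NA, k, k)
  test_span <- function(i, j) {
    if (j <= i || !is.na(sig[i, j])) return(invisible())
    span <- j - i + 1L
    if (se == 0) {
      is_sig <- means[j] != means[i]   # degenerate: zero within-group variance
    } else {
      q_obs <- (means[j] - means[i]) / se
      q_crit <- stats::qtukey(1 - alpha, span, df_w)
      is_sig <- q_obs > q_crit
    }
    if (!is_sig) {
      for (a in i:(j - 1)) for (b in (a + 1):j) {
        if (is.na(sig[a, b])) sig[a, b] <<- FALSE
      }
    } else {
      sig[i, j] <<- TRUE
      test_span(i, j - 1L)
      test_span(i + 1L, j)
    }
    invisible()
  }
  if (k >= 2) test_span(1L, k)

  rows <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    span <- j - i + 1L
    q_crit <- if (se == 0) NA_real_ else stats::qtukey(1 - alpha, span, df_w)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = labs[i], group2 = labs[j],
      mean_diff = means[j] - means[i], span = span,
      q_observed = if (se == 0) NA_real_ else (means[j] - means[i]) / se,
      q_critical = q_crit,
      critical_range = q_crit * se,
      significant = isTRUE(sig[i, j]),
      stringsAsFactors = FALSE)
  }
  structure(list(pairs = do.call(rbind, rows), alpha = alpha,
                 n_harmonic = n_h, anova = aov_res),
            class = "snk_result")
}

#' Is a given pair significant in an SNK result?
#' @param snk An `snk_result`.
#' @param g1,g2 Group labels.
#' @return Logical.
#' @export
snk_pair_significant <- function(snk, g1, g2) {
  p <- snk$pairs
  hit <- (p$group1 == g1 & p$group2 == g2) | (p$group1 == g2 & p$group2 == g1)
  if (!any(hit)) stop("pair not found in SNK result")
  unname(p$significant[hit])
}

#' Summarise per-subject metrics by group and test group differences
#'
#' Takes a per-subject metrics table and produces, per metric, the group
#' mean +/- SEM summary plus a one-way ANOVA with SNK post-hoc comparisons
#' (skipped, with a note, when fewer than two groups have two or more
#' subjects).
#'
#' @param metrics Data.frame with columns `subject_id`, `group`, and one
#'   numeric column per metric (e.g. `D_star`, `lambda`, `k_prime`,
#'   `t_half`, `v_max`).
#' @param alpha Significance level for SNK. Default 0.05.
#' @return Object of class `group_report`: `summary` (data.frame metric x
#'   group with n, mean, sem), `tests` (named list of `snk_result` or NULL
#'   per metric), `alpha`.
#' @export
summarize_groups <- function(metrics, alpha = 0.05) {
  stopifnot(is.data.frame(metrics), all(c("subject_id", "group") %in%
                                          names(metrics)))
  metric_cols <- setdiff(names(metrics), c("subject_id", "group"))
  if (!length(metric_cols)) stop("no metric columns present")
  rows <- list(); tests <- list()
  for (mc in metric_cols) {
    vals <- metrics[[mc]]
    ok <- is.finite(vals)
    if (any(!ok)) {
      warning(sprintf("%d subject(s) missing metric '%s'; excluded",
                      sum(!ok), mc))
    }
    sub <- metrics[ok, ]
    for (g in unique(sub$group)) {
      v <- sub[[mc]][sub$group == g]
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mc, group = g, n = length(v), mean = mean(v),
        sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
        stringsAsFactors = FALSE)
    }
    gl <- split(sub[[mc]], sub$group)
    gl <- gl[lengths(gl) >= 2L]
    tests[[mc]] <- if (length(gl) >= 2L) snk_test(gl, alpha = alpha) else NULL
  }
  structure(list(summary = do.call(rbind, rows), tests = tests, alpha = alpha),
            class = "group_report")
}

#' Draw a synthetic per-subject metrics table
#'
#' Emulates a between-subject experiment at the metrics level: each group's
#' subjects are drawn Normal(mean, sd) independently per metric. Used for
#' power checks of the ANOVA + SNK stage.
#'
#' @param means Data.frame or matrix, groups x metrics, of central values
#'   (rownames = group labels, colnames = metric names).
#' @param sds Same shape: between-subject standard deviations.
#' @param n_per_group Subjects per group.
#' @param seed Optional integer seed.
#' @return Data.frame with `subject_id`, `group`, and one column per metric.
#' @export
simulate_metric_study <- function(means, sds, n_per_group = 10L, seed = NULL) {
  means <- as.matrix(means); sds <- as.matrix(sds)
  stopifnot(identical(dim(means), dim(sds)))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  out <- list()
  for (g in rownames(means)) {
    df <- data.frame(
      subject_id = sprintf("%s-%02d", g, seq_len(n_per_group)),
      group = g, stringsAsFactors = FALSE)
    for (mc in colnames(means)) {
      df[[mc]] <- stats::rnorm(n_per_group, means[g, mc], sds[g, mc])
    }
    out[[g]] <- df
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' @export
print.snk_result <- function(x, ...) {
  print(x$anova)
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
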