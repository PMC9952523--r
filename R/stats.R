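#' One-way fixed-effects ANOVA
#'
#' Closed-form one-way ANOVA of a metric across gait-score groups:
#' `F = MS_between / MS_within` with `(k - 1, N - k)` degrees of
#' freedom.  Degenerate variance structures are flagged instead of
#' failing: zero variance everywhere gives `p = 1` by convention, and
#' zero within-group variance with real group differences gives
#' `F = Inf`, `p = 0`.
#'
#' @param data Data frame with one row per experimental unit (bird).
#' @param value Column name (string) of the response.
#' @param group Column name (string) of the grouping factor.
#' @return One-row tibble: `F`, `df_between`, `df_within`, `p_value`,
#'   `ms_within`, `degenerate`.
#' @export
one_way_anova <- function(data, value = "value", group = "gait_score") {
  v <- data[[value]]
  g <- as.factor(data[[group]])
  if (any(!is.finite(v))) stop("values must be finite", call. = FALSE)
  ng <- table(g)
  if (length(ng) < 2L || any(ng < 2L)) {
    stop("ANOVA needs at least 2 groups with at least 2 values each",
         call. = FALSE)
  }
  k <- length(ng)
  n_tot <- length(v)
  gm <- tapply(v, g, mean)
  grand <- mean(v)
  ss_b <- sum(as.numeric(ng) * (gm - grand)^2)
  ss_w <- sum((v - gm[g])^2)
  df_b <- k - 1L
  df_w <- n_tot - k
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  if (ms_w == 0) {
    degen <- TRUE
    if (ms_b == 0) {
      f <- NA_real_; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    degen <- FALSE
    f <- ms_b / ms_w
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  tibble::tibble(F = f, df_between = df_b, df_within = df_w, p_value = p,
                 ms_within = ms_w, degenerate = degen)
}

#' Pooled standard error of a group mean
#'
#' `sqrt(MS_within / n)` with `n` the common group size.  For
#' unbalanced groups the pooled value is `NA` and per-group standard
#' errors `sqrt(MS_within / n_g)` are attached as the `"per_group"`
#' attribute.
#'
#' @inheritParams one_way_anova
#' @return A single number (or `NA` with a `"per_group"` tibble
#'   attribute when unbalanced).
#' @export
pooled_se <- function(data, value = "value", group = "gait_score") {
  a <- one_way_anova(data, value, group)
  ng <- table(as.factor(data[[group]]))
  per <- tibble::tibble(
    group = names(ng), n = as.integer(ng),
    se = sqrt(a$ms_within / as.integer(ng))
  )
  if (length(unique(as.integer(ng))) == 1L) {
    out <- sqrt(a$ms_within / as.integer(ng[1L]))
  } else {
    out <- NA_real_
  }
  attr(out, "per_group") <- per
  out
}

#' Fisher's LSD pairwise comparisons with letter display
#'
#' Unprotected least-significant-difference tests: every pair of groups
#' is compared with a two-sided t-test using the ANOVA `MS_within` and
#' residual degrees of freedom, regardless of the omnibus p-value (the
#' convention under which letters accompany non-significant rows in a
#' means table).  Letters come from the insert-and-absorb display
#' algorithm with groups ordered by descending mean, so two groups share
#' a letter exactly when their pairwise p-value exceeds `alpha`.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level (default 0.05).
#' @return A list of class `fisher_lsd`: `pairwise` (tibble with
#'   `group1`, `group2`, `diff`, `se_diff`, `t`, `p_value`) and
#'   `letters` (tibble with `group`, `n`, `mean`, `letter`, ordered by
#'   descending mean).
#' @export
fisher_lsd <- function(data, value = "value", group = "gait_score",
                       alpha = 0.05) {
  a <- one_way_anova(data, value, group)
  v <- data[[value]]
  g <- as.factor(data[[group]])
  ng <- table(g)
  gm <- tapply(v, g, mean)
  ord <- order(-gm)
  lev <- names(gm)[ord]
  pairs <- utils::combn(lev, 2L)
  diffs <- gm[pairs[1L, ]] - gm[pairs[2L, ]]
  se_d <- sqrt(a$ms_within * (1 / as.numeric(ng[pairs[1L, ]]) +
                                1 / as.numeric(ng[pairs[2L, ]])))
  tval <- ifelse(se_d == 0, ifelse(diffs == 0, 0, Inf * sign(diffs)),
                 diffs / se_d)
  pv <- ifelse(se_d == 0, ifelse(diffs == 0, 1, 0),
               2 * stats::pt(abs(tval), a$df_within, lower.tail = FALSE))
  pairwise <- tibble::tibble(
    group1 = pairs[1L, ], group2 = pairs[2L, ],
    diff = as.numeric(diffs), se_diff = se_d,
    t = as.numeric(tval), p_value = as.numeric(pv)
  )
  sig <- pairwise[pairwise$p_value <= alpha, , drop = FALSE]
  letters_tbl <- letter_display(lev, sig)
  letters_tbl$n <- as.integer(ng[letters_tbl$group])
  letters_tbl$mean <- as.numeric(gm[letters_tbl$group])
  structure(list(pairwise = pairwise,
                 letters = letters_tbl[, c("group", "n", "mean", "letter")],
                 alpha = alpha),
            class = "fisher_lsd")
}

#' @export
print.fisher_lsd <- function(x, ...) {
  cat(sprintf("<fisher_lsd> alpha = %g\n", x$alpha))
  print(x$letters)
  invisible(x)
}

# insert-and-absorb compact letter display.
# `lev`: groups ordered by descending mean; `sig`: pairs that differ.
letter_display <- function(lev, sig) {
  cols <- list(lev)
  if (nrow(sig) > 0L) {
    for (i in seq_len(nrow(sig))) {
      g1 <- sig$group1[i]; g2 <- sig$group2[i]
      nxt <- list()
      for (col in cols) {
        if (g1 %in% col && g2 %in% col) {
          nxt <- c(nxt, list(setdiff(col, g1)), list(setdiff(col, g2)))
        } else {
          nxt <- c(nxt, list(col))
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(nxt))
      for (aa in seq_along(nxt)) {
        for (bb in seq_along(nxt)) {
          if (aa != bb && keep[aa] &&
              all(nxt[[aa]] %in% nxt[[bb]]) &&
              (length(nxt[[aa]]) < length(nxt[[bb]]) || aa > bb)) {
            keep[aa] <- FALSE
          }
        }
      }
      cols <- nxt[keep]
    }
  }
  # order columns by the rank of their best (highest-mean) member
  first_rank <- vapply(cols, function(col) min(match(col, lev)), numeric(1L))
  cols <- cols[order(first_rank)]
  lab <- letters[seq_along(cols)]
  letter_of <- vapply(lev, function(g) {
    paste0(lab[vapply(cols, function(col) g %in% col, logical(1L))],
           collapse = "")
  }, character(1L))
  tibble::tibble(group = lev, letter = unname(letter_of))
}

#' Compare all locomotion metrics across gait scores
#'
#' Runs [one_way_anova()], [pooled_se()] and [fisher_lsd()] for every
#' metric column of a per-bird summary table.  Birds with an absent
#' (`NA`) value for a metric — e.g. no detected bouts — are excluded
#' from that metric's analysis and counted in `n_excluded`.
#'
#' @param data Per-bird tibble with `bird_id`, `gait_score` and metric
#'   columns (all numeric columns except identifiers are treated as
#'   metrics).
#' @param alpha Significance level for the letter display.
#' @return A `gait_comparison` object: tibble `results` with one row
#'   per metric (`metric`, `n_used`, `n_excluded`, `F`, `df_between`,
#'   `df_within`, `p_value`, `degenerate`, `pooled_se`, and list-columns
#'   `letters`, `pairwise`) plus the `alpha` used.
#' @export
compare_metrics <- function(data, alpha = 0.05) {
  if (!all(c("bird_id", "gait_score") %in% names(data))) {
    stop("`data` needs bird_id and gait_score columns", call. = FALSE)
  }
  metric_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1L))],
                         c("gait_score"))
  rows <- list()
  for (m in metric_cols) {
    if (all(is.na(data[[m]]))) next      # metric absent for every bird
    d <- data[!is.na(data[[m]]), c("gait_score", m)]
    names(d)[2L] <- "value"
    n_excl <- sum(is.na(data[[m]]))
    ng <- table(as.factor(d$gait_score))
    if (length(ng) < 2L || any(ng < 2L)) {
      warning("metric ", m, " skipped: fewer than 2 groups with 2 values",
              call. = FALSE)
      next
    }
    a <- one_way_anova(d)
    se <- pooled_se(d)
    lsd <- fisher_lsd(d, alpha = alpha)
    rows[[m]] <- tibble::tibble(
      metric = m, n_used = nrow(d), n_excluded = n_excl,
      F = a$F, df_between = a$df_between, df_within = a$df_within,
      p_value = a$p_value, degenerate = a$degenerate,
      pooled_se = as.numeric(se),
      letters = list(lsd$letters), pairwise = list(lsd$pairwise)
    )
  }
  empty <- tibble::tibble(
    metric = character(), n_used = integer(), n_excluded = integer(),
    F = double(), df_between = integer(), df_within = integer(),
    p_value = double(), degenerate = logical(), pooled_se = double(),
    letters = list(), pairwise = list()
  )
  structure(list(results = dplyr::bind_rows(c(list(empty), rows)),
                 alpha = alpha),
            class = "gait_comparison")
}

#' @export
print.gait_comparison <- function(x, ...) {
  cat(sprintf("<gait_comparison> %d metrics, alpha = %g\n",
              nrow(x$results), x$alpha))
  print(x$results[, c("metric", "n_used", "F", "p_value", "pooled_se")])
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-group summaries of a gait comparison
#'
#' One row per metric and gait score: group mean, group size, pooled
#' standard error, letter, and the metric's omnibus p-value.
#'
#' @param x A `gait_comparison`.
#' @param ... Unused.
#' @method tidy gait_comparison
#' @export
tidy.gait_comparison <- function(x, ...) {
  if (nrow(x$results) == 0L) {
    return(tibble::tibble(metric = character(), p_value = double(),
                          pooled_se = double(), gait_score = character(),
                          n = integer(), mean = double(),
                          letter = character()))
  }
  out <- tidyr::unnest(x$results[, c("metric", "p_value", "pooled_se",
                                     "letters")],
                       "letters")
  dplyr::rename(out, gait_score = "group")
}

#' Per-metric ANOVA summaries of a gait comparison
#'
#' @param x A `gait_comparison`.
#' @param ... Unused.
#' @method glance gait_comparison
#' @export
glance.gait_comparison <- function(x, ...) {
  x$results[, c("metric", "n_used", "n_excluded", "F", "df_between",
                "df_within", "p_value", "degenerate", "pooled_se")]
}

#' Format a comparison as a gait-score means table
#'
#' Mirrors the layout of a means table: for each base quantity, one row
#' per gait score with "mean letter" entries under Average and Maximum,
#' followed by an s.e. row and a p-value row.  Speeds and accelerations
#' round to 1 decimal, durations to 2.
#'
#' @param comparison A `gait_comparison` over the 16 standard metric
#'   columns (`<base>_avg` / `<base>_max`).
#' @return A tibble with columns `quantity`, `row`, `average`,
#'   `maximum` (character).
#' @export
metric_table <- function(comparison) {
  res <- comparison$results
  if (nrow(res) == 0L) {
    return(tibble::tibble(quantity = character(), row = character(),
                          average = character(), maximum = character()))
  }
  bases <- unique(sub("_(avg|max)$", "", res$metric))
  fmt <- function(base) if (grepl("duration", base)) "%.2f" else "%.1f"
  out <- list()
  for (b in bases) {
    cell <- function(kind) {
      i <- match(paste0(b, "_", kind), res$metric)
      if (is.na(i)) return(NULL)
      lt <- res$letters[[i]]
      lt <- lt[order(lt$group), ]
      list(scores = lt$group,
           vals = sprintf(paste(fmt(b), "%s"), lt$mean, lt$letter),
           se = sprintf(fmt(b), res$pooled_se[i]),
           p = ifelse(res$p_value[i] < 0.01, "<0.01",
                      sprintf("%.2f", res$p_value[i])))
    }
    av <- cell("avg"); mx <- cell("max")
    ref <- av %||% mx
    if (is.null(ref)) next
    na_fill <- function(x, f) if (is.null(x)) rep(NA_character_, length(f)) else x
    out[[b]] <- tibble::tibble(
      quantity = b,
      row = c(ref$scores, "s.e.", "p-value"),
      average = if (is.null(av)) NA_character_ else c(av$vals, av$se, av$p),
      maximum = if (is.null(mx)) NA_character_ else c(mx$vals, mx$se, mx$p)
    )
  }
  dplyr::bind_rows(out)
}

#' Plot group means with LSD letters
#'
#' Point-and-error-bar display of each metric's group means (pooled SE)
#' annotated with Fisher LSD letters, faceted by metric.
#'
#' @param object A `gait_comparison`.
#' @param metrics Optional character vector restricting the metrics
#'   shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gait_comparison
#' @export
autoplot.gait_comparison <- function(object, metrics = NULL, ...) {
  df <- tidy(object)
  if (!is.null(metrics)) df <- df[df$metric %in% metrics, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gait_score, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$pooled_se,
                   ymax = .data$mean + .data$pooled_se), width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter),
                       vjust = -1.2, size = 3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "gait score", y = "group mean ± pooled s.e.")
}
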