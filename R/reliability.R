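#' Variance components for a Persons x Occasion design
#'
#' Estimates the generalizability-theory variance components for a fully
#' crossed Persons x Occasion design with one observation per cell: sigma2_p
#' (persons), sigma2_o (occasion), and sigma2_po_e (person-by-occasion
#' interaction confounded with error). For a balanced complete table the
#' closed-form mean-squares solution coincides with the REML optimum, so the
#' components are computed from the two-way ANOVA mean squares:
#' `sigma2_po_e = MS_res`, `sigma2_p = (MS_P - MS_res) / n_o`,
#' `sigma2_o = (MS_O - MS_res) / n_p`. Negative estimates are truncated at
#' zero; the untruncated values are kept in the `raw` field.
#'
#' @param table numeric matrix, persons in rows and occasions in columns;
#'   rows containing any `NA` are dropped (complete-case)
#' @return object of class `variance_components` with fields `sigma2_p`,
#'   `sigma2_o`, `sigma2_po_e`, `raw`, `n_persons`, `n_occasions`
#' @export
variance_components <- function(table) {
  y <- as.matrix(table)
  y <- y[stats::complete.cases(y), , drop = FALSE]
  n_p <- nrow(y); n_o <- ncol(y)
  if (n_p < 2 || n_o < 2)
    stop("need at least 2 persons and 2 occasions with complete data")
  if (!all(is.finite(y))) stop("non-finite values in table")
  mu <- mean(y)
  pm <- rowMeans(y); om <- colMeans(y)
  ss_p <- n_o * sum((pm - mu)^2)
  ss_o <- n_p * sum((om - mu)^2)
  ss_tot <- sum((y - mu)^2)
  ss_res <- ss_tot - ss_p - ss_o
  ms_p <- ss_p / (n_p - 1)
  ms_o <- ss_o / (n_o - 1)
  ms_res <- ss_res / ((n_p - 1) * (n_o - 1))
  raw <- c(sigma2_p = (ms_p - ms_res) / n_o,
           sigma2_o = (ms_o - ms_res) / n_p,
           sigma2_po_e = ms_res)
  structure(
    list(sigma2_p = max(0, raw[["sigma2_p"]]),
         sigma2_o = max(0, raw[["sigma2_o"]]),
         sigma2_po_e = max(0, raw[["sigma2_po_e"]]),
         raw = raw, ms = c(ms_p = ms_p, ms_o = ms_o, ms_res = ms_res),
         n_persons = n_p, n_occasions = n_o),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> n=%d persons x %d occasions\n  sigma2_p=%.4g  sigma2_o=%.4g  sigma2_po+e=%.4g\n",
    x$n_persons, x$n_occasions, x$sigma2_p, x$sigma2_o, x$sigma2_po_e))
  invisible(x)
}

#' G-coefficient (generalizability of relative decisions)
#'
#' `G = sigma2_p / (sigma2_p + sigma2_po_e / n_o)`. Occasion variance is
#' excluded from the error because a shift common to all persons leaves their
#' rank order unchanged. `0/0` is defined as 0. With `n_o = 1` this equals
#' ICC(3,1).
#'
#' @param vc a [variance_components()] object
#' @param n_o number of occasions over which scores would be averaged before
#'   use (default 1)
#' @return object of class `g_result` with `g`, `n_o`, and `category`
#'   (`"poor"` < 0.4 <= `"fair"` < 0.6 <= `"good"` < 0.75 <= `"excellent"`)
#' @export
g_coefficient <- function(vc, n_o = 1) {
  stopifnot(inherits(vc, "variance_components"), n_o >= 1)
  denom <- vc$sigma2_p + vc$sigma2_po_e / n_o
  g <- if (denom == 0) 0 else vc$sigma2_p / denom
  structure(list(g = g, n_o = n_o, category = g_category(g),
                 vc = vc),
            class = "g_result")
}

#' Reliability category for a G-coefficient
#' @param g numeric in `[0, 1]`
#' @return `"poor"`, `"fair"`, `"good"`, or `"excellent"`
#' @export
g_category <- function(g) {
  ifelse(g < 0.4, "poor",
         ifelse(g < 0.6, "fair",
                ifelse(g < 0.75, "good", "excellent")))
}

#' @export
print.g_result <- function(x, ...) {
  cat(sprintf("<g_result> G = %.3f (n_o = %g): %s\n", x$g, x$n_o,
              x$category))
  invisible(x)
}

#' ICC(3,1) for a balanced persons x occasions table
#'
#' Two-way mixed-effects, consistency, single-measurement intraclass
#' correlation: `(MS_P - MS_res) / (MS_P + (n_o - 1) MS_res)`. Serves as the
#' independent check of [g_coefficient()] at `n_o = 1` (the two are equal on
#' balanced tables, before truncation of negative components).
#'
#' @inheritParams variance_components
#' @return numeric ICC(3,1)
#' @export
icc31 <- function(table) {
  y <- as.matrix(table)
  y <- y[stats::complete.cases(y), , drop = FALSE]
  n_p <- nrow(y); n_o <- ncol(y)
  if (n_p < 2 || n_o < 2)
    stop("need at least 2 persons and 2 occasions with complete data")
  mu <- mean(y)
  pm <- rowMeans(y); om <- colMeans(y)
  ss_p <- n_o * sum((pm - mu)^2)
  ss_o <- n_p * sum((om - mu)^2)
  ss_res <- sum((y - mu)^2) - ss_p - ss_o
  ms_p <- ss_p / (n_p - 1)
  ms_res <- ss_res / ((n_p - 1) * (n_o - 1))
  (ms_p - ms_res) / (ms_p + (n_o - 1) * ms_res)
}

#' Paired t-test for occasion stability
#'
#' Two-tailed paired t on follow-up minus baseline differences. Zero-variance
#' differences with nonzero mean are reported as infinite t with a flag.
#'
#' @param table numeric matrix with two columns (baseline, follow-up); rows
#'   with `NA` dropped
#' @return object of class `paired_test` with `t`, `df`, `p`, `mean_diff`,
#'   `n`, `degenerate`
#' @export
paired_t <- function(table) {
  y <- as.matrix(table)
  stopifnot(ncol(y) == 2)
  y <- y[stats::complete.cases(y), , drop = FALSE]
  n <- nrow(y)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- y[, 2] - y[, 1]
  sd_d <- stats::sd(d)
  md <- mean(d)
  if (sd_d == 0) {
    if (md == 0) {
      res <- list(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n,
                  degenerate = FALSE)
    } else {
      res <- list(t = sign(md) * Inf, df = n - 1, p = 0, mean_diff = md,
                  n = n, degenerate = TRUE)
    }
  } else {
    tt <- stats::t.test(y[, 2], y[, 1], paired = TRUE)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, mean_diff = md, n = n, degenerate = FALSE)
  }
  structure(res, class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("<paired_test> t(%d) = %.3f, p = %.4g, mean diff = %.4g%s\n",
              x$df, x$t, x$p, x$mean_diff,
              if (x$degenerate) " [degenerate: zero-variance differences]"
              else ""))
  invisible(x)
}

#' Per-measure test-retest reliability report
#'
#' For every session-level measure (run `"all"`) present at both occasions,
#' estimates the Persons x Occasion variance components on complete cases,
#' the G-coefficient and its category, and the paired stability test
#' (follow-up minus baseline), within the requested group.
#'
#' @param measures a [measure_table()]
#' @param group group to analyze (`"CHR"`, `"CON"`), or `NULL` to pool
#' @param n_o occasions averaged for the G-coefficient (default 1)
#' @param occasions character vector naming the two occasions, in
#'   (baseline, follow-up) order
#' @return data.frame of class `reliability_report` with one row per measure:
#'   `measure`, `n`, `g`, `category`, `sigma2_p`, `sigma2_o`, `sigma2_po_e`,
#'   `t`, `df`, `p`, `mean_diff`
#' @export
reliability_report <- function(measures, group = NULL, n_o = 1,
                               occasions = c("baseline", "month2")) {
  df <- as.data.frame(measures)
  df <- df[df$run_index == "all", ]
  if (!is.null(group)) df <- df[df$group == group, ]
  out <- list()
  for (m in unique(df$measure_name)) {
    sub <- df[df$measure_name == m, ]
    wide <- .to_wide(sub, occasions)
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    if (nrow(wide) < 2) {
      warning("measure ", m, " has < 2 complete persons; skipped")
      next
    }
    vc <- variance_components(wide)
    g <- g_coefficient(vc, n_o = n_o)
    pt <- paired_t(wide)
    out[[m]] <- data.frame(
      measure = m, n = nrow(wide), g = g$g, category = g$category,
      sigma2_p = vc$sigma2_p, sigma2_o = vc$sigma2_o,
      sigma2_po_e = vc$sigma2_po_e,
      t = pt$t, df = pt$df, p = pt$p, mean_diff = pt$mean_diff,
      stringsAsFactors = FALSE
    )
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  class(rep) <- c("reliability_report", "data.frame")
  rep
}

.to_wide <- function(sub, occasions) {
  subjects <- unique(sub$subject_id)
  wide <- matrix(NA_real_, length(subjects), length(occasions),
                 dimnames = list(subjects, occasions))
  for (j in seq_along(occasions)) {
    occ <- sub[sub$occasion == occasions[j], ]
    wide[match(occ$subject_id, subjects), j] <- occ$value
  }
  wide
}
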