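#' Session x Run repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Two-way fully within-subject ANOVA on a persons x (2 sessions x k runs)
#' layout, as used to test amplitude habituation over task runs and sessions.
#' Each effect is tested through its orthonormal within-person contrast
#' scores: for contrast matrix C (q x p), scores `U = Y C'`; then
#' `F = n * ||mean(U)||^2 / q  /  (tr(S_U) / q)` with `df = (q, q(n-1))`,
#' where `S_U` is the sample covariance of the scores. The
#' Greenhouse-Geisser epsilon is the standard sample estimator
#' `eps = tr(S_U)^2 / (q * tr(S_U^2))`, and adjusted p-values use
#' `(eps*q, eps*q*(n-1))` degrees of freedom. Follow-up one-degree
#' polynomial trend contrasts (linear, quadratic) are reported for Run and
#' for the Session x Run interaction.
#'
#' @param data numeric matrix or 3-d array of complete data. Either an array
#'   `persons x 2 x k` (sessions, runs), or a matrix `persons x (2*k)` with
#'   columns ordered session-major (session 1 runs 1..k, then session 2
#'   runs 1..k)
#' @param n_runs number of run levels k (required when `data` is a matrix)
#' @return object of class `rm_anova`: list with an `effects` data.frame
#'   (F, df1, df2, epsilon, p_gg, p_unadjusted per effect) and a `trends`
#'   data.frame (one-df F tests for Run linear/quadratic and
#'   Session x Run linear/quadratic)
#' @export
rm_anova_session_run <- function(data, n_runs = NULL) {
  if (is.array(data) && length(dim(data)) == 3) {
    d <- dim(data)
    stopifnot(d[2] == 2)
    n_runs <- d[3]
    # flatten persons x session x run to session-major columns
    # (session 1 runs 1..k, then session 2 runs 1..k)
    y <- matrix(data, d[1], 2 * n_runs)
    idx <- as.vector(outer(seq_len(n_runs), 1:2,
                           function(r, s) (r - 1) * 2 + s))
    y <- y[, idx, drop = FALSE]
  } else {
    y <- as.matrix(data)
    if (is.null(n_runs)) stop("n_runs required for matrix input")
    stopifnot(ncol(y) == 2 * n_runs)
  }
  keep <- stats::complete.cases(y)
  n_dropped <- sum(!keep)
  y <- y[keep, , drop = FALSE]
  n <- nrow(y)
  k <- n_runs
  if (n < 3) stop("need at least 3 complete persons")
  if (!k %in% 2:10) stop("unsupported number of runs")

  # orthonormal contrasts
  c_sess <- matrix(c(1, -1) / sqrt(2), 1, 2)
  c_run <- t(stats::contr.poly(k))            # (k-1) x k, orthonormal rows
  ones_s <- matrix(1 / sqrt(2), 1, 2)
  ones_r <- matrix(1 / sqrt(k), 1, k)

  # column structure is session-major: kron(session, run)
  eff <- rbind(
    .rm_effect("Session", kronecker(c_sess, ones_r), y, n),
    .rm_effect("Run", kronecker(ones_s, c_run), y, n),
    .rm_effect("Session:Run", kronecker(c_sess, c_run), y, n)
  )

  trends <- NULL
  if (k >= 3) {
    lin <- c_run[1, , drop = FALSE]; quad <- c_run[2, , drop = FALSE]
    trends <- rbind(
      .rm_effect("Run linear", kronecker(ones_s, lin), y, n),
      .rm_effect("Run quadratic", kronecker(ones_s, quad), y, n),
      .rm_effect("Session:Run linear", kronecker(c_sess, lin), y, n),
      .rm_effect("Session:Run quadratic", kronecker(c_sess, quad), y, n)
    )
  }
  structure(list(effects = eff, trends = trends, n = n, n_runs = k,
                 n_dropped = n_dropped),
            class = "rm_anova")
}

# F test of one within-person effect given its orthonormal contrast matrix
.rm_effect <- function(name, C, y, n) {
  u <- y %*% t(C)                       # n x q contrast scores
  q <- ncol(u)
  ubar <- colMeans(u)
  s_u <- stats::cov(u)
  ss_eff <- n * sum(ubar^2)
  ss_err <- (n - 1) * sum(diag(as.matrix(s_u)))
  df1 <- q; df2 <- q * (n - 1)
  f <- (ss_eff / df1) / (ss_err / df2)
  if (q == 1) {
    eps <- 1
  } else {
    tr <- sum(diag(as.matrix(s_u)))
    eps <- tr^2 / (q * sum(s_u^2))
    eps <- min(1, max(1 / q, eps))
  }
  data.frame(effect = name, F = f, df1 = df1, df2 = df2, epsilon = eps,
             p_gg = stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE),
             p_unadjusted = stats::pf(f, df1, df2, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> Session (2) x Run (%d), n = %d complete persons",
              x$n_runs, x$n))
  if (x$n_dropped) cat(sprintf(" (%d dropped)", x$n_dropped))
  cat("\n")
  eff <- x$effects
  for (i in seq_len(nrow(eff)))
    cat(sprintf("  %-12s F(%g, %g) = %8.3f  eps = %.3f  p_GG = %.4g\n",
                eff$effect[i], eff$df1[i], eff$df2[i], eff$F[i],
                eff$epsilon[i], eff$p_gg[i]))
  if (!is.null(x$trends)) {
    tr <- x$trends
    for (i in seq_len(nrow(tr)))
      cat(sprintf("  %-22s F(1, %g) = %8.3f  p = %.4g\n",
                  tr$effect[i], tr$df2[i], tr$F[i], tr$p_unadjusted[i]))
  }
  invisible(x)
}

#' Extract run-level scores from a measure table into an ANOVA-ready array
#'
#' @param measures a [measure_table()]
#' @param measure measure name to extract
#' @param n_runs number of runs
#' @param occasions occasion labels in session order
#' @return persons x 2 x n_runs array (complete persons only)
#' @export
run_score_array <- function(measures, measure, n_runs,
                            occasions = c("baseline", "month2")) {
  df <- as.data.frame(measures)
  df <- df[df$measure_name == measure & df$run_index != "all", ]
  subjects <- unique(df$subject_id)
  arr <- array(NA_real_, c(length(subjects), 2, n_runs),
               dimnames = list(subjects, occasions, NULL))
  for (s in seq_along(occasions)) {
    for (r in seq_len(n_runs)) {
      sub <- df[df$occasion == occasions[s] & df$run_index == as.character(r), ]
      arr[match(sub$subject_id, subjects), s, r] <- sub$value
    }
  }
  ok <- apply(arr, 1, function(m) all(is.finite(m)))
  arr[ok, , , drop = FALSE]
}
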