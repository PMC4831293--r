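#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `y/se` on the precision
#' `1/se`; the intercept estimates the asymmetry of the funnel (zero under
#' symmetry), tested two-sided against a t distribution with k - 2 degrees
#' of freedom.  Equivalent to weighted regression of `y` on `se` with
#' `1/se^2` weights.
#'
#' @param effects A log-effect data frame (columns `y`, `se`), k >= 3.
#' @return An object of class `bias_test` with the intercept and its
#'   standard error, the t statistic, the two-sided p-value, and k.
#' @export
egger_test <- function(effects) {
  effects <- .check_effects(effects)
  k <- nrow(effects)
  if (k < 3L) stop("insufficient-data error: Egger's test needs k >= 3")
  prec <- 1 / effects$se
  if (stats::sd(prec) < sqrt(.Machine$double.eps) * mean(prec))
    stop("singular-design error: all precisions equal")
  snd <- effects$y / effects$se
  X <- cbind(1, prec)
  XtX <- crossprod(X)
  beta <- drop(solve(XtX, crossprod(X, snd)))
  res <- snd - drop(X %*% beta)
  s2 <- sum(res^2) / (k - 2L)
  se_b <- unname(sqrt(diag(s2 * solve(XtX))))
  tstat <- unname(beta[1L] / se_b[1L])
  structure(list(
    method = "egger",
    statistic = c(t = unname(tstat)),
    intercept = unname(beta[1L]), intercept_se = se_b[1L],
    slope = unname(beta[2L]),
    p_value = 2 * stats::pt(abs(tstat), df = k - 2L, lower.tail = FALSE),
    k = k
  ), class = "bias_test")
}

#' Begg-Mazumdar rank-correlation test for funnel-plot asymmetry
#'
#' Standardizes the effects against the fixed-effects pooled value,
#' `y* = (y - y_FE) / sqrt(se^2 - se_FE^2)`, and computes Kendall's tau
#' between `y*` and the study variances.  The two-sided p-value uses the
#' normal approximation with the tie-corrected Kendall variance and a
#' continuity correction (|S| reduced by 1), matching common meta-analysis
#' software; `exact = TRUE` (available for k <= 8) enumerates the full
#' permutation distribution of the Kendall score instead.
#'
#' @param effects A log-effect data frame (columns `y`, `se`), k >= 3.
#' @param exact Use the exact permutation distribution (k <= 8 only).
#' @return An object of class `bias_test` with the Kendall score `S`, tau,
#'   the standardized z statistic, the two-sided p-value, and k.
#' @export
begg_test <- function(effects, exact = FALSE) {
  effects <- .check_effects(effects)
  k <- nrow(effects)
  if (k < 3L) stop("insufficient-data error: Begg's test needs k >= 3")
  y <- effects$y
  v <- effects$se^2
  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  v_fe <- 1 / sum(w)
  ystar <- (y - y_fe) / sqrt(pmax(v - v_fe, .Machine$double.eps))
  S <- .kendall_score(ystar, v)
  n_pairs <- k * (k - 1) / 2
  tau <- S / n_pairs
  if (exact) {
    if (k > 8L) stop("exact enumeration only offered for k <= 8")
    p <- .kendall_exact_p(ystar, v, S)
    zstat <- NA_real_
  } else {
    vS <- .kendall_var(ystar, v, k)
    zstat <- if (S == 0 || vS == 0) 0 else (abs(S) - 1) / sqrt(vS)
    zstat <- max(zstat, 0)
    p <- min(1, 2 * stats::pnorm(zstat, lower.tail = FALSE))
  }
  structure(list(
    method = "begg",
    statistic = c(z = unname(zstat)),
    S = S, tau = tau,
    p_value = p,
    k = k
  ), class = "bias_test")
}

.kendall_score <- function(a, b) {
  n <- length(a)
  S <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      S <- S + sign(a[j] - a[i]) * sign(b[j] - b[i])
    }
  }
  S
}

# Tie-corrected null variance of the Kendall score.
.kendall_var <- function(a, b, n) {
  tie_term <- function(x) {
    t <- table(x)
    t <- t[t > 1]
    sum(t * (t - 1) * (2 * t + 5))
  }
  (n * (n - 1) * (2 * n + 5) - tie_term(a) - tie_term(b)) / 18
}

# Exact two-sided p: permute one margin, count |S_perm| >= |S_obs|.
.kendall_exact_p <- function(a, b, S_obs) {
  perms <- .permutations(length(a))
  scores <- apply(perms, 1L, function(p) .kendall_score(a[p], b))
  mean(abs(scores) >= abs(S_obs))
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' @export
print.bias_test <- function(x, ...) {
  if (x$method == "egger") {
    cat(sprintf("Egger regression test (k = %d)\n", x$k))
    cat(sprintf("  intercept %.4f (se %.4f), t = %.3f, two-sided p = %.4f\n",
                x$intercept, x$intercept_se, x$statistic, x$p_value))
  } else {
    cat(sprintf("Begg rank-correlation test (k = %d)\n", x$k))
    cat(sprintf("  Kendall S = %d (tau = %.3f), two-sided p = %.4f\n",
                x$S, x$tau, x$p_value))
  }
  invisible(x)
}

#' Funnel-plot data table
#'
#' @param effects A log-effect data frame.
#' @return A data frame with `report_id`, `y`, `se` per report, ready for
#'   plotting a funnel.
#' @export
funnel_table <- function(effects) {
  effects <- .check_effects(effects)
  data.frame(report_id = effects$report_id, y = effects$y, se = effects$se,
             stringsAsFactors = FALSE)
}
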