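# Independent brute-force oracles, written as spelled-out arithmetic so they
# share no code path with the package internals they check.

Z95 <- qnorm(0.975)

oracle_pool_fixed <- function(y, se) {
  sw <- 0; swy <- 0
  for (i in seq_along(y)) {
    sw <- sw + 1 / se[i]^2
    swy <- swy + y[i] / se[i]^2
  }
  yp <- swy / sw
  Q <- 0
  for (i in seq_along(y)) Q <- Q + (y[i] - yp)^2 / se[i]^2
  df <- length(y) - 1
  list(y = yp, se = sqrt(1 / sw), Q = Q,
       i2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0,
       p_het = if (df == 0) 1 else 1 - pchisq(Q, df))
}

oracle_pool_dl <- function(y, se) {
  fx <- oracle_pool_fixed(y, se)
  sw <- 0; sw2 <- 0
  for (i in seq_along(y)) {
    sw <- sw + 1 / se[i]^2
    sw2 <- sw2 + (1 / se[i]^2)^2
  }
  tau2 <- max(0, (fx$Q - (length(y) - 1)) / (sw - sw2 / sw))
  sws <- 0; swys <- 0
  for (i in seq_along(y)) {
    wi <- 1 / (se[i]^2 + tau2)
    sws <- sws + wi
    swys <- swys + wi * y[i]
  }
  list(y = swys / sws, se = sqrt(1 / sws), tau2 = tau2)
}

# Explicit 2x2 normal-equations solve for the Egger precision regression.
oracle_egger <- function(y, se) {
  snd <- y / se
  prec <- 1 / se
  n <- length(y)
  sx <- sum(prec); sxx <- sum(prec^2); sy <- sum(snd); sxy <- sum(prec * snd)
  det <- n * sxx - sx^2
  b0 <- (sxx * sy - sx * sxy) / det
  b1 <- (n * sxy - sx * sy) / det
  rss <- sum((snd - b0 - b1 * prec)^2)
  s2 <- rss / (n - 2)
  se_b0 <- sqrt(s2 * sxx / det)
  t <- b0 / se_b0
  list(intercept = b0, se = se_b0, t = t, p = 2 * pt(-abs(t), n - 2))
}

# Kendall score by exhaustive pair enumeration.
oracle_kendall_score <- function(a, b) {
  S <- 0
  n <- length(a)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    da <- a[j] - a[i]; db <- b[j] - b[i]
    if (da * db > 0) S <- S + 1
    if (da * db < 0) S <- S - 1
  }
  S
}

# GLS slope through the origin by explicit matrix arithmetic.
oracle_gls_slope <- function(y, x, C) {
  Ci <- solve(C)
  num <- as.numeric(t(x) %*% Ci %*% y)
  den <- as.numeric(t(x) %*% Ci %*% x)
  c(slope = num / den, se = sqrt(1 / den))
}

# Build a study_report through the public CSV surface.
make_report <- function(id, rr, lcl, ucl, lower, upper,
                        design = "case_control",
                        design_detail = "population_cc", region = "Europe",
                        nos = 7, adjusted = TRUE, total_cases = 100,
                        total_subjects = 100, labels = NULL,
                        n_cases = NA, n_denominator = NA,
                        parous = NULL) {
  k <- length(rr)
  if (is.null(labels))
    labels <- ifelse(is.na(upper), paste0(">=", lower),
                     ifelse(lower == upper, as.character(lower),
                            paste0(lower, "-", upper)))
  rows <- data.frame(
    report_id = id, author_year = id, design = design,
    design_detail = design_detail, region = region, nos_score = nos,
    adjusted = adjusted, total_cases = total_cases,
    total_subjects = total_subjects,
    category_label = c("Nulliparous", labels),
    lower = c(0, lower), upper = c(0, upper),
    is_reference = c(TRUE, rep(FALSE, k)),
    rr = c(1, rr), lcl = c(1, lcl), ucl = c(1, ucl),
    n_cases = c(n_cases[1], if (length(n_cases) > 1) n_cases[-1] else
      rep(NA, k)),
    n_denominator = c(n_denominator[1],
                      if (length(n_denominator) > 1) n_denominator[-1] else
                        rep(NA, k)),
    stringsAsFactors = FALSE)
  if (!is.null(parous)) {
    rows <- rbind(rows, data.frame(
      report_id = id, author_year = id, design = design,
      design_detail = design_detail, region = region, nos_score = nos,
      adjusted = adjusted, total_cases = total_cases,
      total_subjects = total_subjects, category_label = "Parous",
      lower = 1, upper = NA, is_reference = FALSE,
      rr = parous[1], lcl = parous[2], ucl = parous[3],
      n_cases = NA, n_denominator = NA, stringsAsFactors = FALSE))
  }
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(rows, f, row.names = FALSE, na = "")
  read_catalog(f)[[1]]
}

as_catalog <- function(...) {
  structure(list(...), class = "parity_catalog")
}

random_effects <- function(k, seed) {
  set.seed(seed)
  data.frame(report_id = sprintf("s%d", 1:k),
             contrast_label = "x",
             y = rnorm(k, 0, 0.4),
             se = runif(k, 0.05, 0.5), stringsAsFactors = FALSE)
}
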