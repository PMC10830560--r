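# Shared statistical procedures. Standard machinery (t-test, OLS, ANOVA) is
# delegated to stats/car; the two-sample Kolmogorov-Smirnov test is
# implemented here because the counts it is applied to are heavily tied
# integers, for which stats::ks.test downgrades its p-value with warnings.

#' Two-sample t test
#'
#' Thin adapter around [stats::t.test()] returning a flat result. Welch
#' (unequal variances) is the default; the pooled-variance Student variant is
#' available because group sizes in the age comparisons differ and either
#' convention may be needed to match an existing analysis. The degenerate
#' case of zero variance in both samples with equal means is defined as
#' statistic 0, p 1.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param variant `"welch"` or `"pooled"`.
#' @return List with `statistic`, `df`, `p_value`, `method`.
#' @export
tTwoSample <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    df <- if (variant == "pooled") length(a) + length(b) - 2 else NA_real_
    return(list(statistic = 0, df = df, p_value = 1,
                method = paste0(variant, " t-test (degenerate)")))
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, method = paste0(variant, " two-sample t-test"))
}

#' Bonferroni-corrected alpha
#'
#' @param m number of comparisons (>= 1).
#' @param family_alpha family-wise error target (default 0.05).
#' @return `family_alpha / m`.
#' @examples
#' bonferroniAlpha(9)   # 0.00556, prints as 0.006
#' @export
bonferroniAlpha <- function(m, family_alpha = 0.05) {
  if (length(m) != 1L || is.na(m) || m < 1)
    stop("m must be a positive integer")
  family_alpha / m
}

.ksStatistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

# Asymptotic two-sided Kolmogorov tail: Q(z) = 2 sum (-1)^(k-1) exp(-2k^2z^2)
.kolmogorovQ <- function(z) {
  if (z <= 0) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * z^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic = supremum of the absolute difference between the two empirical
#' distribution functions (well defined under ties). The p-value is the
#' asymptotic Kolmogorov tail at `sqrt(n*m/(n+m)) * D` by default; for small
#' samples (`max(n, m) <= 10`) an exact permutation p — the fraction of all
#' `choose(n+m, n)` group assignments of the pooled values whose statistic is
#' at least the observed one — is available, which remains exact under ties.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact `"never"` (default: asymptotic, matching the convention used
#'   for large trial-count comparisons), `"auto"` (exact when
#'   `max(n, m) <= 10`) or `"always"`.
#' @return List with `statistic`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
ksTwoSample <- function(a, b, exact = c("never", "auto", "always")) {
  exact <- match.arg(exact)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  D <- .ksStatistic(a, b)
  n <- length(a); m <- length(b)
  useExact <- switch(exact, never = FALSE, always = TRUE,
                     auto = max(n, m) <= 10L)
  if (useExact) {
    pool <- c(a, b)
    idx <- utils::combn(n + m, n)
    ge <- apply(idx, 2L, function(ia) {
      .ksStatistic(pool[ia], pool[-ia]) >= D - 1e-12
    })
    p <- mean(ge)
    meth <- "two-sample KS (exact permutation)"
  } else {
    en <- n * m / (n + m)
    p <- .kolmogorovQ(sqrt(en) * D)
    meth <- "two-sample KS (asymptotic)"
  }
  list(statistic = D, p_value = p, n_a = n, n_b = m, method = meth)
}

#' Ordinary least squares with categorical predictors
#'
#' Dummy-coded OLS via [stats::lm()] with treatment contrasts. Factors are
#' taken as supplied (character columns are converted, first level =
#' reference). A rank-deficient design is an error naming the aliased
#' columns rather than a silently dropped coefficient.
#'
#' @param data data frame containing the response and predictors.
#' @param response name of the numeric response column.
#' @param predictors character vector of predictor column names.
#' @return List with `coefficients` (data frame: term, estimate, se, t, p),
#'   `r_squared`, `n_observations`, and the underlying `fit`.
#' @export
olsCategorical <- function(data, response, predictors) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)))
  for (p in predictors)
    if (is.character(data[[p]])) data[[p]] <- factor(data[[p]])
  if (!all(is.finite(data[[response]])))
    stop("response contains non-finite values")
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (stats::var(data[[response]]) == 0 || !is.finite(r2))
    r2 <- 0  # constant response: no variance to explain
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co <- cbind(term = rownames(co), co, row.names = NULL,
              stringsAsFactors = FALSE)
  list(coefficients = co, r_squared = r2,
       n_observations = nrow(stats::model.frame(fit)), fit = fit)
}

#' Two-way ANOVA with interaction
#'
#' Fits `y ~ A * B` and returns the F table for the two main effects and the
#' interaction. Type II sums of squares (via [car::Anova()]) are the default
#' because the designs this package analyses are mildly unbalanced across
#' odors; Type I (sequential) and Type III are available. Empty factor cells
#' are an error naming the cells.
#'
#' @param data data frame.
#' @param response numeric response column name.
#' @param factorA,factorB factor column names.
#' @param type `"II"` (default), `"I"` or `"III"`.
#' @return Data frame with rows A, B, A:B and columns `term`, `F`, `df`,
#'   `df_resid`, `p`.
#' @export
anovaTwoWay <- function(data, response, factorA, factorB,
                        type = c("II", "I", "III")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(data))
  A <- factor(data[[factorA]]); B <- factor(data[[factorB]])
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("both factors need at least two levels")
  tab <- table(A, B)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)
    stop("empty design cells: ",
         paste(sprintf("(%s, %s)", rownames(tab)[empty[, 1]],
                       colnames(tab)[empty[, 2]]), collapse = ", "))
  }
  df <- data.frame(y = data[[response]], A = A, B = B)
  if (type == "III") {
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(op))
  }
  fit <- stats::lm(y ~ A * B, data = df)
  at <- if (type == "I") {
    a <- stats::anova(fit)
    data.frame(term = rownames(a), ss = a$`Sum Sq`, df = a$Df,
               F = a$`F value`, p = a$`Pr(>F)`)
  } else {
    a <- car::Anova(fit, type = if (type == "II") 2 else 3)
    data.frame(term = rownames(a), ss = a$`Sum Sq`, df = a$Df,
               F = a$`F value`, p = a$`Pr(>F)`)
  }
  keep <- at$term %in% c("A", "B", "A:B")
  out <- at[keep, c("term", "F", "df", "p")]
  out$term <- c(A = factorA, B = factorB,
                `A:B` = paste0(factorA, ":", factorB))[out$term]
  out$df_resid <- stats::df.residual(fit)
  rownames(out) <- NULL
  out[, c("term", "F", "df", "df_resid", "p")]
}
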