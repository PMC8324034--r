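#' One-way analysis of variance
#'
#' Classical one-way F test from between- and within-group mean
#' squares; unbalanced designs are allowed.
#'
#' @param values numeric response.
#' @param groups grouping vector (coerced to factor), same length.
#' @return object of class `anova_result`: list with `F`, `df_between`,
#'   `df_within`, `p`, `group_means`, `ms_within`, `group_n`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n_g <- tabulate(groups)
  if (any(n_g < 2L)) stop("every group needs at least 2 observations", call. = FALSE)
  N <- length(values)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(n_g * (gm - grand)^2)
  ssw <- sum((values - gm[as.integer(groups)])^2)
  if (ssw == 0 && ssb == 0) {
    stop("degenerate data: zero variance within and between groups; F is undefined",
         call. = FALSE)
  }
  df_b <- k - 1L
  df_w <- N - k
  Fstat <- (ssb / df_b) / (ssw / df_w)
  structure(
    list(F = Fstat, df_between = df_b, df_within = df_w,
         p = stats::pf(Fstat, df_b, df_w, lower.tail = FALSE),
         group_means = gm, ms_within = ssw / df_w, group_n = n_g),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Newman-Keuls (SNK) post hoc test
#'
#' Step-down multiple comparison of group means using studentized-range
#' critical values that depend on the span of the ordered means.
#' The largest span is tested first; whenever a span is declared
#' homogeneous, every pair inside it is declared non-distinct without
#' further testing (implied homogeneity). Unbalanced group sizes are
#' handled with the Tukey-Kramer style standard error
#' `sqrt(MS_within/2 * (1/n_i + 1/n_j))`.
#'
#' @param values,groups as in [one_way_anova()].
#' @param alpha familywise level per span, in `(0, 0.5]`.
#' @return object of class `posthoc_result`: list with `distinct`
#'   (logical k x k matrix), `letters` (named character vector of
#'   letter displays), `means` (sorted), `alpha`, `anova`.
#' @export
newman_keuls <- function(values, groups, alpha = 0.05) {
  if (alpha <= 0 || alpha > 0.5) stop("`alpha` must be in (0, 0.5]", call. = FALSE)
  an <- one_way_anova(values, groups)
  k <- length(an$group_means)
  ord <- order(an$group_means)
  means <- an$group_means[ord]
  ns <- an$group_n[ord]
  lev <- names(means)

  distinct <- matrix(NA, k, k, dimnames = list(lev, lev))
  diag(distinct) <- FALSE

  # level order: widest spans first; a non-significant span blankets every
  # pair inside it as homogeneous, and blanketed spans are never re-tested.
  for (r in rev(seq_len(k)[-1])) {
    for (i in seq_len(k - r + 1L)) {
      j <- i + r - 1L
      if (isFALSE(distinct[i, j])) next
      se <- sqrt(an$ms_within / 2 * (1 / ns[i] + 1 / ns[j]))
      q <- abs(means[j] - means[i]) / se
      qcrit <- stats::qtukey(1 - alpha, r, an$df_within)
      if (q > qcrit) {
        distinct[i, j] <- distinct[j, i] <- TRUE
      } else {
        distinct[i:j, i:j] <- FALSE
      }
    }
  }
  distinct[is.na(distinct)] <- FALSE

  # letter display: maximal runs of mutually non-distinct ordered means
  stretches <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !distinct[i, j + 1L]) j <- j + 1L
    stretches[[length(stretches) + 1L]] <- i:j
  }
  keep <- rep(TRUE, length(stretches))
  for (a in seq_along(stretches)) {
    for (b in seq_along(stretches)) {
      if (a != b && all(stretches[[a]] %in% stretches[[b]])) keep[a] <- FALSE
    }
  }
  stretches <- stretches[keep]
  letters_out <- stats::setNames(rep("", k), lev)
  for (s in seq_along(stretches)) {
    idx <- stretches[[s]]
    letters_out[idx] <- paste0(letters_out[idx], letters[s])
  }

  structure(
    list(distinct = distinct, letters = letters_out, means = means,
         alpha = alpha, anova = an),
    class = "posthoc_result"
  )
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat("Newman-Keuls at alpha =", x$alpha, "\n")
  print(data.frame(mean = x$means, group = x$letters))
  invisible(x)
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation; p-value from the t transform with
#' `n - 2` degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, both with
#'   non-zero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Variance inflation factors
#'
#' For each predictor column j, regresses it on all the others and
#' returns `VIF_j = 1 / (1 - R^2_j)`. Exact collinearity is reported as
#' `Inf`, not raised as an error.
#'
#' @param design data.frame or matrix of numeric predictors (>= 2
#'   columns, more rows than columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.data.frame(design)
  stopifnot(ncol(X) >= 2L)
  if (nrow(X) <= ncol(X)) stop("need more observations than predictors", call. = FALSE)
  out <- vapply(seq_along(X), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[-j])
    r2 <- summary(fit)$r.squared
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, names(X))
}
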