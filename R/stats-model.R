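#' Backward model selection by AIC
#'
#' Starting from the full ordinary-least-squares model, repeatedly
#' removes the single term whose removal most decreases
#' `AIC = n * log(RSS / n) + 2k` (k counting the intercept; the
#' constant-free convention of [stats::extractAIC()]), stopping when no
#' removal improves the criterion. Delegates the stepping to
#' [stats::step()].
#'
#' @param data data.frame containing the response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of candidate predictor columns.
#' @return list with `final_model` (an `lm`), `final_terms`,
#'   `aic_trail` (data.frame of `step`, `AIC`), `aic_final`.
#' @export
backward_aic <- function(data, response, predictors) {
  data <- as.data.frame(data)
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  n <- nrow(data)
  if (n <= length(predictors) + 2L) {
    stop("need n > p + 2 observations for backward selection", call. = FALSE)
  }
  if (length(predictors) == 0L) {
    fit <- stats::lm(stats::reformulate("1", response), data = data)
    aic0 <- stats::extractAIC(fit)[2]
    return(list(final_model = fit, final_terms = character(0),
                aic_trail = data.frame(step = "<intercept only>", AIC = aic0),
                aic_final = aic0))
  }
  full <- stats::lm(stats::reformulate(predictors, response), data = data)
  sel <- stats::step(full, direction = "backward", trace = 0)
  trail <- sel$anova
  aic_trail <- data.frame(
    step = ifelse(trail$Step == "", "<full model>", trimws(as.character(trail$Step))),
    AIC = trail$AIC, stringsAsFactors = FALSE)
  final_terms <- attr(stats::terms(sel), "term.labels")
  list(final_model = sel, final_terms = final_terms,
       aic_trail = aic_trail, aic_final = aic_trail$AIC[nrow(aic_trail)])
}

# least-absolute-deviation start for the robust fit, by IRLS with
# epsilon-regularised reciprocal weights
.lad_fit <- function(X, y, maxit = 30L, tol = 1e-8) {
  beta <- stats::lm.fit(X, y)$coefficients
  eps <- 1e-6 * stats::sd(y) + 1e-12
  for (it in seq_len(maxit)) {
    r <- y - X %*% beta
    w <- 1 / pmax(abs(r), eps)
    beta_new <- stats::lm.wfit(X, y, as.numeric(w))$coefficients
    if (max(abs(beta_new - beta)) < tol * (max(abs(beta)) + tol)) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

#' Robust linear regression by IRLS with Tukey's bisquare
#'
#' M-estimation via iteratively reweighted least squares: residual
#' scale is re-estimated at each iteration as `1.4826 * median(|r|)`
#' (MAD about zero), weights are Tukey bisquare
#' `w = (1 - (r / (c * scale))^2)^2` (zero beyond `c * scale`), and the
#' start is a least-absolute-deviation fit. Convergence when the
#' maximum relative coefficient change drops below `1e-8`. When the
#' data admit an exact fit (zero residuals), the OLS solution is
#' returned with unit weights.
#'
#' @param data data.frame with the response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor columns (may be
#'   empty: intercept-only).
#' @param c_tuning bisquare tuning constant; the default 4.685 gives
#'   95 % efficiency under Gaussian errors.
#' @param max_iter iteration cap; exceeding it flags `converged = FALSE`.
#' @return object of class `robust_fit`: list with `coefficients`
#'   (data.frame: estimate, se, z, p), `weights`, `scale`, `converged`,
#'   `fitted`, `residuals`.
#' @export
robust_irls <- function(data, response, predictors, c_tuning = 4.685,
                        max_iter = 200L) {
  data <- as.data.frame(data)
  stopifnot(response %in% names(data))
  y <- data[[response]]
  X <- if (length(predictors)) {
    stats::model.matrix(stats::reformulate(predictors), data = data)
  } else {
    matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients", call. = FALSE)

  ols <- stats::lm.fit(X, y)$coefficients
  scale_floor <- 1e-10 * (stats::sd(y) + 1e-30)

  beta <- .lad_fit(X, y)
  converged <- FALSE
  w <- rep(1, n)
  scale <- NA_real_
  for (it in seq_len(max_iter)) {
    r <- as.numeric(y - X %*% beta)
    scale <- 1.4826 * stats::median(abs(r))
    if (scale < scale_floor) {
      # exact (or numerically exact) fit: all weights 1, OLS solution
      beta <- ols
      w <- rep(1, n)
      converged <- TRUE
      break
    }
    u <- r / (c_tuning * scale)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) <= p) {
      stop("bisquare weights reject too many observations; fit is degenerate",
           call. = FALSE)
    }
    beta_new <- stats::lm.wfit(X, y, w)$coefficients
    if (max(abs(beta_new - beta)) < 1e-8 * (max(abs(beta)) + 1e-8)) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }

  r <- as.numeric(y - X %*% beta)
  # asymptotic covariance of the M-estimator (sandwich form with psi')
  if (is.na(scale) || scale < scale_floor) {
    se <- rep(0, p)
  } else {
    u <- r / (c_tuning * scale)
    psi <- ifelse(abs(u) < 1, r * (1 - u^2)^2, 0)
    dpsi <- ifelse(abs(u) < 1, (1 - u^2) * (1 - 5 * u^2), 0)
    XtX_inv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
    if (is.null(XtX_inv)) {
      se <- rep(NA_real_, p)
    } else {
      kappa <- (n / (n - p)) * sum(psi^2) / (sum(dpsi) / n)^2 / n
      se <- sqrt(pmax(diag(kappa * XtX_inv), 0))
    }
  }
  z <- ifelse(se > 0, beta / se, NA_real_)
  coefs <- data.frame(term = colnames(X), estimate = as.numeric(beta),
                      se = se, z = z,
                      p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(
    list(coefficients = coefs, weights = w, scale = scale,
         converged = converged,
         fitted = as.numeric(X %*% beta), residuals = r),
    class = "robust_fit"
  )
}

#' @export
print.robust_fit <- function(x, ...) {
  cat("Robust IRLS fit (Tukey bisquare)",
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' LMG relative importance of regressors
#'
#' Decomposes the full-model R^2 into non-negative shares, one per
#' predictor: each share is the R^2 increment when that predictor
#' enters the model, averaged over all orderings of entry
#' (Lindeman-Merenda-Gold). Computed exactly through the
#' subset-weighted identity: increments are averaged within each subset
#' size and then across sizes, which equals the average over all `p!`
#' orderings. Exact enumeration over all `2^p` subsets; guarded at
#' `p <= 12`.
#'
#' @param data data.frame with the response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor columns (1 to 12).
#' @return named numeric vector of shares; `sum(shares)` equals the
#'   full-model R^2.
#' @export
lmg_importance <- function(data, response, predictors) {
  data <- as.data.frame(data)
  p <- length(predictors)
  if (p < 1L) stop("need at least one predictor", call. = FALSE)
  if (p > 12L) {
    stop("LMG uses exact subset enumeration; p > 12 is not supported", call. = FALSE)
  }
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  y <- data[[response]]
  X <- as.matrix(data[predictors])
  storage.mode(X) <- "double"
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("response has zero variance", call. = FALSE)

  r2_subset <- function(mask) {
    if (mask == 0L) return(0)
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    Xi <- cbind(1, X[, cols, drop = FALSE])
    rss <- sum(stats::lm.fit(Xi, y)$residuals^2)
    1 - rss / tss
  }
  r2 <- vapply(0:(2^p - 1L), r2_subset, numeric(1))

  shares <- stats::setNames(numeric(p), predictors)
  sizes <- vapply(0:(2^p - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L),
                  numeric(1))
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without_j <- which(bitwAnd(0:(2^p - 1L), bit) == 0L) - 1L
    inc <- r2[without_j + bit + 1L] - r2[without_j + 1L]
    k <- sizes[without_j + 1L]
    # average increments within each subset size, then across the p sizes
    by_size <- tapply(inc, k, mean)
    shares[j] <- mean(by_size)
  }
  shares
}

#' Run the full trait-to-embolism inference chain
#'
#' Reproducible end-to-end inference on a per-stem trait table:
#' \enumerate{
#'   \item collinearity screen (VIF over the candidate predictors;
#'     reported, nothing auto-dropped),
#'   \item backward AIC selection from the full OLS model,
#'   \item robust IRLS refit of the selected model,
#'   \item LMG relative-importance decomposition of the selected OLS
#'     model,
#'   \item Pearson correlation of every candidate with the response.
#' }
#'
#' @param traits data.frame of per-stem trait records including the
#'   response column.
#' @param response response column name, typically `"P50"`, `"P12"` or
#'   `"P88"`.
#' @param candidates candidate predictor columns; the default is the
#'   trait set usually discussed for embolism resistance.
#' @param alpha significance level recorded in the report.
#' @param standardize if `TRUE`, z-scores the predictors (and leaves
#'   the response untouched) before modelling.
#' @param holm if `TRUE`, adds Holm-adjusted p-values across the
#'   Pearson correlation table (raw p-values are always reported).
#' @return object of class `model_report`.
#' @export
run_inference_chain <- function(traits, response = "P50",
                                candidates = c("T_PM", "implosion", "T_V",
                                               "V_G", "P_LIG", "P_FW_F_A",
                                               "D_PC", "D_H"),
                                alpha = 0.05, standardize = FALSE,
                                holm = FALSE) {
  traits <- as.data.frame(traits)
  if (!response %in% names(traits)) {
    stop("response column '", response, "' not found in trait table", call. = FALSE)
  }
  missing_cand <- setdiff(candidates, names(traits))
  if (length(missing_cand)) {
    stop("candidate predictors not in trait table: ",
         paste(missing_cand, collapse = ", "), call. = FALSE)
  }
  dat <- traits[c(response, candidates)]
  if (standardize && length(candidates)) {
    dat[candidates] <- lapply(dat[candidates], function(x) as.numeric(scale(x)))
  }

  vifs <- if (length(candidates) >= 2L) vif(dat[candidates]) else
    stats::setNames(rep(NA_real_, length(candidates)), candidates)

  sel <- backward_aic(dat, response, candidates)
  final_terms <- sel$final_terms

  rob <- robust_irls(dat, response, final_terms)

  lmg <- if (length(final_terms)) {
    lmg_importance(dat, response, final_terms)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  r2 <- if (length(final_terms)) summary(sel$final_model)$r.squared else 0

  cors <- do.call(rbind, lapply(candidates, function(tr) {
    pr <- pearson(dat[[tr]], dat[[response]])
    data.frame(trait = tr, r = pr$r, p = pr$p, n = pr$n,
               stringsAsFactors = FALSE)
  }))
  if (holm && !is.null(cors)) cors$p_holm <- stats::p.adjust(cors$p, "holm")

  structure(
    list(response = response, candidates = candidates, n = nrow(dat),
         standardized = standardize, alpha = alpha,
         vif = vifs, aic_trail = sel$aic_trail, aic_final = sel$aic_final,
         final_terms = final_terms,
         coefficients = rob$coefficients,
         robust_weights = rob$weights,
         robust_converged = rob$converged,
         r_squared = r2, lmg_shares = lmg,
         pearson = cors,
         ols_coefficients = stats::coef(sel$final_model)),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> response = %s (n = %d)\n", x$response, x$n))
  cat("  final model:", if (length(x$final_terms))
    paste(x$final_terms, collapse = " + ") else "(intercept only)",
    sprintf(" [AIC = %.2f, R^2 = %.4f]\n", x$aic_final, x$r_squared))
  if (length(x$lmg_shares)) {
    sh <- sort(x$lmg_shares, decreasing = TRUE)
    cat("  LMG shares:",
        paste(sprintf("%s = %.3f", names(sh), sh), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bar plot of LMG relative importance
#'
#' @param report a `model_report` from [run_inference_chain()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot_importance <- function(report, ...) {
  stopifnot(inherits(report, "model_report"))
  sh <- sort(report$lmg_shares, decreasing = TRUE)
  graphics::barplot(sh, ylab = expression(R^2 ~ "contribution (LMG)"),
                    xlab = "Predictor", ...)
  invisible(report)
}
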