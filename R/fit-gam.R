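#' Fit a penalized smooth age trajectory (low-rank GAM)
#'
#' Penalized least-squares fit of
#' `value ~ intercept + sex + s(age, k = 3) [+ subject random intercepts]`
#' with the smoothing parameter (and, in the longitudinal case, the
#' random-intercept precision) selected by restricted maximum likelihood
#' (REML). The age smooth is the rank-3 basis of [build_smooth_basis()]:
#' an unpenalized linear trend plus one ridge-penalized curvature
#' function. Sex enters as a symmetric `+/- 0.5` contrast (M = +0.5).
#' Subject random intercepts are estimated jointly as a ridge-penalized
#' indicator block whose precision is a second REML variance component,
#' which is the penalized-regression view of a Gaussian random effect.
#'
#' REML is the exact restricted profile likelihood of the Gaussian model,
#' minimized over log smoothing parameters with [stats::optimize()] (one
#' component) or Nelder-Mead (two components), so fits are deterministic.
#'
#' @param data Data frame with columns `age` and `value`, optionally `sex`
#'   (`"F"`/`"M"` or numeric contrast) and `subject`.
#' @param k Maximum basis complexity of the age smooth (fixed at 3).
#' @param random_intercepts Include subject random intercepts (requires a
#'   `subject` column).
#' @param include_age Set `FALSE` to fit the nested reduced model with the
#'   whole age term (linear + curvature) removed.
#' @param lambda Optional fixed smoothing parameter for the curvature
#'   penalty; `NULL` (default) selects it by REML.
#' @param lambda_subject Optional fixed random-intercept precision.
#' @return An object of class `smooth_fit`; see Details. Key fields:
#'   `coefficients`, `Vb` (Bayesian coefficient covariance), `lambda`,
#'   `lambda_subject`, `edf` (total effective degrees of freedom),
#'   `sigma2`, `r_squared` (computed on fixed-effects fitted values),
#'   `deviance` (residual sum of squares including random intercepts),
#'   `fitted`, `fitted_fixed`, `basis`.
#' @export
fit_gam <- function(data, k = 3, random_intercepts = FALSE,
                    include_age = TRUE, lambda = NULL,
                    lambda_subject = NULL) {
  stopifnot(is.data.frame(data), "value" %in% names(data), "age" %in% names(data))
  y <- as.numeric(data$value)
  age <- as.numeric(data$age)
  n <- length(y)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(age))) {
    stop("non-finite values in `value` or `age`", call. = FALSE)
  }
  has_sex <- "sex" %in% names(data)
  if (random_intercepts && !"subject" %in% names(data)) {
    stop("`random_intercepts = TRUE` needs a `subject` column", call. = FALSE)
  }

  sex_c <- if (has_sex) sex_contrast(data$sex) else NULL
  basis <- if (include_age) build_smooth_basis(age, k = k) else NULL

  # design: [intercept | sex | age, z | subject indicators]
  C <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (has_sex) C <- cbind(C, sex = sex_c)
  if (include_age) C <- cbind(C, smooth_basis_eval(basis, age))
  n_fixed <- ncol(C)
  subjects <- NULL
  if (random_intercepts) {
    subjects <- factor(data$subject)
    Z <- stats::model.matrix(~ subjects - 1)
    colnames(Z) <- paste0("subject:", levels(subjects))
    C <- cbind(C, Z)
  }
  qrC <- qr(C[, seq_len(n_fixed), drop = FALSE])
  if (qrC$rank < n_fixed) stop("rank-deficient fixed-effect design", call. = FALSE)

  pen_smooth <- if (include_age) which(colnames(C) == "z") else integer(0)
  pen_subject <- if (random_intercepts) seq(n_fixed + 1L, ncol(C)) else integer(0)
  M <- ncol(C) - length(pen_smooth) - length(pen_subject)  # unpenalized count

  CtC <- crossprod(C)
  Cty <- crossprod(C, y)
  yty <- sum(y^2)

  nreml <- function(loglam) {
    pf <- penalized_solve(CtC, Cty, yty, n, M, pen_smooth, pen_subject,
                          loglam, keep = FALSE)
    pf$nreml
  }

  free_s <- length(pen_smooth) > 0 && is.null(lambda)
  free_b <- length(pen_subject) > 0 && is.null(lambda_subject)
  ll <- c(if (length(pen_smooth)) log(if (is.null(lambda)) 1 else max(lambda, 1e-12)),
          if (length(pen_subject)) log(if (is.null(lambda_subject)) 1 else max(lambda_subject, 1e-12)))
  lam_bounds <- c(-18, 28)
  if (free_s && free_b) {
    obj <- function(p) nreml(pmin(pmax(p, lam_bounds[1]), lam_bounds[2]))
    # coarse grid start, then Nelder-Mead with one restart (the restricted
    # likelihood is smooth but can be very flat along one component)
    grid <- as.matrix(expand.grid(s = seq(-4, 16, by = 4), b = seq(-4, 16, by = 4)))
    vals <- apply(grid, 1, obj)
    opt <- stats::optim(grid[which.min(vals), ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 1000))
    if (opt$convergence != 0) {
      opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-10, maxit = 2000))
    }
    if (opt$convergence != 0) {
      stop(sprintf("REML optimization did not converge (code %d, value %.6g)",
                   opt$convergence, opt$value), call. = FALSE)
    }
    ll <- pmin(pmax(opt$par, lam_bounds[1]), lam_bounds[2])
  } else if (free_s || free_b) {
    which_free <- if (free_s) 1L else length(ll)
    f1 <- function(x) { ll2 <- ll; ll2[which_free] <- x; nreml(ll2) }
    opt <- stats::optimize(f1, interval = lam_bounds, tol = 1e-8)
    ll[which_free] <- opt$minimum
  }

  pf <- penalized_solve(CtC, Cty, yty, n, M, pen_smooth, pen_subject, ll,
                        keep = TRUE)
  beta <- drop(pf$beta)
  names(beta) <- colnames(C)
  fitted <- drop(C %*% beta)
  fitted_fixed <- drop(C[, seq_len(n_fixed), drop = FALSE] %*% beta[seq_len(n_fixed)])
  rss_full <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum((y - fitted_fixed)^2) / tss else 0

  lambda_out <- if (length(pen_smooth)) unname(exp(ll[1])) else NA_real_
  lambda_subj_out <- if (length(pen_subject)) unname(exp(ll[length(ll)])) else NA_real_

  structure(list(
    coefficients = beta,
    Vb = pf$sigma2 * pf$Ainv,
    lambda = lambda_out,
    lambda_subject = lambda_subj_out,
    subject_var = if (length(pen_subject)) unname(pf$sigma2 / exp(ll[length(ll)])) else NA_real_,
    edf = pf$edf,
    edf_by_coef = pf$edf_by_coef,
    sigma2 = pf$sigma2,
    r_squared = r2,
    deviance = rss_full,
    reml = pf$nreml,
    fitted = fitted,
    fitted_fixed = fitted_fixed,
    residuals = y - fitted,
    y = y,
    n = n,
    n_fixed = n_fixed,
    M = M,
    has_sex = has_sex,
    include_age = include_age,
    random_intercepts = random_intercepts,
    subjects = if (random_intercepts) levels(subjects) else NULL,
    basis = basis,
    age_range = range(age)
  ), class = "smooth_fit")
}

# +/- 0.5 contrast; M = +0.5. Numeric input passes through unchanged.
sex_contrast <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  s <- as.character(sex)
  if (!all(s %in% c("F", "M"))) {
    stop('`sex` must be "F"/"M" or numeric', call. = FALSE)
  }
  ifelse(s == "M", 0.5, -0.5)
}

# Penalized normal-equations solve + exact Gaussian restricted likelihood,
# with the scale parameter profiled out:
#   nreml = (n - M)/2 * (log(2 pi sigma2) + 1) + (log|A| - log|S|_+) / 2
# where A = C'C + S and M counts unpenalized coefficients.
penalized_solve <- function(CtC, Cty, yty, n, M, pen_smooth, pen_subject,
                            loglam, keep = TRUE) {
  p <- ncol(CtC)
  Sdiag <- numeric(p)
  logdetS <- 0
  i <- 1L
  if (length(pen_smooth)) {
    Sdiag[pen_smooth] <- exp(loglam[i])
    logdetS <- logdetS + length(pen_smooth) * loglam[i]
    i <- i + 1L
  }
  if (length(pen_subject)) {
    Sdiag[pen_subject] <- exp(loglam[i])
    logdetS <- logdetS + length(pen_subject) * loglam[i]
  }
  A <- CtC
  diag(A) <- diag(A) + Sdiag
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    # ridge-stabilize: only reachable for near-singular unpenalized designs
    diag(A) <- diag(A) + 1e-8 * mean(diag(CtC))
    R <- chol(A)
  }
  beta <- backsolve(R, forwardsolve(t(R), Cty))
  P <- max(yty - sum(beta * Cty), 1e-300)  # RSS + penalty, >= 0 up to rounding
  sigma2 <- P / (n - M)
  logdetA <- 2 * sum(log(diag(R)))
  nreml <- (n - M) / 2 * (log(2 * pi * sigma2) + 1) + (logdetA - logdetS) / 2
  out <- list(nreml = nreml, beta = beta, sigma2 = sigma2)
  if (keep) {
    Ainv <- chol2inv(R)
    H <- Ainv %*% CtC
    out$Ainv <- Ainv
    out$edf_by_coef <- diag(H)
    out$edf <- sum(diag(H))
  }
  out
}

#' Predict the fixed-effects trajectory of a smooth fit
#'
#' @param object A `smooth_fit`.
#' @param age Ages at which to predict.
#' @param sex Sex contrast value (default 0, the mid-point of the
#'   `+/- 0.5` coding, i.e. a sex-averaged prediction).
#' @param se Return standard errors too?
#' @param ... Unused.
#' @return Numeric predictions, or a list `fit`, `se` when `se = TRUE`.
#' @export
predict.smooth_fit <- function(object, age, sex = 0, se = FALSE, ...) {
  X <- fixed_design(object, age, sex)
  mu <- drop(X %*% object$coefficients[seq_len(object$n_fixed)])
  if (!se) return(mu)
  V <- object$Vb[seq_len(object$n_fixed), seq_len(object$n_fixed), drop = FALSE]
  list(fit = mu, se = sqrt(pmax(rowSums((X %*% V) * X), 0)))
}

fixed_design <- function(fit, age, sex = 0) {
  X <- matrix(1, length(age), 1)
  cn <- "(Intercept)"
  if (fit$has_sex) { X <- cbind(X, rep_len(sex, length(age))); cn <- c(cn, "sex") }
  if (fit$include_age) {
    X <- cbind(X, smooth_basis_eval(fit$basis, age))
    cn <- c(cn, "age", "z")
  }
  colnames(X) <- cn
  X
}

#' First derivative of the fitted age smooth
#'
#' Analytic derivative (basis derivative times coefficients) of the fitted
#' trajectory, with its standard error from the Bayesian coefficient
#' covariance.
#'
#' @param fit A `smooth_fit` with an age term.
#' @param age Ages at which to evaluate.
#' @return List with `deriv` and `se`.
#' @export
fit_derivative <- function(fit, age) {
  stopifnot(inherits(fit, "smooth_fit"))
  if (!fit$include_age) stop("fit has no age term", call. = FALSE)
  D <- smooth_basis_deriv(fit$basis, age)
  idx <- match(c("age", "z"), names(fit$coefficients))
  d <- drop(D %*% fit$coefficients[idx])
  V <- fit$Vb[idx, idx, drop = FALSE]
  se <- sqrt(pmax(rowSums((D %*% V) * D), 0))
  list(deriv = d, se = se)
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat("Penalized smooth age-trajectory fit (k = 3)\n")
  cat(sprintf("  n = %d, edf = %.2f, sigma^2 = %.4g, R^2 = %.3f\n",
              x$n, x$edf, x$sigma2, x$r_squared))
  if (x$include_age) cat(sprintf("  lambda (curvature) = %.4g\n", x$lambda))
  if (x$random_intercepts) {
    cat(sprintf("  subject variance = %.4g (%d subjects)\n",
                x$subject_var, length(x$subjects)))
  }
  invisible(x)
}
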