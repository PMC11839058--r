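#' Rank-3 thin-plate age smooth basis
#'
#' Low-rank thin-plate regression spline basis for the age smooth used by
#' every trajectory fit. Construction (1-D, second-order penalty): radial
#' basis functions `eta(r) = r^3 / 12` on knots at the unique observed
#' ages; the knot matrix `E` is eigen-decomposed and the three dominant
#' eigenvectors retained; the side conditions that make the curvature
#' penalty proper (orthogonality of the radial coefficients to the
#' polynomial space `{1, age}`) are absorbed, leaving exactly one
#' penalized curvature function alongside the unpenalized null space
#' `{1, age}`. The curvature column is scaled to unit root-mean-square
#' over the observed ages and carries an identity penalty, so constants
#' and straight lines are reproduced exactly at every smoothing level
#' while curvature is shrunk. With maximum basis complexity k = 3 the
#' smooth can bend once -- what a monotone saturating trajectory needs --
#' and cannot chase wiggly noise.
#'
#' @param ages Numeric vector of observed ages (k distinct values required).
#' @param k Basis dimension; only `k = 3` is supported.
#' @param max_knots Cap on the number of thin-plate knots (quantile-spread
#'   when the unique ages exceed it).
#' @return An object of class `smooth_basis` storing knots, the radial
#'   coefficient vector, scaling, and the observed age range.
#' @export
build_smooth_basis <- function(ages, k = 3, max_knots = 200) {
  stopifnot(is.numeric(ages), all(is.finite(ages)))
  if (k != 3) stop("only the rank-3 smooth (`k = 3`) is implemented", call. = FALSE)
  ux <- sort(unique(ages))
  if (length(ux) < k) {
    stop(sprintf("need at least %d distinct ages", k), call. = FALSE)
  }
  knots <- if (length(ux) > max_knots) {
    unique(stats::quantile(ux, probs = seq(0, 1, length.out = max_knots),
                           names = FALSE, type = 7))
  } else ux
  m <- length(knots)

  E <- abs(outer(knots, knots, `-`))^3 / 12
  Tm <- cbind(1, knots)
  eg <- eigen(E, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)[seq_len(k)]
  Uk <- eg$vectors[, ord, drop = FALSE]
  Dk <- eg$values[ord]
  # absorb the two side conditions T' delta = 0 -> one free direction
  Ct <- crossprod(Tm, Uk)                       # 2 x k
  Z <- qr.Q(qr(t(Ct)), complete = TRUE)[, k, drop = FALSE]
  w <- drop(Uk %*% Z)                           # radial coefficient vector
  pen <- drop(crossprod(Z, Dk * Z))             # penalty on the free direction
  if (pen <= 0) stop("thin-plate penalty is not positive on the curvature direction",
                     call. = FALSE)
  z_raw <- tps_radial(ages, knots, w)
  # remove the training-sample projection onto {1, age} (sum-to-zero style
  # centering; changes only the parameterization of the span)
  pr <- stats::lm.fit(cbind(1, ages), z_raw)
  z_res <- z_raw - pr$fitted.values
  scale <- sqrt(mean(z_res^2))
  if (scale <= 0) stop("degenerate ages: curvature basis is identically zero",
                       call. = FALSE)
  structure(list(k = k, knots = knots, w = w, proj = unname(pr$coefficients),
                 scale = scale, age_mean = mean(ages), age_range = range(ages)),
            class = "smooth_basis")
}

tps_radial <- function(x, knots, w) {
  drop(abs(outer(x, knots, `-`))^3 %*% w) / 12
}

tps_radial_deriv <- function(x, knots, w) {
  d <- outer(x, knots, `-`)
  drop((3 * d * abs(d)) %*% w) / 12
}

#' Evaluate the smooth basis (and its derivative) at new ages
#'
#' @param basis A [build_smooth_basis()] object.
#' @param ages Ages at which to evaluate.
#' @return `smooth_basis_eval`: matrix with columns `age` (centered linear
#'   term) and `z` (penalized curvature function);
#'   `smooth_basis_deriv`: matrix of their first derivatives in age.
#' @export
smooth_basis_eval <- function(basis, ages) {
  stopifnot(inherits(basis, "smooth_basis"))
  z <- (tps_radial(ages, basis$knots, basis$w) -
          basis$proj[1] - basis$proj[2] * ages) / basis$scale
  cbind(age = ages - basis$age_mean, z = z)
}

#' @rdname smooth_basis_eval
#' @export
smooth_basis_deriv <- function(basis, ages) {
  stopifnot(inherits(basis, "smooth_basis"))
  cbind(age = rep(1, length(ages)),
        z = (tps_radial_deriv(ages, basis$knots, basis$w) - basis$proj[2]) /
          basis$scale)
}
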