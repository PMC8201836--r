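#' Fractionation scheme
#'
#' Bundles the three symbols of the linear-quadratic EQD2 conversion: number
#' of fractions `n`, dose per fraction `d` (Gy) and the tissue fractionation
#' sensitivity `alpha_beta` (Gy; 3 for late-responding organs at risk, 10 for
#' the tumour/CTV).
#'
#' @param n Fraction count (>= 1).
#' @param d Dose per fraction in Gy (>= 0).
#' @param alpha_beta Alpha/beta ratio in Gy (> 0).
#' @return An object of class `fractionation_scheme`.
#' @examples
#' eqd2(fractionation_scheme(5, 6, 10))   # 40 Gy
#' @export
fractionation_scheme <- function(n, d, alpha_beta) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  if (length(d) != 1L || !is.finite(d) || d < 0)
    stop("'d' must be a single dose >= 0 Gy", call. = FALSE)
  if (length(alpha_beta) != 1L || !is.finite(alpha_beta) || alpha_beta <= 0)
    stop("'alpha_beta' must be a single value > 0 Gy", call. = FALSE)
  structure(list(n = as.integer(n), d = as.numeric(d),
                 alpha_beta = as.numeric(alpha_beta)),
            class = "fractionation_scheme")
}

#' @export
print.fractionation_scheme <- function(x, ...) {
  cat(sprintf("<fractionation_scheme> %d x %.4g Gy (total %.4g Gy), alpha/beta %.3g Gy\n",
              x$n, x$d, x$n * x$d, x$alpha_beta))
  invisible(x)
}

#' Previously delivered external-beam course
#'
#' The uniform EBRT phase that precedes the boost; its EQD2 is added to the
#' boost metrics when cumulative constraints are checked. Default is the
#' conventional 45 Gy pelvic course in 25 fractions of 1.8 Gy.
#'
#' @param total_gy Total physical dose of the course (Gy).
#' @param n Number of fractions.
#' @return An object of class `prior_course`.
#' @export
prior_course <- function(total_gy = 45, n = 25) {
  if (total_gy < 0) stop("'total_gy' must be >= 0", call. = FALSE)
  structure(list(total_gy = as.numeric(total_gy), n = as.integer(n)),
            class = "prior_course")
}

#' Equivalent dose in 2 Gy fractions
#'
#' Linear-quadratic conversion
#' \deqn{EQD2 = n d \frac{1 + d/(\alpha/\beta)}{1 + 2/(\alpha/\beta)}}
#' which equals the physical total dose exactly when `d = 2` Gy.
#'
#' @param scheme A [fractionation_scheme()].
#' @return EQD2 in Gy.
#' @export
eqd2 <- function(scheme) {
  stopifnot(inherits(scheme, "fractionation_scheme"))
  ab <- scheme$alpha_beta
  scheme$n * scheme$d * (1 + scheme$d / ab) / (1 + 2 / ab)
}

#' EQD2 of a scalar DVH metric
#'
#' Converts a total physical dose metric (e.g. an organ's D2cm3 over the
#' boost course) to EQD2, assuming the metric was delivered uniformly in `n`
#' fractions of `total_dose_gy / n`.
#'
#' @param total_dose_gy Total physical dose (Gy), may be a vector.
#' @param n Number of fractions of the course the metric belongs to.
#' @param alpha_beta Alpha/beta ratio (Gy).
#' @return EQD2 in Gy (vectorised over `total_dose_gy`).
#' @export
eqd2_of_metric <- function(total_dose_gy, n, alpha_beta) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (alpha_beta <= 0) stop("'alpha_beta' must be > 0", call. = FALSE)
  if (any(total_dose_gy < 0)) stop("doses must be >= 0", call. = FALSE)
  d <- total_dose_gy / n
  n * d * (1 + d / alpha_beta) / (1 + 2 / alpha_beta)
}

#' Invert the EQD2 conversion
#'
#' Returns the total physical dose over `n` fractions whose EQD2 equals
#' `target_eqd2`, i.e. the positive root of the quadratic in dose per
#' fraction `d`: `n d (1 + d/ab) / (1 + 2/ab) = target`.
#'
#' @param target_eqd2 Target EQD2 (Gy), may be a vector.
#' @param n Number of fractions.
#' @param alpha_beta Alpha/beta ratio (Gy).
#' @return Total physical dose in Gy.
#' @export
inverse_eqd2 <- function(target_eqd2, n, alpha_beta) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (alpha_beta <= 0) stop("'alpha_beta' must be > 0", call. = FALSE)
  if (any(target_eqd2 < 0)) stop("'target_eqd2' must be >= 0", call. = FALSE)
  # d^2 + ab*d - ab*(1 + 2/ab)*target/n = 0
  ab <- alpha_beta
  c0 <- ab * (1 + 2 / ab) * target_eqd2 / n
  disc <- ab^2 + 4 * c0
  if (any(disc < 0)) stop("no positive root for the requested EQD2", call. = FALSE)
  d <- (-ab + sqrt(disc)) / 2
  n * d
}

#' Cumulative EQD2 of a boost metric plus the prior EBRT course
#'
#' EQD2 of the boost-phase metric (delivered in `n` fractions) plus the EQD2
#' of the previously delivered uniform course, both at the same
#' `alpha_beta`. This is the quantity the cumulative organ-at-risk and CTV
#' objectives are written in.
#'
#' @param boost_metric_gy Boost-phase physical dose metric (Gy), vectorised.
#' @param n Boost fraction count.
#' @param alpha_beta Alpha/beta ratio (Gy).
#' @param prior A [prior_course()].
#' @return Cumulative EQD2 in Gy.
#' @examples
#' # CTV prescription: 30 Gy / 5 fx boost on top of 45 Gy / 25 fx -> 84.25 Gy
#' cumulative_eqd2(30, 5, 10, prior_course(45, 25))
#' @export
cumulative_eqd2 <- function(boost_metric_gy, n, alpha_beta, prior = prior_course()) {
  stopifnot(inherits(prior, "prior_course"))
  eqd2_of_metric(boost_metric_gy, n, alpha_beta) +
    eqd2_of_metric(prior$total_gy, prior$n, alpha_beta)
}
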