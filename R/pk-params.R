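#' Individual pharmacokinetic parameters
#'
#' Disposition constants of a mammillary compartment model with first-order
#' elimination from the central compartment. The default (and primary) case is
#' the two-compartment model used for teicoplanin: clearance `CL`, central
#' volume `Vc`, intercompartmental clearance `CLd` and peripheral volume `Vp`.
#' A one-compartment set omits `CLd`/`Vp`; a three-compartment set adds a
#' second peripheral compartment (`CLd2`, `Vp2`).
#'
#' @param CL clearance from the central compartment (L/h).
#' @param Vc central volume of distribution (L).
#' @param CLd,Vp intercompartmental clearance (L/h) and peripheral volume (L);
#'   omit both for a one-compartment model.
#' @param CLd2,Vp2 optional second peripheral compartment (three-compartment
#'   model).
#' @return An object of class `pk_params`.
#' @examples
#' p <- pk_params(CL = 0.711, Vc = 11.3, CLd = 4.22, Vp = 35.3)
#' hybrid_constants(p)
#' @export
pk_params <- function(CL, Vc, CLd = NULL, Vp = NULL, CLd2 = NULL, Vp2 = NULL) {
  vals <- c(CL = unname(CL), Vc = unname(Vc))
  check_that(is.null(CLd) == is.null(Vp),
             "CLd and Vp must be supplied together")
  check_that(is.null(CLd2) == is.null(Vp2),
             "CLd2 and Vp2 must be supplied together")
  if (!is.null(CLd)) vals <- c(vals, CLd = unname(CLd), Vp = unname(Vp))
  if (!is.null(CLd2)) {
    check_that(!is.null(CLd), "a second peripheral compartment requires a first")
    vals <- c(vals, CLd2 = unname(CLd2), Vp2 = unname(Vp2))
  }
  check_that(all(is.finite(vals)) && all(vals > 0),
             "all pharmacokinetic parameters must be finite and strictly positive")
  structure(as.list(vals),
            n_compartments = 1L + (!is.null(CLd)) + (!is.null(CLd2)),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> %d-compartment disposition\n",
              attr(x, "n_compartments")))
  print(unlist(x))
  invisible(x)
}

#' Hybrid rate constants of the two-compartment model
#'
#' Computes the distribution and elimination macro rate constants
#' (`alpha`, `beta`) as the roots of the characteristic quadratic
#' `s^2 - (k10+k12+k21) s + k10 k21 = 0`, with micro constants
#' `k10 = CL/Vc`, `k12 = CLd/Vc`, `k21 = CLd/Vp`. Always `alpha >= beta > 0`.
#'
#' @param params a two-compartment [pk_params()] object.
#' @return Named numeric vector `c(alpha, beta)` in 1/h.
#' @export
hybrid_constants <- function(params) {
  check_that(inherits(params, "pk_params"), "params must be a pk_params object")
  check_that(attr(params, "n_compartments") == 2L,
             "hybrid_constants is defined for the two-compartment model")
  de <- disp_exp(params$CL, params$Vc, params$CLd, params$Vp)
  c(alpha = de$lambda[1, 1], beta = de$lambda[1, 2])
}

## ---- internal: multi-exponential disposition ---------------------------
## Unit IV bolus central concentration is sum_j A_j exp(-lambda_j t) with
## sum_j A_j = 1/Vc. Vectorized over parameter vectors (one row per subject).
## Returns list(lambda, A): n x m matrices, lambda sorted decreasing per row.
disp_exp <- function(CL, Vc, CLd = NULL, Vp = NULL, CLd2 = NULL, Vp2 = NULL) {
  n <- length(CL)
  if (is.null(CLd)) {                             # one compartment
    return(list(lambda = cbind(CL / Vc), A = cbind(1 / Vc)))
  }
  k10 <- CL / Vc; k12 <- CLd / Vc; k21 <- CLd / Vp
  if (is.null(CLd2)) {                            # two compartments
    s <- k10 + k12 + k21
    disc <- sqrt(pmax(s * s - 4 * k10 * k21, 0))
    alpha <- (s + disc) / 2
    beta  <- (s - disc) / 2
    d <- alpha - beta
    d[d == 0] <- .Machine$double.eps              # coincident-root guard
    A1 <- (alpha - k21) / (Vc * d)
    A2 <- (k21 - beta) / (Vc * d)
    return(list(lambda = cbind(alpha, beta, deparse.level = 0),
                A = cbind(A1, A2, deparse.level = 0)))
  }
  k13 <- CLd2 / Vc; k31 <- CLd2 / Vp2             # three compartments
  a2 <- k10 + k12 + k21 + k13 + k31
  a1 <- k10 * k21 + k10 * k31 + k21 * k31 + k12 * k31 + k13 * k21
  a0 <- k10 * k21 * k31
  ## depressed cubic t^3 + p t + q, lambda = t + a2/3; three real roots
  p <- a1 - a2^2 / 3
  q <- 2 * a2^3 / 27 - a2 * a1 / 3 + a0
  m <- 2 * sqrt(pmax(-p / 3, 0))
  arg <- pmin(pmax(3 * q / (p * m + (p == 0)), -1), 1)
  phi <- acos(arg) / 3
  lam <- cbind(m * cos(phi), m * cos(phi - 2 * pi / 3), m * cos(phi - 4 * pi / 3))
  lam <- lam + a2 / 3
  lam <- t(apply(lam, 1L, sort, decreasing = TRUE))
  A <- matrix(0, n, 3L)
  for (j in 1:3) {
    oth <- setdiff(1:3, j)
    A[, j] <- (k21 - lam[, j]) * (k31 - lam[, j]) /
      (Vc * (lam[, oth[1]] - lam[, j]) * (lam[, oth[2]] - lam[, j]))
  }
  list(lambda = lam, A = A)
}

## params -> disp_exp for a single pk_params object
disp_exp_params <- function(params) {
  disp_exp(params$CL, params$Vc, params$CLd, params$Vp, params$CLd2, params$Vp2)
}
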