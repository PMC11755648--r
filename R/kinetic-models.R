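#' Disappearance-model parameter sets
#'
#' Constructors for the parameter records of the three first-order
#' disappearance models used throughout the package: simple first-order
#' (SFO), biphasic hockey-stick (HS), and first-order multicompartment
#' (FOMC, a Gustafson--Holden-type power-law decay).  Each constructor
#' validates its invariants and returns a classed list that the prediction,
#' DT50 and fitting functions accept.
#'
#' Units follow the conventions of aquatic dissipation studies: `M0` is the
#' initial concentration in mg/L, rate constants `K`, `K1`, `K2` are per
#' day, the breakpoint `tb` and location `beta` are days, and `alpha` is
#' dimensionless.
#'
#' @param M0 initial concentration (mg/L), strictly positive.
#' @param K SFO rate constant (1/day), non-negative.
#' @param K1,K2 HS fast- and slow-phase rate constants (1/day), non-negative.
#' @param tb HS breakpoint time (day) at which the rate switches, non-negative.
#' @param alpha FOMC shape parameter (dimensionless), strictly positive.
#' @param beta FOMC location parameter (day), strictly positive.
#'
#' @return An object of class `c("<model>_params", "kin_params")`, a named
#'   list of the numeric fields with a `model` attribute of `"SFO"`, `"HS"`
#'   or `"FOMC"`.
#' @examples
#' sfo_params(M0 = 10, K = 0.501)
#' hs_params(M0 = 10, K1 = 1.812, K2 = 1.374, tb = 0.1)
#' fomc_params(M0 = 10, alpha = 2.653, beta = 17.547)
#' @name kin_params
NULL

new_kin_params <- function(model, fields) {
  structure(fields, model = model,
            class = c(paste0(tolower(model), "_params"), "kin_params"))
}

check_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  x
}

#' @rdname kin_params
#' @export
sfo_params <- function(M0, K) {
  new_kin_params("SFO", list(
    M0 = check_num(M0, "M0", 0, strict = TRUE),
    K  = check_num(K, "K", 0)))
}

#' @rdname kin_params
#' @export
hs_params <- function(M0, K1, K2, tb) {
  new_kin_params("HS", list(
    M0 = check_num(M0, "M0", 0, strict = TRUE),
    K1 = check_num(K1, "K1", 0),
    K2 = check_num(K2, "K2", 0),
    tb = check_num(tb, "tb", 0)))
}

#' @rdname kin_params
#' @export
fomc_params <- function(M0, alpha, beta) {
  new_kin_params("FOMC", list(
    M0    = check_num(M0, "M0", 0, strict = TRUE),
    alpha = check_num(alpha, "alpha", 0, strict = TRUE),
    beta  = check_num(beta, "beta", 0, strict = TRUE)))
}

#' @export
print.kin_params <- function(x, ...) {
  cat(attr(x, "model"), "parameters:",
      paste(names(x), format(unlist(x), digits = 6), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

check_time <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop("time must be numeric and non-negative", call. = FALSE)
  t
}

#' Predicted concentration under the disappearance models
#'
#' Closed-form concentration at time `t` for each model.  All three are
#' continuous, equal `M0` at `t = 0`, and are non-increasing in time.
#'
#' * SFO: `M(t) = M0 * exp(-K * t)`.
#' * HS: `M(t) = M0 * exp(-K1 * t)` up to the breakpoint `tb`, then
#'   `M0 * exp(-K1 * tb) * exp(-K2 * (t - tb))`; the second branch is
#'   anchored at the value of the first so the curve is continuous at `tb`
#'   by construction.
#' * FOMC: `M(t) = M0 / ((t / beta) + 1)^alpha`, the power-law decay that
#'   arises from a gamma distribution of first-order rates across
#'   subcompartments.
#'
#' @param p parameter object from [sfo_params()], [hs_params()] or
#'   [fomc_params()].
#' @param t time in days; vectorized, must be non-negative.
#' @return Numeric vector of concentrations (mg/L), same length as `t`.
#' @examples
#' predict_sfo(sfo_params(10, 0.501), c(0, 1, 7, 28))
#' predict_hs(hs_params(10, 1.812, 1.374, 0.1), 0.4726)
#' predict_fomc(fomc_params(1, 1, 1), 1) # 0.5
#' @seealso [dt50()] for half-disappearance times.
#' @export
predict_sfo <- function(p, t) {
  stopifnot(inherits(p, "sfo_params"))
  check_time(t)
  p$M0 * exp(-p$K * t)
}

#' @rdname predict_sfo
#' @export
predict_hs <- function(p, t) {
  stopifnot(inherits(p, "hs_params"))
  check_time(t)
  ifelse(t <= p$tb,
         p$M0 * exp(-p$K1 * t),
         p$M0 * exp(-p$K1 * p$tb) * exp(-p$K2 * (t - p$tb)))
}

#' @rdname predict_sfo
#' @export
predict_fomc <- function(p, t) {
  stopifnot(inherits(p, "fomc_params"))
  check_time(t)
  p$M0 * ((t / p$beta) + 1)^(-p$alpha)
}

#' Model prediction dispatched on the parameter class
#'
#' @inheritParams predict_sfo
#' @return Concentrations at `t`.
#' @export
predict_kin <- function(p, t) {
  stopifnot(inherits(p, "kin_params"))
  switch(attr(p, "model"),
         SFO  = predict_sfo(p, t),
         HS   = predict_hs(p, t),
         FOMC = predict_fomc(p, t))
}

nonfinite_dt50 <- function(msg) {
  stop(errorCondition(paste0("non-finite DT50: ", msg),
                      class = c("ibpkin_nonfinite_dt50", "error")))
}

#' Half-disappearance time DT50
#'
#' Time for the concentration to fall to half its initial value under the
#' fitted model, from the closed forms:
#'
#' * SFO: `ln(2) / K`.
#' * HS: `ln(2) / K1` when that lies at or before the breakpoint `tb`
#'   (the fast phase alone reaches 50%), otherwise
#'   `tb + (ln(2) - K1 * tb) / K2`.  When `ln(2)/K1` equals `tb` exactly the
#'   two branches coincide and the first is returned.
#' * FOMC: `beta * (2^(1/alpha) - 1)`.
#'
#' A zero rate on the branch that applies makes DT50 infinite; this is
#' signaled as an error condition of class `"ibpkin_nonfinite_dt50"` rather
#' than returned as a number, so callers must handle the degenerate no-decay
#' case explicitly.
#'
#' @param p parameter object from [sfo_params()], [hs_params()] or
#'   [fomc_params()].
#' @return DT50 in days (finite, positive).  At the returned time the model
#'   prediction equals `M0 / 2` to numerical precision.
#' @examples
#' dt50(sfo_params(10, 0.501))                 # 1.38 d
#' dt50(hs_params(10, 0.526, 5.711, 2.6))      # 1.32 d (first branch)
#' dt50(fomc_params(10, 2.653, 17.547))        # 5.24 d
#' @export
dt50 <- function(p) {
  stopifnot(inherits(p, "kin_params"))
  switch(attr(p, "model"),
    SFO = {
      if (p$K <= 0) nonfinite_dt50("SFO rate constant is zero")
      log(2) / p$K
    },
    HS = {
      if (p$K1 > 0 && log(2) / p$K1 <= p$tb) {
        log(2) / p$K1
      } else {
        if (p$K2 <= 0)
          nonfinite_dt50("HS slow-phase rate is zero and the fast phase does not reach 50%")
        p$tb + (log(2) - p$K1 * p$tb) / p$K2
      }
    },
    FOMC = p$beta * (2^(1 / p$alpha) - 1))
}

#' Extent of removal
#'
#' Percentage decrease of the parent concentration between time zero and the
#' end of the experiment, `100 * (1 - M_end / M0)`.
#'
#' An end concentration above the initial one (possible with noisy data)
#' yields an apparent negative removal: the untruncated negative value is
#' returned with attribute `negative_removal = TRUE` and a warning, so the
#' anomaly is visible rather than silently clamped.
#'
#' @param M0 initial concentration (mg/L), strictly positive.
#' @param M_end final concentration (mg/L), non-negative.
#' @return Removal percentage in `[0, 100]` for `M_end <= M0`.
#' @examples
#' extent_of_removal(10, 6.0) # 40
#' @export
extent_of_removal <- function(M0, M_end) {
  check_num(M0, "M0", 0, strict = TRUE)
  check_num(M_end, "M_end", 0)
  pct <- 100 * (1 - M_end / M0)
  if (M_end > M0) {
    warning("apparent negative removal: M_end > M0", call. = FALSE)
    attr(pct, "negative_removal") <- TRUE
    return(pct)
  }
  min(max(pct, 0), 100)
}
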