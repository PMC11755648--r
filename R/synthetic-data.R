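#' Specification for a synthetic degradation time course
#'
#' Captures everything needed to generate one treatment's worth of data
#' emulating the triplicate-flask microcosm design: the generating model and
#' its true parameters, the sampling grid, the replicate count, the noise
#' model, the parent detection limit and the master seed.
#'
#' The noise model is additive Gaussian (`sigma`, mg/L) plus proportional
#' Gaussian (`cv`, percent of the model prediction), both applied
#' independently at every observation and the sum clipped at zero.  Defaults
#' (`sigma = 0.2` mg/L, `cv = 2`%) give synthetic fits with coefficients of
#' determination in the 0.85-1.00 range typical of shake-flask HPLC data.
#' The default grid 0, 1, 2, 3, 4, 7, 14, 21, 28 days spans the 28-day
#' incubation with the denser early sampling needed to resolve fast initial
#' decay.
#'
#' @param params generating [kin_params] object (ignored when
#'   `control = TRUE` except for its `M0`).
#' @param times sampling grid in days; sorted, must include 0.
#' @param n_replicates number of flasks (default 3).
#' @param sigma additive noise SD (mg/L).
#' @param cv proportional noise coefficient of variation (%).
#' @param detection_limit parent detection limit (mg/L).
#' @param seed master seed (integer); replicate-level substreams are derived
#'   from it so adding replicates never perturbs existing ones.
#' @param control if `TRUE`, generate a non-inoculated abiotic control: the
#'   no-decay identity model at `params$M0` with the same noise.
#' @param treatment label attached to the generated series.
#' @return List of class `"synthetic_spec"`.
#' @examples
#' spec <- synthetic_spec(sfo_params(10, 0.501), seed = 42)
#' tc <- simulate_timecourse(spec)
#' @export
synthetic_spec <- function(params,
                           times = c(0, 1, 2, 3, 4, 7, 14, 21, 28),
                           n_replicates = 3L, sigma = 0.2, cv = 2,
                           detection_limit = 0.05, seed,
                           control = FALSE, treatment = "") {
  stopifnot(inherits(params, "kin_params"))
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (!is.numeric(times) || is.unsorted(times) || !any(times == 0))
    stop("'times' must be sorted and include 0", call. = FALSE)
  if (sigma < 0 || cv < 0) stop("noise parameters must be >= 0", call. = FALSE)
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1", call. = FALSE)
  structure(list(params = params, times = as.numeric(times),
                 n_replicates = as.integer(n_replicates),
                 sigma = sigma, cv = cv,
                 detection_limit = detection_limit,
                 seed = as.integer(seed), control = isTRUE(control),
                 treatment = treatment),
            class = "synthetic_spec")
}

# Deterministic substream seed for stream index i under master seed.
# Kept below 2^31 (doubles are exact far beyond that range).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807 + 1) %%
               2147483647)
}

# One replicate's noisy observations on the grid
sim_replicate <- function(pred, sigma, cv, sub_seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(sub_seed)
  n <- length(pred)
  obs <- pred + stats::rnorm(n, 0, sigma) +
    stats::rnorm(n, 0, 1) * (cv / 100) * pred
  pmax(obs, 0)
}

#' Generate a synthetic degradation time course
#'
#' Draws replicate observations around the generating model on the sampling
#' grid, with additive plus proportional Gaussian noise, clipped at zero.
#' Each replicate uses its own substream derived from the master seed, so
#' the same spec and seed always give byte-identical output, and raising
#' `n_replicates` appends new flasks without changing existing ones.
#' Observations below the detection limit are flagged in the `below_dl`
#' column.  Control specs use the no-decay identity model.
#'
#' @param spec a [synthetic_spec()].
#' @return A [timecourse()] with an extra `below_dl` column and the
#'   generating spec attached as attribute `generating_spec`.
#' @export
simulate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pred <- if (spec$control) rep(spec$params$M0, length(spec$times))
          else predict_kin(spec$params, spec$times)
  obs <- lapply(seq_len(spec$n_replicates), function(r)
    sim_replicate(pred, spec$sigma, spec$cv, derive_seed(spec$seed, r)))
  # row order: all replicates at each time, times increasing
  # (rbind gives replicates x times; column-major stacking matches
  # time-major rows with replicate fastest)
  conc <- as.vector(do.call(rbind, obs))
  tc <- timecourse(
    time_days = rep(spec$times, each = spec$n_replicates),
    replicate = rep(seq_len(spec$n_replicates), times = length(spec$times)),
    concentration_mg_L = conc,
    treatment = spec$treatment,
    nominal_M0 = spec$params$M0,
    is_control = spec$control)
  tc$below_dl <- tc$concentration_mg_L < spec$detection_limit
  attr(tc, "generating_spec") <- spec
  tc
}

#' Generate a synthetic dose-response series
#'
#' Responses follow the log-linear model `a + b * log10(dose)` plus
#' Gaussian noise, clipped to the plausible percentage range `[0, 120]`.
#' For viability data the true slope must be negative (growth falls with
#' dose); for luminescence inhibition it must be positive.
#'
#' @param kind `"viability"` or `"luminescence_inhibition"`.
#' @param true_a,true_b intercept and slope of the generating line.
#' @param doses dose grid (mg/L or % v/v), strictly positive.
#' @param sigma response noise SD (percentage points).
#' @param seed master seed.
#' @return A [dose_response()].
#' @examples
#' # back-solve the intercept so the line crosses 50% viability at 217 mg/L
#' b <- -36.74; a <- 50 - b * log10(217)
#' s <- simulate_dose_response("viability", a, b,
#'                             doses = c(10, 50, 100, 500, 3000),
#'                             sigma = 0, seed = 1)
#' estimate_ic50(s)$ic50 # 217
#' @export
simulate_dose_response <- function(kind = c("viability", "luminescence_inhibition"),
                                   true_a, true_b, doses, sigma = 0, seed) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (kind == "viability" && true_b >= 0)
    stop("viability must fall with dose: 'true_b' must be < 0", call. = FALSE)
  if (kind == "luminescence_inhibition" && true_b <= 0)
    stop("inhibition must grow with dose: 'true_b' must be > 0", call. = FALSE)
  mu <- true_a + true_b * log10(doses)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, 101L))
  resp <- pmin(pmax(mu + stats::rnorm(length(doses), 0, sigma), 0), 120)
  dose_response(doses, resp, kind = kind)
}

#' Default metabolite limits of quantification (ug/L)
#'
#' LC-MS/MS limits for the hydroxylated metabolites (1 ug/L) and the
#' carboxylated metabolite (10 ug/L).
#' @export
METABOLITE_LOQ <- c("1-OH-IBP" = 1, "2-OH-IBP" = 1, "CBX-IBP" = 10)

# Closed-form metabolite concentration (ug/L) for first-order formation from
# an SFO parent (M0 mg/L, rate K) with yield f and first-order decay k.
metabolite_sfo_closed_form <- function(t, M0, K, f, k) {
  scale <- 1000 * f * M0 # mg/L parent mass -> ug/L metabolite
  if (K <= 0) return(rep(0, length(t)))
  if (k == 0) return(scale * (1 - exp(-K * t)))
  if (abs(k - K) < 1e-12) return(scale * K * t * exp(-K * t))
  scale * K / (k - K) * (exp(-K * t) - exp(-k * t))
}

#' Simulate LOQ-censored metabolite series
#'
#' Each metabolite forms in proportion to parent loss (yield fraction) and
#' decays first-order.  When the parent time course carries a generating
#' SFO spec (as produced by [simulate_timecourse()]) the exact
#' formation-decay closed form is evaluated on the sampling grid; otherwise
#' the parent loss is integrated piecewise from the replicate means,
#' treating the loss rate as constant within each sampling interval.
#' Concentrations below each analyte's limit of quantification are emitted
#' censored: the numeric value is `NA` and the `censored` flag is set, so no
#' reported number is ever below its LOQ.  Optional proportional noise uses
#' per-analyte substreams of the master seed.
#'
#' @param parent a [timecourse()] for the parent compound.
#' @param yields named yield fractions in `[0, 1]` per analyte.
#' @param decay_rates named first-order decay rates (1/day) per analyte.
#' @param loqs named limits of quantification (ug/L); default
#'   [METABOLITE_LOQ].
#' @param seed master seed.
#' @param cv proportional noise CV (%) applied to uncensored values
#'   (default 0: fully deterministic trajectories).
#' @return Named list of data frames (class `"metabolite_series"`), one per
#'   analyte, with columns `time_days`, `concentration_ug_L` (`NA` when
#'   censored), `censored`, and attributes `analyte` and `loq`.
#' @export
simulate_metabolites <- function(parent,
                                 yields = c("1-OH-IBP" = 0.01,
                                            "2-OH-IBP" = 0.02,
                                            "CBX-IBP" = 0.009),
                                 decay_rates = c("1-OH-IBP" = 0.05,
                                                 "2-OH-IBP" = 0.05,
                                                 "CBX-IBP" = 0.05),
                                 loqs = METABOLITE_LOQ, seed, cv = 0) {
  stopifnot(inherits(parent, "timecourse"))
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (any(yields < 0 | yields > 1))
    stop("'yields' must lie in [0, 1]", call. = FALSE)
  if (any(decay_rates < 0)) stop("'decay_rates' must be >= 0", call. = FALSE)
  analytes <- names(yields)
  if (is.null(analytes) || !setequal(analytes, names(decay_rates)) ||
      !all(analytes %in% names(loqs)))
    stop("'yields', 'decay_rates' and 'loqs' must share analyte names",
         call. = FALSE)

  gs <- attr(parent, "generating_spec")
  use_closed <- !is.null(gs) && !gs$control &&
    attr(gs$params, "model") == "SFO"
  tmean <- summary_times(parent)
  tt <- tmean$time_days

  out <- lapply(seq_along(analytes), function(i) {
    a <- analytes[i]
    f <- yields[[a]]; k <- decay_rates[[a]]; loq <- loqs[[a]]
    conc <- if (use_closed) {
      metabolite_sfo_closed_form(tt, gs$params$M0, gs$params$K, f, k)
    } else {
      m <- numeric(length(tt))
      for (j in seq_along(tt)[-1]) {
        dt <- tt[j] - tt[j - 1]
        loss <- max(tmean$concentration_mg_L[j - 1] -
                      tmean$concentration_mg_L[j], 0)
        rate <- 1000 * f * loss / dt # ug/L/day constant input
        m[j] <- if (k > 0)
          m[j - 1] * exp(-k * dt) + rate / k * (1 - exp(-k * dt))
        else m[j - 1] + rate * dt
      }
      m
    }
    if (cv > 0) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(derive_seed(seed, 200L + i))
      conc <- pmax(conc * (1 + stats::rnorm(length(conc), 0, cv / 100)), 0)
    }
    censored <- conc < loq
    structure(data.frame(time_days = tt,
                         concentration_ug_L = ifelse(censored, NA_real_, conc),
                         censored = censored),
              analyte = a, loq = loq,
              class = c("metabolite_series", "data.frame"))
  })
  names(out) <- analytes
  out
}
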