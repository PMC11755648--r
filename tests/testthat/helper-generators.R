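# Random valid parameter sets for property-style tests.  HS draws are split
# between the fast-phase branch (ln2/K1 <= tb) and the two-phase branch so
# both DT50 formulas get exercised.
random_kin_params <- function(model) {
  switch(model,
    SFO = sfo_params(M0 = runif(1, 0.5, 200), K = runif(1, 0.01, 5)),
    FOMC = fomc_params(M0 = runif(1, 0.5, 200),
                       alpha = runif(1, 0.05, 8),
                       beta = runif(1, 0.01, 50)),
    HS = {
      K1 <- runif(1, 0.05, 5)
      tb <- if (runif(1) < 0.5) log(2) / K1 * runif(1, 1.05, 3) # first branch
            else log(2) / K1 * runif(1, 0.05, 0.95)             # second branch
      hs_params(M0 = runif(1, 0.5, 200), K1 = K1,
                K2 = runif(1, 0.01, 5), tb = tb)
    })
}

hs_branch <- function(p) if (log(2) / p$K1 <= p$tb) "first" else "second"

# Exhaustive grid search oracle for the least-squares optimum: evaluates the
# SSR over a box, zooms on the best cell, and repeats.  Independent of the
# package's fitter.
grid_search_ssr <- function(times, means, model, box, n = 15, refinements = 2) {
  make_grid <- function(b) {
    axes <- lapply(b, function(r) seq(r[1], r[2], length.out = n))
    do.call(expand.grid, axes)
  }
  best <- NULL
  b <- box
  for (it in seq_len(refinements + 1)) {
    g <- make_grid(b)
    ssr <- apply(g, 1, function(row) {
      p <- switch(model,
        SFO = sfo_params(row[1], row[2]),
        FOMC = fomc_params(row[1], row[2], row[3]))
      sum((means - predict_kin(p, times))^2)
    })
    i <- which.min(ssr)
    best <- list(par = as.numeric(g[i, ]), ssr = ssr[i])
    # zoom: one grid step around the best point in every dimension
    b <- lapply(seq_along(b), function(j) {
      step <- (b[[j]][2] - b[[j]][1]) / (n - 1)
      c(max(b[[j]][1], best$par[j] - step), best$par[j] + step)
    })
  }
  best
}
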