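#' Packaged reference tables
#'
#' Transcriptions of the published kinetic-parameter table (per-treatment
#' model choice, rate/shape parameters, DT50, extent of removal and
#' adequacy statistics for initial ibuprofen 1-100 mg/L with glucose 0, 1 or
#' 3 g/L) and the Microtox acute-toxicity table (Toxic Units and Persoone
#' class at day 0 and day 28 per treatment).  Every row carries its
#' table-of-origin tag in `source_table`; transcription ambiguities are
#' recorded in the `note` column (one DT50 is printed with a European
#' thousands separator and stored as 30506 days).
#'
#' @param which `"kinetics"` (the parameter table) or `"toxicity"` (the
#'   Microtox table).
#' @return A data frame.
#' @examples
#' head(ibp_fixture("kinetics"))
#' ibp_fixture("toxicity")
#' @export
ibp_fixture <- function(which = c("kinetics", "toxicity")) {
  which <- match.arg(which)
  file <- switch(which, kinetics = "table2_kinetics.csv",
                 toxicity = "table3_toxicity.csv")
  path <- system.file("extdata", file, package = "ibpkin", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Parameter object from a kinetics fixture row
#'
#' @param row a single row of `ibp_fixture("kinetics")`.
#' @param M0 initial concentration to attach (the fixture stores rates and
#'   shapes, not the fitted M0); defaults to the row's nominal ibuprofen
#'   concentration.
#' @return The corresponding [kin_params] object.
#' @export
fixture_params <- function(row, M0 = row$ibp_mg_L) {
  stopifnot(nrow(row) == 1L)
  switch(row$model,
         SFO  = sfo_params(M0, row$K1),
         HS   = hs_params(M0, row$K1, row$K2, row$tb),
         FOMC = fomc_params(M0, row$alpha, row$beta),
         stop("unknown model in fixture row: ", row$model, call. = FALSE))
}
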