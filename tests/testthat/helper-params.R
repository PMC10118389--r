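## Table-3 defaults at two system sizes used throughout the suite
defaultParams <- function(C0 = 1e4, e = 0.95, eta = 1e-3, mu = 1e-5, ...) {
  simParams(C0 = C0, e = e, eta = eta, mu = mu, ...)
}

## steady-state window of a totals table
steadyWindow <- function(result, startGen = NULL) {
  tot <- result@totals
  if (is.null(startGen))
    startGen <- result@schedule$steadyStateStart * result@params@gC0
  tot[tot$tGen >= startGen, ]
}
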