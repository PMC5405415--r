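# Random but reproducible fundamental-constant draws used across the suite.
# Rates are log-uniform on [0.3, 3] s^-1; `dilute` shrinks the diffusion
# affinity so that bimolecular intermediates hold negligible mass at unit
# totals (the regime in which the two-state bookkeeping of the single-step
# and FRET reductions is meaningful).
draw_fundamental <- function(seed, dimension = "2D", dilute = FALSE) {
  set.seed(seed)
  r <- 10^stats::runif(6, log10(0.3), log10(3))
  names(r) <- c("d_plus", "d_minus", "e_plus", "e_minus", "k_plus", "k_minus")
  if (dilute) r["d_plus"] <- 1e-5 * r["d_minus"] * r["d_plus"]
  do.call(fundamental_constants, c(list(dimension), as.list(r)))
}

# dilute draws are needed for the kinds whose reduced model has no explicit
# pre-binding species
needs_dilution <- function(kind) kind %in% c("FRET", "SS")

# an effective-constants list per panel row, for the matched-assay estimators
panel_effective_list <- function(panel, shared, kind) {
  lapply(seq_len(nrow(panel)), function(i) {
    reduce_to_effective(panel_params(panel, i, shared), kind)
  })
}
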