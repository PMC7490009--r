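#' Drug-condition presets for the simulator
#'
#' Each preset fixes the probability that an mRNA carries nascent chains
#' (`p_translating`), the ribosome-load law on translating mRNAs, and the
#' expected number of released single SunTag peptides per cell. The
#' `p_translating` values are the mean per-cell colocalized fractions
#' reported for the four drug conditions of the SunTag reporter experiment:
#' 63% untreated, 3% after 5 min puromycin, 5% after emetine pre-treatment
#' followed by puromycin, and 50% after anisomycin pre-treatment followed by
#' puromycin.
#'
#' The nascent-chain count on a translating mRNA is drawn as
#' `k = 1 + Poisson(lambda_nascent)`; the default `lambda_nascent = 4`
#' puts almost all translating sites well above the one-peptide association
#' threshold (P(k = 1) ~ 1.8%), so the per-cell colocalized fraction
#' estimates `p_translating` directly.
#'
#' @param name one of `"untreated"`, `"puromycin"`, `"emetine_puromycin"`,
#'   `"anisomycin"`.
#' @param p_translating probability in \[0, 1\] that an mRNA is translating.
#' @param lambda_nascent Poisson rate of the `k = 1 + Poisson(lambda)`
#'   nascent-count law.
#' @param free_peptide_density expected released single peptides per cell.
#' @return An object of class `condition_preset`.
#' @export
condition_preset <- function(name, p_translating, lambda_nascent = 4,
                             free_peptide_density = 20) {
  stopifnot(is.character(name), length(name) == 1,
            p_translating >= 0, p_translating <= 1,
            lambda_nascent >= 0, free_peptide_density >= 0)
  structure(list(name = name, p_translating = p_translating,
                 lambda_nascent = lambda_nascent,
                 free_peptide_density = free_peptide_density),
            class = "condition_preset")
}

#' The four study condition presets
#'
#' @param which character vector of preset names, or `"all"`.
#' @return Named list of `condition_preset` objects.
#' @export
condition_presets <- function(which = "all") {
  all <- list(
    untreated         = condition_preset("untreated",         0.63),
    puromycin         = condition_preset("puromycin",         0.03),
    emetine_puromycin = condition_preset("emetine_puromycin", 0.05),
    anisomycin        = condition_preset("anisomycin",        0.50)
  )
  if (identical(which, "all")) return(all)
  missing <- setdiff(which, names(all))
  if (length(missing))
    stop("unknown preset(s): ", paste(missing, collapse = ", "))
  all[which]
}
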