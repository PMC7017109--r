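#' Bundled calibration knowledge base
#'
#' A ten-drug knowledge base distilled from the published worked example of
#' a hormone-positive breast-cancer case (bundled here as
#' [patient51_profile()]): hormone agents matching estrogen-receptor
#' expression directly (anastrozole additionally matching progesterone-
#' receptor expression indirectly through hormone signaling), everolimus
#' matching PTEN copy loss as a sensitivity biomarker and mTOR activation
#' directly, trastuzumab matching ERBB2, and six conventional cytotoxics
#' carrying no rules. The rule weights are a package convention (direct
#' 1.0, indirect 0.5) -- the platform the worked example comes from does not
#' publish its weights -- chosen as the minimal scheme under which all four
#' published scores for that case (17%, 42%, and 0% twice) reproduce
#' against the six-biomarker profile.
#'
#' @return A `knowledge_base`.
#' @seealso [patient51_profile()]
#' @export
calibration_kb <- function() {
  load_kb(system.file("extdata", "kb_calibration.json", package = "oncomatch"),
          format = "json")
}

#' Bundled worked-example patient profile
#'
#' The profile of the published breast-cancer case used to calibrate the
#' scoring convention: estrogen- and progesterone-receptor positive, Her2
#' negative, with PTEN gene-copy loss and CCND1, FGFR1 and PRKDC
#' amplifications. Six alterations are scoreable; the Her2-negative finding
#' is retained for reporting but excluded from the denominator (a negative
#' finding is not an alteration). Note that the source narrative reports
#' hormone-receptor status without stating explicitly that both receptors
#' enter the score; the six-element denominator is the only reading under
#' which the published 17% = 1/6 single-agent score reproduces.
#'
#' @return A `patient_profile` with id `"P51"`.
#' @export
patient51_profile <- function() {
  load_profiles(system.file("extdata", "profiles_patient51.tsv",
                            package = "oncomatch"),
                format = "tsv",
                patients_path = system.file("extdata", "patients_patient51.tsv",
                                            package = "oncomatch"))[["P51"]]
}
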