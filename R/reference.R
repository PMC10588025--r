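#' Reference claims-cohort margins
#'
#' Patient counts (total and diabetic) by gender and age band from a
#' province-wide Iranian health-insurance pharmacy-claims cohort. These
#' margins calibrate the synthetic generator's defaults — roughly 10%
#' diabetic prevalence, diabetics predominantly female and in the Old age
#' band — and supply the worked in-cohort arithmetic (diabetic over total
#' patients) that the acceptance checks recompute.
#'
#' @return `data.table(stratum, n_total, n_diabetic)` with rows `all`,
#'   `female`, `male`, `Young`, `Middle-Aged`, `Old`.
#' @export
reference_cohort_counts <- function() {
  fread(system.file("extdata", "reference_cohort_counts.csv",
                    package = "rxmine"), colClasses = list(
                      character = "stratum",
                      integer = c("n_total", "n_diabetic")))
}
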