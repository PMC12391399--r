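# Physiological calculations: Evans blue mortality/viability normalization,
# chlorophyll and carotenoid quantification in 80% acetone with 720 nm
# turbidity correction, and pigment yield per culture volume.

#' Default pigment equation coefficients (80% acetone)
#'
#' Coefficient set for chlorophyll a, chlorophyll b and total carotenoids
#' from absorbances of an 80% acetone extract at 663, 646 and 470 nm
#' (baseline-corrected). Exposed so alternative published coefficient tables
#' can be swapped in.
#'
#' @return a named list with components `chl_a` (A663, A646 weights),
#'   `chl_b` (A646, A663 weights) and `car` (A470 scale, chl_a and chl_b
#'   corrections, denominator).
#' @export
pigment_coefficients <- function() {
  list(chl_a = c(a663 = 12.21, a646 = -2.81),
       chl_b = c(a646 = 20.13, a663 = -5.03),
       car = c(a470 = 1000, chl_a = -3.27, chl_b = -104, denom = 198))
}

#' Evans blue mortality and viability
#'
#' Absorbance (600 nm) of dye solubilized from the test culture is
#' standardized against a matched heat-killed control representing ~100%
#' mortality: `mortality = 100 * a600_sample / a600_heatkilled`. Viability is
#' `100 - mortality`, clipped to [0, 100]; raw mortality above 100% (sample
#' stains more than the killed control) is QC-flagged, not an error.
#'
#' @param a600_sample absorbance(s) of the test sample, >= 0.
#' @param a600_heatkilled absorbance(s) of the heat-killed control, > 0.
#' @return a `data.frame` with `mortality` (raw percent), `viability`
#'   (clipped percent) and logical `qc_over100`.
#' @export
mortality_percent <- function(a600_sample, a600_heatkilled) {
  if (any(a600_sample < 0)) stopf("sample absorbance must be >= 0")
  if (any(a600_heatkilled <= 0)) stopf("heat-killed absorbance must be > 0")
  mortality <- 100 * a600_sample / a600_heatkilled
  data.frame(mortality = mortality,
             viability = pmin(pmax(100 - mortality, 0), 100),
             qc_over100 = mortality > 100)
}

#' Pigment concentrations from extract absorbances
#'
#' Each analytical wavelength is first baseline-corrected by subtracting the
#' 720 nm reading (the conventional turbidity correction, which makes the
#' result exactly invariant to a uniform absorbance offset), then the 80%
#' acetone equations are applied: `chl_a = 12.21 A663' - 2.81 A646'`,
#' `chl_b = 20.13 A646' - 5.03 A663'`,
#' `carotenoids = (1000 A470' - 3.27 chl_a - 104 chl_b) / 198` (all ug/mL
#' extract).
#'
#' @param a470,a646,a663 absorbances of the extract (vectors recycled to a
#'   common length).
#' @param a720 baseline absorbance at 720 nm (default 0).
#' @param coef coefficient set, see [pigment_coefficients()].
#' @return a `data.frame` with `chl_a`, `chl_b`, `chl_total`, `carotenoids`
#'   (ug/mL extract) and a logical `qc_negative` flag set when any corrected
#'   absorbance or concentration is negative (flagged, never an error).
#' @export
pigment_concentrations <- function(a470, a646, a663, a720 = 0,
                                   coef = pigment_coefficients()) {
  if (any(c(a470, a646, a663, a720) < 0)) stopf("absorbances must be >= 0")
  n <- max(length(a470), length(a646), length(a663), length(a720))
  a470 <- rep_len(a470, n); a646 <- rep_len(a646, n)
  a663 <- rep_len(a663, n); a720 <- rep_len(a720, n)
  c470 <- a470 - a720; c646 <- a646 - a720; c663 <- a663 - a720
  qc <- c470 < 0 | c646 < 0 | c663 < 0
  chl_a <- coef$chl_a[["a663"]] * c663 + coef$chl_a[["a646"]] * c646
  chl_b <- coef$chl_b[["a646"]] * c646 + coef$chl_b[["a663"]] * c663
  car <- (coef$car[["a470"]] * c470 + coef$car[["chl_a"]] * chl_a +
            coef$car[["chl_b"]] * chl_b) / coef$car[["denom"]]
  data.frame(chl_a = chl_a, chl_b = chl_b, chl_total = chl_a + chl_b,
             carotenoids = car,
             qc_negative = qc | chl_a < 0 | chl_b < 0 | car < 0)
}

#' Pigment yield per culture volume (and per cell)
#'
#' Converts extract concentrations to yields per unit culture volume by the
#' extract-to-culture volume factor, and to per-cell contents when a cell
#' density is supplied.
#'
#' @param conc a [pigment_concentrations()] result (or a data.frame with the
#'   same concentration columns).
#' @param extract_to_culture_factor ratio of extract volume to culture
#'   volume; > 0. Factor 1 means the yield equals the extract concentration.
#' @param cell_density optional cells/mL of culture for per-cell contents.
#' @return a `data.frame` with yields `chl_a`, `chl_b`, `chl_total`,
#'   `carotenoids` (ug/mL culture) and, when `cell_density` is given,
#'   `chl_total_per_cell` and `carotenoids_per_cell` (ug/cell).
#' @export
pigment_yield <- function(conc, extract_to_culture_factor,
                          cell_density = NULL) {
  if (any(extract_to_culture_factor <= 0)) stopf("factor must be > 0")
  cols <- c("chl_a", "chl_b", "chl_total", "carotenoids")
  miss <- setdiff(cols, names(conc))
  if (length(miss)) stopf("`conc` lacks column(s): %s", paste(miss, collapse = ", "))
  out <- as.data.frame(lapply(conc[cols], `*`, extract_to_culture_factor))
  if (!is.null(cell_density)) {
    if (any(cell_density <= 0)) stopf("cell_density must be > 0")
    out$chl_total_per_cell <- out$chl_total / cell_density
    out$carotenoids_per_cell <- out$carotenoids / cell_density
  }
  out
}

#' Invert the pigment equations: absorbances from known concentrations
#'
#' Exact inverse of [pigment_concentrations()] under the same coefficient
#' set; used by the synthetic physiology generator so that zero-noise
#' readings recover the planted truth exactly.
#'
#' @param chl_a,chl_b,carotenoids target concentrations (ug/mL extract).
#' @param a720 baseline offset added to all four wavelengths (default 0).
#' @param coef coefficient set, see [pigment_coefficients()].
#' @return a `data.frame` with columns `a470`, `a646`, `a663`, `a720`.
#' @export
absorbances_from_pigments <- function(chl_a, chl_b, carotenoids, a720 = 0,
                                      coef = pigment_coefficients()) {
  c1 <- coef$chl_a[["a663"]]; c2 <- -coef$chl_a[["a646"]]
  c3 <- coef$chl_b[["a646"]]; c4 <- -coef$chl_b[["a663"]]
  det <- c1 * c3 - c2 * c4
  a663 <- (c3 * chl_a + c2 * chl_b) / det
  a646 <- (c4 * chl_a + c1 * chl_b) / det
  a470 <- (coef$car[["denom"]] * carotenoids -
             coef$car[["chl_a"]] * chl_a -
             coef$car[["chl_b"]] * chl_b) / coef$car[["a470"]]
  data.frame(a470 = a470 + a720, a646 = a646 + a720, a663 = a663 + a720,
             a720 = a720 + numeric(length(a470)))
}
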