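# Retention-index identification and internal-standard semi-quantification.

#' Reference ladder for retention-index calculation
#'
#' A homologous series (n-alkanes or n-ketones) with known carbon numbers
#' and observed retention times, used to place analytes on the retention
#' index scale.
#'
#' @param carbon_number integer carbon numbers, strictly increasing.
#' @param retention_time retention times in seconds, strictly increasing.
#' @return A \code{reference_ladder}.
#' @export
reference_ladder <- function(carbon_number, retention_time) {
  if (length(carbon_number) != length(retention_time)) {
    stop("carbon_number and retention_time lengths differ")
  }
  if (length(carbon_number) < 2) stop("ladder needs at least 2 rungs")
  if (any(diff(carbon_number) <= 0) || any(diff(retention_time) <= 0)) {
    stop("ladder must be strictly increasing in index and time")
  }
  structure(list(carbon_number = as.numeric(carbon_number),
                 retention_time = as.numeric(retention_time)),
            class = "reference_ladder")
}

#' Linear (van den Dool-Kratz) retention index
#'
#' Piecewise-linear interpolation of the carbon number between the ladder
#' rungs bracketing the observed retention time, times 100: for rt between
#' rungs n and n+1, \eqn{RI = 100 [n + (t - t_n)/(t_{n+1} - t_n)]}. This
#' linear form is appropriate for temperature-programmed runs (the
#' logarithmic Kovats form applies to isothermal ones). At a rung the RI
#' is exactly 100 times its carbon number.
#'
#' @param rt observed retention time(s), seconds.
#' @param ladder a \code{\link{reference_ladder}}.
#' @param extrapolate permit linear extrapolation outside the ladder span
#'   (with a warning); by default out-of-span times are an error.
#' @return Numeric retention index (vectorized over \code{rt}).
#' @export
retention_index <- function(rt, ladder, extrapolate = FALSE) {
  stopifnot(inherits(ladder, "reference_ladder"))
  n <- ladder$carbon_number
  t <- ladder$retention_time
  outside <- rt < t[1] | rt > t[length(t)]
  if (any(outside)) {
    if (!extrapolate) {
      stop(sprintf("retention time outside ladder span [%g, %g]",
                   t[1], t[length(t)]))
    }
    warning("extrapolating retention index outside the ladder span")
  }
  idx <- pmin(pmax(findInterval(rt, t), 1), length(t) - 1)
  100 * (n[idx] + (rt - t[idx]) / (t[idx + 1] - t[idx]) *
           (n[idx + 1] - n[idx]))
}

#' Retention-index library match rule
#'
#' An observed RI matches a library RI when their absolute difference is
#' strictly below the tolerance (default 50 RI units); a difference of
#' exactly 50 is not a match.
#'
#' @param ri_observed,ri_library retention indices (vectorized).
#' @param tolerance RI units.
#' @return Logical.
#' @export
match_library <- function(ri_observed, ri_library, tolerance = 50) {
  if (any(ri_observed <= 0) || any(ri_library <= 0)) {
    stop("retention indices must be positive")
  }
  abs(ri_observed - ri_library) < tolerance
}

#' Identify peaks against a compound library by RI
#'
#' For each observed RI, candidate library compounds within the tolerance
#' are ranked by closeness; the closest wins, ties broken alphabetically
#' by compound name. Unmatched peaks return \code{NA}.
#'
#' @param ri_observed observed retention indices.
#' @param library a \code{gcms_library}.
#' @param tolerance RI units (strict).
#' @return Character vector of matched compound names (or \code{NA}).
#' @export
match_compound <- function(ri_observed, library, tolerance = 50) {
  stopifnot(inherits(library, "gcms_library"))
  lib_ri <- library$records$retention_index
  lib_name <- library$records$name
  vapply(ri_observed, function(ri) {
    d <- abs(ri - lib_ri)
    ok <- d < tolerance
    if (!any(ok)) return(NA_character_)
    cand <- which(ok)
    cand <- cand[order(d[cand], lib_name[cand])]
    lib_name[cand[1]]
  }, character(1))
}

#' Internal-standard quantification configuration
#'
#' Defaults match the study protocol: 1 uL of a 0.816 ug/uL
#' 2-methyl-3-heptanone solution spiked into a 2 g rice sample.
#'
#' @param is_name internal standard name.
#' @param is_mass_ug spiked internal-standard mass, micrograms.
#' @param sample_mass_g sample mass, grams.
#' @return A \code{quant_config}.
#' @export
quant_config <- function(is_name = "2-Methyl-3-heptanone",
                         is_mass_ug = 0.816, sample_mass_g = 2.0) {
  if (is_mass_ug <= 0 || sample_mass_g <= 0) stop("masses must be positive")
  structure(list(is_name = is_name, is_mass_ug = is_mass_ug,
                 sample_mass_g = sample_mass_g),
            class = "quant_config")
}

#' Semi-quantify a compound against the internal standard
#'
#' Content = (analyte area / IS area) x IS mass / sample mass, expressed
#' per kg of sample. With the default 0.816 ug IS in 2 g, an area ratio of
#' 1 corresponds to 408 ug/kg. The result is linear in the area ratio, so
#' it is a relative (IS-equivalent) content, not an absolute calibration.
#'
#' @param area_analyte analyte peak area(s), >= 0.
#' @param area_is internal-standard peak area, > 0.
#' @param config a \code{\link{quant_config}}.
#' @return Content in ug per kg of sample (IS-equivalent).
#' @export
semi_quantify <- function(area_analyte, area_is, config = quant_config()) {
  stopifnot(inherits(config, "quant_config"))
  if (any(area_is <= 0)) stop("internal-standard peak area must be > 0")
  if (any(area_analyte < 0)) stop("analyte peak area must be >= 0")
  (area_analyte / area_is) * config$is_mass_ug /
    (config$sample_mass_g / 1000)
}
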