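#' @useDynLib echosens, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats lm coef vcov qt pt qnorm pnorm rnorm runif rexp rbinom
#'   rchisq rWishart sd var aggregate complete.cases setNames plogis qlogis
#' @importFrom utils read.csv write.csv
NULL

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(what, " must be finite and non-negative", call. = FALSE)
  }
  invisible(x)
}

#' Mean left-ventricular wall thickness
#'
#' Average of the interventricular septal and posterior wall thickness in
#' diastole.
#'
#' @param ivsd interventricular septal thickness in diastole (mm).
#' @param pwd posterior wall thickness in diastole (mm).
#' @return Mean LV wall thickness in mm.
#' @examples
#' mean_lv_wall_thickness(20, 16)  # 18
#' @export
mean_lv_wall_thickness <- function(ivsd, pwd) {
  check_nonneg(ivsd, "ivsd"); check_nonneg(pwd, "pwd")
  (ivsd + pwd) / 2
}

#' Relative wall thickness
#'
#' Twice the posterior wall thickness in diastole divided by the LV
#' end-diastolic diameter. Dimensionless; both inputs in mm (or both in cm).
#'
#' @param pwd posterior wall thickness in diastole.
#' @param lvedd LV end-diastolic diameter, same units as `pwd`; must be > 0.
#' @return Relative wall thickness (dimensionless).
#' @export
relative_wall_thickness <- function(pwd, lvedd) {
  check_nonneg(pwd, "pwd")
  if (any(!is.finite(lvedd)) || any(lvedd <= 0)) {
    stop("lvedd must be positive", call. = FALSE)
  }
  2 * pwd / lvedd
}

#' Left-ventricular mass by the Devereux formula
#'
#' ASE-recommended linear-dimension estimate:
#' `0.8 * 1.04 * ((IVSd + LVEDD + PWd)^3 - LVEDD^3) + 0.6`, inputs in cm,
#' output in grams.
#'
#' @param ivsd septal thickness in diastole (cm).
#' @param lvedd LV end-diastolic diameter (cm).
#' @param pwd posterior wall thickness in diastole (cm).
#' @return LV mass in grams.
#' @examples
#' lv_mass_devereux(1.8, 4.3, 1.8)
#' @export
lv_mass_devereux <- function(ivsd, lvedd, pwd) {
  check_nonneg(ivsd, "ivsd"); check_nonneg(pwd, "pwd")
  if (any(!is.finite(lvedd)) || any(lvedd <= 0)) {
    stop("lvedd must be positive", call. = FALSE)
  }
  if (any(ivsd > 10) || any(lvedd > 12) || any(pwd > 10)) {
    stop("Devereux inputs must be in cm (values look like mm)", call. = FALSE)
  }
  0.8 * 1.04 * ((ivsd + lvedd + pwd)^3 - lvedd^3) + 0.6
}

#' Index a mass or volume to body surface area
#'
#' @param x quantity to index (e.g. LV mass in g).
#' @param bsa body surface area in m^2; must be > 0.
#' @return `x / bsa`.
#' @export
index_to_bsa <- function(x, bsa) {
  if (any(!is.finite(bsa)) || any(bsa <= 0)) {
    stop("bsa must be positive", call. = FALSE)
  }
  x / bsa
}

#' Body surface area
#'
#' Du Bois (default): `0.007184 * height^0.725 * weight^0.425`;
#' Mosteller: `sqrt(height * weight / 3600)`.
#'
#' @param height_cm height in cm, > 0.
#' @param weight_kg weight in kg, > 0.
#' @param method `"dubois"` (default) or `"mosteller"`.
#' @return Body surface area in m^2.
#' @export
body_surface_area <- function(height_cm, weight_kg,
                              method = c("dubois", "mosteller")) {
  method <- match.arg(method)
  if (any(!is.finite(height_cm)) || any(height_cm <= 0) ||
      any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  switch(method,
    dubois    = 0.007184 * height_cm^0.725 * weight_kg^0.425,
    mosteller = sqrt(height_cm * weight_kg / 3600)
  )
}

#' Biplane Simpson (method of discs) left-ventricular volume
#'
#' The ventricle is sliced into 20 elliptical discs of thickness `L/20`
#' whose orthogonal diameters come from the apical four- and two-chamber
#' views: `V = (pi/4) * sum(a_i * b_i) * L / 20`.
#'
#' @param disc_diameters_a4c numeric vector of 20 disc diameters (cm),
#'   apical four-chamber view.
#' @param disc_diameters_a2c numeric vector of 20 disc diameters (cm),
#'   apical two-chamber view.
#' @param lv_length LV long-axis length (cm), > 0.
#' @return LV volume in ml.
#' @examples
#' # cylinder of diameter 4 cm, length 8 cm
#' biplane_simpson_volume(rep(4, 20), rep(4, 20), 8)
#' @export
biplane_simpson_volume <- function(disc_diameters_a4c, disc_diameters_a2c,
                                   lv_length) {
  if (length(disc_diameters_a4c) != 20L || length(disc_diameters_a2c) != 20L) {
    stop("disc diameter vectors must have length 20", call. = FALSE)
  }
  check_nonneg(disc_diameters_a4c, "disc_diameters_a4c")
  check_nonneg(disc_diameters_a2c, "disc_diameters_a2c")
  if (!is.finite(lv_length) || lv_length <= 0) {
    stop("lv_length must be positive", call. = FALSE)
  }
  (pi / 4) * sum(disc_diameters_a4c * disc_diameters_a2c) * lv_length / 20
}

#' Left-ventricular ejection fraction
#'
#' @param edv end-diastolic volume (ml), > 0 and >= `esv`.
#' @param esv end-systolic volume (ml), >= 0.
#' @return LVEF in percent.
#' @export
lvef <- function(edv, esv) {
  check_nonneg(esv, "esv")
  if (any(!is.finite(edv)) || any(edv <= 0)) {
    stop("edv must be positive", call. = FALSE)
  }
  if (any(esv > edv)) stop("esv must not exceed edv", call. = FALSE)
  100 * (edv - esv) / edv
}

#' Left-ventricular outflow-tract stroke volume
#'
#' `pi * (d/2)^2 * VTI` with the LVOT diameter `d` and velocity-time
#' integral in cm.
#'
#' @param lvot_diameter LVOT diameter (cm), >= 0.
#' @param lvot_vti LVOT velocity-time integral (cm), >= 0.
#' @return Stroke volume in ml.
#' @export
stroke_volume_lvot <- function(lvot_diameter, lvot_vti) {
  check_nonneg(lvot_diameter, "lvot_diameter")
  check_nonneg(lvot_vti, "lvot_vti")
  pi * (lvot_diameter / 2)^2 * lvot_vti
}

#' Transmitral and tissue-Doppler ratios
#'
#' Computes E/A, E/e' lateral, E/e' septal and E/e' average from mitral
#' inflow and annular tissue velocities (all in the same velocity units,
#' which cancel). The average E/e' divides E by the mean of the lateral and
#' septal e' velocities. A zero or missing denominator flags the affected
#' ratio as `NA` rather than aborting.
#'
#' @param e_wave peak early diastolic transmitral velocity.
#' @param a_wave peak late diastolic transmitral velocity.
#' @param e_prime_lateral,e_prime_septal early diastolic annular tissue
#'   velocities.
#' @return Named list with `e_a_ratio`, `e_over_e_prime_lateral`,
#'   `e_over_e_prime_septal`, `e_over_e_prime_average`.
#' @export
doppler_ratios <- function(e_wave, a_wave = NA_real_,
                           e_prime_lateral = NA_real_,
                           e_prime_septal = NA_real_) {
  safe_ratio <- function(num, den) {
    ifelse(is.na(den) | den <= 0 | is.na(num), NA_real_, num / den)
  }
  e_prime_avg <- ifelse(
    is.na(e_prime_lateral) | is.na(e_prime_septal),
    NA_real_, (e_prime_lateral + e_prime_septal) / 2
  )
  list(
    e_a_ratio              = safe_ratio(e_wave, a_wave),
    e_over_e_prime_lateral = safe_ratio(e_wave, e_prime_lateral),
    e_over_e_prime_septal  = safe_ratio(e_wave, e_prime_septal),
    e_over_e_prime_average = safe_ratio(e_wave, e_prime_avg)
  )
}

#' Change from baseline for a per-visit series
#'
#' @param values named numeric vector of parameter values with names among
#'   `baseline, m12, m18, m24, m30`; `NA` marks a missed assessment.
#' @return Data frame with `visit`, `value`, `change_from_baseline` and
#'   `observed` for the four post-baseline visits. A missing baseline is an
#'   error: such patients are excluded from the parameter's analysis set.
#' @examples
#' change_from_baseline(c(baseline = 55, m12 = 53, m18 = NA, m24 = 50, m30 = 49))
#' @export
change_from_baseline <- function(values) {
  visits <- c("baseline", "m12", "m18", "m24", "m30")
  if (is.null(names(values)) || !all(names(values) %in% visits)) {
    stop("values must be named with visits among: ",
         paste(visits, collapse = ", "), call. = FALSE)
  }
  base <- unname(values["baseline"])
  if (is.na(base)) {
    stop("baseline value missing: patient excluded from this parameter's ",
         "analysis set", call. = FALSE)
  }
  post <- visits[-1]
  v <- unname(values[post])
  names(v) <- NULL
  data.frame(
    visit = post,
    value = as.numeric(v),
    change_from_baseline = as.numeric(v) - base,
    observed = !is.na(v),
    stringsAsFactors = FALSE
  )
}

#' Derive the echocardiographic parameter panel from raw measurements
#'
#' Applies the derivation formulas to one visit's raw measurement record.
#' Linear dimensions are expected in mm, Simpson discs / LVOT quantities
#' in cm, velocities in mm/s (TR velocity in m/s). A record mixing units
#' (e.g. an LVEDD that is plausibly in cm) is rejected rather than
#' converted.
#'
#' @param record named list of raw measurements; recognised names include
#'   `ivsd`, `pwd`, `lvedd`, `lvesd` (mm), `lvot_diameter`, `lvot_vti`,
#'   `disc_diameters_a4c`, `disc_diameters_a2c`, `lv_length` (cm),
#'   `e_wave`, `a_wave`, `e_prime_lateral`, `e_prime_septal` (mm/s),
#'   `height`, `weight`, and optionally `gls` (signed percent).
#' @param bsa_method forwarded to [body_surface_area()].
#' @return Named list of derived parameter values (registry keys).
#' @export
derive_panel <- function(record, bsa_method = "dubois") {
  g <- function(nm) if (!is.null(record[[nm]])) record[[nm]] else NA_real_
  ivsd <- g("ivsd"); pwd <- g("pwd"); lvedd <- g("lvedd")
  # unit sanity: adult LV linear dimensions in mm are > 3; cm values are not
  lin <- c(ivsd, pwd, lvedd)
  lin <- lin[!is.na(lin)]
  if (length(lin) && any(lin < 3)) {
    stop("linear dimensions must be in mm; record looks like cm ",
         "(mixed units are rejected, not converted)", call. = FALSE)
  }
  out <- list()
  if (!is.na(ivsd) && !is.na(pwd)) {
    out$mean_lv_wall_thickness <- mean_lv_wall_thickness(ivsd, pwd)
  }
  if (!is.na(pwd) && !is.na(lvedd)) {
    out$relative_wall_thickness <- relative_wall_thickness(pwd, lvedd)
  }
  if (!is.na(ivsd) && !is.na(pwd) && !is.na(lvedd)) {
    mass <- lv_mass_devereux(ivsd / 10, lvedd / 10, pwd / 10)
    h <- g("height"); w <- g("weight")
    if (!is.na(h) && !is.na(w)) {
      out$lv_mass_index <- index_to_bsa(mass, body_surface_area(h, w, bsa_method))
    }
  }
  a4c <- record[["disc_diameters_a4c_ed"]]; a2c <- record[["disc_diameters_a2c_ed"]]
  a4s <- record[["disc_diameters_a4c_es"]]; a2s <- record[["disc_diameters_a2c_es"]]
  led <- g("lv_length_ed"); les <- g("lv_length_es")
  if (!is.null(a4c) && !is.null(a2c) && !is.na(led)) {
    out$lvedv <- biplane_simpson_volume(a4c, a2c, led)
    if (!is.null(a4s) && !is.null(a2s) && !is.na(les)) {
      out$lvesv <- biplane_simpson_volume(a4s, a2s, les)
      out$lvef <- lvef(out$lvedv, out$lvesv)
    }
  }
  d <- g("lvot_diameter"); vti <- g("lvot_vti")
  if (!is.na(d) && !is.na(vti)) {
    if (d > 5) {
      stop("lvot_diameter must be in cm; record looks like mm ",
           "(mixed units are rejected, not converted)", call. = FALSE)
    }
    out$stroke_volume <- stroke_volume_lvot(d, vti)
  }
  ratios <- doppler_ratios(g("e_wave"), g("a_wave"),
                           g("e_prime_lateral"), g("e_prime_septal"))
  out <- c(out, ratios[!vapply(ratios, is.na, logical(1))])
  if (!is.na(g("gls"))) out$absolute_gls <- abs(g("gls"))
  out
}
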