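#' Echocardiographic parameter registry
#'
#' Every derived parameter handled by the package is keyed through this
#' registry, which records its reporting units and its "worse direction" --
#' whether a decrease or an increase from baseline represents clinical
#' deterioration in ATTR-CM. The worse direction drives the worst-decile
#' imputation rule used for patients who died before month 30: the donor
#' pool is taken from the extreme tail of observed changes on the side the
#' registry declares worse.
#'
#' The direction assignments follow standard ATTR-CM interpretation:
#' systolic/diastolic function indices (LVEF, absolute GLS, stroke volume,
#' tissue velocities, A wave, deceleration time) worsen by decreasing, while
#' hypertrophy/congestion indices (wall thickness, LV mass index, E/e',
#' E/A, atrial size, end-systolic volume, RV areas, IVC diameter, TR
#' velocity) worsen by increasing. GLS is stored as an absolute magnitude,
#' so a decrease is worse.
#'
#' @param overrides optional named character vector mapping parameter keys
#'   to `"decrease_is_worse"` or `"increase_is_worse"`, replacing the
#'   defaults for those keys.
#' @return A data frame with columns `key`, `label`, `units` and
#'   `worse_direction`.
#' @examples
#' reg <- echo_registry()
#' reg[reg$key == "lvef", ]
#' @export
echo_registry <- function(overrides = NULL) {
  reg <- data.frame(
    key = c(
      "mean_lv_wall_thickness", "lvedd", "lvedv", "lvesd", "lvesv",
      "lv_mass_index", "relative_wall_thickness",
      "lvef", "absolute_gls", "stroke_volume",
      "s_prime_lateral", "s_prime_septal",
      "e_a_ratio", "e_wave", "a_wave", "deceleration_time",
      "e_prime_lateral", "e_prime_septal",
      "e_over_e_prime_lateral", "e_over_e_prime_septal",
      "e_over_e_prime_average",
      "la_diameter", "la_volume_index", "a_prime_lateral", "a_prime_septal",
      "rv_wall_thickness", "rv_ed_area", "rv_es_area", "rv_s_prime",
      "tr_velocity", "ivc_diameter"
    ),
    label = c(
      "Mean LV wall thickness", "LVEDD", "LVEDV", "LVESD", "LVESV",
      "LV mass index", "Relative wall thickness",
      "LVEF", "Absolute GLS", "Stroke volume",
      "TDI lateral s'", "TDI septal s'",
      "E/A ratio", "E wave", "A wave", "Deceleration time",
      "TDI lateral e'", "TDI septal e'",
      "E/e' lateral", "E/e' septal", "E/e' average",
      "LA diameter", "LA volume index", "TDI lateral a'", "TDI septal a'",
      "RV free wall thickness", "RV end-diastolic area",
      "RV end-systolic area", "RV S'", "TR velocity", "Maximal IVC diameter"
    ),
    units = c(
      "mm", "mm", "ml", "mm", "ml", "g/m^2", "",
      "%", "%", "ml", "mm/s", "mm/s",
      "", "mm/s", "mm/s", "ms", "mm/s", "mm/s", "", "", "",
      "mm", "ml/m^2", "mm/s", "mm/s",
      "mm", "cm^2", "cm^2", "mm/s", "m/s", "mm"
    ),
    worse_direction = c(
      "increase_is_worse",  # wall thickness
      "increase_is_worse",  # lvedd
      "increase_is_worse",  # lvedv
      "increase_is_worse",  # lvesd
      "increase_is_worse",  # lvesv
      "increase_is_worse",  # lv mass index
      "increase_is_worse",  # rwt
      "decrease_is_worse",  # lvef
      "decrease_is_worse",  # absolute gls
      "decrease_is_worse",  # stroke volume
      "decrease_is_worse",  # s' lat
      "decrease_is_worse",  # s' sep
      "increase_is_worse",  # e/a
      "increase_is_worse",  # e wave
      "decrease_is_worse",  # a wave
      "decrease_is_worse",  # deceleration time
      "decrease_is_worse",  # e' lat
      "decrease_is_worse",  # e' sep
      "increase_is_worse",  # e/e' lat
      "increase_is_worse",  # e/e' sep
      "increase_is_worse",  # e/e' avg
      "increase_is_worse",  # la diameter
      "increase_is_worse",  # la volume index
      "decrease_is_worse",  # a' lat
      "decrease_is_worse",  # a' sep
      "increase_is_worse",  # rv wall
      "increase_is_worse",  # rv ed area
      "increase_is_worse",  # rv es area
      "decrease_is_worse",  # rv s'
      "increase_is_worse",  # tr velocity
      "increase_is_worse"   # ivc
    ),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), reg$key)
    if (length(bad)) {
      stop("unknown registry keys in overrides: ", paste(bad, collapse = ", "))
    }
    ok <- overrides %in% c("decrease_is_worse", "increase_is_worse")
    if (!all(ok)) stop("invalid worse_direction value in overrides")
    reg$worse_direction[match(names(overrides), reg$key)] <- unname(overrides)
  }
  reg
}

#' Worse direction of a registered parameter
#'
#' @param key parameter registry key.
#' @param registry registry data frame, defaults to [echo_registry()].
#' @return `"decrease_is_worse"` or `"increase_is_worse"`.
#' @export
worse_direction <- function(key, registry = echo_registry()) {
  i <- match(key, registry$key)
  if (any(is.na(i))) {
    stop("parameter not in registry: ", paste(key[is.na(i)], collapse = ", "))
  }
  registry$worse_direction[i]
}
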