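#' Equivalent-circle vessel diameter
#'
#' Converts a vessel lumen area to the diameter of the circle with the
#' same area: `D = sqrt(4 * A / pi)`.
#'
#' @param area lumen area(s) in um^2, strictly positive. Vectorised.
#' @return diameter(s) in um.
#' @examples
#' vessel_diameter(78.5398)  # ~10 um (circle of radius 5)
#' @export
vessel_diameter <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("`area` must be finite and strictly positive", call. = FALSE)
  }
  sqrt(4 * area / pi)
}

#' Hydraulically weighted vessel diameter
#'
#' The quartic mean `D_H = (sum(D^4) / N)^(1/4)`. Because conductance
#' scales with the fourth power of diameter (Hagen-Poiseuille), this
#' weighting reflects each vessel's hydraulic contribution; it is
#' always >= the arithmetic mean diameter, with equality only when all
#' vessels are equal.
#'
#' @param diameters vessel diameters in um, non-empty, all positive.
#' @return D_H in um.
#' @examples
#' hydraulic_diameter(c(10, 20))  # 17.075 um
#' @export
hydraulic_diameter <- function(diameters) {
  if (length(diameters) == 0L) {
    stop("`diameters` must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("`diameters` must be finite and positive", call. = FALSE)
  }
  (sum(diameters^4) / length(diameters))^(1 / 4)
}

# Table of minimum measurement counts recommended per trait.
.anatomy_min_counts <- c(
  vessel_lumen_areas = 50L,
  vessel_wall_thicknesses = 30L,
  double_intervessel_wall_thicknesses = 30L,
  fibre_areas = 30L,
  pit_membrane_thicknesses = 25L,
  pit_chamber_depths = 25L,
  vessel_group_sizes = 50L,
  xylem_count_areas = 5L
)

#' Raw per-stem anatomical measurements
#'
#' Container for the microscopy measurements taken on one stem
#' cross-section, from which all derived traits are computed by
#' [derive_traits()]. Lengths below the recommended measurement counts
#' trigger a warning, not an error.
#'
#' @param stem_id,accession labels.
#' @param vessel_lumen_areas vessel lumen areas, um^2 (>= 50 recommended).
#' @param vessel_wall_thicknesses single vessel wall thicknesses, um (>= 30).
#' @param double_intervessel_wall_thicknesses double intervessel wall
#'   thicknesses T_VW, um (>= 30).
#' @param fibre_areas data.frame with columns `A_F` (fibre cell area)
#'   and `A_FL` (fibre lumen area), um^2, `A_FL < A_F` per fibre (>= 30).
#' @param pit_membrane_thicknesses intervessel pit membrane
#'   thicknesses T_PM, um (>= 25).
#' @param pit_chamber_depths pit chamber depths D_PC, um (>= 25).
#' @param vessel_group_sizes integer sizes of vessel groupings
#'   (solitary vessel = 1) (>= 50 groups).
#' @param xylem_count_areas data.frame with columns `n_vessels` and
#'   `area_mm2` from vessel-density counting frames (>= 5).
#' @param A_S total stem cross-section area, mm^2.
#' @param A_LIG lignified area, mm^2, `<= A_S`.
#' @param A_PITH pith area, mm^2.
#' @return object of class `anatomy_raw`.
#' @export
anatomy_raw <- function(stem_id, accession,
                        vessel_lumen_areas,
                        vessel_wall_thicknesses,
                        double_intervessel_wall_thicknesses,
                        fibre_areas,
                        pit_membrane_thicknesses,
                        pit_chamber_depths,
                        vessel_group_sizes,
                        xylem_count_areas,
                        A_S, A_LIG, A_PITH) {
  problems <- character(0)
  chk_pos <- function(x, nm) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      problems <<- c(problems, sprintf("%s must be finite and > 0", nm))
    }
  }
  chk_pos(vessel_lumen_areas, "vessel_lumen_areas")
  chk_pos(vessel_wall_thicknesses, "vessel_wall_thicknesses")
  chk_pos(double_intervessel_wall_thicknesses, "double_intervessel_wall_thicknesses")
  chk_pos(pit_membrane_thicknesses, "pit_membrane_thicknesses")
  chk_pos(pit_chamber_depths, "pit_chamber_depths")
  fibre_areas <- as.data.frame(fibre_areas)
  if (!all(c("A_F", "A_FL") %in% names(fibre_areas))) {
    problems <- c(problems, "fibre_areas needs columns A_F and A_FL")
  } else {
    chk_pos(fibre_areas$A_F, "fibre A_F")
    chk_pos(fibre_areas$A_FL, "fibre A_FL")
    if (any(fibre_areas$A_FL >= fibre_areas$A_F)) {
      problems <- c(problems, "every fibre must satisfy A_FL < A_F")
    }
  }
  if (any(vessel_group_sizes < 1) || any(vessel_group_sizes != round(vessel_group_sizes))) {
    problems <- c(problems, "vessel_group_sizes must be integers >= 1")
  }
  xylem_count_areas <- as.data.frame(xylem_count_areas)
  if (!all(c("n_vessels", "area_mm2") %in% names(xylem_count_areas))) {
    problems <- c(problems, "xylem_count_areas needs columns n_vessels and area_mm2")
  } else {
    chk_pos(xylem_count_areas$area_mm2, "count-frame area_mm2")
    if (any(xylem_count_areas$n_vessels < 0)) {
      problems <- c(problems, "n_vessels must be >= 0")
    }
  }
  chk_pos(A_S, "A_S"); chk_pos(A_LIG, "A_LIG"); chk_pos(A_PITH, "A_PITH")
  if (is.finite(A_LIG) && is.finite(A_S) && A_LIG > A_S) {
    problems <- c(problems, "A_LIG must not exceed A_S")
  }
  if (length(problems)) {
    stop("invalid anatomy_raw for stem '", stem_id, "':\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  counts <- c(
    vessel_lumen_areas = length(vessel_lumen_areas),
    vessel_wall_thicknesses = length(vessel_wall_thicknesses),
    double_intervessel_wall_thicknesses = length(double_intervessel_wall_thicknesses),
    fibre_areas = nrow(fibre_areas),
    pit_membrane_thicknesses = length(pit_membrane_thicknesses),
    pit_chamber_depths = length(pit_chamber_depths),
    vessel_group_sizes = length(vessel_group_sizes),
    xylem_count_areas = nrow(xylem_count_areas)
  )
  low <- counts < .anatomy_min_counts[names(counts)]
  if (any(low)) {
    warning("stem '", stem_id, "': measurement counts below recommendation for: ",
            paste(names(counts)[low], collapse = ", "), call. = FALSE)
  }

  structure(
    list(stem_id = as.character(stem_id), accession = as.character(accession),
         vessel_lumen_areas = as.numeric(vessel_lumen_areas),
         vessel_wall_thicknesses = as.numeric(vessel_wall_thicknesses),
         double_intervessel_wall_thicknesses =
           as.numeric(double_intervessel_wall_thicknesses),
         fibre_areas = fibre_areas,
         pit_membrane_thicknesses = as.numeric(pit_membrane_thicknesses),
         pit_chamber_depths = as.numeric(pit_chamber_depths),
         vessel_group_sizes = as.integer(vessel_group_sizes),
         xylem_count_areas = xylem_count_areas,
         A_S = A_S, A_LIG = A_LIG, A_PITH = A_PITH,
         measurement_counts = counts),
    class = "anatomy_raw"
  )
}

#' Derive the anatomical trait set from raw measurements
#'
#' Computes, for one stem, the standard trait table:
#' \describe{
#'   \item{D}{mean equivalent-circle vessel diameter, um}
#'   \item{D_H}{hydraulically weighted (quartic-mean) diameter, um}
#'   \item{D_MAX}{diameter of the single largest vessel, um}
#'   \item{T_V}{mean vessel wall thickness, um}
#'   \item{TS_ratio}{mean double intervessel wall thickness / D_MAX}
#'   \item{implosion}{theoretical vessel implosion resistance, TS_ratio^2}
#'   \item{V_D}{vessel density, vessels mm^-2 (mean over counting frames)}
#'   \item{V_G}{vessel grouping index, total vessels / number of groups}
#'   \item{P_LIG}{lignified area fraction, A_LIG / A_S}
#'   \item{P_FW_F_A}{mean per-fibre wall fraction, (A_F - A_FL) / A_F}
#'   \item{T_PM}{mean intervessel pit membrane thickness, um}
#'   \item{D_PC}{mean pit chamber depth, um}
#'   \item{A_PITH}{pith area, mm^2}
#' }
#'
#' @param raw an [anatomy_raw()] object.
#' @param centre aggregation of measurement lists: `"mean"` (default)
#'   or `"median"`.
#' @return one-row data.frame (a trait record).
#' @export
derive_traits <- function(raw, centre = c("mean", "median")) {
  stopifnot(inherits(raw, "anatomy_raw"))
  centre <- match.arg(centre)
  agg <- if (centre == "mean") mean else stats::median

  D_all <- vessel_diameter(raw$vessel_lumen_areas)
  D <- agg(D_all)
  D_H <- hydraulic_diameter(D_all)
  D_MAX <- max(D_all)
  T_V <- agg(raw$vessel_wall_thicknesses)
  TS_ratio <- agg(raw$double_intervessel_wall_thicknesses) / D_MAX
  A_FW <- raw$fibre_areas$A_F - raw$fibre_areas$A_FL
  P_FW_F_A <- agg(A_FW / raw$fibre_areas$A_F)
  V_D <- agg(raw$xylem_count_areas$n_vessels / raw$xylem_count_areas$area_mm2)
  V_G <- sum(raw$vessel_group_sizes) / length(raw$vessel_group_sizes)

  data.frame(
    stem_id = raw$stem_id, accession = raw$accession,
    D = D, D_H = D_H, D_MAX = D_MAX, T_V = T_V,
    TS_ratio = TS_ratio, implosion = TS_ratio^2,
    V_D = V_D, V_G = V_G,
    P_LIG = raw$A_LIG / raw$A_S,
    P_FW_F_A = P_FW_F_A,
    T_PM = agg(raw$pit_membrane_thicknesses),
    D_PC = agg(raw$pit_chamber_depths),
    A_PITH = raw$A_PITH,
    stringsAsFactors = FALSE
  )
}

#' Per-accession trait summary
#'
#' @param records data.frame of per-stem trait records (rows from
#'   [derive_traits()], possibly with response columns appended).
#' @return data.frame with one row per accession x trait: `accession`,
#'   `trait`, `mean`, `sd`, `n`. `sd` is `0` when `n = 1` and the row
#'   is flagged in `single_stem`.
#' @export
aggregate_by_accession <- function(records) {
  records <- as.data.frame(records)
  stopifnot("accession" %in% names(records))
  num <- names(records)[vapply(records, is.numeric, logical(1))]
  out <- do.call(rbind, lapply(split(records, records$accession), function(d) {
    do.call(rbind, lapply(num, function(tr) {
      x <- d[[tr]]
      n <- sum(is.finite(x))
      data.frame(accession = d$accession[1], trait = tr,
                 mean = mean(x, na.rm = TRUE),
                 sd = if (n > 1) stats::sd(x, na.rm = TRUE) else 0,
                 n = n, single_stem = n == 1L,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
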