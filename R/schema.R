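#' @keywords internal
"_PACKAGE"

## Variable schema of the cohort table.
##
## 9 numeric attributes (urinary protein is stored as a dipstick grade and
## converted to mg/dl when features are built), 13 three-level lab labels,
## one delivery type, 15 binary maternal manifestations and 3 perinatal
## outcome fields.

lab_variables <- function() {
  c("dsDNA", "ANA", "APL", "CRP", "ESR", "SSA", "SSB",
    "C3", "C4", "HB", "PLT", "RBC", "WBC")
}

lab_levels <- function() c("L", "N", "H")

delivery_levels <- function() c("CS", "FD", "ND")

## fixed label order used for deterministic mode tie-breaking
label_order <- function() c("L", "N", "H", "CS", "FD", "ND")

manifestation_variables <- function() paste0("y", 1:15)

#' Human-readable names of the 15 maternal manifestations
#'
#' The binary base attributes recorded per patient: y1 gestational
#' hypertension, y2 oligohydramnios, y3 preeclampsia/eclampsia, y4 lupus
#' nephritis, y5 thrombocytopenia, y6 antiphospholipid syndrome, y7 uterus
#' scar, y8 prelabor rupture of membrane (PROM), y9 placenta abruption,
#' y10 encephalopathy, y11 anemia, y12 pneumonia, y13 femoral head necrosis,
#' y14 hypothyroidism, y15 no manifestations.
#'
#' @return Named character vector, names `y1..y15`.
#' @export
manifestation_names <- function() {
  stats::setNames(
    c("gestational hypertension", "oligohydramnios", "preeclampsia",
      "lupus nephritis", "thrombocytopenia", "antiphospholipid syndrome",
      "uterus scar", "prelabor rupture of membrane", "placenta abruption",
      "encephalopathy", "anemia", "pneumonia", "femoral head necrosis",
      "hypothyroidism", "no manifestations"),
    manifestation_variables()
  )
}

numeric_variables <- function() {
  c("disease_duration_y", "maternal_age_y", "gestational_age_d",
    "newborn_weight_g", "gravid", "para", "abortion", "live")
}

## the canonical column order of the on-disk CSV
cohort_columns <- function() {
  c("patient_id", "disease_duration_y", "maternal_age_y",
    "urinary_protein_grade", "gestational_age_d", "newborn_weight_g",
    "gravid", "para", "abortion", "live",
    lab_variables(), "delivery_type",
    manifestation_variables(),
    "live_birth", "term", "apgar_1min")
}

dipstick_grades <- function() c("negative", "trace", "1+", "2+", "3+", "4+")

#' Convert a urinary-protein dipstick grade to mg/dl
#'
#' Maps the six dipstick grades to protein concentrations: negative 0,
#' trace 5 (midpoint of the sub-10 mg/dl band), 1+ 30, 2+ 100, 3+ 300,
#' 4+ 1000 mg/dl. The trace value can be overridden.
#'
#' @param grade Character vector of grades in
#'   `c("negative","trace","1+","2+","3+","4+")`.
#' @param trace_value Concentration assigned to "trace" (default 5 mg/dl).
#' @return Numeric vector of concentrations in mg/dl.
#' @examples
#' grade_to_mg_dl(c("negative", "1+", "3+"))
#' @export
grade_to_mg_dl <- function(grade, trace_value = 5) {
  map <- c(negative = 0, trace = trace_value,
           "1+" = 30, "2+" = 100, "3+" = 300, "4+" = 1000)
  bad <- !is.na(grade) & !(grade %in% names(map))
  if (any(bad)) {
    stop("unknown dipstick grade(s): ",
         paste(unique(grade[bad]), collapse = ", "), call. = FALSE)
  }
  out <- unname(map[grade])
  out[is.na(grade)] <- NA_real_
  out
}
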