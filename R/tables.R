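# Published reference tables from the 22-expert military hospital-bed study:
# the factor-level priority table and the eight per-factor subfactor blocks,
# scores at three decimals and dense priorities exactly as printed. Code C31
# is absent from the published subfactor list; the gap is preserved.

.factor_table <- function() {
  tibble::tibble(
    code = paste0("F", 1:8),
    label = c(
      "Geographic situation",
      "Demographic status",
      "Economic status",
      "Health status",
      "Health care centers and organizations",
      "Financial and human resources",
      "Laws and regulations and bylaws",
      "The military nature of service recipients"
    ),
    score = c(0.109, 0.087, 0.040, 0.080, 0.154, 0.096, 0.184, 0.249),
    priority = c(4L, 6L, 8L, 7L, 3L, 5L, 2L, 1L)
  )
}

.subfactor_table <- function() {
  tibble::tribble(
    ~factor_code, ~code, ~label, ~score, ~priority,
    "F1", "C1", "Province distance from the major and big cities", 0.055, 5L,
    "F1", "C2", "Position and situation of the health care center and organization", 0.260, 2L,
    "F1", "C3", "Boundary conditions of the province", 0.123, 4L,
    "F1", "C4", "Distance from the nearest equipped military health care center and organization", 0.200, 3L,
    "F1", "C5", "Population density in the urban and rural areas", 0.361, 1L,
    "F2", "C6", "Need for full implementation of the Adaptation Plan", 0.160, 3L,
    "F2", "C7", "Being a host province", 0.119, 4L,
    "F2", "C8", "Sex and age distribution of the urban and rural population", 0.088, 5L,
    "F2", "C9", "Annual population growth rate", 0.088, 5L,
    "F2", "C10", "Rates of births and deaths", 0.054, 6L,
    "F2", "C11", "Rates of illiteracy and literacy", 0.035, 7L,
    "F2", "C12", "Cultural values, social and political characteristics", 0.201, 2L,
    "F2", "C13", "Population of the considered province or city/pato-geographic status", 0.255, 1L,
    "F3", "C14", "High cost of civilian health care services", 0.075, 6L,
    "F3", "C15", "Economic evaluation of providing services", 0.319, 1L,
    "F3", "C16", "Sources of income", 0.176, 2L,
    "F3", "C17", "Per capita income per year", 0.102, 4L,
    "F3", "C18", "Employment rate", 0.045, 8L,
    "F3", "C19", "Rate of inflation", 0.060, 7L,
    "F3", "C20", "Interest rate for investment in the health insurance", 0.137, 3L,
    "F3", "C21", "Being an industrial province", 0.085, 5L,
    "F4", "C22", "Common diseases in the military forces", 0.136, 3L,
    "F4", "C23", "Understanding the epidemiology of diseases and the number of patients in the society", 0.049, 7L,
    "F4", "C24", "Vulnerable groups", 0.099, 5L,
    "F4", "C25", "Vulnerability to common diseases in the region", 0.075, 6L,
    "F4", "C26", "Life expectancy", 0.134, 4L,
    "F4", "C27", "Health Promotion", 0.186, 2L,
    "F4", "C28", "Equity in health care", 0.322, 1L,
    "F5", "C29", "Existence of empty capacities in the province", 0.050, 7L,
    "F5", "C30", "Training and research services", 0.131, 4L,
    "F5", "C32", "Lack of appropriate health care centers and organizations and the ease of service delivery to the armed forces", 0.325, 1L,
    "F5", "C33", "Bed occupancy rate", 0.165, 2L,
    "F5", "C34", "Admission rate per bed in each year", 0.102, 5L,
    "F5", "C35", "Average length of stay", 0.092, 6L,
    "F5", "C36", "Existence of physical spaces", 0.135, 3L,
    "F6", "C37", "Status of the existing health technologies", 0.047, 6L,
    "F6", "C38", "Resources available to build the new hospital wards", 0.197, 3L,
    "F6", "C39", "Having the potential for developing the existing hospital beds", 0.242, 2L,
    "F6", "C40", "Existence of modern and updated equipment", 0.071, 5L,
    "F6", "C41", "Having extensive specialty and subspecialty facilities and equipment", 0.091, 4L,
    "F6", "C42", "Having access to medical and paramedical personnel", 0.353, 1L,
    "F7", "C43", "Health policies at the national level", 0.115, 3L,
    "F7", "C44", "Empathy among the commanders of military units stationed in the province", 0.444, 1L,
    "F7", "C45", "Having appropriate intersectoral cooperation in the province", 0.069, 5L,
    "F7", "C46", "Cooperation among province authorities in setting up a specialty hospital", 0.048, 6L,
    "F7", "C47", "Hospital beds per capita approved by the General Staff of the Armed Forces", 0.085, 4L,
    "F7", "C48", "Hospital beds per capita approved by the Ministry of Health", 0.198, 2L,
    "F8", "C49", "Maintaining dignity and increasing job satisfaction", 0.087, 4L,
    "F8", "C50", "Maintaining the dignity of military personnel", 0.081, 5L,
    "F8", "C51", "Necessity for paying attention to the military families' well-being", 0.057, 6L,
    "F8", "C52", "Necessity for direct treatment of the military forces, especially in the crises", 0.258, 2L,
    "F8", "C53", "Necessity for maintaining the security of the armed forces", 0.293, 1L,
    "F8", "C54", "Necessity for conducting special clinical studies on the military forces", 0.041, 7L,
    "F8", "C55", "Number of military forces in the province", 0.183, 3L
  )
}

#' Reference tables of the hospital-bed prioritization study
#'
#' Returns the published reference data of the case study this package
#' reproduces: a 22-expert fuzzy-AHP prioritization of the factors affecting
#' the development of military hospital beds. Because the underlying raw
#' questionnaires were never published, these tables — the linguistic scale,
#' the eight factor scores and the 54 subfactor scores with their dense
#' priorities, all at the printed precision — are the recomputable ground
#' truth available for testing.
#'
#' @return A list with elements:
#'   * `scale`: the nine-level linguistic scale, as [fuzzy_scale()];
#'   * `factors`: tibble `code`, `label`, `score`, `priority` (8 rows);
#'   * `subfactors`: tibble `factor_code`, `code`, `label`, `score`,
#'     `priority` (54 rows; code C31 is absent from the published list and
#'     the gap is preserved).
#' @examples
#' hospital_bed_tables()$factors
#' @export
hospital_bed_tables <- function() {
  list(scale = fuzzy_scale(),
       factors = .factor_table(),
       subfactors = .subfactor_table())
}

#' The goal/factor/subfactor hierarchy of the hospital-bed study
#'
#' The two-level criterion hierarchy of the case study: one goal, eight
#' factors (F1--F8) and 54 subfactors (C1--C55 with C31 absent), as a long
#' node table suitable for [assemble_hierarchy()].
#'
#' @param goal_code,goal_label Code and label for the root node.
#' @return A tibble with columns `code`, `label`, `parent` (root has
#'   `parent = NA`).
#' @examples
#' h <- hospital_bed_hierarchy()
#' assemble_hierarchy(h)
#' @export
hospital_bed_hierarchy <- function(goal_code = "GOAL",
                                   goal_label = "Development of military hospital beds") {
  fa <- .factor_table()
  sf <- .subfactor_table()
  dplyr::bind_rows(
    tibble::tibble(code = goal_code, label = goal_label, parent = NA_character_),
    tibble::tibble(code = fa$code, label = fa$label, parent = goal_code),
    tibble::tibble(code = sf$code, label = sf$label, parent = sf$factor_code)
  )
}
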