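# Packaged code lists: Quan's ICD-9-CM Charlson mapping and the comorbidity
# prefix lists used as propensity-model covariates. Both ship as editable CSVs.

#' Quan ICD-9-CM Charlson comorbidity mapping
#'
#' One row per (category, ICD-9 prefix) with the Charlson weight of the
#' category. Prefixes are dot-stripped; matching is dot-insensitive.
#'
#' @param path Optional CSV path overriding the packaged table.
#' @return A tibble with columns `category`, `icd9_prefix`, `weight`.
#' @export
quan_cci_map <- function(path = NULL) {
  if (is.null(path)) path <- system.file("extdata", "quan_cci.csv", package = "claimsce")
  map <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  needed <- c("category", "icd9_prefix", "weight")
  if (!all(needed %in% names(map)) || !is.numeric(map$weight)) {
    rlang::abort("malformed Quan code-list file", class = "claimsce_config_error")
  }
  map$icd9_prefix <- as.character(map$icd9_prefix)
  map
}

#' Comorbidity flag code lists
#'
#' ICD-9-CM prefix lists defining the binary comorbidity covariates
#' (cardiovascular disease, diabetes, obesity, drug abuse, hepatitis C,
#' HIV/AIDS).
#'
#' @param path Optional CSV path overriding the packaged table.
#' @return A tibble with columns `name`, `icd9_prefix`.
#' @export
comorbidity_map <- function(path = NULL) {
  if (is.null(path)) path <- system.file("extdata", "comorbidities.csv", package = "claimsce")
  map <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("name", "icd9_prefix") %in% names(map))) {
    rlang::abort("malformed comorbidity code-list file", class = "claimsce_config_error")
  }
  map$icd9_prefix <- as.character(map$icd9_prefix)
  map
}

#' Medical-care consumer price index table
#'
#' Annual index values of the medical-care CPI component used to standardize
#' paid amounts to a reference year.
#'
#' @param path Optional CSV path (columns `year`, `index`) overriding the
#'   packaged table.
#' @return A named numeric vector, names = years.
#' @export
cpi_medical <- function(path = NULL) {
  if (is.null(path)) path <- system.file("extdata", "cpi_medical.csv", package = "claimsce")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$index, tab$year)
}

#' Charlson comorbidity index from ICD-9 codes (Quan mapping)
#'
#' Sums Charlson weights over distinct comorbidity categories present among
#' the supplied codes. Hierarchy rules: complicated diabetes supersedes
#' uncomplicated diabetes, metastatic solid tumor supersedes other malignancy,
#' and moderate/severe liver disease supersedes mild liver disease.
#'
#' @param codes Character vector of ICD-9-CM codes (dots optional).
#' @param map The mapping table from [quan_cci_map()].
#' @return A single non-negative integer score.
#' @export
compute_quan_cci <- function(codes, map = quan_cci_map()) {
  if (length(codes) == 0) return(0L)
  cats <- unique(map$category[vapply(seq_len(nrow(map)), function(i) {
    any(match_any_prefix(codes, map$icd9_prefix[i]))
  }, logical(1))])
  if ("diabetes_complicated" %in% cats) cats <- setdiff(cats, "diabetes")
  if ("metastatic_solid_tumor" %in% cats) cats <- setdiff(cats, "malignancy")
  if ("liver_severe" %in% cats) cats <- setdiff(cats, "liver_mild")
  weights <- map$weight[match(cats, map$category)]
  as.integer(sum(weights))
}

#' Comorbidity flags from ICD-9 codes
#'
#' @param codes Character vector of ICD-9-CM codes.
#' @param map The mapping table from [comorbidity_map()].
#' @return Named logical vector, one element per comorbidity name in `map`.
#' @export
comorbidity_flags <- function(codes, map = comorbidity_map()) {
  nm <- unique(map$name)
  vapply(nm, function(x) {
    any(match_any_prefix(codes, map$icd9_prefix[map$name == x]))
  }, logical(1))
}
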