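#' Drug catalogs: product codes to OAT classes
#'
#' A catalog maps jurisdiction-specific product identifiers (DIN/PIN) to
#' the four OAT classes used throughout the package: `methadone`,
#' `bup_nal` (buprenorphine/naloxone), `srom` (slow-release oral morphine)
#' and `ioat` (injectable OAT). Codes must be disjoint across classes;
#' catalogs are configuration, not code, so jurisdictions supply their own
#' CSV (`din,drug_class,form`).
#'
#' @name drug_catalog
NULL

#' The four OAT drug classes
#' @return Character vector of class labels.
#' @export
oat_drug_classes <- function() c("methadone", "bup_nal", "srom", "ioat")

#' A synthetic example catalog
#'
#' Entirely synthetic product codes (the real DIN/PIN lists are
#' jurisdiction-specific and access-restricted); useful for examples,
#' tests and the synthetic cohort generator.
#'
#' @return Tibble with columns `din`, `drug_class`, `form`.
#' @export
default_drug_catalog <- function() {
  tibble(
    din = c(
      "90000001", "90000002", "90000003",
      "90000011", "90000012",
      "90000021",
      "90000031", "90000032"
    ),
    drug_class = c(
      "methadone", "methadone", "methadone",
      "bup_nal", "bup_nal",
      "srom",
      "ioat", "ioat"
    ),
    form = c(
      "liquid", "unflavoured", "compound",
      "tablet", "injection",
      "capsule-24h",
      "injectable-dam", "injectable-hdm"
    )
  )
}

#' Read a drug catalog CSV
#'
#' @param path CSV with header `din,drug_class,form`.
#' @return Validated catalog tibble.
#' @export
read_drug_catalog <- function(path) {
  cat_tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_catalog(cat_tbl)
}

validate_catalog <- function(cat_tbl) {
  need <- c("din", "drug_class")
  missing <- setdiff(need, names(cat_tbl))
  if (length(missing)) {
    abort(paste("catalog is missing column(s):", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(cat_tbl$din)) {
    dup <- unique(cat_tbl$din[duplicated(cat_tbl$din)])
    abort(paste(
      "catalog codes must be disjoint across drug classes; duplicated din:",
      paste(dup, collapse = ", ")
    ))
  }
  as_tibble(cat_tbl)
}
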