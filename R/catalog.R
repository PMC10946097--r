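#' Antiretroviral drug catalog
#'
#' The classifier needs to know, for every drug code appearing in the
#' regimen-episode table, its drug class and whether it is a pharmacokinetic
#' booster. Boosters (ritonavir used as a booster, cobicistat) are excluded
#' from all drug counts. The packaged default catalog covers the commonly
#' registered antiretrovirals; site-specific codes can be added by editing a
#' copy of the CSV and loading it with [load_drug_catalog()].
#'
#' @return A `data.table` with columns `drug_code`, `name`, `drug_class`
#'   (one of NRTI, NNRTI, PI, INSTI, ENTRY, CAPSID, OTHER) and `is_booster`.
#' @examples
#' cat <- default_drug_catalog()
#' cat[cat$is_booster, ]
#' @export
default_drug_catalog <- function() {
  path <- system.file("extdata", "drug_catalog.csv", package = "dtthiv",
                      mustWork = TRUE)
  load_drug_catalog(path)
}

#' Load and validate a drug catalog
#'
#' @param path CSV file with columns `drug_code`, `name`, `drug_class`,
#'   `is_booster`.
#' @return A validated catalog `data.table` (see [default_drug_catalog()]).
#' @export
load_drug_catalog <- function(path) {
  cat <- data.table::fread(path, colClasses = list(character = 1:3,
                                                   logical = 4))
  validate_catalog(cat)
}

drug_classes <- c("NRTI", "NNRTI", "PI", "INSTI", "ENTRY", "CAPSID", "OTHER")

validate_catalog <- function(cat) {
  cat <- data.table::as.data.table(cat)
  need <- c("drug_code", "name", "drug_class", "is_booster")
  miss <- setdiff(need, names(cat))
  if (length(miss))
    stop("drug catalog is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cat$drug_code))
    stop("duplicate drug_code in catalog: ",
         paste(unique(cat$drug_code[duplicated(cat$drug_code)]), collapse = ", "))
  bad <- setdiff(unique(cat$drug_class), drug_classes)
  if (length(bad))
    stop("unknown drug_class in catalog: ", paste(bad, collapse = ", "))
  cat[]
}

## look up a catalog column for a vector of codes, erroring on unknowns
catalog_lookup <- function(codes, catalog, what = c("is_booster", "drug_class")) {
  what <- match.arg(what)
  idx <- match(codes, catalog$drug_code)
  if (anyNA(idx))
    stop("drug code(s) not in catalog: ",
         paste(unique(codes[is.na(idx)]), collapse = ", "))
  catalog[[what]][idx]
}
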