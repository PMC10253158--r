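#' ATC code utilities
#'
#' The Anatomical Therapeutic Chemical (ATC) classification is a hierarchy of
#' five levels encoded positionally in a 7-character code: level 1 is the
#' anatomical main group (1 letter), level 2 the therapeutic subgroup
#' (+2 digits), levels 3 and 4 pharmacological/chemical subgroups (+1 letter
#' each) and level 5 the chemical substance (+2 digits). `atc_prefix()`
#' truncates a code to the prefix length of a given level (1, 3, 4, 5 or 7
#' characters for levels 1 to 5).
#'
#' @param code Character vector of ATC codes (any level at or below `level`).
#' @param level Integer scalar in 1..5.
#' @return Character vector of level prefixes.
#' @examples
#' atc_prefix("A10BA02", 2) # "A10"
#' atc_prefix("C09AA05", 4) # "C09AA"
#' @export
atc_prefix <- function(code, level) {
  if (length(level) != 1L || !level %in% 1:5) {
    stop("`level` must be a single integer in 1..5", call. = FALSE)
  }
  len <- c(1L, 3L, 4L, 5L, 7L)[level]
  bad <- !is_valid_atc(code, partial = TRUE) | nchar(code) < len
  if (any(bad)) {
    stop("malformed or too-short ATC code(s): ",
         paste(unique(code[bad]), collapse = ", "), call. = FALSE)
  }
  substr(code, 1L, len)
}

#' Validate the structure of an ATC code
#'
#' A structurally valid code is 1 letter, 2 digits, up to 2 letters, up to 2
#' digits — i.e. a prefix of lengths 1, 3, 4, 5 or 7. With `partial = FALSE`
#' only full 7-character level-5 codes pass, the form dispensing records must
#' carry.
#'
#' @param code Character vector.
#' @param partial Accept prefixes at any level (default `FALSE`).
#' @return Logical vector.
#' @export
is_valid_atc <- function(code, partial = FALSE) {
  pattern <- if (partial) {
    "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"
  } else {
    "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
  }
  !is.na(code) & grepl(pattern, code)
}

#' Is a drug an antidiabetic?
#'
#' Antidiabetic drugs (ADs) are the ATC level-2 group A10: blood-glucose
#' lowering drugs including insulins (A10A) and all oral/injectable
#' non-insulin agents (A10B), fixed-dose combinations included (A10BD).
#'
#' @param code Character vector of structurally valid ATC codes (level 2+).
#' @return Logical vector, `TRUE` where the level-2 prefix is "A10".
#' @examples
#' is_antidiabetic(c("A10BA02", "C10AA01", "A10BD07"))
#' @export
is_antidiabetic <- function(code) {
  atc_prefix(code, 2) == "A10"
}

# Plain metformin at ATC level 5.
ATC_METFORMIN <- "A10BA02"

# Fixed-dose antidiabetic combinations (A10BD) and their components.
# contains_metformin drives the add-on rule for metformin initiators.
atc_fdc_components <- tibble::tribble(
  ~atc_code,  ~components,                              ~contains_metformin,
  "A10BD01", "phenformin/sulfonylureas",                FALSE,
  "A10BD02", "metformin/sulfonylureas",                 TRUE,
  "A10BD03", "metformin/rosiglitazone",                 TRUE,
  "A10BD04", "glimepiride/rosiglitazone",               FALSE,
  "A10BD05", "metformin/pioglitazone",                  TRUE,
  "A10BD06", "glimepiride/pioglitazone",                FALSE,
  "A10BD07", "metformin/sitagliptin",                   TRUE,
  "A10BD08", "metformin/vildagliptin",                  TRUE,
  "A10BD09", "pioglitazone/alogliptin",                 FALSE,
  "A10BD10", "metformin/saxagliptin",                   TRUE,
  "A10BD11", "metformin/linagliptin",                   TRUE,
  "A10BD12", "pioglitazone/sitagliptin",                FALSE,
  "A10BD13", "metformin/alogliptin",                    TRUE,
  "A10BD14", "metformin/repaglinide",                   TRUE,
  "A10BD15", "metformin/dapagliflozin",                 TRUE,
  "A10BD16", "metformin/canagliflozin",                 TRUE,
  "A10BD17", "metformin/acarbose",                      TRUE,
  "A10BD18", "metformin/gemigliptin",                   TRUE,
  "A10BD19", "linagliptin/empagliflozin",               FALSE,
  "A10BD20", "metformin/empagliflozin",                 TRUE,
  "A10BD21", "saxagliptin/dapagliflozin",               FALSE,
  "A10BD22", "metformin/evogliptin",                    TRUE,
  "A10BD23", "metformin/ertugliflozin",                 TRUE,
  "A10BD24", "sitagliptin/ertugliflozin",               FALSE,
  "A10BD25", "metformin/saxagliptin/dapagliflozin",     TRUE,
  "A10BD26", "metformin/lobeglitazone",                 TRUE,
  "A10BD27", "metformin/sitagliptin/dapagliflozin",     TRUE
)

#' Does a fixed-dose combination contain metformin?
#'
#' @param code Character vector of level-5 ATC codes.
#' @return Logical vector; `TRUE` only for A10BD codes whose component list
#'   includes metformin. Unknown A10BD codes return `FALSE` with a warning.
#' @export
is_metformin_fdc <- function(code) {
  out <- rep(FALSE, length(code))
  fdc <- !is.na(code) & startsWith(code, "A10BD")
  if (any(fdc)) {
    idx <- match(code[fdc], atc_fdc_components$atc_code)
    if (anyNA(idx)) {
      warning("unknown A10BD code(s) treated as non-metformin: ",
              paste(unique(code[fdc][is.na(idx)]), collapse = ", "),
              call. = FALSE)
    }
    out[fdc] <- !is.na(idx) & atc_fdc_components$contains_metformin[idx]
  }
  out
}

# Human-readable names for the antidiabetic ATC level-4 classes.
atc_ad_class_names <- c(
  "A10A"  = "insulins alone or in combination",
  "A10BA" = "biguanides",
  "A10BB" = "sulfonylureas",
  "A10BD" = "fixed-dose combinations",
  "A10BF" = "alpha-glucosidase inhibitors",
  "A10BG" = "thiazolidinediones",
  "A10BH" = "DPP-4 inhibitors",
  "A10BJ" = "GLP-1 receptor agonists",
  "A10BK" = "SGLT-2 inhibitors",
  "A10BX" = "other blood-glucose lowering drugs"
)
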