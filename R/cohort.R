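#' Build and validate a discordant sibling-pair cohort
#'
#' A cohort is a tibble with one row per sample and columns `sample`,
#' `family`, `phenotype` and `age`. Each family holds exactly one brother
#' with cerebral disease (`"CALD"`) and one without (`"non-CALD"`);
#' unrelated controls carry phenotype `"control"` and no family id.
#'
#' @param samples A data frame with columns `sample` (character, unique),
#'   `family` (character; `NA` for controls), `phenotype` (one of
#'   `"CALD"`, `"non-CALD"`, `"control"`) and `age` (years, non-negative).
#' @return A validated cohort tibble of class `disco_cohort`.
#' @export
#' @examples
#' cohort_design(data.frame(
#'   sample = c("F1_C", "F1_N"), family = "fam1",
#'   phenotype = c("CALD", "non-CALD"), age = c(10, 12)
#' ))
cohort_design <- function(samples) {
  stopifnot(is.data.frame(samples))
  required <- c("sample", "family", "phenotype", "age")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("cohort sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(samples)[required]
  x$sample <- as.character(x$sample)
  x$family <- as.character(x$family)
  x$family[!is.na(x$family) & x$family == ""] <- NA_character_
  x$phenotype <- as.character(x$phenotype)
  x$age <- as.numeric(x$age)

  bad_pheno <- setdiff(unique(x$phenotype), c("CALD", "non-CALD", "control"))
  if (length(bad_pheno) > 0) {
    stop("unknown phenotype label(s): ", paste(bad_pheno, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$sample)) {
    stop("duplicate sample id(s): ",
         paste(unique(x$sample[duplicated(x$sample)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(x$age)) || any(x$age < 0)) {
    stop("ages must be finite and non-negative", call. = FALSE)
  }
  ctl_with_family <- x$phenotype == "control" & !is.na(x$family)
  if (any(ctl_with_family)) {
    stop("control sample(s) must not carry a family id: ",
         paste(x$sample[ctl_with_family], collapse = ", "), call. = FALSE)
  }
  fam_without_pair <- x$phenotype != "control" & is.na(x$family)
  if (any(fam_without_pair)) {
    stop("non-control sample(s) missing a family id: ",
         paste(x$sample[fam_without_pair], collapse = ", "), call. = FALSE)
  }

  fam <- x[!is.na(x$family), ]
  for (f in unique(fam$family)) {
    rows <- fam[fam$family == f, ]
    n_cald <- sum(rows$phenotype == "CALD")
    n_non <- sum(rows$phenotype == "non-CALD")
    if (n_cald != 1L || n_non != 1L) {
      stop(sprintf(
        "family '%s' must have exactly one CALD and one non-CALD member (has %d CALD, %d non-CALD)",
        f, n_cald, n_non), call. = FALSE)
    }
  }
  class(x) <- c("disco_cohort", class(x))
  x
}

#' Read a cohort sheet from a delimited file
#'
#' Reads a tab-delimited sheet with columns `sample`, `family`, `phenotype`
#' and `age` and validates the one-CALD/one-non-CALD pairing per family.
#'
#' @param path Path to a tab-delimited cohort sheet.
#' @return A validated cohort tibble (see [cohort_design()]).
#' @export
load_cohort <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  cohort_design(x)
}

#' Write a cohort sheet
#'
#' @param cohort A cohort tibble.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(tibble::as_tibble(unclass_cohort(cohort)), path)
  invisible(path)
}

unclass_cohort <- function(cohort) {
  class(cohort) <- setdiff(class(cohort), "disco_cohort")
  cohort
}

#' Family pairing table of a cohort
#'
#' @param cohort A cohort tibble.
#' @return A tibble with one row per family and columns `family`, `cald`
#'   and `noncald` holding the two brothers' sample ids.
#' @export
cohort_pairs <- function(cohort) {
  fam <- cohort[!is.na(cohort$family), ]
  out <- dplyr::summarise(
    dplyr::group_by(fam, .data$family),
    cald = .data$sample[.data$phenotype == "CALD"],
    noncald = .data$sample[.data$phenotype == "non-CALD"],
    .groups = "drop"
  )
  dplyr::arrange(out, .data$family)
}

#' Control sample ids of a cohort
#' @param cohort A cohort tibble.
#' @return Character vector of control sample ids (possibly empty).
#' @export
cohort_controls <- function(cohort) {
  cohort$sample[cohort$phenotype == "control"]
}

#' Affected-cohort (non-control) sample ids
#' @param cohort A cohort tibble.
#' @return Character vector of the sibling-pair sample ids.
#' @export
cohort_ald_samples <- function(cohort) {
  cohort$sample[cohort$phenotype != "control"]
}
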