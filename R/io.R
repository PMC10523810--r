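# Canonical age grouping: 18 five-year bands plus UNKNOWN.
AGE_BANDS <- c(
  "0-4", "5-9", "10-14", "15-19", "20-24", "25-29", "30-34", "35-39",
  "40-44", "45-49", "50-54", "55-59", "60-64", "65-69", "70-74", "75-79",
  "80-84", "85+"
)
AGE_LEVELS <- c(AGE_BANDS, "UNKNOWN")
SEX_LEVELS <- c("male", "female", "unknown")

#' Canonicalize and validate a mortality table
#'
#' A mortality table is a long tibble with columns `country`, `year`, `sex`
#' (`"male"`, `"female"` or `"unknown"`), `age_group` (one of the 18 five-year
#' bands `0-4` ... `85+`, or `UNKNOWN`), `cause` (ICD-10 code) and `deaths`
#' (non-negative, possibly fractional). Rows are sorted canonically by
#' country, year, sex, age band, cause; duplicate keys and negative or
#' non-finite counts are errors.
#'
#' @param df A data frame with the columns above.
#' @return A validated tibble in canonical order.
#' @export
mortality_table <- function(df) {
  required <- c("country", "year", "sex", "age_group", "cause", "deaths")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)[required]
  df$country <- as.character(df$country)
  df$year <- as.integer(df$year)
  df$sex <- as.character(df$sex)
  df$age_group <- as.character(df$age_group)
  df$cause <- as.character(df$cause)
  df$deaths <- as.double(df$deaths)

  bad_sex <- setdiff(unique(df$sex), SEX_LEVELS)
  if (length(bad_sex) > 0) {
    abort(paste0("Unknown sex value(s): ", paste(bad_sex, collapse = ", ")))
  }
  bad_age <- setdiff(unique(df$age_group), AGE_LEVELS)
  if (length(bad_age) > 0) {
    abort(paste0("Unknown age group(s): ", paste(bad_age, collapse = ", ")))
  }
  icd_validate(df$cause)
  if (any(!is.finite(df$deaths) | df$deaths < 0)) {
    bad <- which(!is.finite(df$deaths) | df$deaths < 0)
    abort(paste0("Negative or non-finite deaths in row(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  key <- paste(df$country, df$year, df$sex, df$age_group, df$cause, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("Duplicate (country, year, sex, age_group, cause) key: ",
                 gsub("\r", " / ", dup)))
  }
  df[order(df$country, df$year,
           match(df$sex, SEX_LEVELS),
           match(df$age_group, AGE_LEVELS),
           df$cause), , drop = FALSE]
}

#' Read / write the canonical long mortality CSV
#'
#' Columns `country, year, sex, age_group, cause, deaths`. Writing then
#' reading yields an identical table (canonical row order, numeric counts).
#'
#' @param path File path.
#' @return `read_mortality_csv()` returns a validated mortality tibble.
#' @export
read_mortality_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    country = readr::col_character(),
    year = readr::col_integer(),
    sex = readr::col_character(),
    age_group = readr::col_character(),
    cause = readr::col_character(),
    deaths = readr::col_double()
  ))
  mortality_table(df)
}

#' @rdname read_mortality_csv
#' @param table A mortality table.
#' @export
write_mortality_csv <- function(table, path) {
  table <- mortality_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

# ---- WHO Mortality Database ICD-10 part dialect -----------------------------

# Deaths column layout of the documented WHO dialect. Deaths1 is the all-age
# total (used as a checksum only); Deaths2..Deaths6 are ages 0,1,2,3,4 in the
# detail formats; Deaths7..Deaths22 are 5-9 ... 80-84; Deaths23..Deaths25 are
# 85-89, 90-94, 95+; Deaths26 is age unknown.
WHO_SUPPORTED_FRMATS <- c(0L, 1L, 2L)

#' Read a WHO Mortality Database ICD-10 part file
#'
#' Parses the documented CSV dialect (columns `Country, Admin1, SubDiv, Year,
#' List, Cause, Sex, Frmat, IM_Frmat, Deaths1...Deaths26`) into the canonical
#' long mortality table. Age columns are mapped onto the 18 canonical
#' five-year bands according to the row's age format (`Frmat`): formats 0, 1
#' and 2 — the detail layouts, which only require aggregating fine ages up —
#' are supported; coarser lumped layouts are rejected. `Deaths26` (age
#' unknown) maps to the `UNKNOWN` band; `Deaths1` is used only as a checksum
#' (a mismatch beyond 0.5 deaths raises a warning naming the row key).
#' Subnational rows (non-empty `Admin1`/`SubDiv`) are excluded. Causes in the
#' undotted WHO style (`"V873"`) are normalized to explicit decimals
#' (`"V87.3"`); sex codes 1/2/9 become male/female/unknown.
#'
#' @param path File path.
#' @param frmat_policy What to do with a row in an unsupported age format:
#'   `"strict"` (default) errors naming the row, `"drop"` drops it with a
#'   warning.
#' @return A validated mortality tibble.
#' @export
read_who_mortality <- function(path, frmat_policy = c("strict", "drop")) {
  frmat_policy <- match.arg(frmat_policy)
  df <- readr::read_csv(path, col_types = readr::cols(
    Country = readr::col_character(),
    Admin1 = readr::col_character(),
    SubDiv = readr::col_character(),
    Year = readr::col_integer(),
    List = readr::col_character(),
    Cause = readr::col_character(),
    Sex = readr::col_integer(),
    Frmat = readr::col_integer(),
    IM_Frmat = readr::col_integer(),
    .default = readr::col_double()
  ))
  death_cols <- paste0("Deaths", 1:26)
  missing_cols <- setdiff(c("Country", "Year", "Cause", "Sex", "Frmat", death_cols),
                          names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("WHO file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  # national rows only
  sub_rows <- (!is.na(df$Admin1) & df$Admin1 != "") |
    (!is.na(df$SubDiv) & df$SubDiv != "")
  df <- df[!sub_rows, , drop = FALSE]

  bad_frmat <- !(df$Frmat %in% WHO_SUPPORTED_FRMATS)
  if (any(bad_frmat)) {
    keys <- paste0(df$Country[bad_frmat], "/", df$Year[bad_frmat], "/",
                   df$Cause[bad_frmat], " (Frmat ", df$Frmat[bad_frmat], ")")
    msg <- paste0("Unsupported age format in row(s): ",
                  paste(utils::head(unique(keys), 5), collapse = "; "))
    if (frmat_policy == "strict") abort(msg)
    warn(paste0(msg, " — dropped"))
    df <- df[!bad_frmat, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    return(mortality_table(tibble(
      country = character(), year = integer(), sex = character(),
      age_group = character(), cause = character(), deaths = double()
    )))
  }

  dmat <- as.matrix(df[death_cols])
  dmat[is.na(dmat)] <- 0
  # canonical bands: 0-4 aggregates Deaths2..Deaths6 in every supported
  # format (Frmat 2 stores 1-4 lumped in Deaths3 with Deaths4..6 empty)
  bands <- cbind(
    `0-4` = rowSums(dmat[, 2:6, drop = FALSE]),
    dmat[, 7:22, drop = FALSE],
    `85+` = rowSums(dmat[, 23:25, drop = FALSE]),
    UNKNOWN = dmat[, 26]
  )
  colnames(bands) <- c(AGE_BANDS, "UNKNOWN")

  checksum_gap <- abs(dmat[, 1] - rowSums(bands))
  if (any(checksum_gap > 0.5)) {
    i <- which(checksum_gap > 0.5)
    warn(paste0(
      "Deaths1 checksum mismatch (> 0.5) in row(s): ",
      paste(utils::head(paste0(df$Country[i], "/", df$Year[i], "/",
                               df$Cause[i], "/sex", df$Sex[i]), 5),
            collapse = "; ")
    ))
  }

  cause <- normalize_who_cause(df$Cause)
  sex <- c(`1` = "male", `2` = "female", `9` = "unknown")[as.character(df$Sex)]
  if (anyNA(sex)) abort("Unknown Sex code in WHO file (expected 1, 2 or 9).")

  long <- tibble(
    country = rep(df$Country, times = ncol(bands)),
    year = rep(df$Year, times = ncol(bands)),
    sex = rep(sex, times = ncol(bands)),
    age_group = rep(colnames(bands), each = nrow(bands)),
    cause = rep(cause, times = ncol(bands)),
    deaths = as.vector(bands)
  )
  long <- long[long$deaths > 0, , drop = FALSE]
  mortality_table(long)
}

# "V873" (WHO undotted 4-character style) -> "V87.3"; 3-character codes pass.
normalize_who_cause <- function(cause) {
  cause <- toupper(as.character(cause))
  undotted <- grepl("^[A-Z][0-9]{3}$", cause)
  cause[undotted] <- paste0(substr(cause[undotted], 1, 3), ".",
                            substr(cause[undotted], 4, 4))
  icd_validate(cause)
  cause
}

#' Redistribute unknown-age deaths across age bands
#'
#' Deaths recorded with `UNKNOWN` age are spread proportionally across the
#' known age bands within (country, year, sex) before any rate computation,
#' using the cause's own age distribution when it has known-age deaths and the
#' stratum's all-cause age distribution otherwise. Strata with no known-age
#' deaths at all keep their `UNKNOWN` rows, with a warning.
#'
#' @param table A mortality table.
#' @return A mortality tibble without (or with residual) `UNKNOWN` rows;
#'   totals are conserved per (country, year, sex).
#' @export
redistribute_unknown_age <- function(table) {
  table <- mortality_table(table)
  unk <- table[table$age_group == "UNKNOWN", , drop = FALSE]
  if (nrow(unk) == 0) return(table)
  known <- table[table$age_group != "UNKNOWN", , drop = FALSE]

  cause_dist <- known |>
    group_by(.data$country, .data$year, .data$sex, .data$cause,
             .data$age_group) |>
    summarise(w = sum(.data$deaths), .groups = "drop")
  all_dist <- known |>
    group_by(.data$country, .data$year, .data$sex, .data$age_group) |>
    summarise(w = sum(.data$deaths), .groups = "drop")

  alloc_one <- function(row) {
    pool <- cause_dist[cause_dist$country == row$country &
                         cause_dist$year == row$year &
                         cause_dist$sex == row$sex &
                         cause_dist$cause == row$cause, ]
    if (nrow(pool) == 0 || sum(pool$w) == 0) {
      pool <- all_dist[all_dist$country == row$country &
                         all_dist$year == row$year &
                         all_dist$sex == row$sex, ]
    }
    if (nrow(pool) == 0 || sum(pool$w) == 0) return(NULL)
    tibble(
      country = row$country, year = row$year, sex = row$sex,
      age_group = pool$age_group, cause = row$cause,
      deaths = row$deaths * pool$w / sum(pool$w)
    )
  }
  allocated <- purrr::map(seq_len(nrow(unk)), function(i) alloc_one(unk[i, ]))
  unplaced <- unk[purrr::map_lgl(allocated, is.null), , drop = FALSE]
  if (nrow(unplaced) > 0) {
    warn(paste0(nrow(unplaced),
                " unknown-age row(s) kept: no known-age deaths in stratum."))
  }
  out <- bind_rows(known, bind_rows(allocated), unplaced) |>
    group_by(.data$country, .data$year, .data$sex, .data$age_group,
             .data$cause) |>
    summarise(deaths = sum(.data$deaths), .groups = "drop")
  mortality_table(out)
}

# ---- population & standard population ---------------------------------------

#' Read a population CSV
#'
#' Columns `country, year, sex, age_group, population` (UN World Population
#' Prospects style, reshaped long). Population must be strictly positive.
#'
#' @param path File path.
#' @return A validated population tibble.
#' @export
read_population_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    country = readr::col_character(),
    year = readr::col_integer(),
    sex = readr::col_character(),
    age_group = readr::col_character(),
    population = readr::col_double()
  ))
  population_table(df)
}

#' @rdname read_population_csv
#' @param df A data frame with population columns.
#' @export
population_table <- function(df) {
  required <- c("country", "year", "sex", "age_group", "population")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)[required]
  df$year <- as.integer(df$year)
  if (any(!is.finite(df$population) | df$population <= 0)) {
    abort("Population must be strictly positive.")
  }
  bad_age <- setdiff(unique(df$age_group), AGE_BANDS)
  if (length(bad_age) > 0) {
    abort(paste0("Unknown age group(s) in population: ",
                 paste(bad_age, collapse = ", ")))
  }
  df
}

#' Load a standard population
#'
#' The bundled default is the new WHO world standard population, collapsed to
#' the 18 canonical bands (85-89/90-94/95-99/100+ aggregated into 85+) and
#' normalized so the weights sum to exactly 1.
#'
#' @param path Path to a CSV with columns `age_group, weight`, or `NULL` for
#'   the bundled WHO world standard.
#' @return A tibble `age_group, weight` covering all 18 bands, weights
#'   summing to 1 within 1e-6.
#' @export
load_standard_population <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "who_world_standard.csv", package = "rtmortality")
  df <- readr::read_csv(path, col_types = readr::cols(
    age_group = readr::col_character(),
    weight = readr::col_double()
  ))
  missing_bands <- setdiff(AGE_BANDS, df$age_group)
  if (length(missing_bands) > 0) {
    abort(paste0("Standard population is missing band(s): ",
                 paste(missing_bands, collapse = ", ")))
  }
  extra <- setdiff(df$age_group, AGE_BANDS)
  if (length(extra) > 0) {
    abort(paste0("Standard population has unknown band(s): ",
                 paste(extra, collapse = ", ")))
  }
  if (abs(sum(df$weight) - 1) > 1e-6) {
    abort("Standard population weights must sum to 1 (within 1e-6).")
  }
  df[match(AGE_BANDS, df$age_group), ]
}
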