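#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn `%||%`
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows distinct across all_of n
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

# Five nonspecific ("garbage") categories, in cascade (hierarchy) order:
# all causes > injuries > unintentional injuries > transport > road traffic.
GARBAGE_CATEGORIES <- c(
  "ILL_DEFINED", "UNDETERMINED_INTENT", "UNSPEC_UNINTENTIONAL",
  "UNSPEC_TRANSPORT", "UNSPEC_RT"
)

ROAD_USER_GROUPS <- c(
  "PEDESTRIAN", "PEDAL_CYCLIST", "MOTORCYCLIST", "OCCUPANT", "OTHER_RT", "NON_RT"
)

# ---- code syntax ------------------------------------------------------------

ICD_PATTERN <- "^[A-Z][0-9]{2}(\\.[0-9])?$"

#' Validate ICD-10 cause codes
#'
#' A valid code is an uppercase letter followed by two digits ("X59"),
#' optionally with an explicit one-digit decimal ("V87.3").
#'
#' @param codes Character vector of candidate codes.
#' @return `codes`, invisibly, if all are valid; otherwise an error naming
#'   every offending string.
#' @export
#' @examples
#' icd_validate(c("R99", "V87.3"))
icd_validate <- function(codes) {
  codes <- as.character(codes)
  bad <- codes[is.na(codes) | !grepl(ICD_PATTERN, codes)]
  if (length(bad) > 0) {
    abort(paste0(
      "Malformed ICD-10 code(s): ",
      paste(sQuote(unique(bad)), collapse = ", ")
    ))
  }
  invisible(codes)
}

icd_root <- function(codes) substr(codes, 1L, 3L)

# Orderable integer for the 3-character root: letter rank * 100 + number.
icd_root_ord <- function(codes) {
  root <- icd_root(codes)
  match(substr(root, 1L, 1L), LETTERS) * 100L +
    as.integer(substr(root, 2L, 3L))
}

# ---- registry ---------------------------------------------------------------

# A parsed code-set entry: list(ranges = 2-col matrix of root ords,
# roots = 3-char codes matched with all children, exact = 4-char codes).
parse_code_set <- function(items) {
  items <- as.character(items)
  is_range <- grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", items)
  ranges <- items[is_range]
  singles <- items[!is_range]
  icd_validate(singles)
  lo <- icd_root_ord(sub("-.*", "", ranges))
  hi <- icd_root_ord(sub(".*-", "", ranges))
  if (any(lo > hi)) abort("Registry range with reversed endpoints.")
  list(
    ranges = cbind(lo = lo, hi = hi),
    roots = singles[nchar(singles) == 3L],
    exact = singles[nchar(singles) == 5L]
  )
}

# Membership of codes in a parsed set. 3-char singletons match themselves and
# all their 4th-character children; 4-char singletons match exactly; ranges
# match on the 3-char root.
in_code_set <- function(codes, set) {
  ord <- icd_root_ord(codes)
  hit <- rep(FALSE, length(codes))
  if (nrow(set$ranges) > 0) {
    for (i in seq_len(nrow(set$ranges))) {
      hit <- hit | (ord >= set$ranges[i, "lo"] & ord <= set$ranges[i, "hi"])
    }
  }
  if (length(set$roots) > 0) hit <- hit | icd_root(codes) %in% set$roots
  if (length(set$exact) > 0) hit <- hit | codes %in% set$exact
  hit
}

#' Load the ICD-10 code-set registry
#'
#' The registry defines, for each of the five nonspecific categories, its
#' garbage code set, its denominator (the parent set of its hierarchy level,
#' used for coding-quality proportions and the temporal-window rule) and its
#' redistribution target set, plus the road-user group ranges. The bundled
#' default follows the standard ICD-10 Chapter XX transport blocks; users can
#' supply their own YAML to align with GBD/WHO variants.
#'
#' @param path Path to a registry YAML file, or `NULL` for the bundled default.
#' @return An object of class `rt_registry`.
#' @export
load_registry <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "icd10_registry.yaml", package = "rtmortality")
  raw <- yaml::read_yaml(path)
  for (key in c("garbage_sets", "denominators", "targets", "road_user_groups")) {
    if (is.null(raw[[key]])) abort(paste0("Registry is missing key ", sQuote(key)))
  }
  garbage_codes <- lapply(raw$garbage_sets[GARBAGE_CATEGORIES], function(x) {
    icd_validate(as.character(x))
    as.character(x)
  })
  reg <- structure(
    list(
      version = raw$version %||% NA,
      garbage = garbage_codes,
      denominators = lapply(raw$denominators[GARBAGE_CATEGORIES], parse_code_set),
      targets = lapply(raw$targets[GARBAGE_CATEGORIES], parse_code_set),
      groups = lapply(raw$road_user_groups, parse_code_set),
      road_traffic = parse_code_set(raw$road_traffic %||% list("V01-V89"))
    ),
    class = "rt_registry"
  )
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  all_garbage <- unlist(reg$garbage, use.names = FALSE)
  if (anyDuplicated(all_garbage)) {
    abort("Garbage code sets are not pairwise disjoint.")
  }
  # every garbage code must sit inside its own denominator set
  for (cat in GARBAGE_CATEGORIES) {
    inside <- in_code_set(reg$garbage[[cat]], reg$denominators[[cat]])
    if (!all(inside)) {
      abort(paste0(
        "Garbage codes outside their denominator for ", cat, ": ",
        paste(reg$garbage[[cat]][!inside], collapse = ", ")
      ))
    }
  }
  invisible(reg)
}

#' @export
print.rt_registry <- function(x, ...) {
  cat("<rt_registry> version", as.character(x$version), "\n")
  for (cat_ in GARBAGE_CATEGORIES) {
    cat(format(cat_, width = 22), length(x$garbage[[cat_]]), "garbage codes\n")
  }
  invisible(x)
}

rt_env <- new.env(parent = emptyenv())

default_registry <- function() {
  if (is.null(rt_env$registry)) rt_env$registry <- load_registry()
  rt_env$registry
}

# ---- classification ---------------------------------------------------------

#' Classify ICD-10 codes into nonspecific (garbage) categories
#'
#' Returns, for each code, the nonspecific category it belongs to:
#' `ILL_DEFINED` (R95, R96, R98, R99), `UNDETERMINED_INTENT` (Y34, Y87.2,
#' Y89.9), `UNSPEC_UNINTENTIONAL` (X59), `UNSPEC_TRANSPORT` (V99, Y85.9),
#' `UNSPEC_RT` (V87, V87.0-V87.8, V89.2), or `"NONE"` for a fully specific
#' code.
#'
#' Matching rules: a 4-character code matches by exact listing, except that it
#' inherits from a listed bare 3-character code when the registry lists no
#' 4th-character children for that root (so "X59.0" is garbage via "X59", but
#' "V87.9" is specific because the registry distinguishes V87's children). A
#' bare 3-character query additionally matches a set when all ten of its
#' children are listed.
#'
#' @param codes Character vector of ICD-10 codes.
#' @param registry An `rt_registry`; defaults to the bundled one.
#' @return Character vector: one of the five category names or `"NONE"`.
#' @export
#' @examples
#' icd_classify(c("R99", "V87.3", "V87.9", "A00"))
icd_classify <- function(codes, registry = default_registry()) {
  codes <- as.character(codes)
  icd_validate(codes)
  out <- rep("NONE", length(codes))
  for (cat in GARBAGE_CATEGORIES) {
    set <- registry$garbage[[cat]]
    roots3 <- set[nchar(set) == 3L]
    exact4 <- set[nchar(set) == 5L]
    exact4_roots <- unique(icd_root(exact4))
    hit <- codes %in% set
    # 4-char codes inherit from a bare 3-char member unless the registry
    # distinguishes that root's children explicitly
    is4 <- nchar(codes) == 5L
    hit <- hit | (is4 & icd_root(codes) %in% setdiff(roots3, exact4_roots))
    # a 3-char query matches when all ten children are listed
    if (length(exact4) > 0) {
      children_per_root <- table(icd_root(exact4))
      covered <- names(children_per_root)[children_per_root == 10L]
      hit <- hit | (!is4 & codes %in% covered)
    }
    out[hit & out == "NONE"] <- cat
  }
  out
}

#' Map specific ICD-10 codes to road-user groups
#'
#' Pedestrian (V01-V09), pedal cyclist (V10-V19), motorcyclist (V20-V29),
#' vehicle occupant (V30-V79), other road-traffic (V80-V89, excluding the
#' unspecified-road-traffic garbage codes), everything else `NON_RT`.
#' Only specific (non-garbage) codes have a road-user group.
#'
#' @inheritParams icd_classify
#' @param strict If `TRUE` (default), passing a garbage code is an error; if
#'   `FALSE`, garbage codes return `NA`.
#' @return Character vector of group names.
#' @export
#' @examples
#' icd_road_user(c("V03.1", "V23.4", "J18.9"))
icd_road_user <- function(codes, registry = default_registry(), strict = TRUE) {
  codes <- as.character(codes)
  icd_validate(codes)
  garbage <- icd_classify(codes, registry) != "NONE"
  if (strict && any(garbage)) {
    abort(paste0(
      "Road-user group requested for nonspecific code(s): ",
      paste(sQuote(unique(codes[garbage])), collapse = ", ")
    ))
  }
  out <- rep("NON_RT", length(codes))
  for (grp in names(registry$groups)) {
    out[in_code_set(codes, registry$groups[[grp]])] <- grp
  }
  out[garbage] <- NA_character_
  out
}

#' Is a code a road traffic death?
#'
#' Road traffic deaths are V01-V89 at the 3-character level; this includes the
#' unspecified-road-traffic garbage codes (V87.0-V87.8, V89.2), which are road
#' traffic deaths of unspecified user. V90-V98 (water/air/other transport) and
#' V99 are transport but not road traffic.
#'
#' @inheritParams icd_classify
#' @return Logical vector.
#' @export
#' @examples
#' icd_is_road_traffic(c("V48.5", "V99", "X59"))
icd_is_road_traffic <- function(codes, registry = default_registry()) {
  codes <- as.character(codes)
  icd_validate(codes)
  in_code_set(codes, registry$road_traffic)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Denominator / target membership used by quality assessment & redistribution.
in_denominator <- function(codes, category, registry) {
  in_code_set(codes, registry$denominators[[category]])
}

# Targets always exclude every garbage code, of any category.
in_target <- function(codes, category, registry) {
  in_code_set(codes, registry$targets[[category]]) &
    icd_classify(codes, registry) == "NONE"
}
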