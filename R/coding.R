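# Survey-variable coding: education recoding to years, additive involvement
# scales, scale reliability, standardization.

.norm_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

.load_education_map <- function(which = c("child", "parent"), path = NULL) {
  which <- match.arg(which)
  if (is.null(path)) {
    path <- system.file("extdata",
                        sprintf("education_map_%s.csv", which),
                        package = "rgepath", mustWork = TRUE)
  }
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "years") %in% names(map)))
    stop("education map file must have columns 'label' and 'years'")
  map$label <- .norm_label(map$label)
  if (anyDuplicated(map$label))
    stop("education map contains duplicated labels")
  map
}

#' Education recoding maps
#'
#' Return the response-category-to-years map used to recode reported
#' educational attainment into years of education.  The child map has 13
#' response categories (8--20 years), the parent map 10 categories (0--18
#' years).  The maps are shipped as plain CSV files under
#' `inst/extdata/` so they can be audited or overridden via `path`.
#'
#' @param which `"child"` or `"parent"`.
#' @param path Optional path to a user-supplied two-column CSV
#'   (`label`, `years`) overriding the shipped map.
#' @return A data frame with columns `label` (normalized to lower case,
#'   collapsed whitespace) and `years` (integer).
#' @export
education_map <- function(which = c("child", "parent"), path = NULL) {
  .load_education_map(which, path)
}

.recode_education <- function(label, map, what) {
  key <- .norm_label(label)
  idx <- match(key, map$label)
  if (anyNA(idx[!is.na(label)])) {
    bad <- unique(label[is.na(idx) & !is.na(label)])
    stop(sprintf("unknown %s education label(s): %s",
                 what, paste(sQuote(bad), collapse = ", ")))
  }
  out <- map$years[idx]
  out[is.na(label)] <- NA_integer_
  out
}

#' Recode reported education categories to years of education
#'
#' Category labels are matched case-insensitively after collapsing
#' whitespace; an unknown label is an error (never silently converted to
#' missing).  `NA` input propagates to `NA` output.
#'
#' @param label Character vector of response-category labels.
#' @param map Optional map data frame as returned by [education_map()];
#'   defaults to the shipped map.
#' @return Integer vector of years of education.
#' @examples
#' recode_child_education("High school graduate")  # 12
#' recode_parent_education("never went to school") # 0
#' @export
recode_child_education <- function(label, map = education_map("child")) {
  .recode_education(label, map, "child")
}

#' @rdname recode_child_education
#' @export
recode_parent_education <- function(label, map = education_map("parent")) {
  .recode_education(label, map, "parent")
}

#' Build an additive parental-involvement scale from binary items
#'
#' School-specific involvement sums 3 yes/no items (score 0--3); leisure
#' involvement sums 5 yes/no items (score 0--5).  Rows with any missing
#' item are returned as `NA` (listwise rule for the affected scale).
#'
#' @param items Numeric matrix or data frame of binary (0/1) items, one row
#'   per person, or a single person's vector.
#' @param scale `"school"` (3 items) or `"leisure"` (5 items).
#' @return Integer scores, `NA` where any item is missing.
#' @export
build_involvement_scale <- function(items, scale = c("school", "leisure")) {
  scale <- match.arg(scale)
  k <- if (scale == "school") 3L else 5L
  if (is.vector(items) && !is.list(items)) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != k)
    stop(sprintf("%s involvement scale requires %d items, got %d",
                 scale, k, ncol(items)))
  vals <- items[!is.na(items)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("involvement items must be binary (0/1)")
  score <- rowSums(items)          # NA whenever any item is missing
  as.integer(score)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`,
#' using sample variances (n-1 denominator).
#'
#' @param items Numeric matrix or data frame, persons in rows, at least 2
#'   items and 3 persons, no missing values.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2) stop("cronbach_alpha needs at least 2 items")
  if (nrow(items) < 3) stop("cronbach_alpha needs at least 3 persons")
  if (anyNA(items)) stop("cronbach_alpha does not accept missing values")
  k <- ncol(items)
  v_items <- apply(items, 2, stats::var)
  v_total <- stats::var(rowSums(items))
  if (v_total == 0) stop("total score has zero variance; alpha undefined")
  k / (k - 1) * (1 - sum(v_items) / v_total)
}

#' Standardize a numeric column to z-scores
#'
#' Mean 0 and standard deviation 1 with the n-1 denominator.  A constant
#' column is an error rather than a division by zero.
#'
#' @param x Numeric vector without missing values.
#' @return Numeric vector of z-scores.
#' @export
standardize <- function(x) {
  if (anyNA(x)) stop("standardize does not accept missing values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant column")
  (x - mean(x)) / s
}

#' Coalesce two measurement waves
#'
#' Generic two-column coalesce used for wave fallback: take the primary
#' wave's value and fall back to the secondary wave where the primary is
#' missing.
#'
#' @param primary,secondary Vectors of equal length.
#' @return `primary` with `NA` entries filled from `secondary`.
#' @export
coalesce_waves <- function(primary, secondary) {
  if (length(primary) != length(secondary))
    stop("wave columns must have equal length")
  out <- primary
  miss <- is.na(out)
  out[miss] <- secondary[miss]
  out
}
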