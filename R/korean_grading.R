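# Korean meat-quantity (1st) grade: rectangular carcass-weight x backfat
# bands, half-open [low, high) as in the printed "low <= x < high" rules.

# Grade ordering used for the "lower of the two" final-grade rule.
GRADE_RANK <- c("1+" = 3, "1" = 2, "2" = 1)

#' Korean meat-quantity grade bands
#'
#' Returns the rectangular grade bands used by [classify_meat_quantity()].
#' The default bands are the scalding-carcass criteria: grade 1+ covers
#' 83 kg <= carcass weight < 93 kg and 17 mm <= backfat < 25 mm; grade 1
#' covers 80 kg <= carcass weight < 98 kg and 15 mm <= backfat < 28 mm
#' (excluding the 1+ rectangle); everything else is grade 2. All bounds are
#' half-open `[low, high)`. Bands ship as a plain CSV so an alternative
#' national grid can be swapped in via `path`.
#'
#' @param path CSV file with columns `grade, cw_low, cw_high, bf_low, bf_high`.
#'   Defaults to the bands bundled with the package.
#' @return data.frame of bands, best grade first.
#' @export
grade_bands <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "korean_grade_bands.csv",
                        package = "farmgrade", mustWork = TRUE)
  }
  bands <- utils::read.csv(path, colClasses = c(grade = "character"))
  required <- c("grade", "cw_low", "cw_high", "bf_low", "bf_high")
  missing <- setdiff(required, names(bands))
  if (length(missing)) {
    stop("grade band file misses column(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(all(bands$cw_low < bands$cw_high),
            all(bands$bf_low < bands$bf_high))
  bands[order(-GRADE_RANK[bands$grade]), , drop = FALSE]
}

#' Classify carcasses into Korean meat-quantity grades
#'
#' Applies the rectangular band rules to carcass weight and backfat
#' thickness. A carcass is graded 1+ if it falls inside the 1+ rectangle,
#' otherwise 1 if inside the grade-1 rectangle, otherwise 2. Bounds are
#' half-open: the lower bound belongs to the band, the upper does not.
#'
#' @param carcass_weight carcass weight(s), kg; must be > 0.
#' @param backfat backfat thickness(es), mm; must be >= 0.
#' @param bands band table as returned by [grade_bands()].
#' @return character vector of grades in `{"1+", "1", "2"}`.
#' @examples
#' classify_meat_quantity(86.43, 21.99)  # "1+"
#' classify_meat_quantity(c(83, 93, 79.9), c(17, 20, 20))
#' @export
classify_meat_quantity <- function(carcass_weight, backfat,
                                   bands = grade_bands()) {
  if (length(carcass_weight) != length(backfat)) {
    stop("carcass_weight and backfat must have equal length")
  }
  if (any(!is.finite(carcass_weight)) || any(!is.finite(backfat))) {
    stop("carcass_weight and backfat must be finite")
  }
  if (any(carcass_weight <= 0)) stop("carcass_weight must be > 0")
  if (any(backfat < 0)) stop("backfat must be >= 0")
  grade <- rep("2", length(carcass_weight))
  # bands come best-first; later (worse) bands must not overwrite earlier hits
  for (i in seq_len(nrow(bands))) {
    b <- bands[i, ]
    inside <- carcass_weight >= b$cw_low & carcass_weight < b$cw_high &
      backfat >= b$bf_low & backfat < b$bf_high
    grade[inside & grade == "2"] <- b$grade
  }
  grade
}

#' Combine meat-quantity and quality grades into the final grade
#'
#' The final Korean pig grade is the lower of the meat-quantity (1st) grade
#' and the meat-quality (2nd) grade under the ordering 1+ > 1 > 2.
#'
#' @param first,second grade symbols in `{"1+", "1", "2"}` (vectorized).
#' @return the lower grade of each pair.
#' @examples
#' combine_final_grade("1+", "1")  # "1"
#' @export
combine_final_grade <- function(first, second) {
  r1 <- GRADE_RANK[first]
  r2 <- GRADE_RANK[second]
  if (any(is.na(r1)) || any(is.na(r2))) {
    bad <- unique(c(first[is.na(r1)], second[is.na(r2)]))
    stop("unknown grade symbol(s): ", paste(bad, collapse = ", "))
  }
  names(GRADE_RANK)[match(pmin(r1, r2), GRADE_RANK)]
}

#' Grade distribution of a pig table
#'
#' Counts and percentages per Korean grade. Grades are taken from the given
#' column if present, otherwise computed on the fly from carcass weight and
#' backfat.
#'
#' @param pigs pig data.frame (see [read_pig_csv()] for the schema).
#' @param column grade column to tabulate; computed if absent.
#' @param digits rounding for the percentage column.
#' @return data.frame with `grade`, `n`, `percent` (empty for empty input).
#' @export
grade_distribution <- function(pigs, column = "meat_quantity_grade",
                               digits = 1) {
  if (nrow(pigs) == 0) {
    return(data.frame(grade = character(), n = integer(),
                      percent = numeric()))
  }
  grades <- if (column %in% names(pigs)) {
    pigs[[column]]
  } else {
    classify_meat_quantity(pigs$carcass_weight_kg, pigs$backfat_mm)
  }
  tab <- table(factor(grades, levels = names(GRADE_RANK)))
  tab <- tab[tab > 0]
  data.frame(grade = names(tab),
             n = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(grades), digits),
             row.names = NULL)
}

#' Annotate a pig table with Korean grades
#'
#' Adds `meat_quantity_grade` from the band rules and, when a
#' `quality_grade` column is present, `final_grade` as the lower of the two.
#' Without quality information the final grade equals the meat-quantity
#' grade (quality downgrading affects only a few percent of carcasses and no
#' quality rules are modeled here).
#'
#' @param pigs pig data.frame with `carcass_weight_kg` and `backfat_mm`.
#' @param bands band table, see [grade_bands()].
#' @return `pigs` with grade columns added.
#' @export
grade_pigs <- function(pigs, bands = grade_bands()) {
  pigs$meat_quantity_grade <- classify_meat_quantity(
    pigs$carcass_weight_kg, pigs$backfat_mm, bands)
  pigs$final_grade <- if ("quality_grade" %in% names(pigs) &&
                          !all(is.na(pigs$quality_grade))) {
    combine_final_grade(pigs$meat_quantity_grade, pigs$quality_grade)
  } else {
    pigs$meat_quantity_grade
  }
  pigs
}
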