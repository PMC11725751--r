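# Farm Management Grade: a farm's mean carcass weight and backfat,
# standardized with the whole-population parameters stored in the fitted
# model (never farm-level moments), is assigned to a cluster/group and the
# group letter becomes the grade: I -> A, II -> B, III -> C, IV -> D.

GROUP_TO_GRADE <- setNames(FARM_GRADES, PIG_GROUPS)

#' Summarize pigs to farms
#'
#' One row per farm with pig count and arithmetic mean carcass weight and
#' backfat. Farms shipping fewer than `min_pigs` pigs are flagged excluded
#' (default 30, the shipment threshold used when selecting farms for
#' grading) and receive no grade downstream.
#'
#' @param pigs pig data.frame with `farm_id`, `carcass_weight_kg`,
#'   `backfat_mm`.
#' @param min_pigs minimum shipment size for a farm to be graded.
#' @return data.frame `farm_id`, `n_pigs`, `mean_cw`, `mean_bf`,
#'   `excluded`, `excluded_reason`.
#' @export
summarize_farms <- function(pigs, min_pigs = 30) {
  if (!"farm_id" %in% names(pigs)) stop("pigs must carry a 'farm_id' column")
  farms <- do.call(rbind, lapply(
    split(pigs, pigs$farm_id), function(d) {
      data.frame(farm_id = d$farm_id[1],
                 n_pigs = nrow(d),
                 mean_cw = mean(d$carcass_weight_kg),
                 mean_bf = mean(d$backfat_mm))
    }))
  rownames(farms) <- NULL
  farms$excluded <- farms$n_pigs < min_pigs
  farms$excluded_reason <- ifelse(
    farms$excluded, sprintf("fewer than %d pigs shipped", min_pigs), "")
  farms
}

#' Assign Farm Management Grades
#'
#' Pushes each included farm's mean carcass weight and backfat through the
#' fitted k-means model: standardization with the whole-population
#' parameters, nearest-centroid cluster, cluster-to-group map, and group to
#' grade letter (I -> A, II -> B, III -> C, IV -> D). Excluded farms get NA
#' everywhere. The model is the one fitted on pigs; it is never refit on
#' farm means.
#'
#' @param farms farm summaries from [summarize_farms()].
#' @param model fitted, relabeled model from [fit_pig_clusters()].
#' @return `farms` with `abs_z_cw`, `abs_z_bf`, `cluster`, `group`,
#'   `management_grade` columns added.
#' @export
assign_farm_grades <- function(farms, model) {
  stopifnot(inherits(model, "kmeans_model"))
  if (!isTRUE(model$relabeled) || is.null(model$params)) {
    stop("model must be fitted with standardization params and relabeled")
  }
  farms$abs_z_cw <- abs_z(farms$mean_cw, model$params$mu_cw,
                          model$params$sigma_cw)
  farms$abs_z_bf <- abs_z(farms$mean_bf, model$params$mu_bf,
                          model$params$sigma_bf)
  a <- assign_cluster(model, farms$mean_cw, farms$mean_bf)
  farms$cluster <- ifelse(farms$excluded, NA_integer_, a$cluster)
  farms$group <- ifelse(farms$excluded, NA_character_, a$group)
  farms$management_grade <- unname(GROUP_TO_GRADE[farms$group])
  farms
}

# Within-farm percentage shares of `categories` for one farm's pigs.
farm_shares <- function(values, categories) {
  100 * as.vector(table(factor(values, levels = categories))) / length(values)
}

#' Composition of pig groups and Korean grades by farm grade
#'
#' For each Farm Management Grade, the mean (and SD across farms, when the
#' grade holds more than one farm) of the within-farm percentage shares of
#' pig groups I–IV and of Korean grades 1+/1/2. Farm grades with no
#' (included) farms are omitted.
#'
#' @param pigs pig data.frame carrying `group` (see [assign_pigs()]) and a
#'   grade column (`final_grade` or `meat_quantity_grade`, see
#'   [grade_pigs()]).
#' @param farms graded farm summaries from [assign_farm_grades()].
#' @return list of two data.frames (`group_by_grade`, `korean_by_grade`)
#'   in long form: `farm_grade`, `category`, `mean_share`, `sd_share`
#'   (NA for single-farm grades), `n_farms`.
#' @export
composition_report <- function(pigs, farms) {
  if (!"group" %in% names(pigs)) stop("pigs must carry a 'group' column")
  grade_col <- if ("final_grade" %in% names(pigs)) {
    "final_grade"
  } else if ("meat_quantity_grade" %in% names(pigs)) {
    "meat_quantity_grade"
  } else {
    stop("pigs must carry a Korean grade column; see grade_pigs()")
  }
  graded <- farms[!farms$excluded & !is.na(farms$management_grade), ]
  pigs <- pigs[pigs$farm_id %in% graded$farm_id, ]

  one_table <- function(values, categories) {
    rows <- list()
    for (fg in FARM_GRADES) {
      ids <- graded$farm_id[graded$management_grade == fg]
      if (!length(ids)) next
      shares <- vapply(ids, function(id) {
        sel <- pigs$farm_id == id
        farm_shares(values[sel], categories)
      }, numeric(length(categories)))
      shares <- matrix(shares, nrow = length(categories))
      rows[[fg]] <- data.frame(
        farm_grade = fg,
        category = categories,
        mean_share = rowMeans(shares),
        sd_share = if (length(ids) > 1) apply(shares, 1, sd) else NA_real_,
        n_farms = length(ids))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  list(group_by_grade = one_table(pigs$group, PIG_GROUPS),
       korean_by_grade = one_table(pigs[[grade_col]], names(GRADE_RANK)))
}
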