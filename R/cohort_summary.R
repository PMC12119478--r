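# Economic-impact summarization of per-patient cohorts: per-group
# aggregates and between-group reductions. Missing cells are excluded
# from every aggregate; relative reductions are defined only for a
# positive control-group mean (otherwise an explicit "undefined" marker).

mean_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}

group_aggregates <- function(df) {
  acc <- df$access[!is.na(df$access)]
  list(
    n = nrow(df),
    n_with_cost = sum(!is.na(df$cost)),
    mean_cost = mean_na(df$cost),
    mean_misdiagnosis = mean_na(df$misdiagnosis_pct),
    min_misdiagnosis = if (all(is.na(df$misdiagnosis_pct))) NA_real_
                       else min(df$misdiagnosis_pct, na.rm = TRUE),
    max_misdiagnosis = if (all(is.na(df$misdiagnosis_pct))) NA_real_
                       else max(df$misdiagnosis_pct, na.rm = TRUE),
    mean_premium = mean_na(df$premium_per_month),
    access_rate = if (length(acc) == 0L) NA_real_ else mean(acc == "yes")
  )
}

reduction <- function(control_mean, ai_mean) {
  if (is.na(control_mean) || is.na(ai_mean)) {
    return(list(absolute = NA_real_, relative_pct = NA_real_,
                relative_defined = FALSE))
  }
  abs_red <- control_mean - ai_mean
  if (control_mean > 0) {
    list(absolute = abs_red, relative_pct = abs_red / control_mean * 100,
         relative_defined = TRUE)
  } else {
    list(absolute = abs_red, relative_pct = NA_real_,
         relative_defined = FALSE)
  }
}

#' Summarize a patient cohort
#'
#' Per-group aggregates (count with observed cost, mean cost, mean and
#' min/max misdiagnosis rate, mean monthly premium, access rate among
#' non-missing access cells) and between-group reductions
#' `(control - ai)` in mean cost, mean premium and mean misdiagnosis,
#' absolute and relative (% of the control mean). All aggregates skip
#' missing cells; record order never matters.
#'
#' @param records Cohort `data.frame` (see [generate_cohort()]).
#' @return An object of class `cohort_summary`: list with `groups`
#'   (sublists `control`, `ai` as present) and `reductions` (sublists
#'   `cost`, `premium`, `misdiagnosis`, each with `absolute`,
#'   `relative_pct`, `relative_defined`; only when both groups are
#'   present).
#' @export
summarize_cohort <- function(records) {
  records <- validate_cohort(records)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  groups <- list()
  for (g in c("control", "ai")) {
    sub <- records[records$group == g, , drop = FALSE]
    if (nrow(sub) > 0L) groups[[g]] <- group_aggregates(sub)
  }
  reductions <- NULL
  if (!is.null(groups$control) && !is.null(groups$ai)) {
    reductions <- list(
      cost = reduction(groups$control$mean_cost, groups$ai$mean_cost),
      premium = reduction(groups$control$mean_premium,
                          groups$ai$mean_premium),
      misdiagnosis = reduction(groups$control$mean_misdiagnosis,
                               groups$ai$mean_misdiagnosis)
    )
  }
  structure(list(groups = groups, reductions = reductions),
            class = "cohort_summary")
}

#' Render a two-group comparison report
#'
#' Human-readable and JSON renderings of an existing summary; nothing is
#' recomputed. Relative reductions whose control mean was zero or missing
#' render as the explicit marker `"undefined"`, never as a number.
#'
#' @param summary A [summarize_cohort()] result with both groups present.
#' @return List with `text` (character vector of report lines) and
#'   `json` (a JSON string).
#' @export
compare_groups <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  if (is.null(summary$groups$control) || is.null(summary$groups$ai)) {
    stop("both groups must be present to compare", call. = FALSE)
  }
  fmt_num <- function(x) {
    if (is.na(x)) "NA" else formatC(x, format = "f", digits = 2,
                                    big.mark = ",")
  }
  fmt_rel <- function(r) {
    if (isTRUE(r$relative_defined)) sprintf("%.2f%%", r$relative_pct)
    else "undefined"
  }
  g <- summary$groups
  r <- summary$reductions
  text <- c(
    sprintf("%-28s %15s %15s", "", "control", "ai"),
    sprintf("%-28s %15d %15d", "patients", g$control$n, g$ai$n),
    sprintf("%-28s %15d %15d", "with observed cost",
            g$control$n_with_cost, g$ai$n_with_cost),
    sprintf("%-28s %15s %15s", "mean cost",
            fmt_num(g$control$mean_cost), fmt_num(g$ai$mean_cost)),
    sprintf("%-28s %15s %15s", "mean misdiagnosis (%)",
            fmt_num(g$control$mean_misdiagnosis),
            fmt_num(g$ai$mean_misdiagnosis)),
    sprintf("%-28s %15s %15s", "misdiagnosis range (%)",
            sprintf("%s-%s", fmt_num(g$control$min_misdiagnosis),
                    fmt_num(g$control$max_misdiagnosis)),
            sprintf("%s-%s", fmt_num(g$ai$min_misdiagnosis),
                    fmt_num(g$ai$max_misdiagnosis))),
    sprintf("%-28s %15s %15s", "mean premium (/mo)",
            fmt_num(g$control$mean_premium), fmt_num(g$ai$mean_premium)),
    sprintf("%-28s %15s %15s", "access rate",
            fmt_num(g$control$access_rate), fmt_num(g$ai$access_rate)),
    "",
    sprintf("cost reduction:         %s (%s)", fmt_num(r$cost$absolute),
            fmt_rel(r$cost)),
    sprintf("premium reduction:      %s (%s)", fmt_num(r$premium$absolute),
            fmt_rel(r$premium)),
    sprintf("misdiagnosis reduction: %s pp (%s)",
            fmt_num(r$misdiagnosis$absolute), fmt_rel(r$misdiagnosis))
  )
  json_obj <- summary_to_list(summary)
  list(text = text,
       json = as.character(jsonlite::toJSON(json_obj, auto_unbox = TRUE,
                                            digits = NA, null = "null")))
}

summary_to_list <- function(summary) {
  mark_undefined <- function(r) {
    if (is.null(r)) return(NULL)
    list(absolute = r$absolute,
         relative_pct = if (isTRUE(r$relative_defined)) r$relative_pct
                        else "undefined")
  }
  list(groups = summary$groups,
       reductions = if (is.null(summary$reductions)) NULL else
         lapply(summary$reductions, mark_undefined))
}

#' Write a cohort summary as JSON
#'
#' @param summary A [summarize_cohort()] result.
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  jsonlite::write_json(summary_to_list(summary), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @export
print.cohort_summary <- function(x, ...) {
  if (!is.null(x$groups$control) && !is.null(x$groups$ai)) {
    cat(compare_groups(x)$text, sep = "\n")
  } else {
    utils::str(x$groups)
  }
  invisible(x)
}
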