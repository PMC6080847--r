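## Group-level statistics on Alignment Index tables.
##
## A GroupTable is a plain long-format data.frame with one row per image:
## columns image_id, group, timepoint, condition ("unwounded"/"wounded")
## and ai (in [0, 1]).  Developmental designs are compared by one-way ANOVA
## with Tukey's HSD multiple comparisons; wound timecourses by per-timepoint
## two-sample t-tests (Welch by default).

.validateGroupTable <- function(table, need = c("group", "ai")) {
  if (!is.data.frame(table) || !nrow(table))
    stop("GroupTable must be a non-empty data.frame")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("GroupTable lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(table$ai) || any(table$ai < 0) || any(table$ai > 1))
    stop("ai values must lie in [0, 1]")
  if (any(!nzchar(as.character(table$group))))
    stop("group labels must be non-empty")
  invisible(table)
}

#' Significance stars for p values
#'
#' The conventional ladder: \code{****} p < 0.0001, \code{***} p < 0.001,
#' \code{**} p < 0.01, \code{*} p < 0.05, otherwise \code{ns}.
#'
#' @param p numeric vector of p values in [0, 1] (NA allowed).
#' @return character vector of star codes.
#' @examples
#' pStars(c(0.2, 0.03, 0.004, 2e-4, 5e-6))
#' @export
pStars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Per-group summary of Alignment Index values
#'
#' @param table a GroupTable data.frame with at least columns \code{group}
#'   and \code{ai}.
#' @param groups optional ordered group labels (defaults to order of
#'   appearance).
#'
#' @return a data.frame with columns \code{group}, \code{n}, \code{mean}
#'   and \code{sd} (sample SD, n - 1 denominator; \code{NA} for n = 1).
#'
#' @examples
#' tbl <- data.frame(group = rep(c("a", "b"), each = 3),
#'                   ai = c(1, 2, 3, rep(0.5, 3)) / 4)
#' summarizeGroups(tbl)
#'
#' @export
summarizeGroups <- function(table, groups = NULL) {
  .validateGroupTable(table)
  g <- as.character(table$group)
  if (is.null(groups)) groups <- unique(g)
  out <- do.call(rbind, lapply(groups, function(lv) {
    x <- table$ai[g == lv]
    data.frame(group = lv, n = length(x), mean = mean(x),
               sd = if (length(x) >= 2L) stats::sd(x) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD comparisons across groups
#'
#' Fits \code{ai ~ group}, reports the omnibus F test and all pairwise
#' Tukey honest-significant-difference comparisons with family-wise
#' adjusted p values, starred by the conventional ladder (see
#' [pStars()]).  Unadjusted pairwise p values (pooled-SD t tests on the
#' same error term) are included for reference.
#'
#' @param table a GroupTable data.frame with columns \code{group},
#'   \code{ai}.
#' @param groups optional ordered group labels.
#'
#' @return a TestReport data.frame with columns \code{test},
#'   \code{comparison}, \code{statistic} (omnibus F, or the pairwise mean
#'   difference), \code{p.value}, \code{p.unadjusted} and \code{stars}.
#'   With zero variance everywhere a degenerate single-row report (NA
#'   statistics) is returned rather than an error.
#'
#' @examples
#' set.seed(1)
#' tbl <- data.frame(group = rep(c("2dpf", "3dpf", "4dpf"), each = 6),
#'                   ai = c(rnorm(6, .2, .05), rnorm(6, .6, .05),
#'                          rnorm(6, .65, .05)))
#' tbl$ai <- pmin(pmax(tbl$ai, 0), 1)
#' anovaTukey(tbl)
#'
#' @export
anovaTukey <- function(table, groups = NULL) {
  .validateGroupTable(table)
  g <- as.character(table$group)
  if (is.null(groups)) groups <- unique(g)
  if (length(groups) < 2L) stop("ANOVA requires >= 2 groups")
  counts <- table(factor(g, levels = groups))
  if (any(counts < 2L)) stop("every group needs n >= 2")
  df <- data.frame(ai = table$ai, group = factor(g, levels = groups))
  withinSd <- tapply(df$ai, df$group, stats::sd)
  if (all(withinSd == 0)) {
    ## zero within-group variance: the F statistic is undefined (identical
    ## means) or unbounded (distinct means); report without crashing
    distinct <- length(unique(tapply(df$ai, df$group, mean))) > 1L
    out <- data.frame(test = "anova", comparison = "omnibus",
                      statistic = if (distinct) Inf else NA_real_,
                      p.value = if (distinct) 0 else NA_real_,
                      p.unadjusted = if (distinct) 0 else NA_real_)
    out$stars <- pStars(out$p.value)
    return(out)
  }
  fit <- stats::aov(ai ~ group, data = df)
  an <- summary(fit)[[1L]]
  omnibus <- data.frame(test = "anova", comparison = "omnibus",
                        statistic = an[["F value"]][1L],
                        p.value = an[["Pr(>F)"]][1L])
  omnibus$p.unadjusted <- omnibus$p.value
  tk <- stats::TukeyHSD(fit)$group
  raw <- stats::pairwise.t.test(df$ai, df$group, p.adjust.method = "none",
                                pool.sd = TRUE)$p.value
  pairs <- data.frame(test = "tukey", comparison = rownames(tk),
                      statistic = tk[, "diff"], p.value = tk[, "p adj"])
  pairs$p.unadjusted <- vapply(rownames(tk), function(nm) {
    ## Tukey labels are "second-first" over the factor levels
    for (i in seq_along(groups)[-1L]) for (j in seq_len(i - 1L)) {
      if (nm == paste(groups[i], groups[j], sep = "-"))
        return(raw[groups[i], groups[j]])
    }
    NA_real_
  }, numeric(1))
  out <- rbind(omnibus, pairs)
  out$stars <- pStars(out$p.value)
  rownames(out) <- NULL
  out
}

## Two-sample t test robust to zero-variance input.
.safeTTest <- function(x, y, var.equal = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, p.value = 1,
                  estimate = 0, df = length(x) + length(y) - 2))
    return(list(statistic = Inf, p.value = 0,
                estimate = mean(x) - mean(y),
                df = length(x) + length(y) - 2))
  }
  tt <- stats::t.test(x, y, var.equal = var.equal)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       estimate = unname(diff(rev(tt$estimate))), df = unname(tt$parameter))
}

#' Wounded versus unwounded t-tests over a timecourse
#'
#' For each requested timepoint, compares the Alignment Index of wounded
#' versus unwounded images by a two-sided two-sample t test (Welch by
#' default; set \code{var.equal = TRUE} for the pooled-variance test).  A
#' timepoint missing either condition (or with n < 2 in one of them) is
#' skipped with a warning.
#'
#' @param table a GroupTable data.frame with columns \code{timepoint},
#'   \code{condition} (values \code{"wounded"} / \code{"unwounded"}) and
#'   \code{ai}.
#' @param timepoints optional ordered timepoint labels.
#' @param var.equal logical, use the pooled-variance (Student) test.
#'
#' @return a TestReport data.frame with columns \code{test},
#'   \code{timepoint}, \code{comparison}, \code{statistic} (t),
#'   \code{df}, \code{estimate} (mean wounded - mean unwounded),
#'   \code{p.value} and \code{stars}.
#'
#' @export
woundedVsUnwoundedTTests <- function(table, timepoints = NULL,
                                     var.equal = FALSE) {
  .validateGroupTable(table, need = c("timepoint", "condition", "ai"))
  tp <- as.character(table$timepoint)
  if (is.null(timepoints)) timepoints <- unique(tp)
  rows <- lapply(timepoints, function(lv) {
    x <- table$ai[tp == lv & table$condition == "wounded"]
    y <- table$ai[tp == lv & table$condition == "unwounded"]
    if (length(x) < 2L || length(y) < 2L) {
      warning("timepoint '", lv,
              "' skipped: needs both conditions with n >= 2", call. = FALSE)
      return(NULL)
    }
    tt <- .safeTTest(x, y, var.equal = var.equal)
    data.frame(test = if (var.equal) "t_student" else "t_welch",
               timepoint = lv, comparison = "wounded-unwounded",
               statistic = tt$statistic, df = tt$df,
               estimate = tt$estimate, p.value = tt$p.value)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no testable timepoint")
  out <- do.call(rbind, rows)
  out$stars <- pStars(out$p.value)
  rownames(out) <- NULL
  out
}
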