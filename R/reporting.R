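## Reporting helpers: HLE/LE ratios, gender differences, age decrements,
## weighted descriptive tables, and the published reference tables used as
## a worked example of the reporting arithmetic.

#' Round half away from zero
#'
#' Reporting-layer rounding convention (base `round()` rounds half to
#' even). Applied only when printing tables; internal arithmetic stays
#' unrounded.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' HLE/LE ratio in percent
#'
#' @param hle healthy life expectancy (years), `0 <= hle <= le`.
#' @param le life expectancy (years), `> 0`.
#' @return `100 * hle / le`, rounded half away from zero to 1 decimal.
#' @export
hle_le_ratio <- function(hle, le) {
  if (any(le <= 0)) stop("life expectancy must be positive")
  if (any(hle < 0)) stop("HLE must be non-negative")
  if (any(hle > le + 1e-9)) stop("HLE cannot exceed LE")
  round_half_up(100 * hle / le, 1L)
}

#' HLE/LE series over age
#'
#' @param age strictly increasing ages.
#' @param ratio HLE/LE values in percent, within \[0, 100\].
#' @param ... group labels (e.g. `gender`, `group`, `indicator`) stored as
#'   attributes.
#' @return Data frame of class `hle_series`.
#' @export
hle_series <- function(age, ratio, ...) {
  stopifnot(length(age) == length(ratio), all(diff(age) > 0),
            all(ratio >= 0 & ratio <= 100))
  out <- data.frame(age = age, ratio = ratio)
  labels <- list(...)
  for (nm in names(labels)) attr(out, nm) <- labels[[nm]]
  class(out) <- c("hle_series", "data.frame")
  out
}

#' Gender difference in HLE/LE
#'
#' Men's minus women's HLE/LE at each age (the sign convention matching
#' the published positive values), rounded to 1 decimal.
#'
#' @param men,women `hle_series` (or data frames with `age` and `ratio`)
#'   on identical age grids.
#' @return Data frame `age`, `gd` (percentage points).
#' @export
gender_difference <- function(men, women) {
  if (!identical(as.numeric(men$age), as.numeric(women$age)))
    stop("age grids differ between the two series")
  data.frame(age = men$age,
             gd = round_half_up(men$ratio - women$ratio, 1L))
}

#' Age decrement in HLE/LE
#'
#' HLE/LE at `from_age` minus HLE/LE at `to_age`; negative when the ratio
#' rises with age.
#'
#' @param series an `hle_series`.
#' @param from_age,to_age endpoint ages (must be present in the series).
#' @return Scalar decrement in percentage points, rounded to 1 decimal.
#' @export
age_decrement <- function(series, from_age = 65, to_age = 99) {
  i <- match(from_age, series$age)
  j <- match(to_age, series$age)
  if (is.na(i) || is.na(j)) stop("endpoint age missing from the series")
  round_half_up(series$ratio[i] - series$ratio[j], 1L)
}

#' Published reference tables for the reporting arithmetic
#'
#' Point estimates (LE, HLE, HLE/LE with confidence intervals, and
#' gender-specific HLE/LE series with printed gender-difference and
#' age-decrement summaries) from a published CLHLS-based multistate
#' analysis of loneliness and healthy life expectancy, bundled as
#' plain-text CSV. They serve as the worked example for [hle_le_ratio()],
#' [gender_difference()] and [age_decrement()]; some printed difference
#' cells reflect the original unrounded internals, which is why reporting
#' functions expose both from-rounded and printed values.
#'
#' @return List of data frames: `expectancy` (per indicator, loneliness
#'   group and age), `ratio_series` (per indicator, group, gender and
#'   age), `gd` (printed gender differences), `ad` (printed age
#'   decrements).
#' @export
reference_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "mshle"), stringsAsFactors = FALSE)
  list(expectancy = rd("published_expectancy.csv"),
       ratio_series = rd("published_ratio_series.csv"),
       gd = rd("published_gd.csv"),
       ad = rd("published_ad.csv"))
}

#' Weighted descriptive table with gender comparison
#'
#' Weighted means (SD) for continuous variables and weighted percentages
#' for categorical ones, overall and by gender, with two-sample Welch t
#' tests (continuous) or chi-square tests on weighted counts
#' (categorical). With unit weights these reduce to the textbook
#' unweighted tests.
#'
#' @param baseline one row per individual, containing the listed variables,
#'   a 0/1 `gender_col` (1 = female) and a weight column.
#' @param continuous,categorical variable names.
#' @param gender_col,weight_col column names.
#' @return Data frame with one row per variable (per level for categorical
#'   variables): summaries for all / men / women, the test statistic and
#'   p-value.
#' @export
descriptives_table <- function(baseline, continuous = character(),
                               categorical = character(),
                               gender_col = "female", weight_col = "weight") {
  w <- baseline[[weight_col]]
  g <- baseline[[gender_col]]
  if (any(tapply(w, g, sum) <= 0)) stop("zero total weight in a gender stratum")
  men <- g == 0; wom <- g == 1
  wmean <- function(x, i) sum(w[i] * x[i]) / sum(w[i])
  wsd <- function(x, i) {
    m <- wmean(x, i)
    sqrt(sum(w[i] * (x[i] - m)^2) / (sum(w[i]) - 1))
  }
  rows <- list()
  for (v in continuous) {
    x <- baseline[[v]]
    m1 <- wmean(x, men); m2 <- wmean(x, wom)
    v1 <- wsd(x, men)^2; v2 <- wsd(x, wom)^2
    n1 <- sum(w[men]); n2 <- sum(w[wom])
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = NA_character_,
      overall = sprintf("%.2f (%.2f)", wmean(x, rep(TRUE, nrow(baseline))),
                        wsd(x, rep(TRUE, nrow(baseline)))),
      men = sprintf("%.2f (%.2f)", m1, sqrt(v1)),
      women = sprintf("%.2f (%.2f)", m2, sqrt(v2)),
      statistic = tstat, p_value = 2 * stats::pt(-abs(tstat), df),
      test = "weighted t")
  }
  for (v in categorical) {
    x <- as.factor(baseline[[v]])
    lev <- levels(x)
    O <- vapply(lev, function(l) c(sum(w[men & x == l]), sum(w[wom & x == l])),
                numeric(2))
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    chi2 <- sum((O - E)^2 / E)
    p <- stats::pchisq(chi2, df = (nrow(O) - 1) * (ncol(O) - 1),
                       lower.tail = FALSE)
    for (l in lev) {
      pct <- function(i) 100 * sum(w[i & x == l]) / sum(w[i])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = l,
        overall = sprintf("%.1f%%", pct(rep(TRUE, nrow(baseline)))),
        men = sprintf("%.1f%%", pct(men)),
        women = sprintf("%.1f%%", pct(wom)),
        statistic = chi2, p_value = p, test = "weighted chi-square")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot HLE/LE, HLE or LE against age
#'
#' Line chart of a life-table summary by profile, the standard display for
#' comparing loneliness groups across age.
#'
#' @param x an `hle_table`.
#' @param what column to plot (`"ratio"`, `"hle"` or `"le"`).
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.hle_table <- function(x, what = c("ratio", "hle", "le"), ...) {
  what <- match.arg(what)
  profs <- unique(x$profile)
  ages <- sort(unique(x$age))
  Y <- vapply(profs, function(p) x[[what]][x$profile == p][order(x$age[x$profile == p])],
              numeric(length(ages)))
  ylab <- c(ratio = "HLE/LE (%)", hle = "HLE (years)", le = "LE (years)")[what]
  graphics::matplot(ages, Y, type = "b", pch = 16, lty = 1,
                    xlab = "Age (years)", ylab = ylab, ...)
  graphics::legend("topright", legend = profs, col = seq_along(profs),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
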