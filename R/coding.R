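#' Coding rules for health and loneliness items
#'
#' Bundles the item-level coding conventions used to turn CLHLS-style
#' questionnaire responses into the binary states of the multistate model:
#' a single-item loneliness frequency question dichotomized at
#' "sometimes"-or-more, the six Katz ADL items dichotomized at full
#' independence, and single-item self-rated health dichotomized at
#' "good"-or-better.
#'
#' @param loneliness_cutoff responses coded as lonely.
#' @param adl_items names of the six ADL items, in reporting order.
#' @param srh_healthy_levels responses coded as healthy.
#' @param indicator which health indicator drives the model state,
#'   `"ADL"` or `"SRH"`.
#' @return An object of class `coding_rules`.
#' @export
coding_rules <- function(loneliness_cutoff = c("always", "often", "sometimes"),
                         adl_items = c("eating", "dressing", "toileting",
                                       "transfer", "continence", "bathing"),
                         srh_healthy_levels = c("very good", "good"),
                         indicator = c("ADL", "SRH")) {
  indicator <- match.arg(indicator)
  stopifnot(length(adl_items) == 6L)
  if (length(loneliness_cutoff) == 0L || length(loneliness_cutoff) >= 5L)
    stop("loneliness_cutoff must be a non-empty proper subset of the 5-level scale")
  if (length(srh_healthy_levels) == 0L || length(srh_healthy_levels) >= 5L)
    stop("srh_healthy_levels must be a non-empty proper subset of the 5-level scale")
  structure(list(loneliness_cutoff = loneliness_cutoff,
                 adl_items = adl_items,
                 srh_healthy_levels = srh_healthy_levels,
                 indicator = indicator),
            class = "coding_rules")
}

.loneliness_levels <- c("always", "often", "sometimes", "seldom", "never")
.srh_levels <- c("very good", "good", "so-so", "bad", "very bad")

#' Dichotomize the single-item loneliness response
#'
#' Responses of "sometimes" or more frequent are coded lonely; "seldom" and
#' "never" are coded non-lonely. Missing responses propagate as `NA`.
#'
#' @param response character vector on the 5-level frequency scale
#'   (`always`, `often`, `sometimes`, `seldom`, `never`), or `NA`.
#' @param rules a [coding_rules()] object.
#' @return Integer vector: 1 = lonely, 0 = non-lonely, `NA` preserved.
#' @export
dichotomize_loneliness <- function(response, rules = coding_rules()) {
  response <- tolower(as.character(response))
  bad <- !is.na(response) & !(response %in% .loneliness_levels)
  if (any(bad))
    stop("unrecognized loneliness level(s): ",
         paste(unique(response[bad]), collapse = ", "))
  ifelse(is.na(response), NA_integer_,
         as.integer(response %in% rules$loneliness_cutoff))
}

#' Dichotomize the six ADL independence items
#'
#' Full independence on all six Katz items (eating, dressing, toileting,
#' indoor transfer, continence, bathing) codes as no limitation; any
#' dependence codes as limitation.
#'
#' @param item_scores a length-6 vector (one person) or a matrix / data frame
#'   with 6 columns (one row per person) of 0/1 independence flags
#'   (1 = independent). `NA` in any item propagates.
#' @return Integer vector: 1 = healthy (no limitation), 2 = unhealthy
#'   (limitation), `NA` when any item is missing.
#' @export
dichotomize_adl <- function(item_scores) {
  if (is.data.frame(item_scores)) item_scores <- as.matrix(item_scores)
  if (!is.matrix(item_scores)) item_scores <- matrix(item_scores, nrow = 1L)
  if (ncol(item_scores) != 6L)
    stop("exactly 6 ADL items are required, got ", ncol(item_scores))
  if (any(!item_scores %in% c(0, 1, NA)))
    stop("ADL items must be 0/1 independence flags")
  all_indep <- apply(item_scores, 1L, function(r) {
    if (anyNA(r)) NA else all(r == 1)
  })
  ifelse(is.na(all_indep), NA_integer_, ifelse(all_indep, 1L, 2L))
}

#' Dichotomize self-rated health
#'
#' "good" and "very good" code as healthy; "so-so", "bad" and "very bad"
#' code as unhealthy. Missing responses propagate.
#'
#' @param response character vector on the scale `very good`, `good`,
#'   `so-so`, `bad`, `very bad`, or `NA`.
#' @param rules a [coding_rules()] object.
#' @return Integer vector: 1 = healthy, 2 = unhealthy, `NA` preserved.
#' @export
dichotomize_srh <- function(response, rules = coding_rules()) {
  response <- tolower(as.character(response))
  bad <- !is.na(response) & !(response %in% .srh_levels)
  if (any(bad))
    stop("unrecognized self-rated health level(s): ",
         paste(unique(response[bad]), collapse = ", "))
  ifelse(is.na(response), NA_integer_,
         ifelse(response %in% rules$srh_healthy_levels, 1L, 2L))
}
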