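#' Stimulus categories of the viewing reaction time paradigm
#'
#' The paradigm presents computer-generated nude images of males and females
#' in Tanner developmental stages 1 through 5, giving 10 stimulus categories.
#' Categories with Tanner stage 1-3 depict pre-/peripubertal ("child")
#' stimuli; stages 4-5 depict postpubertal ("adult") stimuli. Category labels
#' combine sex and stage, e.g. `"FT3"` = female, Tanner 3.
#'
#' @return A data frame with one row per category and columns `category`
#'   (label), `sex` (`"M"`/`"F"`), `tanner` (integer 1-5) and `is_child`
#'   (logical, `tanner <= 3`). Rows are in the canonical order used for
#'   deterministic tie-breaking: males before females, ascending Tanner
#'   stage within sex.
#' @examples
#' vrt_categories()
#' @export
vrt_categories <- function() {
  sex <- rep(c("M", "F"), each = 5L)
  tanner <- rep(1:5, times = 2L)
  data.frame(
    category = paste0(sex, "T", tanner),
    sex = sex,
    tanner = tanner,
    is_child = tanner <= 3L,
    stringsAsFactors = FALSE
  )
}

# canonical label vectors, used throughout for ordering and tie-breaking
.vrt_all_categories <- function() vrt_categories()$category

.vrt_child_categories <- function() {
  cats <- vrt_categories()
  cats$category[cats$is_child]
}

.vrt_adult_categories <- function() {
  cats <- vrt_categories()
  cats$category[!cats$is_child]
}

#' Build a category label from sex and Tanner stage
#'
#' @param sex Character vector of `"M"`/`"F"`.
#' @param tanner Integer vector of Tanner stages 1-5.
#' @return Character vector of labels such as `"MT1"`, `"FT5"`.
#' @export
category_label <- function(sex, tanner) {
  sex <- toupper(as.character(sex))
  tanner <- as.integer(tanner)
  bad_sex <- !is.na(sex) & !sex %in% c("M", "F")
  if (any(bad_sex)) {
    stop("invalid stimulus sex code(s): ",
         paste(unique(sex[bad_sex]), collapse = ", "),
         " (expected 'M' or 'F')", call. = FALSE)
  }
  bad_t <- !is.na(tanner) & !tanner %in% 1:5
  if (any(bad_t)) {
    stop("invalid Tanner stage(s): ",
         paste(unique(tanner[bad_t]), collapse = ", "),
         " (expected integers 1-5)", call. = FALSE)
  }
  paste0(sex, "T", tanner)
}
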