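#' Read and write household survey tables
#'
#' The long occupation table has columns `community_id`, `country`,
#' `household_id`, `occupation`, `rank`; the wide item table has the same id
#' columns plus 16 binary `item_01` ... `item_16` columns. Real survey
#' exports in the same schema are accepted interchangeably with synthetic
#' ones.
#'
#' @param survey Long occupation data frame.
#' @param items Wide item data frame.
#' @param survey_path,items_path CSV paths.
#' @return Reader: list with `survey` and `items`. Writers return the path,
#'   invisibly.
#' @export
read_survey_csv <- function(survey_path, items_path = NULL) {
  survey <- utils::read.csv(survey_path, stringsAsFactors = FALSE)
  need <- c("community_id", "country", "household_id", "occupation", "rank")
  if (!all(need %in% names(survey)))
    stop("survey file must have columns: ", paste(need, collapse = ", "))
  items <- NULL
  if (!is.null(items_path)) {
    items <- utils::read.csv(items_path, stringsAsFactors = FALSE)
    icol <- sprintf("item_%02d", 1:16)
    if (!all(icol %in% names(items)))
      stop("item file must have columns item_01 ... item_16")
    if (!all(unlist(items[icol]) %in% c(0L, 1L)))
      stop("item columns must be 0/1")
  }
  list(survey = survey, items = items)
}

#' @rdname read_survey_csv
#' @export
write_survey_csv <- function(survey, items, survey_path, items_path = NULL) {
  utils::write.csv(survey, survey_path, row.names = FALSE)
  if (!is.null(items_path))
    utils::write.csv(items, items_path, row.names = FALSE)
  invisible(survey_path)
}
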