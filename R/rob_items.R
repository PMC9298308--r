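#' The five risk-of-bias items
#'
#' Each item is a methodological safeguard whose reporting in a full-text
#' publication is classified yes/no. The one-sentence description is the
#' canonical definition of the item; sentence extraction
#' ([extract_relevant_sentences()]) ranks document sentences by similarity
#' to this description.
#'
#' @return A data frame with columns `key` and `description`, one row per
#'   item, in canonical order: `random_allocation`, `blinding`,
#'   `conflict_of_interest`, `welfare_compliance`, `animal_exclusion`.
#' @examples
#' rob_items()$key
#' @export
rob_items <- function() {
  data.frame(
    key = c("random_allocation", "blinding", "conflict_of_interest",
            "welfare_compliance", "animal_exclusion"),
    description = c(
      "animals are randomly allocated to treatment or control groups",
      "group identity is concealed from the scientist measuring the outcome",
      "authors report any relationship which might be perceived to introduce a potential conflict of interests or the absence of such a relationship",
      "researchers report that they complied with relevant animal welfare regulations",
      "a statement of whether or not all animals all data and all outcomes measured are accounted for and presented in the final analysis"
    ),
    stringsAsFactors = FALSE
  )
}

#' Canonical item keys
#' @return Character vector of the five item keys.
#' @export
rob_item_keys <- function() rob_items()$key

#' Look up one item's description
#' @param item One of [rob_item_keys()].
#' @return The item's one-sentence description.
#' @export
rob_item_description <- function(item) {
  items <- rob_items()
  i <- match(item, items$key)
  if (is.na(i)) {
    stop("unknown risk-of-bias item: ", item,
         " (expected one of ", paste(items$key, collapse = ", "), ")")
  }
  items$description[i]
}
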