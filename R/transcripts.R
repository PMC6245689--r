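#' Transcript identifier conventions
#'
#' Transcripts are identified by plain character strings. A sense transcript
#' carries the bare gene identifier; its complementary anti-sense transcript
#' carries the same identifier with the suffix `"_AS"`. A sense/anti-sense
#' pair sharing a base identifier is called a *couple*.
#'
#' @param id,base character vector of transcript or gene identifiers.
#' @return `antisense_id()` returns the anti-sense identifier for a base gene
#'   id; `is_antisense()` a logical vector; `base_id()` the gene identifier
#'   with any `"_AS"` suffix removed.
#' @examples
#' antisense_id("MDP0000251669")
#' is_antisense(c("g1", "g1_AS"))
#' base_id("g1_AS")
#' @name transcript-ids
NULL

#' @rdname transcript-ids
#' @export
antisense_id <- function(base) {
  if (any(grepl("_AS$", base)))
    stop("identifier is already anti-sense", call. = FALSE)
  paste0(base, "_AS")
}

#' @rdname transcript-ids
#' @export
is_antisense <- function(id) grepl("_AS$", id)

#' @rdname transcript-ids
#' @export
base_id <- function(id) sub("_AS$", "", id)

#' Count sense/anti-sense couples
#'
#' A couple is a base gene identifier present on both strands in the given
#' set of transcripts (typically the differentially expressed set).
#'
#' @param de either a character vector of transcript identifiers or a
#'   data frame with a `transcript` column, as returned by
#'   [differential_expression()] (rows should already be restricted to the
#'   flagged transcripts).
#' @return integer, the number of couples.
#' @export
#' @examples
#' count_couples(c("g1", "g1_AS", "g2"))  # 1
count_couples <- function(de) {
  ids <- if (is.data.frame(de)) as.character(de$transcript) else as.character(de)
  if (length(ids) == 0L) return(0L)
  sense <- unique(base_id(ids[!is_antisense(ids)]))
  anti <- unique(base_id(ids[is_antisense(ids)]))
  length(intersect(sense, anti))
}
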