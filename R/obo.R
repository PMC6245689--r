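#' Read an OBO-format ontology file (minimal parser)
#'
#' Parses `[Term]` stanzas for `id:`, `name:` and `is_a:` lines, which is
#' all the enrichment machinery needs (the parent DAG and term names).
#' Obsolete terms (`is_obsolete: true`) are skipped.
#'
#' @param path path to an OBO file.
#' @return list with `parents` (named list term -> parent ids, suitable for
#'   [annotation_map()]) and `names` (named character vector term -> name).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parents <- list()
  nm <- character(0)
  cur_id <- NULL
  cur_parents <- character(0)
  cur_name <- NA_character_
  obsolete <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur_id) && !obsolete) {
      parents[[cur_id]] <<- cur_parents
      nm[cur_id] <<- cur_name
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE
      cur_id <- NULL
      cur_parents <- character(0)
      cur_name <- NA_character_
      obsolete <- FALSE
    } else if (grepl("^\\[", ln)) {
      flush()
      in_term <- FALSE
      cur_id <- NULL
    } else if (in_term) {
      if (startsWith(ln, "id: ")) cur_id <- sub("^id: ", "", ln)
      else if (startsWith(ln, "name: ")) cur_name <- sub("^name: ", "", ln)
      else if (startsWith(ln, "is_a: ")) {
        p <- sub("^is_a: ", "", ln)
        p <- trimws(sub("!.*$", "", p))
        cur_parents <- c(cur_parents, p)
      } else if (ln == "is_obsolete: true") obsolete <- TRUE
    }
  }
  flush()
  list(parents = parents, names = nm)
}
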