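#' The merged 7-stage ordinal coding of embryo development
#'
#' Developmental stages are encoded as ordinal codes 1 through 7:
#' 2-cell, 3-cell, 4-cell, 5-cell, 8/9-cell (merged), morula, blastocyst.
#' The 8-cell and 9-cell stages share code 5 because they are graded as one
#' class in clinical practice.
#'
#' @return `stage_codes()` returns the integer vector `1:7` named by the
#'   short stage labels; `stage_names()` returns the human-readable stage
#'   names in ordinal order.
#' @examples
#' stage_codes()
#' stage_names()
#' @export
stage_codes <- function() {
  c(t2 = 1L, t3 = 2L, t4 = 3L, t5 = 4L, t8 = 5L, t9 = 5L, tM = 6L, tB = 7L)
}

#' @rdname stage_codes
#' @export
stage_names <- function() {
  c("2-cell", "3-cell", "4-cell", "5-cell", "8/9-cell", "morula", "blastocyst")
}

n_stages <- function() 7L

#' Encode stage labels as merged ordinal codes
#'
#' Normalizes stage labels to the 1..7 ordinal coding. Accepts integer codes
#' (passed through after range validation), short names (`t2`, `t3`, `t4`,
#' `t5`, `t8`, `t9`, `tM`, `tB`) and full names (`2-cell`, ..., `morula`,
#' `blastocyst`). `t8` and `t9` both map to code 5.
#'
#' @param label Character or integer vector of stage labels.
#' @return Integer vector of stage codes in 1..7.
#' @examples
#' encode_stage(c("t2", "t9", "tB"))
#' encode_stage(c(1, 5, 7))
#' @export
encode_stage <- function(label) {
  if (length(label) == 0L) return(integer(0))
  if (is.numeric(label)) {
    code <- as.integer(label)
    bad <- is.na(code) | code != label | code < 1L | code > 7L
    if (any(bad)) {
      abort(sprintf("unknown stage code(s): %s",
                    paste(unique(label[bad]), collapse = ", ")),
            class = "embryoxai_parse_error")
    }
    return(code)
  }
  lab <- trimws(as.character(label))
  lut <- c(stage_codes(),
           setNames(1:7, stage_names()),
           setNames(1:7, as.character(1:7)))
  code <- unname(lut[lab])
  bad <- is.na(code)
  if (any(bad)) {
    abort(sprintf("unknown stage label(s): %s",
                  paste(unique(lab[bad]), collapse = ", ")),
          class = "embryoxai_parse_error")
  }
  as.integer(code)
}

#' @rdname encode_stage
#' @param code Integer vector of stage codes in 1..7.
#' @return `decode_stage()` returns the human-readable stage name for each code.
#' @export
decode_stage <- function(code) {
  stopifnot(all(code %in% 1:7))
  stage_names()[code]
}

rater_columns <- function(data) {
  setdiff(names(data), c("embryo_id", "frame_id", "reference"))
}

assert_rating_table <- function(data, raters = NULL) {
  need <- c("embryo_id", "frame_id", "reference")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    abort(sprintf("rating table is missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "embryoxai_data_error")
  }
  if (nrow(data) == 0L) {
    abort("rating table has no rows", class = "embryoxai_empty_error")
  }
  raters <- raters %||% rater_columns(data)
  miss <- setdiff(raters, names(data))
  if (length(miss) > 0L) {
    abort(sprintf("rater(s) not present in table: %s",
                  paste(miss, collapse = ", ")),
          class = "embryoxai_data_error")
  }
  invisible(raters)
}
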