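#' Developmental stage labels
#'
#' Early seedling development passes through four ordinal stages observed from
#' the top view: bare soil (`Soil`), first appearance of the cotyledon (`FA`),
#' opening of the cotyledons (`OC`) and appearance of the first leaf (`FL`).
#' The stages occur in a fixed ontological order, which the chained
#' classifiers and the temporal post-processing exploit as prior knowledge.
#' Throughout the package stages are represented either as ordered factors
#' (user-facing tables) or as integer codes 0..3 (internal arithmetic, where
#' the ordinal median and the running maximum are computed on codes).
#'
#' @return `stage_levels()` returns the four stage names in ontological order.
#' @examples
#' stage_levels()
#' stage_factor(c("Soil", "OC"))
#' stage_code(stage_factor(c("Soil", "OC")))
#' @export
stage_levels <- function() c("Soil", "FA", "OC", "FL")

#' @rdname stage_levels
#' @param x stage names, codes (0..3) or an existing stage factor.
#' @return `stage_factor()` returns an ordered factor with the four levels.
#' @export
stage_factor <- function(x) {
  if (is.numeric(x)) {
    if (any(!is.na(x) & (x < 0 | x > 3 | x != round(x)))) {
      ss_abort("stage codes must be integers in 0..3", "seedstage_bad_stage")
    }
    x <- stage_levels()[x + 1L]
  }
  if (!all(is.na(x) | x %in% stage_levels())) {
    ss_abort(
      paste0(
        "unknown stage name(s): ",
        paste(unique(setdiff(x, stage_levels())), collapse = ", ")
      ),
      "seedstage_bad_stage"
    )
  }
  factor(x, levels = stage_levels(), ordered = TRUE)
}

#' @rdname stage_levels
#' @return `stage_code()` returns integer ordinal codes 0 (Soil) .. 3 (FL).
#' @export
stage_code <- function(x) {
  if (is.numeric(x)) {
    return(as.integer(stage_code(stage_factor(x)))) # validate via round trip
  }
  as.integer(stage_factor(x)) - 1L
}
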