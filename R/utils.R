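# Internal helpers shared across modules.

new_selection_log <- function() {
  tibble::tibble(snp_id = character(), rule = character(), detail = character())
}

log_removal <- function(log, snp_id, rule, detail = "") {
  dplyr::bind_rows(log, tibble::tibble(
    snp_id = as.character(snp_id),
    rule = rule,
    detail = as.character(detail)
  ))
}

#' Retrieve the selection log of an instrument table
#'
#' Filtering and harmonisation functions record every SNP they remove,
#' together with the rule that removed it, in a `selection_log` attribute.
#' This accessor returns that log as a tibble (empty if nothing was removed
#' or the attribute was lost to later data manipulation).
#'
#' @param x A tibble produced by [harmonise()], [ld_prune()],
#'   [filter_weak()] or [read_summary_table()].
#' @return A tibble with columns `snp_id`, `rule`, `detail`.
#' @export
selection_log <- function(x) {
  attr(x, "selection_log") %||% new_selection_log()
}

# carry (and extend) a selection log across a filtering step
set_selection_log <- function(x, log) {
  attr(x, "selection_log") <- log
  x
}

assert_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing mandatory column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

assert_scalar_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) abort(sprintf("`%s` must be a single number in %s0, 1%s",
                         name, if (open_left) "(" else "[",
                         if (open_right) ")" else "]"))
  invisible(x)
}

# two-sided normal p-value for an estimate/SE pair
z_pvalue <- function(theta, se) 2 * pnorm(-abs(theta / se))
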