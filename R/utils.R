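#' @keywords internal
"_PACKAGE"

# Probability clipping bound used before any inverse-normal transform.
# Keeps scores finite: qnorm(1e-16) is about -8.22.
.PROB_EPS <- 1e-16

#' Clip probabilities away from 0 and 1
#'
#' Probabilities fed into the inverse normal CDF are clipped to
#' `[1e-16, 1 - 1e-16]` so the resulting scores stay finite (|score| <= 8.22).
#'
#' @param p Numeric vector of probabilities.
#' @param warn Warn when values fall outside `[0, 1]` before clipping.
#' @return Clipped numeric vector.
#' @export
clip_prob <- function(p, warn = TRUE) {
  if (warn && any(p < 0 | p > 1, na.rm = TRUE)) {
    warning("probabilities outside [0, 1] were clipped")
  }
  pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)
}

# Stable per-call RNG: evaluates `expr` with the given seed without
# clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Read a TSV with '#' comment lines ignored; always stringsAsFactors = FALSE.
read_tsv_table <- function(path, col_names = TRUE) {
  utils::read.delim(path, header = col_names, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
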