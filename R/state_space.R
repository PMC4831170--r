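#' Build the visual-acuity state space
#'
#' Health states are contiguous bands of best corrected visual acuity (BCVA)
#' on the ETDRS letter scale (0--100), two lines (10 letters) wide by default,
#' plus a single absorbing death state appended last.  Interior band edges are
#' upper bounds: with edges `c(25, 35, ...)` the first band is "letters <= 25"
#' and the second "26--35".  The lowest band is open below and the highest
#' open above, so every letter score maps to exactly one band.
#'
#' @param band_edges Strictly increasing interior edges on the letter scale.
#'   The default `c(25, 35, 45, 55, 65, 75, 85)` yields eight bands with one
#'   boundary at the visual-impairment threshold.
#' @param vi_threshold Letter score at or below which a state counts as
#'   visually impaired (default 35, i.e. "without visual impairment" means
#'   BCVA > 35 letters).
#'
#' @return An object of class `dme_state_space`: a list with `bands` (a tibble
#'   with one row per live band: `state`, `label`, `lower`, `upper`,
#'   `visually_impaired`), `n_states` (live bands + death), `death_index`,
#'   and `vi_threshold`.
#' @examples
#' ss <- build_state_space()
#' ss$bands
#' classify_letters(c(10, 35, 36, 90), ss)
#' @export
build_state_space <- function(band_edges = c(25, 35, 45, 55, 65, 75, 85),
                              vi_threshold = 35) {
  if (length(band_edges) < 1) {
    abort("`band_edges` must define at least 2 bands (>= 1 interior edge).")
  }
  bad <- which(diff(band_edges) <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "`band_edges` must be strictly increasing; offending pair: %s >= %s (positions %d, %d).",
      band_edges[bad[1]], band_edges[bad[1] + 1], bad[1], bad[1] + 1
    ))
  }
  lower <- c(-Inf, band_edges)
  upper <- c(band_edges, Inf)
  n_bands <- length(lower)
  label <- character(n_bands)
  for (i in seq_len(n_bands)) {
    label[i] <- if (is.infinite(lower[i])) {
      sprintf("<=%g", upper[i])
    } else if (is.infinite(upper[i])) {
      sprintf(">=%g", lower[i] + 1)
    } else {
      sprintf("%g-%g", lower[i] + 1, upper[i])
    }
  }
  bands <- tibble(
    state = seq_len(n_bands),
    label = label,
    lower = lower,
    upper = upper,
    visually_impaired = upper <= vi_threshold
  )
  structure(
    list(
      bands = bands,
      n_states = n_bands + 1L,
      n_bands = n_bands,
      death_index = n_bands + 1L,
      vi_threshold = vi_threshold,
      labels = c(label, "death")
    ),
    class = "dme_state_space"
  )
}

#' Map letter scores to states
#'
#' @param letters Numeric vector of BCVA letter scores in \[0, 100\].
#' @param state_space A `dme_state_space`.
#' @return Integer vector of band indices (1 = worst band).
#' @export
classify_letters <- function(letters, state_space) {
  if (any(letters < 0 | letters > 100, na.rm = TRUE)) {
    abort("letter scores must lie in [0, 100].")
  }
  # band i is (lower_i, upper_i]; count edges strictly below the score
  findInterval(letters, state_space$bands$upper[-state_space$n_bands],
               left.open = TRUE) + 1L
}

#' Which states count as visually impaired?
#'
#' @param state_space A `dme_state_space`.
#' @return Logical vector over all states (death is `FALSE`; it is counted
#'   separately, not as time with visual impairment).
#' @export
is_vi_state <- function(state_space) {
  c(state_space$bands$visually_impaired, FALSE)
}

#' @export
print.dme_state_space <- function(x, ...) {
  cat(sprintf(
    "<dme_state_space> %d BCVA bands + death; visual impairment at <= %g letters\n",
    x$n_bands, x$vi_threshold
  ))
  print(x$bands, ...)
  invisible(x)
}
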