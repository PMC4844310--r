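#' Default developmental-stage vocabulary
#'
#' Named numeric vector mapping non-numeric stage labels to an ordering
#' midpoint on the days-after-pollination (DAP) axis. Numeric labels such as
#' `"3 DAP"` or interval labels such as `"3-4 DAP"` / `"2 to 4 DAP"` are
#' parsed directly and do not need an entry here. Pre-pollination states sit
#' at negative midpoints so they order before every DAP stage.
#'
#' @return Named numeric vector of stage midpoints.
#' @export
default_stage_vocabulary <- function() {
  c("vegetative" = -10, "seedling" = -10, "before anthesis" = -1,
    "anthesis" = 0)
}

#' Default stage windows used for rendering expression labels
#'
#' Coarse caryopsis-development windows into which fine-grained stages
#' (e.g. a daily time-course) are folded when an exclusivity call is
#' rendered as a label such as `"3-4 DAP, 5-10 DAP, endosperm"`.
#'
#' @return Character vector of window labels, ordered by midpoint.
#' @export
default_stage_windows <- function() {
  c("before anthesis", "1-2 DAP", "3-4 DAP", "5-10 DAP", "11-20 DAP")
}

# Parse one stage label to its DAP midpoint; NA when unparseable and not in
# the vocabulary.
stage_midpoint <- function(stage, vocabulary = default_stage_vocabulary()) {
  vapply(as.character(stage), function(s) {
    s <- trimws(s)
    if (s %in% names(vocabulary)) {
      return(unname(vocabulary[[s]]))
    }
    # "3 DAP", "3-4 DAP", "2 to 4 DAP", bare "3.5"; the hyphen is a range
    # separator, never a minus sign (pre-pollination states live in the
    # vocabulary at negative midpoints instead)
    nums <- regmatches(s, gregexpr("[0-9]+(\\.[0-9]+)?", s))[[1]]
    if (length(nums) == 0L) {
      return(NA_real_)
    }
    mean(as.numeric(nums))
  }, numeric(1), USE.NAMES = FALSE)
}

# Interval [lo, hi] covered by a stage window label; "before anthesis"-style
# vocabulary entries cover everything up to and including their midpoint.
stage_window_bounds <- function(window,
                                vocabulary = default_stage_vocabulary()) {
  w <- trimws(window)
  if (w %in% names(vocabulary)) {
    return(c(-Inf, unname(vocabulary[[w]])))
  }
  nums <- as.numeric(regmatches(w, gregexpr("[0-9]+(\\.[0-9]+)?", w))[[1]])
  if (length(nums) == 0L) {
    stop("stage window '", window, "' is neither numeric nor in the vocabulary")
  }
  range(nums)
}

# Fold a numeric stage midpoint into the first containing window (windows are
# checked in midpoint order); NA when no window contains it.
stage_to_window <- function(midpoint, windows = default_stage_windows(),
                            vocabulary = default_stage_vocabulary()) {
  bounds <- lapply(windows, stage_window_bounds, vocabulary = vocabulary)
  ord <- order(vapply(bounds, mean, numeric(1)))
  windows <- windows[ord]
  bounds <- bounds[ord]
  vapply(midpoint, function(m) {
    if (is.na(m)) {
      return(NA_character_)
    }
    for (i in seq_along(windows)) {
      if (m >= bounds[[i]][1] && m <= bounds[[i]][2]) {
        return(windows[i])
      }
    }
    NA_character_
  }, character(1))
}
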