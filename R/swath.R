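#' Build a SWATH isolation-window scheme
#'
#' Windows are the half-open intervals `[low, low + width)` with lows spaced
#' `stride` apart starting at `start`; lows are generated while they are
#' below `end` and the last window is clipped at `end`.  With
#' `stride < width` adjacent windows overlap by `width - stride`.
#'
#' The default acquisition scheme used for global quantification here is 26
#' m/z windows with a 1 m/z overlap across roughly 400–1250 m/z
#' (`swath_scheme(399.5, 1250, 26, 25)`); the derivatized-GLA scheme is
#' non-overlapping 6.2 m/z windows across 400–917
#' (`swath_scheme(400, 917, 6.2, 6.2)`).
#'
#' @param start,end Scheme range in m/z (`end > start`).
#' @param width Window width in m/z (> 0).
#' @param stride Spacing between window lows, `0 < stride <= width`
#'   (default: `width`, i.e. no overlap).
#' @return A tibble of class `swath_scheme` with columns `window` (index),
#'   `low`, `high`, and attributes `start`, `end`, `width`, `stride`.
#' @export
#' @examples
#' swath_scheme(399.5, 1250, 26, 25)   # 35 windows
swath_scheme <- function(start, end, width, stride = width) {
  if (!(end > start)) abort("end must exceed start")
  if (!(width > 0)) abort("width must be positive")
  if (!(stride > 0 && stride <= width)) {
    abort("stride must satisfy 0 < stride <= width")
  }
  lows <- seq(start, end - 1e-9, by = stride)
  lows <- lows[lows < end]
  out <- tibble(
    window = seq_along(lows),
    low = lows,
    high = pmin(lows + width, end)
  )
  attr(out, "start") <- start
  attr(out, "end") <- end
  attr(out, "width") <- width
  attr(out, "stride") <- stride
  class(out) <- c("swath_scheme", class(out))
  out
}

#' Windows of a scheme containing given m/z values
#'
#' @param mz Numeric vector of precursor m/z values.
#' @param scheme A [swath_scheme()].
#' @return A tibble with one row per (mz, window) containment: columns `mz`
#'   and `window`.  An m/z in an overlap strip maps to two windows; an m/z
#'   outside the scheme range yields no rows and a warning.
#' @export
assign_windows <- function(mz, scheme) {
  stopifnot(inherits(scheme, "swath_scheme"))
  out <- purrr::map_dfr(mz, function(x) {
    hit <- which(scheme$low <= x & x < scheme$high)
    if (length(hit) == 0L) {
      warn(paste0("m/z ", format(x), " falls outside the scheme range"))
      return(tibble(mz = numeric(), window = integer()))
    }
    tibble(mz = x, window = hit)
  })
  out
}

#' Detect co-isolated, co-eluting peptidoforms in an ion library
#'
#' Two library entries must be quantified jointly when their precursors fall
#' in the same isolation window and elute at a similar retention time: their
#' transitions cannot be attributed to either precursor alone.  Within each
#' window, entries are grouped greedily along the RT axis so that every
#' group's RT span is at most `rt_tolerance` (hence pairwise |dRT| <=
#' `rt_tolerance`); groups with a single member are dropped, duplicated
#' groups found through several windows are reported once.  The result is
#' independent of entry order.
#'
#' @param entries A tibble with one row per library entry, columns `entry`
#'   (unique key), `precursor_mz`, `rt` (minutes).  See [library_entries()].
#' @param scheme A [swath_scheme()].
#' @param rt_tolerance Maximum RT span of a conflict group, minutes
#'   (default 1).
#' @return A tibble with columns `group` (integer id), `entry`, `window`
#'   (a shared window index) and `rt_span`; zero rows when no conflicts.
#' @export
detect_conflicts <- function(entries, scheme, rt_tolerance = 1) {
  stopifnot(all(c("entry", "precursor_mz", "rt") %in% names(entries)))
  if (anyDuplicated(entries$entry)) abort("entry keys must be unique")
  ent <- entries %>% arrange(.data$rt, .data$entry)
  win <- purrr::map_dfr(seq_len(nrow(ent)), function(i) {
    hit <- which(scheme$low <= ent$precursor_mz[i] & ent$precursor_mz[i] < scheme$high)
    tibble(entry = ent$entry[i], rt = ent$rt[i], window = hit)
  })
  groups <- list()
  for (w in sort(unique(win$window))) {
    members <- win %>% filter(.data$window == w) %>% arrange(.data$rt, .data$entry)
    if (nrow(members) < 2L) next
    anchor <- members$rt[1]
    cur <- members[1, ]
    for (i in 2:nrow(members)) {
      if (members$rt[i] - anchor <= rt_tolerance) {
        cur <- dplyr::bind_rows(cur, members[i, ])
      } else {
        if (nrow(cur) >= 2L) groups[[length(groups) + 1L]] <- cur
        cur <- members[i, ]
        anchor <- members$rt[i]
      }
    }
    if (nrow(cur) >= 2L) groups[[length(groups) + 1L]] <- cur
  }
  if (length(groups) == 0L) {
    return(tibble(
      group = integer(), entry = character(),
      window = integer(), rt_span = numeric()
    ))
  }
  # deduplicate groups with identical member sets (found via two windows)
  keys <- purrr::map_chr(groups, ~ paste(sort(.x$entry), collapse = "\r"))
  groups <- groups[!duplicated(keys)]
  purrr::imap_dfr(groups, function(g, i) {
    tibble(
      group = i, entry = g$entry, window = g$window[1],
      rt_span = max(g$rt) - min(g$rt)
    )
  })
}
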