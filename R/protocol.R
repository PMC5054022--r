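#' Stimulus protocol
#'
#' An ordered list of constant-level segments, in current clamp (levels in pA)
#' or voltage clamp (levels in mV). A sweep axis turns one protocol into a
#' family by replacing the level of one segment.
#'
#' @param mode \code{"cc"} (current clamp) or \code{"vc"} (voltage clamp).
#' @param durations Segment durations, ms (> 0).
#' @param levels Segment levels (pA in cc, mV in vc); same length.
#' @param sweep_segment Optional index of the segment swept across sweeps.
#' @param sweep_levels Levels taken by the swept segment.
#' @param label Free-text label.
#' @return An object of class \code{protocol}.
#' @export
protocol <- function(mode = c("cc", "vc"), durations, levels,
                     sweep_segment = NULL, sweep_levels = NULL, label = "") {
  mode <- match.arg(mode)
  stopifnot(length(durations) >= 1,
            length(durations) == length(levels), all(durations > 0),
            all(is.finite(levels)))
  if (!is.null(sweep_segment)) {
    stopifnot(sweep_segment >= 1, sweep_segment <= length(durations),
              length(sweep_levels) >= 1)
  }
  structure(list(mode = mode, durations = as.numeric(durations),
                 levels = as.numeric(levels),
                 sweep_segment = sweep_segment,
                 sweep_levels = sweep_levels, label = label),
            class = "protocol")
}

#' Expand a protocol's sweep axis into a list of single-sweep protocols
#'
#' @param p A \code{\link{protocol}}.
#' @return List of protocols, one per sweep level (a length-1 list when no
#'   sweep axis is set).
#' @export
protocol_sweeps <- function(p) {
  stopifnot(inherits(p, "protocol"))
  if (is.null(p$sweep_segment)) return(list(p))
  lapply(p$sweep_levels, function(lv) {
    q <- p
    q$levels[q$sweep_segment] <- lv
    q$sweep_segment <- NULL
    q$sweep_levels <- NULL
    q$label <- sprintf("%s [sweep %g]", p$label, lv)
    q
  })
}

# cumulative segment boundary times (ms), starting at 0
.seg_bounds <- function(rec_or_proto) {
  d <- if (inherits(rec_or_proto, "protocol")) rec_or_proto$durations
       else rec_or_proto$segments$duration
  c(0, cumsum(d))
}
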