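#' Reconstruct headings and angular velocities from sampled positions
#'
#' The observed signal is the change of turning speed, i.e. the third
#' derivative of position. From a uniformly sampled track this is built
#' without smoothing: the heading assigned to frame k is the direction
#' of the displacement from frame k to k+1 (unwrapped), the speed its
#' length times the frame rate, and the angular velocity at frame k the
#' difference of the two adjacent displacement headings times the frame
#' rate -- the centred turning estimate from three consecutive
#' positions. Because a displacement heading estimates the true heading
#' half a frame late, this difference is a one-frame average of omega
#' centred exactly on frame k, and consecutive estimates use
#' non-overlapping windows. Frames with zero displacement are flagged
#' and split the series; missing frames split it, too.
#'
#' @param tracks a track table with columns `t`, `id`, `x`, `y`, and --
#'   when `use_recorded = TRUE` -- `heading` and `omega`.
#' @param fps frame rate; default taken from the table attribute or
#'   inferred from the time grid.
#' @param use_recorded use the table's own `heading`/`omega` columns
#'   (e.g. simulator state output, or orientations measured directly by
#'   a tracker) instead of reconstructing them from displacements.
#'   Default `FALSE`: kinematics are re-derived from positions.
#' @return object of class `kinematics_series`: list with `fps`, `vbar`
#'   (named per-fish mean speed), `per_fish` (list of segment lists,
#'   each segment holding `frames`, `t`, `heading` (unwrapped), `speed`,
#'   `omega` -- `omega[k]` is aligned with `heading[k]`, `NA` at the
#'   first frame of a segment), and `states`: a data.frame
#'   `t, id, x, y, heading`
#'   of frames with a defined heading estimate, used downstream to
#'   evaluate the stimuli every fish experienced.
#' @export
track_kinematics <- function(tracks, fps = NULL, use_recorded = FALSE) {
  stopifnot(all(c("t", "id", "x", "y") %in% names(tracks)))
  if (use_recorded &&
      !all(c("heading", "omega") %in% names(tracks)))
    stop("use_recorded = TRUE needs 'heading' and 'omega' columns")
  if (is.null(fps)) fps <- attr(tracks, "fps")
  tracks <- tracks[order(tracks$id, tracks$t), ]
  ids <- sort(unique(tracks$id))
  if (is.null(fps)) {
    dts <- diff(sort(unique(tracks$t)))
    fps <- 1 / stats::median(dts)
  }
  dt <- 1 / fps
  per_fish <- list()
  states <- list()
  vbar <- numeric(0)
  for (fid in ids) {
    tr <- tracks[tracks$id == fid, ]
    if (nrow(tr) < 4) stop("fish ", fid, " has fewer than 4 frames")
    fr_index <- round(tr$t * fps)
    off <- abs(tr$t * fps - fr_index)
    if (any(off > 1e-6))
      stop("fish ", fid, " has off-grid frame times at t = ",
           paste(utils::head(tr$t[off > 1e-6], 5), collapse = ", "))
    # segment boundaries: frame gaps or zero displacements
    gap_after <- diff(fr_index) != 1
    dx <- diff(tr$x); dy <- diff(tr$y)
    zero_disp <- (dx == 0 & dy == 0)
    if (any(gap_after))
      message("fish ", fid, ": ", sum(gap_after), " frame gap(s), series split")
    cut_after <- gap_after | zero_disp
    seg_id <- cumsum(c(0, cut_after))
    segs <- list()
    for (s in unique(seg_id)) {
      rows <- which(seg_id == s)
      # displacement rows: all but the last row of the segment
      if (length(rows) < 4) next
      hrows <- rows[-length(rows)]
      speed <- sqrt(dx[hrows]^2 + dy[hrows]^2) * fps
      if (use_recorded) {
        th_raw <- tr$heading[hrows]
        omega <- tr$omega[hrows]
        heading <- th_raw[1] + c(0, cumsum(wrap_angle(diff(th_raw))))
      } else {
        th_raw <- atan2(dy[hrows], dx[hrows])
        heading <- th_raw[1] + c(0, cumsum(wrap_angle(diff(th_raw))))
        H <- length(heading)
        omega <- rep(NA_real_, H)
        omega[2:H] <- (heading[2:H] - heading[1:(H - 1)]) * fps
      }
      segs[[length(segs) + 1]] <- list(
        frames = fr_index[hrows], t = tr$t[hrows], heading = heading,
        speed = speed, omega = omega)
      states[[length(states) + 1]] <- data.frame(
        t = tr$t[hrows], id = fid, x = tr$x[hrows], y = tr$y[hrows],
        heading = wrap_angle(heading), omega = omega)
    }
    if (length(segs) == 0)
      stop("fish ", fid, ": no usable segment of >= 4 frames")
    per_fish[[as.character(fid)]] <- segs
    vbar[as.character(fid)] <-
      mean(unlist(lapply(segs, function(s) s$speed)))
  }
  states <- do.call(rbind, states)
  attr(states, "fps") <- fps
  structure(list(fps = fps, dt = dt, vbar = vbar, per_fish = per_fish,
                 states = states, recorded = use_recorded),
            class = "kinematics_series")
}

#' @export
print.kinematics_series <- function(x, ...) {
  cat(sprintf("kinematics_series: %d fish at %.3g fps, mean speeds %s m/s\n",
              length(x$per_fish), x$fps,
              paste(sprintf("%.3g", x$vbar), collapse = ", ")))
  invisible(x)
}
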