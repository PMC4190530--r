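# Centroid-distance trajectory statistics and complexation-state calling.

#' Centroid-centroid distance time series of two molecules
#'
#' Computes, frame by frame, the Euclidean distance between the unweighted
#' geometric centroids of two atom-coordinate trajectories. The two
#' trajectories must share the same timebase. Coordinates are assumed
#' whole-molecule and unwrapped (no periodic-boundary handling).
#'
#' @param traj_a,traj_b Data frames with columns `time_ns`, `x`, `y`, `z`
#'   (one row per atom per frame; a single row per frame is a point
#'   particle). As read by [read_xyz_trajectory()].
#' @param pair_label Optional label naming the molecule pair.
#' @return A `distance_series` tibble: `time_ns`, `distance_A`.
#' @export
#' @examples
#' a <- tibble::tibble(time_ns = c(0, 1), x = 0, y = 0, z = 0)
#' b <- tibble::tibble(time_ns = c(0, 1), x = 3, y = 4, z = 0)
#' centroid_distance_series(a, b)$distance_A # 5 5
centroid_distance_series <- function(traj_a, traj_b, pair_label = NULL) {
  for (nm in c("traj_a", "traj_b")) {
    .require_columns(get(nm), c("time_ns", "x", "y", "z"), sprintf("`%s`", nm))
  }
  cent <- function(tr) {
    dplyr::summarise(dplyr::group_by(as_tibble(tr), .data$time_ns),
                     x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                     .groups = "drop")
  }
  ca <- cent(traj_a)
  cb <- cent(traj_b)
  if (nrow(ca) != nrow(cb) || !isTRUE(all.equal(ca$time_ns, cb$time_ns))) {
    abort(sprintf(
      "Frame mismatch: trajectories have %d vs %d frames (timebases must match).",
      nrow(ca), nrow(cb)
    ))
  }
  out <- tibble(
    time_ns = ca$time_ns,
    distance_A = sqrt((ca$x - cb$x)^2 + (ca$y - cb$y)^2 + (ca$z - cb$z)^2)
  )
  attr(out, "pair_label") <- pair_label
  class(out) <- c("distance_series", class(out))
  out
}

#' Windowed mean and standard deviation of a distance series
#'
#' Arithmetic mean and sample standard deviation of the distance over a time
#' window; both window ends are inclusive, so boundary frames count once.
#'
#' @param series A `distance_series` (or any data frame with `time_ns`,
#'   `distance_A`).
#' @param t_start,t_end Window limits, ns.
#' @return A one-row tibble: `t_start`, `t_end`, `mean_A`, `sd_A`,
#'   `n_frames`.
#' @export
#' @examples
#' s <- tibble::tibble(time_ns = 0:2, distance_A = c(4, 5, 6))
#' windowed_stats(s, 0, 2) # mean 5, sd 1
windowed_stats <- function(series, t_start, t_end) {
  .require_columns(series, c("time_ns", "distance_A"), "`series`")
  .check_scalar(t_start, "t_start")
  .check_scalar(t_end, "t_end")
  if (t_end < t_start) abort("`t_end` must be >= `t_start`.")
  sel <- series$time_ns >= t_start & series$time_ns <= t_end
  if (sum(sel) < 2) {
    abort(sprintf(
      "Window [%g, %g] ns contains %d frame(s); need >= 2 (series covers [%g, %g] ns).",
      t_start, t_end, sum(sel), min(series$time_ns), max(series$time_ns)
    ))
  }
  vals <- series$distance_A[sel]
  tibble(t_start = t_start, t_end = t_end,
         mean_A = mean(vals), sd_A = sd(vals), n_frames = sum(sel))
}

#' Classify complexation states from centroid-distance series
#'
#' Assigns each frame a state from threshold bands on the primary
#' drug-to-host distance — `inclusion` below `t_inc`, `association` below
#' `t_assoc`, otherwise `unbound` — and upgrades inclusion/association
#' frames to `dual` when a second host's distance (the `secondary` series)
#' drops below `t_cover`, the signature of a 1:2 complex in which the second
#' cyclodextrin covers, without enclosing, the drug. Runs shorter than
#' `min_dwell` are merged into their neighbours to suppress flicker.
#'
#' The default thresholds are engineering calibrations chosen to separate
#' typical centroid-distance regimes (enclosed ~3.6-5.3 A, covering second
#' host ~6.7 A); they are configurable and carry no special status.
#'
#' @param primary Distance series for the drug and first host (`time_ns`,
#'   `distance_A`).
#' @param secondary Optional aligned distance series for the drug and second
#'   host.
#' @param t_inc Inclusion threshold, A (default 5.8).
#' @param t_cover Covering threshold on the secondary distance, A
#'   (default 7.5).
#' @param t_assoc Association threshold, A (default 9.0). Must exceed
#'   `t_inc`.
#' @param min_dwell Minimum state dwell time, ns (default 0.05); shorter
#'   runs are absorbed by the preceding (or, at the start, following) run.
#' @return A `state_call` tibble of intervals: `t_start`, `t_end`, `state`,
#'   with the thresholds in `attr(, "thresholds")`.
#' @export
classify_states <- function(primary, secondary = NULL,
                            t_inc = 5.8, t_cover = 7.5, t_assoc = 9.0,
                            min_dwell = 0.05) {
  .require_columns(primary, c("time_ns", "distance_A"), "`primary`")
  .check_scalar(t_inc, "t_inc", positive = TRUE)
  .check_scalar(t_cover, "t_cover", positive = TRUE)
  .check_scalar(t_assoc, "t_assoc", positive = TRUE)
  .check_scalar(min_dwell, "min_dwell", nonneg = TRUE)
  if (t_inc >= t_assoc) {
    abort(sprintf(
      "Thresholds misordered: need t_inc (%g) < t_assoc (%g).", t_inc, t_assoc
    ))
  }
  d <- primary$distance_A
  state <- ifelse(d < t_inc, "inclusion",
                  ifelse(d < t_assoc, "association", "unbound"))
  if (!is.null(secondary)) {
    .require_columns(secondary, c("time_ns", "distance_A"), "`secondary`")
    if (nrow(secondary) != nrow(primary) ||
        !isTRUE(all.equal(secondary$time_ns, primary$time_ns))) {
      abort("`secondary` must be aligned with `primary` (same frames/times).")
    }
    covered <- secondary$distance_A < t_cover
    state[covered & state %in% c("inclusion", "association")] <- "dual"
  }

  t <- primary$time_ns
  run_duration <- function(r, i) {
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    t[idx_end[i]] - t[idx_start[i]]
  }
  # absorb sub-dwell runs into the previous run (next run at the start)
  repeat {
    r <- rle(state)
    if (length(r$lengths) <= 1) break
    short <- which(vapply(seq_along(r$lengths),
                          function(i) run_duration(r, i) < min_dwell,
                          logical(1)))
    if (length(short) == 0) break
    i <- short[1]
    r$values[i] <- if (i == 1) r$values[i + 1] else r$values[i - 1]
    state <- inverse.rle(r)
  }

  r <- rle(state)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  out <- tibble(
    t_start = t[idx_start],
    t_end = t[idx_end],
    state = r$values
  )
  attr(out, "thresholds") <- list(t_inc = t_inc, t_cover = t_cover,
                                  t_assoc = t_assoc, min_dwell = min_dwell)
  class(out) <- c("state_call", class(out))
  out
}
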