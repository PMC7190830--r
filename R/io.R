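#' Read trajectories from CSV
#'
#' Expects a header `worm_id,t_s,x_mm,y_mm`. Rows are grouped by worm and
#' sorted by time; the time grid is snapped to the nearest multiple of `dt`
#' (with a warning) so that all downstream windowed rules operate on a uniform
#' grid. Speed is left unset until preprocessing.
#'
#' @param path CSV file path.
#' @param dt target sample spacing in s (default 0.5, i.e. 2 frames/s).
#' @return a list of [trajectory()] objects (possibly empty).
#' @export
read_trajectories <- function(path, dt = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("worm_id", "t_s", "x_mm", "y_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trajectory CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) return(list())
  for (col in c("t_s", "x_mm", "y_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                   col, bad[1], as.character(df[[col]][bad[1]])))
    df[[col]] <- v
  }
  out <- lapply(split(df, df$worm_id), function(d) {
    d <- d[order(d$t_s), , drop = FALSE]
    if (anyDuplicated(d$t_s))
      stop(sprintf("worm '%s': duplicated time %g s", d$worm_id[1],
                   d$t_s[which(duplicated(d$t_s))[1]]))
    t <- d$t_s
    if (length(t) > 1) {
      snapped <- round(t / dt) * dt
      if (max(abs(snapped - t)) > 1e-6) {
        warning(sprintf("worm '%s': time grid snapped to %.3g s spacing",
                        d$worm_id[1], dt))
        if (anyDuplicated(snapped))
          stop(sprintf("worm '%s': regridding to %.3g s collapses samples",
                       d$worm_id[1], dt))
        t <- snapped
      }
      dts <- diff(t)
      if (any(dts <= 0))
        stop(sprintf("worm '%s': non-monotone time after sort", d$worm_id[1]))
      if (max(dts) - min(dts) > 1e-6)
        stop(sprintf("worm '%s': non-uniform time grid (spacings %g to %g s)",
                     d$worm_id[1], min(dts), max(dts)))
    }
    trajectory(d$worm_id[1], t, cbind(d$x_mm, d$y_mm), source = "imported")
  })
  unname(out[order(names(out))])
}

#' Write trajectories to CSV
#'
#' Inverse of [read_trajectories()]; values are written with 6 decimal places
#' so CSV round trips preserve all fields to that precision.
#'
#' @param trajs a list of [trajectory()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  rows <- lapply(trajs, function(tr)
    data.frame(worm_id = tr$worm_id, t_s = sprintf("%.6f", tr$t),
               x_mm = sprintf("%.6f", tr$xy[, 1]),
               y_mm = sprintf("%.6f", tr$xy[, 2])))
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) df <- data.frame(worm_id = character(), t_s = character(),
                                    x_mm = character(), y_mm = character())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-sample behavioral state labels to CSV
#'
#' Header `worm_id,t_s,state`.
#'
#' @param anns a list of behavior annotations (see [segment_trajectory()]),
#'   or of trajectories carrying `$state_truth`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(anns, path) {
  rows <- lapply(anns, function(a) {
    state <- if (!is.null(a$state)) a$state else a$state_truth
    data.frame(worm_id = a$worm_id, t_s = sprintf("%.6f", a$t), state = state)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) df <- data.frame(worm_id = character(), t_s = character(),
                                    state = character())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-sample behavioral state labels from CSV
#'
#' @param path CSV with header `worm_id,t_s,state`.
#' @return a named list (by worm id) of data frames with `t` and `state`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("worm_id", "t_s", "state")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("annotation CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  lapply(split(df, df$worm_id), function(d) {
    d <- d[order(d$t_s), , drop = FALSE]
    data.frame(t = as.numeric(d$t_s), state = d$state)
  })
}
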