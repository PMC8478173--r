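#' Vasoactive response traces
#'
#' A vaso trace records outer diameter against time while a cannulated
#' vessel, held at fixed pressure (15 mmHg) and its specimen-specific axial
#' stretch, responds to a vasoactive agent.  Contraction assays (KCl,
#' phenylephrine) are normalized to the pre-stimulus diameter at t = 0;
#' the L-NAME dilation assay is normalized to the post-PE/ACh diameter at
#' t = 0.  The sign convention reports contraction as a positive percent
#' reduction.
#'
#' @param time_min time points in minutes, strictly increasing from 0.
#' @param outer_diameter_um outer diameters (um), positive.
#' @param agent one of \code{"KCl"}, \code{"PE"}, \code{"ACh"},
#'   \code{"L-NAME"}.
#' @param vessel_id,group optional identifiers carried into summaries.
#' @return object of class \code{"vaso_trace"} (a data.frame with
#'   attributes).
#' @export
vaso_trace <- function(time_min, outer_diameter_um,
                       agent = c("KCl", "PE", "ACh", "L-NAME"),
                       vessel_id = NA_character_, group = NA_character_) {
  agent <- match.arg(agent)
  stopifnot(length(time_min) == length(outer_diameter_um),
            all(outer_diameter_um > 0))
  if (time_min[1] != 0) stop("trace must start at t = 0 (baseline sample)")
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  structure(data.frame(time_min = time_min,
                       outer_diameter_um = outer_diameter_um),
            agent = agent, vessel_id = vessel_id, group = group,
            class = c("vaso_trace", "data.frame"))
}

#' Normalize a vaso trace by its baseline diameter
#'
#' Divides every diameter by the t = 0 sample (the baseline per the
#' agent-specific convention), so the normalized trace starts at exactly 1.
#' Idempotent.
#'
#' @param trace a \code{\link{vaso_trace}}.
#' @return the trace with an added \code{normalized} column.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "vaso_trace"))
  d0 <- trace$outer_diameter_um[trace$time_min == 0]
  if (length(d0) != 1) stop("missing baseline sample at t = 0")
  trace$normalized <- trace$outer_diameter_um / d0
  trace
}

#' Percent diameter change at a given time
#'
#' \eqn{100 (1 - d(t)/d(0))}: positive for contraction.  \eqn{d(t)} is
#' linearly interpolated between neighboring samples when no sample falls
#' exactly at \code{t}.  Default t = 15 min, the end of the contraction
#' period.
#'
#' @param trace a \code{\link{vaso_trace}}.
#' @param t_min evaluation time (minutes), within the trace span.
#' @return percent reduction in outer diameter (\%).
#' @export
percent_change_at <- function(trace, t_min = 15) {
  stopifnot(inherits(trace, "vaso_trace"))
  if (t_min < min(trace$time_min) || t_min > max(trace$time_min))
    stop(sprintf("t = %g min lies outside the trace span [%g, %g]",
                 t_min, min(trace$time_min), max(trace$time_min)))
  d0 <- trace$outer_diameter_um[trace$time_min == 0]
  if (length(d0) != 1) stop("missing baseline sample at t = 0")
  dt <- stats::approx(trace$time_min, trace$outer_diameter_um,
                      xout = t_min)$y
  100 * (1 - dt / d0)
}

#' Group mean +/- SEM time course and endpoint summary
#'
#' Resamples every trace onto a common time grid by linear interpolation,
#' then reports the per-time mean and standard error of the mean for each
#' group, plus the per-vessel endpoint percent changes (the quantities that
#' enter the group statistics).
#'
#' @param traces list of \code{\link{vaso_trace}} objects (each must carry
#'   a \code{group} attribute).
#' @param t_grid_min common time grid; defaults to 0..15 min at 0.5 min.
#' @param endpoint_min endpoint time for percent change.
#' @return list with \code{time_course} (data.frame: group, time_min,
#'   mean_normalized, sem_normalized, n) and \code{endpoints} (data.frame:
#'   vessel_id, group, percent_change).
#' @export
group_response_summary <- function(traces, t_grid_min = seq(0, 15, by = 0.5),
                                   endpoint_min = 15) {
  stopifnot(length(traces) >= 2, all(vapply(traces, inherits, TRUE,
                                            "vaso_trace")))
  groups <- vapply(traces, attr, "", "group")
  if (any(table(groups) < 2))
    stop("SEM undefined: every group needs at least 2 traces")
  norm <- lapply(traces, function(tr) {
    tr <- normalize_trace(tr)
    stats::approx(tr$time_min, tr$normalized, xout = t_grid_min)$y
  })
  tc <- do.call(rbind, lapply(unique(groups), function(g) {
    m <- do.call(cbind, norm[groups == g])
    data.frame(group = g, time_min = t_grid_min,
               mean_normalized = rowMeans(m),
               sem_normalized = apply(m, 1, stats::sd) / sqrt(ncol(m)),
               n = ncol(m))
  }))
  ep <- data.frame(
    vessel_id = vapply(traces, attr, "", "vessel_id"),
    group = groups,
    percent_change = vapply(traces, percent_change_at, numeric(1),
                            t_min = endpoint_min))
  list(time_course = tc, endpoints = ep)
}
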