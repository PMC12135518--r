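#' Intravenous infusion regimen
#'
#' Builds the timed infusion events of a loading + maintenance schedule.
#' Loading doses are given every `loading_interval` hours starting at time 0;
#' the first maintenance dose is given one maintenance interval after the last
#' loading dose, so that with three q12h loading doses (0, 12, 24 h) and a
#' 24 h maintenance interval the maintenance doses fall at 48, 72, ... h and a
#' pre-dose trough exists at exactly 72 h and 168 h.
#'
#' @param loading_dose loading dose (mg).
#' @param loading_count number of loading doses (typically 3 or 5).
#' @param loading_interval hours between loading doses (default 12).
#' @param maintenance_dose maintenance dose (mg); 0 suppresses maintenance.
#' @param maintenance_interval hours between maintenance doses (default 24).
#' @param infusion_duration infusion length in hours (default 1).
#' @param horizon end of the dosing horizon (h); maintenance doses are
#'   generated for start times strictly below `horizon`.
#' @return An object of class `pk_regimen`: a list with an `events`
#'   data.frame (`start`, `amount`, `duration`, `rate`) and the constructor
#'   arguments.
#' @seealso [regimen_from_events()], [as_regimen()]
#' @examples
#' r <- regimen(400, loading_count = 3, maintenance_dose = 400)
#' head(r$events)
#' @export
regimen <- function(loading_dose = 400, loading_count = 3,
                    loading_interval = 12, maintenance_dose = 400,
                    maintenance_interval = 24, infusion_duration = 1,
                    horizon = 192) {
  check_that(loading_dose >= 0 && maintenance_dose >= 0, "doses must be >= 0")
  check_that(loading_count >= 1, "loading_count must be >= 1")
  check_that(loading_interval > 0 && maintenance_interval > 0 &&
               infusion_duration > 0, "intervals and duration must be > 0")
  last_load <- (loading_count - 1) * loading_interval
  starts <- seq(0, last_load, by = loading_interval)
  amounts <- rep(loading_dose, length(starts))
  m_start <- last_load + maintenance_interval
  if (maintenance_dose > 0 && m_start < horizon) {
    k <- floor((horizon - m_start) / maintenance_interval - 1e-9)
    m_times <- m_start + maintenance_interval * (0:max(k, 0))
    starts <- c(starts, m_times)
    amounts <- c(amounts, rep(maintenance_dose, length(m_times)))
  }
  ev <- data.frame(start = starts, amount = amounts,
                   duration = infusion_duration,
                   rate = amounts / infusion_duration)
  structure(list(events = ev, loading_dose = loading_dose,
                 loading_count = loading_count,
                 loading_interval = loading_interval,
                 maintenance_dose = maintenance_dose,
                 maintenance_interval = maintenance_interval,
                 infusion_duration = infusion_duration, horizon = horizon),
            class = "pk_regimen")
}

#' Regimen from explicit dose events
#'
#' @param start,amount,duration numeric vectors of equal length: event start
#'   times (h), dose amounts (mg) and infusion durations (h).
#' @param horizon dosing horizon (h).
#' @return A `pk_regimen` object without loading/maintenance structure.
#' @export
regimen_from_events <- function(start, amount, duration, horizon = max(start) + 24) {
  check_that(length(start) == length(amount) && length(start) == length(duration),
             "start, amount, duration must have equal length")
  check_that(all(amount >= 0), "amounts must be >= 0")
  check_that(all(duration > 0), "durations must be > 0")
  check_that(!anyDuplicated(start), "no two events may share a start time")
  o <- order(start)
  ev <- data.frame(start = start[o], amount = amount[o], duration = duration[o],
                   rate = amount[o] / duration[o])
  structure(list(events = ev, horizon = horizon), class = "pk_regimen")
}

#' Serialize / deserialize a regimen as a flat config record
#'
#' @param x a `pk_regimen` built by [regimen()], or (for `as_regimen`) a named
#'   list with fields `loading_dose_mg`, `loading_count`, `loading_interval_h`,
#'   `maintenance_dose_mg`, `maintenance_interval_h`, `infusion_h`,
#'   `horizon_h`.
#' @return `regimen_config()` returns the named list; `as_regimen()` the
#'   reconstructed `pk_regimen`.
#' @export
regimen_config <- function(x) {
  check_that(inherits(x, "pk_regimen") && !is.null(x$loading_dose),
             "x must be a structured (loading/maintenance) regimen")
  list(loading_dose_mg = x$loading_dose, loading_count = x$loading_count,
       loading_interval_h = x$loading_interval,
       maintenance_dose_mg = x$maintenance_dose,
       maintenance_interval_h = x$maintenance_interval,
       infusion_h = x$infusion_duration, horizon_h = x$horizon)
}

#' @rdname regimen_config
#' @export
as_regimen <- function(x) {
  need <- c("loading_dose_mg", "loading_count", "loading_interval_h",
            "maintenance_dose_mg", "maintenance_interval_h", "infusion_h",
            "horizon_h")
  check_that(all(need %in% names(x)),
             paste("config must contain:", paste(need, collapse = ", ")))
  regimen(loading_dose = x$loading_dose_mg, loading_count = x$loading_count,
          loading_interval = x$loading_interval_h,
          maintenance_dose = x$maintenance_dose_mg,
          maintenance_interval = x$maintenance_interval_h,
          infusion_duration = x$infusion_h, horizon = x$horizon_h)
}

#' @export
print.pk_regimen <- function(x, ...) {
  if (!is.null(x$loading_dose)) {
    cat(sprintf("<pk_regimen> %g mg q%gh x %d, then %g mg q%gh (%g-h infusions, horizon %g h)\n",
                x$loading_dose, x$loading_interval, x$loading_count,
                x$maintenance_dose, x$maintenance_interval,
                x$infusion_duration, x$horizon))
  } else {
    cat(sprintf("<pk_regimen> %d dose events, horizon %g h\n",
                nrow(x$events), x$horizon))
  }
  invisible(x)
}
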