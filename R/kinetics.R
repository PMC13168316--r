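# Cell-specific rates from daily fed-batch time courses. All quantities use
# the field's customary units: VCD in 1e6 cells/mL, glucose in g/L, lactate in
# mM, titer in mg/L, time in days. Rates: specific growth rate mu (1/d) from
# log-VCD differences; IVCD (1e6 cells * d / mL) by the trapezoid rule;
# q_LAC (pmol/cell/d) and q_P (pg/cell/d) as concentration deltas over IVCD
# increments; q_GLC from a per-feed-window linear regression of glucose
# concentration on cumulative IVCD.

#' Construct a culture time course
#'
#' @param day Numeric vector of sampling days since inoculation (strictly
#'   increasing; samples are taken pre-feed).
#' @param vcd Viable cell density, 1e6 cells/mL.
#' @param viability Percent viable cells.
#' @param glucose Extracellular glucose, g/L.
#' @param lactate Extracellular lactate, mM.
#' @param titer Product titer, mg/L.
#' @param ph Culture pH.
#' @param diameter Mean cell diameter, um.
#' @param feed_events `data.frame` with columns `day`, `feed_pct_vv`,
#'   `glucose_target_g_l`, `gal_plus` (logical); may be empty.
#' @param replicate,strategy Identifiers carried through to outputs.
#' @return Object of class `culture_time_course` (a list of the validated
#'   vectors plus the feed-event table).
#' @export
culture_time_course <- function(day, vcd, viability = NULL, glucose = NULL,
                                lactate = NULL, titer = NULL, ph = NULL,
                                diameter = NULL, feed_events = NULL,
                                replicate = "r1", strategy = NA_character_) {
  n <- length(day)
  stopifnot(n >= 1, !is.unsorted(day, strictly = TRUE))
  fill <- function(x) if (is.null(x)) rep(NA_real_, n) else {
    stopifnot(length(x) == n); as.numeric(x)
  }
  vcd <- fill(vcd); viability <- fill(viability)
  if (any(vcd < 0, na.rm = TRUE)) stop("VCD must be nonnegative")
  if (any(viability < 0 | viability > 100, na.rm = TRUE)) {
    stop("viability must lie in [0, 100]")
  }
  if (is.null(feed_events)) {
    feed_events <- data.frame(day = numeric(0), feed_pct_vv = numeric(0),
                              glucose_target_g_l = numeric(0),
                              gal_plus = logical(0))
  }
  need <- c("day", "feed_pct_vv", "glucose_target_g_l", "gal_plus")
  miss <- setdiff(need, names(feed_events))
  if (length(miss)) stop("feed_events lacks column(s): ",
                         paste(miss, collapse = ", "))
  structure(
    list(day = as.numeric(day), vcd = vcd, viability = viability,
         glucose = fill(glucose), lactate = fill(lactate),
         titer = fill(titer), ph = fill(ph), diameter = fill(diameter),
         feed_events = feed_events[order(feed_events$day), need],
         replicate = replicate, strategy = strategy),
    class = "culture_time_course"
  )
}

#' @export
print.culture_time_course <- function(x, ...) {
  cat("culture_time_course: ", x$strategy, "/", x$replicate, ", days ",
      min(x$day), "-", max(x$day), ", ", nrow(x$feed_events),
      " feed events\n", sep = "")
  invisible(x)
}

#' Specific growth rate per sampling interval
#'
#' \eqn{\mu_i = (\ln VCD_i - \ln VCD_{i-1}) / (t_i - t_{i-1})}, in 1/d.
#' Intervals with nonpositive or missing VCD are returned as `NA` rather than
#' raising an error.
#'
#' @param course A [culture_time_course()].
#' @return `data.frame` with columns `t_start`, `t_end`, `mu`.
#' @export
specific_growth_rate <- function(course) {
  stopifnot(inherits(course, "culture_time_course"))
  n <- length(course$day)
  if (n < 2) stop("need at least 2 time points")
  v0 <- course$vcd[-n]; v1 <- course$vcd[-1]
  dt <- diff(course$day)
  mu <- ifelse(!is.na(v0) & !is.na(v1) & v0 > 0 & v1 > 0,
               (log(v1) - log(v0)) / dt, NA_real_)
  data.frame(t_start = course$day[-n], t_end = course$day[-1], mu = mu)
}

#' Incremental integral of viable cell density (trapezoid rule)
#'
#' \eqn{IVCD_i = (VCD_{i-1} + VCD_i)(t_i - t_{i-1}) / 2}, in
#' 1e6 cells d / mL.
#'
#' @param course A [culture_time_course()].
#' @return `data.frame` with columns `t_start`, `t_end`, `ivcd`.
#' @export
incremental_ivcd <- function(course) {
  stopifnot(inherits(course, "culture_time_course"))
  n <- length(course$day)
  if (n < 2) stop("need at least 2 time points")
  data.frame(
    t_start = course$day[-n], t_end = course$day[-1],
    ivcd = (course$vcd[-n] + course$vcd[-1]) / 2 * diff(course$day)
  )
}

#' Cumulative integral of viable cell density
#'
#' Running sum of [incremental_ivcd()] increments; by convention the value at
#' the first sampling day is 0.
#'
#' @param course A [culture_time_course()].
#' @return `data.frame` with columns `t`, `ivcd_sum` (one row per sampling
#'   day).
#' @export
cumulative_ivcd <- function(course) {
  inc <- incremental_ivcd(course)
  data.frame(t = course$day, ivcd_sum = c(0, cumsum(inc$ivcd)))
}

# interval series of delta(conc)/delta(IVCD); spacing_d is the nominal
# interval length in days; missing sampling days widen the interval (flagged)
.specific_rate <- function(course, values, spacing_d, scale) {
  ok <- which(!is.na(values))
  if (length(ok) < 2) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      rate = numeric(0), widened = logical(0)))
  }
  cum <- cumulative_ivcd(course)
  t <- course$day[ok]; v <- values[ok]; iv <- cum$ivcd_sum[ok]
  # walk the available measurements at the nominal spacing
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i < length(t)) {
    j <- which(t >= t[i] + spacing_d - 1e-9)
    j <- if (length(j)) min(j) else length(t)
    if (j == i) break
    starts <- c(starts, i); ends <- c(ends, j)
    i <- j
  }
  div <- iv[ends] - iv[starts]
  rate <- ifelse(abs(div) > 0, (v[ends] - v[starts]) * scale / div, NA_real_)
  data.frame(
    t_start = t[starts], t_end = t[ends], rate = rate,
    widened = (t[ends] - t[starts]) > spacing_d + 1e-9
  )
}

#' Cell-specific lactate rate over 48-h intervals
#'
#' \eqn{q_{LAC,i} = \Delta LAC_i / \Delta IVCD_i} in pmol/cell/d (1 mM =
#' 1e6 pmol/mL). Positive values are production, negative consumption.
#' Intervals with zero IVCD increment are `NA`; missing sampling days widen
#' the interval to the nearest available points (`widened` flag).
#'
#' @param course A [culture_time_course()].
#' @param spacing_d Nominal interval in days (default 2 = 48 h).
#' @return `data.frame` with columns `t_start`, `t_end`, `q_lac`, `widened`.
#' @export
specific_lactate_rate <- function(course, spacing_d = 2) {
  out <- .specific_rate(course, course$lactate, spacing_d, scale = 1)
  names(out)[names(out) == "rate"] <- "q_lac"
  out
}

#' Cell-specific productivity over 24-h intervals
#'
#' \eqn{q_{P,i} = \Delta P_i / \Delta IVCD_i} in pg/cell/d (1 mg/L =
#' 1e6 pg/mL). Negative values are permitted (feed dilution). Also returns
#' the process-average productivity over a day window (default 3-11) as the
#' total titer change over the total IVCD accrued in the window.
#'
#' @param course A [culture_time_course()].
#' @param average_window Length-2 numeric, day range of the process average.
#' @return List with `intervals` (`data.frame`: `t_start`, `t_end`, `q_p`,
#'   `widened`) and `average` (scalar pg/cell/d).
#' @export
specific_productivity <- function(course, average_window = c(3, 11)) {
  intervals <- .specific_rate(course, course$titer, spacing_d = 1, scale = 1)
  names(intervals)[names(intervals) == "rate"] <- "q_p"
  cum <- cumulative_ivcd(course)
  inw <- which(course$day >= average_window[1] - 1e-9 &
               course$day <= average_window[2] + 1e-9 &
               !is.na(course$titer))
  avg <- NA_real_
  if (length(inw) >= 2) {
    a <- min(inw); b <- max(inw)
    div <- cum$ivcd_sum[b] - cum$ivcd_sum[a]
    if (div > 0) avg <- (course$titer[b] - course$titer[a]) / div
  }
  list(intervals = intervals, average = avg)
}

#' Cell-specific glucose consumption rate per feeding window
#'
#' Within each feeding interval, fits the ordinary least-squares regression
#' \eqn{c_{GLC,i} = slope \cdot IVCD_{sum,i} + d + \epsilon_i} and reports the
#' consumption rate \eqn{q_{GLC} = -slope} (consumption positive), both on the
#' regression's native scale (g/L per 1e6 cells d/mL) and converted to
#' pg/cell/d (x 1000). Windows are half-open `[feed_k, feed_{k+1})`: the
#' pre-feed sample taken on the day of `feed_{k+1}` belongs to window `k`.
#' Because samples are drawn pre-feed, a daily-fed window contains a single
#' measured point; with `use_postfeed = TRUE` (default) the known post-feed
#' replenishment concentration (the feed event's glucose target) is added as
#' a synthetic point at the feed day, giving every window at least two
#' points. Windows that still have fewer than two points are skipped with a
#' warning.
#'
#' @param course A [culture_time_course()] with feed events.
#' @param use_postfeed Include the post-feed target concentration as a point.
#' @return `data.frame` with one row per window: `t_start`, `t_end`,
#'   `n_points`, `slope`, `intercept`, `q_glc` (= -slope), `q_glc_pg`
#'   (pg/cell/d), `rss` (residual sum of squares).
#' @export
specific_glucose_rate <- function(course, use_postfeed = TRUE) {
  stopifnot(inherits(course, "culture_time_course"))
  fe <- course$feed_events
  if (nrow(fe) < 1) stop("no feed events: cannot define q_GLC windows")
  cum <- cumulative_ivcd(course)
  bounds <- c(fe$day, Inf)
  out <- list()
  for (k in seq_len(nrow(fe))) {
    lo <- bounds[k]; hi <- bounds[k + 1]
    sel <- which(course$day > lo + 1e-9 & course$day <= hi + 1e-9 &
                 !is.na(course$glucose))
    x <- cum$ivcd_sum[sel]; y <- course$glucose[sel]
    if (use_postfeed && is.finite(fe$glucose_target_g_l[k])) {
      at <- which(abs(course$day - lo) < 1e-9)
      if (length(at) == 1) {
        x <- c(cum$ivcd_sum[at], x)
        y <- c(fe$glucose_target_g_l[k], y)
      }
    }
    if (length(x) < 2 || length(unique(x)) < 2) {
      warning("q_GLC window starting day ", lo,
              " has fewer than 2 usable points; skipped")
      next
    }
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    out[[length(out) + 1L]] <- data.frame(
      t_start = lo, t_end = if (is.finite(hi)) hi else max(course$day),
      n_points = length(x), slope = slope,
      intercept = fit$coefficients[1],
      q_glc = -slope, q_glc_pg = -slope * 1000,
      rss = sum(fit$residuals^2)
    )
  }
  if (!length(out)) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      n_points = integer(0), slope = numeric(0),
                      intercept = numeric(0), q_glc = numeric(0),
                      q_glc_pg = numeric(0), rss = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' All cell-specific rates of a time course in tidy form
#'
#' @param course A [culture_time_course()].
#' @return Tidy `data.frame` with columns `replicate`, `strategy`,
#'   `quantity`, `t_start`, `t_end`, `value`.
#' @export
compute_rates <- function(course) {
  mu <- specific_growth_rate(course)
  iv <- incremental_ivcd(course)
  cum <- cumulative_ivcd(course)
  qp <- specific_productivity(course)
  ql <- specific_lactate_rate(course)
  tidy <- function(t0, t1, q, v) data.frame(
    replicate = course$replicate, strategy = course$strategy,
    quantity = q, t_start = t0, t_end = t1, value = v,
    stringsAsFactors = FALSE
  )
  out <- rbind(
    tidy(mu$t_start, mu$t_end, "mu", mu$mu),
    tidy(iv$t_start, iv$t_end, "ivcd", iv$ivcd),
    tidy(cum$t, cum$t, "ivcd_sum", cum$ivcd_sum),
    tidy(qp$intervals$t_start, qp$intervals$t_end, "q_p", qp$intervals$q_p),
    tidy(ql$t_start, ql$t_end, "q_lac", ql$q_lac)
  )
  if (nrow(course$feed_events)) {
    qg <- tryCatch(specific_glucose_rate(course), warning = function(w) {
      suppressWarnings(specific_glucose_rate(course))
    })
    if (nrow(qg)) {
      out <- rbind(out, tidy(qg$t_start, qg$t_end, "q_glc_pg", qg$q_glc_pg))
    }
  }
  out <- rbind(out, tidy(min(course$day), max(course$day), "q_p_avg",
                         qp$average))
  out
}

#' Read culture time courses from CSV
#'
#' Expected columns: `replicate`, `strategy`, `day`, `vcd_1e6_per_ml`,
#' `viability_pct`, `diameter_um`, `glucose_g_l`, `lactate_mm`, `titer_mg_l`,
#' `ph`. Feed events (per strategy) come from a second CSV with columns
#' `strategy`, `day`, `feed_pct_vv`, `glucose_target_g_l`, `gal_plus`.
#'
#' @param path Time-course CSV path.
#' @param feed_path Optional feed-event CSV path.
#' @return Named list of [culture_time_course()] objects, one per
#'   (strategy, replicate).
#' @export
read_time_courses <- function(path, feed_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate", "strategy", "day", "vcd_1e6_per_ml")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("time-course file '", path, "' lacks column(s): ",
                         paste(miss, collapse = ", "))
  feeds <- if (!is.null(feed_path)) {
    utils::read.csv(feed_path, stringsAsFactors = FALSE)
  } else NULL
  opt <- function(d, col) if (col %in% names(d)) d[[col]] else NULL
  out <- list()
  for (key in unique(paste(df$strategy, df$replicate, sep = "/"))) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    d <- df[df$strategy == parts[1] & df$replicate == parts[2], ]
    d <- d[order(d$day), ]
    fe <- if (!is.null(feeds)) feeds[feeds$strategy == parts[1], ] else NULL
    out[[key]] <- culture_time_course(
      day = d$day, vcd = d$vcd_1e6_per_ml, viability = opt(d, "viability_pct"),
      glucose = opt(d, "glucose_g_l"), lactate = opt(d, "lactate_mm"),
      titer = opt(d, "titer_mg_l"), ph = opt(d, "ph"),
      diameter = opt(d, "diameter_um"), feed_events = fe,
      replicate = parts[2], strategy = parts[1]
    )
  }
  out
}
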