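# Seeded fed-batch study simulator. Emulates seven feeding strategies of a
# CHO fed-batch process (varying feed interval, glucose replenishment target,
# and galactose/manganese supplementation, including a pH-triggered
# HIPDOG-like regime), the resulting strategy/phase-dependent glycoform
# compositions, and residual-glucose-driven antibody glycation. All
# generating parameters are retained as ground truth so estimators can be
# checked against them.

#' The seven packaged feeding strategies
#'
#' @return Named list of strategy specs, each a list with `name`,
#'   `feed_interval_h` (24/48), `glucose_target_g_l` (2/4/8), `gal_plus`,
#'   `feed_pct_vv` (2.5/5), `ph_triggered`.
#' @export
strategy_presets <- function() {
  spec <- function(name, interval, target, gal, vol, ph) {
    list(name = name, feed_interval_h = interval,
         glucose_target_g_l = target, gal_plus = gal,
         feed_pct_vv = vol, ph_triggered = ph)
  }
  list(
    "STD"  = spec("STD",  48, 8, FALSE, 5.0, FALSE),
    "STD+" = spec("STD+", 48, 8, TRUE,  5.0, FALSE),
    "LoG"  = spec("LoG",  48, 4, FALSE, 5.0, FALSE),
    "LoG+" = spec("LoG+", 48, 4, TRUE,  5.0, FALSE),
    "HiF"  = spec("HiF",  24, 4, FALSE, 2.5, FALSE),
    "HIP"  = spec("HIP",  24, 2, FALSE, 2.5, TRUE),
    "HIP+" = spec("HIP+", 24, 2, TRUE,  2.5, TRUE)
  )
}

#' Default glycoform composition and species vocabulary
#'
#' Baseline fractional abundances (percent) over the observed paired-glycan
#' vocabulary of a CHO-produced IgG, dominated by agalactosylated
#' core-fucosylated species.
#'
#' @return Named numeric vector summing to 100.
#' @export
baseline_glycoforms <- function() {
  v <- c(1.5, 4.0, 1.0, 45.5, 28.0, 12.0, 6.0, 2.0)
  names(v) <- canonical_glycoform(c(
    "G0 . G0", "G0 . G0F", "none . G0F", "G0F . G0F",
    "G0F . G1F", "G1F . G1F", "G1F . G2F", "G2F . G2F"
  ))
  v
}

#' Simulation configuration
#'
#' Kinetic, glycan and glycation parameters of the study simulator, with
#' defaults chosen to emulate a realistic small-scale CHO fed-batch: maximum
#' specific growth rate ~0.65/d, peak viable cell densities in the
#' 17-26e6 cells/mL range, lactate production early with a metabolic shift to
#' consumption mid-process, rapid viability loss after total carbon
#' exhaustion, and a stationary-phase glycation index of a few percent.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    horizon_days = 11,         # process duration
    feed_start_day = 3,        # first feed event
    v0_ml = 30,                # initial working volume, mL
    sample_ml = 1.5,           # daily sampling volume, mL
    vcd0 = 0.5,                # inoculation density, 1e6 cells/mL
    viability0 = 98,           # percent
    glucose0_g_l = 6,          # basal-medium glucose
    mu_max = 0.65,             # 1/d
    k_monod = 0.15,            # g/L, half-saturation on glucose
    alt_growth_frac = 0.5,     # growth efficiency on lactate/galactose
    vcd_max = 25,              # 1e6 cells/mL carrying capacity
    q_p = 16,                  # true productivity, pg/cell/d
    q_glc_maint = 80,          # maintenance glucose uptake, pg/cell/d
    q_glc_growth = 220,        # growth-coupled uptake at mu = mu_max
    y_lac_early = 5,           # mM lactate per g/L glucose, pre-shift
    y_lac_late = 0.3,          # mM per g/L after the metabolic shift
    lac_shift_day = 5,         # day of the metabolic shift
    glc_switch_g_l = 1,        # below this, galactose is consumed
    q_lac_cons = 2,            # pmol/cell/d peak lactate consumption
    k_lac_mm = 1.0,            # mM half-saturation of lactate consumption
    q_gal_cons = 80,           # pg/cell/d galactose consumption when needed
    gal_feed_g_l = 0.225,      # galactose added per Gal+ feed (1.25 mM)
    death_rate = 2,            # 1/d viability decay at full starvation
    starv_tolerance = 0.25,    # unmet-demand fraction cells tolerate
    ph_base = 7.6,             # pH at zero lactate
    ph_slope = 0.025,          # pH drop per mM lactate
    ph_feed_threshold = 7.2,   # HIPDOG-like feed trigger
    diameter_um = 13.5,        # nominal cell diameter
    meas_noise = list(vcd = 0, glucose = 0, lactate = 0, titer = 0,
                      viability = 0, diameter = 0),
    # glycan effect model (clr scale)
    glyco_baseline = baseline_glycoforms(),
    delta_gal = 0.3,           # Gal+ clr shift of galactosylated species
    delta_fuc = 0.3,           # stationary shift per fucosylated-arm fraction
    delta_afuc = 0.3,          # stationary decline of afucosylated species
    sigma_clr = 0.1,           # between-replicate clr noise sd
    # glycation model
    glycation_slope = 1.4e-3,  # probability per g d/L glucose exposure
    glycation_pmax = 1,        # saturation of the site probability
    glycation_noise = 0,       # sd of multiplicative noise on p
    replicates = c("STD" = 4, "STD+" = 4, "LoG" = 4, "LoG+" = 4,
                   "HiF" = 3, "HIP" = 3, "HIP+" = 3)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$mu_max >= 0, cfg$sigma_clr >= 0, cfg$death_rate >= 0,
            cfg$glycation_pmax >= 0, cfg$glycation_pmax <= 1)
  class(cfg) <- "simulation_config"
  cfg
}

# lactate molar mass, g/mol (concentration conversions mM <-> g/L)
.LAC_MW <- 90.08

#' Simulate one fed-batch culture replicate
#'
#' Daily update with exact within-day exponential growth: growth follows a
#' Monod factor on glucose, with reduced-efficiency support from lactate and
#' galactose and a carrying-capacity factor; glucose is consumed against the
#' daily trapezoid of VCD at a maintenance + growth-coupled cell-specific
#' rate; lactate is produced in proportion to glucose consumption (high
#' yield before the metabolic shift day, low after) and consumed post-shift
#' at a saturating cell-specific rate; titer accrues at the true
#' cell-specific productivity; viability and VCD decay once the day's
#' carbon demand goes substantially unmet (starvation beyond the tolerated
#' fraction). Feeds run from day 3 at the strategy's interval, diluting the
#' culture by the feed volume and replenishing glucose to the strategy's
#' target; pH-triggered strategies add glucose only when the simulated pH
#' (a decreasing function of lactate) is at or above 7.2. Samples are drawn
#' daily pre-feed.
#'
#' @param spec A strategy spec (see [strategy_presets()]).
#' @param config A [simulation_config()].
#' @param seed Integer seed (measurement noise only; the dynamics are
#'   deterministic).
#' @param replicate Replicate id carried into the output.
#' @return A [culture_time_course()]; attribute `truth` holds the generating
#'   parameters and the mass-balance accumulators (`glc_initial_g`,
#'   `glc_fed_g`, `glc_consumed_g`, `glc_sampled_g`, `glc_residual_g`).
#' @export
simulate_culture <- function(spec, config = simulation_config(), seed = 1L,
                             replicate = "r1") {
  need <- c("name", "feed_interval_h", "glucose_target_g_l", "gal_plus",
            "feed_pct_vv", "ph_triggered")
  miss <- setdiff(need, names(spec))
  if (length(miss)) stop("invalid strategy spec, missing: ",
                         paste(miss, collapse = ", "))
  if (config$horizon_days < config$feed_start_day) {
    stop("horizon must reach the first feed day")
  }
  cfg <- config
  days <- 0:cfg$horizon_days

  v <- cfg$v0_ml / 1000           # L
  vcd <- cfg$vcd0                 # 1e6 cells/mL
  viab <- cfg$viability0
  glc <- cfg$glucose0_g_l
  lac <- 0                        # mM
  gal <- 0                        # g/L
  titer <- 0                      # mg/L

  bal <- list(glc_initial_g = glc * v, glc_fed_g = 0, glc_consumed_g = 0,
              glc_sampled_g = 0)
  ph_of <- function(l) cfg$ph_base - cfg$ph_slope * l

  rec <- data.frame(day = days, vcd = NA_real_, viability = NA_real_,
                    glucose = NA_real_, lactate = NA_real_,
                    titer = NA_real_, ph = NA_real_, diameter = NA_real_)
  feed_log <- list()
  interval_d <- spec$feed_interval_h / 24

  for (i in seq_along(days)) {
    t <- days[i]
    # ---- pre-feed sample -------------------------------------------------
    rec$vcd[i] <- vcd; rec$viability[i] <- viab
    rec$glucose[i] <- glc; rec$lactate[i] <- lac
    rec$titer[i] <- titer; rec$ph[i] <- ph_of(lac)
    rec$diameter[i] <- cfg$diameter_um - 1 * (1 - viab / 100)
    samp <- min(cfg$sample_ml / 1000, v)
    bal$glc_sampled_g <- bal$glc_sampled_g + glc * samp
    v <- v - samp

    # ---- feed ------------------------------------------------------------
    fed_today <- t >= cfg$feed_start_day &&
      abs((t - cfg$feed_start_day) %% interval_d) < 1e-9
    if (fed_today && t < cfg$horizon_days) {
      fv <- v * spec$feed_pct_vv / 100
      if (fv > 0) {
        dil <- v / (v + fv)
        vcd <- vcd * dil; glc <- glc * dil; lac <- lac * dil
        gal <- gal * dil; titer <- titer * dil
        v <- v + fv
      }
      glc_added <- 0
      allow_glc <- !spec$ph_triggered ||
        ph_of(lac) >= cfg$ph_feed_threshold
      if (allow_glc && glc < spec$glucose_target_g_l) {
        glc_added <- (spec$glucose_target_g_l - glc) * v
        glc <- spec$glucose_target_g_l
        bal$glc_fed_g <- bal$glc_fed_g + glc_added
      }
      gal_plus_today <- spec$gal_plus &&
        abs((t - cfg$feed_start_day) %% 2) < 1e-9
      if (gal_plus_today) gal <- gal + cfg$gal_feed_g_l
      feed_log[[length(feed_log) + 1L]] <- data.frame(
        day = t, feed_pct_vv = spec$feed_pct_vv,
        glucose_target_g_l = if (allow_glc) spec$glucose_target_g_l else NA,
        gal_plus = gal_plus_today
      )
    }
    if (i == length(days)) break

    # ---- advance one day -------------------------------------------------
    # glucose is the primary substrate; lactate and galactose support growth
    # at reduced efficiency once glucose runs short
    lac_gl <- lac * .LAC_MW / 1000
    alt <- lac_gl + gal
    s_glc <- glc / (cfg$k_monod + glc)
    s_alt <- alt / (cfg$k_monod + alt)
    mu <- cfg$mu_max * min(1, s_glc + cfg$alt_growth_frac * s_alt) *
      max(0, 1 - vcd / cfg$vcd_max)
    vcd_next <- vcd * exp(mu)
    ivcd_day <- (vcd + vcd_next) / 2  # 1e6 cells d / mL

    q_glc_eff <- cfg$q_glc_maint +
      cfg$q_glc_growth * (if (cfg$mu_max > 0) mu / cfg$mu_max else 0)
    demand <- 1e-3 * q_glc_eff * ivcd_day          # g/L over the day
    glc_consumed <- min(glc, demand)
    glc_next <- glc - glc_consumed
    bal$glc_consumed_g <- bal$glc_consumed_g + glc_consumed * v

    y <- if (t < cfg$lac_shift_day) cfg$y_lac_early else cfg$y_lac_late
    lac_cons <- if (t >= cfg$lac_shift_day) {
      min(lac, cfg$q_lac_cons * ivcd_day * lac / (lac + cfg$k_lac_mm))
    } else 0
    lac_next <- max(0, lac + y * glc_consumed - lac_cons)

    gal_next <- gal
    gal_consumed <- 0
    if (glc_next <= cfg$glc_switch_g_l && gal > 0) {
      gal_consumed <- min(gal, 1e-3 * cfg$q_gal_cons * ivcd_day)
      gal_next <- gal - gal_consumed
    }

    # starvation: fraction of the day's carbon demand left unmet after
    # glucose, lactate and galactose; drives viability loss and caps
    # productivity (titer still accrues at the true q_p while fed)
    satisfied <- min(1, (glc_consumed + lac_cons * .LAC_MW / 1000 +
                           gal_consumed) / demand)
    starv <- max(0, (1 - satisfied - cfg$starv_tolerance) /
                   (1 - cfg$starv_tolerance))
    titer_next <- titer + cfg$q_p * satisfied * ivcd_day
    viab_next <- viab * exp(-cfg$death_rate * starv)
    if (starv > 0) vcd_next <- vcd * exp(mu - cfg$death_rate * starv)

    vcd <- vcd_next; glc <- glc_next; lac <- lac_next; gal <- gal_next
    titer <- titer_next; viab <- viab_next
  }
  bal$glc_residual_g <- glc * v

  # measurement noise (multiplicative, seeded)
  noisy <- with_seed(seed, function() {
    nz <- function(x, s) if (s > 0) x * exp(stats::rnorm(length(x), 0, s))
      else x
    rec$vcd <- nz(rec$vcd, cfg$meas_noise$vcd)
    rec$glucose <- nz(rec$glucose, cfg$meas_noise$glucose)
    rec$lactate <- nz(rec$lactate, cfg$meas_noise$lactate)
    rec$titer <- nz(rec$titer, cfg$meas_noise$titer)
    rec$viability <- pmin(100, nz(rec$viability, cfg$meas_noise$viability))
    rec$diameter <- nz(rec$diameter, cfg$meas_noise$diameter)
    rec
  })

  feeds <- if (length(feed_log)) do.call(rbind, feed_log) else NULL
  course <- culture_time_course(
    day = noisy$day, vcd = noisy$vcd, viability = noisy$viability,
    glucose = noisy$glucose, lactate = noisy$lactate, titer = noisy$titer,
    ph = noisy$ph, diameter = noisy$diameter, feed_events = feeds,
    replicate = replicate, strategy = spec$name
  )
  attr(course, "truth") <- c(
    list(q_p = cfg$q_p, q_glc_maint = cfg$q_glc_maint,
         q_glc_growth = cfg$q_glc_growth, mu_max = cfg$mu_max),
    bal
  )
  course
}

# per-species clr effect covariates of the generator
.species_effects <- function(labels) {
  sp <- lapply(labels, parse_glycoform)
  gal <- as.numeric(vapply(sp, `[[`, integer(1), "g_j") > 0)
  n_fuc <- vapply(sp, function(s)
    sum(s$arm_a$fucosylated, s$arm_b$fucosylated), numeric(1))
  n_present <- vapply(sp, function(s)
    sum(s$arm_a$present, s$arm_b$present), numeric(1))
  afuc <- as.numeric(n_present > 0 & n_fuc == 0)
  list(gal = gal, fuc = n_fuc / 2, afuc = afuc)
}

#' Simulate glycoform fractional abundances for one strategy and phase
#'
#' Replicate compositions are drawn in clr space as
#' `baseline + gal_plus * delta_gal * (galactosylated indicator)
#'  + stationary * delta_fuc * (fucosylated-arm fraction)
#'  - stationary * delta_afuc * (afucosylated indicator) + N(0, sigma)`
#' and mapped back to fractions summing to 100 (logistic-normal noise).
#'
#' @param spec Strategy spec (see [strategy_presets()]).
#' @param phase `"exp"` or `"sta"`.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param n_rep Number of biological replicates (default from config).
#' @return A [glycoform_table()]; attribute `truth` stores the shift vector
#'   applied in clr space.
#' @export
simulate_glycoforms <- function(spec, phase = c("exp", "sta"),
                                config = simulation_config(), seed = 1L,
                                n_rep = NULL) {
  phase <- match.arg(phase)
  cfg <- config
  if (cfg$sigma_clr < 0) stop("sigma_clr must be nonnegative")
  if (is.null(n_rep)) n_rep <- unname(cfg$replicates[spec$name])
  if (is.na(n_rep)) n_rep <- 3L
  base <- cfg$glyco_baseline
  eff <- .species_effects(names(base))
  lbase <- log(base / sum(base))
  shift <- (if (spec$gal_plus) cfg$delta_gal * eff$gal else 0) +
    (if (phase == "sta") cfg$delta_fuc * eff$fuc else 0) -
    (if (phase == "sta") cfg$delta_afuc * eff$afuc else 0)
  mu_clr <- lbase + shift

  draws <- with_seed(seed, function() {
    t(vapply(seq_len(n_rep), function(r) {
      z <- mu_clr + stats::rnorm(length(mu_clr), 0, cfg$sigma_clr)
      p <- exp(z); 100 * p / sum(p)
    }, numeric(length(base))))
  })
  colnames(draws) <- names(base)
  ids <- paste(spec$name, phase, paste0("r", seq_len(n_rep)), sep = "_")
  rownames(draws) <- ids
  md <- data.frame(sample_id = ids, strategy = spec$name, phase = phase,
                   replicate = paste0("r", seq_len(n_rep)),
                   stringsAsFactors = FALSE)
  tab <- glycoform_table(draws, md)
  attr(tab, "truth") <- list(shift_clr = shift, sigma = cfg$sigma_clr,
                             baseline = base)
  tab
}

#' Simulate an antibody glycation profile from a culture time course
#'
#' The per-site glycation probability is a bounded linear function of the
#' cumulative residual-glucose exposure of the secreted antibody,
#' `p = min(pmax, slope * integral(glucose dt))` up to the sampling day; the
#' hexose-count distribution is binomial with 3 trials, expressed in percent.
#'
#' @param course A [culture_time_course()].
#' @param config A [simulation_config()].
#' @param seed Integer seed (used when `glycation_noise > 0`).
#' @param day Sampling day (default: last day of the course).
#' @param sample_id Sample id of the resulting profile row.
#' @return A [glycation_profile()] with one row; attribute `truth` stores
#'   the generating probability.
#' @export
simulate_glycation <- function(course, config = simulation_config(),
                               seed = 1L, day = max(course$day),
                               sample_id = NULL) {
  stopifnot(inherits(course, "culture_time_course"))
  cfg <- config
  sel <- course$day <= day + 1e-9
  t <- course$day[sel]; g <- course$glucose[sel]
  if (sum(sel) < 2) {
    exposure <- 0
  } else {
    exposure <- sum((g[-1] + g[-length(g)]) / 2 * diff(t))  # g d / L
  }
  p <- min(cfg$glycation_pmax, cfg$glycation_slope * exposure)
  if (cfg$glycation_noise > 0) {
    p <- with_seed(seed, function() {
      min(cfg$glycation_pmax,
          max(0, p * exp(stats::rnorm(1, 0, cfg$glycation_noise))))
    })
  }
  f <- 100 * stats::dbinom(0:3, 3, p)
  if (is.null(sample_id)) {
    sample_id <- paste(course$strategy, course$replicate, sep = "_")
  }
  prof <- glycation_profile(matrix(f, 1, dimnames = list(sample_id, NULL)))
  attr(prof, "truth") <- list(p = p, exposure = exposure)
  prof
}

#' Generate a full synthetic feeding-strategy study
#'
#' Simulates all configured strategies and replicates: culture time courses,
#' glycoform tables sampled in the exponential phase (day 5) and the
#' stationary phase (day 10 for the low-glucose strategies, day 11
#' otherwise), and per-sample glycation profiles, together with a
#' ground-truth ledger of every generating parameter.
#'
#' @param config A [simulation_config()].
#' @param seed Integer master seed; per-replicate seeds are derived from it.
#' @param strategies Character vector of strategy names (default all seven).
#' @return List of class `glyco_study` with elements `courses` (named list),
#'   `glycoforms` (one combined [glycoform_table()]), `glycation`
#'   (combined [glycation_profile()]), `truth`, `seed`.
#' @export
generate_study <- function(config = simulation_config(), seed = 1L,
                           strategies = names(strategy_presets())) {
  cfg <- config
  presets <- strategy_presets()[strategies]
  courses <- list()
  ab <- NULL; md <- NULL; fmat <- NULL
  truth <- list(config = cfg)

  for (si in seq_along(presets)) {
    spec <- presets[[si]]
    n_rep <- unname(cfg$replicates[spec$name])
    if (is.na(n_rep)) n_rep <- 3L
    sta_day <- if (spec$name %in% c("LoG", "LoG+")) 10 else 11

    for (r in seq_len(n_rep)) {
      cseed <- (seed * 1009L + si * 101L + r) %% .Machine$integer.max
      course <- simulate_culture(spec, cfg, seed = cseed,
                                 replicate = paste0("r", r))
      courses[[paste(spec$name, paste0("r", r), sep = "/")]] <- course
      for (ph in c("exp", "sta")) {
        d <- if (ph == "exp") 5 else sta_day
        sid <- paste(spec$name, ph, paste0("r", r), sep = "_")
        prof <- simulate_glycation(course, cfg, seed = cseed + 7L,
                                   day = d, sample_id = sid)
        fmat <- rbind(fmat, prof$f)
      }
    }
    for (ph in c("exp", "sta")) {
      gseed <- (seed * 2003L + si * 17L + (ph == "sta")) %%
        .Machine$integer.max
      tab <- simulate_glycoforms(spec, ph, cfg, seed = gseed, n_rep = n_rep)
      ab <- rbind(ab, tab$abundance)
      md <- rbind(md, tab$metadata)
      truth[[paste("shift", spec$name, ph, sep = "_")]] <-
        attr(tab, "truth")$shift_clr
    }
  }
  glycoforms <- glycoform_table(ab, md)
  glycation <- glycation_profile(fmat)
  structure(
    list(courses = courses, glycoforms = glycoforms, glycation = glycation,
         truth = truth, seed = seed),
    class = "glyco_study"
  )
}

#' @export
print.glyco_study <- function(x, ...) {
  cat("glyco_study: ", length(x$courses), " culture replicates, ",
      nrow(x$glycoforms$abundance), " glycoform samples, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}
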