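#' Model configuration preset
#'
#' Bundles geometry, wiring, dynamics and protocol settings for one of
#' the two model instantiations, at a chosen desk scale.
#'
#' Protocol defaults follow the backward-masking design: a 20 ms target,
#' a 60 ms (model 1) or 50 ms (model 2) mask, relay firing at 50 Hz
#' (hence one spike per stimulated relay for the target and three for the
#' mask), an SOA sweep of 20-120 ms in 20 ms steps, presentations every
#' 1000 ms (target onset 100 ms into each slot), and 5 individuals x 5
#' trials per condition.
#'
#' @param model \code{"model1"} or \code{"model2"}.
#' @param scale desk-scale divisor for per-minicolumn cell counts.
#' @param mask_points stimulated LGN locations in the model 1 noise mask
#'   (4, or 5 for higher masking salience).
#' @param mask_distance model 2 mask-line distance from the target line,
#'   in hypercolumns (1, 2 or 3).
#' @param feedback wire V2-to-V1 feedback projections?
#' @param g_exc,g_inh calibrated global conductance scales; defaults are
#'   the shipped calibration for each model at the default desk scale.
#' @param ... overrides forwarded to \code{\link{wiring_config}}.
#' @return A list of class \code{"model_config"}.
#' @export
model_config <- function(model = c("model1", "model2"), scale = 0.25,
                         mask_points = 4L, mask_distance = 2L,
                         feedback = TRUE,
                         g_exc = NULL, g_inh = NULL, ...) {
  model <- match.arg(model)
  cal <- calibrated_scales(model)
  g_exc <- g_exc %||% cal[["g_exc"]]
  g_inh <- g_inh %||% cal[["g_inh"]]
  geometry <- geometry_config(model, scale = scale)
  wiring <- wiring_config(model, g_exc = g_exc, g_inh = g_inh, ...)
  protocol <- list(
    soas = c(20, 40, 60, 80, 100, 120),
    spacing = 1000,
    target_onset = 100,
    target_duration = 20,
    mask_duration = if (model == "model1") 60 else 50,
    relay_rate = 50,
    target_points = 4L,
    mask_points = as.integer(mask_points),
    mask_distance = as.integer(mask_distance),
    n_individuals = 5L,
    n_trials = 5L,
    n_patterns = 18L,
    minicolumns_per_pattern = 10L
  )
  structure(list(model = model, geometry = geometry, wiring = wiring,
                 dynamics = dynamics_config(), protocol = protocol,
                 feedback = feedback),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("Model config: %s (scale %g), feedback %s\n", x$model,
              x$geometry$scale, if (x$feedback) "on" else "off"))
  cat(sprintf("  SOAs: %s ms; mask %s\n", paste(x$protocol$soas, collapse = ","),
              if (x$model == "model1") {
                sprintf("%d-point noise", x$protocol$mask_points)
              } else {
                sprintf("lines at distance %d", x$protocol$mask_distance)
              }))
  invisible(x)
}

# Shipped global conductance scale factors (per model), produced by
# calibrate() at the default desk scale and persisted here.  Model 2 runs
# slightly hotter: its line patterns span more hypercolumns and lean harder
# on long-range completion, so the calibrated excitatory scale is higher.
calibrated_scales <- function(model) {
  if (model == "model1") c(g_exc = 0.95, g_inh = 1.0) else c(g_exc = 1.25, g_inh = 1.0)
}

#' Build the network for one simulated individual
#'
#' Generates the stored attractor memories for both areas (random sparse
#' patterns for model 1, vertical lines for model 2), links them across
#' areas, and wires the full network with the individual's seed.
#'
#' @param cfg a \code{\link{model_config}}.
#' @param individual_seed integer; a different seed gives a different
#'   simulated individual (fresh patterns for model 1 and fresh
#'   connection matrices for both models).
#' @return A \code{cortical_network}.
#' @export
build_model <- function(cfg, individual_seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  geom <- build_geometry(cfg$geometry)
  seed1 <- derive_seed(individual_seed, 1000003, 1)
  seed2 <- derive_seed(individual_seed, 1000003, 2)
  if (cfg$model == "model1") {
    v1 <- generate_patterns_random(geom, cfg$protocol$n_patterns,
                                   cfg$protocol$minicolumns_per_pattern,
                                   seed = seed1, area = "V1")
    v2 <- generate_patterns_random(geom, cfg$protocol$n_patterns,
                                   cfg$protocol$minicolumns_per_pattern,
                                   seed = seed2, area = "V2")
  } else {
    v1 <- generate_patterns_lines(geom, area = "V1")
    v2 <- generate_patterns_lines(geom, area = "V2")
  }
  linkage <- link_patterns(v1, v2)
  assemble_network(geom, v1, v2, linkage, cfg$wiring, cfg$dynamics,
                   individual_seed = individual_seed,
                   feedback_enabled = cfg$feedback)
}

#' Relay spike schedule for one stimulus presentation
#'
#' Every relay cell of every stimulated LGN location fires
#' \code{round(rate x duration)} spikes (half-up), each at an independent
#' uniform time within the presentation window.
#'
#' @param geom a \code{network_geometry}.
#' @param locations stimulated LGN location ids (= V1 minicolumn ids).
#' @param onset window start (ms).
#' @param duration window length (ms).
#' @param rate assumed relay firing rate (Hz, default 50).
#' @return data.frame of forced spikes (\code{cell}, \code{time}).
#' @export
make_stimulus <- function(geom, locations, onset, duration, rate = 50) {
  if (length(locations) == 0L) stop("stimulus location set is empty")
  if (duration <= 0) return(data.frame(cell = integer(0), time = numeric(0)))
  n_spikes <- as.integer(round_half_up(rate * duration / 1000))
  relays <- cell_ids(geom, "LGN", mc = locations, class = "relay")
  if (n_spikes == 0L) return(data.frame(cell = integer(0), time = numeric(0)))
  cells <- rep(relays, each = n_spikes)
  times <- onset + stats::runif(length(cells)) * duration
  data.frame(cell = cells, time = times)
}

# model 1: sample stimulated minicolumns for target and noise mask
sample_model1_points <- function(net, target_pattern_id, n_target, n_mask) {
  v1p <- net$v1_patterns$patterns
  tp <- v1p[[target_pattern_id]]
  t_locs <- resample(tp, n_target)
  target_hcs <- net$geom$hc_of_mc[tp]
  other_mcs <- setdiff(unlist(v1p[-target_pattern_id]), tp)
  pool <- other_mcs[net$geom$hc_of_mc[other_mcs] %in% target_hcs]
  if (length(pool) < n_mask) stop("not enough non-target minicolumns in the target's hypercolumns")
  m_locs <- resample(pool, n_mask)
  list(target = t_locs, mask = m_locs)
}

#' Build one backward-masking trial
#'
#' A trial consists of 8 presentations spaced \code{spacing} ms apart:
#' the target alone, the mask alone, and target+mask at each SOA in
#' ascending order.  The mask onset is the target onset plus the SOA.
#'
#' Model 1 uses one stored memory as the target for the whole trial; the
#' stimulated target points (4 of its 10 minicolumns) and noise-mask
#' points (minicolumns of other memories in the same hypercolumns) are
#' re-drawn for every presentation from the trial seed.  Model 2 uses the
#' middle grid column as the target line and the two parallel lines
#' \code{mask_distance} hypercolumns to each side as the mask; every
#' presentation consumes a fresh minicolumn index, so no line pattern is
#' re-used within a trial (attractor adaptation does not recover between
#' presentations).
#'
#' @param net a \code{\link{build_model}} network.
#' @param cfg the \code{\link{model_config}}.
#' @param trial_seed integer seed for stimulus randomness.
#' @param soas SOA sweep (default from the config).
#' @return list with \code{plan} (one row per presentation: condition,
#'   SOA, onsets, analysed target pattern) and \code{schedule} (forced
#'   relay spikes).
#' @export
build_trial <- function(net, cfg, trial_seed = 1L, soas = cfg$protocol$soas) {
  pr <- cfg$protocol
  if (length(soas) && max(soas) + pr$target_onset + pr$mask_duration > pr$spacing) {
    stop("SOA exceeds the presentation spacing")
  }
  conds <- c("target_only", "mask_only", rep("target_mask", length(soas)))
  soa_col <- c(NA, NA, sort(soas))
  n_pres <- length(conds)
  with_seed(trial_seed, {
    plan <- data.frame(presentation = seq_len(n_pres), condition = conds,
                       soa = soa_col,
                       slot_start = (seq_len(n_pres) - 1L) * pr$spacing)
    plan$target_onset <- plan$slot_start + pr$target_onset
    plan$mask_onset <- ifelse(plan$condition == "target_only", NA,
                              plan$target_onset + ifelse(is.na(plan$soa), 0, plan$soa))
    sched <- vector("list", n_pres)
    if (cfg$model == "model1") {
      target_id <- resample(seq_along(net$v1_patterns$patterns), 1L)
      plan$pattern <- target_id
      for (i in seq_len(n_pres)) {
        pts <- sample_model1_points(net, target_id, pr$target_points, pr$mask_points)
        s <- list()
        if (plan$condition[i] != "mask_only") {
          s$t <- make_stimulus(net$geom, pts$target, plan$target_onset[i],
                               pr$target_duration, pr$relay_rate)
        }
        if (plan$condition[i] != "target_only") {
          s$m <- make_stimulus(net$geom, pts$mask, plan$mask_onset[i],
                               pr$mask_duration, pr$relay_rate)
        }
        sched[[i]] <- do.call(rbind, s)
      }
    } else {
      meta <- net$v1_patterns$meta
      cols <- net$geom$grid[2]
      mid <- (cols + 1L) %/% 2L
      d <- pr$mask_distance
      if (mid - d < 1L || mid + d > cols) stop("mask distance falls outside the grid")
      kmax <- net$geom$mc_per_hc
      if (n_pres > kmax) {
        stop("more presentations than independent line patterns per column")
      }
      ks <- resample(seq_len(kmax), n_pres)   # fresh pattern per presentation
      pattern_of <- function(column, k) which(meta$column == column & meta$mc_index == k)
      plan$pattern <- vapply(ks, function(k) pattern_of(mid, k), integer(1))
      for (i in seq_len(n_pres)) {
        k <- ks[i]
        s <- list()
        if (plan$condition[i] != "mask_only") {
          t_mcs <- net$v1_patterns$patterns[[pattern_of(mid, k)]]
          s$t <- make_stimulus(net$geom, t_mcs, plan$target_onset[i],
                               pr$target_duration, pr$relay_rate)
        }
        if (plan$condition[i] != "target_only") {
          m_mcs <- c(net$v1_patterns$patterns[[pattern_of(mid - d, k)]],
                     net$v1_patterns$patterns[[pattern_of(mid + d, k)]])
          s$m <- make_stimulus(net$geom, m_mcs, plan$mask_onset[i],
                               pr$mask_duration, pr$relay_rate)
        }
        sched[[i]] <- do.call(rbind, s)
      }
    }
    schedule <- do.call(rbind, sched)
    rownames(schedule) <- NULL
    list(plan = plan, schedule = schedule,
         duration = n_pres * pr$spacing)
  })
}

#' Run one backward-masking trial
#'
#' Simulates the full trial and applies the completion criterion to the
#' analysed target pattern of every presentation, in V1, V2 and both.
#'
#' @param net the individual's network.
#' @param cfg the \code{\link{model_config}}.
#' @param trial_seed trial seed (stimulus times and background noise).
#' @param soas SOA sweep.
#' @param criterion a \code{\link{completion_criterion}}; default derives
#'   the minicolumn threshold from the pattern size.
#' @param dt integration step (ms).
#' @return data.frame with one row per presentation: condition, soa,
#'   completion flags for V1, V2 and both.
#' @export
run_trial <- function(net, cfg, trial_seed = 1L, soas = cfg$protocol$soas,
                      criterion = completion_criterion(), dt = 0.1) {
  trial <- build_trial(net, cfg, trial_seed, soas)
  raster <- run_network(net, trial$schedule, duration = trial$duration,
                        dt = dt, seed = trial_seed)
  plan <- trial$plan
  res <- vector("list", nrow(plan))
  spacing <- cfg$protocol$spacing
  for (i in seq_len(nrow(plan))) {
    window <- c(plan$target_onset[i], plan$slot_start[i] + spacing)
    pat <- plan$pattern[i]
    comp <- detect_completion(raster,
                              list(V1 = net$v1_patterns$patterns[[pat]],
                                   V2 = net$v2_patterns$patterns[[linked_pattern(net, pat)]]),
                              criterion, window)
    res[[i]] <- data.frame(condition = plan$condition[i], soa = plan$soa[i],
                           pattern = pat,
                           complete_v1 = comp[["V1"]], complete_v2 = comp[["V2"]],
                           complete_both = comp[["both"]])
  }
  do.call(rbind, res)
}

linked_pattern <- function(net, v1_pattern_id) {
  net$linkage$v2[match(v1_pattern_id, net$linkage$v1)]
}

#' Run a full masking experiment
#'
#' Simulates \code{n_individuals} independently wired individuals for
#' \code{n_trials} trials each (25 trials per condition set on the
#' defaults), for one or both feedback conditions, and collects the
#' per-presentation completion flags.
#'
#' @param cfg a \code{\link{model_config}}.
#' @param n_individuals,n_trials experiment size (defaults from config).
#' @param feedback logical vector of feedback conditions to run
#'   (default just \code{cfg$feedback}).
#' @param seed master seed; individual seeds and trial seeds are derived
#'   from it deterministically.
#' @param soas SOA sweep.
#' @param dt integration step (ms).
#' @param verbose print per-trial progress lines.
#' @return A data.frame of class \code{"masking_experiment"}: one row per
#'   (individual, trial, feedback, presentation).
#' @export
run_experiment <- function(cfg, n_individuals = cfg$protocol$n_individuals,
                           n_trials = cfg$protocol$n_trials,
                           feedback = cfg$feedback,
                           seed = 1L, soas = cfg$protocol$soas, dt = 0.1,
                           verbose = FALSE) {
  out <- list()
  for (fb in feedback) {
    cfg_fb <- cfg; cfg_fb$feedback <- fb
    for (ind in seq_len(n_individuals)) {
      ind_seed <- derive_seed(seed, 7919, ind)
      net <- build_model(cfg_fb, individual_seed = ind_seed)
      for (tr in seq_len(n_trials)) {
        trial_seed <- derive_seed(seed, 104729, ind * 389 + tr)
        rows <- run_trial(net, cfg_fb, trial_seed = trial_seed, soas = soas, dt = dt)
        rows <- cbind(individual = ind, trial = tr, feedback = fb, rows)
        out[[length(out) + 1L]] <- rows
        if (verbose) {
          message(sprintf("[%s fb=%s] individual %d trial %d: both-complete %d/%d",
                          cfg$model, fb, ind, tr,
                          sum(rows$complete_both), nrow(rows)))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("masking_experiment", "data.frame")
  res
}

#' Calibrate the global conductance scale factors
#'
#' Searches the excitatory and inhibitory conductance scales so that (i)
#' target-only presentations complete regionally (layer 2/3 of both V1
#' and V2) in at least \code{target_rate} of calibration trials, (ii)
#' mask-only presentations never complete the target pattern, and (iii)
#' there is no runaway activity (mean pyramidal rate below 100 Hz).  The
#' search is a coarse grid on the excitatory scale crossed with the
#' inhibitory candidates, followed by a bisection refinement on the
#' excitatory scale, using a fixed calibration seed and short
#' (target-only + mask-only) probe trials.
#'
#' @param cfg a \code{\link{model_config}}.
#' @param g_exc_grid,g_inh_grid candidate scale factors.
#' @param n_probe calibration trials per candidate (>= 10 for the final
#'   acceptance check of a chosen candidate).
#' @param target_rate required target-only regional completion rate.
#' @param seed fixed calibration seed.
#' @param refine bisection steps on the excitatory scale.
#' @param dt integration step.
#' @param verbose print probe summaries.
#' @return list with the chosen \code{g_exc}, \code{g_inh}, the probe
#'   table, and \code{ok}; if no candidate satisfies all three criteria,
#'   an error carries the diagnostic table.
#' @export
calibrate <- function(cfg, g_exc_grid = c(0.8, 1.0, 1.25, 1.5),
                      g_inh_grid = c(0.8, 1.0, 1.25),
                      n_probe = 10L, target_rate = 0.9,
                      seed = 42L, refine = 3L, dt = 0.1, verbose = FALSE) {
  probe <- function(ge, gi) {
    cfg2 <- cfg
    cfg2$wiring$g_exc <- ge; cfg2$wiring$g_inh <- gi
    res <- run_experiment(cfg2, n_individuals = 2L,
                          n_trials = ceiling(n_probe / 2), feedback = cfg$feedback,
                          seed = seed, soas = numeric(0), dt = dt)
    t_rows <- res[res$condition == "target_only", ]
    m_rows <- res[res$condition == "mask_only", ]
    c(target = mean(t_rows$complete_both), mask = mean(m_rows$complete_both))
  }
  rows <- list()
  best <- NULL
  for (gi in g_inh_grid) for (ge in g_exc_grid) {
    p <- probe(ge, gi)
    rows[[length(rows) + 1L]] <- data.frame(g_exc = ge, g_inh = gi,
                                            target_rate = p[["target"]],
                                            mask_rate = p[["mask"]])
    if (verbose) message(sprintf("g_exc=%.3g g_inh=%.3g: target %.2f mask %.2f",
                                 ge, gi, p[["target"]], p[["mask"]]))
    ok <- p[["target"]] >= target_rate && p[["mask"]] == 0
    if (ok && (is.null(best) || ge < best$g_exc)) {
      best <- list(g_exc = ge, g_inh = gi)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(best)) {
    stop(paste0("calibration failure: no candidate met all criteria\n",
                paste(utils::capture.output(print(tab)), collapse = "\n")))
  }
  # bisect the excitatory scale downward toward the completion transition
  lo_candidates <- g_exc_grid[g_exc_grid < best$g_exc]
  lo <- if (length(lo_candidates)) max(lo_candidates) else best$g_exc * 0.7
  hi <- best$g_exc
  for (i in seq_len(refine)) {
    mid <- (lo + hi) / 2
    p <- probe(mid, best$g_inh)
    if (verbose) message(sprintf("bisect g_exc=%.4g: target %.2f mask %.2f",
                                 mid, p[["target"]], p[["mask"]]))
    if (p[["target"]] >= target_rate && p[["mask"]] == 0) hi <- mid else lo <- mid
  }
  list(g_exc = hi, g_inh = best$g_inh, probes = tab, ok = TRUE)
}
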