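test_that("a silenced network stays silent and at rest", {
  net <- tiny1()
  r <- run_network(net, NULL, duration = 1000, seed = 1, background = FALSE,
                   trace_cells = net$cells$id[net$cells$class == "pyramidal"][1],
                   trace_every = 100L)
  expect_identical(nrow(r$events), 0L)
  # resting fixed point: after settling onto the numerical rest state
  # (a few ms), the membrane potential does not drift at all
  tr <- attr(r, "trace")
  expect_lt(max(abs(tr[-1] - tr[2])), 1e-9)
  expect_lt(max(abs(tr - tr[1])), 1e-3)   # and settling itself is tiny
})

test_that("identical seed pairs replay bit-identically; trial seeds differ", {
  net <- tiny1()
  sched <- force_spikes(net, cell_ids(net$geom, "LGN", mc = 1, class = "relay"),
                        c(50, 60, 70))
  a <- run_network(net, sched, duration = 400, seed = 7)
  b <- run_network(net, sched, duration = 400, seed = 7)
  c <- run_network(net, sched, duration = 400, seed = 8)
  expect_identical(a$events, b$events)
  expect_false(identical(a$events, c$events))
})

test_that("forced spikes appear exactly at their scheduled times", {
  net <- tiny1()
  relays <- cell_ids(net$geom, "LGN", mc = 1:2, class = "relay")[1:5]
  sched <- force_spikes(net, relays, 100)
  r <- run_network(net, sched, duration = 200, seed = 1, background = FALSE)
  lgn <- r$events[r$events$area == "LGN", ]
  expect_identical(nrow(lgn), 5L)
  expect_true(all(lgn$time == 100))
  expect_setequal(lgn$cell, relays)
})

test_that("force_spikes validates ids and bounds", {
  net <- tiny1()
  expect_identical(nrow(force_spikes(net, integer(0), numeric(0))), 0L)
  expect_error(force_spikes(net, net$geom$n_cells + 1L, 10), "unknown cell")
  sched <- force_spikes(net, 1L, 500)
  expect_error(run_network(net, sched, duration = 500), "overflow")
})

test_that("inter-areal delay is respected end to end", {
  net <- tiny1()
  # force a volley on V1 L4 pyramidals of one pattern minicolumn; with
  # background off, nothing can reach V2 before the 10 ms projection delay
  mc <- net$v1_patterns$patterns[[1]][1]
  l4 <- cell_ids(net$geom, "V1", "L4", mc, "pyramidal")
  sched <- force_spikes(net, rep(l4, 3), rep(c(50, 52, 54), each = length(l4)))
  r <- run_network(net, sched, duration = 300, seed = 1, background = FALSE)
  v1_first <- min(r$events$time[r$events$area == "V1"])
  v2 <- r$events$time[r$events$area == "V2"]
  if (length(v2)) expect_gte(min(v2), v1_first + 10)
  # and the membrane of a V2 cell with a feedforward synapse from one of the
  # forced cells is flat for the first 10 ms, depolarized afterwards
  ct <- net$cells
  syn <- which(net$frag$src %in% l4 & ct$area[net$frag$tgt] == "V2")[1]
  expect_false(is.na(syn))
  tgt <- net$frag$tgt[syn]
  r2 <- run_network(net, sched, duration = 100, seed = 1, background = FALSE,
                    trace_cells = tgt, trace_every = 1L)
  tr <- attr(r2, "trace")
  # quiescent (settled) until 50 + 10 ms, depolarized afterwards
  expect_lt(max(abs(tr[100:599] - tr[599])), 1e-9)
  expect_gt(max(abs(tr[600:1000] - tr[599])), 1e-3)
})

test_that("an adapting pyramidal cell lengthens its inter-spike intervals", {
  net <- tiny1()
  pyr <- net$cells$id[net$cells$area == "V1" & net$cells$layer == "L23" &
                        net$cells$class == "pyramidal"][1]
  inj <- data.frame(cell = pyr, compartment = "soma", amp = 0.6,
                    from = 100, to = 1100)
  r <- run_network(net, NULL, duration = 1100, seed = 1, background = FALSE,
                   inject = inj)
  isi <- diff(r$events$time[r$events$cell == pyr])
  expect_gte(length(isi), 10)
  # after the first interval (sodium gates still settling), intervals
  # lengthen monotonically up to integration jitter (5% of the mean)
  first10 <- isi[2:10]
  expect_true(all(diff(first10) >= -0.05 * mean(first10)))
  expect_gt(first10[length(first10)], 1.2 * first10[1])
})

test_that("a basket cell fires at constant inter-spike intervals", {
  net <- tiny1()
  bas <- net$cells$id[net$cells$class == "basket"][1]
  inj <- data.frame(cell = bas, compartment = "soma", amp = 0.1,
                    from = 100, to = 1100)
  r <- run_network(net, NULL, duration = 1100, seed = 1, background = FALSE,
                   inject = inj)
  isi <- diff(r$events$time[r$events$cell == bas])
  expect_gte(length(isi), 20)
  after_first <- isi[-1]
  expect_lt(max(abs(after_first - mean(after_first))) / mean(after_first), 0.05)
})

test_that("NMDA input passes more current at depolarized potentials", {
  # an NMDA-dominated synapse driven by a forced presynaptic train; the
  # magnesium block makes the EPSP shrink disproportionately when the cell
  # is held hyperpolarized relative to rest (rest being the more
  # depolarized of the two holding levels)
  net <- fixture_network("tiny_model1", individual_seed = 4L, nmda_ratio = 8,
                         g_exc = 0.04)
  st <- synapse_table(net)
  ct <- net$cells
  sel <- which(st$receptor == "NMDA" & st$target == "distal" &
                 ct$class[st$tgt] == "pyramidal")[1]
  src <- st$src[sel]; tgt <- st$tgt[sel]
  sched <- force_spikes(net, rep(src, 5), c(300, 320, 340, 360, 380))
  epsp <- function(hold) {
    inj <- if (hold != 0) {
      data.frame(cell = tgt, compartment = "soma", amp = hold, from = 0, to = 800)
    } else NULL
    r <- run_network(net, sched, duration = 800, seed = 2, background = FALSE,
                     inject = inj, trace_cells = tgt, trace_every = 1L)
    expect_identical(sum(r$events$cell == tgt), 0L)  # subthreshold probe
    tr <- attr(r, "trace")
    baseline <- tr[2990]   # just before the first presynaptic spike
    max(tr[3000:7000]) - baseline
  }
  drop_hyper <- epsp(-0.15)
  at_rest <- epsp(0)
  expect_gt(at_rest, 1.3 * drop_hyper)
})

test_that("sustained re-excitation burns out through calcium adaptation", {
  net <- tiny1()
  mc <- net$v1_patterns$patterns[[1]][1]
  pyr <- cell_ids(net$geom, "V1", "L23", mc, "pyramidal")
  inj <- data.frame(cell = pyr, compartment = "soma", amp = 0.6,
                    from = 50, to = 900)
  r <- run_network(net, NULL, duration = 900, seed = 3, background = FALSE,
                   inject = inj)
  ev <- r$events[r$events$cell %in% pyr, ]
  early <- sum(ev$time >= 50 & ev$time < 150)
  late <- sum(ev$time >= 750 & ev$time < 850)
  expect_gt(early, 0)
  expect_lt(late, 0.5 * early)
})

test_that("numerical instability is reported with the offending cell", {
  net <- tiny1()
  pyr <- net$cells$id[net$cells$class == "pyramidal"][1]
  inj <- data.frame(cell = pyr, compartment = "initial_segment", amp = 1e7,
                    from = 10, to = 400)
  expect_error(run_network(net, NULL, duration = 400, seed = 1, inject = inj),
               "instability")
})

test_that("raster round-trips through the tab-separated event format", {
  net <- tiny1()
  sched <- force_spikes(net, cell_ids(net$geom, "LGN", mc = 1, class = "relay"), 50)
  r <- run_network(net, sched, duration = 200, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_raster_tsv(r, path)
  back <- read_raster_tsv(path, duration = 200, n_cells = r$n_cells)
  expect_equal(back$events$time, r$events$time)
  expect_equal(back$events$cell, r$events$cell)
  expect_equal(back$events$mc, r$events$mc)
  unlink(path)
})

test_that("total spiking grows sublinearly with background rate beyond saturation", {
  net <- tiny1()
  spikes_at <- function(rate) {
    net2 <- net
    net2$dyn <- dynamics_config(background_rate = rate)
    net2$comp <- attractormask:::build_comp_tables(net2$geom, net2$dyn, net2$cells)
    nrow(run_network(net2, NULL, duration = 1000, seed = 5)$events)
  }
  a <- spikes_at(1000); b <- spikes_at(2000); c <- spikes_at(4000)
  expect_gt(a, 0)
  # refractoriness and adaptation saturate the response: doubling the
  # drive must yield far less than double the spikes
  expect_lt(b / a, 1.8)
  expect_lt(c / b, 1.8)
})
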