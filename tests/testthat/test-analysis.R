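test_that("completion requires the strict minicolumn and spike thresholds", {
  # 10 spikes in exactly 7 of 10 minicolumns -> complete
  ev <- do.call(rbind, lapply(1:7, function(m) l23_events(m, 10)))
  r <- make_raster(ev)
  crit <- completion_criterion()
  expect_true(detect_completion(r, list(V1 = 1:10), crit)[["V1"]])
  # 10 spikes in 6 minicolumns plus 9 in a 7th -> incomplete
  ev2 <- rbind(do.call(rbind, lapply(1:6, function(m) l23_events(m, 10))),
               l23_events(7, 9))
  expect_false(detect_completion(make_raster(ev2), list(V1 = 1:10), crit)[["V1"]])
})

test_that("the minicolumn threshold generalizes as ceiling(0.7 n)", {
  crit <- completion_criterion()
  # 9-minicolumn line pattern: needs 7
  ev <- do.call(rbind, lapply(1:7, function(m) l23_events(m, 10)))
  expect_true(detect_completion(make_raster(ev), list(V1 = 1:9), crit)[["V1"]])
  ev6 <- do.call(rbind, lapply(1:6, function(m) l23_events(m, 10)))
  expect_false(detect_completion(make_raster(ev6), list(V1 = 1:9), crit)[["V1"]])
})

test_that("scope 'both' requires simultaneous V1 and V2 completion", {
  crit <- completion_criterion()
  ev_v1 <- do.call(rbind, lapply(1:7, function(m) l23_events(m, 10, area = "V1")))
  ev_v2 <- do.call(rbind, lapply(1:7, function(m) l23_events(m, 10, area = "V2")))
  both <- detect_completion(make_raster(rbind(ev_v1, ev_v2)),
                            list(V1 = 1:10, V2 = 1:10), crit)
  expect_true(both[["both"]])
  v1only <- detect_completion(make_raster(ev_v1), list(V1 = 1:10, V2 = 1:10), crit)
  expect_true(v1only[["V1"]])
  expect_false(v1only[["V2"]])
  expect_false(v1only[["both"]])
})

test_that("only pyramidal spikes of the analysed layer inside the window count", {
  base <- l23_events(1, 10)
  crit <- completion_criterion(min_minicolumns = 1L)
  expect_true(detect_completion(make_raster(base), list(V1 = 1), crit)[["V1"]])
  wrong_layer <- transform(base, layer = "L4")
  expect_false(detect_completion(make_raster(wrong_layer), list(V1 = 1), crit)[["V1"]])
  wrong_class <- transform(base, class = "basket")
  expect_false(detect_completion(make_raster(wrong_class), list(V1 = 1), crit)[["V1"]])
  expect_false(detect_completion(make_raster(base), list(V1 = 1), crit,
                                 window = c(500, 1000))[["V1"]])
})

test_that("detector agrees with a brute-force counting oracle on random rasters", {
  oracle <- function(events, mcs, min_spikes, min_mc, window, area) {
    n_ok <- 0
    for (m in mcs) {
      cnt <- 0
      for (i in seq_len(nrow(events))) {
        if (events$area[i] == area && events$layer[i] == "L23" &&
            events$class[i] == "pyramidal" && events$mc[i] == m &&
            events$time[i] >= window[1] && events$time[i] < window[2]) {
          cnt <- cnt + 1
        }
      }
      if (cnt >= min_spikes) n_ok <- n_ok + 1
    }
    n_ok >= min_mc
  }
  set.seed(11)
  crit <- completion_criterion()
  for (i in 1:1000) {
    n <- sample(0:60, 1)
    ev <- data.frame(
      time = stats::runif(n, 0, 100),
      cell = seq_len(max(n, 1))[seq_len(n)],
      area = sample(c("V1", "V2"), n, replace = TRUE),
      layer = sample(c("L23", "L4"), n, replace = TRUE),
      mc = sample(1:6, n, replace = TRUE),
      hc = rep(NA_integer_, n),
      class = sample(c("pyramidal", "basket"), n, replace = TRUE))
    mcs <- sort(sample(1:6, 4))
    crit_i <- completion_criterion(min_minicolumns = sample(1:3, 1),
                                   min_spikes = sample(1:4, 1))
    win <- sort(stats::runif(2, 0, 100))
    got <- detect_completion(make_raster(ev, duration = 100), list(V1 = mcs),
                             crit_i, window = win)[["V1"]]
    want <- oracle(ev, mcs, crit_i$min_spikes, crit_i$min_minicolumns, win, "V1")
    expect_identical(got, want)
  }
})

test_that("completion is monotone: adding spikes never revokes completion", {
  set.seed(21)
  crit <- completion_criterion()
  for (i in 1:50) {
    n <- sample(5:40, 1)
    ev <- data.frame(time = stats::runif(n, 0, 100), cell = seq_len(n), area = "V1",
                     layer = "L23", mc = sample(1:10, n, replace = TRUE),
                     hc = NA_integer_, class = "pyramidal")
    base <- detect_completion(make_raster(ev, 100), list(V1 = 1:10),
                              completion_criterion(min_minicolumns = 2L,
                                                   min_spikes = 3L))[["V1"]]
    extra <- rbind(ev, l23_events(sample(1:10, 1), sample(1:10, 1)))
    more <- detect_completion(make_raster(extra, 100), list(V1 = 1:10),
                              completion_criterion(min_minicolumns = 2L,
                                                   min_spikes = 3L))[["V1"]]
    if (base) expect_true(more)
  }
})

test_that("masking curves use exact percentage arithmetic", {
  res <- data.frame(
    individual = rep(1:5, each = 5), trial = rep(1:5, 5), feedback = TRUE,
    condition = "target_mask", soa = 40, pattern = 1,
    complete_v1 = rep(c(TRUE, FALSE), c(20, 5)),
    complete_v2 = rep(c(TRUE, FALSE), c(13, 12)),
    complete_both = rep(c(TRUE, FALSE), c(13, 12)))
  mc <- masking_curve(res)
  expect_equal(mc$percent[mc$scope == "both"], 52)
  expect_equal(mc$percent[mc$scope == "V1"], 80)
  expect_equal(mc$n[1], 25)
  all_done <- transform(res, complete_both = TRUE)
  expect_equal(masking_curve(all_done)$percent[
    masking_curve(all_done)$scope == "both"], 100)
})

test_that("masking curves are invariant to row permutation", {
  set.seed(3)
  res <- data.frame(
    individual = sample(1:5, 50, TRUE), trial = sample(1:5, 50, TRUE),
    feedback = sample(c(TRUE, FALSE), 50, TRUE),
    condition = sample(c("target_only", "target_mask"), 50, TRUE),
    soa = sample(c(NA, 20, 40), 50, TRUE), pattern = 1,
    complete_v1 = sample(c(TRUE, FALSE), 50, TRUE),
    complete_v2 = sample(c(TRUE, FALSE), 50, TRUE),
    complete_both = sample(c(TRUE, FALSE), 50, TRUE))
  res$condition[is.na(res$soa)] <- "target_only"
  res$soa[res$condition == "target_only"] <- NA
  a <- masking_curve(res)
  b <- masking_curve(res[sample(nrow(res)), ])
  expect_equal(a, b)
})

test_that("masking-type rule matches its definitional examples", {
  expect_identical(classify_masking_type(c(10, 30, 50, 70, 90, 95)), "type_A")
  expect_identical(classify_masking_type(c(60, 40, 20, 35, 70, 90)), "type_B")
  expect_identical(classify_masking_type(c(50, 51, 49, 50, 52, 48)), "flat")
  expect_identical(classify_masking_type(c(90, 70, 50, 30, 20, 10)), "ambiguous")
  expect_error(classify_masking_type(c(10, 20, 30)), "4 SOA")
})

test_that("rule agrees with a definition-enumeration oracle on the percentage lattice", {
  oracle <- function(v, tol) {
    # direct transcription of the definitions, checked in precedence order
    rng <- max(v) - min(v)
    if (rng <= tol) return("flat")
    nondecr <- TRUE
    for (i in 2:length(v)) if (v[i] < v[i - 1] - tol) nondecr <- FALSE
    if (nondecr) return("type_A")
    dip <- FALSE
    for (i in 2:(length(v) - 1)) {
      if (v[i] < v[1] - tol && v[i] < v[length(v)] - tol) dip <- TRUE
    }
    if (dip) return("type_B")
    "ambiguous"
  }
  lattice <- c(0, 25, 50, 75, 100)
  grid <- expand.grid(rep(list(lattice), 6))
  for (i in seq_len(nrow(grid))) {
    v <- as.numeric(grid[i, ])
    expect_identical(classify_masking_type(v, tolerance = 4), oracle(v, 4))
  }
})

test_that("classification is invariant to affine rescaling with the tolerance", {
  set.seed(13)
  for (i in 1:100) {
    v <- stats::runif(6, 0, 100)
    a <- stats::runif(1, 0.1, 3); b <- stats::runif(1, -10, 10)
    expect_identical(classify_masking_type(v, 4),
                     classify_masking_type(a * v + b, a * 4))
  }
})
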