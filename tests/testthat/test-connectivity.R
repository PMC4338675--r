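test_that("every inter-areal synapse carries the 10 ms latency", {
  net <- tiny1()
  st <- synapse_table(net)
  ct <- net$cells
  inter <- (ct$area[st$src] == "V1" & ct$area[st$tgt] == "V2") |
    (ct$area[st$src] == "V2" & ct$area[st$tgt] == "V1")
  expect_gt(sum(inter), 0)
  expect_true(all(st$delay[inter] == 10))
  expect_true(all(st$delay >= 0))
})

test_that("no cell synapses onto itself", {
  st <- synapse_table(tiny1())
  expect_false(any(st$src == st$tgt))
})

test_that("basket cells receive no NMDA", {
  net <- tiny1()
  st <- synapse_table(net)
  onto_basket <- net$cells$class[st$tgt] == "basket"
  expect_gt(sum(onto_basket), 0)
  expect_false(any(st$receptor[onto_basket] == "NMDA"))
  # pyramidal and RSNP cells do receive NMDA
  expect_true(any(st$receptor[net$cells$class[st$tgt] == "pyramidal"] == "NMDA"))
})

test_that("GABA_A lands on somata; excitation on dendritic slots", {
  st <- synapse_table(tiny1())
  expect_true(all(st$target[st$receptor == "GABA_A"] == "soma"))
  expect_true(all(st$target[st$receptor != "GABA_A"] != "soma"))
})

test_that("wiring replays bit-identically per individual seed and differs across seeds", {
  a <- fixture_network("tiny_model1", individual_seed = 5L)
  b <- fixture_network("tiny_model1", individual_seed = 5L)
  c <- fixture_network("tiny_model1", individual_seed = 6L)
  expect_identical(a$frag, b$frag)
  expect_false(identical(a$frag, c$frag))
  expect_identical(a$geom, c$geom)   # geometry unaffected by the seed
})

test_that("disabling feedback removes exactly the V2-to-V1 synapses", {
  on <- fixture_network("tiny_model1", individual_seed = 3L, feedback = TRUE)
  off <- fixture_network("tiny_model1", individual_seed = 3L, feedback = FALSE)
  ct <- on$cells
  is_fb <- function(net) {
    ct$area[net$frag$src] == "V2" & ct$area[net$frag$tgt] == "V1"
  }
  expect_gt(sum(is_fb(on)), 0)
  expect_identical(sum(is_fb(off)), 0L)
  # the remaining synapses are identical (paired individuals)
  keep <- !is_fb(on)
  expect_identical(lapply(on$frag, `[`, keep), off$frag)
})

test_that("long-range excitatory synapses stay within their memory pattern", {
  net <- tiny1()
  st <- synapse_table(net)
  ct <- net$cells
  for (area in c("V1", "V2")) {
    ps <- if (area == "V1") net$v1_patterns else net$v2_patterns
    pattern_of <- rep(NA_integer_, net$geom$n_mc)
    for (i in seq_along(ps$patterns)) pattern_of[ps$patterns[[i]]] <- i
    # distal excitatory pyramidal->pyramidal synapses within the area are
    # the long-range within-pattern connections
    sel <- ct$area[st$src] == area & ct$area[st$tgt] == area &
      st$target == "distal" & ct$class[st$src] == "pyramidal" &
      ct$class[st$tgt] == "pyramidal"
    if (!any(sel)) next
    src_pat <- pattern_of[ct$mc[st$src[sel]]]
    tgt_pat <- pattern_of[ct$mc[st$tgt[sel]]]
    expect_true(all(!is.na(src_pat) & src_pat == tgt_pat))
  }
})

test_that("pattern projections target exactly proj_fanin destination minicolumns", {
  net <- tiny2()   # line patterns of 3 minicolumns: fan-in capped at 3
  st <- synapse_table(net)
  ct <- net$cells
  fanin <- min(net$wc$proj_fanin, 3L)
  for (i in seq_len(nrow(net$linkage))) {
    p1 <- net$v1_patterns$patterns[[net$linkage$v1[i]]]
    p2 <- net$v2_patterns$patterns[[net$linkage$v2[i]]]
    sel <- ct$area[st$src] == "V1" & ct$area[st$tgt] == "V2" &
      ct$mc[st$src] %in% p1 & ct$class[st$tgt] == "pyramidal"
    dest <- unique(ct$mc[st$tgt[sel]])
    expect_lte(length(dest), fanin)
    expect_true(all(dest %in% p2))
  }
})

test_that("realized long-range destination fraction matches the 25% probability", {
  # in L2/3 the pairwise minicolumn connection probability is 1, so the
  # number of axons is known exactly: one per ordered within-pattern pair,
  # each hitting the destination pyramidals independently at p = 0.25
  hits <- 0; candidates <- 0
  for (seed in 1:6) {
    net <- fixture_network("tiny_model1", individual_seed = seed)
    st <- synapse_table(net)
    ct <- net$cells
    P <- net$geom$counts[["pyramidal"]]
    sel <- st$target == "distal" & st$receptor == "AMPA" &
      ct$class[st$tgt] == "pyramidal" & ct$area[st$src] == ct$area[st$tgt] &
      ct$layer[st$tgt] == "L23"
    hits <- hits + sum(sel)
    axons <- sum(vapply(list(net$v1_patterns, net$v2_patterns), function(ps) {
      sum(lengths(ps$patterns) * (lengths(ps$patterns) - 1L))
    }, numeric(1)))
    candidates <- candidates + axons * P
  }
  p_hat <- hits / candidates
  se <- sqrt(0.25 * 0.75 / candidates)
  expect_lt(abs(p_hat - 0.25), 3 * se)
})

test_that("model 2 lateral inhibition follows the (0.5, 0.25, 0) distance profile", {
  counts <- c(d1_hit = 0, d1_all = 0, d2_hit = 0, d2_all = 0, d3 = 0)
  for (seed in 1:4) {
    net <- fixture_network("tiny_model2", individual_seed = seed)
    st <- synapse_table(net)
    ct <- net$cells
    g <- net$geom
    sel <- which(st$receptor == "GABA_A" & ct$class[st$src] == "basket")
    src_hc <- ct$hc[st$src[sel]]; tgt_hc <- ct$hc[st$tgt[sel]]
    dcol <- abs(g$hc_col[src_hc] - g$hc_col[tgt_hc])
    same_row <- g$hc_row[src_hc] == g$hc_row[tgt_hc]
    expect_true(all(dcol[src_hc != tgt_hc] <= 2))
    expect_true(all(same_row | src_hc == tgt_hc))
    # candidate synapse counts per distance: ordered same-row hc pairs
    # x baskets in the source hc x pyramidals in the target hc,
    # per area (2) and layer (3)
    B <- g$counts[["basket"]] * g$mc_per_hc
    P <- g$counts[["pyramidal"]] * g$mc_per_hc
    pairs_d1 <- g$grid[1] * (g$grid[2] - 1) * 2
    pairs_d2 <- g$grid[1] * max(g$grid[2] - 2, 0) * 2
    counts["d1_hit"] <- counts["d1_hit"] + sum(dcol == 1 & src_hc != tgt_hc)
    counts["d1_all"] <- counts["d1_all"] + 2 * 3 * pairs_d1 * B * P
    counts["d2_hit"] <- counts["d2_hit"] + sum(dcol == 2)
    counts["d2_all"] <- counts["d2_all"] + 2 * 3 * pairs_d2 * B * P
  }
  p1 <- counts[["d1_hit"]] / counts[["d1_all"]]
  p2 <- counts[["d2_hit"]] / counts[["d2_all"]]
  se1 <- sqrt(0.5 * 0.5 / counts[["d1_all"]])
  se2 <- sqrt(0.25 * 0.75 / counts[["d2_all"]])
  expect_lt(abs(p1 - 0.5), 3 * se1)
  expect_lt(abs(p2 - 0.25), 3 * se2)
})

test_that("model 1 lateral inhibition stays inside the hypercolumn", {
  net <- tiny1()
  st <- synapse_table(net)
  ct <- net$cells
  sel <- st$receptor == "GABA_A" & ct$class[st$src] == "basket"
  expect_true(all(ct$hc[st$src[sel]] == ct$hc[st$tgt[sel]]))
})

test_that("an all-zero probability configuration yields no synapses", {
  geom <- build_geometry(geometry_config("model1", grid = c(2, 2),
                                         minicolumns_per_hypercolumn = 4L,
                                         pyramidal = 2L, basket = 1L, rsnp = 1L,
                                         relays = 1L))
  wc <- wiring_config("model1", p_recurrent = 0, p_pyr_basket = 0,
                      lateral_profile = c(0), p_interlaminar = 0, p_rsnp_pyr = 0,
                      p_longrange_pyr = 0, p_longrange_rsnp = 0, p_pair_l23 = 0,
                      p_pair_l4 = 0, p_lgn_pyr = 0, p_lgn_basket = 0)
  set.seed(1)
  frag <- wire_microcircuit(geom, wc, "V1")
  expect_length(frag$src, 0L)
  expect_length(wire_lgn(geom, wc)$src, 0L)
})

test_that("single-minicolumn patterns produce no long-range synapses", {
  geom <- build_geometry(geometry_config("model1", grid = c(2, 2),
                                         minicolumns_per_hypercolumn = 4L,
                                         pyramidal = 2L, basket = 1L, rsnp = 1L,
                                         relays = 1L))
  ps <- generate_patterns_random(geom, 2L, 1L, hypercolumns_sampled = 1L, seed = 1L)
  set.seed(2)
  expect_length(wire_longrange(geom, ps, wiring_config("model1"), "V1")$src, 0L)
})
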