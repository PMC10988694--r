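test_that("base morphology has two terminal branches and five nodal compartments", {
  g <- build_morphology(morphology_config())
  nseg_t <- sum(g$region == "terminal")
  expect_equal(nseg_t %% 2, 0)                    # two equal branches
  expect_equal(sum(g$region %in% c("heminode", "node")), 5)
  expect_equal(sum(g$region == "heminode"), 1)
  # connected tree: exactly one root, all parents precede children
  expect_equal(sum(is.na(g$parent)), 1)
  ok <- vapply(seq_along(g$parent), function(i)
    is.na(g$parent[i]) || g$parent[i] < i, TRUE)
  expect_true(all(ok))
  expect_error(build_morphology(morphology_config(0)), "> 0")
})

test_that("terminal length multiplier scales terminal membrane area", {
  a1 <- with(build_morphology(morphology_config(1)),
             sum(area_cm2[region == "terminal"]))
  a10 <- with(build_morphology(morphology_config(10)),
              sum(area_cm2[region == "terminal"]))
  expect_equal(a10 / a1, 10, tolerance = 1e-9)
})

test_that("density table is applied with pS/um2 -> S/cm2 conversion", {
  g <- assign_channels(build_morphology(morphology_config()))
  hemi <- which(g$region == "heminode")
  expect_equal(unname(g$densities[hemi, "nav16"]), 2500 * 1e-4)  # 0.25 S/cm2
  para <- g$region == "paranode"
  expect_true(all(g$densities[para, "kv1"] == 0.01))
  expect_true(all(g$densities[!para, "kv1"] == 0))
  inter <- g$region == "internode"
  expect_true(all(g$densities[inter, ] == 0))
  expect_error(assign_channels(build_morphology(morphology_config()),
                               list(terminal = c(navX = 1))),
               "unknown channel")
})

test_that("passive steady-state profile matches the finite-cable closed form", {
  # hand-built uniform passive cable, sealed ends, current at one end
  n <- 50; L <- 40; d <- 1.5; Ra <- 100; gl <- 1e-4; El <- -65
  area <- pi * d * L * 1e-8
  r_half <- Ra * (L * 1e-4 / 2) / (pi * (d * 1e-4 / 2)^2)
  g <- structure(list(
    region = rep("terminal", n), length_um = rep(L, n),
    diam_um = rep(d, n), area_cm2 = rep(area, n),
    cm_nF = rep(1 * area * 1e3, n), g_leak_uS = rep(gl * area * 1e6, n),
    parent = c(NA, seq_len(n - 1)),
    g_axial_uS = c(0, rep(1e6 / (2 * r_half), n - 1)),
    e_leak_mV = El,
    probes = list(terminal = 1L, heminode = 2L, node5 = n),
    terminal_comps = 1L, terminal_ref_area_cm2 = area,
    densities = NULL, channels = NULL, config = NULL
  ), class = "compartment_graph")
  inj <- numeric(n); inj[1] <- 0.05                 # nA at the sealed end
  res <- simulate_afferent(g, NULL,
                           sim_config(dt_ms = 0.05, settle_ms = 0,
                                      i_inj_nA = inj),
                           duration_ms = 400)
  V <- res$V_final - El
  lambda <- sqrt((d * 1e-4) / (4 * Ra * gl)) * 1e4   # um
  x <- (seq_len(n) - 0.5) * L                        # segment centres
  ltot <- n * L
  shape <- cosh((ltot - x) / lambda) / cosh(ltot / lambda)
  expect_lt(max(abs(V / V[1] - shape / shape[1])), 0.01)
})

test_that("zero drive leaves the afferent quiescent at rest", {
  g <- assign_channels(build_morphology(morphology_config()))
  res <- simulate_afferent(g, NULL, sim_config(settle_ms = 500),
                           duration_ms = 300)
  for (s in colnames(res$V)) {
    expect_equal(length(detect_spikes(res$t_s, res$V[, s])$times), 0)
    expect_lt(diff(range(res$V[, s])), 1)     # no drift after settling
    expect_lt(res$V[1, s], -60)
  }
})

test_that("coarse 1-segment-per-region build matches the fine resting potential", {
  coarse_regions <- lapply(default_region_specs(), function(r) {
    r$nseg <- 1; r
  })
  g1 <- assign_channels(build_morphology(
    morphology_config(regions = coarse_regions)))
  g2 <- assign_channels(build_morphology(morphology_config()))
  r1 <- simulate_afferent(g1, NULL, sim_config(settle_ms = 300),
                          duration_ms = 100)
  r2 <- simulate_afferent(g2, NULL, sim_config(settle_ms = 300),
                          duration_ms = 100)
  expect_lt(abs(tail(r1$V[, "node5"], 1) - tail(r2$V[, "node5"], 1)), 0.5)
})

test_that("halving dt preserves the spike-train structure", {
  pair <- cached_dt_pair()
  t1 <- pair$coarse$spikes$times
  t2 <- pair$fine$spikes$times
  expect_gt(length(t1), 10)
  expect_equal(length(t1), length(t2))
  # onset and dynamic-phase spikes are tightly reproducible; late
  # hold-phase spikes accumulate phase through the SK feedback loop
  expect_lt(max(abs(t1[1:5] - t2[1:5])) * 1e3, 0.1)
  expect_lt(max(abs(t1 - t2)) * 1e3, 2.5)
})

test_that("drive injected at node5 makes node5 the initiation site", {
  g <- assign_channels(build_morphology(morphology_config()))
  inj <- numeric(length(g$region)); inj[g$probes$node5] <- 0.15
  res <- simulate_afferent(g, NULL,
                           sim_config(settle_ms = 300, i_inj_nA = inj),
                           duration_ms = 300)
  io <- initiation_order(res)
  expect_gt(length(io), 3)
  # once adaptation equilibrates other sites can phase-lead occasionally;
  # the onset events are unambiguous
  lead <- vapply(io[1:3], function(o) o[1] == "node5", TRUE)
  expect_true(all(lead))
})

test_that("voltage divergence is reported with a dt suggestion", {
  g <- assign_channels(build_morphology(morphology_config()))
  drv <- structure(list(t = c(0, 0.05), g_uS = c(5, 5), e_rev_mV = 500),
                   class = "drive_signal")
  expect_error(simulate_afferent(g, drv, sim_config(settle_ms = 0)),
               "dt")
})
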