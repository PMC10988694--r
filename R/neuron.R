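#' Morphology configuration of the Ia afferent
#'
#' The modelled afferent has a fixed topology: two receptor terminal
#' (annulospiral) branches converging on a single preterminal axon, which
#' connects to five nodes of Ranvier (the first being the heminode)
#' separated by myelinated internodes, with paranode segments immediately
#' flanking each node.  Architecture experiments are expressed as length
#' multipliers on the terminal and preterminal regions so that results
#' are fold-changes relative to the base dimensions.
#'
#' @param terminal_length_multiplier,preterminal_length_multiplier
#'   Positive length multipliers applied to the base region dimensions.
#' @param regions Named list of region specifications (see
#'   [default_region_specs()]).
#' @param ra_ohm_cm Axial resistivity (ohm cm).
#' @param e_leak_mV Leak reversal potential (mV).
#' @return An object of class `morphology_config`.
#' @export
morphology_config <- function(terminal_length_multiplier = 1,
                              preterminal_length_multiplier = 1,
                              regions = default_region_specs(),
                              ra_ohm_cm = 100, e_leak_mV = -65) {
  if (terminal_length_multiplier <= 0 || preterminal_length_multiplier <= 0)
    stop("length multipliers must be > 0")
  structure(list(terminal_length_multiplier = terminal_length_multiplier,
                 preterminal_length_multiplier = preterminal_length_multiplier,
                 regions = regions, ra_ohm_cm = ra_ohm_cm,
                 e_leak_mV = e_leak_mV),
            class = "morphology_config")
}

#' Base region dimensions and passive properties
#'
#' Defaults represent an adult-rat-scale Ia ending: 80 um terminal
#' branches, a 10 um preterminal axon, 1.5 um nodes, 3 um paranodes and
#' 100 um myelinated internodes (membrane capacitance and leak reduced
#' 50-fold by myelin).  Lengths/diameters in um, `cm` in uF/cm2,
#' `g_leak` in S/cm2.
#'
#' @return Named list of region specs.
#' @export
default_region_specs <- function() {
  list(
    terminal    = list(length_um = 80, diam_um = 1.5, cm = 1,
                       g_leak = 1e-4, nseg = 4),
    preterminal = list(length_um = 10, diam_um = 0.6, cm = 1,
                       g_leak = 1e-4, nseg = 2),
    heminode    = list(length_um = 1.5, diam_um = 1.5, cm = 1,
                       g_leak = 1e-3, nseg = 1),
    node        = list(length_um = 1.5, diam_um = 1.5, cm = 1,
                       g_leak = 1e-3, nseg = 1),
    paranode    = list(length_um = 3, diam_um = 1.5, cm = 1,
                       g_leak = 1e-4, nseg = 1),
    internode   = list(length_um = 100, diam_um = 1.5, cm = 1 / 50,
                       g_leak = 1e-4 / 50, nseg = 3)
  )
}

# DC space constant (um) for segmentation control
lambda_dc_um <- function(diam_um, ra, g_leak) {
  1e4 * sqrt((diam_um * 1e-4) / (4 * ra * g_leak))
}

#' Build the discretized compartment graph
#'
#' Compartments are ordered root-first (Hines ordering) from the distal
#' tip of the first terminal branch; segment counts are increased where
#' needed so that no segment exceeds one tenth of the region's DC space
#' constant.  Probe sites `terminal` (distal terminal tip), `heminode`
#' and `node5` (most proximal node) are registered.
#'
#' @param cfg A [morphology_config()].
#' @return A `compartment_graph`.
#' @export
build_morphology <- function(cfg = morphology_config()) {
  stopifnot(inherits(cfg, "morphology_config"))
  rg <- cfg$regions
  rg$terminal$length_um <- rg$terminal$length_um * cfg$terminal_length_multiplier
  rg$preterminal$length_um <-
    rg$preterminal$length_um * cfg$preterminal_length_multiplier

  nseg_for <- function(r) {
    lam <- lambda_dc_um(r$diam_um, cfg$ra_ohm_cm, r$g_leak)
    max(r$nseg, ceiling(r$length_um / (0.1 * lam)))
  }

  region <- character(0); len <- numeric(0); diam <- numeric(0)
  cmv <- numeric(0); glv <- numeric(0); parent <- integer(0)
  add_region <- function(kind, parent_of_first, reverse = FALSE) {
    r <- rg[[kind]]
    ns <- nseg_for(r)
    seg_len <- r$length_um / ns
    idx0 <- length(region)
    region <<- c(region, rep(kind, ns))
    len <<- c(len, rep(seg_len, ns))
    diam <<- c(diam, rep(r$diam_um, ns))
    cmv <<- c(cmv, rep(r$cm, ns))
    glv <<- c(glv, rep(r$g_leak, ns))
    parent <<- c(parent, c(parent_of_first, idx0 + seq_len(ns - 1)))
    idx0 + seq_len(ns)             # 1-based indices of the new segments
  }

  iA <- add_region("terminal", NA_integer_)            # branch A, tip = root
  iP <- add_region("preterminal", iA[length(iA)])      # head joins branch A
  iB <- add_region("terminal", iP[1])                  # branch B joins head
  last <- iP[length(iP)]
  ih <- add_region("heminode", last); last <- ih
  nodes <- c(ih)
  for (k in 1:4) {
    ip1 <- add_region("paranode", last)
    ii <- add_region("internode", ip1[length(ip1)])
    ip2 <- add_region("paranode", ii[length(ii)])
    inn <- add_region("node", ip2[length(ip2)])
    nodes <- c(nodes, inn)
    last <- inn
  }

  n <- length(region)
  area_cm2 <- pi * diam * len * 1e-8
  cm_nF <- cmv * area_cm2 * 1e3
  g_leak_uS <- glv * area_cm2 * 1e6
  # axial conductance to parent: series half-cylinder resistances
  r_half <- cfg$ra_ohm_cm * (len * 1e-4 / 2) / (pi * (diam * 1e-4 / 2)^2)
  g_ax <- numeric(n)
  for (i in 2:n) {
    p <- parent[i]
    if (!is.na(p)) g_ax[i] <- 1e6 / (r_half[i] + r_half[p])
  }

  structure(list(
    region = region, length_um = len, diam_um = diam,
    area_cm2 = area_cm2, cm_nF = cm_nF, g_leak_uS = g_leak_uS,
    parent = parent, g_axial_uS = g_ax,
    e_leak_mV = cfg$e_leak_mV,
    probes = list(terminal = 1L, heminode = ih,
                  node5 = nodes[length(nodes)]),
    terminal_comps = c(iA, iB),
    # base-model terminal membrane area: the transduction conductance is
    # distributed at constant density, so total drive scales with
    # terminal area relative to this reference
    terminal_ref_area_cm2 = 2 * pi * cfg$regions$terminal$diam_um *
      cfg$regions$terminal$length_um * 1e-8,
    densities = NULL, channels = NULL,
    config = cfg
  ), class = "compartment_graph")
}

#' @export
print.compartment_graph <- function(x, ...) {
  cat(sprintf("<compartment_graph: %d compartments (%s)%s>\n",
              length(x$region),
              paste(names(table(x$region)), table(x$region),
                    sep = ":", collapse = ", "),
              if (is.null(x$densities)) ", no channels" else ""))
  invisible(x)
}

#' Base channel-density table
#'
#' Region-wise maximal conductance densities of the seven channels, in
#' the conventional units: sodium channels in pS/um2, potassium and SK
#' channels in S/cm2 (the KCNQ density is treated as S/cm2).  Nodes of
#' Ranvier carry the heminode complement; myelinated internodes carry no
#' voltage-gated channels.
#'
#' @return Named list mapping region to a named density vector.
#' @export
default_density_table <- function() {
  list(
    terminal    = c(nav11 = 250, nav16 = 25, nav17 = 250,
                    kv1 = 0, kv33 = 0.012, sk2 = 0.0025, kcnq = 0.0005),
    preterminal = c(nav11 = 0, nav16 = 250, nav17 = 500,
                    kv1 = 0, kv33 = 0, sk2 = 0.0025, kcnq = 0),
    heminode    = c(nav11 = 0, nav16 = 2500, nav17 = 0,
                    kv1 = 0, kv33 = 0.012, sk2 = 0, kcnq = 0.0005),
    node        = c(nav11 = 0, nav16 = 2500, nav17 = 0,
                    kv1 = 0, kv33 = 0.012, sk2 = 0, kcnq = 0.0005),
    paranode    = c(nav11 = 0, nav16 = 0, nav17 = 0,
                    kv1 = 0.01, kv33 = 0, sk2 = 0, kcnq = 0),
    internode   = c(nav11 = 0, nav16 = 0, nav17 = 0,
                    kv1 = 0, kv33 = 0, sk2 = 0, kcnq = 0)
  )
}

# channels whose printed densities are in pS/um2 (converted internally,
# 1 pS/um2 = 1e-4 S/cm2)
.ps_um2_channels <- c("nav11", "nav16", "nav17")

#' Attach channel densities to a compartment graph
#'
#' @param g A `compartment_graph`.
#' @param table Region-to-density map as in [default_density_table()].
#' @param channels Channel model library (defaults to
#'   [spindle_channels()]).
#' @return The graph with a `densities` matrix (S/cm2 per compartment and
#'   channel) and the channel models attached.
#' @export
assign_channels <- function(g, table = default_density_table(),
                            channels = spindle_channels()) {
  stopifnot(inherits(g, "compartment_graph"))
  chnames <- names(channels)
  for (reg in names(table)) {
    unknown <- setdiff(names(table[[reg]]), chnames)
    if (length(unknown))
      stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  }
  dens <- matrix(0, length(g$region), length(chnames),
                 dimnames = list(NULL, chnames))
  for (i in seq_along(g$region)) {
    row <- table[[g$region[i]]]
    if (is.null(row)) next
    for (nm in names(row)) {
      v <- row[[nm]]
      if (nm %in% .ps_um2_channels) v <- v * 1e-4
      dens[i, nm] <- v
    }
  }
  if (any(dens < 0)) stop("densities must be >= 0")
  g$densities <- dens
  g$channels <- channels
  g
}

#' Simulation configuration
#'
#' @param dt_ms Integration step (ms); the default resolves nodal spikes.
#' @param method `"cn"` (Crank-Nicolson with staggered gating, second
#'   order, the default) or `"euler"` (backward Euler).
#' @param settle_ms Settling period at zero drive before stimulus onset
#'   (discarded from the outputs).
#' @param v_init Initial voltage (mV); defaults to the leak reversal.
#' @param record Probe sites to record (names in `graph$probes`).
#' @param ca_tau_ms,ca_phi,ca0_uM Calcium pool parameters: decay time
#'   constant, influx coupling to inward sodium current (a modelling
#'   surrogate for the unspecified calcium source of SK2), and initial
#'   concentration.
#' @param i_inj_nA Optional per-compartment constant current injection
#'   (diagnostic use).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt_ms = 0.0125, settle_ms = 500, v_init = NULL,
                       record = c("terminal", "heminode", "node5"),
                       method = c("cn", "euler"),
                       ca_tau_ms = 50, ca_phi = 0.27, ca0_uM = 0,
                       i_inj_nA = NULL) {
  if (dt_ms <= 0) stop("dt_ms must be > 0")
  method <- match.arg(method)
  structure(list(dt_ms = dt_ms, settle_ms = settle_ms, v_init = v_init,
                 record = record, method = method,
                 theta = if (method == "cn") 0.5 else 1,
                 ca_tau_ms = ca_tau_ms, ca_phi = ca_phi,
                 ca0_uM = ca0_uM, i_inj_nA = i_inj_nA),
            class = "sim_config")
}

# lookup-table voltage grid shared by R channel models and the C++ solver
.vgrid <- function() list(v0 = -120, dv = 0.05, n = 3601L)

channel_tables <- function(chan, vg = .vgrid()) {
  V <- vg$v0 + vg$dv * (seq_len(vg$n) - 1)
  if (chan$kind == "hh") {
    gates <- lapply(chan$gates, function(g) {
      ss <- gate_steady_state(g, V)
      list(inf = ss$x_inf, tau = ss$tau_ms, power = g$power)
    })
    list(kind = "hh", gates = gates)
  } else if (chan$kind == "markov") {
    nt <- length(chan$transitions$from)
    rt <- matrix(0, nt, vg$n)
    for (k in seq_len(nt)) rt[k, ] <- chan$transitions$fn[[k]](V)
    if (any(rt < 0) || any(!is.finite(rt)))
      stop("negative/non-finite Markov rate in '", chan$name, "'")
    list(kind = "markov", n_states = chan$n,
         from = chan$transitions$from - 1L, to = chan$transitions$to - 1L,
         conducting = chan$conducting - 1L, rate_tab = rt)
  } else {
    list(kind = "sk", k_half = chan$k_half_uM, hill = chan$hill,
         tau_ms = chan$tau_ms)
  }
}

#' Simulate the Ia afferent driven by a receptor-potential conductance
#'
#' Integrates the multicompartment cable equations with backward Euler.
#' The model first settles for `settle_ms` at zero drive; the stimulus
#' then starts at t = 0.  The transduction conductance is distributed
#' over the terminal compartments in proportion to membrane area.
#'
#' @param g A `compartment_graph` with channels assigned (or all-zero
#'   densities for a passive run).
#' @param drive A `drive_signal` (or `NULL` for zero drive; duration then
#'   comes from `duration_ms`).
#' @param cfg A [sim_config()].
#' @param duration_ms Simulated time when `drive` is `NULL`.
#' @return A `sim_result` with voltage/calcium traces at the probe sites.
#' @export
simulate_afferent <- function(g, drive, cfg = sim_config(),
                              duration_ms = 1000) {
  stopifnot(inherits(g, "compartment_graph"))
  if (is.null(g$densities))
    g$densities <- matrix(0, length(g$region), 0)
  n <- length(g$region)
  v_init <- if (is.null(cfg$v_init)) g$e_leak_mV else cfg$v_init

  vg <- .vgrid()
  ch_list <- list()
  if (ncol(g$densities) > 0) {
    for (nm in colnames(g$densities)) {
      dd <- g$densities[, nm]
      comps <- which(dd > 0)
      if (!length(comps)) next
      chan <- g$channels[[nm]]
      tabs <- channel_tables(chan, vg)
      init <- channel_init(chan, v_init, Ca = cfg$ca0_uM)
      entry <- c(list(e_rev = chan$e_rev,
                      is_na = chan$kind == "markov" && chan$e_rev > 0,
                      comps = as.integer(comps - 1L),
                      g_uS = dd[comps] * g$area_cm2[comps] * 1e6,
                      init = as.numeric(init)),
                 tabs)
      ch_list[[length(ch_list) + 1L]] <- entry
    }
  }

  if (is.null(drive)) {
    drive_g <- c(0, 0)
    drive_dt <- duration_ms
    e_drive <- 0
    total_ms <- duration_ms
  } else {
    stopifnot(inherits(drive, "drive_signal"))
    drive_g <- drive$g_uS
    drive_dt <- (drive$t[2] - drive$t[1]) * 1e3
    e_drive <- if (is.null(drive$e_rev_mV)) 0 else drive$e_rev_mV
    total_ms <- (length(drive_g) - 1) * drive_dt
  }
  # The transduction conductance is carried by mechanosensitive channels
  # where the terminal contacts the intrafusal sensory (equatorial)
  # zone, which the base terminal covers exactly: total drive scales
  # down with terminal area when the terminal shrinks below the contact
  # zone, but does not grow beyond the full-zone drive when the terminal
  # membrane extends past it.
  weight <- numeric(n)
  tc <- g$terminal_comps
  a_tot <- sum(g$area_cm2[tc])
  ref <- if (is.null(g$terminal_ref_area_cm2)) a_tot
    else g$terminal_ref_area_cm2
  weight[tc] <- g$area_cm2[tc] / max(a_tot, ref)

  i_inj <- numeric(n)
  if (!is.null(cfg$i_inj_nA)) {
    stopifnot(length(cfg$i_inj_nA) == n)
    i_inj <- cfg$i_inj_nA
  }

  n_steps <- max(1L, as.integer(round(total_ms / cfg$dt_ms)))
  n_settle <- as.integer(round(cfg$settle_ms / cfg$dt_ms))
  parent0 <- g$parent - 1L
  parent0[is.na(parent0)] <- -1L

  res <- cpp_simulate_afferent(
    neuron = list(parent = parent0, g_axial_uS = g$g_axial_uS,
                  area_cm2 = g$area_cm2, cm_nF = g$cm_nF,
                  g_leak_uS = g$g_leak_uS, e_leak = g$e_leak_mV),
    channels = ch_list,
    vgrid = vg,
    drive = list(g_uS = drive_g, dt_ms = drive_dt, weight = weight,
                 e_rev = e_drive, i_inj_nA = i_inj),
    sim = list(dt_ms = cfg$dt_ms, n_steps = n_steps, n_settle = n_settle,
               v_init = v_init,
               theta = if (is.null(cfg$theta)) 0.5 else cfg$theta,
               record = as.integer(unlist(g$probes[cfg$record]) - 1L)),
    ca_cfg = list(tau_ms = cfg$ca_tau_ms, phi = cfg$ca_phi,
                  ca0 = cfg$ca0_uM))

  colnames(res$V) <- cfg$record
  colnames(res$Ca) <- cfg$record
  structure(list(t_s = res$t_ms * 1e-3, V = res$V, Ca = res$Ca,
                 V_final = res$V_final, sites = cfg$record,
                 dt_ms = cfg$dt_ms,
                 max_occupancy_error = res$max_occupancy_error,
                 graph = g),
            class = "sim_result")
}

#' Per-spike ordering of threshold crossings across probe sites
#'
#' Groups near-coincident upward threshold crossings at the recorded
#' sites into spike events and orders the sites by crossing time within
#' each event (ties broken by the earlier time of maximal dV/dt).  Sites
#' with no crossing in an event are reported as non-initiating (absent
#' from that event's ordering).
#'
#' @param r A `sim_result`.
#' @param threshold_mV Crossing threshold (mV).
#' @param window_ms Half-width for grouping crossings into one event.
#' @return List of character vectors (site names, earliest first), one
#'   per spike event.
#' @export
initiation_order <- function(r, threshold_mV = -20, window_ms = 3) {
  stopifnot(inherits(r, "sim_result"))
  sites <- colnames(r$V)
  crossings <- lapply(sites, function(s)
    detect_spikes(r$t_s, r$V[, s], threshold_mV = threshold_mV,
                  min_isi_ms = 1)$times)
  names(crossings) <- sites
  anchor <- crossings[[which.max(vapply(crossings, length, 0L))]]
  if (!length(anchor)) return(list())
  win <- window_ms * 1e-3
  lapply(anchor, function(t0) {
    tt <- vapply(sites, function(s) {
      ts <- crossings[[s]]
      if (!length(ts)) return(NA_real_)
      d <- abs(ts - t0)
      if (min(d) > win) NA_real_ else ts[which.min(d)]
    }, 0)
    ord <- order(tt, na.last = NA)
    sites[ord]
  })
}
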