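#' Genotypic parameter bounds
#'
#' Calibration intervals for the eight genotypic parameters of the growth
#' model. These intervals bound both Differential Evolution search and the
#' clamping of genomically predicted parameters before simulation.
#'
#' @return A 2 x 8 numeric matrix with rows `lower`, `upper` and one column
#'   per parameter (`epsib`, `plasto_init`, `phyllo_init`, `ligulo_init`,
#'   `ict`, `mgr_init`, `ll_to_il`, `slap`).
#' @export
#' @examples
#' parameter_bounds()
parameter_bounds <- function() {
  b <- cbind(
    epsib       = c(3.0, 8.0),    # light conversion coefficient, g MJ^-1
    plasto_init = c(25.0, 45.0),  # plastochron, degree-days
    phyllo_init = c(25.0, 45.0),  # phyllochron, degree-days
    ligulo_init = c(25.0, 45.0),  # ligulochron, degree-days
    ict         = c(0.5, 2.5),    # IC threshold enabling tillering
    mgr_init    = c(6.0, 14.0),   # meristem growth rate, mm per leaf rank
    ll_to_il    = c(0.1, 0.2),    # internode-to-leaf length ratio
    slap        = c(0.0, 0.1)     # per-rank SLA decrease rate
  )
  rownames(b) <- c("lower", "upper")
  b
}

#' Names of the eight genotypic parameters, in canonical order
#' @return Character vector of length 8.
#' @export
parameter_names <- function() colnames(parameter_bounds())

#' Build a genotypic parameter set
#'
#' @param epsib Light conversion coefficient (g dry biomass per MJ
#'   intercepted radiation).
#' @param plasto_init Plastochron: thermal time between initiation of two
#'   successive phytomers (degree-days).
#' @param phyllo_init Phyllochron: thermal time between appearances of two
#'   successive leaves (degree-days).
#' @param ligulo_init Ligulochron: thermal time between ligulation of two
#'   successive leaves (degree-days).
#' @param ict Threshold on the internal competition index (carbon
#'   supply/demand ratio) above which a tiller may emerge.
#' @param mgr_init Meristem growth rate: additive increment of potential
#'   blade length per leaf rank (mm per rank).
#' @param ll_to_il Ratio of internode length to the corresponding blade
#'   length (dimensionless).
#' @param slap Fractional decrease of specific leaf area between successive
#'   leaf ranks (per rank).
#' @param check If `TRUE` (default), warn when a value falls outside its
#'   calibration interval.
#' @return Named numeric vector of class `genotype_parameters`.
#' @export
genotype_parameters <- function(epsib = 5, plasto_init = 35, phyllo_init = 35,
                                ligulo_init = 35, ict = 1.2, mgr_init = 10,
                                ll_to_il = 0.15, slap = 0.05, check = TRUE) {
  p <- c(epsib = epsib, plasto_init = plasto_init, phyllo_init = phyllo_init,
         ligulo_init = ligulo_init, ict = ict, mgr_init = mgr_init,
         ll_to_il = ll_to_il, slap = slap)
  stopifnot(all(is.finite(p)))
  if (check) {
    b <- parameter_bounds()
    out <- p < b["lower", ] | p > b["upper", ]
    if (any(out))
      warning("parameter(s) outside calibration bounds: ",
              paste(names(p)[out], collapse = ", "))
  }
  class(p) <- c("genotype_parameters", class(p))
  p
}

as_genotype_parameters <- function(x) {
  x <- unlist(x)
  if (is.null(names(x))) {
    if (length(x) != length(parameter_names()))
      stop("unnamed parameter vector must have length 8 (canonical order)")
    names(x) <- parameter_names()
  }
  x <- unname(x[parameter_names()])
  if (anyNA(x)) stop("incomplete genotype parameter set")
  genotype_parameters(x[1], x[2], x[3], x[4], x[5], x[6], x[7], x[8],
                      check = FALSE)
}

#' Clamp a parameter vector (or matrix) into the calibration bounds
#'
#' @param params Named numeric vector, or matrix with parameter columns.
#' @param bounds Bounds matrix as returned by [parameter_bounds()].
#' @return Object of the same shape with every entry inside its interval.
#' @export
clamp_parameters <- function(params, bounds = parameter_bounds()) {
  nm <- if (is.matrix(params)) colnames(params) else names(params)
  stopifnot(all(nm %in% colnames(bounds)))
  lo <- bounds["lower", nm]; hi <- bounds["upper", nm]
  if (is.matrix(params)) {
    for (j in seq_along(nm)) params[, j] <- pmin(pmax(params[, j], lo[j]), hi[j])
  } else {
    params <- pmin(pmax(params, lo), hi)
  }
  params
}

#' Functional constants of the growth model
#'
#' Species- and setup-level constants that are not part of the genotypic
#' parameter set: thermal base, light interception, organ allometry, carbon
#' bookkeeping and tillering structure. Defaults describe a single sorghum
#' plant in a greenhouse pot trial (0.4 m x 0.2 m spacing).
#'
#' @param tbase Base temperature for thermal time (degrees C).
#' @param k_light Canopy light extinction coefficient.
#' @param ground_area Ground area per plant (m^2).
#' @param first_leaf_length Potential length of leaf rank 1 (mm).
#' @param width_to_length Blade width / blade length ratio.
#' @param shape_factor Blade area = shape_factor * length * width.
#' @param sla_first Specific leaf area of leaf 1 (mm^2 per g dry).
#' @param dmc Dry matter content of fresh biomass (g dry per g fresh).
#' @param internode_diameter Internode diameter (mm).
#' @param internode_density Internode dry density (g dry per mm^3).
#' @param seed_biomass Seed reserve fuelling early growth (g dry).
#' @param heterotrophic_days Days over which the seed reserve is released.
#' @param tiller_first_rank First mainstem leaf rank carrying a tiller site.
#' @param tiller_size_factor Size reduction of tiller organs vs mainstem.
#' @param max_tillers Maximum number of tillers emitted.
#' @param max_rank Maximum phytomer rank per axis.
#' @param ic_max Upper clamp of the internal competition index.
#' @return Named list of class `model_constants`.
#' @export
model_constants <- function(tbase = 11, k_light = 0.5, ground_area = 0.08,
                            first_leaf_length = 100, width_to_length = 0.1,
                            shape_factor = 0.72, sla_first = 30000,
                            dmc = 0.15, internode_diameter = 8,
                            internode_density = 1e-4, seed_biomass = 0.2,
                            heterotrophic_days = 3, tiller_first_rank = 4,
                            tiller_size_factor = 0.8, max_tillers = 8,
                            max_rank = 25, ic_max = 5) {
  cst <- list(tbase = tbase, k_light = k_light, ground_area = ground_area,
              first_leaf_length = first_leaf_length,
              width_to_length = width_to_length, shape_factor = shape_factor,
              sla_first = sla_first, dmc = dmc,
              internode_diameter = internode_diameter,
              internode_density = internode_density,
              seed_biomass = seed_biomass,
              heterotrophic_days = heterotrophic_days,
              tiller_first_rank = tiller_first_rank,
              tiller_size_factor = tiller_size_factor,
              max_tillers = max_tillers, max_rank = max_rank, ic_max = ic_max)
  pos <- vapply(cst[setdiff(names(cst), "tbase")], function(x) x > 0, logical(1))
  if (!all(pos)) stop("model constants must be strictly positive")
  if (dmc <= 0 || dmc > 1) stop("dmc must lie in (0, 1]")
  if (tiller_size_factor <= 0 || tiller_size_factor > 1)
    stop("tiller_size_factor must lie in (0, 1]")
  class(cst) <- "model_constants"
  cst
}

#' Daily thermal time increment
#'
#' @param tmean Daily mean air temperature (degrees C).
#' @param tbase Base temperature (degrees C).
#' @return Degree-days, `max(0, tmean - tbase)`. Vectorised over `tmean`.
#' @export
thermal_time_increment <- function(tmean, tbase) pmax(0, tmean - tbase)

#' Daily carbon supply from light interception
#'
#' Radiation is converted to dry biomass through the genotypic light
#' conversion coefficient, after Beer-Lambert interception by the current
#' plant leaf area.
#'
#' @param epsib Light conversion coefficient (g per MJ).
#' @param radiation Incident radiation (MJ m^-2 day^-1).
#' @param pla Plant leaf area (mm^2).
#' @param constants [model_constants()] list.
#' @return Dry biomass supply (g day^-1).
#' @export
daily_supply <- function(epsib, radiation, pla, constants = model_constants()) {
  stopifnot(pla >= 0, radiation >= 0)
  lai <- pla / (constants$ground_area * 1e6)  # mm^2 -> m^2 per m^2 ground
  epsib * radiation * constants$ground_area * (1 - exp(-constants$k_light * lai))
}

#' Internal competition index
#'
#' Ratio of summed carbon supply to summed carbon demand over a trailing
#' window, the plant-state variable gating tillering and pre-dimensioning.
#'
#' @param supply_window,demand_window Equal-length numeric vectors of daily
#'   supply and demand (g day^-1).
#' @param ic_max Upper clamp; also the value returned when demand is zero.
#' @return Scalar IC in `[0, ic_max]`.
#' @export
competition_index <- function(supply_window, demand_window, ic_max = 5) {
  stopifnot(length(supply_window) == length(demand_window))
  d <- sum(demand_window)
  if (d <= 0) return(ic_max)
  min(max(sum(supply_window) / d, 0), ic_max)
}

#' Potential dimensions of a leaf blade
#'
#' Potential blade length grows additively with rank at the meristem growth
#' rate, modulated by the competition index at pre-dimensioning; blade dry
#' biomass is area divided by the rank-specific specific leaf area, which
#' decreases multiplicatively at rate `slap` per rank.
#'
#' @param rank Leaf rank on its axis (1-based).
#' @param mgr Meristem growth rate (mm per rank).
#' @param slap Per-rank SLA decrease rate.
#' @param ic_at_predim Competition index when the organ is pre-dimensioned.
#' @param constants [model_constants()] list.
#' @param size_factor Axis size scaling (1 for the main stem).
#' @return List with `length` (mm), `area` (mm^2), `dry` (g).
#' @export
potential_blade <- function(rank, mgr, slap, ic_at_predim,
                            constants = model_constants(), size_factor = 1) {
  stopifnot(rank >= 1)
  if (rank > constants$max_rank) return(NULL)
  len <- size_factor *
    (constants$first_leaf_length + mgr * (rank - 1) * min(1, ic_at_predim))
  area <- constants$shape_factor * len * (constants$width_to_length * len)
  sla <- constants$sla_first * (1 - slap)^(rank - 1)
  list(length = len, area = area, dry = area / sla)
}

#' Potential dimensions of an internode
#'
#' Internode length is a genotypic fraction of the corresponding blade
#' length; dry biomass follows from cylinder volume times tissue density.
#'
#' @param blade_length Potential length of the subtending blade (mm).
#' @param ll_to_il Internode-to-leaf length ratio.
#' @param constants [model_constants()] list.
#' @param size_factor Axis size scaling (applied to the diameter; the blade
#'   length is assumed already scaled).
#' @return List with `length` (mm) and `dry` (g).
#' @export
potential_internode <- function(blade_length, ll_to_il,
                                constants = model_constants(),
                                size_factor = 1) {
  len <- ll_to_il * blade_length
  radius <- size_factor * constants$internode_diameter / 2
  list(length = len, dry = pi * radius^2 * len * constants$internode_density)
}

#' Simulate sorghum vegetative growth
#'
#' Daily sink-driven simulation of one plant: thermal-time organogenesis on
#' the main stem and tillers, organ pre-dimensioning under the internal
#' competition index, carbon demand from growing organs, supply from light
#' interception (plus a seed reserve over an initial heterotrophic window),
#' and proportional down-scaling of growth when the day's supply does not
#' meet demand. Tillers emerge at mainstem leaf-appearance events when the
#' windowed competition index exceeds the genotypic threshold `ict`.
#'
#' The simulation is fully deterministic.
#'
#' @param params [genotype_parameters()] vector (or coercible named vector).
#' @param weather Data frame with columns `day`, `tmean_C`, `rad_MJ_m2`.
#' @param constants [model_constants()] list.
#' @return Object of class `cgm_simulation`: a list with `daily` (data frame
#'   of day, Biomaerofw (g fresh), PLA (mm^2), PHT (mm), App, Lig, Tillernb,
#'   IC, supply, demand, and the mainstem/tiller split `mainstem_fw`,
#'   `tiller_fw`), `harvest` (list with `Mainstemfw` g fresh and `Arealfel`
#'   mm^2), and the echoed `params`.
#' @export
simulate_growth <- function(params, weather, constants = model_constants()) {
  params <- as_genotype_parameters(params)
  weather <- validate_weather(weather)
  n_days <- nrow(weather)
  if (n_days < 1) stop("empty weather series")

  plasto <- params[["plasto_init"]]; phyllo <- params[["phyllo_init"]]
  ligulo <- params[["ligulo_init"]]; mgr <- params[["mgr_init"]]
  slap <- params[["slap"]]; ll_to_il <- params[["ll_to_il"]]
  epsib <- params[["epsib"]]; ict <- params[["ict"]]
  cst <- constants

  # axis state (axis 1 = main stem)
  ax_tt <- 0; ax_sf <- 1; ax_app <- 0L; ax_lig <- 0L

  # organ state, preallocated parallel vectors
  cap <- 2L * cst$max_rank * (cst$max_tillers + 1L)
  n_org <- 0L
  o_axis <- o_kind <- o_rank <- integer(cap)  # kind: 1 blade, 2 internode
  o_pot_len <- o_pot_area <- o_pot_dry <- o_cur <- numeric(cap)
  o_win_len <- o_win_left <- numeric(cap)

  dtt_h <- sup_h <- dem_h <- numeric(n_days)
  v_biom <- v_pla <- v_pht <- v_ic <- v_mfw <- v_tfw <- numeric(n_days)
  v_app <- v_lig <- v_til <- integer(n_days)
  ic_prev <- cst$ic_max  # no demand yet: favourable by convention
  pht_run <- 0

  add_organ <- function(axis, kind, rank, len, area, dry, win) {
    n_org <<- n_org + 1L
    o_axis[n_org] <<- axis; o_kind[n_org] <<- kind; o_rank[n_org] <<- rank
    o_pot_len[n_org] <<- len; o_pot_area[n_org] <<- area
    o_pot_dry[n_org] <<- dry; o_cur[n_org] <<- 0
    o_win_len[n_org] <<- win; o_win_left[n_org] <<- win
  }

  for (t in seq_len(n_days)) {
    dtt <- thermal_time_increment(weather$tmean_C[t], cst$tbase)
    dtt_h[t] <- dtt
    ax_tt <- ax_tt + dtt

    # supply uses leaf area realized at the start of the day
    io <- seq_len(n_org)
    bl_i <- io[o_kind[io] == 1L]
    pla_start <- if (length(bl_i))
      sum(o_pot_area[bl_i] * (o_cur[bl_i] / o_pot_dry[bl_i])) else 0
    supply <- daily_supply(epsib, weather$rad_MJ_m2[t], pla_start, cst)
    if (t <= cst$heterotrophic_days)
      supply <- supply + cst$seed_biomass / cst$heterotrophic_days

    # phenology per axis: initiation caps appearance; appearance at r*phyllo,
    # ligulation ligulo degree-days later
    n_axes <- length(ax_tt)
    for (a in seq_len(n_axes)) {
      n_init <- min(cst$max_rank, floor(ax_tt[a] / plasto) + 1)
      n_app <- min(n_init, floor(ax_tt[a] / phyllo))
      if (n_app > ax_app[a]) {
        for (r in (ax_app[a] + 1L):n_app) {
          bl <- potential_blade(r, mgr, slap, ic_prev, cst, ax_sf[a])
          if (!is.null(bl))
            add_organ(a, 1L, r, bl$length, bl$area, bl$dry, ligulo)
          # tillering at mainstem appearance events
          if (a == 1L && r >= cst$tiller_first_rank &&
              (length(ax_tt) - 1L) < cst$max_tillers && ic_prev > ict) {
            ax_tt <- c(ax_tt, 0); ax_sf <- c(ax_sf, cst$tiller_size_factor)
            ax_app <- c(ax_app, 0L); ax_lig <- c(ax_lig, 0L)
          }
        }
        ax_app[a] <- n_app
      }
      n_lig <- max(0, min(n_app, floor((ax_tt[a] - ligulo) / phyllo)))
      if (n_lig > ax_lig[a]) {
        for (r in (ax_lig[a] + 1L):n_lig) {
          io <- seq_len(n_org)
          bi <- io[o_axis[io] == a & o_kind[io] == 1L & o_rank[io] == r]
          blen <- if (length(bi)) o_pot_len[bi[1]] else
            cst$first_leaf_length * ax_sf[a]
          ino <- potential_internode(blen, ll_to_il, cst, ax_sf[a])
          add_organ(a, 2L, r, ino$length, 0, ino$dry, 3 * ligulo)
        }
        ax_lig[a] <- n_lig
      }
    }

    # demand from growing organs, proportional allocation of realized growth
    io <- seq_len(n_org)
    growing <- io[o_win_left[io] > 0 & o_cur[io] < o_pot_dry[io]]
    dem_i <- numeric(n_org)
    if (length(growing)) {
      dem_i[growing] <- pmin(o_pot_dry[growing] * dtt / o_win_len[growing],
                             o_pot_dry[growing] - o_cur[growing])
    }
    demand <- sum(dem_i)
    scale <- if (demand > 0) min(1, supply / demand) else 0
    if (n_org) {
      o_cur[io] <- o_cur[io] + dem_i * scale
      o_win_left[io] <- pmax(0, o_win_left[io] - dtt)
    }
    sup_h[t] <- supply; dem_h[t] <- demand

    # windowed IC (trailing days spanning one phyllochron), for next day's
    # events and as diagnostic
    w <- 1L
    while (w < t && sum(dtt_h[(t - w + 1L):t]) < phyllo) w <- w + 1L
    ic_prev <- competition_index(sup_h[(t - w + 1L):t], dem_h[(t - w + 1L):t],
                                 cst$ic_max)

    # outputs
    frac <- if (n_org) o_cur[io] / pmax(o_pot_dry[io], 1e-300) else numeric(0)
    blade <- o_kind[io] == 1L
    v_pla[t] <- sum(o_pot_area[io][blade] * frac[blade])
    main <- o_axis[io] == 1L
    v_mfw[t] <- (sum(o_cur[io][main]) + cst$seed_biomass) / cst$dmc
    v_tfw[t] <- sum(o_cur[io][!main]) / cst$dmc
    v_biom[t] <- v_mfw[t] + v_tfw[t]
    mint <- main & !blade
    pht_raw <- sum(o_pot_len[io][mint] * frac[mint])
    mb_lig <- main & blade & o_rank[io] <= ax_lig[1]
    if (any(mb_lig)) {
      top <- which(mb_lig)[which.max(o_rank[io][mb_lig])]
      pht_raw <- pht_raw + o_pot_len[io][top] * frac[top]
    }
    pht_run <- max(pht_run, pht_raw)
    v_pht[t] <- pht_run
    v_app[t] <- ax_app[1]; v_lig[t] <- ax_lig[1]
    v_til[t] <- length(ax_tt) - 1L
    v_ic[t] <- ic_prev
  }

  out <- data.frame(day = weather$day, Biomaerofw = v_biom, PLA = v_pla,
                    PHT = v_pht, App = v_app, Lig = v_lig, Tillernb = v_til,
                    IC = v_ic, supply = sup_h, demand = dem_h,
                    mainstem_fw = v_mfw, tiller_fw = v_tfw)
  io <- seq_len(n_org)
  main <- o_axis[io] == 1L
  frac <- if (n_org) o_cur[io] / pmax(o_pot_dry[io], 1e-300) else numeric(0)
  mb_lig <- main & o_kind[io] == 1L & o_rank[io] <= ax_lig[1]
  arealfel <- if (any(mb_lig)) {
    top <- which(mb_lig)[which.max(o_rank[io][mb_lig])]
    o_pot_area[io][top] * frac[top]
  } else 0
  res <- list(daily = out,
              harvest = list(
                Mainstemfw = (sum(o_cur[io][main]) + cst$seed_biomass) / cst$dmc,
                Arealfel = arealfel),
              params = params, constants = cst)
  class(res) <- "cgm_simulation"
  res
}

validate_weather <- function(weather) {
  stopifnot(is.data.frame(weather),
            all(c("day", "tmean_C", "rad_MJ_m2") %in% names(weather)))
  if (anyNA(weather$tmean_C) || anyNA(weather$rad_MJ_m2) ||
      any(weather$rad_MJ_m2 < 0))
    stop("weather contains missing or negative values")
  weather
}

#' @export
print.cgm_simulation <- function(x, ...) {
  n <- nrow(x$daily)
  cat("<cgm_simulation> ", n, " days\n", sep = "")
  cat("  final Biomaerofw: ", signif(x$daily$Biomaerofw[n], 4), " g fresh\n",
      sep = "")
  cat("  final PLA: ", signif(x$daily$PLA[n], 4), " mm^2; leaves (App/Lig): ",
      x$daily$App[n], "/", x$daily$Lig[n], "; tillers: ",
      x$daily$Tillernb[n], "\n", sep = "")
  invisible(x)
}

#' Extract a trait series from a simulation at given days
#'
#' Harvest traits (`Mainstemfw`, `Arealfel`) return their final value
#' irrespective of `days`.
#'
#' @param sim A `cgm_simulation`.
#' @param trait Trait name (one of the daily columns or a harvest trait).
#' @param days Integer days at which to read the daily series.
#' @return Numeric vector.
#' @export
simulated_trait <- function(sim, trait, days = sim$daily$day) {
  if (trait %in% names(sim$harvest)) return(sim$harvest[[trait]])
  if (!trait %in% names(sim$daily)) stop("unknown trait: ", trait)
  idx <- match(days, sim$daily$day)
  if (anyNA(idx)) stop("requested days outside the simulated range")
  sim$daily[[trait]][idx]
}
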