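#' Pipeline run configuration
#'
#' Bundles everything an end-to-end analysis run needs: the morphology
#' and protocol specifications (or file paths), body and fluid
#' parameters, scenario flags and numerical resolutions.
#'
#' @param morph a [morph_spec()], or a path to a YAML morphology file.
#' @param protocol a [protocol_spec()].
#' @param body a [body_model()]; the default uses the study-animal-like
#'   body mass 2.43 ug with a slender-body pitch inertia estimate and a
#'   centre of mass slightly behind and below the wing bases.
#' @param fluid a [fluid_properties()].
#' @param forces_source `"surrogate"` to generate quasi-steady forces,
#'   or a named list of force-file paths (per part) readable by
#'   [load_force_series()].
#' @param with_elytra include the elytra recoil torque in the pitch
#'   simulation (`FALSE` zeroes only the recoil, keeping the negligible
#'   elytra aerodynamic torque).
#' @param quad_step membrane quadrature step (um).
#' @param n_phase phase-grid resolution for the averaged cycle.
#' @param sim_cycles wingbeat cycles for the pitch simulation.
#' @param seed integer seed forwarded to the protocol spec.
#' @param out_dir optional directory; when given, the report and the
#'   generated force series are written there.
#' @return object of class `run_config`.
#' @export
run_config <- function(morph = morph_spec(),
                       protocol = protocol_spec(),
                       body = body_model(mass = 2.43, inertia = 3.2e4,
                                         com = c(40, 0, -30)),
                       fluid = fluid_properties(),
                       forces_source = "surrogate",
                       with_elytra = TRUE,
                       quad_step = 2, n_phase = 512, sim_cycles = 6,
                       seed = NULL, out_dir = NULL) {
  if (is.character(morph) && !file.exists(morph)) {
    stop("morphology file not found: ", morph, call. = FALSE)
  }
  if (is.list(forces_source)) {
    missing <- forces_source[!vapply(unlist(forces_source), file.exists, TRUE)]
    if (length(missing) > 0) {
      stop("force file(s) not found: ", paste(unlist(missing), collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(seed)) protocol$seed <- as.integer(seed)
  stopifnot(inherits(body, "body_model"), inherits(fluid, "fluid_properties"),
            quad_step > 0, n_phase >= 64, sim_cycles >= 2)
  structure(list(morph = morph, protocol = protocol, body = body,
                 fluid = fluid, forces_source = forces_source,
                 with_elytra = with_elytra, quad_step = quad_step,
                 n_phase = n_phase, sim_cycles = sim_cycles,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full flight-mechanics pipeline
#'
#' Orchestrates every stage on synthetic (or file-based) inputs:
#' morphology and mass properties (bristled wing and membranous
#' substitutes), kinematic reconstruction (cycle detection, phase
#' averaging, angle of attack, Reynolds number, clap distance),
#' aerodynamic forces with lift/drag decomposition and vertical-force
#' accounting, the mechanical power budget with elastic-storage
#' scenarios for the bristled wing and each membranous substitute, and
#' the body-pitch simulation with and without elytra recoil. Every
#' reported number is traceable to a module call listed in the log.
#'
#' @param config a [run_config()].
#' @return object of class `flight_report`: a nested list of results
#'   plus a `log` of completed stages; see [glance.flight_report()].
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## morphology and mass properties -----------------------------------
  morph <- stage("morphology", {
    if (is.character(config$morph)) {
      wing <- read_morphology(config$morph)
      subs <- purrr::map(c(0.73, 0.85, 1.12), ~membranous_substitute(wing, .x))
      names(subs) <- format(c(0.73, 0.85, 1.12))
      outline <- subs[[1]]$boundary
      list(wing = wing, substitutes = subs, elytron = NULL,
           outline = outline, planform = wing_planform(outline),
           setae_area_fraction = NA_real_)
    } else {
      make_morphology(config$morph)
    }
  })
  note("morphology: make_morphology/read_morphology")
  mp_wing <- stage("mass_properties", mass_properties(morph$wing, step = config$quad_step))
  validate_mass_properties(mp_wing)
  mp_subs <- stage("mass_properties", purrr::map(morph$substitutes, function(p) {
    validate_mass_properties(mass_properties(p, step = config$quad_step))
  }))
  mp_elytron <- NULL
  if (!is.null(morph$elytron)) {
    mp_elytron <- stage("mass_properties",
                        mass_properties(morph$elytron, step = config$quad_step))
  }
  note("mass properties: mass_properties() on wing, %d substitutes%s",
       length(mp_subs), if (is.null(mp_elytron)) "" else ", elytron")

  ## kinematics --------------------------------------------------------
  proto <- stage("protocol", make_protocol(config$protocol, morph$planform,
                                           config$fluid))
  note("protocol: make_protocol (f = %.4g kHz, phi_amp = %.4g deg)",
       proto$truth$f, proto$truth$phi_amp)
  rs <- stage("resample", purrr::map(proto$series, resample_uniform))
  cyc <- stage("cycles", detect_cycles(rs$left_wing))
  avg_wing <- stage("phase_average",
                    phase_average(rs$left_wing, rs$right_wing, cycles = cyc,
                                  n_phase = config$n_phase))
  avg_elytron <- stage("phase_average",
                       phase_average(rs$left_elytron, rs$right_elytron,
                                     cycles = cyc, n_phase = config$n_phase))
  note("cycles: detect_cycles (f = %.5g kHz over %d cycles); phase_average",
       cyc$f, cyc$n_cycles)
  el_planform <- if (!is.null(morph$elytron)) wing_planform(morph$elytron) else NULL
  kin <- stage("derive_kinematics", {
    k <- list(
      left_wing = derive_kinematics(avg_wing, proto$frames$left_wing,
                                    morph$planform, config$fluid, f = cyc$f),
      right_wing = derive_kinematics(mirror_angles(avg_wing),
                                     proto$frames$right_wing,
                                     morph$planform, config$fluid, f = cyc$f)
    )
    if (!is.null(el_planform)) {
      k$left_elytron <- derive_kinematics(avg_elytron, proto$frames$left_elytron,
                                          el_planform, config$fluid, f = cyc$f)
      k$right_elytron <- derive_kinematics(mirror_angles(avg_elytron),
                                           proto$frames$right_elytron,
                                           el_planform, config$fluid, f = cyc$f)
    }
    k
  })
  note("kinematics: derive_kinematics per part (Re mean %.3g, peak %.3g)",
       attr(kin$left_wing, "re_mean"), attr(kin$left_wing, "re_peak"))
  # signed AoA where the wing speed peaks inside each power stroke (the
  # phase the study animal's stroke AoA figures refer to)
  aoa_power <- vapply(proto$truth$power_windows, function(w) {
    ph <- kin$left_wing$phase
    inw <- if (w[1] <= w[2]) ph >= w[1] & ph <= w[2] else ph >= w[1] | ph <= w[2]
    i <- which(inw)[which.max(kin$left_wing$speed[inw])]
    kin$left_wing$aoa[i]
  }, 0)
  clap <- stage("clap_distance", {
    lw <- pose_from_angles(avg_wing, proto$frames$left_wing,
                           span = morph$planform$R)
    rw <- pose_from_angles(mirror_angles(avg_wing), proto$frames$right_wing,
                           span = morph$planform$R)
    clap_distance(lw, rw, windows = list(proto$truth$clap_windows$ventral))
  })
  note("clap: clap_distance (min %.3g um)", clap$distance)

  ## forces -------------------------------------------------------------
  wings <- c("left_wing", "right_wing")
  el_parts <- intersect(c("left_elytron", "right_elytron"), names(kin))
  forces <- stage("forces", {
    if (identical(config$forces_source, "surrogate")) {
      purrr::imap(kin, function(k, nm) quasisteady_surrogate(k, part = nm))
    } else {
      purrr::imap(config$forces_source, function(path, nm) {
        load_force_series(path, grid = kin[[nm]])
      })
    }
  })
  note("forces: %s per part",
       if (identical(config$forces_source, "surrogate")) "quasisteady_surrogate"
       else "load_force_series")
  decomp <- stage("decompose", purrr::map(wings, function(nm) {
    decompose(forces[[nm]], kin[[nm]])
  }) |> stats::setNames(wings))
  vb <- stage("vertical_breakdown",
              vertical_breakdown(forces, decomp, body_mass = config$body$mass,
                                 g = config$body$g))
  note("vertical: vertical_breakdown (%.3g ug weight-equivalent, %.1f%%/%.1f%% drag/lift)",
       vb$total_weight_equiv, vb$drag_share, vb$lift_share)

  ## power ---------------------------------------------------------------
  power_for <- function(mp_one_wing) {
    pa <- rep(0, config$n_phase); pi_ <- rep(0, config$n_phase)
    for (nm in wings) {
      pa <- pa + aerodynamic_power(forces[[nm]], kin[[nm]])$p_aero
      pi_ <- pi_ + inertial_power(mp_one_wing, kin[[nm]], kin[[nm]]$t)$p_inert
    }
    for (nm in el_parts) {
      pa <- pa + aerodynamic_power(forces[[nm]], kin[[nm]])$p_aero
      pi_ <- pi_ + inertial_power(mp_elytron, kin[[nm]], kin[[nm]]$t)$p_inert
    }
    power_breakdown(pa, pi_, body_mass = config$body$mass, t = kin$left_wing$t)
  }
  power <- stage("power", {
    res <- list(bristled = power_for(mp_wing))
    for (nm in names(mp_subs)) res[[paste0("membranous_", nm)]] <- power_for(mp_subs[[nm]])
    res
  })
  note("power: aerodynamic_power + inertial_power + power_breakdown (bristled mean %.3g W/kg)",
       power$bristled$scenarios$mean_no_storage)

  ## pitch dynamics ------------------------------------------------------
  pitch <- NULL
  if (length(el_parts) == 2 && !is.null(mp_elytron)) {
    pitch <- stage("pitch_simulation", {
      aero_com <- purrr::map(forces[c(wings, el_parts)], function(fs) {
        shift_torque_reference(fs, to = config$body$com)
      })
      recoil <- NULL
      if (config$with_elytra) {
        r1 <- recoil_torque(kin$left_elytron, mp_elytron)
        r2 <- recoil_torque(kin$right_elytron, mp_elytron)
        recoil <- r1
        recoil$ty <- r1$ty + r2$ty
      }
      pitch_simulation(unname(aero_com), recoil = recoil, body = config$body,
                       f = cyc$f, cycles = config$sim_cycles)
    })
    note("pitch: pitch_simulation (amplitude ratio %.1f%%)", pitch$amplitude_ratio)
  }

  report <- structure(
    list(
      morphology = list(
        wing_mass = mp_wing$mass,
        wing_izz = mp_wing$inertia[3, 3],
        wing_to_body_mass_pct = 100 * mp_wing$mass / config$body$mass,
        substitute_mass = purrr::map_dbl(mp_subs, "mass"),
        substitute_izz = purrr::map_dbl(mp_subs, function(m) m$inertia[3, 3]),
        setae_area_fraction = morph$setae_area_fraction,
        planform = morph$planform
      ),
      kinematics = list(
        f = cyc$f, T = cyc$T, n_cycles = cyc$n_cycles,
        beta = proto$frames$left_wing$beta,
        re_mean = attr(kin$left_wing, "re_mean"),
        re_peak = attr(kin$left_wing, "re_peak"),
        aoa_max = max(kin$left_wing$aoa, na.rm = TRUE),
        aoa_min = min(kin$left_wing$aoa, na.rm = TRUE),
        aoa_power_strokes = aoa_power,
        clap_distance = clap$distance,
        truth = proto$truth[c("f", "phi_amp", "clap_distance")]
      ),
      forces = vb,
      power = power,
      pitch = pitch,
      averaged = list(wing = avg_wing, elytron = avg_elytron),
      kin = kin,
      config = config,
      log = log
    ),
    class = "flight_report"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(config$out_dir, "report.json"))
    for (nm in names(forces)) {
      write_force_series(forces[[nm]], file.path(config$out_dir,
                                                 paste0("forces_", nm, ".csv")))
    }
  }
  report
}

#' @export
print.flight_report <- function(x, ...) {
  cat("<flight_report>\n")
  cat(sprintf("  wing mass %.4g ug (%.2g%% of body), Izz %.4g ug um^2\n",
              x$morphology$wing_mass, x$morphology$wing_to_body_mass_pct,
              x$morphology$wing_izz))
  cat(sprintf("  f = %.4g kHz, Re mean %.3g / peak %.3g, power-stroke AoA %+.3g / %+.3g deg\n",
              x$kinematics$f, x$kinematics$re_mean, x$kinematics$re_peak,
              x$kinematics$aoa_power_strokes[1], x$kinematics$aoa_power_strokes[2]))
  cat(sprintf("  vertical force %.3g ug-equivalent (%.0f%% drag / %.0f%% lift)\n",
              x$forces$total_weight_equiv, x$forces$drag_share, x$forces$lift_share))
  s <- x$power$bristled$scenarios
  cat(sprintf("  power (bristled): mean %.3g W/kg, peak %.3g W/kg, always positive: %s\n",
              s$mean_no_storage, s$peak, s$always_positive))
  if (!is.null(x$pitch)) {
    cat(sprintf("  pitch amplitude ratio with/without elytra recoil: %.0f%%\n",
                x$pitch$amplitude_ratio))
  }
  invisible(x)
}

#' One-row summary of a flight report
#'
#' @param x a `flight_report`.
#' @param ... unused.
#' @return tibble with the headline quantities of the run.
#' @export
glance.flight_report <- function(x, ...) {
  s <- x$power$bristled$scenarios
  mem <- x$power[[length(x$power)]]$scenarios
  tibble::tibble(
    wing_mass = x$morphology$wing_mass,
    wing_izz = x$morphology$wing_izz,
    f = x$kinematics$f,
    re_mean = x$kinematics$re_mean,
    re_peak = x$kinematics$re_peak,
    aoa_max = x$kinematics$aoa_max,
    aoa_min = x$kinematics$aoa_min,
    aoa_power1 = x$kinematics$aoa_power_strokes[1],
    aoa_power2 = x$kinematics$aoa_power_strokes[2],
    clap_distance = x$kinematics$clap_distance,
    vertical_weight_equiv = x$forces$total_weight_equiv,
    drag_share = x$forces$drag_share,
    lift_share = x$forces$lift_share,
    power_mean = s$mean_no_storage,
    power_peak = s$peak,
    power_always_positive = s$always_positive,
    power_mean_membranous_no_storage = mem$mean_no_storage,
    power_mean_membranous_perfect = mem$mean_perfect_storage,
    pitch_amplitude_ratio = if (is.null(x$pitch)) NA_real_ else x$pitch$amplitude_ratio
  )
}

#' Write a flight report as structured JSON
#'
#' Emits the report's scalar results with an embedded units table.
#'
#' @param report a `flight_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  g <- glance.flight_report(report)
  obj <- list(
    results = as.list(g),
    substitutes = list(mass = as.list(report$morphology$substitute_mass),
                       izz = as.list(report$morphology$substitute_izz)),
    units = list(mass = "ug", inertia = "ug um^2", f = "kHz",
                 clap_distance = "um", power = "W/kg",
                 vertical_weight_equiv = "ug", shares = "percent",
                 aoa = "deg"),
    log = report$log
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
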