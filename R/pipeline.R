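# End-to-end orchestration: simulate (or ingest) gas-exchange curves,
# determine saturating irradiance from the light curves, fit the three
# conductance models to every curve, compare parameters across models, and
# write reports plus a reproducibility manifest.

#' Default synthetic study: three C3 species configurations
#'
#' Generating conditions for a three-species comparison study: a clover-like
#' species with a peaked light response (photosynthesis declining beyond
#' ~1200 umol m-2 s-1) measured on the 13-level light protocol, and two
#' grass-like species with saturating light responses on the 15-level
#' protocol, all at 420 umol mol-1 ambient CO2 with chamber humidity
#' controlled in the 45--75% band and three replicates. The generating
#' stomatal model is BWB with species slopes/offsets in the range reported
#' for these species (clover g1 = 3.446, g0 = 0.087; ryegrass-like
#' g1 = 4.515, g0 = 0.045; wheat-like g1 = 4.574, g0 = 0.040).
#'
#' @param seed Base seed from which per-species simulation seeds are
#'   derived.
#' @param noise_sd_An,noise_sd_gsc Noise SDs passed to each
#'   [simulation_config()].
#' @param n_replicates Replicates per species.
#' @return Named list of per-species lists with elements `label`, `gs_spec`,
#'   `demand`, `light_levels`, `co2_levels`, `seed`.
#' @export
default_species_configs <- function(seed = 1L, noise_sd_An = 0.3,
                                    noise_sd_gsc = 0.01, n_replicates = 3L) {
  species <- list(
    list(label = "T. repens",
         gs_spec = gs_model_spec("bwb", g0 = 0.087, g1 = 3.446),
         demand = demand_params(Vm = 90, Jmax = 150, Tp = 10,
                                light_form = "peaked",
                                light_beta = 1.9e-4, light_gamma = 2e-3)),
    list(label = "L. perenne",
         gs_spec = gs_model_spec("bwb", g0 = 0.045, g1 = 4.515),
         demand = demand_params(Vm = 110, Jmax = 170, Tp = 12)),
    list(label = "T. aestivum",
         gs_spec = gs_model_spec("bwb", g0 = 0.040, g1 = 4.574),
         demand = demand_params(Vm = 130, Jmax = 200, Tp = 14))
  )
  out <- lapply(seq_along(species), function(i) {
    sp <- species[[i]]
    sp$light_levels <- light_protocol(sp$label)
    sp$co2_levels <- co2_protocol(sp$label)
    sp$seed <- seed + 101L * i
    sp$noise_sd_An <- noise_sd_An
    sp$noise_sd_gsc <- noise_sd_gsc
    sp$n_replicates <- n_replicates
    sp
  })
  names(out) <- vapply(out, `[[`, character(1L), "label")
  out
}

.fit_all_models <- function(curves, models, medlyn_variant) {
  fits <- list()
  for (cv in curves) {
    for (m in models) {
      f <- tryCatch(
        suppressWarnings(fit_gs_model(cv, m, medlyn_variant)),
        error = function(e) {
          warning("fit failed for ", cv$species, "/", cv$replicate, "/", m,
                  ": ", conditionMessage(e), call. = FALSE)
          NULL
        }
      )
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
  }
  fits
}

.paired_t_table <- function(curves, fits) {
  rows <- list()
  for (f in fits) {
    cv <- Filter(function(cv) cv$species == f$species &&
                   cv$replicate == f$replicate &&
                   cv$protocol_kind == f$protocol_kind, curves)[[1L]]
    pt <- paired_t_observed_vs_predicted(cv$data$An, f$fitted)
    rows[[length(rows) + 1L]] <- data.frame(
      species = f$species, replicate = f$replicate, model = f$model_id,
      t = pt$t, p = pt$p, df = pt$df, n = pt$n, flag = pt$flag,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  # pooled across records of all replicates, per species x model
  pooled <- list()
  for (sp in unique(out$species)) {
    for (m in unique(out$model)) {
      idx <- vapply(fits, function(f) f$species == sp && f$model_id == m,
                    logical(1L))
      if (!any(idx)) next
      obs <- unlist(lapply(fits[idx], function(f) f$fitted + f$residuals))
      prd <- unlist(lapply(fits[idx], function(f) f$fitted))
      pt <- paired_t_observed_vs_predicted(obs, prd)
      pooled[[length(pooled) + 1L]] <- data.frame(
        species = sp, replicate = "pooled", model = m,
        t = pt$t, p = pt$p, df = pt$df, n = pt$n, flag = pt$flag,
        stringsAsFactors = FALSE
      )
    }
  }
  rbind(out, do.call(rbind, pooled))
}

#' Run the full model-comparison workflow
#'
#' Reproduces the study workflow end to end on synthetic (or ingested)
#' data: (1) light-response curves at 420 umol mol-1 CO2 for each species;
#' (2) light-response fits determine each species' saturating irradiance
#' Isat; (3) CO2-response curves at Isat and at Isat/2; (4) the BWB, Medlyn
#' and Ye conductance models fitted to every replicate curve; (5) replicate
#' aggregation, within-species ANOVA letter displays on g0, and paired
#' t-tests of observed versus model-predicted An; (6) optional reports and
#' a run manifest. Deterministic given the seed.
#'
#' @param species_configs As from [default_species_configs()]; when
#'   `curves` is supplied these are ignored for data generation.
#' @param curves Optional pre-loaded list of [response_curve()] objects
#'   (e.g. from [read_gas_exchange_table()]); light curves are used for
#'   Isat, all curves are fitted.
#' @param input_files Optional CSV paths to ingest instead of simulating;
#'   unreadable files are skipped with a warning, and the run fails only
#'   when no file yields curves.
#' @param column_map Column map for `input_files` (see
#'   [li6400_column_map()]).
#' @param models Models to fit.
#' @param medlyn_variant `"printed"` or `"sqrt"`.
#' @param alpha Significance level.
#' @param out_dir Output directory for CSV reports and the manifest; `NULL`
#'   writes nothing.
#' @param seed Base seed (used only when simulating).
#' @return List with `curves` (per condition), `isat` (per-species table),
#'   `fits` (per condition), `tables` (per-condition `comparison_table`),
#'   `paired_t` (per condition), `manifest`.
#' @export
run_full_comparison <- function(species_configs = default_species_configs(seed),
                                curves = NULL, input_files = NULL,
                                column_map = canonical_column_map(),
                                models = c("bwb", "medlyn", "ye"),
                                medlyn_variant = c("printed", "sqrt"),
                                alpha = 0.05, out_dir = NULL, seed = 1L) {
  medlyn_variant <- match.arg(medlyn_variant)
  stopifnot(length(models) >= 1L, alpha > 0, alpha < 1)

  if (!is.null(input_files)) {
    curves <- list()
    for (path in input_files) {
      got <- tryCatch(
        read_gas_exchange_table(path, column_map),
        error = function(e) {
          warning("skipping unreadable input '", path, "': ",
                  conditionMessage(e), call. = FALSE)
          list()
        }
      )
      curves <- c(curves, got)
    }
    if (length(curves) == 0L) {
      stop("no usable curves in any input file", call. = FALSE)
    }
  }

  if (is.null(curves)) {
    light_curves <- list()
    for (sp in species_configs) {
      cfg <- simulation_config(
        sp$label, sp$gs_spec, sp$demand,
        protocol = list(kind = "light", levels = sp$light_levels, Ca = 420),
        noise_sd_An = sp$noise_sd_An, noise_sd_gsc = sp$noise_sd_gsc,
        n_replicates = sp$n_replicates, seed = sp$seed
      )
      light_curves <- c(light_curves, simulate_response_curve(cfg))
    }
  } else {
    light_curves <- Filter(function(cv) cv$protocol_kind == "light", curves)
  }

  # per-species Isat: mean over replicate light-response fits
  isat_rows <- list()
  for (sp in unique(vapply(light_curves, `[[`, character(1L), "species"))) {
    reps <- Filter(function(cv) cv$species == sp, light_curves)
    lf <- lapply(reps, fit_light_response)
    ok <- vapply(lf, `[[`, logical(1L), "converged")
    isat <- mean(vapply(lf[ok], `[[`, numeric(1L), "Isat"))
    isat_rows[[sp]] <- data.frame(
      species = sp, Isat = isat,
      Amax = mean(vapply(lf[ok], `[[`, numeric(1L), "Amax")),
      n_replicates = sum(ok), stringsAsFactors = FALSE
    )
  }
  isat_tab <- do.call(rbind, isat_rows)
  rownames(isat_tab) <- NULL

  condition_curves <- list(light_420 = light_curves)
  if (is.null(curves)) {
    for (cond in c("co2_isat", "co2_half_isat")) {
      cc <- list()
      for (sp in species_configs) {
        isat <- isat_tab$Isat[isat_tab$species == sp$label]
        I <- if (cond == "co2_isat") isat else isat / 2
        cfg <- simulation_config(
          sp$label, sp$gs_spec, sp$demand,
          protocol = list(kind = "co2", levels = sp$co2_levels, I = I),
          noise_sd_An = sp$noise_sd_An, noise_sd_gsc = sp$noise_sd_gsc,
          n_replicates = sp$n_replicates,
          seed = sp$seed + if (cond == "co2_isat") 7L else 13L
        )
        cc <- c(cc, simulate_response_curve(cfg))
      }
      condition_curves[[cond]] <- cc
    }
  } else {
    co2 <- Filter(function(cv) cv$protocol_kind == "co2", curves)
    if (length(co2) > 0L) condition_curves$co2 <- co2
  }

  fits <- lapply(condition_curves, .fit_all_models, models = models,
                 medlyn_variant = medlyn_variant)
  tables <- Map(function(fl, nm) {
    build_comparison_table(fl, alpha = alpha, condition = nm)
  }, fits, names(fits))
  paired_t <- Map(.paired_t_table, condition_curves, fits)

  manifest <- list(
    package = "gscompare",
    version = as.character(packageVersion("gscompare")),
    r_version = as.character(getRversion()),
    seed = seed,
    models = models, medlyn_variant = medlyn_variant, alpha = alpha,
    conditions = names(condition_curves),
    species = isat_tab$species,
    simulated = is.null(curves)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(isat_tab, file.path(out_dir, "isat.csv"), row.names = FALSE)
    for (nm in names(tables)) {
      write_fit_report(tables[[nm]],
                       file.path(out_dir, paste0("table_", nm, ".csv")), "csv")
      write.csv(paired_t[[nm]],
                file.path(out_dir, paste0("paired_t_", nm, ".csv")),
                row.names = FALSE)
      write_gas_exchange_table(condition_curves[[nm]],
                               file.path(out_dir, paste0("curves_", nm, ".csv")))
    }
    fit_rows <- do.call(rbind, lapply(names(fits), function(nm) {
      do.call(rbind, lapply(fits[[nm]], function(f) {
        data.frame(condition = nm, species = f$species,
                   replicate = f$replicate, model = f$model_id,
                   g0 = f$g0, se_g0 = f$se_g0, g1 = f$g1, se_g1 = f$se_g1,
                   n = f$n, rss = f$rss, r2_adj = f$r2_adj, aic = f$aic,
                   converged = f$converged, stringsAsFactors = FALSE)
      }))
    }))
    write.csv(fit_rows, file.path(out_dir, "fits.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(curves = condition_curves, isat = isat_tab, fits = fits,
       tables = tables, paired_t = paired_t, manifest = manifest)
}
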