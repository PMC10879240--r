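#' Run the full analysis pipeline
#'
#' Orchestrates the four stages on one synthetic cohort: `simulate`
#' (cohort + anisotropy generation), `stats` (forest table, PCA
#' signature, correlation heatmaps, CHO-SE slope comparison),
#' `viscosity` (model fit and group contrast) and `abm` (membrane
#' simulation for both group compositions). Outputs are deterministic
#' given the seed; every stage output is listed in the returned
#' manifest, which is also written as `manifest.json`.
#'
#' @param config path to a YAML configuration file, or an equivalent
#'   named list. Recognized keys: `seed`, `out_dir`, `stages`
#'   (subset of simulate/stats/viscosity/abm), `cohort`
#'   (`n_nsl`, `n_als`, `cv`), `viscosity` (`noise_sd`), `abm`
#'   (`lattice_size`, `sweeps_burnin`, `sweeps_measure`, `replicates`,
#'   `temperature`).
#' @param out_dir output directory (overrides the config value).
#' @return a `run_manifest` list: per-stage output files, seeds,
#'   wall-clock seconds, package version and the config hash.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  config_hash <- NA_character_
  if (is.character(config)) {
    config_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(seed = 1L, out_dir = "raftscape_out",
                   stages = c("simulate", "stats", "viscosity", "abm"),
                   cohort = list(n_nsl = 6, n_als = 4, cv = 0.15),
                   viscosity = list(noise_sd = 0.002),
                   abm = list(lattice_size = 32, sweeps_burnin = 300,
                              sweeps_measure = 50, replicates = 3,
                              temperature = 1.0))
  # validate the user-supplied keys before defaults fill the gaps, so a
  # half-specified section is reported rather than silently completed
  missing_keys <- c(
    if (!is.null(config$stages) &&
        length(bad <- setdiff(config$stages, defaults$stages)))
      paste("unknown stage(s):", paste(bad, collapse = ", ")),
    if (!is.null(config$cohort) &&
        !all(c("n_nsl", "n_als") %in% names(config$cohort)))
      "cohort requires n_nsl and n_als"
  )
  cfg <- utils::modifyList(defaults, config)
  if (length(missing_keys)) {
    stop("invalid pipeline config: ", paste(missing_keys, collapse = "; "),
         call. = FALSE)
  }
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(seed = cfg$seed, config = cfg, config_hash = config_hash,
                   package_version = as.character(utils::packageVersion("raftscape")),
                   stages = list())
  out <- function(...) file.path(cfg$out_dir, ...)
  ccfg <- default_cohort_config(n_nsl = cfg$cohort$n_nsl,
                                n_als = cfg$cohort$n_als,
                                cv = cfg$cohort$cv, seed = cfg$seed)
  vparams <- default_viscosity_params(ccfg)
  cohort <- NULL
  aniso <- NULL

  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      files = files, seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }

  if ("simulate" %in% cfg$stages) {
    run_stage("simulate", function() {
      cohort <<- generate_cohort(ccfg)
      aniso <<- generate_anisotropy(cohort, vparams,
                                    noise_sd = cfg$viscosity$noise_sd,
                                    seed = cfg$seed + 1L)
      write_cohort(cohort, out("cohort.csv"))
      write.csv(aniso, out("anisotropy.csv"), row.names = FALSE)
      export_indexes_json(cohort, out("indexes.json"))
      c(out("cohort.csv"), out("anisotropy.csv"), out("indexes.json"))
    })
  } else if (any(c("stats", "viscosity", "abm") %in% cfg$stages)) {
    cohort <- read_cohort(out("cohort.csv"))
    if (file.exists(out("anisotropy.csv"))) {
      aniso <- read.csv(out("anisotropy.csv"))
    }
  }

  if ("stats" %in% cfg$stages) {
    run_stage("stats", function() {
      forest <- forest_table(cohort)
      write.csv(forest, out("forest_table.csv"), row.names = FALSE)
      vars <- c(fa_cols(cohort), class_cols(cohort))
      pca <- pca_signature(as.matrix(as.data.frame(cohort)[, vars]),
                           cohort$group)
      jsonlite::write_json(
        list(variance_fraction = pca$variance_fraction,
             rotated_variance_fraction = pca$rotated_variance_fraction,
             anova_f = pca$anova_f, anova_p = pca$anova_p,
             loadings = as.data.frame(pca$loadings)),
        out("pca.json"), digits = NA, auto_unbox = TRUE)
      hm <- correlation_heatmap(
        cohort,
        row_vars = intersect(c("PC", "PE", "PS", "PI", "PG", "SM", "SULF"),
                             names(cohort)),
        col_vars = intersect(c("20:4n-6", "22:6n-3", "18:1n-9", "16:0 DMA",
                               "18:1n-9 DMA"), names(cohort)))
      write.csv(hm$r$NSL, out("heatmap_nsl.csv"))
      write.csv(hm$r$ALS, out("heatmap_als.csv"))
      write.csv(hm$q_diff, out("heatmap_diff.csv"))
      slopes <- compare_slopes(cohort$CHO, cohort$SE, cohort$group)
      jsonlite::write_json(slopes[names(slopes) != "fit"],
                           out("regressions.json"), digits = NA,
                           auto_unbox = TRUE)
      c(out("forest_table.csv"), out("pca.json"), out("heatmap_nsl.csv"),
        out("heatmap_als.csv"), out("heatmap_diff.csv"),
        out("regressions.json"))
    })
  }

  if ("viscosity" %in% cfg$stages) {
    run_stage("viscosity", function() {
      eta_obs <- setNames(perrin_viscosity(aniso$r, vparams),
                          aniso$subject_id)
      fit <- fit_viscosity_model(cohort, eta_obs)
      cmp <- compare_group_viscosity(cohort, eta = eta_obs)
      jsonlite::write_json(
        list(coefficients = as.list(fit$params$coefficients),
             intercept = fit$params$intercept,
             r_squared = fit$r_squared,
             group_means = as.list(cmp$group_means),
             pct_fluidity_change = cmp$pct_fluidity_change,
             cohens_d = cmp$cohens_d, p_value = cmp$p_value),
        out("viscosity.json"), digits = NA, auto_unbox = TRUE)
      out("viscosity.json")
    })
  }

  if ("abm" %in% cfg$stages) {
    run_stage("abm", function() {
      acfg <- abm_config(default_composition("NSL", ccfg),
                         lattice_size = cfg$abm$lattice_size,
                         temperature = cfg$abm$temperature,
                         sweeps_burnin = cfg$abm$sweeps_burnin,
                         sweeps_measure = cfg$abm$sweeps_measure,
                         seed = cfg$seed)
      res <- lapply(c(NSL = "NSL", ALS = "ALS"), function(gl) {
        sim <- simulate_group(default_composition(gl, ccfg), acfg,
                              n_replicates = cfg$abm$replicates,
                              seed = cfg$seed + match(gl, c("NSL", "ALS")))
        list(mean = as.list(sim$mean), sd = as.list(sim$sd),
             raft_composition = as.list(sim$raft_composition))
      })
      jsonlite::write_json(res, out("abm_summary.json"), digits = NA,
                           auto_unbox = TRUE)
      out("abm_summary.json")
    })
  }

  manifest$out_dir <- cfg$out_dir
  class(manifest) <- "run_manifest"
  jsonlite::write_json(
    list(seed = manifest$seed, config_hash = manifest$config_hash,
         package_version = manifest$package_version,
         stages = lapply(manifest$stages, function(s) s)),
    out("manifest.json"), digits = NA, auto_unbox = TRUE)
  manifest
}

#' Render a markdown summary report from a run manifest
#'
#' Assembles the stage outputs into one document with sections for the
#' forest table, PCA, correlation heatmaps, CHO-SE regression, the
#' viscosity contrast and the ABM group contrast; stages absent from
#' the manifest are flagged explicitly.
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @param path optional file to write the report to.
#' @return the report as a character vector of lines, invisibly when
#'   `path` is given.
#' @export
render_report <- function(manifest, path = NULL) {
  if (!inherits(manifest, "run_manifest") || !length(manifest$stages)) {
    stop("empty or invalid manifest", call. = FALSE)
  }
  out_dir <- manifest$out_dir
  lines <- c("# raftscape run report", "",
             paste0("Seed: ", manifest$seed,
                    "; package version: ", manifest$package_version), "")
  section <- function(title, stage, body_fn) {
    if (is.null(manifest$stages[[stage]])) {
      c(paste("##", title), "", paste0("_Stage `", stage, "` absent from ",
                                       "this run._"), "")
    } else {
      c(paste("##", title), "", body_fn(), "")
    }
  }
  fmt_num <- function(x) formatC(x, digits = 4, format = "g")

  lines <- c(lines, section("Cohort", "simulate", function() {
    cohort <- read_cohort(file.path(out_dir, "cohort.csv"))
    paste0(nrow(cohort), " subjects (",
           paste(names(table(cohort$group)), table(cohort$group),
                 sep = ": ", collapse = ", "), "), ",
           length(fa_cols(cohort)), " fatty-acid and ",
           length(class_cols(cohort)), " lipid-class variables.")
  }))

  lines <- c(lines, section("Effect-size forest table", "stats", function() {
    forest <- read.csv(file.path(out_dir, "forest_table.csv"))
    big <- forest[forest$large_effect, ]
    c(paste0(nrow(big), " of ", nrow(forest),
             " tokens flagged as large effects (|d| > 0.8):"),
      "",
      paste0("- ", big$token, ": d = ", fmt_num(big$d),
             " [", fmt_num(big$ci_low), ", ", fmt_num(big$ci_high),
             "], M-W p = ", fmt_num(big$p_value)))
  }))

  lines <- c(lines, section("PCA lipid signature", "stats", function() {
    pca <- jsonlite::read_json(file.path(out_dir, "pca.json"),
                               simplifyVector = TRUE)
    paste0("Component ", seq_along(pca$variance_fraction),
           ": variance fraction ", fmt_num(pca$variance_fraction),
           ", factor-score ANOVA F = ", fmt_num(pca$anova_f),
           ", p = ", fmt_num(pca$anova_p))
  }))

  lines <- c(lines, section("Correlation remodelling", "stats", function() {
    hm_n <- read.csv(file.path(out_dir, "heatmap_nsl.csv"), row.names = 1,
                     check.names = FALSE)
    hm_a <- read.csv(file.path(out_dir, "heatmap_als.csv"), row.names = 1,
                     check.names = FALSE)
    c("Pearson r (NSL | ALS) for selected pairs:",
      "",
      unlist(lapply(rownames(hm_n), function(rv) {
        paste0("- ", rv, " vs ", colnames(hm_n)[1], ": ",
               fmt_num(hm_n[rv, 1]), " | ", fmt_num(hm_a[rv, 1]))
      })))
  }))

  lines <- c(lines, section("Cholesterol-cholesteryl ester regression",
                            "stats", function() {
    reg <- jsonlite::read_json(file.path(out_dir, "regressions.json"),
                               simplifyVector = TRUE)
    paste0("beta_", names(reg$beta_by_group), " = ",
           fmt_num(unlist(reg$beta_by_group)), collapse = "; ") |>
      paste0("; slope-heterogeneity F = ", fmt_num(reg$f_stat),
             ", p = ", fmt_num(reg$p_value))
  }))

  lines <- c(lines, section("Microviscosity", "viscosity", function() {
    v <- jsonlite::read_json(file.path(out_dir, "viscosity.json"),
                             simplifyVector = TRUE)
    paste0("eta(NSL) = ", fmt_num(v$group_means$NSL), " P, eta(ALS) = ",
           fmt_num(v$group_means$ALS), " P; fluidity change ",
           fmt_num(v$pct_fluidity_change), "%, Cohen's d = ",
           fmt_num(v$cohens_d), ", p = ", fmt_num(v$p_value))
  }))

  lines <- c(lines, section("Membrane simulation", "abm", function() {
    a <- jsonlite::read_json(file.path(out_dir, "abm_summary.json"),
                             simplifyVector = TRUE)
    unlist(lapply(c("NSL", "ALS"), function(gl) {
      m <- a[[gl]]$mean
      paste0("- ", gl, ": rafts = ", fmt_num(m$n_rafts),
             ", mean size = ", fmt_num(m$mean_size),
             ", area fraction = ", fmt_num(m$area_fraction),
             ", mobility raft/non-raft = ", fmt_num(m$mobility_raft),
             "/", fmt_num(m$mobility_nonraft))
    }))
  }))

  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
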