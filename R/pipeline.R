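# End-to-end orchestration: configuration, the tactics pipeline
# (eigenbasis -> scalogram -> PCA classification) and the movement-tree
# pipeline (grow -> unit-blocked CV -> 1-SE prune -> permutation test),
# with machine-readable reports and a reproducibility manifest.

#' Default run configuration
#'
#' @param ... overrides for any defaults: `n_hours` (450), `n_harmonics`
#'   (205), `alpha` (0.05), `vif_threshold` (10), `missing_cap` (0.35, the
#'   per-fish missing-data retention cap), `min_leaf` (5), `cp` (0.01),
#'   `n_folds` (10), `n_permutations` (999), `seed` (1), `output_dir`
#'   (`NULL` = write nothing), and input paths `body_temps`, `excursions`
#'   or synthetic settings `synthetic` (a list passed to the generators).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(n_hours = 450L, n_harmonics = 205L, alpha = 0.05,
              vif_threshold = 10, missing_cap = 0.35,
              min_leaf = 5L, cp = 0.01, n_folds = 10L,
              n_permutations = 999L, seed = 1L,
              output_dir = NULL, body_temps = NULL, excursions = NULL,
              synthetic = list())
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  if (cfg$n_hours < 96L) stop("analysis window must span >= 96 h", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Load a configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return A [`run_config`][run_config].
#' @export
load_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

write_manifest <- function(cfg, dir, stage) {
  cfg_plain <- unclass(cfg)
  jsonlite::write_json(
    list(stage = stage,
         config = cfg_plain,
         config_hash = sum(utf8ToInt(paste(deparse(cfg_plain), collapse = ""))),
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("thermotactics"))),
    file.path(dir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the thermal-tactics pipeline
#'
#' Loads (or simulates) the body-temperature series, drops fish above the
#' missing-data cap, builds and Moran-filters the eigenfunction basis,
#' fits each fish, aggregates scale-band totals and classifies tactics.
#' When `output_dir` is set, writes `scalogram.csv`, `band_totals.csv`,
#' `tactics.csv`, `loadings.csv`, a JSON `tactics_report.json` and a
#' manifest.
#'
#' @param config a [`run_config`][run_config] (or path accepted by
#'   [load_config()]).
#' @return Invisibly, a list: `fits`, `scalogram`, `band_matrix`,
#'   `tactics`, `excluded` (fish over the cap, with reasons), `basis`.
#' @export
run_tactics <- function(config = run_config()) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  series <- if (!is.null(config$body_temps)) {
    if (!file.exists(config$body_temps))
      stop("cannot read body temperatures: ", config$body_temps, call. = FALSE)
    read_body_temps(config$body_temps)
  } else {
    do.call(simulate_population,
            c(list(n_hours = config$n_hours, seed = config$seed),
              config$synthetic))
  }
  frac <- vapply(series, `[[`, numeric(1), "missing_fraction")
  drop <- frac > config$missing_cap
  excluded <- data.frame(
    fish_id = vapply(series[drop], `[[`, character(1), "fish_id"),
    missing_fraction = frac[drop],
    reason = rep("missing_data_above_cap", sum(drop)))
  if (any(drop))
    message("excluded ", sum(drop), " fish over the missing-data cap: ",
            paste(excluded$fish_id, collapse = ", "))
  series <- series[!drop]
  if (length(series) < 3L)
    stop("fewer than 3 fish retained; cannot classify tactics", call. = FALSE)

  n_hours <- length(series[[1L]]$temps)
  basis <- filter_by_moran(build_basis(n_hours, config$n_harmonics),
                           config$alpha)
  fits <- lapply(series, function(s)
    fit_individual(s$temps, basis, config$vif_threshold, fish_id = s$fish_id))
  bands <- scale_bands(config$n_harmonics, n_hours)
  band_matrix <- do.call(rbind, lapply(fits, aggregate_bands, bands = bands))
  rownames(band_matrix) <- vapply(fits, function(f) as.character(f$fish_id),
                                  character(1))
  scal <- population_scalogram(fits, basis)
  tactics <- classify_tactics(band_matrix)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$output_dir
    utils::write.csv(scal, file.path(od, "scalogram.csv"), row.names = FALSE)
    utils::write.csv(data.frame(fish_id = rownames(band_matrix), band_matrix),
                     file.path(od, "band_totals.csv"), row.names = FALSE)
    utils::write.csv(tactics, file.path(od, "tactics.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(band = rownames(attr(tactics, "loadings")),
                 attr(tactics, "loadings")),
      file.path(od, "loadings.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(n_fish = length(fits),
           excluded = excluded,
           r2adj = stats::setNames(vapply(fits, `[[`, numeric(1), "r2adj_full"),
                                   rownames(band_matrix)),
           band_totals = as.data.frame(band_matrix),
           tactic = stats::setNames(tactics$tactic, tactics$fish_id),
           pooled = stats::setNames(tactics$pooled, tactics$fish_id),
           var_fraction = attr(tactics, "var_fraction")),
      file.path(od, "tactics_report.json"),
      auto_unbox = TRUE, digits = NA)
    write_manifest(config, od, "tactics")
  }
  invisible(list(fits = fits, scalogram = scal, band_matrix = band_matrix,
                 tactics = tactics, excluded = excluded, basis = basis))
}

#' Run the excursion regression-tree pipeline
#'
#' Loads (or simulates) the excursion dataset, grows the tree on mean
#' daily epilimnion/metalimnion temperature, day of year and year, runs
#' unit-blocked cross-validation (units = fish), prunes by the 1-SE rule
#' and applies the permutation test.  When `output_dir` is set, writes
#' `tree_report.json`, a text rendering of the tree, and a manifest.
#'
#' @param config a [`run_config`][run_config] (or a path accepted by
#'   [load_config()]).
#' @return Invisibly, a list: `data`, `tree` (full), `cv`, `pruned`,
#'   `permutation`.
#' @export
run_tree <- function(config = run_config()) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  dat <- if (!is.null(config$excursions)) {
    if (!file.exists(config$excursions))
      stop("cannot read excursions: ", config$excursions, call. = FALSE)
    read_excursions(config$excursions)
  } else {
    do.call(simulate_excursion_dataset,
            c(list(seed = config$seed), config$synthetic))
  }
  X <- dat[, c("epi_mean", "meta_mean", "day_of_year", "year")]
  y <- dat$excursion_pct
  cv <- grouped_cv(X, y, units = dat$fish_id, n_folds = config$n_folds,
                   seed = config$seed, min_leaf = config$min_leaf,
                   cp = config$cp)
  pruned <- prune_1se(cv)
  perm <- if (pruned$leaf_count >= 2L) {
    permutation_test(pruned, X, y, units = dat$fish_id,
                     m = config$n_permutations, seed = config$seed)
  } else NULL

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$output_dir
    fr <- pruned$frame
    jsonlite::write_json(
      list(n = length(y),
           leaf_count = pruned$leaf_count,
           r2 = pruned$r2,
           splits = fr[!fr$leaf, c("node", "var", "split", "n")],
           leaves = fr[fr$leaf, c("node", "yval", "n")],
           cv = cv$table,
           p_value = if (is.null(perm)) NA else perm$p_value),
      file.path(od, "tree_report.json"), auto_unbox = TRUE, digits = NA)
    writeLines(utils::capture.output(print(pruned)),
               file.path(od, "tree_report.txt"))
    write_manifest(config, od, "tree")
  }
  invisible(list(data = dat, tree = cv$tree, cv = cv, pruned = pruned,
                 permutation = perm))
}
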