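#' Run the full consortium analysis pipeline
#'
#' Wires the stages end to end: read (or reconstruct) the two member models,
#' compute mono-culture growth on the medium, build the balanced-growth
#' community, run the interaction screen with redundancy-group discovery,
#' and write the artifacts: the community flux report, the interaction
#' table, the group table, and a JSON run manifest (package version, solver
#' identity, seed, config echo).  Identical config and seed give identical
#' TSV outputs.
#'
#' A config is a flat named list (or a YAML file of one): `model_a`,
#' `model_b` (paths), `medium` (path), `out_dir`, and optional `pfba`
#' (default `TRUE`), `knockout_side` (`"recipient"` or `"donor"`),
#' `fva_fraction` (default 0.999), `seed` (default 1), `max_group_size`
#' (default 3).
#'
#' @param config named list or path to a YAML config file.
#' @return invisibly, a list with the screen report, the interaction table,
#'   the groups, and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(knockout_side = "recipient", fva_fraction = 0.999,
                   seed = 1L, max_group_size = 3)
  config <- modifyList(defaults, config)
  for (field in c("model_a", "model_b", "medium", "out_dir"))
    if (is.null(config[[field]]))
      stop("config lacks required field '", field, "'", call. = FALSE)
  for (field in c("model_a", "model_b", "medium"))
    if (!file.exists(config[[field]]))
      stop("config path does not exist: ", config[[field]], call. = FALSE)
  stopifnot(config$fva_fraction > 0, config$fva_fraction <= 1)
  set.seed(config$seed)

  model_a <- read_model(config$model_a)
  model_b <- read_model(config$model_b)
  med <- read_medium(config$medium)
  community <- build_community(model_a, model_b, med)
  report <- screen_interactions(community, side = config$knockout_side,
                                fraction = config$fva_fraction)
  groups <- auto_groups(community, max_size = config$max_group_size)
  report$groups_tested <- screen_groups(community, groups)
  tab <- interaction_table(report, groups)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    interactions = file.path(config$out_dir, "interactions.tsv"),
    groups = file.path(config$out_dir, "groups.tsv"),
    fluxes = file.path(config$out_dir, "community_fluxes.tsv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write_interaction_table(tab, paths$interactions)
  utils::write.table(report$groups_tested, paths$groups, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pf <- solve_pfba(community$system)
  write_flux_report(community$system, pf, paths$fluxes)
  manifest <- list(package = "crossfeedr",
                   version = as.character(utils::packageVersion("crossfeedr")),
                   solver = .solver_info()$name,
                   seed = config$seed,
                   baseline_growth = report$baseline_growth,
                   mono_growth = list(a = report$mono_growth_A,
                                      b = report$mono_growth_B),
                   config = config[c("model_a", "model_b", "medium",
                                     "knockout_side", "fva_fraction",
                                     "max_group_size")])
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(report = report, table = tab, groups = groups,
                 paths = paths))
}
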