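## Command-line front end. The R functions are the real interface; this is
## a thin dispatcher so the tool can be driven from a shell:
##   Rscript -e 'commfba::cli_main(commandArgs(TRUE))' <subcommand> ...
## Every run writes a manifest (arguments, versions, seed, solver settings)
## beside its outputs so results can be reproduced exactly. Diagnostics go
## to stderr; data files never receive log lines.

cli_usage <- "usage: commfba <subcommand> [--key value ...]
subcommands:
  validate  --model FILE [--out qc.tsv]
  fba       --model FILE --medium FILE [--out sol.json]
  community --models DIR --strains a,b,c --medium FILE
            [--scenario no_limitation|equal_abundance|target_strain|defined_abundances]
            [--target STRAIN] [--pfba true] [--out sol.json]
  screen    --models DIR --pool a,b,c --sizes MIN:MAX --media FILE[,FILE...]
            [--scenario no_limitation] [--out results.tsv]
  depletion --models DIR --strains a,b,c --medium FILE [--dt 1] [--vmax 10]
            [--out trajectory.tsv]
  crossfeed --models DIR --strains a,b,c --medium FILE [--classmap FILE]
            [--format graphml|edge_tsv] [--out network.graphml]
  pci       --dhp NUM --dh NUM
  media     --sources glc,cit,ac,fum [--budget 100] --out DIR
  synth     [--preset dhp] [--seed 7] --out DIR"

cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    key <- argv[[i]]
    if (!startsWith(key, "--"))
      stop("unexpected argument '", key, "'", call. = FALSE)
    if (i + 1L > length(argv)) stop("missing value for ", key, call. = FALSE)
    out[[substring(key, 3L)]] <- argv[[i + 1L]]
    i <- i + 2L
  }
  out
}

cli_need <- function(args, keys) {
  miss <- setdiff(keys, names(args))
  if (length(miss)) stop("missing required option --", miss[1L], call. = FALSE)
}

cli_models <- function(dir, ids) {
  files <- file.path(dir, paste0(ids, ".json"))
  missing <- !file.exists(files)
  if (any(missing)) stop("no model file for strain '", ids[missing][1L],
                         "' under ", dir, call. = FALSE)
  stats::setNames(lapply(files, load_strain_model), ids)
}

cli_scenario <- function(args, ids) {
  sc <- if (is.null(args$scenario)) "no_limitation" else args$scenario
  objective_spec(sc, target = args$target,
                 abundances = if (sc == "defined_abundances")
                   stats::setNames(rep(1 / length(ids), length(ids)), ids))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce an output file exactly: the
#' subcommand and arguments, package and R versions, seed, solver
#' tolerances and the md5 of each produced output.
#'
#' @param command subcommand name.
#' @param args named list of parsed options.
#' @param outputs character vector of produced file paths.
#' @param seed integer seed used by the run (NA when the run is
#'   deterministic by construction).
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(command, args, outputs, seed = NA_integer_) {
  anchor <- if (length(outputs)) outputs[[1L]] else file.path(".", command)
  path <- paste0(anchor, ".manifest.json")
  manifest <- list(
    command = command,
    arguments = args,
    package = "commfba",
    package_version = as.character(utils::packageVersion("commfba")),
    r_version = as.character(getRversion()),
    seed = seed,
    solver = list(backend = "bounded-variable two-phase simplex",
                  feasibility_tol = 1e-9, flux_epsilon = EPS_FLUX),
    config_hash = substr(digest_args(c(command = command, args)), 1, 32),
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

digest_args <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Command-line entry point
#'
#' Dispatches the subcommands listed in the usage text. Returns (rather
#' than calls \code{quit} with) the process exit code so it can be tested
#' in-process: 0 on success, 2 on usage or validation errors, 1 on any
#' other failure.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv) || argv[[1L]] %in% c("-h", "--help", "help")) {
    message(cli_usage)
    return(invisible(if (length(argv)) 0L else 2L))
  }
  cmd <- argv[[1L]]
  res <- tryCatch({
    args <- cli_args(argv[-1L])
    switch(cmd,
           validate = cli_validate(args),
           fba = cli_fba(args),
           community = cli_community(args),
           screen = cli_screen(args),
           depletion = cli_depletion(args),
           crossfeed = cli_crossfeed(args),
           pci = cli_pci(args),
           media = cli_media(args),
           synth = cli_synth(args),
           stop("unknown subcommand '", cmd, "'", call. = FALSE))
    0L
  }, usage_error = function(e) {
    message(conditionMessage(e)); message(cli_usage); 2L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (is.null(conditionCall(e))) {  # raised by the CLI layer itself
      message(cli_usage); 2L
    } else 1L
  })
  invisible(res)
}

cli_validate <- function(args) {
  cli_need(args, "model")
  model <- load_strain_model(args$model)
  rep <- validate_strain_model(model)
  out <- if (is.null(args$out)) paste0(args$model, ".qc.tsv") else args$out
  write_qc_tsv(rep, out)
  message("QC: ", sum(rep$status == "FAIL"), " FAIL / ", nrow(rep), " checks -> ", out)
  write_manifest("validate", args, out)
}

cli_fba <- function(args) {
  cli_need(args, c("model", "medium"))
  model <- load_strain_model(args$model)
  med <- read_medium_tsv(args$medium)
  sol <- solve_fba(model, med)
  message("status ", sol$status, "; objective ", format(sol$objective_value))
  if (!is.null(args$out)) {
    jsonlite::write_json(list(status = sol$status,
                              objective_value = sol$objective_value,
                              fluxes = as.list(sol$fluxes)),
                         args$out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest("fba", args, args$out)
  }
}

cli_community <- function(args) {
  cli_need(args, c("models", "strains", "medium"))
  ids <- strsplit(args$strains, ",")[[1L]]
  models <- cli_models(args$models, ids)
  med <- read_medium_tsv(args$medium)
  com <- assemble_community(models, med)
  obj <- cli_scenario(args, ids)
  sol <- if (identical(args$pfba, "false")) solve_community(com, obj)
  else solve_community_pfba(com, obj)
  message("status ", sol$status, "; total biomass ", format(sol$total_biomass))
  if (!is.null(args$out)) {
    write_solution_json(sol, args$out)
    write_manifest("community", args, args$out)
  }
}

cli_screen <- function(args) {
  cli_need(args, c("models", "pool", "sizes", "media"))
  ids <- strsplit(args$pool, ",")[[1L]]
  models <- cli_models(args$models, ids)
  sizes <- as.integer(strsplit(args$sizes, ":")[[1L]])
  media <- lapply(strsplit(args$media, ",")[[1L]], read_medium_tsv)
  cfg <- screen_config(ids, sizes[[1L]], sizes[[length(sizes)]], media,
                       scenarios = list(cli_scenario(args, ids)),
                       seed = as.integer(if (is.null(args$seed)) 1 else args$seed))
  results <- run_screen(cfg, models)
  out <- if (is.null(args$out)) "results.tsv" else args$out
  write_screen_tsv(results, out)
  message(nrow(results), " screen rows -> ", out)
  write_manifest("screen", args, out, seed = cfg$seed)
}

cli_depletion <- function(args) {
  cli_need(args, c("models", "strains", "medium"))
  ids <- strsplit(args$strains, ",")[[1L]]
  models <- cli_models(args$models, ids)
  med <- read_medium_tsv(args$medium)
  com <- assemble_community(models, med)
  dep <- simulate_depletion(com, cli_scenario(args, ids),
                            dt = as.numeric(if (is.null(args$dt)) 1 else args$dt),
                            vmax = as.numeric(if (is.null(args$vmax)) 10 else args$vmax))
  message("growth_time ", dep$growth_time, " (", dep$stopped_because, ")")
  if (!is.null(args$out)) {
    utils::write.table(dep$trajectory, args$out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_manifest("depletion", args, args$out)
  }
}

cli_crossfeed <- function(args) {
  cli_need(args, c("models", "strains", "medium"))
  ids <- strsplit(args$strains, ",")[[1L]]
  models <- cli_models(args$models, ids)
  med <- read_medium_tsv(args$medium)
  sol <- solve_community_pfba(assemble_community(models, med),
                              cli_scenario(args, ids))
  cmap <- read_class_map(args$classmap)
  nw <- extract_cross_feeding(sol, cmap)
  fmt <- if (is.null(args$format)) "graphml" else args$format
  out <- if (is.null(args$out)) paste0("network.", fmt) else args$out
  export_network(nw, out, fmt)
  message(nrow(nw$edges), " edges -> ", out)
  write_manifest("crossfeed", args, out)
}

cli_pci <- function(args) {
  cli_need(args, c("dhp", "dh"))
  cat(format(compute_pci(as.numeric(args$dhp), as.numeric(args$dh))), "\n")
}

cli_media <- function(args) {
  cli_need(args, c("sources", "out"))
  media <- build_media_series(strsplit(args$sources, ",")[[1L]],
                              as.numeric(if (is.null(args$budget)) 100
                                         else args$budget))
  dir.create(args$out, showWarnings = FALSE, recursive = TRUE)
  outs <- vapply(media, function(m)
    write_medium_tsv(m, file.path(args$out, paste0(m$name, ".tsv"))),
    character(1))
  message(length(outs), " media -> ", args$out)
  write_manifest("media", args, outs)
}

cli_synth <- function(args) {
  cli_need(args, "out")
  preset <- if (is.null(args$preset)) "dhp" else args$preset
  seed <- as.integer(if (is.null(args$seed)) 7 else args$seed)
  set <- switch(preset,
                dhp = make_paperlike_consortium(dhp_spec(seed = seed)),
                dhp_bystander = make_paperlike_consortium(
                  dhp_spec(bystander = TRUE, seed = seed)),
                demo6 = make_paperlike_consortium(
                  dhp_spec(n_helpers = 3, n_potentiators = 2, seed = seed)),
                stop("unknown preset '", preset, "'", call. = FALSE))
  write_toy_set(set$models, set$media, args$out)
  message(length(set$models), " models + ", length(set$media),
          " media -> ", args$out)
  write_manifest("synth", args,
                 file.path(args$out, paste0(names(set$models), ".json")),
                 seed = seed)
}
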