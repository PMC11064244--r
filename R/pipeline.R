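#' Assemble a run configuration
#'
#' A single serializable object describing one end-to-end analysis: the six
#' input TSVs, which formulas to analyse, the filter switches, the weighting,
#' and the null-model settings. \code{\link{runPipeline}} records the whole
#' configuration into \code{run-metadata.json} so every report is exactly
#' reproducible.
#'
#' @param formulaHerb,herbCompound,compoundTarget,drugTarget,modules paths to
#'   the five association / module-definition TSVs
#' @param admet path to the ADMET annotation TSV, or NULL to skip the filter
#' @param universe path to a one-column \code{gene_symbol} TSV to use as the
#'   null-model universe, or NULL to default to the union of all genes in
#'   the drug-target table
#' @param formulaIds formulas to analyse (NULL = every formula in the
#'   formula-herb table, in file order)
#' @param excludeCyp remove CYP isozymes from all spaces (default TRUE)
#' @param rules a \linkS4class{FilterRuleSet} (default: all three rules on,
#'   unknown compounds kept)
#' @param mainWeight weight of the main-indication support (default 0.5)
#' @param nullDraws random target spaces per formula for the null model
#'   (default 1000); set to 0 to skip the null model
#' @param seed integer base seed for the null draws
#' @param outDir report output directory
#' @return a run-configuration list (class \code{tomspaceRunConfig})
#' @export
runConfig <- function(formulaHerb, herbCompound, compoundTarget, drugTarget,
                      modules, admet = NULL, universe = NULL,
                      formulaIds = NULL, excludeCyp = TRUE,
                      rules = admetRules(), mainWeight = 0.5,
                      nullDraws = 1000L, seed = 1L, outDir = tempfile("run")) {
  cfg <- list(
    paths = list(formula_herb = formulaHerb, herb_compound = herbCompound,
                 compound_target = compoundTarget, drug_target = drugTarget,
                 modules = modules, admet = admet, universe = universe),
    formulaIds = formulaIds, excludeCyp = isTRUE(excludeCyp), rules = rules,
    mainWeight = mainWeight, nullDraws = as.integer(nullDraws),
    seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "tomspaceRunConfig"
  cfg
}

#' Build a run configuration from a synthetic bundle
#'
#' Convenience wrapper pointing \code{\link{runConfig}} at the files written
#' by \code{\link{generateDataset}}.
#'
#' @param bundle the list returned by \code{\link{generateDataset}}
#' @param ... further arguments passed to \code{\link{runConfig}}
#' @return a run-configuration list
#' @export
runConfigFromBundle <- function(bundle, ...) {
  p <- bundle$paths
  runConfig(formulaHerb = p[["formula_herb"]],
            herbCompound = p[["herb_compound"]],
            compoundTarget = p[["compound_target"]],
            drugTarget = p[["drug_target"]],
            modules = p[["modules"]],
            admet = p[["admet"]],
            universe = p[["universe"]], ...)
}

#' Build a run configuration from a YAML file
#'
#' The YAML mirrors \code{\link{runConfig}}'s arguments: top-level keys
#' \code{paths} (with \code{formula_herb}, \code{herb_compound},
#' \code{compound_target}, \code{drug_target}, \code{modules}, optional
#' \code{admet}, \code{universe}), plus optional \code{formula_ids},
#' \code{exclude_cyp}, \code{rules} (\code{ames}, \code{carcinogenicity},
#' \code{herg}, \code{unknown_policy}), \code{main_weight},
#' \code{null_draws}, \code{seed}, \code{out_dir}. Relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path
#' @return a run-configuration list
#' @export
runConfigFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rp <- function(p) {
    if (is.null(p)) NULL
    else if (startsWith(p, "/")) p
    else file.path(base, p)
  }
  r <- y$rules
  runConfig(
    formulaHerb = rp(y$paths$formula_herb),
    herbCompound = rp(y$paths$herb_compound),
    compoundTarget = rp(y$paths$compound_target),
    drugTarget = rp(y$paths$drug_target),
    modules = rp(y$paths$modules),
    admet = rp(y$paths$admet),
    universe = rp(y$paths$universe),
    formulaIds = unlist(y$formula_ids),
    excludeCyp = if (is.null(y$exclude_cyp)) TRUE else isTRUE(y$exclude_cyp),
    rules = admetRules(
      excludeAmes = if (is.null(r$ames)) TRUE else isTRUE(r$ames),
      excludeCarcinogenicity = if (is.null(r$carcinogenicity)) TRUE
                               else isTRUE(r$carcinogenicity),
      excludeHerg = if (is.null(r$herg)) TRUE else isTRUE(r$herg),
      unknownPolicy = if (is.null(r$unknown_policy)) "keep" else r$unknown_policy),
    mainWeight = if (is.null(y$main_weight)) 0.5 else y$main_weight,
    nullDraws = if (is.null(y$null_draws)) 1000L else y$null_draws,
    seed = if (is.null(y$seed)) 1L else y$seed,
    outDir = if (is.null(y$out_dir)) tempfile("run") else rp(y$out_dir))
}

#' Validate a run configuration
#'
#' Checks everything \code{\link{runPipeline}} needs before any work is
#' done. Returns a character vector of human-readable problems; an empty
#' vector means the configuration is runnable.
#'
#' @param config a run-configuration list from \code{\link{runConfig}}
#' @return character vector of problems (empty when valid)
#' @export
validateConfig <- function(config) {
  problems <- character()
  required <- c("formula_herb", "herb_compound", "compound_target",
                "drug_target", "modules")
  for (nm in required) {
    p <- config$paths[[nm]]
    if (is.null(p) || !file.exists(p))
      problems <- c(problems, sprintf("missing input file for %s: %s", nm,
                                      if (is.null(p)) "<unset>" else p))
  }
  for (nm in c("admet", "universe")) {
    p <- config$paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      problems <- c(problems, sprintf("configured %s file does not exist: %s",
                                      nm, p))
  }
  if (!is.numeric(config$mainWeight) || config$mainWeight < 0 ||
      config$mainWeight > 1)
    problems <- c(problems, "main_weight must lie in [0, 1]")
  if (config$nullDraws < 0)
    problems <- c(problems, "null_draws must be >= 0")
  if (!length(problems) && !is.null(config$paths$modules)) {
    mods <- tryCatch(loadModuleDefinitions(config$paths$modules),
                     error = function(e) conditionMessage(e))
    if (is.character(mods))
      problems <- c(problems, mods)
  }
  problems
}

#' Run the full target-space analysis
#'
#' Orchestrates the whole method: load the association tables, apply the
#' ADMET exclusion rules to the compound pool, build the CYP-excluded target
#' space of every formula and drug module, compute one support per
#' (module, formula) pair, aggregate each formula's supports into the
#' weighted score, resample the random-target-space null against the main
#' module's cardinality, and write the report files into
#' \code{config$outDir}:
#' \itemize{
#'   \item \code{report.tsv} — support matrix (modules x formulas) with the
#'     weighted-average row, 2-decimal rounding;
#'   \item \code{report.json} — full-precision scores, overlap gene lists,
#'     null summaries, and run metadata;
#'   \item \code{exclusions.tsv} — audit trail of every ADMET exclusion with
#'     the rule(s) it triggered;
#'   \item \code{run-metadata.json} — the resolved configuration, including
#'     the CYP rule, variance convention, RNG identity and seed.
#' }
#'
#' Per-formula null draws use seeds \code{seed}, \code{seed + 1}, ... so the
#' whole report is byte-identical across reruns with the same configuration.
#'
#' @param config a run-configuration list from \code{\link{runConfig}}
#' @return invisibly, a list with \code{scores}, \code{supports},
#'   \code{nulls}, \code{exclusions}, \code{formulaSpaces},
#'   \code{moduleSpaces}, and the output \code{paths}
#' @export
runPipeline <- function(config) {
  problems <- validateConfig(config)
  if (length(problems))
    stop(paste(c("invalid run configuration:", problems), collapse = "\n  "))

  fh <- loadAssociationTable(config$paths$formula_herb, "formula_herb")
  hc <- loadAssociationTable(config$paths$herb_compound, "herb_compound")
  ct <- loadAssociationTable(config$paths$compound_target, "compound_target")
  dt <- loadAssociationTable(config$paths$drug_target, "drug_target")
  mods <- loadModuleDefinitions(config$paths$modules)

  # ADMET triage of the compound pool
  allCompounds <- unique(edges(hc)$target)
  if (!is.null(config$paths$admet)) {
    admet <- loadAdmetTable(config$paths$admet)
    filt <- applyAdmetFilter(allCompounds, admet, config$rules)
    kept <- filt$kept
    exclusions <- filt$excluded
  } else {
    kept <- NULL
    exclusions <- data.frame(compound_id = character(), rule = character())
  }

  # module spaces (input file order, main first as returned by the loader)
  moduleSpaces <- lapply(mods, buildModuleSpace, drugTarget = dt,
                         excludeCyp = config$excludeCyp)
  modulePairs <- Map(function(d, s) list(def = d, space = s),
                     mods, moduleSpaces)
  moduleLabels <- stats::setNames(
    vapply(mods, diseaseLabel, ""), vapply(mods, moduleId, ""))

  formulaIds <- config$formulaIds
  if (is.null(formulaIds)) formulaIds <- unique(edges(fh)$source)
  missingF <- setdiff(formulaIds, edges(fh)$source)
  if (length(missingF))
    stop(sprintf("formula(s) not present in formula-herb table: %s",
                 paste(missingF, collapse = ", ")))

  universe <- if (!is.null(config$paths$universe)) {
    df <- .readTsv(config$paths$universe)
    if (!"gene_symbol" %in% colnames(df))
      stop(sprintf("schema error in %s: missing column gene_symbol",
                   config$paths$universe))
    geneUniverse(df$gene_symbol, sourceTag = basename(config$paths$universe))
  } else {
    geneUniverse(edges(dt)$target, sourceTag = "drug_target union")
  }

  scores <- list(); supports <- list(); nulls <- list()
  formulaSpaces <- list()
  mainK <- length(genes(moduleSpaces[[1]]))
  for (i in seq_along(formulaIds)) {
    f <- formulaIds[i]
    fs <- buildFormulaSpace(f, fh, hc, ct, keptCompounds = kept,
                            excludeCyp = config$excludeCyp)
    formulaSpaces[[f]] <- fs
    cmp <- compareFormulaToModules(fs, modulePairs,
                                   mainWeight = config$mainWeight)
    scores[[f]] <- cmp$score
    supports <- c(supports, cmp$supports)
    if (config$nullDraws > 0L) {
      nulls[[f]] <- sampleNull(fs, universe, k = mainK,
                               nDraws = config$nullDraws,
                               seed = config$seed + i - 1L,
                               observed = cmp$score@mainSupport)
    }
  }

  if (!dir.exists(config$outDir))
    dir.create(config$outDir, recursive = TRUE)

  metadata <- list(
    cyp_rule = "symbol matches ^CYP<digit>; applied to both formula and module spaces",
    cyp_excluded = config$excludeCyp,
    admet_rules = list(ames = config$rules@excludeAmes,
                       carcinogenicity = config$rules@excludeCarcinogenicity,
                       herg = config$rules@excludeHerg,
                       unknown_policy = config$rules@unknownPolicy,
                       enabled = !is.null(config$paths$admet)),
    main_weight = config$mainWeight,
    null_model = list(n_draws = config$nullDraws, base_seed = config$seed,
                      k = mainK, universe_size = length(genes(universe)),
                      universe_source = universe@sourceTag,
                      rng = "Mersenne-Twister",
                      variance_convention = "population (divide by n_draws)"),
    formula_ids = as.list(formulaIds),
    module_ids = as.list(vapply(mods, moduleId, ""))
  )

  reportPaths <- writeReport(scores = unname(scores), nulls = unname(nulls),
                             dir = config$outDir,
                             supportResults = supports,
                             moduleLabels = moduleLabels,
                             metadata = metadata)
  exclPath <- file.path(config$outDir, "exclusions.tsv")
  utils::write.table(exclusions, exclPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  metaPath <- file.path(config$outDir, "run-metadata.json")
  jsonlite::write_json(metadata, metaPath, auto_unbox = TRUE, digits = NA)

  invisible(list(scores = scores, supports = supports, nulls = nulls,
                 exclusions = exclusions, formulaSpaces = formulaSpaces,
                 moduleSpaces = moduleSpaces,
                 paths = c(reportPaths, exclusions = exclPath,
                           metadata = metaPath)))
}
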