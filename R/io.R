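## Expected header columns for each association kind.
.assocColumns <- list(
  formula_herb    = c("formula_id", "herb_id"),
  herb_compound   = c("herb_id", "compound_id"),
  compound_target = c("compound_id", "gene_symbol"),
  drug_target     = c("drug_id", "gene_symbol")
)

.readTsv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path))
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8",
                    blank.lines.skip = TRUE)
}

#' Construct an association table from source/target id vectors
#'
#' Trims whitespace, normalizes gene symbols when the target column carries
#' genes, and collapses duplicate (source, target) pairs, recording how many
#' rows were collapsed. Used by both the file loader and the synthetic
#' generator.
#'
#' @param source,target character vectors of equal length
#' @param kind one of \code{"formula_herb"}, \code{"herb_compound"},
#'   \code{"compound_target"}, \code{"drug_target"}
#' @return an \linkS4class{AssociationTable}
#' @export
associationTable <- function(source, target, kind) {
  kind <- match.arg(kind, names(.assocColumns))
  source <- trimws(as.character(source))
  target <- trimws(as.character(target))
  if (length(source) != length(target))
    stop("source and target must have equal length")
  if (any(!nzchar(source)) || any(!nzchar(target)))
    stop(sprintf("empty id in %s association", kind))
  if (endsWith(kind, "_target"))
    target <- normalizeGeneSymbols(target)
  df <- data.frame(source = source, target = target, stringsAsFactors = FALSE)
  dup <- duplicated(df)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  new("AssociationTable", kind = kind, edges = df,
      nDuplicates = as.integer(sum(dup)))
}

#' Load an association table from a TSV file
#'
#' Files are tab-separated UTF-8 with a header row naming the two id columns
#' (e.g. \code{compound_id}, \code{gene_symbol}); lines starting with
#' \code{#} are ignored. Duplicate rows are collapsed silently but counted —
#' curated herb-target data legitimately report more associations than
#' distinct targets, and both numbers stay reportable.
#'
#' @param path TSV file path
#' @param kind association kind; decides the expected column names
#' @return an \linkS4class{AssociationTable}
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("compound_id\tgene_symbol", "c1\tALB", "c1\tgabrb1"), tsv)
#' loadAssociationTable(tsv, "compound_target")
#' @export
loadAssociationTable <- function(path, kind) {
  kind <- match.arg(kind, names(.assocColumns))
  df <- .readTsv(path)
  cols <- .assocColumns[[kind]]
  missing <- setdiff(cols, colnames(df))
  if (length(missing))
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  if (nrow(df) == 0L)
    stop(sprintf("schema error in %s: table is empty", path))
  tab <- associationTable(df[[cols[1]]], df[[cols[2]]], kind)
  if (tab@nDuplicates > 0L)
    message(sprintf("%s: collapsed %d duplicate edge(s)", basename(path),
                    tab@nDuplicates))
  tab
}

.mapVocabulary <- function(x, canon, synonyms, column, path) {
  x <- tolower(trimws(x))
  x[!nzchar(x) | is.na(x)] <- "unknown"
  for (s in names(synonyms)) x[x == s] <- synonyms[[s]]
  bad <- setdiff(unique(x), canon)
  if (length(bad)) {
    rows <- which(x %in% bad)
    stop(sprintf("schema error in %s: value '%s' in column %s (row %d) outside vocabulary {%s}",
                 path, x[rows[1]], column, rows[1], paste(canon, collapse = ", ")))
  }
  x
}

#' Load per-compound ADMET annotations
#'
#' Expects columns \code{compound_id}, \code{ames}, \code{carcinogenicity},
#' \code{herg}. Vocabulary is enforced case-insensitively; blank cells map to
#' \code{"unknown"}. Accepted values: ames toxic / non-toxic; carcinogenicity
#' danger / safe (also "non-required", a common export spelling of the safe
#' class); hERG strong inhibitor / inhibitor / non-inhibitor (also "weak
#' inhibitor", folded into the non-risk tier).
#'
#' @param path TSV file path
#' @return an \linkS4class{AdmetTable}
#' @export
loadAdmetTable <- function(path) {
  df <- .readTsv(path)
  need <- c("compound_id", "ames", "carcinogenicity", "herg")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  if (nrow(df) == 0L)
    stop(sprintf("schema error in %s: table is empty", path))
  ann <- data.frame(
    compound_id = trimws(df$compound_id),
    ames = .mapVocabulary(df$ames, .amesLevels, list(), "ames", path),
    carcinogenicity = .mapVocabulary(df$carcinogenicity, .carcLevels,
                                     list("non-required" = "safe"),
                                     "carcinogenicity", path),
    herg = .mapVocabulary(df$herg, .hergLevels,
                          list("weak inhibitor" = "non-inhibitor"),
                          "herg", path),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(ann$compound_id)))
    stop(sprintf("schema error in %s: empty compound_id", path))
  new("AdmetTable", annotations = ann)
}

#' Load drug-module definitions
#'
#' One row per (module, drug); columns \code{module_id}, \code{disease_label},
#' \code{role}, \code{drug_id}. Exactly one module must carry role
#' \code{main}. Module order (hence report row order) follows first
#' appearance in the file.
#'
#' @param path TSV file path
#' @return list of \linkS4class{ModuleDefinition}, main module first
#' @export
loadModuleDefinitions <- function(path) {
  df <- .readTsv(path)
  need <- c("module_id", "disease_label", "role", "drug_id")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  if (nrow(df) == 0L)
    stop(sprintf("schema error in %s: table is empty", path))
  df$role <- tolower(trimws(df$role))
  ids <- unique(df$module_id)
  mods <- lapply(ids, function(id) {
    sub <- df[df$module_id == id, , drop = FALSE]
    role <- unique(sub$role)
    if (length(role) != 1L)
      stop(sprintf("module %s has conflicting roles", id))
    new("ModuleDefinition", moduleId = id,
        diseaseLabel = unique(sub$disease_label)[1],
        role = role, drugIds = unique(trimws(sub$drug_id)))
  })
  roles <- vapply(mods, function(m) m@role, "")
  if (sum(roles == "main") != 1L)
    stop(sprintf("exactly one module with role=main required, found %d",
                 sum(roles == "main")))
  c(mods[roles == "main"], mods[roles != "main"])
}

# report-time rounding: half away from zero at 2 decimals, with a small
# epsilon so exact decimal ties (e.g. 0.605, 0.725) are not lost to binary
# representation; matches how the reference support tables print ties
.round2 <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100
.fmt2 <- function(x) formatC(.round2(x), format = "f", digits = 2)

#' Load a per-module support table
#'
#' Reads a TSV of already-computed support values shaped like the package's
#' own \code{report.tsv}: columns \code{module}, \code{role}, then one column
#' per formula; roles are \code{main}, \code{side_effect}, and optionally
#' \code{reported_weighted_avg} for a published aggregate row to compare
#' against. Two such tables ship with the package (see
#' \code{system.file("extdata", package = "tomspace")}) and drive the
#' weighted-average demonstration in the README.
#'
#' @param path TSV file path
#' @return list with \code{formulaIds}, \code{mainSupport} (named numeric),
#'   \code{sideSupports} (modules x formulas matrix), \code{sideLabels}, and
#'   \code{reported} (named numeric of published weighted averages, or NULL)
#' @export
loadSupportTable <- function(path) {
  df <- .readTsv(path)
  need <- c("module", "role")
  if (!all(need %in% colnames(df)))
    stop(sprintf("schema error in %s: need columns module, role", path))
  fids <- setdiff(colnames(df), need)
  if (length(fids) == 0L)
    stop(sprintf("schema error in %s: no formula columns", path))
  num <- function(rows) {
    m <- as.matrix(df[rows, fids, drop = FALSE])
    storage.mode(m) <- "numeric"
    m
  }
  mainRow <- which(df$role == "main")
  if (length(mainRow) != 1L)
    stop(sprintf("schema error in %s: exactly one role=main row required", path))
  sideRows <- which(df$role == "side_effect")
  repRow <- which(df$role == "reported_weighted_avg")
  list(
    formulaIds = fids,
    mainSupport = drop(num(mainRow)),
    sideSupports = num(sideRows),
    sideLabels = df$module[sideRows],
    reported = if (length(repRow)) drop(num(repRow[1])) else NULL
  )
}

.scoreToList <- function(sc) {
  list(
    formula_id = sc@formulaId,
    main_module_id = sc@mainModuleId,
    main_support = sc@mainSupport,
    side_module_ids = as.list(sc@sideModuleIds),
    side_supports = as.list(sc@sideSupports),
    weights = as.list(sc@weights),
    weighted_average = sc@weightedAverage
  )
}

.nullToList <- function(nd) {
  list(
    formula_id = nd@formulaId, k = nd@k, n_draws = nd@nDraws,
    mean = nd@mean, variance = nd@variance,
    observed = nd@observed, empirical_p = nd@empiricalP, seed = nd@seed
  )
}

#' Write the analysis report
#'
#' Emits two files into \code{dir}: \code{report.tsv}, a matrix shaped like
#' the published support tables — one column per formula, one row per drug
#' module (labelled \code{Drugs (<disease>)}) and a final
#' \code{Support (weighted avg.)} row, all values rounded to 2 decimals with
#' round-half-even — and \code{report.json} holding full-precision supports,
#' weights, overlap gene lists, and null-distribution summaries.
#'
#' @param scores list of \linkS4class{WeightedScore}, one per formula; all
#'   scores must share the same side-module ordering
#' @param nulls optional list of \linkS4class{NullDistribution}
#' @param dir output directory (created if absent)
#' @param supportResults optional list of \linkS4class{SupportResult} whose
#'   overlap gene lists go into the JSON
#' @param moduleLabels optional named character vector mapping module ids to
#'   disease labels for the TSV row names
#' @param metadata optional named list copied verbatim into the JSON
#' @return invisibly, the paths of the two files written
#' @export
writeReport <- function(scores, nulls = list(), dir,
                        supportResults = list(), moduleLabels = NULL,
                        metadata = list()) {
  if (length(scores) == 0L) stop("scores must be non-empty")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create output directory: %s", dir))

  first <- scores[[1]]
  sideIds <- first@sideModuleIds
  for (sc in scores)
    if (!identical(sc@sideModuleIds, sideIds))
      stop("all scores must share the same side-module ordering")

  labelOf <- function(id) {
    if (!is.null(moduleLabels) && id %in% names(moduleLabels))
      sprintf("Drugs (%s)", moduleLabels[[id]])
    else sprintf("Drugs (%s)", id)
  }
  mainLabel <- labelOf(first@mainModuleId)

  mat <- vapply(scores, function(sc) c(sc@mainSupport, sc@sideSupports,
                                       sc@weightedAverage),
                numeric(2L + length(sideIds)))
  mat <- matrix(mat, ncol = length(scores))
  tsv <- data.frame(
    module = c(mainLabel, vapply(sideIds, labelOf, ""),
               "Support (weighted avg.)"),
    apply(mat, 2, .fmt2),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  colnames(tsv) <- c("module", vapply(scores, function(sc) sc@formulaId, ""))

  # internal consistency: the printed weighted-average row must equal the
  # aggregation of the support rows directly above it
  for (j in seq_along(scores)) {
    sc <- scores[[j]]
    recomputed <- sum(sc@weights * c(sc@mainSupport, sc@sideSupports))
    stopifnot(abs(recomputed - sc@weightedAverage) < 1e-12)
  }

  tsvPath <- file.path(dir, "report.tsv")
  utils::write.table(tsv, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  payload <- list(
    scores = lapply(scores, .scoreToList),
    overlaps = lapply(supportResults, function(sr) list(
      formula_id = sr@formulaId, module_id = sr@drugId,
      drug_space_size = sr@drugSpaceSize,
      formula_space_size = sr@formulaSpaceSize,
      support = sr@support,
      overlap_genes = as.list(sr@overlapGenes)
    )),
    nulls = lapply(nulls, .nullToList),
    metadata = metadata
  )
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(c(tsv = tsvPath, json = jsonPath))
}

#' Read a report back into score objects
#'
#' Reconstructs the \linkS4class{WeightedScore} list from a
#' \code{report.json} written by \code{\link{writeReport}}. Because the JSON
#' stores full-precision values, the round trip is exact.
#'
#' @param path path to \code{report.json} (or the directory containing it)
#' @return list with elements \code{scores} (list of WeightedScore) and
#'   \code{raw} (the parsed JSON)
#' @export
readReport <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  scores <- lapply(raw$scores, function(s) {
    new("WeightedScore",
        formulaId = s$formula_id,
        mainModuleId = s$main_module_id,
        mainSupport = as.numeric(s$main_support),
        sideModuleIds = vapply(s$side_module_ids, as.character, ""),
        sideSupports = vapply(s$side_supports, as.numeric, 0),
        weights = vapply(s$weights, as.numeric, 0),
        weightedAverage = as.numeric(s$weighted_average))
  })
  list(scores = scores, raw = raw)
}
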