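# Shared fixture builders. All fixtures are generated in code at test time.

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a TargetSpace without going through the builders
mkSpace <- function(genes, id = "x", kind = "drug_module",
                    tags = character()) {
  new("TargetSpace", ownerId = id, ownerKind = kind,
      genes = sort(unique(genes)), filtersApplied = tags)
}

mkAdmet <- function(compound_id, ames = "non-toxic", carcinogenicity = "safe",
                    herg = "non-inhibitor") {
  n <- length(compound_id)
  new("AdmetTable", annotations = data.frame(
    compound_id = compound_id,
    ames = rep_len(ames, n),
    carcinogenicity = rep_len(carcinogenicity, n),
    herg = rep_len(herg, n),
    stringsAsFactors = FALSE))
}

# small fully deterministic formula -> herb -> compound -> target tables
mkFormulaTables <- function(compoundTargets,
                            herbs = list(herbA = names(compoundTargets)),
                            formulaId = "F1") {
  fh <- associationTable(rep(formulaId, length(herbs)), names(herbs),
                         "formula_herb")
  hc <- associationTable(rep(names(herbs), lengths(herbs)),
                         unlist(herbs, use.names = FALSE), "herb_compound")
  ct <- associationTable(rep(names(compoundTargets), lengths(compoundTargets)),
                         unlist(compoundTargets, use.names = FALSE),
                         "compound_target")
  list(fh = fh, hc = hc, ct = ct)
}

# small synthetic bundle for pipeline tests
smallConfig <- function(...) {
  args <- list(universeSize = 400, nFormulas = 2, herbsPerFormula = c(3, 5),
               compoundsPerHerb = c(4, 8), formulaSpaceSize = 50,
               moduleSizes = c(40, 24), plantedOverlaps = c(20, 6),
               toxicFraction = 0, cypFraction = 0, seed = 11)
  args[names(list(...))] <- list(...)
  do.call(syntheticConfig, args)
}
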