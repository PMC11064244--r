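#' Construct an ADMET filter rule set
#'
#' Three independent exclusion rules triage potentially toxic herbal
#' ingredients before any target space is built: AMES mutagenicity predicted
#' \code{toxic}, carcinogenicity predicted \code{danger}, and hERG inhibition
#' predicted \code{inhibitor} or \code{strong inhibitor}. Each rule can be
#' switched off independently. Compounds with no annotation row are kept by
#' default — the filter acts only on positive toxicity predictions, and
#' absence of a prediction is not evidence of toxicity; set
#' \code{unknownPolicy = "drop"} for a conservative run.
#'
#' @param excludeAmes,excludeCarcinogenicity,excludeHerg logical flags
#' @param unknownPolicy \code{"keep"} (default) or \code{"drop"}
#' @return a \linkS4class{FilterRuleSet}
#' @export
admetRules <- function(excludeAmes = TRUE, excludeCarcinogenicity = TRUE,
                       excludeHerg = TRUE, unknownPolicy = c("keep", "drop")) {
  new("FilterRuleSet",
      excludeAmes = isTRUE(excludeAmes),
      excludeCarcinogenicity = isTRUE(excludeCarcinogenicity),
      excludeHerg = isTRUE(excludeHerg),
      unknownPolicy = match.arg(unknownPolicy))
}

#' Apply the ADMET exclusion rules to a compound set
#'
#' Partitions \code{compounds} into kept and excluded ids. A compound is
#' excluded iff at least one active rule fires on its annotation; every rule
#' it triggers is recorded (not just the first), so the exclusion log is a
#' complete audit trail. Compounds without an annotation row follow
#' \code{unknownPolicy} with a warning.
#'
#' @param compounds character vector of compound ids (non-empty)
#' @param admet an \linkS4class{AdmetTable}
#' @param rules a \linkS4class{FilterRuleSet} from \code{\link{admetRules}}
#' @return list with \code{kept} (character vector) and \code{excluded}
#'   (data.frame with columns \code{compound_id}, \code{rule}; one row per
#'   triggered rule)
#' @examples
#' adm <- new("AdmetTable", annotations = data.frame(
#'   compound_id = c("c1", "c2"),
#'   ames = c("toxic", "non-toxic"),
#'   carcinogenicity = c("safe", "safe"),
#'   herg = c("non-inhibitor", "non-inhibitor")))
#' applyAdmetFilter(c("c1", "c2"), adm, admetRules())
#' @export
applyAdmetFilter <- function(compounds, admet, rules = admetRules()) {
  stopifnot(is(admet, "AdmetTable"), is(rules, "FilterRuleSet"))
  compounds <- unique(as.character(compounds))
  if (length(compounds) == 0L) stop("compounds must be non-empty")
  ann <- admet@annotations
  idx <- match(compounds, ann$compound_id)

  unannotated <- compounds[is.na(idx)]
  if (length(unannotated))
    warning(sprintf("%d compound(s) without ADMET annotation (%s policy): %s",
                    length(unannotated), rules@unknownPolicy,
                    paste(utils::head(unannotated, 5), collapse = ", ")))

  hits <- vector("list", length(compounds))
  for (i in seq_along(compounds)) {
    if (is.na(idx[i])) {
      if (rules@unknownPolicy == "drop") hits[[i]] <- "unannotated"
      next
    }
    row <- ann[idx[i], ]
    fired <- character()
    if (rules@excludeAmes && row$ames == "toxic")
      fired <- c(fired, "AMES")
    if (rules@excludeCarcinogenicity && row$carcinogenicity == "danger")
      fired <- c(fired, "Carcinogenicity")
    if (rules@excludeHerg && row$herg %in% c("inhibitor", "strong inhibitor"))
      fired <- c(fired, "hERG")
    if (length(fired)) hits[[i]] <- fired
  }

  dropped <- lengths(hits) > 0L
  excluded <- data.frame(
    compound_id = rep(compounds[dropped], lengths(hits)[dropped]),
    rule = unlist(hits[dropped], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(excluded) == 0L)
    excluded <- data.frame(compound_id = character(), rule = character(),
                           stringsAsFactors = FALSE)
  list(kept = compounds[!dropped], excluded = excluded)
}
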