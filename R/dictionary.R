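
#' Drug dictionary for the five TNF-alpha inhibitors
#'
#' Maps verbatim FAERS drug-name strings to the five study agents. Each
#' agent carries its generic name, brand synonyms and an approval quarter;
#' reports received before the approval quarter are excluded during
#' curation (relevant for golimumab and certolizumab, approved after the
#' 2004 start of the study window).
#'
#' The default synonym sets cover the generic names and the brand names
#' marketed in the US (Remicade; Enbrel, Erelzi; Humira, Amjevita,
#' Cyltezo; Simponi; Cimzia). Synonyms are matched after normalisation
#' (uppercase, punctuation stripped) as whole token sequences, so
#' \code{"REMICADE 100MG"} matches but \code{"REMICADEX"} does not.
#'
#' @param extra named list agent -> extra synonyms to append.
#' @return a \code{drug_dictionary}: named list with one element per agent,
#'   each a list of \code{synonyms} and \code{approval_quarter}.
#' @export
default_drug_dictionary <- function(extra = NULL) {
  dict <- list(
    infliximab = list(
      synonyms = c("INFLIXIMAB", "REMICADE"),
      approval_quarter = "1998Q3"),
    etanercept = list(
      synonyms = c("ETANERCEPT", "ENBREL", "ERELZI"),
      approval_quarter = "1998Q4"),
    adalimumab = list(
      synonyms = c("ADALIMUMAB", "HUMIRA", "AMJEVITA", "MJEVITA", "CYLTEZO"),
      approval_quarter = "2002Q4"),
    golimumab = list(
      synonyms = c("GOLIMUMAB", "SIMPONI"),
      approval_quarter = "2009Q1"),
    certolizumab = list(
      synonyms = c("CERTOLIZUMAB", "CERTOLIZUMAB PEGOL", "CIMZIA"),
      approval_quarter = "2008Q1")
  )
  if (!is.null(extra)) {
    for (ag in names(extra)) {
      dict[[ag]]$synonyms <- unique(c(dict[[ag]]$synonyms,
                                      toupper(extra[[ag]])))
    }
  }
  validate_dictionary(dict)
}

validate_dictionary <- function(dict) {
  syn <- lapply(dict, function(d) normalize_drugname(d$synonyms))
  all_syn <- unlist(syn, use.names = FALSE)
  if (anyDuplicated(all_syn)) {
    stop("drug dictionary synonym sets overlap after normalisation: ",
         paste(unique(all_syn[duplicated(all_syn)]), collapse = ", "))
  }
  for (ag in names(dict)) {
    dict[[ag]]$synonyms <- syn[[ag]]
    stopifnot(grepl("^[0-9]{4}Q[1-4]$", dict[[ag]]$approval_quarter))
  }
  structure(dict, class = "drug_dictionary")
}

#' Load a drug dictionary from YAML
#'
#' Expected shape: a top-level map agent -> \{synonyms: [..],
#' approval_quarter: "YYYYQn"\}.
#'
#' @param path YAML file path.
#' @return a \code{drug_dictionary}.
#' @export
read_drug_dictionary <- function(path) {
  validate_dictionary(yaml::read_yaml(path))
}

#' Map verbatim drug names to study agents
#'
#' Normalises each name (uppercase, punctuation to spaces) and looks for
#' any dictionary synonym occurring as a whole token sequence. Names
#' matching synonyms of more than one agent are ambiguous and map to
#' \code{NA} (logged by the caller).
#'
#' @param drugname character vector of verbatim names.
#' @param dictionary a \code{drug_dictionary}.
#' @return character vector of agent names, \code{NA} where unmatched or
#'   ambiguous; attribute \code{"ambiguous"} lists ambiguous inputs.
#' @export
#' @examples
#' map_drug(c("HUMIRA", "Remicade 100mg", "aspirin"))
map_drug <- function(drugname, dictionary = default_drug_dictionary()) {
  uniq <- unique(as.character(drugname))
  norm <- normalize_drugname(uniq)
  agents <- names(dictionary)
  hits <- matrix(FALSE, length(uniq), length(agents),
                 dimnames = list(NULL, agents))
  for (ag in agents) {
    for (syn in dictionary[[ag]]$synonyms) {
      pat <- paste0("(^| )", syn, "( |$)")
      hits[, ag] <- hits[, ag] | grepl(pat, norm)
    }
  }
  nhit <- rowSums(hits)
  res <- rep(NA_character_, length(uniq))
  one <- nhit == 1L
  if (any(one)) res[one] <- agents[apply(hits[one, , drop = FALSE], 1L, which)]
  ambiguous <- uniq[nhit > 1L]
  out <- res[match(as.character(drugname), uniq)]
  attr(out, "ambiguous") <- ambiguous
  out
}
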