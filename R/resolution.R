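#' Build a chemical name dictionary
#'
#' Maps normalised (case-folded, single-spaced) chemical names to lists of
#' \code{\link{chemical_structure}} records.
#'
#' @param names Character vector of chemical names.
#' @param structures List (same length) of \code{chemical_structure} objects
#'   or lists thereof; repeated names accumulate structures.
#' @param name_tag Dictionary name tag.
#' @return An object of class \code{"chem_name_dict"}.
#' @export
chem_name_dict <- function(names, structures, name_tag = "dict") {
  stopifnot(length(names) == length(structures), length(names) > 0)
  tab <- list()
  for (i in seq_along(names)) {
    key <- normalise_term(names[i])
    s <- structures[[i]]
    if (inherits(s, "chem_structure")) s <- list(s)
    tab[[key]] <- c(tab[[key]], s)
  }
  structure(list(table = tab, name = name_tag), class = "chem_name_dict")
}

#' Read a chemical name dictionary from TSV
#'
#' Format: \code{name<TAB>format<TAB>value} with formats SMILES, InChI or
#' CML; repeated name lines accumulate structures in file order. No header.
#'
#' @param path Path to the TSV file.
#' @param name_tag Dictionary name tag (defaults to the file name).
#' @return A \code{"chem_name_dict"}.
#' @export
read_chem_name_dict <- function(path, name_tag = basename(path)) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8",
                          col.names = c("name", "format", "value"))
  chem_name_dict(df$name,
                 lapply(seq_len(nrow(df)), function(i)
                   chemical_structure(df$format[i], df$value[i])),
                 name_tag)
}

#' Build a dictionary registry
#'
#' An ordered list of name dictionaries — order defines lookup precedence —
#' plus an optional fallback resolver invoked only when every dictionary
#' misses (the hook point for an external systematic-nomenclature parser).
#'
#' @param dicts List of \code{\link{chem_name_dict}} objects.
#' @param fallback \code{NULL} or \code{function(name)} returning a list of
#'   \code{chemical_structure}s (possibly empty).
#' @return An object of class \code{"dictionary_registry"}.
#' @export
dictionary_registry <- function(dicts = list(), fallback = NULL) {
  stopifnot(all(vapply(dicts, inherits, logical(1), "chem_name_dict")),
            is.null(fallback) || is.function(fallback))
  structure(list(dicts = dicts, fallback = fallback),
            class = "dictionary_registry")
}

#' Resolve a chemical entity to structures
#'
#' Looks up the normalised entity surface in every dictionary in registry
#' order, concatenates the structure lists in that order and removes
#' duplicates (same format and value). When every dictionary misses, the
#' fallback hook (if configured) is consulted. Returns \code{NULL} when no
#' source yields a structure.
#'
#' @param entity A CM \code{\link{named_entity}}.
#' @param registry A \code{\link{dictionary_registry}}.
#' @return A \code{\link{resolved_named_entity}} or \code{NULL}.
#' @export
resolve_entity <- function(entity, registry) {
  stopifnot(identical(entity$type, "CM"),
            inherits(registry, "dictionary_registry"))
  key <- normalise_term(entity$surface)
  structures <- list()
  for (d in registry$dicts) {
    hit <- d$table[[key]]
    if (!is.null(hit)) structures <- c(structures, hit)
  }
  if (!length(structures) && !is.null(registry$fallback)) {
    structures <- registry$fallback(key)
  }
  if (!length(structures)) return(NULL)
  seen <- character()
  kept <- list()
  for (s in structures) {
    id <- paste0(s$format, "\r", s$value)
    if (!id %in% seen) {
      seen <- c(seen, id)
      kept[[length(kept) + 1L]] <- s
    }
  }
  resolved_named_entity(entity, kept)
}

#' First structure of a given format
#'
#' Returns the first structure in stored order whose format matches, or
#' \code{NULL} if none does.
#'
#' @param r A \code{\link{resolved_named_entity}}.
#' @param format \code{"SMILES"}, \code{"INCHI"} or \code{"CML"}.
#' @return A \code{\link{chemical_structure}} or \code{NULL}.
#' @export
get_first_structure <- function(r, format) {
  format <- match.arg(toupper(format), STRUCTURE_FORMATS)
  for (s in r$structures) if (s$format == format) return(s)
  NULL
}
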