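# Registry of trGTPase subfamilies: load/validate/query/write.

#' Path to the packaged trGTPase registry
#'
#' @return Path to the JSON registry file shipped with the package.
#' @export
packagedRegistryPath <- function() {
  system.file("extdata", "trg_registry.json", package = "trgpipe",
              mustWork = TRUE)
}

.validateRegistryRecords <- function(rec) {
  msg <- character()
  if (nrow(rec) == 0L) return("registry has no records")
  dup <- rec$name[duplicated(rec$name)]
  if (length(dup))
    msg <- c(msg, paste("duplicate record name(s):",
                        paste(unique(dup), collapse = ", ")))
  syn <- unlist(rec$synonyms, use.names = FALSE)
  clash <- intersect(syn, rec$name)
  if (length(clash))
    msg <- c(msg, paste("synonym(s) colliding with record names:",
                        paste(clash, collapse = ", ")))
  dupsyn <- syn[duplicated(syn)]
  if (length(dupsyn))
    msg <- c(msg, paste("synonym(s) assigned to multiple records:",
                        paste(unique(dupsyn), collapse = ", ")))
  badDom <- !rec$domain_of_life %in% REGISTRY_DOMAINS
  if (any(badDom))
    msg <- c(msg, paste("unknown domain_of_life for record(s):",
                        paste(rec$name[badDom], collapse = ", ")))
  badComp <- !rec$compartment %in% REGISTRY_COMPARTMENTS
  if (any(badComp))
    msg <- c(msg, paste("unknown compartment for record(s):",
                        paste(rec$name[badComp], collapse = ", ")))
  badFam <- !rec$family %in% REGISTRY_FAMILIES
  if (any(badFam))
    msg <- c(msg, paste("unknown family for record(s):",
                        paste(rec$name[badFam], collapse = ", ")))
  badMid <- rec$family == "EF1S" &
    (is.na(rec$midfamily) | !rec$midfamily %in% REGISTRY_MIDFAMILIES)
  if (any(badMid))
    msg <- c(msg, paste("EF1S record(s) without a valid midfamily:",
                        paste(rec$name[badMid], collapse = ", ")))
  badNode <- !rec$origin_node %in% REGISTRY_NODES
  if (any(badNode))
    msg <- c(msg, paste("unknown origin_node for record(s):",
                        paste(rec$name[badNode], collapse = ", ")))
  badOrg <- rec$organellar != (rec$compartment != "cytoplasmic")
  if (any(badOrg))
    msg <- c(msg, paste("organellar flag inconsistent with compartment:",
                        paste(rec$name[badOrg], collapse = ", ")))
  hasEq <- !is.na(rec$bacterial_equivalent)
  if (any(hasEq & !rec$organellar))
    msg <- c(msg, paste("bacterial_equivalent on non-organellar record(s):",
                        paste(rec$name[hasEq & !rec$organellar],
                              collapse = ", ")))
  dangling <- hasEq & !rec$bacterial_equivalent %in% rec$name
  if (any(dangling))
    msg <- c(msg, paste("dangling bacterial_equivalent in record(s):",
                        paste(rec$name[dangling], collapse = ", ")))
  eqOK <- hasEq & rec$bacterial_equivalent %in% rec$name
  if (any(eqOK)) {
    eqDom <- rec$domain_of_life[match(rec$bacterial_equivalent[eqOK],
                                      rec$name)]
    if (any(eqDom != "bacteria"))
      msg <- c(msg, paste("bacterial_equivalent not bacterial for:",
                          paste(rec$name[eqOK][eqDom != "bacteria"],
                                collapse = ", ")))
  }
  hasVar <- !is.na(rec$variant_of)
  if (any(hasVar & !rec$variant_of %in% rec$name))
    msg <- c(msg, paste("dangling variant_of in record(s):",
                        paste(rec$name[hasVar & !rec$variant_of %in%
                                         rec$name], collapse = ", ")))
  badTok <- vapply(rec$architecture,
                   function(a) any(!a %in% ARCHITECTURE_TOKENS), logical(1))
  if (any(badTok))
    msg <- c(msg, paste("unknown architecture token(s) in record(s):",
                        paste(rec$name[badTok], collapse = ", ")))
  msg
}

.validateRegistryExtras <- function(object) {
  msg <- character()
  if (length(object@timeline)) {
    empty <- vapply(object@timeline, function(x) length(x) == 0L,
                    logical(1))
    if (any(empty))
      msg <- c(msg, paste("empty timeline complement at node(s):",
                          paste(names(object@timeline)[empty],
                                collapse = ", ")))
  }
  for (dom in names(object@minimal)) {
    if (!dom %in% REGISTRY_DOMAINS) {
      msg <- c(msg, paste("minimal composition for unknown domain:", dom))
      next
    }
    members <- object@minimal[[dom]]
    rec <- object@records
    known <- members %in% rec$name
    if (any(!known)) {
      msg <- c(msg, paste("minimal composition of", dom,
                          "names unknown record(s):",
                          paste(members[!known], collapse = ", ")))
    } else {
      mdom <- rec$domain_of_life[match(members, rec$name)]
      if (any(mdom != dom))
        msg <- c(msg, paste("minimal composition of", dom,
                            "contains record(s) of another domain:",
                            paste(members[mdom != dom], collapse = ", ")))
    }
  }
  msg
}

.recordsFromList <- function(lst) {
  asChr1 <- function(x) if (is.null(x) || length(x) == 0L)
    NA_character_ else as.character(x)[1]
  S4Vectors::DataFrame(
    name = vapply(lst, function(r) asChr1(r$name), character(1)),
    family = vapply(lst, function(r) asChr1(r$family), character(1)),
    midfamily = vapply(lst, function(r) asChr1(r$midfamily), character(1)),
    domain_of_life = vapply(lst, function(r) asChr1(r$domain_of_life),
                            character(1)),
    compartment = vapply(lst, function(r) asChr1(r$compartment),
                         character(1)),
    organellar = vapply(lst, function(r) asChr1(r$compartment),
                        character(1)) != "cytoplasmic",
    synonyms = I(lapply(lst, function(r)
      as.character(unlist(r$synonyms)))),
    origin_node = vapply(lst, function(r) asChr1(r$origin_node),
                         character(1)),
    architecture = I(lapply(lst, function(r)
      as.character(unlist(r$architecture)))),
    bacterial_equivalent = vapply(lst, function(r)
      asChr1(r$bacterial_equivalent), character(1)),
    variant_of = vapply(lst, function(r) asChr1(r$variant_of),
                        character(1)),
    flags = I(lapply(lst, function(r) as.character(unlist(r$flags)))),
    note = vapply(lst, function(r) asChr1(r$note), character(1)))
}

#' Load a trGTPase registry file
#'
#' Reads a registry JSON file (see \code{packagedRegistryPath()} for the
#' packaged one), builds a \linkS4class{TrgRegistry} and runs the full set
#' of structural validations: unique names, synonym collisions, enum
#' membership, organellar/compartment consistency, resolvable
#' \code{bacterial_equivalent} references pointing at bacterial records,
#' non-empty timeline complements and minimal compositions naming records
#' of the matching domain. A violation raises an error listing the
#' offending records.
#'
#' @param path Path to a registry JSON file; defaults to the packaged
#'   registry.
#' @return A validated \linkS4class{TrgRegistry}.
#' @examples
#' reg <- loadRegistry()
#' nRecords(reg)
#' @export
loadRegistry <- function(path = packagedRegistryPath()) {
  if (!file.exists(path)) stop("registry file does not exist: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$subfamilies)) stop("registry file has no subfamilies")
  rec <- .recordsFromList(raw$subfamilies)
  timeline <- stats::setNames(
    lapply(raw$timeline, function(n) as.character(unlist(n$lineages))),
    vapply(raw$timeline, function(n) n$node, character(1)))
  minimal <- stats::setNames(
    lapply(raw$minimal_compositions,
           function(m) as.character(unlist(m$subfamily_names))),
    vapply(raw$minimal_compositions, function(m) m$domain_of_life,
           character(1)))
  methods::new("TrgRegistry", records = rec, timeline = timeline,
               minimal = minimal,
               metadata = if (is.null(raw$metadata)) list()
                          else raw$metadata)
}

#' Write a registry to JSON (and optionally TSV)
#'
#' The JSON output round-trips losslessly through \code{loadRegistry}.
#' The TSV export has one row per record; list-valued fields are
#' semicolon-joined.
#'
#' @param registry A \linkS4class{TrgRegistry}.
#' @param path Output JSON path.
#' @param tsv Optional output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeRegistry <- function(registry, path, tsv = NULL) {
  stopifnot(methods::is(registry, "TrgRegistry"))
  rec <- registry@records
  subfam <- lapply(seq_len(nrow(rec)), function(i) {
    list(name = rec$name[i], family = rec$family[i],
         midfamily = if (is.na(rec$midfamily[i])) NULL
                     else rec$midfamily[i],
         domain_of_life = rec$domain_of_life[i],
         compartment = rec$compartment[i],
         synonyms = as.list(rec$synonyms[[i]]),
         origin_node = rec$origin_node[i],
         architecture = as.list(rec$architecture[[i]]),
         bacterial_equivalent = if (is.na(rec$bacterial_equivalent[i]))
           NULL else rec$bacterial_equivalent[i],
         variant_of = if (is.na(rec$variant_of[i])) NULL
                      else rec$variant_of[i],
         flags = as.list(rec$flags[[i]]),
         note = if (is.na(rec$note[i])) "" else rec$note[i])
  })
  out <- list(
    format = "trgpipe-registry/1",
    metadata = registry@metadata,
    subfamilies = subfam,
    timeline = lapply(names(registry@timeline), function(n)
      list(node = n, lineages = as.list(registry@timeline[[n]]))),
    minimal_compositions = lapply(names(registry@minimal), function(d)
      list(domain_of_life = d,
           subfamily_names = as.list(registry@minimal[[d]]))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  if (!is.null(tsv)) {
    df <- data.frame(
      name = rec$name, family = rec$family, midfamily = rec$midfamily,
      domain_of_life = rec$domain_of_life, compartment = rec$compartment,
      organellar = rec$organellar,
      synonyms = vapply(rec$synonyms, paste, character(1),
                        collapse = ";"),
      origin_node = rec$origin_node,
      architecture = vapply(rec$architecture, paste, character(1),
                            collapse = ";"),
      bacterial_equivalent = rec$bacterial_equivalent,
      variant_of = rec$variant_of,
      flags = vapply(rec$flags, paste, character(1), collapse = ";"),
      note = rec$note, stringsAsFactors = FALSE)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Count subfamilies satisfying attribute filters
#'
#' Filters are named values matched (conjunctively) against record
#' columns, e.g. \code{domain_of_life = "archaea"},
#' \code{organellar = TRUE}, \code{family = "EF2"},
#' \code{compartment = "plastid"}, \code{midfamily = "SelB"}.
#'
#' By default records flagged as variants of another subfamily
#' (\code{variant_of} set; only lEFG, the probable spdEFG2 orthologue in
#' Leptospira) are not counted as distinct classification units, which
#' reproduces the printed per-domain subfamily counts; set
#' \code{countVariants = TRUE} to count every record.
#'
#' @param registry A \linkS4class{TrgRegistry}.
#' @param ... Named attribute filters.
#' @param countVariants Count variant-flagged records too?
#' @return Integer count.
#' @examples
#' reg <- loadRegistry()
#' countSubfamilies(reg, domain_of_life = "archaea")
#' countSubfamilies(reg, organellar = TRUE)
#' @export
countSubfamilies <- function(registry, ..., countVariants = FALSE) {
  stopifnot(methods::is(registry, "TrgRegistry"))
  rec <- registry@records
  filters <- list(...)
  keep <- rep(TRUE, nrow(rec))
  if (!countVariants) keep <- keep & is.na(rec$variant_of)
  for (attr in names(filters)) {
    if (!attr %in% colnames(rec))
      stop("unknown attribute in filter: ", attr)
    keep <- keep & !is.na(rec[[attr]]) & rec[[attr]] == filters[[attr]]
  }
  sum(keep)
}

#' Ancestral trGTPase complement at a timeline node
#'
#' @param registry A \linkS4class{TrgRegistry}.
#' @param node Timeline node id, one of LUCA, bLCA, a+eLCA, aLCA, eLCA.
#' @return Character vector of ancestral lineage names.
#' @examples
#' ancestralComplement(loadRegistry(), "a+eLCA")
#' @export
ancestralComplement <- function(registry, node) {
  stopifnot(methods::is(registry, "TrgRegistry"))
  if (!node %in% names(registry@timeline))
    stop("unknown timeline node: ", node, " (known: ",
         paste(names(registry@timeline), collapse = ", "), ")")
  registry@timeline[[node]]
}

#' Cytoplasmic trGTPase lineages added on the eukaryote stem
#'
#' Lineages present in the eukaryotic ancestor's complement but not in
#' the archaea+eukaryote ancestor's: the factors gained between the two
#' nodes.
#'
#' @param registry A \linkS4class{TrgRegistry}.
#' @return Character vector of lineage names.
#' @export
eukaryoteStemAdditions <- function(registry) {
  setdiff(ancestralComplement(registry, "eLCA"),
          ancestralComplement(registry, "a+eLCA"))
}

#' Minimal trGTPase repertoire for a domain of life
#'
#' @param registry A \linkS4class{TrgRegistry}.
#' @param domain_of_life One of bacteria, archaea, eukaryote.
#' @return Character vector of subfamily names.
#' @export
minimalComposition <- function(registry, domain_of_life) {
  stopifnot(methods::is(registry, "TrgRegistry"))
  if (!domain_of_life %in% names(registry@minimal))
    stop("no minimal composition recorded for domain: ", domain_of_life)
  registry@minimal[[domain_of_life]]
}

#' Resolve a subfamily name or synonym to its canonical name
#'
#' @param registry A \linkS4class{TrgRegistry}.
#' @param name A canonical name or synonym.
#' @return The canonical subfamily name, or NA_character_ if the name
#'   matches neither a record nor a synonym (no-match is a value, not an
#'   error).
#' @examples
#' resolveSynonym(loadRegistry(), "EF4")
#' @export
resolveSynonym <- function(registry, name) {
  stopifnot(methods::is(registry, "TrgRegistry"))
  rec <- registry@records
  if (name %in% rec$name) return(name)
  hit <- which(vapply(rec$synonyms, function(s) name %in% s, logical(1)))
  if (length(hit)) rec$name[hit[1]] else NA_character_
}
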