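#' Normalize a gene or protein identifier
#'
#' Deterministic, conservative normalization used throughout the package:
#' strip a leading database prefix (text up to the first `:` when present),
#' strip surrounding whitespace and parenthetical annotations, and case-fold
#' to upper case. No cross-namespace mapping is attempted; choosing a
#' consistent identifier type across database and gene list is the user's
#' responsibility.
#'
#' @param raw character vector of raw identifiers.
#' @return character vector of normalized identifiers.
#' @examples
#' normalizeId("uniprotkb:p04637")   # "P04637"
#' normalizeId(" ensembl:ENSG00000115415 ")
#' normalizeId("STAT1")
#' @export
normalizeId <- function(raw) {
  if (!is.character(raw) || length(raw) == 0L)
    stop("unusable identifier: input must be a non-empty character vector")
  x <- trimws(raw)
  has_prefix <- grepl(":", x, fixed = TRUE)
  x[has_prefix] <- sub("^[^:]*:", "", x[has_prefix])
  x <- gsub("\\([^()]*\\)", "", x)
  x <- toupper(trimws(x))
  if (any(!nzchar(x)))
    stop("unusable identifier: '", raw[which(!nzchar(x))[1L]],
         "' is empty after normalization")
  x
}

#' Construct filter criteria
#'
#' @param species optional NCBI taxon id (string); when set, BOTH interactors
#'   of a record must carry this taxon for the record to qualify. Records with
#'   an empty taxon field fail a set species filter.
#' @param interactionTypes optional character vector of interaction-type
#'   terms. A term of the form `"MI:dddd"` is matched exactly against the
#'   PSI-MI identifier in the record's type field; any other term is matched
#'   as a case-insensitive substring of the type label.
#' @param idNamespace optional identifier prefix (e.g. `"uniprotkb"`); records
#'   whose identifiers do not carry this prefix are dropped and counted.
#' @return a [FilterCriteria-class] object.
#' @examples
#' filterCriteria(species = "9606", interactionTypes = "MI:0915")
#' @export
filterCriteria <- function(species = NULL, interactionTypes = NULL,
                           idNamespace = NULL) {
  new("FilterCriteria",
      species = as.character(species %||% character(0)),
      interactionTypes = as.character(interactionTypes %||% character(0)),
      idNamespace = as.character(idNamespace %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip "taxid:" prefix and parenthetical annotation from a MITAB taxon field;
# "-" and "" both mean unknown
.cleanTaxid <- function(x) {
  x <- trimws(x)
  x[x == "-"] <- ""
  x <- sub("^taxid:", "", x, ignore.case = TRUE)
  x <- gsub("\\([^()]*\\)", "", x)
  trimws(x)
}

.readSource <- function(stream) {
  if (inherits(stream, "connection")) readLines(stream, warn = FALSE)
  else if (is.character(stream) && length(stream) == 1L && file.exists(stream))
    readLines(stream, warn = FALSE)
  else if (is.character(stream)) stream
  else stop("unsupported input: expected a file path, connection or lines")
}

#' Parse PSI-MITAB interaction records
#'
#' Reads the 15 core tab-separated columns of PSI-MITAB 2.5 (later versions
#' append columns and parse identically). Unique interactor identifiers are
#' taken from columns 1-2, taxon ids from columns 10-11 (with `taxid:` prefix
#' and parenthetical species name stripped), and the interaction type from
#' column 12. Lines starting with `#` are treated as headers/comments. Lines
#' with fewer than 15 columns, or with an absent (`-`) interactor identifier,
#' are skipped and counted in the `nMalformed` attribute rather than being
#' fatal.
#'
#' @param stream a file path, a connection, or a character vector of lines.
#' @param criteria a [FilterCriteria-class]; retained for interface symmetry
#'   (filtering happens in [buildInteractionDb()]).
#' @return data.frame of interaction records with columns `id_a`, `id_b`,
#'   `taxid_a`, `taxid_b`, `interaction_type`, `source_line`, and attribute
#'   `nMalformed`.
#' @seealso [parseEdgeList()], [buildInteractionDb()]
#' @export
parseMitab <- function(stream, criteria = filterCriteria()) {
  lines <- .readSource(stream)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("empty database: no data lines found")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 15L
  if (any(ok)) {
    ida <- vapply(fields[ok], `[[`, character(1), 1L)
    idb <- vapply(fields[ok], `[[`, character(1), 2L)
    bad_id <- trimws(ida) %in% c("", "-") | trimws(idb) %in% c("", "-")
    ok[which(ok)[bad_id]] <- FALSE
  }
  nMalformed <- sum(!ok)
  if (!any(ok))
    stop("empty database: zero parseable MITAB lines (",
         nMalformed, " malformed)")
  f <- fields[ok]
  records <- data.frame(
    id_a = vapply(f, `[[`, character(1), 1L),
    id_b = vapply(f, `[[`, character(1), 2L),
    taxid_a = .cleanTaxid(vapply(f, `[[`, character(1), 10L)),
    taxid_b = .cleanTaxid(vapply(f, `[[`, character(1), 11L)),
    interaction_type = vapply(f, `[[`, character(1), 12L),
    source_line = lineno[ok],
    stringsAsFactors = FALSE
  )
  attr(records, "nMalformed") <- nMalformed
  records
}

#' Parse a two-column edge-list TSV
#'
#' Zero-dependency fixture format: two tab-separated identifier columns, no
#' header required, `#` comment lines skipped. Taxon and interaction-type
#' fields of the returned records are empty, so species/type filters will
#' reject these records if set.
#'
#' @inheritParams parseMitab
#' @return data.frame of interaction records as in [parseMitab()].
#' @export
parseEdgeList <- function(stream, criteria = filterCriteria()) {
  lines <- .readSource(stream)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("empty database: no data lines found")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2L
  if (any(ok)) {
    ida <- vapply(fields[ok], `[[`, character(1), 1L)
    idb <- vapply(fields[ok], `[[`, character(1), 2L)
    bad <- !nzchar(trimws(ida)) | !nzchar(trimws(idb))
    ok[which(ok)[bad]] <- FALSE
  }
  nMalformed <- sum(!ok)
  if (!any(ok))
    stop("empty database: zero parseable edge-list lines")
  f <- fields[ok]
  records <- data.frame(
    id_a = vapply(f, `[[`, character(1), 1L),
    id_b = vapply(f, `[[`, character(1), 2L),
    taxid_a = "", taxid_b = "", interaction_type = "",
    source_line = lineno[ok],
    stringsAsFactors = FALSE
  )
  attr(records, "nMalformed") <- nMalformed
  records
}

#' Read an interaction database from a file
#'
#' Convenience wrapper: parse a PSI-MITAB or edge-list file and build the
#' filtered, deduplicated database in one step.
#'
#' @param path file path.
#' @param format `"mitab"` or `"edgelist"`.
#' @param criteria a [FilterCriteria-class].
#' @return an [InteractionDb-class].
#' @export
readInteractionDb <- function(path, format = c("edgelist", "mitab"),
                              criteria = filterCriteria()) {
  format <- match.arg(format)
  records <- switch(format,
    mitab = parseMitab(path, criteria),
    edgelist = parseEdgeList(path, criteria))
  buildInteractionDb(records, criteria)
}

# internal: does a record's type field match any requested type term?
.typeMatches <- function(typeField, terms) {
  mi <- regmatches(typeField, regexpr("MI:[0-9]{4}", typeField))
  vapply(terms, function(term) {
    if (grepl("^MI:[0-9]{4}$", term)) {
      length(mi) == 1L && identical(mi, term)
    } else {
      grepl(tolower(term), tolower(typeField), fixed = TRUE)
    }
  }, logical(1)) |> any()
}

# internal constructor from a raw two-column character matrix of pairs
.newInteractionDb <- function(pairs) {
  a <- pmin(pairs[, 1L], pairs[, 2L])
  b <- pmax(pairs[, 1L], pairs[, 2L])
  keep <- !duplicated(paste(a, b, sep = "\t"))
  a <- a[keep]; b <- b[keep]
  ord <- order(a, b, method = "radix")
  edges <- cbind(a[ord], b[ord])
  colnames(edges) <- c("id_a", "id_b")
  nodes <- sort(unique(c(edges)), method = "radix")
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    sort(unique(c(edges[edges[, 1L] == v, 2L],
                  edges[edges[, 2L] == v, 1L])), method = "radix")
  })
  new("InteractionDb", edges = edges, adjacency = adj)
}

#' Build the interaction database
#'
#' Applies the filter criteria (species on BOTH interactors, interaction type,
#' identifier namespace), normalizes identifiers, disregards self-interactions
#' and collapses duplicate evidence lines for a pair into one undirected edge.
#' The resulting node set is the statistical background of the contextual-hub
#' test.
#'
#' @param records data.frame of interaction records from [parseMitab()] or
#'   [parseEdgeList()].
#' @param criteria a [FilterCriteria-class].
#' @return an [InteractionDb-class].
#' @examples
#' rec <- data.frame(id_a = c("A", "B", "F"), id_b = c("B", "A", "F"),
#'                   taxid_a = "", taxid_b = "", interaction_type = "",
#'                   source_line = 1:3)
#' db <- buildInteractionDb(rec)   # duplicate and self-loop removed
#' nEdges(db)
#' @export
buildInteractionDb <- function(records, criteria = filterCriteria()) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("empty database: no interaction records supplied")
  keep <- rep(TRUE, nrow(records))
  if (length(criteria@idNamespace) == 1L) {
    ns <- tolower(criteria@idNamespace)
    pref_a <- tolower(sub(":.*$", "", records$id_a))
    pref_b <- tolower(sub(":.*$", "", records$id_b))
    drop_ns <- !(pref_a == ns & pref_b == ns &
                   grepl(":", records$id_a, fixed = TRUE) &
                   grepl(":", records$id_b, fixed = TRUE))
    if (any(drop_ns))
      message(sum(drop_ns & keep),
              " record(s) dropped: identifier namespace != '",
              criteria@idNamespace, "'")
    keep <- keep & !drop_ns
  }
  if (length(criteria@species) == 1L) {
    keep <- keep & records$taxid_a == criteria@species &
      records$taxid_b == criteria@species
  }
  if (length(criteria@interactionTypes) > 0L) {
    keep <- keep & vapply(records$interaction_type, .typeMatches,
                          logical(1), terms = criteria@interactionTypes)
  }
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L)
    stop("empty database after filtering: no record satisfies the criteria")
  a <- normalizeId(records$id_a)
  b <- normalizeId(records$id_b)
  non_self <- a != b
  if (!any(non_self))
    stop("empty database after filtering: only self-interactions remain")
  .newInteractionDb(cbind(a[non_self], b[non_self]))
}

#' Warn when a database is below the recommended size
#'
#' Interaction databases with fewer than 10,000 interactions give unstable
#' background frequencies K/N; public registries exclude them from querying.
#' Here small databases are allowed (test fixtures are tiny) but flagged.
#'
#' @param db an [InteractionDb-class].
#' @param threshold minimum number of interactions; default 10,000. The check
#'   is strict: exactly `threshold` edges does not warn.
#' @return logical: `TRUE` when the database has fewer edges than `threshold`.
#' @export
checkMinSize <- function(db, threshold = 10000L) {
  stopifnot(is(db, "InteractionDb"), threshold >= 0)
  nEdges(db) < threshold
}

#' Write a database as edge-list TSV
#'
#' Writes the deduplicated edges in stable lexicographic pair order (smaller
#' identifier first), suitable for provenance records and round-tripping
#' through [parseEdgeList()].
#'
#' @param db an [InteractionDb-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(db, path) {
  stopifnot(is(db, "InteractionDb"))
  e <- dbEdges(db)
  writeLines(paste(e[, 1L], e[, 2L], sep = "\t"), path)
  invisible(path)
}

#' @rdname backgroundSize
setMethod("backgroundSize", "InteractionDb", function(db) {
  length(db@adjacency)
})

#' @rdname db-accessors
setMethod("dbNodes", "InteractionDb", function(db) names(db@adjacency))

#' @rdname db-accessors
setMethod("dbEdges", "InteractionDb", function(db) db@edges)

#' @rdname db-accessors
setMethod("nEdges", "InteractionDb", function(db) nrow(db@edges))

#' @rdname db-accessors
setMethod("dbDegree", "InteractionDb", function(db, nodes) {
  if (missing(nodes)) nodes <- dbNodes(db)
  unknown <- setdiff(nodes, dbNodes(db))
  if (length(unknown) > 0L)
    stop("unknown node: '", unknown[1L], "' is not in the database")
  stats::setNames(lengths(db@adjacency[nodes]), nodes)
})

#' @rdname db-accessors
setMethod("interactorsOf", "InteractionDb", function(db, node) {
  stopifnot(length(node) == 1L)
  nb <- db@adjacency[[node]]
  if (is.null(nb))
    stop("unknown node: '", node, "' is not in the database")
  nb
})

#' @export
setMethod("show", "InteractionDb", function(object) {
  cat("InteractionDb with", backgroundSize(object), "nodes and",
      nEdges(object), "edges\n")
  deg <- lengths(object@adjacency)
  cat("  degree: median", stats::median(deg), ", max", max(deg), "\n")
})

#' @export
setMethod("show", "FilterCriteria", function(object) {
  fmt <- function(x) if (length(x) == 0L) "<unset>" else
    paste(x, collapse = ", ")
  cat("FilterCriteria\n",
      "  species:          ", fmt(object@species), "\n",
      "  interactionTypes: ", fmt(object@interactionTypes), "\n",
      "  idNamespace:      ", fmt(object@idNamespace), "\n", sep = "")
})
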