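#' Construct a contextual predicate
#'
#' Defines which genes in the uploaded table are contextually relevant, e.g.
#' `contextPredicate("logFC", "gt", 2)` for genes with a greater-than-2-fold
#' change. Numeric comparators (`gt`, `ge`, `lt`, `le`) require the attribute
#' to parse as a number; `eq` compares numerically when both sides parse and
#' as trimmed strings otherwise; `in` tests membership of the attribute value
#' in a set.
#'
#' @param attribute name of the attribute column the predicate reads.
#' @param comparator one of `"gt"`, `"ge"`, `"lt"`, `"le"`, `"eq"`, `"in"`.
#' @param value threshold (numeric comparators), value (`eq`) or value set
#'   (`in`).
#' @return a predicate specification list.
#' @export
contextPredicate <- function(attribute,
                             comparator = c("gt", "ge", "lt", "le",
                                            "eq", "in"),
                             value) {
  comparator <- match.arg(comparator)
  stopifnot(is.character(attribute), length(attribute) == 1L)
  if (comparator != "in" && length(value) != 1L)
    stop("comparator '", comparator, "' requires a single value")
  list(attribute = attribute, comparator = comparator, value = value)
}

# evaluate a predicate on the parsed table; returns a logical row mask
.evalPredicate <- function(table, predicate) {
  if (identical(predicate, "all") ||
      identical(predicate, list(all = TRUE)))
    return(rep(TRUE, nrow(table)))
  attribute <- predicate$attribute
  if (!(attribute %in% colnames(table)))
    stop("attribute not found: '", attribute,
         "' is not a column of the context table")
  vals <- trimws(as.character(table[[attribute]]))
  cmp <- predicate$comparator
  if (cmp %in% c("gt", "ge", "lt", "le")) {
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1L]
      stop("unparseable attribute value: row ", bad, " has '",
           vals[bad], "' under numeric comparator '", cmp, "'")
    }
    thr <- as.numeric(predicate$value)
    switch(cmp,
      gt = num > thr, ge = num >= thr,
      lt = num < thr, le = num <= thr)
  } else if (cmp == "eq") {
    num <- suppressWarnings(as.numeric(vals))
    thr <- suppressWarnings(as.numeric(predicate$value))
    if (!anyNA(num) && !is.na(thr)) num == thr
    else vals == trimws(as.character(predicate$value))
  } else {  # in
    vals %in% trimws(as.character(predicate$value))
  }
}

#' Parse the user's contextual gene table
#'
#' Reads a CSV or TSV gene table (delimiter auto-detected from the header
#' line), normalizes the gene identifiers, collapses duplicate identifiers to
#' their first occurrence with a warning, and evaluates the contextual
#' predicate to mark which genes are contextually relevant. All listed genes
#' later seed the network; the predicate controls only contextual status.
#'
#' @param stream a file path, connection, or character vector of lines.
#' @param idColumn name of the gene-identifier column.
#' @param predicate a [contextPredicate()] specification, or the string
#'   `"all"` to mark every listed gene contextual.
#' @return a [ContextInput-class].
#' @examples
#' tab <- c("gene\tlogFC", "B\t2.5", "C\t1.1", "E\t3.0", "Z\t2.2")
#' ci <- parseContextTable(tab, "gene", contextPredicate("logFC", "gt", 2))
#' eligibleNodes(ci)   # B, E, Z
#' @export
parseContextTable <- function(stream, idColumn, predicate = "all") {
  lines <- .readSource(stream)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("context table must have a header row and at least one data row")
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  table <- utils::read.table(text = lines, sep = sep, header = TRUE,
                             colClasses = "character", check.names = FALSE,
                             comment.char = "", quote = "\"",
                             stringsAsFactors = FALSE)
  if (!(idColumn %in% colnames(table)))
    stop("column not found: '", idColumn,
         "' is not in the context table header")
  table[[idColumn]] <- normalizeId(table[[idColumn]])
  dup <- duplicated(table[[idColumn]])
  if (any(dup)) {
    warning(sum(dup), " duplicate gene id(s) collapsed to first occurrence: ",
            paste(unique(table[[idColumn]][dup]), collapse = ", "))
    table <- table[!dup, , drop = FALSE]
    rownames(table) <- NULL
  }
  eligible <- table[[idColumn]][.evalPredicate(table, predicate)]
  pred_meta <- if (identical(predicate, "all")) list(all = TRUE) else predicate
  new("ContextInput", table = table, idColumn = idColumn,
      eligible = eligible, predicate = pred_meta)
}

#' Genes satisfying the contextual predicate
#'
#' @param x a [ContextInput-class].
#' @return character vector of normalized gene identifiers (input order).
#' @export
eligibleNodes <- function(x) {
  stopifnot(is(x, "ContextInput"))
  x@eligible
}

#' All uploaded gene identifiers
#'
#' @param x a [ContextInput-class].
#' @return character vector of normalized gene identifiers (input order).
#' @export
inputNodes <- function(x) {
  stopifnot(is(x, "ContextInput"))
  x@table[[x@idColumn]]
}

#' Resolve the contextual set against a database
#'
#' Splits the predicate-eligible genes into those with at least one database
#' interaction (the contextual set, whose size is K) and those absent from
#' the database. Genes without any qualifying interaction cannot contribute
#' to the background and are excluded from the statistic, but are reported so
#' the user can audit identifier mismatches.
#'
#' @param input a [ContextInput-class].
#' @param db an [InteractionDb-class].
#' @return a [ContextSet-class].
#' @export
resolveContext <- function(input, db) {
  stopifnot(is(input, "ContextInput"), is(db, "InteractionDb"))
  eligible <- eligibleNodes(input)
  present <- eligible[eligible %in% dbNodes(db)]
  absent <- eligible[!(eligible %in% dbNodes(db))]
  if (length(present) == 0L)
    stop("no contextual genes in database: the statistic is undefined")
  if (length(absent) > 0L)
    message(length(absent), " contextual gene(s) not found in the database")
  new("ContextSet",
      contextual = sort(unique(present), method = "radix"),
      missing = absent)
}

#' @rdname context-accessors
setMethod("contextK", "ContextSet", function(x) length(x@contextual))

#' @rdname context-accessors
setMethod("contextualNodes", "ContextSet", function(x) x@contextual)

#' @rdname context-accessors
setMethod("missingNodes", "ContextSet", function(x) x@missing)

#' @export
setMethod("show", "ContextSet", function(object) {
  cat("ContextSet: K =", contextK(object), "contextual gene(s) in database;",
      length(object@missing), "not found\n")
})

#' @export
setMethod("show", "ContextInput", function(object) {
  cat("ContextInput:", nrow(object@table), "gene(s),",
      length(object@eligible), "contextually eligible\n")
})
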