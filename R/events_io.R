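## Readers and writers for the tabular dialects the pipeline touches:
## PSI matrices, clinical tables and expression matrices.  Delimiter is
## sniffed from the file extension (.csv = comma, anything else = tab).

.delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.MISSING_TOKENS <- c("", "NA", "NaN", "null")

#' Parse a canonical event-id string
#'
#' Event ids follow \code{"SYMBOL|as_id|TYPE[|exon_label]"} with \code{"|"}
#' as separator (gene symbols may legitimately contain \code{"-"} and
#' \code{"_"}, so those are not used).  \code{TYPE} must be one of the 7
#' category codes of [spliceCategories()].
#'
#' @param raw A single event-id string, e.g. \code{"KIF4A|10001|AT|exon32"}.
#' @return A named list with fields \code{symbol}, \code{as_id} (integer),
#'   \code{splice_type} and \code{exon_label} (\code{""} when absent).
#' @examples
#' parseEventId("KIF4A|10001|AT|exon32")
#' parseEventId("GENE|1|ES")$exon_label  # ""
#' @export
parseEventId <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  parts <- strsplit(raw, "|", fixed = TRUE)[[1L]]
  if (length(parts) < 3L || length(parts) > 4L)
    stop("malformed event id '", raw,
         "': expected SYMBOL|as_id|TYPE[|exon_label]")
  as_id <- suppressWarnings(as.integer(parts[2L]))
  if (is.na(as_id))
    stop("malformed event id '", raw, "': as_id must be an integer")
  if (!parts[3L] %in% spliceCategories())
    stop("unknown splice type '", parts[3L], "' in '", raw,
         "'; legal codes are: ", paste(spliceCategories(), collapse = ", "))
  list(symbol = parts[1L], as_id = as_id, splice_type = parts[3L],
       exon_label = if (length(parts) == 4L) parts[4L] else "")
}

#' Format canonical event-id strings
#'
#' Inverse of [parseEventId()]: builds \code{"SYMBOL|as_id|TYPE|exon_label"}
#' strings from an event table (the trailing field is kept even when empty
#' so the format round-trips).
#'
#' @param events \code{data.frame} with columns \code{symbol}, \code{as_id},
#'   \code{splice_type}, \code{exon_label}.
#' @return Character vector of event ids.
#' @export
eventId <- function(events) {
  paste(events$symbol, events$as_id, events$splice_type, events$exon_label,
        sep = "|")
}

#' Read a PSI table
#'
#' Two dialects are supported.  \code{"simple"}: first column
#' \code{event_id} holding canonical event-id strings, remaining columns one
#' per sample.  \code{"tcgaspliceseq"}: leading columns \code{symbol},
#' \code{as_id}, \code{splice_type}, \code{exons}, then one column per
#' sample.  Cells equal to \code{""}, \code{"NA"}, \code{"NaN"} or
#' \code{"null"} (and any unparseable cell) become missing.  PSI must be on
#' the fraction scale: a value outside [0, 1] is an error naming the
#' offending event and sample (inputs on the 0-100 percent scale must be
#' divided by 100 beforehand; no auto-detection is attempted).
#'
#' @param path Path to a .tsv/.csv file.
#' @param dialect \code{"simple"} (default) or \code{"tcgaspliceseq"}.
#' @return A \linkS4class{PsiExperiment}.
#' @seealso [writePsiTable()]
#' @export
readPsiTable <- function(path, dialect = c("simple", "tcgaspliceseq")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.table(path, sep = .delim(path), header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (dialect == "simple") {
    if (colnames(raw)[1L] != "event_id")
      stop("format error: first column must be 'event_id' (simple dialect)")
    ids <- raw[[1L]]
    events <- do.call(rbind, lapply(ids, function(id)
      as.data.frame(parseEventId(id), stringsAsFactors = FALSE)))
    vals <- raw[, -1L, drop = FALSE]
  } else {
    need <- c("symbol", "as_id", "splice_type", "exons")
    if (!all(need %in% colnames(raw)[seq_len(4L)]))
      stop("format error: tcgaspliceseq dialect requires leading columns ",
           paste(need, collapse = ", "))
    events <- data.frame(symbol = raw$symbol,
                         as_id = as.integer(raw$as_id),
                         splice_type = raw$splice_type,
                         exon_label = raw$exons,
                         stringsAsFactors = FALSE)
    bad <- setdiff(unique(events$splice_type), spliceCategories())
    if (length(bad))
      stop("unknown splice type '", bad[1L], "'; legal codes are: ",
           paste(spliceCategories(), collapse = ", "))
    vals <- raw[, setdiff(colnames(raw), need), drop = FALSE]
  }
  if (ncol(vals) == 0L)
    stop("format error: no sample columns found")
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(eventId(events), colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    cell <- vals[[j]]
    cell[cell %in% .MISSING_TOKENS] <- NA
    m[, j] <- suppressWarnings(as.numeric(cell))
  }
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop("PSI value ", m[bad[1L, 1L], bad[1L, 2L]], " outside [0, 1] for event '",
         rownames(m)[bad[1L, 1L]], "', sample '", colnames(m)[bad[1L, 2L]], "'")
  PsiExperiment(m, events)
}

#' Write a PSI table (simple dialect)
#'
#' @param x A \linkS4class{PsiExperiment}.
#' @param path Output path (.tsv or .csv).
#' @return Invisibly, \code{path}.
#' @export
writePsiTable <- function(x, path) {
  m <- psiValues(x)
  df <- data.frame(event_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .delim(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.CLINICAL_CATEGORICAL <- c("grade", "histology", "idh_status", "codel_1p19q",
                           "mgmt_status", "tert_status", "atrx_status",
                           "chr7gain_chr10loss", "chr19_20_gain",
                           "standard_therapy")

#' Read a clinical table
#'
#' Requires columns \code{sample_id}, \code{os_months} (overall-survival
#' time, months) and \code{os_event} (1 = death observed, 0 = censored).
#' Recognised optional columns: \code{age}, \code{karnofsky} (numeric) and
#' the categorical annotations \code{grade}, \code{histology},
#' \code{idh_status}, \code{codel_1p19q}, \code{mgmt_status},
#' \code{tert_status}, \code{atrx_status}, \code{chr7gain_chr10loss},
#' \code{chr19_20_gain} and \code{standard_therapy} (the concurrent
#' chemoradiotherapy flag, \code{"1"}/\code{"0"}/\code{"unknown"}).  Blank
#' categorical cells become \code{"unknown"}.  Samples with missing survival
#' data are retained (downstream survival operations drop them with a note).
#'
#' @param path Path to a .tsv/.csv file.
#' @return A \code{data.frame}, one row per sample.
#' @export
readClinicalTable <- function(path) {
  raw <- utils::read.table(path, sep = .delim(path), header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  need <- c("sample_id", "os_months", "os_event")
  miss <- setdiff(need, colnames(raw))
  if (length(miss))
    stop("format error: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(raw$sample_id))
    stop("sample ids must be unique")
  out <- data.frame(sample_id = raw$sample_id, stringsAsFactors = FALSE)
  blank <- function(x) x %in% .MISSING_TOKENS
  num <- function(x) suppressWarnings(as.numeric(ifelse(blank(x), NA, x)))
  out$os_months <- num(raw$os_months)
  if (any(out$os_months < 0, na.rm = TRUE))
    stop("os_months must be non-negative")
  out$os_event <- num(raw$os_event)
  if (!all(out$os_event %in% c(0, 1) | is.na(out$os_event)))
    stop("os_event must be 0 or 1")
  for (col in intersect(c("age", "karnofsky"), colnames(raw)))
    out[[col]] <- num(raw[[col]])
  for (col in intersect(.CLINICAL_CATEGORICAL, colnames(raw)))
    out[[col]] <- ifelse(blank(raw[[col]]), "unknown", raw[[col]])
  rownames(out) <- out$sample_id
  out
}

#' Write a clinical table
#'
#' @param clin A clinical \code{data.frame} as returned by
#'   [readClinicalTable()].
#' @param path Output path (.tsv or .csv).
#' @return Invisibly, \code{path}.
#' @export
writeClinicalTable <- function(clin, path) {
  utils::write.table(clin, path, sep = .delim(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write an expression matrix
#'
#' First column \code{gene} (unique symbols), remaining columns one per
#' sample; values must be non-negative.  Blank/NA cells become \code{NA}.
#'
#' @param path Path to a .tsv/.csv file.
#' @return \code{readExpressionTable}: numeric genes-x-samples matrix.
#' @export
readExpressionTable <- function(path) {
  raw <- utils::read.table(path, sep = .delim(path), header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (colnames(raw)[1L] != "gene")
    stop("format error: first column must be 'gene'")
  if (anyDuplicated(raw$gene))
    stop("gene symbols must be unique")
  vals <- raw[, -1L, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(raw$gene, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    cell <- vals[[j]]
    cell[cell %in% .MISSING_TOKENS] <- NA
    m[, j] <- suppressWarnings(as.numeric(cell))
  }
  if (any(m < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  m
}

#' @rdname readExpressionTable
#' @param expr Genes-x-samples numeric matrix.
#' @return \code{writeExpressionTable}: invisibly, \code{path}.
#' @export
writeExpressionTable <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .delim(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
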