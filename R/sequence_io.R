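#' @keywords internal
"_PACKAGE"

PROTEIN_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                      "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
NUCLEOTIDE_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a set of sequence records
#'
#' A sequence set is a plain `data.frame` with columns `id`, `description`,
#' `residues` and `kind`. Residues are uppercased and validated against the
#' declared alphabet: the 20 amino acids plus `X` in protein mode, `ACGTN` in
#' nucleotide mode. `X` is accepted on input but is treated as a non-cysteine
#' wildcard by all motif logic.
#'
#' @param id character vector of unique, whitespace-free identifiers.
#' @param residues character vector of sequences.
#' @param kind `"protein"` or `"nucleotide"`.
#' @param description optional free-text descriptions (defaults to `id`).
#' @return data.frame with columns `id`, `description`, `residues`, `kind`.
#' @export
seq_records <- function(id, residues, kind = c("protein", "nucleotide"),
                        description = id) {
  kind <- match.arg(kind)
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("id and residues must have equal length")
  if (anyDuplicated(id))
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(grepl("[[:space:]]", id)))
    stop("record ids must not contain whitespace")
  if (any(!nzchar(residues)))
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(residues)], collapse = ", "))
  alphabet <- if (kind == "protein") PROTEIN_ALPHABET else NUCLEOTIDE_ALPHABET
  bad <- vapply(residues, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    !all(ch %in% alphabet)
  }, logical(1))
  if (any(bad)) {
    stop("invalid ", kind, " characters in record(s): ",
         paste(id[bad], collapse = ", "))
  }
  data.frame(id = id, description = as.character(description),
             residues = residues, kind = rep(kind, length(id)),
             stringsAsFactors = FALSE)
}

#' Read a FASTA file into a sequence-record table
#'
#' Parsing itself is delegated to [Biostrings::readBStringSet()]; this wrapper
#' adds structural validation with line-numbered errors (headers without
#' sequence, sequence before the first header) and alphabet validation that
#' names the offending record. Record ids are the first whitespace-delimited
#' header token; the full header is kept as the description. Lowercase
#' residues are normalised to uppercase.
#'
#' @param path FASTA file (multi-record).
#' @param kind `"protein"` or `"nucleotide"`.
#' @return data.frame as produced by [seq_records()].
#' @export
read_fasta <- function(path, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0L) {
    return(seq_records(character(0), character(0), kind))
  }
  if (!startsWith(trimws(lines[meaningful[1]]), ">"))
    stop("FASTA parse error at line ", meaningful[1],
         ": sequence data before first header")
  hdr <- which(startsWith(trimws(lines), ">"))
  # a header immediately followed by another header (or EOF) has no sequence
  nxt <- c(hdr[-1], length(lines) + 1L)
  for (k in seq_along(hdr)) {
    body <- lines[seq.int(hdr[k] + 1L, length.out = max(0L, nxt[k] - hdr[k] - 1L))]
    if (!any(nzchar(trimws(body))))
      stop("FASTA parse error at line ", hdr[k],
           ": header with empty sequence (", trimws(lines[hdr[k]]), ")")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[[:space:]]+"), `[`, character(1), 1L)
  seq_records(ids, as.character(set), kind, description = headers)
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x))` preserves ids and
#' residues.
#'
#' @param records sequence-record data.frame.
#' @param path output path.
#' @param use_description write the full description line instead of the id.
#' @export
write_fasta <- function(records, path, use_description = TRUE) {
  header <- if (use_description && !is.null(records$description))
    records$description else records$id
  x <- Biostrings::BStringSet(records$residues)
  names(x) <- header
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read Phobius short-format predictions
#'
#' Parses the four-column "short" output (SEQID, TM count, SP flag Y/N,
#' prediction string). A sequence is flagged as having a transmembrane region
#' when the TM count is positive, and as having a signal peptide when the SP
#' flag is `Y`. The cleavage site is taken from the `n..-..c<i>/<j>` part of
#' the prediction string when present: the last residue of the signal peptide
#' is `<i>` of the `c<i>/<j>` cleavage annotation.
#'
#' @param path Phobius short-format file; a leading `SEQENCE ID` header line
#'   is tolerated.
#' @return data.frame with columns `id`, `has_signal_peptide`,
#'   `has_transmembrane`, `cleavage_site` (NA when absent).
#' @export
read_phobius_short <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^SEQ[A-Z]*\\s+ID", lines, ignore.case = TRUE)]
  empty <- data.frame(id = character(0), has_signal_peptide = logical(0),
                      has_transmembrane = logical(0),
                      cleavage_site = integer(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  n_ok <- lengths(fields) >= 4L
  if (any(!n_ok))
    stop("Phobius parse error: expected 4 columns (SEQID TM SP PREDICTION), ",
         "got fewer at line(s) ", paste(which(!n_ok), collapse = ", "))
  ids <- vapply(fields, `[`, character(1), 1L)
  tm <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  sp <- vapply(fields, `[`, character(1), 3L)
  pred <- vapply(fields, `[`, character(1), 4L)
  if (anyNA(tm) || !all(sp %in% c("Y", "N", "0")))
    stop("Phobius parse error: unrecognised TM/SP column layout")
  cleav <- rep(NA_integer_, length(ids))
  m <- regmatches(pred, regexpr("c([0-9]+)/[0-9]+", pred))
  has_c <- lengths(regmatches(pred, gregexpr("c[0-9]+/[0-9]+", pred))) > 0
  for (k in which(has_c)) {
    cm <- regmatches(pred[k], regexpr("c[0-9]+/[0-9]+", pred[k]))
    cleav[k] <- as.integer(sub("c([0-9]+)/[0-9]+", "\\1", cm))
  }
  ann <- data.frame(id = ids,
                    has_signal_peptide = sp == "Y",
                    has_transmembrane = tm > 0L,
                    cleavage_site = cleav,
                    stringsAsFactors = FALSE)
  ann$cleavage_site[!ann$has_signal_peptide] <- NA_integer_
  ann
}

#' Write Phobius-style short-format annotations
#'
#' Emits annotations (e.g. from [heuristic_signal_predict()] or the synthetic
#' generator) in the same four-column layout [read_phobius_short()] consumes,
#' so the file-based secretion gate can be tested end to end.
#'
#' @param annotations data.frame with `id`, `has_signal_peptide`,
#'   `has_transmembrane` and optional `cleavage_site`.
#' @param path output path.
#' @export
write_phobius_short <- function(annotations, path) {
  pred <- mapply(function(sp, tm, cs) {
    if (sp && !is.na(cs)) sprintf("n4-12c%d/%d.", cs, cs + 1L)
    else if (tm) "i7-26o." else "o."
  }, annotations$has_signal_peptide, annotations$has_transmembrane,
     if (is.null(annotations$cleavage_site)) rep(NA_integer_, nrow(annotations))
     else annotations$cleavage_site)
  lines <- sprintf("%s %d %s %s", annotations$id,
                   as.integer(annotations$has_transmembrane),
                   ifelse(annotations$has_signal_peptide, "Y", "0"), pred)
  writeLines(c("SEQENCE ID  TM SP PREDICTION", lines), path)
  invisible(path)
}

#' Write an annotation table (TSV or JSON)
#'
#' Fixed column order: id, class, mature_length, net_charge, gamma_core,
#' kcxn, conserved_gly, cluster. JSON mode round-trips losslessly through
#' [read_table_json()].
#'
#' @param annotated data.frame holding (a subset of) the fixed columns.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_table <- function(annotated, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  cols <- c("id", "class", "mature_length", "net_charge", "gamma_core",
            "kcxn", "conserved_gly", "cluster")
  for (cc in setdiff(cols, names(annotated))) annotated[[cc]] <- NA
  annotated <- annotated[, cols, drop = FALSE]
  if (format == "tsv") {
    utils::write.table(annotated, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(annotated, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a JSON annotation table written by [write_table()]
#' @param path JSON file.
#' @return data.frame in the fixed column order.
#' @export
read_table_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0L || nrow(df) == 0L)
    return(data.frame(id = character(0)))
  df
}
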