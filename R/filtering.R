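# Filtering cascade: size band -> cysteine-spacing motif -> secretion gate.
# Stage reports are always emitted so per-stage attrition is auditable.

#' Cysteine-spacing motif specification
#'
#' The mining pattern is a six-cysteine framework with bounded inter-cysteine
#' gaps, CX(2,18)CX(3)CX(2,12)CX(4,17)CXC: gap 2 is exactly 3 residues and
#' gap 5 exactly 1. `X` matches any residue *including* cysteine, so
#' 8-cysteine sequences can carry extra cysteines inside gap segments; all
#' satisfying framework assignments are enumerated and disambiguated later.
#'
#' @param segment_bounds list of five `c(min, max)` gap bounds.
#' @return object of class `motif_spec`.
#' @export
motif_spec <- function(segment_bounds = list(c(2L, 18L), c(3L, 3L),
                                             c(2L, 12L), c(4L, 17L),
                                             c(1L, 1L))) {
  if (length(segment_bounds) != 5L)
    stop("segment_bounds must give five (min,max) pairs")
  for (b in segment_bounds) {
    if (length(b) != 2L || b[1] < 1L || b[1] > b[2])
      stop("each segment bound must satisfy 1 <= min <= max")
  }
  structure(list(segment_bounds = lapply(segment_bounds, as.integer),
                 n_framework_cysteines = 6L),
            class = "motif_spec")
}

new_filter_report <- function(stage, kept, removed_ids, reasons) {
  stopifnot(length(removed_ids) == length(reasons))
  structure(list(stage = stage, kept = kept,
                 removed = data.frame(id = removed_ids, reason = reasons,
                                      stringsAsFactors = FALSE)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> stage=%s kept=%d removed=%d\n",
              x$stage, length(x$kept), nrow(x$removed)))
  if (nrow(x$removed) > 0)
    print(table(x$removed$reason))
  invisible(x)
}

#' Size filter (30-130 residues, inclusive)
#'
#' Sequences shorter than `min_len` or longer than `max_len` are removed;
#' both bounds are kept (a 30-mer and a 130-mer pass).
#'
#' @param records sequence-record data.frame.
#' @param min_len,max_len inclusive length bounds.
#' @return `filter_report` with reasons `TOO_SHORT` / `TOO_LONG`.
#' @export
size_filter <- function(records, min_len = 30L, max_len = 130L) {
  len <- nchar(records$residues)
  short <- len < min_len
  long <- len > max_len
  new_filter_report("size",
                    kept = records$id[!short & !long],
                    removed_ids = records$id[short | long],
                    reasons = ifelse(short[short | long], "TOO_SHORT", "TOO_LONG"))
}

cys_positions <- function(residues) {
  as.integer(gregexpr("C", residues, fixed = TRUE)[[1]][
    gregexpr("C", residues, fixed = TRUE)[[1]] > 0])
}

# Enumerate every ordered 6-subset of cysteine positions whose five
# consecutive gaps fall within the spec bounds. Depth-first with pruning on
# the reachable position range; positions are 1-based.
enumerate_assignments <- function(cpos, spec) {
  bounds <- spec$segment_bounds
  out <- list()
  n <- length(cpos)
  if (n < 6L) return(out)
  recurse <- function(chosen, next_level) {
    if (next_level == 7L) {
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    b <- bounds[[next_level - 1L]]
    last <- chosen[length(chosen)]
    for (p in cpos[cpos > last]) {
      gap <- p - last - 1L
      if (gap < b[1]) next
      if (gap > b[2]) break
      recurse(c(chosen, p), next_level + 1L)
    }
  }
  for (start in cpos) recurse(start, 2L)
  out
}

#' Scan a sequence for the cysteine-spacing motif
#'
#' Returns whether any six ordered cysteines satisfy the five gap bounds of
#' the motif, together with every satisfying assignment. Residues between
#' framework cysteines may themselves be cysteines, which is what allows
#' 8-cysteine frameworks to match.
#'
#' @param residues protein sequence (string) or a single-row record.
#' @param spec a [motif_spec()].
#' @return list with `match` (logical) and `assignments` (list of integer
#'   vectors of length 6, 1-based cysteine positions).
#' @export
motif_scan <- function(residues, spec = motif_spec()) {
  if (is.data.frame(residues)) {
    stopifnot(nrow(residues) == 1L)
    residues <- residues$residues
  }
  asn <- enumerate_assignments(cys_positions(residues), spec)
  list(match = length(asn) > 0L, assignments = asn)
}

#' Motif filter stage
#'
#' Applies [motif_scan()] to every record; non-matching records are removed
#' with reason `NO_MOTIF`.
#'
#' @param records sequence-record data.frame.
#' @param spec a [motif_spec()].
#' @return `filter_report`.
#' @export
motif_filter <- function(records, spec = motif_spec()) {
  hit <- vapply(records$residues,
                function(s) motif_scan(s, spec)$match, logical(1),
                USE.NAMES = FALSE)
  new_filter_report("motif", kept = records$id[hit],
                    removed_ids = records$id[!hit],
                    reasons = rep("NO_MOTIF", sum(!hit)))
}

#' Kyte-Doolittle hydropathy values (X scored 0)
#' @export
kyte_doolittle <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                    E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                    M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, V = 4.2,
                    W = -0.9, Y = -1.3, X = 0)

#' Heuristic signal-peptide / transmembrane prediction
#'
#' A deliberately simple, deterministic stand-in for an external secretion
#' predictor so the cascade runs self-contained; it is bypassed whenever a
#' Phobius file is supplied. A signal peptide is called when the first 35
#' residues contain a hydrophobic window (length 7, mean Kyte-Doolittle
#' hydropathy >= `h_min`) preceded within 5 residues by at least one K/R
#' (the classical n-region charge). The cleavage site is the `-1` position
#' of the first `[AGSCT]-X-[AGS]` match after that window, else window end
#' + 3. A transmembrane region is called when another such hydrophobic
#' window starts after position 40.
#'
#' @param record single-row record data.frame or residue string (with `id`).
#' @param params list with `h_min` (default 1.5), `window` (7),
#'   `n_search` (35), `tm_after` (40), `kr_lookback` (5).
#' @param id record id when `record` is a bare string.
#' @return one-row annotation data.frame (same columns as
#'   [read_phobius_short()]).
#' @export
heuristic_signal_predict <- function(record, params = list(), id = NULL) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    id <- record$id
    residues <- record$residues
  } else {
    residues <- record
    if (is.null(id)) id <- "seq"
  }
  p <- utils::modifyList(list(h_min = 1.5, window = 7L, n_search = 35L,
                              tm_after = 40L, kr_lookback = 5L), params)
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  kd <- unname(kyte_doolittle[ch])
  kd[is.na(kd)] <- 0
  n <- length(ch)
  w <- p$window
  has_sp <- FALSE; has_tm <- FALSE; cleav <- NA_integer_
  if (n >= w) {
    csum <- cumsum(c(0, kd))
    wmean <- (csum[(w + 1):(n + 1)] - csum[1:(n - w + 1)]) / w
    hydro_start <- which(wmean >= p$h_min)            # window start positions
    sp_starts <- hydro_start[hydro_start + w - 1L <= p$n_search]
    for (s in sp_starts) {
      lo <- max(1L, s - p$kr_lookback)
      if (s > 1L && any(ch[lo:(s - 1L)] %in% c("K", "R"))) {
        has_sp <- TRUE
        wend <- s + w - 1L
        cleav <- wend + 3L
        if (wend + 3L <= n) {
          for (q in (wend + 1L):(n - 2L)) {
            if (ch[q] %in% c("A", "G", "S", "C", "T") &&
                ch[q + 2L] %in% c("A", "G", "S")) {
              cleav <- q + 2L
              break
            }
          }
        }
        cleav <- min(cleav, n - 1L)
        break
      }
    }
    has_tm <- any(hydro_start > p$tm_after)
  }
  data.frame(id = id, has_signal_peptide = has_sp, has_transmembrane = has_tm,
             cleavage_site = if (has_sp) as.integer(cleav) else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Secretion gate
#'
#' Keeps records predicted to carry a signal peptide and no transmembrane
#' region. Every record must have an annotation (from a Phobius file or the
#' built-in heuristic); missing ids raise a configuration error.
#'
#' @param records sequence-record data.frame.
#' @param annotations annotation data.frame (id, has_signal_peptide,
#'   has_transmembrane, cleavage_site).
#' @return `filter_report` with reasons `HAS_TM` / `NO_SIGNAL`; a sequence
#'   that is both TM-positive and signal-negative is reported as `HAS_TM`.
#' @export
secretion_gate <- function(records, annotations) {
  idx <- match(records$id, annotations$id)
  if (anyNA(idx))
    stop("missing secretion annotation for id(s): ",
         paste(records$id[is.na(idx)], collapse = ", "))
  ann <- annotations[idx, , drop = FALSE]
  keep <- ann$has_signal_peptide & !ann$has_transmembrane
  reason <- ifelse(ann$has_transmembrane, "HAS_TM", "NO_SIGNAL")
  new_filter_report("secretion", kept = records$id[keep],
                    removed_ids = records$id[!keep],
                    reasons = reason[!keep])
}

#' Extract the mature peptide after the signal-peptide cleavage site
#'
#' @param record single-row record data.frame.
#' @param annotation matching one-row annotation with a cleavage site.
#' @return one-row record data.frame; id is suffixed `|mature`.
#' @export
extract_mature <- function(record, annotation) {
  stopifnot(nrow(record) == 1L)
  if (is.data.frame(annotation)) {
    annotation <- annotation[annotation$id == record$id, , drop = FALSE]
    stopifnot(nrow(annotation) == 1L)
  }
  if (!isTRUE(annotation$has_signal_peptide) || is.na(annotation$cleavage_site))
    stop("record ", record$id, " has no predicted signal peptide")
  cs <- annotation$cleavage_site
  len <- nchar(record$residues)
  if (cs >= len - 10L)
    stop("record ", record$id, ": cleavage site ", cs,
         " leaves a mature region too short to hold a cysteine framework")
  seq_records(paste0(record$id, "|mature"),
              substring(record$residues, cs + 1L, len),
              kind = "protein",
              description = paste(record$description, "mature"))
}
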