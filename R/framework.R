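# Cysteine-framework features on the mature peptide: tails, inter-cysteine
# gaps, extra cysteines and the inferred disulfide topology. All coordinates
# are 1-based and inclusive.

#' Build the cysteine framework of a mature peptide
#'
#' When several six-cysteine assignments satisfy the spacing bounds the
#' canonical one is chosen deterministically: (a) prefer assignments whose
#' extra cysteines are flanking (first and last cysteine of the sequence) --
#' the plant-like pattern; else (b) smallest framework span; else (c)
#' leftmost assignment. Topology is `SIX_CYS` (no extras),
#' `EIGHT_CYS_FLANKING` (two extras, first and last cysteine of the
#' sequence), `EIGHT_CYS_INTERNAL` (two extras, one before the framework and
#' one strictly between framework C4 and C6), else `OTHER`.
#'
#' @param mature mature-peptide string or single-row record data.frame.
#' @param assignments optional list of assignments from [motif_scan()];
#'   recomputed when missing.
#' @param spec a [motif_spec()].
#' @param id identifier used in the result when `mature` is a bare string.
#' @return object of class `cys_framework`: `mature_id`, `residues`,
#'   `cys_positions`, `assignment`, `segment_gaps` (g1..g5), `n_tail_len`,
#'   `c_tail_len`, `extra_cys`, `topology`.
#' @export
build_framework <- function(mature, assignments = NULL, spec = motif_spec(),
                            id = "mature") {
  if (is.data.frame(mature)) {
    stopifnot(nrow(mature) == 1L)
    id <- mature$id
    mature <- mature$residues
  }
  cpos <- cys_positions(mature)
  if (is.null(assignments))
    assignments <- motif_scan(mature, spec)$assignments
  if (length(assignments) == 0L)
    stop("no motif assignment for ", id,
         ": motif_scan must succeed before building a framework")
  asn <- choose_assignment(assignments, cpos)
  extras <- setdiff(cpos, asn)
  gaps <- diff(asn) - 1L
  structure(list(
    mature_id = id,
    residues = mature,
    cys_positions = cpos,
    assignment = asn,
    segment_gaps = gaps,
    n_tail_len = asn[1] - 1L,
    c_tail_len = nchar(mature) - asn[6],
    extra_cys = extras,
    topology = classify_topology(asn, extras, cpos)
  ), class = "cys_framework")
}

choose_assignment <- function(assignments, cpos) {
  is_flanking <- vapply(assignments, function(a) {
    ex <- setdiff(cpos, a)
    length(ex) == 2L && ex[1] == cpos[1] && ex[2] == cpos[length(cpos)]
  }, logical(1))
  pool <- if (any(is_flanking)) assignments[is_flanking] else assignments
  span <- vapply(pool, function(a) a[6] - a[1], integer(1))
  pool <- pool[span == min(span)]
  if (length(pool) > 1L) {
    ord <- do.call(order, as.data.frame(do.call(rbind, pool)))
    pool <- pool[ord]
  }
  pool[[1]]
}

classify_topology <- function(asn, extras, cpos) {
  if (length(extras) == 0L) return("SIX_CYS")
  if (length(extras) == 2L) {
    if (extras[1] == cpos[1] && extras[2] == cpos[length(cpos)] &&
        extras[1] < asn[1] && extras[2] > asn[6])
      return("EIGHT_CYS_FLANKING")
    if (extras[1] < asn[1] && extras[2] > asn[4] && extras[2] < asn[6])
      return("EIGHT_CYS_INTERNAL")
  }
  "OTHER"
}

#' @export
print.cys_framework <- function(x, ...) {
  cat(sprintf("<cys_framework> %s: tails (%d, %d), gaps (%s), topology %s\n",
              x$mature_id, x$n_tail_len, x$c_tail_len,
              paste(x$segment_gaps, collapse = ","), x$topology))
  invisible(x)
}

#' Infer the disulfide topology of a framework
#'
#' All frameworks carry the canonical cis-defensin connectivity 1-4, 2-5,
#' 3-6 over the six framework cysteines. Eight-cysteine frameworks add a
#' fourth bond: between the first and last cysteine for the flanking
#' (plant-like) pattern, or between the two extra cysteines themselves for
#' the internal pattern. Frameworks with any other extra-cysteine layout are
#' flagged `UNRESOLVED`.
#'
#' @param framework a `cys_framework`.
#' @return list: `canonical_bonds` (framework numbering), `extra_bond`
#'   (full-cysteine numbering or NULL), `unresolved` flag.
#' @export
infer_topology <- function(framework) {
  canonical <- list(c(1L, 4L), c(2L, 5L), c(3L, 6L))
  extra <- NULL
  unresolved <- FALSE
  full_rank <- function(p) match(p, framework$cys_positions)
  if (framework$topology == "EIGHT_CYS_FLANKING") {
    extra <- c(1L, length(framework$cys_positions))  # 1-8 in full numbering
  } else if (framework$topology == "EIGHT_CYS_INTERNAL") {
    extra <- full_rank(framework$extra_cys)
  } else if (framework$topology == "OTHER") {
    unresolved <- TRUE
  }
  list(canonical_bonds = canonical, extra_bond = extra,
       unresolved = unresolved)
}

#' Loop lengths used for class grouping
#'
#' Operational mapping of the n, m and c loops onto the gap segments of the
#' framework: `n_loop` = gap 1, `m_loop` = gap 3, `c_loop` = gap 4 (gaps 2
#' and 5 are fixed by the motif).
#'
#' @param framework a `cys_framework`.
#' @return named integer vector `c(n_loop=, m_loop=, c_loop=)`.
#' @export
loop_lengths <- function(framework) {
  g <- framework$segment_gaps
  c(n_loop = g[1], m_loop = g[3], c_loop = g[4])
}

#' Framework feature table for a set of matures
#'
#' @param matures mature record data.frame.
#' @param spec a [motif_spec()].
#' @return data.frame: id, cys_positions (comma-joined), assignment, gaps,
#'   n_tail_len, c_tail_len, topology.
#' @export
framework_table <- function(matures, spec = motif_spec()) {
  rows <- lapply(seq_len(nrow(matures)), function(i) {
    fw <- build_framework(matures[i, , drop = FALSE], spec = spec)
    data.frame(id = fw$mature_id,
               cys_positions = paste(fw$cys_positions, collapse = ","),
               assignment = paste(fw$assignment, collapse = ","),
               gaps = paste(fw$segment_gaps, collapse = ","),
               n_tail_len = fw$n_tail_len, c_tail_len = fw$c_tail_len,
               topology = fw$topology, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
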