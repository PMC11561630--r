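# Rule-based assignment of mature frameworks to the five bacterial
# cis-defensin structural archetypes, plus the sequence-motif and charge
# annotations shown alongside class alignments.

#' Classifier configuration
#'
#' Default N-terminal tail ranges (residues before framework C1, measured on
#' the mature peptide): class I 1-4, class II 8-13, class III 0-15, class IV
#' 21-53. Classes I, II and IV require the plain six-cysteine topology;
#' class III the internal eight-cysteine pattern; class V the flanking
#' (plant-like) eight-cysteine pattern. The II and IV ranges are the unions
#' of the two printed variants (8-13/9-13 and 21-53/23-53) and every bound
#' is overridable. `tail0_as_I` optionally folds tail-0 six-cysteine
#' frameworks into class I (off by default: class I is described as one to
#' four tail residues).
#'
#' @param tail_I,tail_II,tail_III,tail_IV inclusive `c(min,max)` tail ranges.
#' @param tail0_as_I logical.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(tail_I = c(1L, 4L), tail_II = c(8L, 13L),
                              tail_III = c(0L, 15L), tail_IV = c(21L, 53L),
                              tail0_as_I = FALSE) {
  for (r in list(tail_I, tail_II, tail_III, tail_IV))
    if (length(r) != 2L || r[1] > r[2]) stop("tail ranges must be c(min, max)")
  structure(list(tail_I = as.integer(tail_I), tail_II = as.integer(tail_II),
                 tail_III = as.integer(tail_III), tail_IV = as.integer(tail_IV),
                 tail0_as_I = isTRUE(tail0_as_I)),
            class = "classifier_config")
}

in_range <- function(x, r) x >= r[1] & x <= r[2]

#' Assign a framework to a structural class
#'
#' Topology is evaluated first: the flanking eight-cysteine pattern is class
#' V; the internal eight-cysteine pattern is class III when the tail is
#' within the class III range; six-cysteine frameworks fall to classes I, II
#' or IV by tail length, else `UNCLASSIFIED` with reason `TAIL_GAP`; any
#' other topology is `UNCLASSIFIED` with reason `BAD_TOPOLOGY`. Motif and
#' charge annotations are attached.
#'
#' @param framework a `cys_framework`.
#' @param config a [classifier_config()].
#' @param overrides optional data.frame (id, class, note) of expert calls
#'   applied after the rules; rationale records `OVERRIDE`.
#' @return list of class `class_assignment`: `mature_id`, `label`,
#'   `rationale` (character vector of rule codes), `gamma_core`, `kcxn`,
#'   `conserved_gly`, `net_charge`, `n_tail_len`, `mature_length`.
#' @export
assign_class <- function(framework, config = classifier_config(),
                         overrides = NULL) {
  tl <- framework$n_tail_len
  topo <- framework$topology
  label <- "UNCLASSIFIED"
  rationale <- character(0)
  if (topo == "EIGHT_CYS_FLANKING") {
    label <- "V"; rationale <- "FLANKING_EXTRA_PAIR"
  } else if (topo == "EIGHT_CYS_INTERNAL") {
    if (in_range(tl, config$tail_III)) {
      label <- "III"; rationale <- c("INTERNAL_EXTRA_PAIR", "TAIL_III")
    } else rationale <- c("INTERNAL_EXTRA_PAIR", "TAIL_GAP")
  } else if (topo == "SIX_CYS") {
    if (in_range(tl, config$tail_I) || (tl == 0L && config$tail0_as_I)) {
      label <- "I"; rationale <- c("SIX_CYS", "TAIL_I")
    } else if (in_range(tl, config$tail_II)) {
      label <- "II"; rationale <- c("SIX_CYS", "TAIL_II")
    } else if (in_range(tl, config$tail_IV)) {
      label <- "IV"; rationale <- c("SIX_CYS", "TAIL_IV")
    } else rationale <- c("SIX_CYS", "TAIL_GAP")
  } else {
    rationale <- "BAD_TOPOLOGY"
  }
  if (!is.null(overrides) && framework$mature_id %in% overrides$id) {
    label <- overrides$class[match(framework$mature_id, overrides$id)]
    rationale <- c(rationale, "OVERRIDE")
  }
  gc <- detect_gamma_core(framework$residues, framework)
  kc <- detect_kcxn(framework$residues)
  structure(list(mature_id = framework$mature_id, label = label,
                 rationale = rationale,
                 gamma_core = gc$found, gamma_core_pos = gc$position,
                 kcxn = length(kc) > 0L, kcxn_positions = kc,
                 conserved_gly = detect_conserved_gly(framework$residues,
                                                      framework),
                 net_charge = net_charge(framework$residues),
                 n_tail_len = tl,
                 mature_length = nchar(framework$residues)),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat(sprintf("<class_assignment> %s -> %s [%s] charge %+d\n", x$mature_id,
              x$label, paste(x$rationale, collapse = ","), x$net_charge))
  invisible(x)
}

#' Detect the gamma-core GXC motif ending at framework C5
#'
#' True iff the residues at (p-2, p-1, p) are (G, any, C) where p is the
#' framework's fifth cysteine, i.e. the cysteine closing the loop between
#' beta-strands 1 and 2.
#'
#' @param mature mature-peptide string.
#' @param framework its `cys_framework`.
#' @return list(found = logical, position = start of the motif or NA).
#' @export
detect_gamma_core <- function(mature, framework) {
  p <- framework$assignment[5]
  found <- p >= 3L && substring(mature, p - 2L, p - 2L) == "G"
  list(found = found, position = if (found) p - 2L else NA_integer_)
}

#' Find all KCXN motif occurrences (overlap-aware)
#' @param mature mature-peptide string.
#' @return integer vector of 1-based start positions (possibly empty).
#' @export
detect_kcxn <- function(mature) {
  m <- gregexpr("(?=KC.N)", mature, perl = TRUE)[[1]]
  as.integer(m[m > 0])
}

#' Net (liquid) charge
#'
#' Counts only Lys/Arg as +1 and Asp/Glu as -1; histidine and the termini
#' are ignored, matching the convention used for per-peptide charges in
#' class alignments.
#'
#' @param mature peptide string.
#' @return integer charge.
#' @export
net_charge <- function(mature) {
  ch <- strsplit(mature, "", fixed = TRUE)[[1]]
  as.integer(sum(ch %in% c("K", "R")) - sum(ch %in% c("D", "E")))
}

#' Detect the conserved glycine in gap segment 4
#'
#' Reported separately from the gamma-core so alignment reports can
#' highlight it; by default it is the gamma-core glycine (the G two before
#' framework C5).
#'
#' @param mature mature-peptide string.
#' @param framework its `cys_framework`.
#' @return logical.
#' @export
detect_conserved_gly <- function(mature, framework) {
  detect_gamma_core(mature, framework)$found
}

#' Classify a set of mature records
#'
#' @param matures mature record data.frame.
#' @param config a [classifier_config()].
#' @param spec a [motif_spec()].
#' @param overrides optional override data.frame (id, class, note).
#' @return data.frame: id, class, rationale, n_tail_len, mature_length,
#'   net_charge, gamma_core, kcxn, conserved_gly, topology.
#' @export
classify_set <- function(matures, config = classifier_config(),
                         spec = motif_spec(), overrides = NULL) {
  rows <- lapply(seq_len(nrow(matures)), function(i) {
    fw <- build_framework(matures[i, , drop = FALSE], spec = spec)
    a <- assign_class(fw, config, overrides)
    data.frame(id = a$mature_id, class = a$label,
               rationale = paste(a$rationale, collapse = ";"),
               n_tail_len = a$n_tail_len, mature_length = a$mature_length,
               net_charge = a$net_charge, gamma_core = a$gamma_core,
               kcxn = a$kcxn, conserved_gly = a$conserved_gly,
               topology = fw$topology, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
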