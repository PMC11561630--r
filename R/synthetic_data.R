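# Seeded generator for labelled defensin precursors and stage-targeted
# decoys. Every positive is checked at generation time to be consistent
# with its own ground truth (passes the size/motif/secretion cascade, the
# mature region round-trips, and the framework/classifier recover the
# intended label); draws failing the check are resampled. This is what
# makes clean-data recovery exact by construction: without it, rare
# accidental cysteine layouts (e.g. a background window that looks
# transmembrane, or an extra cysteine landing two before framework C5)
# would leak label noise into every downstream test.

BG_ALPHABET <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
                 "Q", "R", "S", "T", "V", "W", "Y")  # no cysteine

CLASS_TAIL_DEFAULTS <- list(I = c(1L, 4L), II = c(8L, 13L), III = c(1L, 15L),
                            IV = c(21L, 53L), V = c(1L, 4L))

sample_bg <- function(n) {
  if (n == 0L) return("")
  paste(sample(BG_ALPHABET, n, replace = TRUE), collapse = "")
}

gen_signal_peptide <- function() {
  n_reg <- paste0("M", paste(sample(c("K", "R"), sample(1:2, 1),
                                    replace = TRUE), collapse = ""))
  h_reg <- paste(sample(c("L", "I", "V", "F", "M"), sample(7:10, 1),
                        replace = TRUE), collapse = "")
  c_reg <- paste0("A", sample(c("N", "Q", "D", "E", "H"), 1), "A")
  paste0(n_reg, h_reg, c_reg)
}

# one positive draw; no seeding, no consistency check (see gen_positive)
draw_positive <- function(class, tail_range, gamma_core) {
  signal <- gen_signal_peptide()
  sig_len <- nchar(signal)
  tail_len <- sample(tail_range[1]:tail_range[2], 1)
  budget <- 130L - sig_len - tail_len - 6L
  g1 <- sample(2:min(18L, budget - 3L - 2L - 4L - 1L), 1)
  g2 <- 3L
  g3 <- sample(2:min(12L, budget - g1 - 3L - 4L - 1L), 1)
  g4 <- sample(4:min(17L, budget - g1 - 3L - g3 - 1L), 1)
  g5 <- 1L
  ct_max <- min(8L, budget - g1 - g2 - g3 - g4 - g5)
  ct_min <- if (class == "V") 1L else 0L
  c_tail_len <- sample(ct_min:max(ct_min, ct_max), 1)

  tail <- strsplit(sample_bg(tail_len), "")[[1]]
  if (length(tail) == 0L) tail <- character(0)
  s4 <- strsplit(sample_bg(g4), "")[[1]]
  if (gamma_core) s4[g4 - 1L] <- "G"
  extra_mature <- integer(0)
  if (class == "III") {
    tpos <- sample(tail_len, 1)
    tail[tpos] <- "C"
    spos <- sample(max(1L, g4 - 2L), 1)       # keep clear of the G at g4-1
    s4[spos] <- "C"
  } else if (class == "V") {
    tail[sample(tail_len, 1)] <- "C"
  }
  c_tail <- strsplit(sample_bg(c_tail_len), "")[[1]]
  if (class == "V") c_tail[sample(c_tail_len, 1)] <- "C"

  segs <- list(paste(tail, collapse = ""), sample_bg(g1), sample_bg(g2),
               sample_bg(g3), paste(s4, collapse = ""), sample_bg(g5),
               paste(c_tail, collapse = ""))
  mature <- paste0(segs[[1]], "C", segs[[2]], "C", segs[[3]], "C",
                   segs[[4]], "C", segs[[5]], "C", segs[[6]], "C", segs[[7]])
  c1 <- tail_len + 1L
  fw_pos <- cumsum(c(c1, g1 + 1L, g2 + 1L, g3 + 1L, g4 + 1L, g5 + 1L))
  list(signal = signal, mature = mature,
       precursor = paste0(signal, mature),
       cleavage_site = sig_len, tail_len = tail_len,
       gaps = c(g1, g2, g3, g4, g5), framework_positions = fw_pos,
       gamma_core_pos = if (gamma_core) fw_pos[5] - 2L else NA_integer_)
}

positive_consistent <- function(d, class, gamma_core,
                                config = classifier_config()) {
  len <- nchar(d$precursor)
  if (len < 30L || len > 130L) return(FALSE)
  if (!motif_scan(d$precursor)$match) return(FALSE)
  ann <- heuristic_signal_predict(d$precursor, id = "x")
  if (!ann$has_signal_peptide || ann$has_transmembrane) return(FALSE)
  if (is.na(ann$cleavage_site) || ann$cleavage_site != d$cleavage_site)
    return(FALSE)
  fw <- tryCatch(build_framework(d$mature), error = function(e) NULL)
  if (is.null(fw)) return(FALSE)
  if (!identical(fw$assignment, as.integer(d$framework_positions)))
    return(FALSE)
  if (fw$n_tail_len != d$tail_len) return(FALSE)
  expected_topo <- switch(class, III = "EIGHT_CYS_INTERNAL",
                          V = "EIGHT_CYS_FLANKING", "SIX_CYS")
  if (fw$topology != expected_topo) return(FALSE)
  a <- assign_class(fw, config)
  if (a$label != class) return(FALSE)
  if (gamma_core && !a$gamma_core) return(FALSE)
  TRUE
}

gen_positive <- function(class, tail_range = NULL, gamma_core = TRUE,
                         max_tries = 200L) {
  if (is.null(tail_range)) tail_range <- CLASS_TAIL_DEFAULTS[[class]]
  tail_floor <- if (class %in% c("III", "V")) 1L else 0L
  if (tail_range[1] < tail_floor ||
      tail_range[1] > tail_range[2] || tail_range[2] > 53L)
    stop("tail_range incompatible with class ", class,
         " and the 30-130 length band")
  for (k in seq_len(max_tries)) {
    d <- draw_positive(class, tail_range, gamma_core)
    if (positive_consistent(d, class, gamma_core)) {
      d$class <- class
      return(d)
    }
  }
  stop("could not draw a consistent class ", class, " precursor in ",
       max_tries, " tries")
}

#' Generate one labelled synthetic defensin precursor
#'
#' Builds a precursor as signal peptide + mature region, where the mature
#' region is an N-terminal tail (length drawn from the class range), a
#' six-cysteine framework with gaps drawn uniformly within the motif
#' bounds, and a C-terminal tail; classes III and V receive their two extra
#' cysteines (internal / flanking). The gamma-core glycine is placed two
#' residues before framework C5 unless disabled. The output is guaranteed
#' consistent with its ground truth (see the generation-time check above);
#' the seed fully determines the record.
#'
#' @param class `"I"`..`"V"`.
#' @param seed integer seed.
#' @param tail_range optional override of the class tail range.
#' @param gamma_core place the gamma-core glycine (default TRUE).
#' @param id record id.
#' @return list: `id`, `precursor`, `signal`, `mature`, `cleavage_site`,
#'   `tail_len`, `gaps`, `framework_positions` (mature coordinates),
#'   `gamma_core_pos`, `class`.
#' @export
generate_defensin <- function(class = c("I", "II", "III", "IV", "V"),
                              seed = 1L, tail_range = NULL,
                              gamma_core = TRUE, id = NULL) {
  class <- match.arg(class)
  set.seed(seed)
  d <- gen_positive(class, tail_range, gamma_core)
  d$id <- if (is.null(id)) sprintf("syn_%s_%d", class, seed) else id
  d
}

labelled_to_tables <- function(recs) {
  records <- seq_records(vapply(recs, `[[`, character(1), "id"),
                         vapply(recs, `[[`, character(1), "precursor"),
                         kind = "protein")
  truth <- data.frame(
    id = vapply(recs, `[[`, character(1), "id"),
    class = vapply(recs, `[[`, character(1), "class"),
    cleavage_site = vapply(recs, `[[`, integer(1), "cleavage_site"),
    mature = vapply(recs, `[[`, character(1), "mature"),
    tail_len = vapply(recs, `[[`, integer(1), "tail_len"),
    framework_positions = vapply(recs, function(r)
      paste(r$framework_positions, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Generate a labelled set of synthetic defensins
#'
#' One RNG stream seeded once, so the whole set is reproducible from
#' `(class, n, seed)`.
#'
#' @param class `"I"`..`"V"`.
#' @param n number of records.
#' @param seed integer seed.
#' @param ... passed to the per-record generator (`tail_range`,
#'   `gamma_core`).
#' @return list with `records` (sequence-record data.frame of precursors)
#'   and `truth` (ground-truth table).
#' @export
generate_defensin_set <- function(class, n, seed = 1L, ...) {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i) {
    d <- gen_positive(class, ...)
    d$id <- sprintf("syn_%s_%03d", class, i)
    d
  })
  labelled_to_tables(recs)
}

DECOY_KINDS <- c("TOO_SHORT", "TOO_LONG", "NO_CYS", "BAD_SPACING",
                 "NO_SIGNAL", "TM_LIKE", "SHUFFLED_POSITIVE")

draw_decoy <- function(kind) {
  if (kind == "TOO_SHORT") {
    return(sample_bg(sample(20:29, 1)))
  }
  if (kind == "TOO_LONG") {
    repeat {
      d <- gen_positive("II")
      s <- paste0(d$precursor, sample_bg(sample(131:150, 1) - nchar(d$precursor)))
      ann <- heuristic_signal_predict(s, id = "x")
      if (ann$has_signal_peptide && !ann$has_transmembrane) return(s)
    }
  }
  if (kind == "NO_CYS") {
    repeat {
      s <- paste0(gen_signal_peptide(), sample_bg(sample(30:60, 1)))
      ann <- heuristic_signal_predict(s, id = "x")
      if (ann$has_signal_peptide && !ann$has_transmembrane &&
          nchar(s) >= 30L && nchar(s) <= 130L) return(s)
    }
  }
  if (kind == "BAD_SPACING") {
    # class I layout but gap 2 forced outside its exact bound of 3
    repeat {
      d <- gen_positive("I")
      bad_g2 <- sample(c(1L, 2L, 4L, 5L), 1)
      m <- with(d, {
        p <- framework_positions
        seg <- function(a, b) substring(mature, a, b)
        paste0(seg(1, p[2]), sample_bg(bad_g2), seg(p[3], nchar(mature)))
      })
      s <- paste0(d$signal, m)
      ann <- heuristic_signal_predict(s, id = "x")
      if (!motif_scan(s)$match && ann$has_signal_peptide &&
          !ann$has_transmembrane && nchar(s) >= 30L && nchar(s) <= 130L)
        return(s)
    }
  }
  if (kind == "NO_SIGNAL") {
    repeat {
      d <- gen_positive("II")
      s <- d$mature
      if (nchar(s) < 30L) s <- paste0(s, sample_bg(30L - nchar(s)))
      ann <- heuristic_signal_predict(s, id = "x")
      if (!ann$has_signal_peptide && !ann$has_transmembrane &&
          motif_scan(s)$match) return(s)
    }
  }
  if (kind == "TM_LIKE") {
    repeat {
      d <- gen_positive("II")
      pad <- max(0L, 41L - nchar(d$precursor))
      s <- paste0(d$precursor, sample_bg(pad), strrep("L", 10L))
      ann <- heuristic_signal_predict(s, id = "x")
      if (ann$has_signal_peptide && ann$has_transmembrane &&
          nchar(s) <= 130L && motif_scan(s)$match) return(s)
    }
  }
  if (kind == "SHUFFLED_POSITIVE") {
    d <- gen_positive("II")
    shuffled <- paste(sample(strsplit(d$mature, "")[[1]]), collapse = "")
    return(paste0(d$signal, shuffled))
  }
  stop("unknown decoy kind: ", kind)
}

#' Generate stage-targeted decoy sequences
#'
#' Each decoy violates exactly the rule named by its kind and is verified at
#' generation time to carry a valid signal peptide (so that only the
#' targeted stage rejects it) where applicable. `SHUFFLED_POSITIVE`
#' permutes a positive's mature residues preserving composition; such
#' decoys carry no rejection guarantee and are meant for pass-rate
#' tracking.
#'
#' @param kind one of TOO_SHORT, TOO_LONG, NO_CYS, BAD_SPACING, NO_SIGNAL,
#'   TM_LIKE, SHUFFLED_POSITIVE.
#' @param n number of decoys.
#' @param seed integer seed.
#' @return list with `records` and `truth` (`class` column is
#'   `REJECT(<kind>)`; `expected_stage` / `expected_reason` name where the
#'   cascade should drop the decoy, NA for SHUFFLED_POSITIVE).
#' @export
generate_decoys <- function(kind, n, seed = 1L) {
  kind <- match.arg(kind, DECOY_KINDS)
  set.seed(seed)
  residues <- vapply(seq_len(n), function(i) draw_decoy(kind), character(1))
  ids <- sprintf("decoy_%s_%03d", tolower(kind), seq_len(n))
  stage <- switch(kind,
                  TOO_SHORT = "size", TOO_LONG = "size",
                  NO_CYS = "motif", BAD_SPACING = "motif",
                  NO_SIGNAL = "secretion", TM_LIKE = "secretion",
                  SHUFFLED_POSITIVE = NA_character_)
  reason <- switch(kind,
                   TOO_SHORT = "TOO_SHORT", TOO_LONG = "TOO_LONG",
                   NO_CYS = "NO_MOTIF", BAD_SPACING = "NO_MOTIF",
                   NO_SIGNAL = "NO_SIGNAL", TM_LIKE = "HAS_TM",
                   SHUFFLED_POSITIVE = NA_character_)
  list(records = seq_records(ids, residues, kind = "protein"),
       truth = data.frame(id = ids, class = paste0("REJECT(", kind, ")"),
                          expected_stage = stage, expected_reason = reason,
                          stringsAsFactors = FALSE))
}

#' Generate a mutated defensin family for clustering tests
#'
#' One seed defensin plus `n_members - 1` point-mutated copies of its
#' mature region; cysteines are never mutated (and never introduced), so
#' framework positions are identical across the family and expected
#' pairwise identity is controlled by `mutation_rate`.
#'
#' @param n_members family size.
#' @param mutation_rate per-residue substitution probability in `[0, 1]`.
#' @param seed integer seed.
#' @param class archetype of the seed defensin (default `"II"`).
#' @param prefix id prefix.
#' @return list with `records` (mature sequences) and `truth`.
#' @export
generate_family <- function(n_members, mutation_rate, seed = 1L,
                            class = "II", prefix = "fam") {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  set.seed(seed)
  base <- gen_positive(class)
  mut <- function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(ch != "C" & stats::runif(length(ch)) < mutation_rate)
    for (k in hit) ch[k] <- sample(setdiff(BG_ALPHABET, ch[k]), 1)
    paste(ch, collapse = "")
  }
  residues <- c(base$mature,
                vapply(seq_len(max(0L, n_members - 1L)),
                       function(i) mut(base$mature), character(1)))
  ids <- sprintf("%s_%02d", prefix, seq_len(n_members))
  list(records = seq_records(ids, residues, kind = "protein"),
       truth = data.frame(id = ids, family = prefix,
                          is_seed = seq_len(n_members) == 1L,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic NMR-like ensemble around a helix-strand scaffold
#'
#' A deterministic stand-in for a deposited multi-model structure: one
#' idealised backbone (N, CA, C per residue along a curved trace) plus
#' `n_models - 1` copies with isotropic Gaussian coordinate noise of width
#' `noise` on a chosen residue span and `3 * noise` elsewhere (mimicking
#' flexible termini), each given a random rigid motion. Synthetic by
#' construction and labelled as such; it does not reproduce any deposited
#' ensemble.
#'
#' @param n_res residues (default 44, a class II-like length).
#' @param n_models models (default 20).
#' @param noise core coordinate noise SD in Angstrom.
#' @param core residue span treated as well-ordered.
#' @param seed integer seed.
#' @return `structure_ensemble`.
#' @export
generate_synthetic_ensemble <- function(n_res = 44L, n_models = 20L,
                                        noise = 0.3, core = c(10L, 36L),
                                        seed = 1L) {
  set.seed(seed)
  t <- seq(0, 4 * pi, length.out = n_res)
  ca <- cbind(3.8 * seq_len(n_res) * 0.8, 4 * sin(t), 4 * cos(t))
  n_at <- ca + matrix(rep(c(-0.8, 0.6, 0.2), each = n_res), ncol = 3)
  c_at <- ca + matrix(rep(c(0.9, 0.5, -0.3), each = n_res), ncol = 3)
  base <- matrix(NA_real_, n_res * 3L, 3L)
  base[seq(1, by = 3, length.out = n_res), ] <- n_at
  base[seq(2, by = 3, length.out = n_res), ] <- ca
  base[seq(3, by = 3, length.out = n_res), ] <- c_at
  resno <- rep(seq_len(n_res), each = 3L)
  elety <- rep(c("N", "CA", "C"), n_res)
  sd_atom <- ifelse(resno >= core[1] & resno <= core[2], noise, 3 * noise)
  coords <- array(NA_real_, c(nrow(base), 3L, n_models))
  coords[, , 1] <- base
  for (m in seq_len(n_models)[-1]) {
    jit <- base + matrix(stats::rnorm(length(base), sd = rep(sd_atom, 3)),
                         ncol = 3)
    R <- random_rotation()
    coords[, , m] <- sweep(jit %*% t(R), 2, stats::runif(3, -5, 5), "+")
  }
  structure_ensemble(coords, data.frame(resno = resno, elety = elety,
                                        resid = "ALA",
                                        stringsAsFactors = FALSE))
}

#' Draw a uniformly random proper rotation matrix
#' @return 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a three-family clustering benchmark with verified separation
#'
#' Draws one mutated family per archetype in `classes` and verifies the
#' identity structure the clustering benchmark assumes: every within-family
#' pair at `within_min` identity or better and every between-family pair
#' below `between_max` (identities from [global_align()] with the CD-HIT
#' style shorter-sequence denominator). Draws violating the bounds are
#' rejected and redrawn, so the returned set carries the stated separation
#' by construction for any seed. With `within_min` 0.8 and `between_max`
#' 0.5, greedy clustering at 0.70 must recover exactly one cluster per
#' family.
#'
#' @param members family size (default 10).
#' @param mutation_rate per-residue substitution probability (default 0.05).
#' @param seed integer seed.
#' @param classes archetypes seeding the families (default I, II, IV).
#' @param within_min,between_max identity bounds.
#' @param max_tries redraw budget.
#' @return list: `records` (all matures), `truth` (id, family, is_seed),
#'   `within_min_observed`, `between_max_observed`.
#' @export
generate_family_benchmark <- function(members = 10L, mutation_rate = 0.05,
                                      seed = 1L,
                                      classes = c("I", "II", "IV"),
                                      within_min = 0.8, between_max = 0.5,
                                      max_tries = 50L) {
  set.seed(seed)
  prefixes <- paste0("fam", LETTERS[seq_along(classes)])
  for (try in seq_len(max_tries)) {
    fams <- lapply(seq_along(classes), function(k) {
      base <- gen_positive(classes[k])
      mut <- function(s) {
        ch <- strsplit(s, "")[[1]]
        hit <- which(ch != "C" & stats::runif(length(ch)) < mutation_rate)
        for (q in hit) ch[q] <- sample(setdiff(BG_ALPHABET, ch[q]), 1)
        paste(ch, collapse = "")
      }
      residues <- c(base$mature, vapply(seq_len(members - 1L),
                                        function(i) mut(base$mature),
                                        character(1)))
      ids <- sprintf("%s_%02d", prefixes[k], seq_len(members))
      list(records = seq_records(ids, residues, kind = "protein"),
           truth = data.frame(id = ids, family = prefixes[k],
                              is_seed = seq_len(members) == 1L,
                              stringsAsFactors = FALSE))
    })
    records <- do.call(rbind, lapply(fams, `[[`, "records"))
    truth <- do.call(rbind, lapply(fams, `[[`, "truth"))
    wi <- 1; be <- 0
    n <- nrow(records)
    ok <- TRUE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        idy <- global_align(records$residues[i],
                            records$residues[j])$identity
        same <- truth$family[i] == truth$family[j]
        if (same) wi <- min(wi, idy) else be <- max(be, idy)
        if ((same && idy < within_min) || (!same && idy >= between_max)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok)
      return(list(records = records, truth = truth,
                  within_min_observed = wi, between_max_observed = be))
  }
  stop("could not draw families with the required identity separation in ",
       max_tries, " tries")
}
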