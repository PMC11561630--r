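mk_six <- function(tail_len) {
  paste0(strrep("A", tail_len), "CAACAAACAACAAGACAC")
}

test_that("tail length and topology drive the class assignment", {
  cfg <- classifier_config()
  expect_equal(assign_class(build_framework(mk_six(10), id = "a"), cfg)$label,
               "II")
  expect_equal(assign_class(build_framework(mk_six(30), id = "b"), cfg)$label,
               "IV")
  expect_equal(assign_class(build_framework(mk_six(2), id = "c"), cfg)$label,
               "I")
  un <- assign_class(build_framework(mk_six(6), id = "d"), cfg)
  expect_equal(un$label, "UNCLASSIFIED")
  expect_true("TAIL_GAP" %in% un$rationale)

  v <- generate_defensin("V", seed = 2)
  expect_equal(assign_class(build_framework(v$mature), cfg)$label, "V")
  iii <- generate_defensin("III", seed = 2)
  expect_equal(assign_class(build_framework(iii$mature), cfg)$label, "III")

  # tail-0 six-cysteine frameworks are unclassified unless opted into I
  fw0 <- build_framework(mk_six(0), id = "e")
  expect_equal(assign_class(fw0, cfg)$label, "UNCLASSIFIED")
  expect_equal(assign_class(fw0, classifier_config(tail0_as_I = TRUE))$label,
               "I")
})

test_that("every assignment carries a label and a nonempty rationale", {
  set.seed(4)
  for (i in 1:50) {
    s <- random_protein(sample(30:90, 1), sample(6:9, 1))
    if (!motif_scan(s)$match) next
    a <- assign_class(build_framework(s, id = "r"))
    expect_true(a$label %in% c("I", "II", "III", "IV", "V", "UNCLASSIFIED"))
    expect_gt(length(a$rationale), 0L)
  }
})

test_that("widening a tail range never unclassifies a classified sequence", {
  base <- classifier_config()
  wide <- classifier_config(tail_I = c(1, 5), tail_II = c(7, 14),
                            tail_IV = c(20, 55))
  for (tl in c(1:5, 7:14, 20:30)) {
    fw <- build_framework(mk_six(tl), id = "w")
    lab0 <- assign_class(fw, base)$label
    lab1 <- assign_class(fw, wide)$label
    if (lab0 != "UNCLASSIFIED") expect_equal(lab1, lab0)
  }
})

test_that("per-id overrides record an expert call", {
  fw <- build_framework(mk_six(6), id = "lond1")
  ov <- data.frame(id = "lond1", class = "V", note = "structure-aligned")
  a <- assign_class(fw, overrides = ov)
  expect_equal(a$label, "V")
  expect_true("OVERRIDE" %in% a$rationale)
})

test_that("gamma-core is the GXC triplet ending at framework C5", {
  fw <- build_framework("CAACAAACAACAAGACAC", id = "g")
  gc <- detect_gamma_core("CAACAAACAACAAGACAC", fw)
  expect_true(gc$found)
  expect_equal(gc$position, fw$assignment[5] - 2L)
  expect_true(detect_conserved_gly("CAACAAACAACAAGACAC", fw))

  noG <- "CAACAAACAACAAAACAC"
  fw2 <- build_framework(noG, id = "g2")
  expect_false(detect_gamma_core(noG, fw2)$found)
  expect_false(detect_conserved_gly(noG, fw2))

  # generators emit the gamma-core glycine by default
  s <- generate_defensin_set("I", 25, seed = 17)
  hits <- vapply(s$truth$mature, function(m)
    detect_gamma_core(m, build_framework(m))$found, logical(1))
  expect_true(all(hits))
  off <- generate_defensin("I", seed = 17, gamma_core = FALSE)
  expect_false(detect_gamma_core(off$mature,
                                 build_framework(off$mature))$found)
})

test_that("KCXN detection reports every overlapping occurrence", {
  expect_equal(detect_kcxn("AKCANG"), 2L)
  expect_equal(detect_kcxn("AAAAAA"), integer(0))
  expect_equal(detect_kcxn("KCKNKCAN"), c(1L, 5L))

  # brute-force scan oracle on random strings
  set.seed(12)
  for (i in 1:50) {
    s <- random_protein(40, 6)
    exp <- which(vapply(seq_len(nchar(s) - 3L), function(p) {
      ch <- strsplit(substring(s, p, p + 3L), "")[[1]]
      ch[1] == "K" && ch[2] == "C" && ch[4] == "N"
    }, logical(1)))
    expect_equal(detect_kcxn(s), as.integer(exp))
  }
})

test_that("net charge counts K/R against D/E and is additive", {
  expect_equal(net_charge("GGGG"), 0L)
  expect_equal(net_charge("KKRDE"), 1L)
  expect_equal(net_charge("HHHH"), 0L)   # histidine ignored
  set.seed(3)
  for (i in 1:100) {
    a <- random_protein(sample(1:40, 1), 0)
    b <- random_protein(sample(1:40, 1), 2)
    expect_equal(net_charge(paste0(a, b)), net_charge(a) + net_charge(b))
  }
})
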