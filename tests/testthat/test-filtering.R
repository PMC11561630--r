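test_that("size filter keeps the 30-130 band inclusively", {
  recs <- seq_records(c("s29", "s30", "s130", "s131"),
                      vapply(c(29, 30, 130, 131), function(n)
                        strrep("A", n), character(1)))
  rep <- size_filter(recs)
  expect_setequal(rep$kept, c("s30", "s130"))
  expect_equal(rep$removed$reason[rep$removed$id == "s29"], "TOO_SHORT")
  expect_equal(rep$removed$reason[rep$removed$id == "s131"], "TOO_LONG")
  # kept and removed partition the input
  expect_setequal(c(rep$kept, rep$removed$id), recs$id)

  empty <- size_filter(recs[0, ])
  expect_length(empty$kept, 0L)
  expect_equal(nrow(empty$removed), 0L)

  all60 <- seq_records(paste0("x", 1:5), rep(strrep("K", 60), 5))
  expect_length(size_filter(all60)$kept, 5L)
})

test_that("motif scan matches the minimal spacing example and rejects 5 cysteines", {
  s <- "CAACAAACAACAAAACAC"   # gaps 2,3,2,4,1
  res <- motif_scan(s)
  expect_true(res$match)
  expect_length(res$assignments, 1L)
  expect_equal(res$assignments[[1]], c(1L, 4L, 8L, 11L, 16L, 18L))

  expect_false(motif_scan("CAACAAACAACAAAAC")$match)  # only 5 cysteines
})

test_that("motif scan equals the exhaustive 6-subset oracle", {
  set.seed(101)
  for (i in 1:300) {
    s <- random_protein(sample(30:130, 1), sample(0:12, 1))
    got <- motif_scan(s)
    exp <- oracle_motif(s)
    expect_identical(got$match, exp$match)
    expect_setequal(lapply(got$assignments, paste, collapse = ","),
                    lapply(exp$assignments, paste, collapse = ","))
  }
})

test_that("heuristic secretion predictor follows its window rules", {
  pos <- paste0("MKK", "LLLLLLLL", "AGA", strrep("Q", 30))
  ann <- heuristic_signal_predict(pos, id = "p")
  expect_true(ann$has_signal_peptide)
  expect_false(ann$has_transmembrane)
  expect_equal(ann$cleavage_site, 14L)  # the AGA ends the signal peptide

  neg <- heuristic_signal_predict(strrep("S", 60))
  expect_false(neg$has_signal_peptide)
  expect_true(is.na(neg$cleavage_site))

  tm <- heuristic_signal_predict(
    paste0("MKK", "LLLLLLLL", "AGA", strrep("Q", 30), strrep("L", 10),
           strrep("Q", 10)))
  expect_true(tm$has_signal_peptide)
  expect_true(tm$has_transmembrane)

  # deterministic for fixed params
  expect_identical(heuristic_signal_predict(pos, id = "p"),
                   heuristic_signal_predict(pos, id = "p"))
})

test_that("secretion gate keeps signal-positive TM-negative records only", {
  recs <- seq_records(c("a", "b", "c"), rep(strrep("K", 40), 3))
  ann <- data.frame(id = c("a", "b", "c"),
                    has_signal_peptide = c(TRUE, TRUE, FALSE),
                    has_transmembrane = c(FALSE, TRUE, FALSE),
                    cleavage_site = c(20L, 20L, NA))
  rep <- secretion_gate(recs, ann)
  expect_equal(rep$kept, "a")
  expect_equal(rep$removed$reason[rep$removed$id == "b"], "HAS_TM")
  expect_equal(rep$removed$reason[rep$removed$id == "c"], "NO_SIGNAL")

  expect_error(secretion_gate(recs, ann[1:2, ]), "c")
})

test_that("mature extraction is exact and guards against short matures", {
  rec <- seq_records("p", strrep("A", 70))
  ann <- data.frame(id = "p", has_signal_peptide = TRUE,
                    has_transmembrane = FALSE, cleavage_site = 22L)
  mat <- extract_mature(rec, ann)
  expect_equal(nchar(mat$residues), 48L)
  expect_equal(mat$id, "p|mature")

  ann$cleavage_site <- 65L
  expect_error(extract_mature(rec, ann), "too short")

  # generator round-trip: mature ground truth is recovered exactly
  d <- generate_defensin("II", seed = 31)
  rec <- seq_records(d$id, d$precursor)
  ann <- heuristic_signal_predict(rec)
  expect_equal(extract_mature(rec, ann)$residues, d$mature)
})

test_that("cascade stages nest and reports always partition their input", {
  pos <- generate_defensin_set("I", 15, seed = 8)
  dec <- generate_decoys("TOO_LONG", 5, seed = 8)
  recs <- rbind(pos$records, dec$records)
  r1 <- size_filter(recs)
  s1 <- recs[recs$id %in% r1$kept, ]
  r2 <- motif_filter(s1)
  s2 <- s1[s1$id %in% r2$kept, ]
  expect_true(all(r2$kept %in% r1$kept))
  expect_setequal(c(r1$kept, r1$removed$id), recs$id)
  expect_setequal(c(r2$kept, r2$removed$id), s1$id)
  expect_setequal(r1$removed$reason, "TOO_LONG")
})
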