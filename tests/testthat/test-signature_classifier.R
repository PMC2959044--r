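# Signature engine, position-50 calls, insertion typing, octapeptides,
# rule-based class assignment.

sigs <- load_signatures()

test_that("signature definitions transcribe the printed windows", {
  expect_equal(sigs$NKL$start_column, 41L)
  expect_equal(signature_width(sigs$NKL), 5L)
  expect_equal(sigs$HOXL$start_column + signature_width(sigs$HOXL) - 1L, 58L)
  expect_equal(sigs$HOXL2$start_column, 16L)
  expect_equal(sigs$PRD$start_column + signature_width(sigs$PRD) - 1L, 26L)
  expect_equal(signature_width(sigs$SINE_ETSY), 4L)
  # the PRD and NKL windows are disjoint (16-26 vs 41-45), so one set of
  # residues can never satisfy both signatures at the same columns
  prd_cols <- sigs$PRD$start_column:(sigs$PRD$start_column + signature_width(sigs$PRD) - 1L)
  nkl_cols <- sigs$NKL$start_column:(sigs$NKL$start_column + signature_width(sigs$NKL) - 1L)
  expect_length(intersect(prd_cols, nkl_cols), 0)
})

test_that("NKL window matching follows the printed allowed sets", {
  base <- strrep("G", 60)
  hit <- paste0(substr(base, 1, 40), "ANLQV", substr(base, 46, 60))
  miss <- paste0(substr(base, 1, 40), "WNLQV", substr(base, 46, 60))
  expect_true(match_signature(hit, sigs$NKL))
  expect_false(match_signature(miss, sigs$NKL))
  gap <- paste0(substr(base, 1, 40), "AN-QV", substr(base, 46, 60))
  expect_false(match_signature(gap, sigs$NKL))
  unk <- paste0(substr(base, 1, 40), "ANXQV", substr(base, 46, 60))
  expect_false(match_signature(unk, sigs$NKL))
})

test_that("matcher agrees with a regex oracle on random windows", {
  set.seed(101)
  base <- strrep("G", 60)
  for (sig in sigs) {
    w <- signature_width(sig)
    n_hits <- 0
    for (i in 1:1000) {
      win <- random_window(w)
      seq60 <- paste0(substr(base, 1, sig$start_column - 1), win,
                      substr(base, sig$start_column + w, 60))
      got <- match_signature(seq60, sig)
      expect_identical(got, oracle_signature_regex(win, sig))
      n_hits <- n_hits + got
    }
  }
})

test_that("k-mer match counts equal exhaustive enumeration where feasible", {
  # full enumeration for windows of width <= 5; the NKL window admits
  # exactly 4*5*4*1*1 = 80 of the 20^5 5-mers
  expect_equal(signature_match_count(sigs$NKL), 80)
  expect_equal(enumerate_signature_matches(sigs$NKL), 80)
  for (name in c("NKL", "HOXL2", "SINE_ETSY")) {
    expect_equal(enumerate_signature_matches(sigs[[name]]),
                 signature_match_count(sigs[[name]]))
  }
})

test_that("position 50 calls Q/K/S/G, OTHER and UNKNOWN", {
  base <- strrep("A", 60)
  for (res in c("Q", "K", "S", "G")) {
    s <- base
    substr(s, 50, 50) <- res
    expect_equal(call_position50(s), res)
  }
  s <- base; substr(s, 50, 50) <- "-"
  expect_equal(call_position50(s), "UNKNOWN")
  expect_equal(call_position50(base), "OTHER")
})

test_that("insertion typing distinguishes TALE, atypical loop, helix-3", {
  mk <- function(ins) hd_record("MlX", strrep("A", 60), insertions = ins)
  expect_equal(classify_insertion(
    mk(data.frame(after_column = 22, inserted = "NLA"))), "TALE_TYPICAL")
  expect_equal(classify_insertion(
    mk(data.frame(after_column = 21, inserted = "N"))), "ATYPICAL_LOOP")
  expect_equal(classify_insertion(
    mk(data.frame(after_column = 32, inserted = "LP"))), "HELIX3")
  expect_equal(classify_insertion(mk(NULL)), "NONE")
  expect_equal(classify_insertion(
    mk(data.frame(after_column = 55, inserted = "Q"))), "NONE")
})

test_that("octapeptide scanning scores the printed examples", {
  expect_equal(detect_octapeptide("SSISSLLS")$confidence, "CLEAR")
  expect_equal(detect_octapeptide("HSIDDILG")$confidence, "CLEAR")
  expect_equal(detect_octapeptide("AAAAAAAA")$confidence, "NONE")
  # scanning finds the motif inside a longer upstream peptide
  hit <- detect_octapeptide("MNPQSSISSLLSKRT")
  expect_equal(hit$seq, "SSISSLLS")
  expect_equal(hit$confidence, "CLEAR")
  expect_equal(detect_octapeptide("SHORT")$confidence, "NONE")
})

test_that("class assignment follows evidence precedence and flags conflicts", {
  base <- strrep("G", 60)
  # SIX domain + NKL signature: the domain wins, the disagreement is flagged
  nkl_res <- paste0(substr(base, 1, 40), "ANLQV", substr(base, 46, 60))
  six <- hd_record("MlSIX36", nkl_res, secondary_domains = "SIX")
  a <- assign_class(six, signatures = sigs)
  expect_equal(a$hd_class, "SINE")
  expect_true(a$conflict)
  expect_true(all(c("SECONDARY_DOMAIN", "SIGNATURE") %in% a$evidence$kind))

  pou <- hd_record("MlPou1", base, secondary_domains = "POU_SPECIFIC")
  a2 <- assign_class(pou, tree_hint = "POU", signatures = sigs)
  expect_equal(a2$hd_class, "POU")
  expect_false(a2$conflict)

  blank <- hd_record("MlHD01", base)
  a3 <- assign_class(blank, signatures = sigs)
  expect_equal(a3$hd_class, "UNCLASSIFIED")
  expect_true(is.na(a3$subclass))
  expect_equal(nrow(a3$evidence), 0L)

  # a typical TALE loop insertion implies TALE ahead of any signature
  tale <- hd_record("MlPbx", base,
                    insertions = data.frame(after_column = 22, inserted = "NLA"))
  expect_equal(assign_class(tale, signatures = sigs)$hd_class, "TALE")
})

test_that("ANTP and PRD subclasses derive from signatures and position 50", {
  base <- strrep("G", 60)
  nkl_res <- paste0(substr(base, 1, 40), "ANLQV", substr(base, 46, 60))
  a <- assign_class(hd_record("MlA1", nkl_res), signatures = sigs)
  expect_equal(a$hd_class, "ANTP")
  expect_equal(a$subclass, "NKL")

  hoxl2_res <- paste0(substr(base, 1, 15), "LEAE", substr(base, 20, 60))
  b <- assign_class(hd_record("MlA2", hoxl2_res), signatures = sigs)
  expect_equal(b$hd_class, "ANTP")
  expect_equal(b$subclass, "EXTENDED_HOX")

  # NKL + HOXL2 together: NKL is the subclass, both remain as evidence
  both <- paste0(substr(hoxl2_res, 1, 40), "ANLQV", substr(base, 46, 60))
  d <- assign_class(hd_record("MlA3", both), signatures = sigs)
  expect_equal(d$subclass, "NKL")
  expect_setequal(d$evidence$detail[d$evidence$kind == "SIGNATURE"],
                  c("NKL", "HOXL2"))

  prd_res <- paste0(substr(base, 1, 15), "LESSLSASKFP",
                    substr(base, 27, 60))
  substr(prd_res, 50, 50) <- "Q"
  p <- assign_class(hd_record("MlP1", prd_res), signatures = sigs)
  expect_equal(p$hd_class, "PRD")
  expect_equal(p$subclass, "Q50")
})

test_that("assignment is deterministic", {
  set.seed(5)
  recs <- lapply(1:10, function(i) {
    hd_record(sprintf("Ml%03d", i),
              paste(sample(AA20_test, 60, TRUE), collapse = ""))
  })
  a1 <- classify_records(recs, signatures = sigs)
  a2 <- classify_records(recs, signatures = sigs)
  expect_identical(assignments_table(a1), assignments_table(a2))
  expect_identical(lapply(a1, `[[`, "evidence"), lapply(a2, `[[`, "evidence"))
})
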