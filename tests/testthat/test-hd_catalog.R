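# Record types, alignment/catalog readers, intron notation, class tallies.

test_that("hd_record validates and normalizes its fields", {
  r <- hd_record("MlANTP19", strrep("a", 60))
  expect_equal(r$species_prefix, "Ml")
  expect_equal(r$residues, strrep("A", 60))
  expect_warning(r2 <- hd_record("MlZ", paste0(strrep("A", 59), "?")),
                 "mapped to 'X'")
  expect_equal(substr(r2$residues, 60, 60), "X")
  expect_error(hd_record("MlZ", strrep("A", 59)), "exactly 60 columns")
  expect_error(hd_record("MlZ", strrep("A", 60),
                         insertions = data.frame(after_column = 60, inserted = "Q")),
               "1..59")
  expect_error(hd_record("MlZ", strrep("A", 60),
                         scaffold = list(scaffold_id = "s", start = 10, end = 5,
                                         strand = "+")),
               "start < end")
})

test_that("FASTA alignment reading parses prefixes, insertions and errors", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">MlAAA", strrep("A", 60), ">HsBBB", strrep("C", 60)), tmp)
  recs <- read_hd_alignment(tmp)
  expect_length(recs, 2)
  expect_equal(vapply(recs, `[[`, "", "species_prefix"), c("Ml", "Hs"))

  # 63-residue TALE sequence with a declared loop insertion normalizes to 60
  tale <- paste0(strrep("A", 22), "NLA", strrep("G", 38))
  writeLines(c(">MlPbx insert(NLA) 23", tale, ">MlX", strrep("A", 60)), tmp)
  recs <- read_hd_alignment(tmp)
  expect_equal(nchar(recs[[1]]$residues), 60L)
  expect_equal(recs[[1]]$insertions$after_column, 22L)
  expect_equal(recs[[1]]$insertions$inserted, "NLA")

  writeLines(c(">MlA", strrep("A", 60), ">MlA", strrep("C", 60)), tmp)
  expect_error(read_hd_alignment(tmp), "duplicate")
  writeLines(c(">MlA", strrep("A", 61)), tmp)
  expect_error(read_hd_alignment(tmp), "no declared insertions")
  writeLines(c(">MlA", strrep("A", 58)), tmp)
  expect_error(read_hd_alignment(tmp), "shape")
})

test_that("Phylip alignment reading honours the header", {
  tmp <- withr::local_tempfile(fileext = ".phy")
  seqs <- replicate(7, paste(sample(c("A", "C", "D", "E"), 60, TRUE), collapse = ""))
  writeLines(c(" 7 60", paste0(sprintf("Ml%05d  ", 1:7), seqs)), tmp)
  recs <- read_hd_alignment(tmp, format = "phylip")
  expect_length(recs, 7)
  expect_equal(vapply(recs, function(r) nchar(r$residues), 1L), rep(60L, 7))
})

test_that("alignment write/read round-trip preserves id, residues, insertions", {
  set.seed(11)
  recs <- lapply(1:6, function(i) {
    ins <- if (i %% 2 == 0) {
      data.frame(after_column = sample(1:59, 1),
                 inserted = paste(sample(AA20_test, sample(1:3, 1), TRUE),
                                  collapse = ""))
    }
    hd_record(sprintf("Ml%04d", i),
              paste(sample(c(AA20_test, "-"), 60, TRUE), collapse = ""),
              insertions = ins)
  })
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_hd_fasta(recs, tmp)
  back <- read_hd_alignment(tmp)
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$id, recs[[i]]$id)
    expect_equal(back[[i]]$residues, recs[[i]]$residues)
    expect_equal(back[[i]]$insertions, recs[[i]]$insertions)
  }
})

test_that("intron notation parses, rejects bad boundaries, and round-trips", {
  x <- parse_intron_notation("2,47/48")
  expect_equal(x$codon, c(2L, 47L))
  expect_equal(x$placement, c("WITHIN", "BETWEEN_NEXT"))
  y <- parse_intron_notation("57*")
  expect_equal(y$codon, 57L)
  expect_equal(y$flag, "*")
  expect_equal(nrow(parse_intron_notation("")), 0L)
  expect_error(parse_intron_notation("47/49"), "consecutive")

  # formatter is the inverse for generated notations
  set.seed(4)
  for (i in 1:50) {
    n <- sample(0:3, 1)
    toks <- vapply(seq_len(n), function(j) {
      c1 <- sample(1:62, 1)
      tok <- if (runif(1) < 0.5) paste0(c1, "/", c1 + 1) else as.character(c1)
      if (runif(1) < 0.2) paste0(tok, "*") else tok
    }, "")
    notation <- paste(toks, collapse = ",")
    expect_equal(format_intron_notation(parse_intron_notation(notation)), notation)
  }
})

test_that("the packaged catalog loads 76 annotated records", {
  recs <- read_catalog(system.file("extdata", "table1_catalog.tsv",
                                   package = "homeorep"))
  expect_length(recs, 76)
  ids <- vapply(recs, `[[`, "", "id")
  meis <- recs[[which(ids == "MlMeis")]]
  expect_setequal(meis$secondary_domains, c("MEIS_A", "MEIS_D"))
  expect_equal(meis$insertions$after_column, 22L)
  expect_equal(meis$insertions$inserted, "HLT")
  expect_equal(meis$introns$codon, c(25L, 51L))
  expect_equal(meis$introns$placement, c("BETWEEN_NEXT", "WITHIN"))
  # '*' on an accession is preserved as a flag
  a65 <- recs[[which(ids == "MlANTP65")]]
  expect_true("ACCESSION_FLAGGED" %in% a65$flags)
  expect_equal(a65$accession, "HM444081")
  # catalog round-trip through the writer
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(recs, tmp)
  back <- read_catalog(tmp)
  expect_equal(vapply(back, `[[`, "", "id"), ids)
  expect_equal(tally_classes(back), tally_classes(recs))
})

test_that("catalog parsing errors name the offending input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tdomain\tsignature\tintron_codons\taccession",
               "NOTACLASS\t\t\t\t", "MlX\t\t\t\t"), tmp)
  expect_error(read_catalog(tmp), "NOTACLASS")
  writeLines("name\tdomain\tsignature\tintron_codons\taccession", tmp)
  expect_length(read_catalog(tmp), 0)
})

test_that("class tallies cover all classes and sum to the input size", {
  recs <- read_catalog(system.file("extdata", "table1_catalog.tsv",
                                   package = "homeorep"))
  tl <- tally_classes(recs)
  expect_equal(tl[["ANTP"]], 22L)
  expect_equal(tl[["PRD"]], 7L)
  expect_equal(tl[["TALE"]], 3L)
  expect_equal(tl[["POU"]], 4L)
  expect_equal(tl[["LIM"]], 4L)
  expect_equal(tl[["SINE"]], 18L)
  expect_equal(tl[["UNCLASSIFIED"]], 18L)
  expect_equal(sum(tl), 76L)
  expect_equal(sum(tally_classes(list())), 0L)
  three <- lapply(1:3, function(i) hd_record(paste0("Ml", i), strrep("A", 60),
                                             hd_class = "SINE"))
  t3 <- tally_classes(three)
  expect_equal(t3[["SINE"]], 3L)
  expect_equal(sum(t3), 3L)
})
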