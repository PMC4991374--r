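test_that("IUPAC matching follows the standard degeneracy sets", {
  expect_true(iupac_char_match("A", "R"))
  expect_false(iupac_char_match("C", "R"))
  expect_true(iupac_char_match("C", "Y"))
  # full 5 x 15 truth table against an independently written table;
  # sequence 'N' matches nothing, including consensus 'N'
  for (base in c("A", "C", "G", "T", "N")) {
    for (code in names(ORACLE_IUPAC)) {
      expected <- base != "N" && base %in% ORACLE_IUPAC[[code]]
      expect_identical(iupac_char_match(base, code), expected)
    }
  }
  expect_error(iupac_char_match("X", "R"), "base")
  expect_error(iupac_char_match("A", "Z"), "code")
  expect_error(iupac_motif("bad", "GTAZ"), "invalid")
  expect_error(iupac_motif("bad", ""), "non-empty")
})

test_that("scanner reports every overlapping hit with exact coordinates", {
  p <- gen_promoters(1, length = 1000, seed = 13,
                     spikes = data.frame(gene_index = 1, word = "GTAAACA",
                                         offset = 108, motif = "DBE"))
  hits <- scan_motifs(p$promoters, dbe_motifs())
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 108L)
  expect_identical(hits$word, "GTAAACA")

  adj <- scan_motifs("GTAAACAGTAAACA", iupac_motif("DBE", "GTAAACA"))
  expect_identical(adj$start, c(1L, 8L))

  # motif longer than sequence: warning, empty result
  expect_warning(none <- scan_motifs("ACGT", iupac_motif("long", "ACGTACGT")),
                 "longer")
  expect_identical(nrow(none), 0L)

  # self-overlapping pattern: all occurrences reported
  aa <- scan_motifs("AAAA", iupac_motif("m", "AA"))
  expect_identical(aa$start, 1:3)

  # masked bases match nothing
  expect_identical(nrow(scan_motifs("GTANACA", iupac_motif("DBE", "GTAAACA"))),
                   0L)
  expect_identical(nrow(scan_motifs("GTANACA", iupac_motif("n", "GTANACA"))),
                   0L)
})

test_that("scanner agrees with a naive oracle and with Biostrings", {
  set.seed(37)
  seq10k <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
  for (cons in c("GTAAACA", "RTAAAYA", "TGATAAG", "WSNKYR")) {
    got <- scan_motifs(suppressWarnings(promoter_set("s", seq10k)),
                       iupac_motif("m", cons))$start
    expect_identical(as.integer(got), naive_scan_positions(seq10k, cons))
    bs <- Biostrings::start(
      Biostrings::matchPattern(cons, Biostrings::DNAString(seq10k),
                               fixed = FALSE))
    expect_identical(as.integer(got), as.integer(bs))
  }
  # determinism: repeated scans are identical
  p <- suppressWarnings(promoter_set("s", seq10k))
  expect_identical(scan_motifs(p, dbe_motifs()), scan_motifs(p, dbe_motifs()))
})

test_that("degenerate DBE matches a superset of the strict word's positions", {
  set.seed(41)
  for (rep in 1:5) {
    p <- gen_promoters(20, length = 1000, seed = 500 + rep)$promoters
    strict <- scan_motifs(p, iupac_motif("DBE", "GTAAACA"))
    loose <- scan_motifs(p, dbe_motifs(loose = TRUE))
    strict_keys <- paste(strict$gene, strict$start)
    loose_keys <- paste(loose$gene, loose$start)
    expect_true(all(strict_keys %in% loose_keys))
  }
  # classification under loose mode is a superset of strict mode, for
  # either strict orientation word (TGTTTAC is covered by TRTTTAY)
  spikes <- data.frame(gene_index = 1:2, word = c("GTAAACA", "TGTTTAC"),
                       offset = c(100, 200))
  p2 <- gen_promoters(4, length = 1000, spikes = spikes, seed = 43)$promoters
  strict_cl <- classify_promoters(p2)
  loose_cl <- classify_promoters(p2, dbe = dbe_motifs(loose = TRUE))
  expect_true(all(strict_cl$genes$gene[strict_cl$genes$dbe] %in%
                    loose_cl$genes$gene[loose_cl$genes$dbe]))
})

test_that("classification partitions genes by planted DBE/DAE content", {
  spikes <- data.frame(
    gene_index = c(1, 2, 3, 4, 5, 6, 7, 7, 8, 8),
    word = c("GTAAACA", "TGTTTAC", "GTAAACA",        # DBE only: genes 1-3
             "TGATAAG", "CTTATCA", "TGATAAG",        # DAE only: genes 4-6
             "GTAAACA", "CTTATCA", "TGTTTAC", "TGATAAG"), # both: 7, 8
    offset = c(108, 300, 50, 400, 85, 700, 100, 500, 200, 800))
  p <- gen_promoters(10, length = 1000, spikes = spikes, seed = 17)
  cl <- classify_promoters(p$promoters)
  expect_identical(unname(cl$counts),
                   c(3L, 3L, 2L, 2L)) # DBE_only, DAE_only, both, neither
  expect_identical(sum(cl$counts), 10L)
  expect_identical(cl$genes$category[7], "both")

  # empty motif definitions: everything is 'neither'
  cl0 <- classify_promoters(p$promoters, dbe = list(), dae = list())
  expect_identical(unname(cl0$counts["neither"]), 10L)

  both_lines <- format_both_report(cl)
  expect_length(both_lines, 2)
  expect_match(both_lines[1], "\\[GTAAACA: 100\\]")
})

test_that("random spiking is recovered exactly from generator ground truth", {
  set.seed(53)
  words <- c(DBE = "GTAAACA", DBE = "TGTTTAC", DAE = "TGATAAG",
             DAE = "CTTATCA")
  pick <- sample(4, 120, replace = TRUE)
  spikes <- data.frame(gene_index = sample(200, 120, replace = FALSE),
                       word = unname(words[pick]),
                       motif = names(words)[pick],
                       offset = sample(900, 120, replace = TRUE))
  p <- gen_promoters(200, length = 1000, spikes = spikes, seed = 59)
  cl <- classify_promoters(p$promoters)
  truth <- p$truth$spikes
  want_dbe <- unique(truth$gene[truth$motif == "DBE"])
  want_dae <- unique(truth$gene[truth$motif == "DAE"])
  expect_setequal(cl$genes$gene[cl$genes$dbe], want_dbe)
  expect_setequal(cl$genes$gene[cl$genes$dae], want_dae)
  # every spike recovered at its exact offset
  hits_keys <- paste(cl$hits$gene, cl$hits$word, cl$hits$start)
  expect_true(all(paste(truth$gene, truth$word, truth$offset) %in% hits_keys))
  expect_identical(nrow(cl$hits), nrow(truth))
})

test_that("FASTA I/O round-trips, warns off-length, rejects duplicates", {
  p <- gen_promoters(3, length = 1000, seed = 61)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_promoter_fasta(p$promoters, f)
  back <- read_promoter_fasta(f)
  expect_identical(back$gene, p$promoters$gene)
  expect_identical(back$sequence, p$promoters$sequence)

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">short gene", paste(rep("ACGT", 200), collapse = "")), f2)
  expect_warning(pp <- read_promoter_fasta(f2), "nominal")
  expect_identical(pp$length, 800L)

  f3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">dup", "ACGTACGT", ">dup", "ACGTACGT"), f3)
  expect_error(suppressWarnings(read_promoter_fasta(f3)), "duplicate")

  expect_error(promoter_set("g1", "ACGTQ"), "outside")
  # U is mapped to T
  expect_identical(suppressWarnings(promoter_set("g1", "acgu"))$sequence,
                   "ACGT")
})

test_that("5'-offset and TSS-distance coordinates are consistent", {
  # a 7-mer ending at the window's 3' edge (the TSS) is 1 nt upstream
  expect_identical(upstream_offset(994, 7, 1000), 1)
  # converting back and forth is the identity
  starts <- c(1L, 108L, 500L, 994L)
  d <- upstream_offset(starts, 7, 1000)
  expect_equal(1000 - d - 7 + 2, as.numeric(starts))
})
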