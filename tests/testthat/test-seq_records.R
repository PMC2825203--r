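test_that("read_fasta parses records in order and validates the alphabet", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">one first record", "ACGTACGT", ">two", "GGGG", "CCCC"), f)
  seqs <- read_fasta(f)
  expect_length(seqs, 2)
  expect_identical(names(seqs), c("one", "two"))
  expect_identical(as.character(seqs[["two"]]), "GGGGCCCC")

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_warning(res <- read_fasta(empty), "no records")
  expect_length(res, 0)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">broken", "AC1T"), bad)
  expect_error(read_fasta(bad), "broken")
  expect_error(read_fasta("/nonexistent/file.fasta"), "not found")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">same", "ACGT", ">same", "GGTT"), dup)
  expect_error(read_fasta(dup), "duplicate")
})

test_that("trim_polya removes qualifying tails and is idempotent", {
  expect_identical(trim_polya("ACGT"), list(trimmed = "ACGT", polya_len = 0L))

  tail12 <- paste0("ACGT", strrep("A", 12))
  expect_identical(trim_polya(tail12),
                   list(trimmed = "ACGT", polya_len = 12L))

  expect_warning(res <- trim_polya(strrep("A", 20)), "whole sequence")
  expect_identical(res$trimmed, "")
  expect_identical(res$polya_len, 20L)

  # one non-A tolerated per 10 trailing bases
  noisy <- paste0("ACGT", strrep("A", 8), "G", strrep("A", 6))
  expect_identical(suppressWarnings(trim_polya(noisy))$polya_len, 15L)

  # below min_run nothing happens
  expect_identical(trim_polya(paste0("ACGT", strrep("A", 5)))$polya_len, 0L)

  set.seed(11)
  for (i in 1:20) {
    s <- paste0(random_dna_str(sample(5:40, 1)),
                strrep("A", sample(0:20, 1)))
    once <- suppressWarnings(trim_polya(s))
    twice <- suppressWarnings(trim_polya(once$trimmed))
    expect_identical(twice$trimmed, once$trimmed)
    expect_identical(twice$polya_len, 0L)
  }
})

test_that("translate_cds follows the standard code with UGA read-through", {
  expect_identical(as.character(translate_cds("ATG")), "M")
  expect_identical(as.character(translate_cds("ATGTGAGCGTAA")), "M")
  rt <- translate_cds("ATGTGAGCGTAA", readthrough_uga = 1)
  expect_identical(as.character(rt), "MUA")
  expect_identical(attr(rt, "uga_readthroughs"), 1L)
  # UAA/UAG always terminate, even with allowance left
  expect_identical(as.character(translate_cds("ATGTAAGCG", readthrough_uga = 5)),
                   "M")
  expect_identical(as.character(translate_cds("ATGNNN")), "MX")
  expect_error(translate_cds("ATGA"), "multiple of 3")
})

test_that("find_longest_orf picks the longest ATG-initiated frame", {
  o <- find_longest_orf("TTATGAAATAATT")
  expect_identical(o$protein, "MK")
  expect_identical(o$start, 3L)
  expect_identical(o$end, 11L)
  expect_identical((o$end - o$start + 1L) %% 3L, 0L)

  expect_null(find_longest_orf("CCCCCC"))

  # read-through extends past an internal UGA
  s <- paste0("GG", "ATG", "TGA", "AAA", "AAA", "TAA")
  expect_identical(find_longest_orf(s)$protein, "M")
  o2 <- find_longest_orf(s, readthrough_uga = 1)
  expect_identical(o2$protein, "MUKK")
  expect_identical(o2$uga_readthroughs, 1L)

  # open-ended ORFs only when allowed
  open <- "ATGAAAAAG"
  expect_null(find_longest_orf(open))
  expect_identical(find_longest_orf(open, allow_open_end = TRUE)$protein,
                   "MKK")

  # reverse strand behind the flag
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TTATGAAAAAATAATT")))
  expect_null(find_longest_orf(rc))
  o3 <- find_longest_orf(rc, forward_only = FALSE)
  expect_identical(o3$protein, "MKK")
  expect_identical(o3$strand, "-")
})

test_that("ORF finding then translation recovers a planted protein", {
  set.seed(5)
  for (i in 1:15) {
    prot <- paste0("M", make_lea_like_protein(sample(40:80, 1),
                                              n_k11_runs = 1))
    est <- make_est(prot, sl_name = NULL, polya_len = 0)
    orf <- find_longest_orf(est$sequence)
    expect_identical(orf$protein, prot)
    cds <- substr(est$sequence, orf$start, orf$end)
    expect_identical(as.character(translate_cds(cds)), prot)
  }
})

test_that("global alignment is optimal, symmetric and deterministic", {
  a <- global_align("GATTACA", "GATTACA")
  expect_identical(a$score, 7)
  expect_identical(a$identity_percent, 100)

  b <- global_align("ACGT", "")
  expect_identical(b$score, -4)
  expect_identical(b$identity_percent, 0)

  # gap removal recovers the inputs
  g <- global_align("ACGTAC", "AGTC")
  expect_identical(gsub("-", "", g$aligned_a), "ACGTAC")
  expect_identical(gsub("-", "", g$aligned_b), "AGTC")
  expect_identical(nchar(g$aligned_a), nchar(g$aligned_b))

  # exhaustive-search oracle on short pairs, plus score symmetry
  set.seed(21)
  for (i in 1:20) {
    x <- random_dna_str(sample(1:6, 1))
    y <- random_dna_str(sample(1:6, 1))
    s <- global_align(x, y)$score
    expect_identical(s, oracle_align_score(x, y))
    expect_identical(s, global_align(y, x)$score)
  }
})
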