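test_that("promoter coordinates skip zero and close the printed span", {
  expect_identical(promoter_to_offset(-869, -869), 0L)
  expect_identical(promoter_to_offset(+1, -869), 869L)
  expect_identical(promoter_to_offset(+421, -869), 1289L)
  expect_identical(promoter_span_length(-869, 421), 1290L)
  expect_identical(promoter_span_length(-1, 1), 2L)
  expect_error(promoter_to_offset(0, -869), "skips 0")
  expect_error(promoter_to_offset(-900, -869, 1290), "upstream")
  expect_error(promoter_to_offset(500, -869, 1290), "beyond")
})

test_that("offset mapping is a bijection and -1/+1 are adjacent", {
  origin <- -25L
  n <- 60L
  offs <- 0:(n - 1)
  pos <- offset_to_promoter(offs, origin)
  expect_false(any(pos == 0))
  expect_identical(promoter_to_offset(pos, origin, n), offs)
  expect_identical(diff(promoter_to_offset(c(-1L, 1L), origin)), 1L)
})

test_that("A/T tract finding returns maximal W-runs", {
  s <- genomic_sequence("GGAATTTAGG")
  tr <- find_at_tracts(s, 5)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$length, 6L)
  expect_identical(find_at_tracts(genomic_sequence("GCGCGC"), 2)$length,
                   integer(0))
  # maximality: flanks of every tract are G/C or the sequence ends
  s2 <- gen_control_sequence(500, gc = 0.4, seed = 11)
  tr2 <- find_at_tracts(s2, 5)
  b <- strsplit(s2$bases, "")[[1]]
  for (k in seq_len(nrow(tr2))) {
    i <- promoter_to_offset(tr2$start[k], s2$origin) + 1
    j <- promoter_to_offset(tr2$end[k], s2$origin) + 1
    expect_true(all(b[i:j] %in% c("A", "T")))
    if (i > 1) expect_true(b[i - 1] %in% c("G", "C"))
    if (j < length(b)) expect_true(b[j + 1] %in% c("G", "C"))
  }
})

test_that("tract finding is invariant under A<->T substitution", {
  s <- gen_control_sequence(400, gc = 0.5, seed = 3)
  swapped <- chartr("AT", "TA", s$bases)
  t1 <- find_at_tracts(s, 5)
  t2 <- find_at_tracts(genomic_sequence(swapped, origin = s$origin), 5)
  expect_identical(t1[c("start", "end", "length")],
                   t2[c("start", "end", "length")])
})

test_that("reverse complement is an involution and mirrors tracts", {
  s <- gen_control_sequence(300, gc = 0.45, seed = 5, origin = -100L)
  s$features <- data.frame(name = "f", start = -50L, end = 20L)
  rc <- reverse_complement(s)
  back <- reverse_complement(rc)
  expect_identical(back$bases, s$bases)
  expect_identical(back$origin, s$origin)
  expect_identical(back$features$start, s$features$start)
  # palindrome
  expect_identical(reverse_complement(genomic_sequence("ACGT"))$bases,
                   "ACGT")
  # tract list mirrors: lengths agree, coordinates negate
  t_f <- find_at_tracts(s, 5)
  t_r <- find_at_tracts(rc, 5)
  expect_identical(sort(t_r$length), sort(t_f$length))
  expect_setequal(t_r$start, -t_f$end)
})

test_that("FASTA round trip preserves sequence; bad symbols rejected", {
  tmp <- tempfile(fileext = ".fa")
  s <- gen_control_sequence(120, seed = 9, origin = -60L)
  write_fasta(s, tmp)
  back <- read_fasta(tmp, origin = -60L)
  expect_identical(back$bases, s$bases)
  tmp2 <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGTN"), tmp2)
  expect_error(read_fasta(tmp2), "ambiguity")
  writeLines(c(">y", "acgt"), tmp2)
  expect_identical(read_fasta(tmp2)$bases, "ACGT")
})

test_that("subsequence extraction keeps the promoter frame", {
  p <- synthetic_promoter()
  prr2 <- subseq_promoter(p, -137, -64)
  expect_identical(length(prr2), promoter_span_length(-137L, -64L))
  expect_identical(prr2$origin, -137L)
  expect_true("PRRII" %in% prr2$features$name)
})
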