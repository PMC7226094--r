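test_that("anchors locate VL/VH boundaries on both strands", {
  lib <- tiny_library(revcomp_frac = 0)
  tpl <- lib$template
  exact <- simulate_reads(lib, c(C001 = 1, C002 = 1), seed = 3)
  seg <- locate_anchors(exact, tpl)
  expect_false(any(seg$anchor_fail))
  expect_equal(seg$vl_nt, rep(tpl$vl_nt, 2))
  expect_equal(seg$vh_nt,
               lib$clones$vh_nt[match(exact$clone_id, lib$clones$clone_id)])

  # reverse complement of an exact read yields the same segments
  rc <- exact
  rc$seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rc$seq)))
  rc$qual <- vapply(rc$qual,
                    function(q) paste(rev(strsplit(q, "")[[1]]), collapse = ""),
                    "")
  seg_rc <- locate_anchors(rc, tpl)
  expect_equal(seg_rc$vl_nt, seg$vl_nt)
  expect_equal(seg_rc$vh_nt, seg$vh_nt)
  expect_equal(seg_rc$vl_qual, seg$vl_qual)
  expect_true(all(seg_rc$orientation == "rev"))

  # a read with the linker deleted cannot be segmented
  no_linker <- tibble::tibble(
    read_id = "r1",
    seq = paste0(tpl$flank5, tpl$vl_nt, tpl$vh_nt, tpl$flank3),
    qual = strrep("I", nchar(tpl$flank5) + nchar(tpl$vl_nt) +
                    nchar(tpl$vh_nt) + nchar(tpl$flank3))
  )
  expect_true(locate_anchors(no_linker, tpl)$anchor_fail)
})

test_that("chain validation flags frameshifts, stops, quality and length", {
  lib <- tiny_library()
  tpl <- lib$template

  # 301-nt segment: not a codon multiple
  fs <- manual_segments(substr(tpl$vl_nt, 1, 301), tpl$vh_nt)
  expect_true(validate_chains(fs, tpl)$frameshift)

  # in-frame internal TAA
  vl_stop <- paste0(substr(tpl$vl_nt, 1, 30), "TAA",
                    substr(tpl$vl_nt, 34, nchar(tpl$vl_nt)))
  st <- validate_chains(manual_segments(vl_stop, tpl$vh_nt), tpl)
  expect_true(st$internal_stop)

  # low mean quality trips the Q20 floor
  lq <- manual_segments(tpl$vl_nt, tpl$vh_nt,
                        vl_qual = strrep("+", nchar(tpl$vl_nt)), # Q10
                        vh_qual = strrep("+", nchar(tpl$vh_nt)))
  expect_true(validate_chains(lq, tpl)$low_quality)

  # in-frame 3-nt deletion: no frameshift, but defective chain length
  del3 <- manual_segments(substr(tpl$vl_nt, 4, nchar(tpl$vl_nt)), tpl$vh_nt)
  v <- validate_chains(del3, tpl)
  expect_false(v$frameshift)
  expect_true(v$defective_chain)

  # clean simulated reads carry no flags
  clean <- simulate_reads(lib, c(C001 = 3), seed = 8)
  vc <- validate_chains(locate_anchors(clean, tpl), tpl)
  expect_true(all(vc$qc_pass))
})

test_that("mutation classification separates designed from unintended", {
  lib <- tiny_library()
  tpl <- lib$template
  sch <- tpl$scheme
  wt <- manual_segments(tpl$vl_nt, tpl$vh_nt)
  wt <- classify_mutations(validate_chains(wt, tpl), tpl)
  expect_equal(wt$unintended, 0L)
  wt_vh <- strsplit(tpl$vh_aa, "")[[1]]
  expect_equal(wt$assignments[[1]], wt_vh[sch$position])

  # a library clone differs only at designed, codon-compatible residues
  cl <- manual_segments(tpl$vl_nt, lib$clones$vh_nt[2])
  cl <- classify_mutations(validate_chains(cl, tpl), tpl)
  expect_equal(cl$unintended, 0L)
  expect_equal(cl$assignments[[1]], lib$clones$assignments[[2]])

  # one extra substitution outside the designed positions -> unintended 1
  vh_codons <- substring(lib$clones$vh_nt[2], seq(1, 358, 3), seq(3, 360, 3))
  vh_codons[10] <- if (vh_codons[10] == "GCT") "GAT" else "GCT" # pos 10 not designed
  mut <- manual_segments(tpl$vl_nt, paste(vh_codons, collapse = ""))
  mut <- classify_mutations(validate_chains(mut, tpl), tpl)
  expect_equal(mut$unintended, 1L)

  # a designed residue outside its degenerate codon set counts as unintended
  pos <- sch$position[1]
  bad_res <- setdiff(LETTERS[LETTERS %in% Biostrings::AA_STANDARD],
                     sch$aa_set[[1]])[1]
  bad_codon <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE == bad_res][1]
  vh_codons2 <- substring(tpl$vh_nt, seq(1, 358, 3), seq(3, 360, 3))
  vh_codons2[pos] <- bad_codon
  off <- manual_segments(tpl$vl_nt, paste(vh_codons2, collapse = ""))
  off <- classify_mutations(validate_chains(off, tpl), tpl)
  expect_equal(off$unintended, 1L)
})

test_that("strict and relaxed filters keep the right clones", {
  clones <- tibble::tibble(
    clone_key = sprintf("k%02d", 1:15),
    unintended = c(rep(0L, 10), rep(1L, 5)),
    read_count = 1L
  )
  expect_equal(nrow(filter_clones(clones, 0)), 10)
  expect_equal(nrow(filter_clones(clones, 2)), 15)
  # strict subset of relaxed, for any max
  for (m in 0:3) {
    expect_true(all(filter_clones(clones, m)$clone_key %in%
                      filter_clones(clones, m + 1)$clone_key))
  }
})

test_that("deduplication merges reads by amino-acid clone key", {
  recs <- tibble::tibble(
    read_id = sprintf("r%d", 1:5),
    vl_aa = "QQQ", vh_aa = c("A", "A", "A", "B", "B"),
    assignments = replicate(5, c("A"), simplify = FALSE),
    unintended = 0L
  )
  dd <- dedupe_and_count(recs)
  expect_equal(nrow(dd), 2)
  expect_equal(dd$read_count, c(3, 2))

  # the two dominant clones of a 2963-read pool carry 81.2% of reads
  counts <- c(1823, 584, rep(3, 104), rep(2, 122))
  expect_equal(sum(counts), 2963)
  expect_equal(length(counts), 228)
  expect_equal(round(100 * top_share(counts, 2), 1), 81.2)
  # non-decreasing in k
  shares <- vapply(1:10, function(k) top_share(counts, k), numeric(1))
  expect_true(all(diff(shares) >= 0))
})

test_that("zero-error reads are identified with perfect recall and precision", {
  lib <- tiny_library(n_clones = 12, n_reactive = 4, seed = 21)
  planted <- setNames(c(7L, 5L, 4L, 3L, 2L, 1L), lib$clones$clone_id[1:6])
  reads <- simulate_reads(lib, planted, seed = 22)
  res <- identify_clones(reads, lib)
  expect_equal(nrow(res$clones), 6)
  expect_true(all(res$clones$unintended == 0))
  # map recovered keys back to planted clones via designed residues
  rec <- vapply(res$clones$assignments, paste, "", collapse = "")
  expect_setequal(rec, lib$clones$residues[1:6])
  got <- setNames(res$clones$read_count, rec)
  expect_equal(unname(got[lib$clones$residues[1:6]]), unname(planted))
})

test_that("planted defects are removed by the intended funnel stage", {
  lib <- tiny_library(n_clones = 6, n_reactive = 2, seed = 31,
                      frameshift_rate = 0.25, lowq_rate = 0.2)
  reads <- simulate_reads(lib, setNames(rep(30L, 3), lib$clones$clone_id[1:3]),
                          seed = 32)
  res <- identify_clones(reads, lib)
  rec <- res$records
  # ground-truth low-quality reads are exactly the low_quality-flagged ones
  truth <- reads[match(rec$read_id, reads$read_id), ]
  expect_identical(rec$low_quality, truth$low_quality)
  # an indel inside a variable chain must be caught by frameshift/length QC;
  # an indel confined to a flank or the linker is recoverable (the anchors
  # absorb it) and must not be, unless the anchor itself failed
  in_chain <- truth$frameshift & truth$fs_region %in% c("vl", "vh")
  flagged <- rec$frameshift | rec$defective_chain | rec$anchor_fail
  expect_true(all(flagged[in_chain]))
  expect_false(any(flagged[!truth$frameshift]))
  # funnel is internally consistent: exclusions plus kept reads = input
  cnt <- setNames(res$report$count, res$report$stage)
  expect_equal(cnt[["anchor_fail"]] + cnt[["low_quality"]] +
                 cnt[["frameshift_or_defective"]] + cnt[["internal_stop"]] +
                 cnt[["reads_kept"]], cnt[["input_reads"]])
  # stages never grow along the funnel
  expect_true(cnt[["unique_clones"]] <= cnt[["reads_kept"]])
  expect_true(cnt[["clones_strict"]] <= cnt[["unique_clones"]])
  expect_true(cnt[["clones_strict"]] <= cnt[["clones_relaxed"]])
})

test_that("outputs are invariant to read orientation", {
  lib_f <- tiny_library(n_clones = 6, n_reactive = 2, seed = 41, revcomp_frac = 0)
  lib_r <- tiny_library(n_clones = 6, n_reactive = 2, seed = 41, revcomp_frac = 1)
  counts <- setNames(c(4L, 3L, 2L), lib_f$clones$clone_id[1:3])
  fwd <- identify_clones(simulate_reads(lib_f, counts, seed = 42), lib_f)
  rev <- identify_clones(simulate_reads(lib_r, counts, seed = 42), lib_r)
  expect_equal(fwd$clones[c("clone_key", "read_count", "unintended")],
               rev$clones[c("clone_key", "read_count", "unintended")])
  expect_equal(fwd$report, rev$report)
})

test_that("FASTQ round trip preserves reads and qualities", {
  lib <- tiny_library()
  reads <- simulate_reads(lib, c(C001 = 3, C002 = 2), seed = 51)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)
  # identification works straight from the file
  res <- identify_clones(path, lib)
  expect_equal(sum(res$clones$read_count), 5)
})
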