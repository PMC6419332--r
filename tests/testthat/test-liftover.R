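# Point mapping and allele-aware SNV lifting.

test_that("point queries follow block offset arithmetic on both strands", {
  # plus-strand block src[0,100) -> tgt[50,150)
  cs <- parse_chain(c("chain 1000 srcA 200 + 0 100 tgtA 200 + 50 150 1",
                      "100", ""))
  idx <- build_chain_index(cs)
  r <- map_position(idx, "srcA", 10L)
  expect_equal(r$status, "converted")
  expect_equal(r$tgt_pos, 60L)
  expect_equal(r$strand, "+")
  # minus-strand block: strand-local tgt [0,100) of a 200 bp sequence;
  # pos 10 -> plus-strand coordinate 200 - 1 - 10 = 189
  cs2 <- parse_chain(c("chain 1000 srcA 100 + 0 100 tgtA 200 - 0 100 1",
                       "100", ""))
  r2 <- map_position(build_chain_index(cs2), "srcA", 10L)
  expect_equal(r2$status, "converted")
  expect_equal(r2$tgt_pos, 189L)
  expect_equal(r2$strand, "-")
})

test_that("gaps and uncovered sequence give distinct unmapped statuses", {
  cs <- parse_chain(c("chain 1000 srcA 200 + 0 100 tgtA 90 + 0 90 1",
                      "40 10 0", "50", ""))
  idx <- build_chain_index(cs)
  r <- map_position(idx, rep("srcA", 4L), c(39L, 45L, 150L, 5L))
  expect_equal(r$status, c("converted", "unmapped_in_gap",
                           "unmapped_no_chain", "converted"))
  # unknown sequence name is not an error, just no chain
  expect_equal(map_position(idx, "nope", 3L)$status, "unmapped_no_chain")
})

test_that("overlapping chains resolve by score; equal-score conflicts multimap", {
  overlapping <- c("chain 900 srcA 100 + 0 100 tgtA 100 + 0 100 1", "100", "",
                   "chain 500 srcA 100 + 20 60 tgtB 100 + 10 50 2", "40", "")
  idx <- build_chain_index(parse_chain(overlapping))
  r <- map_position(idx, "srcA", 30L)
  expect_equal(r$status, "converted")   # higher-score chain wins
  expect_equal(r$tgt_name, "tgtA")
  expect_equal(r$chain_id, 1L)
  tied <- c("chain 700 srcA 100 + 0 100 tgtA 100 + 0 100 1", "100", "",
            "chain 700 srcA 100 + 20 60 tgtB 100 + 10 50 2", "40", "")
  r2 <- map_position(build_chain_index(parse_chain(tied)), "srcA", 30L)
  expect_equal(r2$status, "rejected_multimap")
  # equal scores agreeing on the target are not a conflict
  dup <- c("chain 700 srcA 100 + 0 100 tgtA 100 + 0 100 1", "100", "",
           "chain 700 srcA 100 + 20 60 tgtA 100 + 20 60 2", "40", "")
  r3 <- map_position(build_chain_index(parse_chain(dup)), "srcA", 30L)
  expect_equal(r3$status, "converted")
})

test_that("exhaustive mapping equals the generator truth map base by base", {
  pair <- small_pair(seed = 19L)
  tmp <- withr::local_tempfile()
  write_chain(pair$chain_fwd, tmp)
  idx <- build_chain_index(parse_chain(tmp))
  L <- nchar(pair$source_seq)
  res <- map_position(idx, rep(pair$seq_name, L), 0:(L - 1L))
  expect_equal(res$status, truth_status(pair))
  conv <- which(!is.na(pair$src_map))
  expect_equal(res$tgt_pos[conv], pair$src_map[conv])
  expect_equal(res$strand[conv], pair$src_strand[conv])
})

test_that("mapping agrees with rtracklayer's liftOver on a written chain", {
  pair <- small_pair(seed = 77L)
  tmp <- withr::local_tempfile(fileext = ".chain")
  write_chain(pair$chain_fwd, tmp)
  ch <- rtracklayer::import.chain(tmp)
  L <- unname(nchar(pair$source_seq))
  lo <- rtracklayer::liftOver(
    GenomicRanges::GRanges(pair$seq_name, IRanges::IRanges(1:L, 1:L)), ch)
  n <- S4Vectors::elementNROWS(lo)
  res <- map_position(build_chain_index(parse_chain(tmp)),
                      rep(pair$seq_name, L), 0:(L - 1L))
  expect_identical(which(n == 1L), which(res$status == "converted"))
  hit <- unlist(lo[n == 1L])
  expect_identical(GenomicRanges::start(hit) - 1L,
                   res$tgt_pos[res$status == "converted"])
})

test_that("lifting complements alleles across inversions and checks the ref", {
  seqs <- c(tgtA = "AAAAATTTTT")
  # block src[0,5) -> tgt plus [0,5): target bases AAAAA
  cs <- parse_chain(c("chain 1000 srcA 10 + 0 5 tgtA 10 + 0 5 1", "5", ""))
  idx <- build_chain_index(cs)
  snv <- data.table::data.table(seq_name = "srcA", pos = 2L, ref = "A",
                                alt = "G", gt = "0/1", depth = 20L)
  out <- lift_snvs(idx, snv, seqs)
  expect_equal(out$status, "converted")
  expect_equal(out$lifted_ref, "A")
  expect_equal(out$lifted_alt, "G")
  expect_equal(out$gt, "0/1")
  # minus-strand block src[0,5) -> strand-local tgt [0,5); plus coords 5..9
  # are TTTTT, so an A ref complements to T and matches
  cs2 <- parse_chain(c("chain 1000 srcA 10 + 0 5 tgtA 10 - 0 5 1", "5", ""))
  out2 <- lift_snvs(build_chain_index(cs2), snv, seqs)
  expect_equal(out2$status, "converted")
  expect_equal(out2$lifted_ref, "T")
  expect_equal(out2$lifted_alt, "C")
  # a ref that disagrees with the target base is rejected by default...
  snv_bad <- data.table::data.table(seq_name = "srcA", pos = 2L, ref = "C",
                                    alt = "G", gt = "1/1", depth = 10L)
  out3 <- lift_snvs(idx, snv_bad, seqs)
  expect_equal(out3$status, "rejected_ref_mismatch")
  # ...but kept under on_ref_mismatch = "keep"
  out4 <- lift_snvs(idx, snv_bad, seqs, on_ref_mismatch = "keep")
  expect_equal(out4$status, "converted")
  # a mapped sequence missing from the accessor is a hard error
  expect_error(lift_snvs(idx, snv, c(other = "ACGT")), "missing")
})

test_that("lift_callset partitions its input and writes sorted output", {
  fx <- demo_fixture()
  out_vcf <- withr::local_tempfile(fileext = ".vcf")
  rej_vcf <- withr::local_tempfile(fileext = ".vcf")
  res <- lift_callset(fixture_path("source.vcf"), fixture_path("fwd.chain"),
                      fixture_path("target.fa"), out_vcf, rej_vcf)
  tl <- res$tally
  expect_equal(unname(tl["n_input"]),
               unname(tl["n_converted"] + tl["n_unmapped_no_chain"] +
                        tl["n_unmapped_in_gap"] +
                        tl["n_rejected_ref_mismatch"] +
                        tl["n_rejected_multimap"]))
  # the generator ledger predicts exactly which variants fail conversion
  led <- fx$bundle$ledger[assembly == "source"]
  expect_equal(unname(tl["n_converted"]),
               led[class != "unconvertible", .N])
  expect_false(is.unsorted(res$converted$pos))
  # every rejected record surfaces in the rejects file with its status
  rej_lines <- grep("^[^#]", readLines(rej_vcf), value = TRUE)
  expect_length(rej_lines, led[class == "unconvertible", .N])
  expect_true(all(grepl("LIFT_STATUS=unmapped", rej_lines)))
  # converted VCF re-reads with as many SNVs as were converted
  expect_equal(nrow(filter_snvs(out_vcf)$snvs), unname(tl["n_converted"]))
})

test_that("a chain in the wrong direction is detected as a hard error", {
  expect_error(
    lift_callset(fixture_path("source.vcf"), fixture_path("rev.chain"),
                 fixture_path("target.fa")),
    "direction mismatch")
})

test_that("forward-then-reverse lift restores coordinates and alleles", {
  fx <- demo_fixture()
  fwd <- lift_callset(fixture_path("source.vcf"), fixture_path("fwd.chain"),
                      fixture_path("target.fa"))
  idx_rev <- build_chain_index(parse_chain(fixture_path("rev.chain")))
  src_seqs <- refconcord:::read_genome(fixture_path("source.fa"))
  back <- lift_snvs(idx_rev, fwd$converted, src_seqs)
  expect_true(all(back$status == "converted"))
  expect_equal(back$tgt_pos, fwd$converted$src_pos)
  expect_equal(back$lifted_ref, fx$bundle$snvs_source[
    match(back$tgt_pos, pos), ref])
  # variants on inverted blocks complement twice, restoring the alleles
  inv <- which(fwd$converted$strand == "-")
  expect_gt(length(inv), 0L)
  expect_equal(back$lifted_ref[inv],
               fx$bundle$snvs_source[match(back$tgt_pos[inv], pos), ref])
  expect_equal(back$gt, fwd$converted$gt)
})
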