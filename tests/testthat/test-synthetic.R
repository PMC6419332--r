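# The fixture generator: edit scripts, truth maps, chain consistency,
# injected discordances, seeded determinism.

test_that("zero edits give an identical pair and one identity chain", {
  pair <- generate_assembly_pair(2000L, edits = edit_spec(seed = 3L))
  expect_equal(pair$source_seq, pair$target_seq)
  expect_length(pair$chain_fwd$chains, 1L)
  ch <- pair$chain_fwd$chains[[1]]
  expect_equal(nrow(ch$blocks), 1L)
  expect_equal(ch$blocks$size, 2000L)
  expect_equal(pair$src_map, 0:1999)
})

test_that("a single deletion produces two blocks gapped on the source side", {
  pair <- generate_assembly_pair(10000L, edits = edit_spec(
    n_deletions = 1L, deletion_length = c(100L, 100L), seed = 5L))
  ch <- pair$chain_fwd$chains[[1]]
  expect_equal(nrow(ch$blocks), 2L)
  expect_equal(ch$blocks$src_gap, c(100L, 0L))
  expect_equal(ch$blocks$tgt_gap, c(0L, 0L))
  expect_equal(unname(nchar(pair$target_seq)), 9900L)
  del <- which(is.na(pair$src_map))
  expect_length(del, 100L)
  expect_equal(del, seq(min(del), min(del) + 99L))
})

test_that("inversions are reverse-complemented and mapped on the minus strand", {
  pair <- generate_assembly_pair(5000L, edits = edit_spec(
    n_inversions = 1L, inversion_length = c(300L, 300L), seed = 9L))
  inv <- which(pair$src_strand == "-")
  expect_length(inv, 300L)
  src_seg <- unname(substring(pair$source_seq, min(inv), max(inv)))
  tgt_pos <- pair$src_map[inv]
  expect_equal(sort(tgt_pos), min(tgt_pos):max(tgt_pos))
  tgt_seg <- unname(substring(pair$target_seq, min(tgt_pos) + 1L,
                              max(tgt_pos) + 1L))
  expect_equal(tgt_seg, refconcord:::revcomp(src_seg))
})

test_that("written chains satisfy the parser's arithmetic invariants", {
  pair <- small_pair(seed = 23L)
  for (f in c("fwd", "rev")) {
    tmp <- withr::local_tempfile()
    write_chain(if (f == "fwd") pair$chain_fwd else pair$chain_rev, tmp)
    expect_no_error(parse_chain(tmp))
  }
})

test_that("infeasible edit specs fail before any output", {
  expect_error(generate_assembly_pair(1500L, edits = edit_spec(
    n_deletions = 5L, deletion_length = c(400L, 500L), seed = 1L)),
    "infeasible")
})

test_that("injection counts exceeding the convertible pool are an error", {
  pair <- generate_assembly_pair(2000L, edits = edit_spec(seed = 2L))
  expect_error(simulate_callsets(pair, 100L, n_unconvertible = 10L),
               "n_unconvertible")
  expect_error(simulate_callsets(pair, 10L,
                                 spec = discordance_spec(20L, 0L)),
               "exceed")
})

test_that("the ledger covers every written variant and closed forms hold", {
  fx <- demo_fixture()
  b <- fx$bundle
  src <- filter_snvs(fixture_path("source.vcf"))$snvs
  tgt <- filter_snvs(fixture_path("target_direct.vcf"))$snvs
  led <- b$ledger
  expect_equal(nrow(src), led[assembly == "source", .N])
  expect_equal(nrow(tgt),
               led[assembly == "source" &
                     class %in% c("concordant", "genotype_discordant"), .N] +
                 led[assembly == "target", .N])
  expect_setequal(src$pos, led[assembly == "source", pos])
  # closed-form conversion rate from the ledger
  n <- led[assembly == "source", .N]
  n_conv <- led[assembly == "source" & class != "unconvertible", .N]
  expect_equal(conversion_rate(n_conv, n), 100 * 1975 / 2000)
})

test_that("identical specs and seeds give byte-identical fixture trees", {
  build <- function(dir) {
    pair <- generate_assembly_pair(30000L, edits = edit_spec(
      n_deletions = 1L, n_insertions = 1L, n_inversions = 1L, seed = 17L))
    b <- simulate_callsets(pair, 500L,
                           spec = discordance_spec(10L, 5L, 2, seed = 4L),
                           n_unconvertible = 5L, n_target_private = 3L)
    write_fixture(b, dir)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- build(d1); m2 <- build(d2)
  expect_equal(m1, m2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("manifest records the generator seeds and parameters", {
  man <- yaml::read_yaml(fixture_path("manifest.yaml"))
  expect_equal(man$seed, 3L)
  expect_equal(man$edit_seed, 11L)
  expect_equal(man$n_pd, 40L)
  expect_true(file.exists(fixture_path(man$files$chain_fwd)))
})

test_that("depth shift lowers depths of unconvertible and discordant variants", {
  led <- demo_fixture()$bundle$ledger[assembly == "source"]
  m_bad <- led[class != "concordant", mean(depth)]
  m_ok <- led[class == "concordant", mean(depth)]
  expect_lt(m_bad, m_ok / 2)
})
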