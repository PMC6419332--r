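# HC/LC stratification, PR/GR ratios, depth histograms, base composition.

test_that("stratification partitions a roster by interval membership", {
  snvs <- data.table::data.table(seq_name = "chr1", pos = c(5L, 50L, 150L),
                                 ref = "A", alt = "G", gt = "0/1",
                                 depth = 10L)
  none <- stratify(snvs, confidence_regions())
  expect_equal(nrow(none$hc), 0L)
  expect_equal(nrow(none$lc), 3L)
  all_hc <- stratify(snvs, confidence_regions("chr1", 0L, 1000L))
  expect_equal(nrow(all_hc$hc), 3L)
  # half-open boundary: [0, 50) excludes pos 50
  part <- stratify(snvs, confidence_regions("chr1", 0L, 50L))
  expect_equal(part$hc$pos, 5L)
  expect_equal(part$lc$pos, c(50L, 150L))
  expect_equal(nrow(part$hc) + nrow(part$lc), nrow(snvs))
})

test_that("confidence regions round-trip through BED and normalize overlaps", {
  r <- confidence_regions(rep("chr1", 3), c(0L, 40L, 200L),
                          c(50L, 100L, 300L))
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_confidence_bed(r, tmp)
  r2 <- read_confidence_bed(tmp)
  # overlapping [0,50)+[40,100) merged to [0,100)
  expect_equal(GenomicRanges::start(r2$gr), c(1L, 201L))
  expect_equal(GenomicRanges::end(r2$gr), c(100L, 300L))
})

test_that("PR and GR follow the LC/HC enrichment formula", {
  r <- discordance_ratios(list(hc_all = 1000, lc_all = 100,
                               hc_pd = 1, lc_pd = 10,
                               hc_gd = 2, lc_gd = 1))
  expect_equal(r$pr, (10 / 100) / (1 / 1000))
  expect_equal(r$pr, 100)
  expect_equal(r$log2_pr, log2(100))
  expect_equal(r$gr, (1 / 100) / (2 / 1000))
  # equal enrichment gives a ratio of 1 (log2 = 0)
  r2 <- discordance_ratios(list(hc_all = 1000, lc_all = 100,
                                hc_pd = 10, lc_pd = 1,
                                hc_gd = 10, lc_gd = 1))
  expect_equal(r2$pr, 1); expect_equal(r2$log2_pr, 0)
  # zero denominators give the undefined sentinel, not an error
  r3 <- discordance_ratios(list(hc_all = 0, lc_all = 100, hc_pd = 1,
                                lc_pd = 1, hc_gd = 0, lc_gd = 0))
  expect_true(is.na(r3$pr)); expect_true(is.na(r3$log2_gr))
})

test_that("depth histograms tabulate depths with overflow and missing bins", {
  r <- list(a = data.table::data.table(depth = c(5L, 5L, 9L)),
            b = data.table::data.table(depth = integer(0)))
  h <- depth_histogram(r, max_depth = 10L)
  expect_equal(h[depth == "5", a], 2L)
  expect_equal(h[depth == "9", a], 1L)
  expect_equal(sum(h$a), 3L)
  expect_equal(sum(h$b), 0L)
  h2 <- depth_histogram(list(x = data.table::data.table(
    depth = c(0L, 99L, NA))), max_depth = 10L)
  expect_equal(h2[depth == "0", x], 1L)
  expect_equal(h2[depth == "overflow", x], 1L)
  expect_equal(h2[depth == "missing", x], 1L)
})

test_that("base composition sums to 100 and reports G+C", {
  r <- data.table::data.table(ref = c("A", "T", "G", "C"))
  cc <- base_composition(r)
  expect_equal(c(cc$pct_a, cc$pct_t, cc$pct_g, cc$pct_c), rep(25, 4))
  expect_equal(cc$pct_gc, 50)
  allg <- base_composition(data.table::data.table(ref = rep("G", 7)))
  expect_equal(allg$pct_g, 100); expect_equal(allg$pct_gc, 100)
  expect_equal(cc$pct_a + cc$pct_t + cc$pct_g + cc$pct_c, 100,
               tolerance = 1e-9)
  expect_error(base_composition(data.table::data.table(ref = character(0))),
               "empty")
})

test_that("characterize matches an independent recount from raw rosters", {
  rep <- run_comparison(fixture_path("source.vcf"),
                        fixture_path("target_direct.vcf"),
                        fixture_path("fwd.chain"), fixture_path("target.fa"))
  regions <- read_confidence_bed(fixture_path("hc_target.bed"))
  ch <- characterize(rep, regions)
  # brute-force membership via a plain per-base lookup vector
  bed <- data.table::fread(fixture_path("hc_target.bed"),
                           col.names = c("chr", "s", "e"))
  lim <- max(rep$converted$pos) + 1L
  hc_vec <- rep(FALSE, lim)
  for (i in seq_len(nrow(bed)))
    hc_vec[(bed$s[i] + 1L):min(bed$e[i], lim)] <- TRUE
  recount <- function(r) c(hc = sum(hc_vec[r$pos + 1L]),
                           lc = sum(!hc_vec[r$pos + 1L]))
  ca <- recount(rep$converted); cp <- recount(rep$pd_roster)
  cg <- recount(rep$gd_roster)
  expect_equal(ch$stratified_counts$hc_all, unname(ca["hc"]))
  expect_equal(ch$stratified_counts$lc_pd, unname(cp["lc"]))
  expect_equal(ch$stratified_counts$hc_gd, unname(cg["hc"]))
  pr_brute <- (cp["lc"] / ca["lc"]) / (cp["hc"] / ca["hc"])
  expect_equal(ch$ratios$pr, unname(pr_brute))
  # histogram columns sum to roster sizes
  expect_equal(sum(ch$depth_histogram$converted), nrow(rep$converted))
  expect_equal(sum(ch$depth_histogram$unconverted), nrow(rep$unconverted))
  # ledger HC membership agrees with stratify on the converted roster
  led <- demo_fixture()$bundle$ledger[assembly == "source" &
                                        class != "unconvertible"]
  s <- stratify(rep$converted, regions)
  expect_equal(nrow(s$hc), led[hc == TRUE, .N])
})

test_that("a characterization bundle round-trips through JSON", {
  rep <- run_comparison(fixture_path("source.vcf"),
                        fixture_path("target_direct.vcf"),
                        fixture_path("fwd.chain"), fixture_path("target.fa"))
  ch <- characterize(rep, read_confidence_bed(fixture_path("hc_target.bed")))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_characterization(ch, tmp)
  ch2 <- read_characterization(tmp)
  expect_equal(ch2$stratified_counts, ch$stratified_counts)
  expect_equal(ch2$ratios, ch$ratios)
  expect_equal(as.data.frame(ch2$depth_histogram),
               as.data.frame(ch$depth_histogram))
  expect_equal(ch2$composition_pd, ch$composition_pd)
  expect_equal(ch2$composition_gd, ch$composition_gd)
})

test_that("characterizing an identity comparison yields sentinels", {
  s <- data.table::data.table(seq_name = "chr1",
                              pos = c(10L, 40L), ref = c("A", "G"),
                              alt = c("G", "C"), gt = "0/1", depth = 30L)
  rep <- match_callsets(s, s)
  rep$converted <- s
  rep$unconverted <- s[0]
  ch <- characterize(rep, confidence_regions("chr1", 0L, 100L))
  expect_true(is.na(ch$ratios$pr))
  expect_null(ch$composition_pd)
  expect_null(ch$composition_gd)
  expect_equal(sum(ch$depth_histogram$converted), 2L)
})
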