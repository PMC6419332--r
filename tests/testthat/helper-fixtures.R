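# Shared fixture builders. Everything is generated in code under fixed
# seeds; larger fixtures are memoized so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# identity chain over one 100 bp sequence
identity_chain_text <- function(n = 100L) {
  c(sprintf("chain 1000 srcA %d + 0 %d tgtA %d + 0 %d 1", n, n, n, n),
    as.character(n), "")
}

# a small edited pair with every edit type
small_pair <- function(seed = 7L, len = 20000L) {
  generate_assembly_pair(len, edits = edit_spec(
    n_deletions = 2L, deletion_length = c(150L, 400L),
    n_insertions = 2L, insertion_length = c(150L, 400L),
    n_inversions = 1L, inversion_length = c(400L, 900L),
    seed = seed))
}

# mid-size bundle with all injection types, written to disk once
demo_fixture <- function() {
  memo("demo_fixture", {
    pair <- generate_assembly_pair(100000L, edits = edit_spec(
      n_deletions = 3L, n_insertions = 2L, n_inversions = 2L, seed = 11L))
    bundle <- simulate_callsets(
      pair, n_variants = 2000L,
      spec = discordance_spec(n_position_discordant = 40L,
                              n_genotype_discordant = 15L,
                              lc_enrichment = 4, seed = 3L),
      n_unconvertible = 25L, n_target_private = 10L)
    dir <- file.path(tempdir(), "refconcord-demo-fixture")
    write_fixture(bundle, dir)
    list(pair = pair, bundle = bundle, dir = dir)
  })
}

fixture_path <- function(f) file.path(demo_fixture()$dir, f)

# closed-form flagship fixture: 10 000 variants, 50 in deleted regions,
# 120 position- and 35 genotype-discordant injections
flagship_fixture <- function() {
  memo("flagship_fixture", {
    pair <- generate_assembly_pair(150000L, edits = edit_spec(
      n_deletions = 3L, deletion_length = c(500L, 800L),
      n_insertions = 2L, n_inversions = 2L, seed = 21L))
    bundle <- simulate_callsets(
      pair, n_variants = 10000L,
      spec = discordance_spec(n_position_discordant = 120L,
                              n_genotype_discordant = 35L,
                              lc_enrichment = 8, seed = 5L),
      n_unconvertible = 50L)
    dir <- file.path(tempdir(), "refconcord-flagship-fixture")
    write_fixture(bundle, dir)
    list(pair = pair, bundle = bundle, dir = dir)
  })
}

flagship_path <- function(f) file.path(flagship_fixture()$dir, f)

flagship_report <- function() {
  memo("flagship_report", run_comparison(
    flagship_path("source.vcf"), flagship_path("target_direct.vcf"),
    flagship_path("fwd.chain"), flagship_path("target.fa")))
}

# write VCF text lines (header + records given as body lines)
write_vcf_text <- function(body, path, contigs = c(chr1 = 10000L)) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S1", sep = "\t"))
  writeLines(c(hdr, body), path)
  path
}

vcf_rec <- function(chrom, pos1, ref, alt, gt, dp = 30L) {
  paste(chrom, pos1, ".", ref, alt, ".", "PASS", ".", "GT:DP",
        paste0(gt, ":", dp), sep = "\t")
}
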