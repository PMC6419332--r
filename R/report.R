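# Orchestration: one reproducible simulate/lift/compare/characterize run
# with machine-readable reports, plus summary tables over runs.

#' Write a match report as key/value and roster files
#'
#' Emits \code{<prefix>_report.tsv} (key/value pairs, full precision) and
#' \code{<prefix>_pd.tsv} / \code{<prefix>_gd.tsv} rosters with 1-based
#' positions for human consumption.
#'
#' @param report a \code{match_report}.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @export
write_match_report <- function(report, dir, prefix = "comparison") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keys <- c("n_source_total", "n_converted", "n_concordant",
            "n_position_discordant", "n_genotype_discordant",
            "conversion_rate_pct", "pdr_pct", "gdr_pct",
            "pd_to_gd_log2_ratio")
  vals <- vapply(keys, function(k)
    format(report[[k]] %||% NA, digits = 17), character(1))
  kv <- data.table::data.table(statistic = keys, value = vals)
  data.table::fwrite(kv, file.path(dir, paste0(prefix, "_report.tsv")),
                     sep = "\t")
  roster_out <- function(r, f) {
    r <- data.table::as.data.table(r)
    if (nrow(r)) r <- r[, .(seq_name, pos = pos + 1L, ref, alt, gt, depth)]
    data.table::fwrite(r, file.path(dir, f), sep = "\t")
  }
  roster_out(report$pd_roster, paste0(prefix, "_pd.tsv"))
  roster_out(report$gd_roster, paste0(prefix, "_gd.tsv"))
  invisible(dir)
}

#' Run the full cross-assembly comparison pipeline
#'
#' Runs both conversion directions over a fixture tree (or explicit file
#' paths), characterizes each direction against its HC regions, and writes
#' per-direction reports, characterization bundles, a combined summary table
#' and a parameter-echo log. The run directory is atomic: partial outputs
#' are removed on failure.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \code{fixture_dir} (a \code{\link{write_fixture}} tree; or the explicit
#'   path entries it stands for), \code{out_dir}, and optional
#'   \code{label_source}/\code{label_target} direction labels,
#'   \code{on_ref_mismatch}, \code{alt_mismatch_class}, \code{max_depth},
#'   \code{seed} (echoed to the log; the pipeline itself is deterministic).
#' @return named list of per-direction results (\code{report},
#'   \code{characterization}), invisibly; files under \code{out_dir}.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config$fixture_dir)) {
    fd <- config$fixture_dir
    man <- yaml::read_yaml(file.path(fd, "manifest.yaml"))$files
    paths <- lapply(man, function(f) file.path(fd, f))
  } else {
    paths <- config[c("source_fasta", "target_fasta", "chain_fwd",
                      "chain_rev", "vcf_source", "vcf_target_direct",
                      "hc_bed_source", "hc_bed_target")]
  }
  need <- c("source_fasta", "target_fasta", "chain_fwd", "vcf_source",
            "vcf_target_direct")
  missing <- need[!vapply(need, function(k)
    !is.null(paths[[k]]) && file.exists(paths[[k]]), logical(1))]
  if (length(missing))
    stop("unresolvable input path(s): ", paste(missing, collapse = ", "))
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  lab_s <- config$label_source %||% "source"
  lab_t <- config$label_target %||% "target"
  orm <- config$on_ref_mismatch %||% "reject"
  amc <- config$alt_mismatch_class %||% "genotype"
  max_depth <- config$max_depth %||% 60L

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE), add = TRUE)

  log_lines <- c(paste0("refconcord ", as.character(
                   utils::packageVersion("refconcord"))),
                 paste0("seed: ", config$seed %||% "none (deterministic)"),
                 paste0("on_ref_mismatch: ", orm),
                 paste0("alt_mismatch_class: ", amc),
                 paste0("inputs: ", paste(unlist(paths), collapse = " ")))

  one_direction <- function(src_vcf, dir_vcf, chain, fasta, hc_bed, tag) {
    rep <- run_comparison(src_vcf, dir_vcf, chain, fasta,
                          on_ref_mismatch = orm, alt_mismatch_class = amc)
    regions <- if (!is.null(hc_bed) && file.exists(hc_bed))
      read_confidence_bed(hc_bed) else confidence_regions()
    ch <- characterize(rep, regions, max_depth = max_depth)
    write_match_report(rep, out_dir, tag)
    write_characterization(ch, file.path(out_dir,
                                         paste0(tag, "_characterization.json")))
    list(report = rep, characterization = ch)
  }

  results <- list()
  tag_fwd <- paste0(lab_s, "_to_", lab_t)
  results[[tag_fwd]] <- one_direction(
    paths$vcf_source, paths$vcf_target_direct, paths$chain_fwd,
    paths$target_fasta, paths$hc_bed_target, tag_fwd)
  if (!is.null(paths$chain_rev) && file.exists(paths$chain_rev)) {
    tag_rev <- paste0(lab_t, "_to_", lab_s)
    results[[tag_rev]] <- one_direction(
      paths$vcf_target_direct, paths$vcf_source, paths$chain_rev,
      paths$source_fasta, paths$hc_bed_source, tag_rev)
  }

  summary <- render_summary(results)
  data.table::fwrite(summary, file.path(out_dir, "summary.tsv"), sep = "\t")
  writeLines(c(log_lines, paste0("directions: ",
                                 paste(names(results), collapse = ", "))),
             file.path(out_dir, "run.log"))
  ok <- TRUE
  invisible(results)
}

#' Summary table over one or more pipeline runs
#'
#' One row per (direction, run) with the headline statistics; when several
#' runs share a direction, aggregate mean and sd rows are appended.
#'
#' @param results named list of per-direction results as returned by
#'   \code{\link{run_all}} (or a list of such lists for multiple runs).
#' @return a data.table.
#' @export
render_summary <- function(results) {
  if (length(results) == 0L) stop("render_summary needs at least one result")
  # accept either one run (named by direction) or a list of runs
  if (!is.null(results[[1]]$report)) results <- list(run1 = results)
  rows <- list()
  for (run in names(results)) {
    for (dir in names(results[[run]])) {
      rep <- results[[run]][[dir]]$report
      ch <- results[[run]][[dir]]$characterization
      rows[[length(rows) + 1L]] <- data.table::data.table(
        direction = dir, run = run,
        n_source = rep$n_source_total %||% NA_integer_,
        n_converted = rep$n_converted,
        conversion_rate_pct = rep$conversion_rate_pct %||% NA_real_,
        pdr_pct = rep$pdr_pct, gdr_pct = rep$gdr_pct,
        log2_pd_gd = rep$pd_to_gd_log2_ratio,
        log2_pr = ch$ratios$log2_pr, log2_gr = ch$ratios$log2_gr,
        gc_pd_pct = if (is.null(ch$composition_pd)) NA_real_
                    else ch$composition_pd$pct_gc,
        gc_gd_pct = if (is.null(ch$composition_gd)) NA_real_
                    else ch$composition_gd$pct_gc)
    }
  }
  tab <- data.table::rbindlist(rows)
  numcols <- setdiff(names(tab), c("direction", "run"))
  agg <- tab[, .N, by = direction][N > 1L, direction]
  if (length(agg)) {
    means <- tab[direction %in% agg,
                 lapply(.SD, function(x) mean(x, na.rm = TRUE)),
                 by = direction, .SDcols = numcols][, run := "mean"]
    sds <- tab[direction %in% agg,
               lapply(.SD, function(x) stats::sd(x, na.rm = TRUE)),
               by = direction, .SDcols = numcols][, run := "sd"]
    tab <- rbind(tab, means, sds, use.names = TRUE, fill = TRUE)
  }
  tab
}

#' Aggregate base compositions over runs
#'
#' Mean and standard deviation of each composition percentage across a list
#' of \code{base_composition} results, the aggregation style used for
#' multi-run composition tables.
#'
#' @param comps list of \code{\link{base_composition}} results.
#' @return data.table with one row per base (and G+C combined).
#' @export
aggregate_composition <- function(comps) {
  if (!length(comps)) stop("no compositions to aggregate")
  keys <- c("pct_a", "pct_t", "pct_g", "pct_c", "pct_gc")
  m <- sapply(comps, function(cc) unlist(cc[keys]))
  data.table::data.table(base = c("A", "T", "G", "C", "G+C"),
                         mean = rowMeans(m),
                         sd = apply(m, 1L, stats::sd))
}
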